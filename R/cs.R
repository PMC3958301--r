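# Digital compressive sensing of EEG epochs: sparse random binary measurement
# matrices (d ones per column, stored as a flash-style index table),
# addition-only compression, and server-side reconstruction via a
# block-sparse Bayesian learning (BSBL) solver or an l1 solver in a
# discrete-cosine dictionary.

#' Sparse random binary measurement matrix
#'
#' Each of the `N` columns has exactly `d` ones at row positions drawn
#' uniformly without replacement; only the `d` row indices per column are
#' stored (mirroring a flash-resident index table on the sensor node).
#'
#' @param M number of measurements (rows), `d <= M < N`.
#' @param N epoch length (columns).
#' @param d ones per column (default 4).
#' @param seed RNG seed; the matrix is a deterministic function of
#'   `(M, N, d, seed)`.
#' @return object of class `cs_matrix` with fields `M`, `N`, `d`, `seed`,
#'   and `idx` (`d x N` integer matrix of row indices).
#' @export
cs_matrix <- function(M, N, d = 4, seed = 1) {
  M <- as.integer(M); N <- as.integer(N); d <- as.integer(d)
  if (d < 1 || d > M) stop("require 1 <= d <= M (got d = ", d, ", M = ", M, ")")
  if (M >= N) stop("require M < N for compression (got M = ", M, ", N = ", N, ")")
  set.seed(substream_seed(seed, "cs_matrix", M, N, d))
  idx <- vapply(seq_len(N), function(j) sample.int(M, d), integer(d))
  idx <- matrix(idx, nrow = d)
  structure(list(M = M, N = N, d = d, seed = as.integer(seed), idx = idx),
            class = "cs_matrix")
}

#' @export
print.cs_matrix <- function(x, ...) {
  cat(sprintf("<cs_matrix %d x %d, d = %d ones/column, CR %s>\n",
              x$M, x$N, x$d, format_cr(x$M, x$N)))
  invisible(x)
}

#' Dense 0/1 form of a measurement matrix
#'
#' @param phi a [cs_matrix()].
#' @return `M x N` numeric matrix.
#' @export
as_dense <- function(phi) {
  stopifnot(inherits(phi, "cs_matrix"))
  out <- matrix(0, phi$M, phi$N)
  for (j in seq_len(phi$N)) out[phi$idx[, j], j] <- 1
  out
}

#' Compress an epoch with a sparse binary matrix
#'
#' Computes `y = Phi x` using accumulator additions only (no
#' multiplications): each sample is added into the `d` measurement
#' accumulators indexed by its column of the index table. Integer input
#' yields integer output. `x` may be a length-`N` vector or an `N x K`
#' matrix of epochs compressed column-wise.
#'
#' @param x length-`N` numeric vector or `N x K` matrix.
#' @param phi a [cs_matrix()].
#' @return length-`M` vector (or `M x K` matrix) of measurements.
#' @export
cs_compress <- function(x, phi) {
  stopifnot(inherits(phi, "cs_matrix"))
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) != phi$N) {
    stop("input length ", nrow(X), " does not match matrix columns ", phi$N)
  }
  Y <- matrix(0, phi$M, ncol(X))
  for (k in seq_len(phi$d)) {
    g <- phi$idx[k, ]
    s <- rowsum(X, group = g)               # grouped sums: additions only
    rows <- as.integer(rownames(s))
    Y[rows, ] <- Y[rows, , drop = FALSE] + s
  }
  if (vec) drop(Y) else Y
}

#' Compression ratio
#'
#' @param M measurements per epoch.
#' @param N samples per epoch.
#' @return the ratio `N/M` (compression achieved when > 1).
#' @export
compression_ratio <- function(M, N) {
  if (M <= 0 || N <= 0) stop("M and N must be positive")
  N / M
}

#' Render a compression ratio as "N:M" in lowest terms
#' @param M measurements per epoch.
#' @param N samples per epoch.
#' @return character, e.g. `"2:1"`.
#' @export
format_cr <- function(M, N) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  k <- g(N, M)
  sprintf("%d:%d", N %/% k, M %/% k)
}

#' Measurement count for a target compression ratio
#' @param N epoch length.
#' @param cr target ratio `N:M` expressed as the number `N/M`.
#' @return integer `M = round(N / cr)`.
#' @export
cr_to_m <- function(N, cr) {
  stopifnot(cr >= 1)
  as.integer(round(N / cr))
}

#' Reconstruction parameters
#'
#' @param solver `"bsbl"` (block-sparse Bayesian learning, EM updates over
#'   equal-size blocks with a first-order autoregressive intra-block
#'   correlation model) or `"fista_dct"` (l1 minimization in an orthonormal
#'   DCT dictionary via FISTA; fast and batched, the pipeline default).
#' @param block_size block length for BSBL (default 32; for N = 512 this is
#'   16 blocks, last block short if `block_size` does not divide `N`).
#' @param max_iter iteration cap.
#' @param tol relative convergence tolerance (> 0).
#' @param lambda noise-floor / regularization weight. For BSBL this is the
#'   noise variance (default `1e-8` times the measurement energy); for FISTA
#'   the l1 weight as a fraction of `max |A' y|` (default 0.02).
#' @param rho intra-block AR(1) correlation for BSBL (default 0.9).
#' @param dict sparsifying dictionary for BSBL: `"identity"` (signal itself
#'   block-sparse) or `"dct"`.
#' @return object of class `cs_params`.
#' @export
cs_params <- function(solver = c("fista_dct", "bsbl"), block_size = 32,
                      max_iter = NULL, tol = 1e-4, lambda = NULL,
                      rho = 0.9, dict = c("identity", "dct")) {
  solver <- match.arg(solver)
  dict <- match.arg(dict)
  stopifnot(tol > 0, block_size >= 1)
  if (is.null(max_iter)) max_iter <- if (solver == "bsbl") 80L else 120L
  structure(list(solver = solver, block_size = as.integer(block_size),
                 max_iter = as.integer(max_iter), tol = tol, lambda = lambda,
                 rho = rho, dict = dict),
            class = "cs_params")
}

# orthonormal DCT-II synthesis matrix, cached per N
.dct_cache <- new.env(parent = emptyenv())
dct_basis <- function(N) {
  key <- as.character(N)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  t_ <- seq_len(N) - 0.5
  C <- sqrt(2 / N) * cos(outer(seq_len(N) - 1, t_) * pi / N)
  C[1, ] <- sqrt(1 / N)
  Psi <- t(C)                                # columns are basis vectors
  .dct_cache[[key]] <- Psi
  Psi
}

bsbl_em <- function(y, A, params) {
  M <- nrow(A); N <- ncol(A)
  b <- min(params$block_size, N)
  starts <- seq(1, N, by = b)
  blocks <- lapply(starts, function(s) s:min(s + b - 1, N))
  g <- length(blocks)
  B <- lapply(blocks, function(ix) {
    bb <- length(ix)
    params$rho^abs(outer(seq_len(bb), seq_len(bb), "-"))
  })
  Binv <- lapply(B, solve)
  Ai <- lapply(blocks, function(ix) A[, ix, drop = FALSE])
  ABAt <- mapply(function(a, bm) a %*% bm %*% t(a), Ai, B, SIMPLIFY = FALSE)
  AB <- mapply(function(a, bm) a %*% bm, Ai, B, SIMPLIFY = FALSE)

  lambda <- params$lambda
  if (is.null(lambda)) lambda <- 1e-8 * mean(y^2) * M + 1e-12
  gamma <- rep(1, g)
  it <- 0L; converged <- FALSE
  mu <- NULL
  while (it < params$max_iter) {
    it <- it + 1L
    active <- which(gamma > max(gamma) * 1e-8)
    G <- diag(lambda, M)
    for (i in active) G <- G + gamma[i] * ABAt[[i]]
    Ginv <- tryCatch(solve(G), error = function(e) solve(G + diag(1e-10, M)))
    v <- Ginv %*% y
    mu_blocks <- vector("list", g)
    gamma_new <- numeric(g)
    for (i in seq_len(g)) {
      if (!(i %in% active)) { mu_blocks[[i]] <- rep(0, length(blocks[[i]])); next }
      bb <- length(blocks[[i]])
      mu_i <- gamma[i] * t(AB[[i]]) %*% v
      mu_blocks[[i]] <- drop(mu_i)
      tr <- sum(Ginv * ABAt[[i]])
      quad <- drop(t(mu_i) %*% Binv[[i]] %*% mu_i)
      gamma_new[i] <- max(0, gamma[i] - gamma[i]^2 * tr / bb + quad / bb)
    }
    delta <- max(abs(gamma_new - gamma)) / max(max(gamma_new), 1e-12)
    gamma <- gamma_new
    mu <- unlist(mu_blocks)
    if (delta < params$tol) { converged <- TRUE; break }
  }
  list(xhat = mu, iterations = it, converged = converged)
}

fista_l1 <- function(Y, A, params) {
  # batched FISTA for min 0.5||y - As||^2 + lambda||s||_1, per column of Y
  M <- nrow(A); N <- ncol(A)
  At <- t(A)
  # Lipschitz constant by power iteration on A'A
  v <- rep(1 / sqrt(N), N)
  for (i in 1:40) { v <- At %*% (A %*% v); v <- v / sqrt(sum(v^2)) }
  L <- sqrt(sum((At %*% (A %*% v))^2)) * 1.01
  alpha <- if (is.null(params$lambda)) 0.02 else params$lambda
  AtY <- At %*% Y
  lam <- alpha * apply(abs(AtY), 2, max)     # per-column l1 weight
  lamL <- rep(lam / L, each = N)
  S <- matrix(0, N, ncol(Y)); Z <- S; tk <- 1
  it <- 0L; converged <- FALSE
  while (it < params$max_iter) {
    it <- it + 1L
    grad <- At %*% (A %*% Z - Y)
    U <- Z - grad / L
    S_new <- sign(U) * pmax(abs(U) - lamL, 0)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- S_new + ((tk - 1) / t_new) * (S_new - S)
    step <- sqrt(sum((S_new - S)^2)) / max(sqrt(sum(S_new^2)), 1e-12)
    S <- S_new; tk <- t_new
    if (step < params$tol) { converged <- TRUE; break }
  }
  list(shat = S, iterations = it, converged = converged)
}

#' Reconstruct epochs from compressive measurements
#'
#' Server-side inverse of [cs_compress()]. With a square invertible dense
#' matrix (`M = N`, no compression) the linear system is solved exactly.
#' Otherwise the solver named in `params` is used; non-convergence within the
#' iteration cap is flagged in the result, not raised as an error.
#'
#' @param y length-`M` measurement vector or `M x K` matrix (one epoch per
#'   column).
#' @param phi a [cs_matrix()] or a dense `M x N` matrix.
#' @param params a [cs_params()].
#' @return object of class `cs_reconstruction`: `xhat` (length-`N` vector or
#'   `N x K` matrix), `iterations`, `residual` (relative residual norm),
#'   `converged`.
#' @export
cs_reconstruct <- function(y, phi, params = cs_params()) {
  A <- if (inherits(phi, "cs_matrix")) as_dense(phi) else as.matrix(phi)
  M <- nrow(A); N <- ncol(A)
  vec <- !is.matrix(y)
  Y <- if (vec) matrix(y, ncol = 1) else y
  stopifnot(nrow(Y) == M)

  if (M == N) {
    X <- solve(A, Y)
    res <- structure(list(xhat = if (vec) drop(X) else X, iterations = 0L,
                          residual = 0, converged = TRUE),
                     class = "cs_reconstruction")
    return(res)
  }

  if (params$solver == "bsbl") {
    Aeff <- if (params$dict == "dct") A %*% dct_basis(N) else A
    cols <- lapply(seq_len(ncol(Y)), function(k) bsbl_em(Y[, k], Aeff, params))
    Shat <- vapply(cols, `[[`, numeric(N), "xhat")
    X <- if (params$dict == "dct") dct_basis(N) %*% Shat else Shat
    iters <- max(vapply(cols, `[[`, integer(1), "iterations"))
    conv <- all(vapply(cols, `[[`, logical(1), "converged"))
  } else {
    Psi <- dct_basis(N)
    Aeff <- A %*% Psi
    fit <- fista_l1(Y, Aeff, params)
    X <- Psi %*% fit$shat
    iters <- fit$iterations
    conv <- fit$converged
  }
  resid <- sqrt(sum((A %*% X - Y)^2)) / max(sqrt(sum(Y^2)), 1e-12)
  structure(list(xhat = if (vec) drop(X) else X, iterations = iters,
                 residual = resid, converged = conv),
            class = "cs_reconstruction")
}

#' @export
print.cs_reconstruction <- function(x, ...) {
  dim_txt <- if (is.matrix(x$xhat)) paste(dim(x$xhat), collapse = " x ")
             else length(x$xhat)
  cat(sprintf("<cs_reconstruction: %s samples, %d iteration(s), residual %.3g%s>\n",
              dim_txt, x$iterations, x$residual,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Write a measurement-matrix index table to CSV
#'
#' Column-major flat table: one row per matrix column with its `d` row
#' indices, mirroring the flash-resident layout on the sensor.
#'
#' @param phi a [cs_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cs_matrix <- function(phi, path) {
  stopifnot(inherits(phi, "cs_matrix"))
  df <- data.frame(column = seq_len(phi$N), t(phi$idx))
  names(df)[-1] <- paste0("row", seq_len(phi$d))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement-matrix index table from CSV
#'
#' @param path CSV written by [write_cs_matrix()].
#' @param M number of rows of the matrix.
#' @param seed seed to record on the object (metadata only).
#' @return a [cs_matrix()].
#' @export
read_cs_matrix <- function(path, M, seed = NA_integer_) {
  df <- utils::read.csv(path)
  idx <- t(as.matrix(df[, -1, drop = FALSE]))
  out <- structure(list(M = as.integer(M), N = ncol(idx), d = nrow(idx),
                        seed = seed, idx = matrix(as.integer(idx), nrow = nrow(idx))),
                   class = "cs_matrix")
  if (any(out$idx < 1 | out$idx > M)) stop("index table inconsistent with M = ", M)
  out
}
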