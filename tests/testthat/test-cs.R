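test_that("measurement matrices have exactly d ones per column and are seeded", {
  phi <- cs_matrix(128, 512, d = 4, seed = 2)
  D <- as_dense(phi)
  expect_true(all(colSums(D) == 4))
  expect_equal(sum(D), 4 * 512)
  expect_identical(cs_matrix(128, 512, 4, seed = 2)$idx, phi$idx)
  expect_false(identical(cs_matrix(128, 512, 4, seed = 3)$idx, phi$idx))
  expect_error(cs_matrix(3, 512, d = 4), "d <= M")
  expect_error(cs_matrix(512, 512, d = 4), "M < N")
})

test_that("compression is the sparse matrix-vector product, additions only", {
  phi <- cs_matrix(40, 120, 4, seed = 5)
  D <- as_dense(phi)
  # basis vector lights up exactly the column's row indices
  e7 <- numeric(120); e7[7] <- 1
  y <- cs_compress(e7, phi)
  expect_equal(which(y == 1), sort(phi$idx[, 7]))
  expect_equal(sum(y), 4)
  # all-ones vector sums to d*N
  expect_equal(sum(cs_compress(rep(1, 120), phi)), 4 * 120)
  # linearity and integer closure
  set.seed(6)
  x1 <- sample(-500:500, 120, replace = TRUE)
  x2 <- sample(-500:500, 120, replace = TRUE)
  expect_equal(cs_compress(x1 + x2, phi), cs_compress(x1, phi) + cs_compress(x2, phi))
  expect_true(all(cs_compress(x1, phi) == round(cs_compress(x1, phi))))
  expect_error(cs_compress(rep(1, 100), phi), "does not match")
})

test_that("compression agrees with the dense mat-vec oracle on random instances", {
  set.seed(9)
  for (i in 1:100) {
    M <- sample(10:40, 1); N <- M + sample(5:80, 1); d <- sample(1:min(4, M), 1)
    phi <- cs_matrix(M, N, d, seed = i)
    x <- rnorm(N, sd = 100)
    expect_equal(cs_compress(x, phi), drop(as_dense(phi) %*% x),
                 tolerance = 1e-10)
  }
})

test_that("compression ratios compute and render in lowest terms", {
  expect_equal(compression_ratio(512, 512), 1)
  expect_equal(format_cr(512, 512), "1:1")
  expect_equal(format_cr(256, 512), "2:1")
  expect_equal(compression_ratio(26, 512), 512 / 26, tolerance = 1e-12)
  expect_equal(format_cr(26, 512), "256:13")
  expect_equal(cr_to_m(512, 4), 128L)
  expect_error(compression_ratio(0, 512), "positive")
})

test_that("an invertible square system is reconstructed exactly", {
  set.seed(4)
  x <- rnorm(64)
  A <- diag(64)
  fit <- cs_reconstruct(drop(A %*% x), A)
  expect_equal(fit$xhat, x, tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("BSBL recovers a block-sparse signal at CR 2:1 near the oracle benchmark", {
  set.seed(11)
  x <- numeric(512)
  sup <- c(65:96, 321:352)                      # 2 active blocks of 32
  x[sup] <- rnorm(64, sd = 5)
  phi <- cs_matrix(256, 512, 4, seed = 12)
  y <- cs_compress(x, phi)
  fit <- cs_reconstruct(y, phi, cs_params(solver = "bsbl"))
  nmse <- sum((x - fit$xhat)^2) / sum(x^2)
  expect_lte(nmse, 0.05)
  # oracle least squares on the known support: the benchmark solution
  A <- as_dense(phi)[, sup]
  xo <- numeric(512)
  xo[sup] <- qr.solve(A, y)
  nmse_oracle <- sum((x - xo)^2) / sum(x^2)
  expect_lte(nmse_oracle, 1e-12)
  expect_lte(nmse, nmse_oracle + 0.05)
  # determinism
  fit2 <- cs_reconstruct(y, phi, cs_params(solver = "bsbl"))
  expect_identical(fit$xhat, fit2$xhat)
})

test_that("non-convergence is flagged, not raised", {
  set.seed(13)
  phi <- cs_matrix(64, 256, 4, seed = 1)
  y <- cs_compress(rnorm(256, sd = 50), phi)
  fit <- cs_reconstruct(y, phi, cs_params(solver = "fista_dct", max_iter = 2))
  expect_false(fit$converged)
  expect_equal(fit$iterations, 2)
  expect_true(is.finite(fit$residual))
})

test_that("matrix index tables survive a CSV round trip", {
  phi <- cs_matrix(50, 200, 4, seed = 8)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cs_matrix(phi, p)
  back <- read_cs_matrix(p, M = 50)
  expect_identical(back$idx, phi$idx)
  expect_equal(back$d, 4)
})
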