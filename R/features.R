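# Epoch segmentation/labeling and the three time-domain feature extractors:
# energy, line length, and nonlinear autocorrelation (NLACC).

#' Segment a record into labeled epochs
#'
#' Partitions the record into consecutive non-overlapping epochs of `N`
#' samples starting at sample 0 (half-open sample ranges `[kN, (k+1)N)`;
#' any trailing partial epoch is dropped). Each epoch is labeled `SEIZURE`
#' if its span lies entirely within one seizure event, `NONSEIZURE` if it is
#' entirely outside all events, and `MIXED` otherwise. MIXED epochs are kept
#' in the output but are excluded from training and from all detection
#' metrics. Event boundaries are converted to samples conservatively
#' (onset floored, offset ceiled).
#'
#' @param record an [eeg_record()].
#' @param N epoch length in samples (default 512, i.e. 4 s at 128 Hz).
#' @return data.frame with columns `epoch` (1-based index), `start_sample`
#'   (0-based), `start_s`, `end_s`, and `label`
#'   (factor: NONSEIZURE/SEIZURE/MIXED).
#' @export
segment_and_label <- function(record, N = 512) {
  stopifnot(inherits(record, "eeg_record"), N >= 2)
  N <- as.integer(N)
  n <- ncol(record$data)
  n_epochs <- n %/% N
  if (n_epochs == 0) {
    warning("record shorter than one epoch (N = ", N, "); returning no epochs")
    return(data.frame(epoch = integer(0), start_sample = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      label = factor(character(0),
                                     levels = c("NONSEIZURE", "SEIZURE", "MIXED"))))
  }
  start <- (seq_len(n_epochs) - 1L) * N      # 0-based, inclusive
  end <- start + N                           # 0-based, exclusive
  label <- rep("NONSEIZURE", n_epochs)
  for (ev in record$events) {
    on <- floor(ev$onset_s * record$fs)
    off <- ceiling(ev$offset_s * record$fs)
    inside <- start >= on & end <= off
    overlap <- start < off & end > on
    label[overlap & !inside] <- "MIXED"
    label[inside] <- "SEIZURE"
  }
  data.frame(epoch = seq_len(n_epochs), start_sample = start,
             start_s = start / record$fs, end_s = end / record$fs,
             label = factor(label, levels = c("NONSEIZURE", "SEIZURE", "MIXED")))
}

#' Extract one epoch's samples
#'
#' @param record an [eeg_record()].
#' @param N epoch length in samples.
#' @param k 1-based epoch index.
#' @return `n_channels x N` matrix.
#' @export
get_epoch <- function(record, N, k) {
  stopifnot(k >= 1, k * N <= ncol(record$data))
  record$data[, ((k - 1) * N + 1):(k * N), drop = FALSE]
}

#' Epoch energy
#'
#' Mean squared amplitude over the epoch: `E = (1/N) * sum(x_i^2)`.
#'
#' @param x numeric vector of epoch samples (length >= 1).
#' @return non-negative scalar.
#' @export
#' @examples
#' energy(c(1, 2, 3, 4))  # 7.5
energy <- function(x) {
  if (length(x) < 1) stop("energy requires at least one sample")
  sum(x^2) / length(x)
}

#' Epoch line length
#'
#' Mean absolute first difference:
#' `LL = (1/(N-1)) * sum(|x_{i+1} - x_i|)`. Sensitive to both amplitude and
#' frequency increases; invariant to additive constants.
#'
#' @param x numeric vector of epoch samples (length >= 2).
#' @return non-negative scalar.
#' @export
#' @examples
#' line_length(c(1, 3, 2))  # 1.5
line_length <- function(x) {
  if (length(x) < 2) stop("line_length requires at least two samples")
  sum(abs(diff(x))) / (length(x) - 1)
}

#' Epoch nonlinear autocorrelation (NLACC)
#'
#' Targets repetitive spikes with similar maxima and minima over successive
#' short intervals. The epoch is split into `N_S = floor(N/w)` non-overlapping
#' sub-windows of `w` samples (trailing remainder discarded). With
#' `max(S_i)`/`min(S_i)` the per-sub-window extremes,
#' `HV_i = min(max(S_i), max(max(S_{i+1}), max(S_{i+2})))` and
#' `LV_i = max(min(S_i), min(min(S_{i+1}), min(S_{i+2})))` are a conservative
#' high/low value per sub-window, defined for `i = 1..N_S-2`; NLACC is the
#' sum of `HV_i - LV_i` over those defined terms.
#'
#' @param x numeric vector of epoch samples (length >= `3*w`).
#' @param w sub-window width in samples (default 15, i.e. about 0.12 s at
#'   128 Hz).
#' @return scalar (can be negative for drifting signals).
#' @export
#' @examples
#' nlacc(seq_len(45), w = 15)  # -1
nlacc <- function(x, w = 15) {
  N <- length(x)
  w <- as.integer(w)
  if (N < 3 * w) {
    stop("nlacc requires at least 3*w = ", 3 * w, " samples (got ", N, ")")
  }
  ns <- N %/% w
  m <- matrix(x[seq_len(ns * w)], nrow = w)
  mx <- apply(m, 2, max)
  mn <- apply(m, 2, min)
  i <- seq_len(ns - 2)
  hv <- pmin(mx[i], pmax(mx[i + 1], mx[i + 2]))
  lv <- pmax(mn[i], pmin(mn[i + 1], mn[i + 2]))
  sum(hv - lv)
}

feature_funs <- list(energy = energy, line_length = line_length,
                     nlacc = nlacc)

#' Channel-wise feature vector of one epoch
#'
#' Applies the named extractor to each channel individually; the output
#' order is the channel order of the epoch (for a 23-channel montage, a
#' 23-element feature vector).
#'
#' @param epoch `n_channels x N` numeric matrix (see [get_epoch()]).
#' @param feature one of `"energy"`, `"line_length"`, `"nlacc"`.
#' @param w sub-window width for `nlacc`.
#' @return numeric vector of length `n_channels`.
#' @export
extract_features <- function(epoch, feature = c("energy", "line_length", "nlacc"),
                             w = 15) {
  feature <- match.arg(feature)
  stopifnot(is.matrix(epoch))
  if (feature == "nlacc") {
    apply(epoch, 1, nlacc, w = w)
  } else {
    apply(epoch, 1, feature_funs[[feature]])
  }
}

# fast column extremes of a short-row matrix
col_max <- function(m) do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ]))
col_min <- function(m) do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))

#' Feature matrix of a whole record
#'
#' Vectorized equivalent of calling [extract_features()] on every complete
#' epoch of the record: one row per epoch, one column per channel.
#'
#' @param record an [eeg_record()] (or bare `n_channels x n_samples` matrix).
#' @param N epoch length in samples.
#' @param feature extractor name.
#' @param w sub-window width for `nlacc`.
#' @return `n_epochs x n_channels` numeric matrix.
#' @export
feature_matrix <- function(record, N = 512,
                           feature = c("energy", "line_length", "nlacc"),
                           w = 15) {
  feature <- match.arg(feature)
  data <- if (inherits(record, "eeg_record")) record$data else record
  stopifnot(is.matrix(data))
  N <- as.integer(N)
  n_epochs <- ncol(data) %/% N
  if (n_epochs == 0) stop("record shorter than one epoch")
  n_ch <- nrow(data)
  out <- matrix(0, n_epochs, n_ch)
  used <- seq_len(n_epochs * N)
  for (ch in seq_len(n_ch)) {
    X <- matrix(data[ch, used], nrow = N)          # N x n_epochs
    out[, ch] <- switch(feature,
      energy = colSums(X^2) / N,
      line_length = colSums(abs(X[-1, , drop = FALSE] -
                                X[-N, , drop = FALSE])) / (N - 1),
      nlacc = {
        ns <- N %/% w
        if (ns < 3) stop("nlacc requires N >= 3*w")
        S <- matrix(X[seq_len(ns * w), ], nrow = w) # w x (ns*n_epochs)
        mx <- matrix(col_max(S), nrow = ns)
        mn <- matrix(col_min(S), nrow = ns)
        i <- seq_len(ns - 2)
        hv <- pmin(mx[i, , drop = FALSE],
                   pmax(mx[i + 1, , drop = FALSE], mx[i + 2, , drop = FALSE]))
        lv <- pmax(mn[i, , drop = FALSE],
                   pmin(mn[i + 1, , drop = FALSE], mn[i + 2, , drop = FALSE]))
        colSums(hv - lv)
      })
  }
  colnames(out) <- if (inherits(record, "eeg_record")) record$channel_names
                   else sprintf("CH%02d", seq_len(n_ch))
  out
}

#' Write a per-epoch feature table as CSV
#'
#' One row per epoch: record id, epoch index, label, then one column per
#' channel feature.
#'
#' @param features `n_epochs x n_channels` matrix (see [feature_matrix()]).
#' @param epochs epoch table from [segment_and_label()].
#' @param record_id record identifier.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, epochs, record_id, path) {
  stopifnot(nrow(features) == nrow(epochs))
  df <- data.frame(record_id = record_id, epoch = epochs$epoch,
                   label = epochs$label, features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
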