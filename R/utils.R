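#' Derive a reproducible RNG substream seed
#'
#' Mixes a master seed with an arbitrary set of string/numeric tags into a
#' deterministic 31-bit seed. Used throughout the package so that, e.g., the
#' background noise of channel 7 does not depend on how many channels were
#' generated before it, and every grid point of an experiment sweep is
#' independently reproducible.
#'
#' @param seed master seed (integer).
#' @param ... tags (coerced to character) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "background", 7)
substream_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                       character(1)), collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(tags)) {
    # 31-bit multiplicative mix; constants from Park-Miller / FNV folklore
    h <- (h * 48271 + b * 16807 + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Wireless EEG data-rate of a montage
#'
#' Bits per second produced by `n_channels` electrodes sampled at `fs` Hz
#' with `bits`-bit resolution; the figure that motivates sensor-side data
#' reduction (a 32-channel, 250 Hz, 16-bit montage produces 125 kbit/s).
#'
#' @param n_channels number of recorded channels.
#' @param fs sampling rate in Hz.
#' @param bits resolution of the analog-to-digital converter.
#' @return data rate in bits per second.
#' @export
data_rate_bps <- function(n_channels, fs, bits = 16) {
  stopifnot(n_channels > 0, fs > 0, bits > 0)
  n_channels * fs * bits
}

#' Minimum sample count for blind-source-separation artifact removal
#'
#' BSS unmixing estimation is commonly recommended to use at least
#' `k * n_channels^2` time samples; for 23-channel EEG with k = 10 this is
#' 5290 samples (41.3 s at 128 Hz), which is why online artifact removal is
#' impractical at seizure-detection epoch sizes.
#'
#' @param n_channels number of channels.
#' @param k samples-per-parameter multiplier (>= 10 recommended).
#' @return minimum number of time samples.
#' @export
bss_min_samples <- function(n_channels, k = 10) {
  stopifnot(n_channels > 0, k > 0)
  k * n_channels^2
}

#' Epoch duration in seconds
#'
#' @param N epoch length in samples.
#' @param fs sampling rate in Hz.
#' @return duration in seconds.
#' @export
epoch_duration_s <- function(N, fs) {
  stopifnot(N > 0, fs > 0)
  N / fs
}
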