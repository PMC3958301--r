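# Transmission path: 16-bit uniform encoding to a bitstream, i.i.d. bit-flip
# corruption at a specified bit error rate (no forward error correction),
# decoding, and packet/byte accounting.

#' Uniform quantizer specification
#'
#' A 16-bit mid-rise uniform quantizer over the full-scale range
#' `[lo, hi]`. Values outside the range are clipped (silently, but counted);
#' codes are unsigned offset-binary, serialized most-significant-bit first.
#'
#' @param lo,hi full-scale range in signal units (`lo < hi`).
#' @return object of class `quantizer_spec` (word size fixed at 16 bits).
#' @export
quantizer_spec <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  structure(list(lo = lo, hi = hi, bits = 16L), class = "quantizer_spec")
}

#' Quantizer range for a data kind
#'
#' Full-scale conventions used by the pipeline: raw EEG samples use the ADC
#' full scale; compressive measurements (sums of `d` samples) use the exact
#' data-independent bound `d` times the ADC full scale; feature values use a
#' range calibrated as +/- `margin` times the largest absolute value observed
#' on a (training) reference set, transmitted error-free as metadata.
#'
#' @param kind `"raw"`, `"measurements"`, or `"features"`.
#' @param d ones per measurement-matrix column (for `"measurements"`).
#' @param reference numeric values to calibrate on (for `"features"`).
#' @param full_scale ADC full scale (default 32768 signal units).
#' @param margin calibration headroom for features (default 1.2).
#' @return a [quantizer_spec()].
#' @export
quantizer_for <- function(kind = c("raw", "measurements", "features"),
                          d = 4, reference = NULL, full_scale = 32768,
                          margin = 1.2) {
  kind <- match.arg(kind)
  switch(kind,
    raw = quantizer_spec(-full_scale, full_scale),
    measurements = quantizer_spec(-d * full_scale, d * full_scale),
    features = {
      if (is.null(reference)) stop("feature quantizer needs reference values")
      r <- margin * max(abs(reference), 1e-9)
      quantizer_spec(-r, r)
    })
}

bitstream <- function(codes, n_clipped = 0L) {
  structure(list(codes = as.integer(codes), bits = 16L,
                 n_clipped = as.integer(n_clipped)),
            class = "bitstream")
}

#' @export
print.bitstream <- function(x, ...) {
  cat(sprintf("<bitstream: %d x 16-bit words (%d bits)%s>\n",
              length(x$codes), 16L * length(x$codes),
              if (x$n_clipped > 0) sprintf(", %d clipped", x$n_clipped) else ""))
  invisible(x)
}

#' Encode values into a 16-bit bitstream
#'
#' Mid-rise uniform quantization to unsigned 16-bit codes over the spec's
#' full scale. `lo` maps to code 0 and `hi` to code 65535; in-range values
#' round-trip through [decode_stream()] within half a least significant bit,
#' i.e. `(hi - lo) / 2^17`. Out-of-range values are clipped and counted on
#' the returned object (`$n_clipped`).
#'
#' @param values numeric vector.
#' @param spec a [quantizer_spec()].
#' @return object of class `bitstream` (`16 * length(values)` bits).
#' @export
encode_stream <- function(values, spec) {
  stopifnot(inherits(spec, "quantizer_spec"))
  codes <- floor((values - spec$lo) / (spec$hi - spec$lo) * 65536)
  n_clipped <- sum(codes < 0 | codes > 65535)
  codes[codes < 0] <- 0
  codes[codes > 65535] <- 65535
  bitstream(codes, n_clipped)
}

#' Decode a 16-bit bitstream
#'
#' Inverse of [encode_stream()] up to quantization (mid-rise reconstruction
#' levels); there is no error detection or correction.
#'
#' @param stream a `bitstream`.
#' @param spec the [quantizer_spec()] used at the encoder.
#' @return numeric vector, one value per 16-bit word.
#' @export
decode_stream <- function(stream, spec) {
  stopifnot(inherits(stream, "bitstream"), inherits(spec, "quantizer_spec"))
  spec$lo + (stream$codes + 0.5) * (spec$hi - spec$lo) / 65536
}

#' Bits of a stream as a 0/1 vector (MSB first within each word)
#' @param stream a `bitstream`.
#' @return integer vector of length `16 * n_words`.
#' @export
stream_bits <- function(stream) {
  stopifnot(inherits(stream, "bitstream"))
  if (length(stream$codes) == 0) return(integer(0))
  as.integer(t(vapply(stream$codes, function(w) {
    as.integer(bitwAnd(bitwShiftR(w, 15:0), 1L))
  }, integer(16))))
}

#' Build a stream from a 0/1 bit vector (MSB first within each word)
#' @param bits integer vector; length must be a multiple of 16.
#' @return a `bitstream`.
#' @export
bits_to_stream <- function(bits) {
  if (length(bits) %% 16 != 0) {
    stop("ragged stream: ", length(bits), " bits is not a multiple of 16")
  }
  if (length(bits) == 0) return(bitstream(integer(0)))
  m <- matrix(as.integer(bits), nrow = 16)
  bitstream(as.integer(colSums(m * 2^(15:0))))
}

#' Corrupt a bitstream with i.i.d. bit flips
#'
#' Every payload bit is flipped independently with probability `ber`.
#' Seeded-deterministic; flipping twice with the same seed restores the
#' original stream (the flips are involutive). The number of flipped bits is
#' reported on the result (`$n_flips`).
#'
#' @param stream a `bitstream`.
#' @param ber bit error rate in `[0, 1]`.
#' @param seed RNG seed for the flip positions.
#' @return the corrupted `bitstream` with an `n_flips` field.
#' @export
corrupt_stream <- function(stream, ber, seed = 1) {
  stopifnot(inherits(stream, "bitstream"))
  if (!is.numeric(ber) || length(ber) != 1 || ber < 0 || ber > 1) {
    stop("ber must be a probability in [0, 1]")
  }
  n_bits <- 16L * length(stream$codes)
  out <- stream
  out$n_flips <- 0L
  if (n_bits == 0 || ber == 0) return(out)
  set.seed(substream_seed(seed, "channel", n_bits))
  n_flips <- stats::rbinom(1, n_bits, ber)
  if (n_flips > 0) {
    pos <- sample.int(n_bits, n_flips)            # distinct bit positions
    word <- (pos - 1L) %/% 16L + 1L
    mask <- 2^(15L - (pos - 1L) %% 16L)
    agg <- rowsum(mask, group = word)              # distinct bits: xor == sum
    w <- as.integer(rownames(agg))
    out$codes[w] <- bitwXor(out$codes[w], as.integer(agg))
  }
  out$n_flips <- as.integer(n_flips)
  out
}

#' Packet count and byte accounting for a payload
#'
#' Payloads are fragmented into packets of at most `max_payload` bytes, each
#' carrying `mac` bytes of medium-access-control overhead.
#'
#' @param n_bytes payload size in bytes (>= 0).
#' @param max_payload maximum payload bytes per packet (default 114).
#' @param mac overhead bytes per packet (default 13).
#' @return object of class `packet_account`: `n_packets`, `payload_bytes`,
#'   `overhead_bytes`, `total_bytes`.
#' @export
#' @examples
#' packetize_account(114)  # 1 packet, 127 bytes on air
packetize_account <- function(n_bytes, max_payload = 114, mac = 13) {
  stopifnot(n_bytes >= 0, max_payload > 0, mac >= 0)
  n_packets <- as.integer(ceiling(n_bytes / max_payload))
  structure(list(n_packets = n_packets, payload_bytes = n_bytes,
                 overhead_bytes = mac * n_packets,
                 total_bytes = n_bytes + mac * n_packets),
            class = "packet_account")
}

#' @export
print.packet_account <- function(x, ...) {
  cat(sprintf("<packet_account: %d byte(s) in %d packet(s), %d on air>\n",
              x$payload_bytes, x$n_packets, x$total_bytes))
  invisible(x)
}

#' Transmitted payload bytes per epoch for each approach
#'
#' Raw transmission sends every sample; the compressed branch sends `M`
#' measurements per channel; the feature branch sends a single value per
#' channel per epoch (a reduction of `N:1`).
#'
#' @param approach `"raw"`, `"compressed"`, or `"features"`.
#' @param n_channels number of channels.
#' @param N epoch length in samples.
#' @param M measurements per epoch (compressed branch).
#' @param bits word size (default 16).
#' @return payload bytes per epoch (integer).
#' @export
bytes_per_epoch <- function(approach = c("raw", "compressed", "features"),
                            n_channels, N, M = NULL, bits = 16) {
  approach <- match.arg(approach)
  stopifnot(n_channels > 0, bits %% 8 == 0)
  bytes <- bits / 8
  switch(approach,
         raw = { stopifnot(N > 0); n_channels * N * bytes },
         compressed = {
           if (is.null(M)) stop("compressed accounting needs M")
           n_channels * M * bytes
         },
         features = n_channels * bytes)
}
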