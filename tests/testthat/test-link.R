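test_that("the encoder maps range endpoints to the code extremes", {
  qs <- quantizer_spec(-100, 100)
  s <- encode_stream(c(-100, 100), qs)
  expect_equal(s$codes, c(0L, 65535L))
  expect_equal(length(stream_bits(s)), 32)
  expect_error(quantizer_spec(5, 5))
})

test_that("encode-decode round trip stays within half an LSB", {
  qs <- quantizer_spec(-512, 512)
  set.seed(1)
  x <- runif(400, -510, 510)
  xr <- decode_stream(encode_stream(x, qs), qs)
  expect_lte(max(abs(xr - x)), (512 + 512) / 2^17)
})

test_that("out-of-range values are clipped and counted", {
  qs <- quantizer_spec(-1, 1)
  s <- encode_stream(c(-5, 0, 5), qs)
  expect_equal(s$n_clipped, 2L)
  expect_equal(s$codes[c(1, 3)], c(0L, 65535L))
})

test_that("a single most-significant-bit flip moves the value by half the range", {
  qs <- quantizer_spec(-100, 100)
  s <- encode_stream(0, qs)
  bits <- stream_bits(s)
  bits[1] <- 1L - bits[1]
  flipped <- decode_stream(bits_to_stream(bits), qs)
  expect_equal(abs(flipped - decode_stream(s, qs)), 100)  # (hi-lo)/2
})

test_that("corruption at the BER extremes is identity / full inversion", {
  qs <- quantizer_spec(-10, 10)
  s <- encode_stream(rnorm(64), qs)
  expect_identical(corrupt_stream(s, 0, 1)$codes, s$codes)
  all_flipped <- corrupt_stream(s, 1, 1)
  expect_true(all(stream_bits(all_flipped) == 1L - stream_bits(s)))
  expect_error(corrupt_stream(s, 1.5, 1), "probability")
})

test_that("bit flips are involutive and binomial at rate 1e-2", {
  qs <- quantizer_spec(-1, 1)
  s <- encode_stream(rep(0, 62500), qs)          # 1e6 bits
  c1 <- corrupt_stream(s, 1e-2, 77)
  expect_identical(corrupt_stream(c1, 1e-2, 77)$codes, s$codes)
  n <- 1e6; p <- 1e-2
  expect_lt(abs(c1$n_flips - n * p), 3 * sqrt(p * (1 - p) * n))
  expect_equal(sum(stream_bits(c1) != stream_bits(s)), c1$n_flips)
})

test_that("two independent corruption passes compose like p + q - 2pq", {
  qs <- quantizer_spec(-1, 1)
  s <- encode_stream(rep(0, 31250), qs)          # 5e5 bits
  p <- 5e-3; q <- 2e-3
  c2 <- corrupt_stream(corrupt_stream(s, p, 101), q, 202)
  rate <- p + q - 2 * p * q
  n <- 5e5
  flips <- sum(stream_bits(c2) != stream_bits(s))
  expect_lt(abs(flips - n * rate), 3 * sqrt(rate * (1 - rate) * n))
})

test_that("empty and ragged streams are handled", {
  qs <- quantizer_spec(0, 1)
  s <- encode_stream(numeric(0), qs)
  expect_length(decode_stream(s, qs), 0)
  expect_identical(corrupt_stream(s, 0.5, 1)$n_flips, 0L)
  expect_error(bits_to_stream(rep(1L, 20)), "ragged")
})

test_that("packet accounting matches the payload/overhead constants", {
  a <- packetize_account(114)
  expect_equal(a$n_packets, 1L)
  expect_equal(a$total_bytes, 127)
  expect_equal(packetize_account(23 * 512 * 2)$n_packets, 207L)
  z <- packetize_account(0)
  expect_equal(z$n_packets, 0L)
  expect_equal(z$total_bytes, 0)
})

test_that("per-epoch byte accounting is linear and ordered across approaches", {
  expect_equal(bytes_per_epoch("features", 23, 512), 46)
  expect_equal(bytes_per_epoch("raw", 23, 512) /
                 bytes_per_epoch("features", 23, 512), 512)
  expect_equal(bytes_per_epoch("compressed", 23, 512, M = 512),
               bytes_per_epoch("raw", 23, 512))
  # linear in channels and ordered when M < N
  expect_equal(bytes_per_epoch("raw", 46, 512), 2 * bytes_per_epoch("raw", 23, 512))
  expect_lt(bytes_per_epoch("features", 23, 512),
            bytes_per_epoch("compressed", 23, 512, M = 128))
  expect_lt(bytes_per_epoch("compressed", 23, 512, M = 128),
            bytes_per_epoch("raw", 23, 512))
})

test_that("montage data-rate and BSS sample-count helpers match hand arithmetic", {
  expect_equal(data_rate_bps(32, 250, 16), 128000)
  expect_equal(data_rate_bps(32, 250, 16) / 1024, 125)  # binary-prefix kbit/s
  expect_equal(bss_min_samples(23, 10), 5290)
  expect_equal(bss_min_samples(23, 10) / 128, 41.328125)
  expect_equal(epoch_duration_s(512, 128), 4)
})
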