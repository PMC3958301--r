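test_that("identical config and seed give bit-identical records", {
  cfg <- gen_config(duration_s = 30, n_events = 1, event_duration_s = c(6, 10),
                    seed = 3)
  r1 <- generate_record(cfg)
  r2 <- generate_record(cfg)
  expect_identical(r1$data, r2$data)
  expect_equal(r1$events, r2$events)
})

test_that("per-channel substreams make early channels invariant to channel count", {
  c5 <- gen_config(n_channels = 5, duration_s = 20, n_events = 0, seed = 9)
  c23 <- gen_config(n_channels = 23, duration_s = 20, n_events = 0, seed = 9)
  r5 <- generate_record(c5)
  r23 <- generate_record(c23)
  expect_identical(r5$data, r23$data[1:5, ])
})

test_that("gain-0 background is stationary with mean near zero", {
  cfg <- gen_config(n_channels = 4, duration_s = 600, n_events = 0, seed = 5)
  rec <- generate_record(cfg)
  # variance of the sample mean of an AR(2): sigma_e^2 / ((1-a1-a2)^2 n)
  n <- ncol(rec$data)
  se <- cfg$noise_sd / ((1 - sum(cfg$ar_coefs)) * sqrt(n))
  means <- rowMeans(rec$data)
  expect_true(all(abs(means) < 3 * se + 0.5))  # +0.5 for integer rounding
})

test_that("default settings stay inside the 16-bit full scale (no clipping)", {
  cfg <- gen_config(duration_s = 120, n_events = 1,
                    event_duration_s = c(30, 60), seed = 13)
  expect_silent(rec <- generate_record(cfg))
  expect_true(max(abs(rec$data)) <= 32767)
})

test_that("events are sorted, non-overlapping, and rejected when they cannot fit", {
  cfg <- gen_config(duration_s = 300, n_events = 3,
                    event_duration_s = c(10, 20), seed = 17)
  rec <- generate_record(cfg)
  on <- vapply(rec$events, `[[`, numeric(1), "onset_s")
  off <- vapply(rec$events, `[[`, numeric(1), "offset_s")
  expect_equal(length(rec$events), 3)
  expect_true(all(diff(on) > 0))
  expect_true(all(on[-1] >= off[-3]))
  expect_true(all(off <= 300))

  bad <- gen_config(duration_s = 30, n_events = 4,
                    event_duration_s = c(10, 10), seed = 17)
  expect_error(generate_record(bad), "fit")

  expect_error(eeg_record(matrix(0, 2, 100), fs = 10, events = list(
    seizure_event(1, 5), seizure_event(4, 8))), "overlap")
})

test_that("seizure gain drives NLACC separation between classes", {
  sep <- function(gain) {
    cfg <- gen_config(duration_s = 840, n_events = 2,
                      event_duration_s = c(60, 100), seizure_gain = gain,
                      seed = 21)
    rec <- generate_record(cfg)
    fs <- make_feature_set(rec, 512, "nlacc")
    m <- rowMeans(fs$features)
    sz <- m[fs$epochs$label == "SEIZURE"]
    ns <- m[fs$epochs$label == "NONSEIZURE"]
    pooled <- sqrt(((length(sz) - 1) * var(sz) + (length(ns) - 1) * var(ns)) /
                     (length(sz) + length(ns) - 2))
    c(sep = (mean(sz) - mean(ns)) / pooled, n = length(sz) + length(ns))
  }
  s0 <- sep(0)
  expect_gt(s0[["n"]], 200)
  expect_lt(abs(s0[["sep"]]), 0.1)
  s10 <- sep(10)
  expect_gt(s10[["sep"]], 5)
})

test_that("explicit event lists override random placement", {
  cfg <- gen_config(duration_s = 60, seed = 2,
                    events = list(seizure_event(10, 20)))
  rec <- generate_record(cfg)
  expect_equal(rec$events[[1]]$onset_s, 10)
  expect_equal(rec$events[[1]]$offset_s, 20)
})
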