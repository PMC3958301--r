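test_that("energy matches hand-computed values and scaling law", {
  expect_equal(energy(rep(3.5, 64)), 3.5^2)
  expect_equal(energy(c(1, 2, 3, 4)), 7.5)
  set.seed(1)
  x <- rnorm(256)
  expect_equal(energy(3 * x), 9 * energy(x))
  expect_error(energy(numeric(0)), "at least one")
})

test_that("line length matches hand-computed values and invariances", {
  expect_equal(line_length(rep(2, 50)), 0)
  expect_equal(line_length(c(1, 3, 2)), 1.5)
  set.seed(2)
  x <- rnorm(128)
  expect_equal(line_length(x + 17.3), line_length(x))
  expect_equal(line_length(-2 * x), 2 * line_length(x))
  expect_error(line_length(5), "two samples")
})

test_that("nlacc matches hand evaluation on ramp and spike-train signals", {
  expect_equal(nlacc(rep(1, 45)), 0)
  # ramp 1..45, w = 15: HV1 = min(15, 45) = 15, LV1 = max(1, 16) = 16
  expect_equal(nlacc(seq_len(45), w = 15), -1)
  # alternating +/-A in every sub-window: each defined term contributes 2A
  A <- 4
  x <- rep(c(A, -A), length.out = 120)
  ns <- 120 %/% 15
  expect_equal(nlacc(x, 15), 2 * A * (ns - 2))
  expect_error(nlacc(rnorm(40), 15), "3\\*w = 45")
})

test_that("nlacc equals the brute-force transcription on random signals", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(45:512, 1)
    x <- rnorm(n, sd = sample(c(1, 50), 1))
    expect_equal(nlacc(x), nlacc_oracle(x), tolerance = 1e-12)
  }
})

test_that("scaling and shift laws hold on random signals", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(180, sd = 30)
    a <- runif(1, 0.5, 4)
    c0 <- runif(1, -50, 50)
    expect_equal(energy(a * x), a^2 * energy(x))
    expect_equal(line_length(a * x), a * line_length(x))
    expect_equal(nlacc(a * x), a * nlacc(x))
    expect_equal(line_length(x + c0), line_length(x))
    expect_equal(nlacc(x + c0), nlacc(x), tolerance = 1e-9)
  }
})

test_that("an hour at 128 Hz yields 900 epochs of 512 samples", {
  rec <- eeg_record(matrix(0, 1, 3600 * 128), fs = 128)
  seg <- segment_and_label(rec, 512)
  expect_equal(nrow(seg), 900)
  expect_equal(seg$start_sample, (0:899) * 512L)
  # partition: every sample in exactly one epoch
  expect_equal(sum(rep(512, nrow(seg))), 512 * (ncol(rec$data) %/% 512))
})

test_that("epoch labels follow the containment rule", {
  fs <- 128; N <- 512
  # event exactly spanning epochs 11..13 (1-based): samples [10N, 13N)
  ev <- seizure_event(10 * N / fs, 13 * N / fs)
  rec <- eeg_record(matrix(0, 1, 20 * N), fs = fs, events = list(ev))
  seg <- segment_and_label(rec, N)
  expect_equal(as.character(seg$label[11:13]), rep("SEIZURE", 3))
  expect_equal(as.character(seg$label[c(10, 14)]), rep("NONSEIZURE", 2))
  expect_false(any(seg$label == "MIXED"))

  # event starting mid-epoch makes that epoch MIXED
  ev2 <- seizure_event(10 * N / fs + 2, 13 * N / fs)
  rec2 <- eeg_record(matrix(0, 1, 20 * N), fs = fs, events = list(ev2))
  seg2 <- segment_and_label(rec2, N)
  expect_equal(as.character(seg2$label[11]), "MIXED")
  expect_equal(as.character(seg2$label[12:13]), rep("SEIZURE", 2))
})

test_that("a record shorter than one epoch yields an empty warning result", {
  rec <- eeg_record(matrix(0, 1, 100), fs = 128)
  expect_warning(seg <- segment_and_label(rec, 512), "shorter")
  expect_equal(nrow(seg), 0)
})

test_that("feature vectors have one entry per channel, in channel order", {
  rec <- small_record()
  ep <- get_epoch(rec, 512, 2)
  v <- extract_features(ep, "nlacc")
  expect_length(v, 23)
  expect_identical(v, extract_features(ep, "nlacc"))  # stable across calls
  one <- matrix(2.5, 1, 64)
  expect_equal(extract_features(one, "energy"), 6.25)
})

test_that("vectorized feature_matrix agrees with per-epoch extraction", {
  rec <- small_record()
  for (f in c("energy", "line_length", "nlacc")) {
    fm <- feature_matrix(rec, 512, f)
    k <- c(1, 7, 15)
    for (kk in k) {
      expect_equal(fm[kk, ], unname(extract_features(get_epoch(rec, 512, kk), f)),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("feature CSV export writes one labeled row per epoch", {
  rec <- small_record()
  seg <- segment_and_label(rec, 512)
  fm <- feature_matrix(rec, 512, "energy")
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, seg, rec$record_id, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(seg))
  expect_equal(ncol(back), 3 + 23)
  expect_equal(back$label, as.character(seg$label))
})
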