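test_that("a separable toy problem is classified perfectly on its training set", {
  set.seed(1)
  x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 6), 50))
  y <- rep(c("NONSEIZURE", "SEIZURE"), each = 50)
  m <- train_detector(x, y)
  expect_equal(as.character(predict_detector(m, x)), y)
})

test_that("label permutation on random features gives chance-level accuracy", {
  set.seed(2)
  n <- 500
  x <- matrix(rnorm(n * 5), n)
  y <- sample(rep(c("NONSEIZURE", "SEIZURE"), each = n / 2))
  tr <- seq_len(n / 2)
  m <- train_detector(x[tr, ], y[tr])
  acc <- mean(as.character(predict_detector(m, x[-tr, ])) == y[-tr])
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / (n / 2)))
})

test_that("training is deterministic and degenerate inputs predict cleanly", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 4), 30))
  y <- rep(c("NONSEIZURE", "SEIZURE"), each = 30)
  m1 <- train_detector(x, y)
  m2 <- train_detector(x, y)
  xt <- matrix(rnorm(40), 20)
  expect_identical(predict_detector(m1, xt), predict_detector(m2, xt))
  zero <- matrix(0, 1, 2)
  expect_s3_class(as.factor(predict_detector(m1, zero)), "factor")
  expect_error(predict_detector(m1, matrix(0, 1, 5)), "dimensionality")
  expect_error(train_detector(x, rep("SEIZURE", 60)), "single class")
})

test_that("leave-one-record-out folds cover each record once, order-invariantly", {
  sets <- subject_sets(n_records = 3, duration_s = 180, seed = 23)
  res <- loro_cv(sets)
  expect_setequal(unique(res$record_id),
                  vapply(sets, `[[`, character(1), "record_id"))
  per_rec <- table(res$record_id)
  expect_true(all(per_rec == nrow(sets[[1]]$epochs)))
  res_perm <- loro_cv(sets[c(3, 1, 2)])
  expect_identical(res$predicted, res_perm$predicted)
  expect_error(loro_cv(sets[1]), "2")
})

test_that("folds with single-class training data are skipped with a warning", {
  sets <- subject_sets(n_records = 3, duration_s = 180, seed = 23)
  # strip seizure epochs from two records so one fold trains on one class
  for (k in 2:3) {
    keep <- sets[[k]]$epochs$label == "NONSEIZURE"
    sets[[k]]$features <- sets[[k]]$features[keep, , drop = FALSE]
    sets[[k]]$epochs <- sets[[k]]$epochs[keep, , drop = FALSE]
    sets[[k]]$events <- list()
  }
  expect_warning(res <- loro_cv(sets), "single-class")
  skipped <- attr(res, "skipped")
  expect_equal(skipped, sets[[1]]$record_id)
  expect_true(all(is.na(res$predicted[res$record_id == skipped])))
})

test_that("a strongly separable subject reaches full seizure sensitivity", {
  cfg <- gen_config(duration_s = 150, n_events = 1,
                    event_duration_s = c(30, 50), seizure_gain = 10, seed = 31)
  recs <- generate_subject(cfg, 4)
  sets <- lapply(recs, make_feature_set, N = 512, feature = "nlacc")
  met <- loro_metrics(loro_cv(sets))
  expect_equal(met$seizure_sensitivity, 100)
  expect_equal(met$counts$total_events, 4)
})

test_that("metrics match their definitions on crafted cases", {
  fs <- 128; N <- 512; eps <- N / fs
  # one event covering epochs 11..13 exactly; perfect predictions
  ev <- seizure_event(10 * eps, 13 * eps)
  rec <- eeg_record(matrix(0, 1, 20 * N), fs = fs, events = list(ev))
  seg <- segment_and_label(rec, N)
  perfect <- factor(ifelse(seg$label == "SEIZURE", "SEIZURE", "NONSEIZURE"),
                    levels = c("NONSEIZURE", "SEIZURE"))
  m <- compute_metrics(perfect, seg, list(ev), eps)
  expect_equal(m$seizure_sensitivity, 100)
  expect_equal(m$epoch_sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$fpr_per_hour, 0)
  expect_equal(m$mean_latency_s, 4)   # first seizure epoch ends 4 s after onset

  # all-nonseizure predictions
  none <- factor(rep("NONSEIZURE", nrow(seg)), levels = c("NONSEIZURE", "SEIZURE"))
  m0 <- compute_metrics(none, seg, list(ev), eps)
  expect_equal(m0$seizure_sensitivity, 0)
  expect_equal(m0$specificity, 100)
  expect_equal(m0$fpr_per_hour, 0)
  expect_true(is.na(m0$mean_latency_s))

  # exactly 1 false positive among 900 non-seizure epochs of 4 s -> 1/h
  seg900 <- segment_and_label(eeg_record(matrix(0, 1, 900 * N), fs = fs), N)
  p <- factor(rep("NONSEIZURE", 900), levels = c("NONSEIZURE", "SEIZURE"))
  p[37] <- "SEIZURE"
  m1 <- compute_metrics(p, seg900, list(), eps)
  expect_equal(m1$fpr_per_hour, 1)
  expect_true(is.na(m1$seizure_sensitivity))
})

test_that("metrics agree with a brute-force recount on random configurations", {
  for (i in 1:30) {
    case <- random_prediction_case(i)
    got <- compute_metrics(case$pred, case$epochs, case$events, case$epoch_s)
    want <- metrics_oracle(case$pred, case$epochs, case$events, case$epoch_s)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    if (length(case$events) > 0) {
      expect_lte(got$epoch_sensitivity, got$seizure_sensitivity)
    }
  }
})
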