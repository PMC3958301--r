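# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small annotated record: 23 ch, 2 min, one 20-30 s seizure
small_record <- function() {
  cached("small_record", {
    cfg <- gen_config(duration_s = 120, n_events = 1,
                      event_duration_s = c(20, 30), seed = 7)
    generate_record(cfg)
  })
}

# subject of n records with one mid-length event each
subject_sets <- function(n_records = 4, duration_s = 240, gain = 6,
                         seed = 11, feature = "nlacc", N = 512) {
  key <- paste("subject", n_records, duration_s, gain, seed, feature, N)
  cached(key, {
    cfg <- gen_config(duration_s = duration_s, n_events = 1,
                      event_duration_s = c(40, 60), seizure_gain = gain,
                      seed = seed)
    recs <- generate_subject(cfg, n_records)
    lapply(recs, make_feature_set, N = N, feature = feature)
  })
}

# brute-force transcription of the NLACC definition with explicit loops;
# independent oracle for the vectorized implementation
nlacc_oracle <- function(x, w = 15) {
  ns <- length(x) %/% w
  mx <- numeric(ns); mn <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- x[((i - 1) * w + 1):(i * w)]
    mx[i] <- max(s); mn[i] <- min(s)
  }
  total <- 0
  for (i in seq_len(ns - 2)) {
    hv <- min(mx[i], max(mx[i + 1], mx[i + 2]))
    lv <- max(mn[i], min(mn[i + 1], mn[i + 2]))
    total <- total + (hv - lv)
  }
  total
}

# brute-force recount of all five metrics from first principles
metrics_oracle <- function(pred, epochs, events, epoch_s) {
  keep <- epochs$label != "MIXED" & !is.na(pred)
  ep <- epochs[keep, , drop = FALSE]
  pr <- as.character(pred[keep])
  if (is.null(ep$record_id)) ep$record_id <- "record"
  if (length(events) > 0 && inherits(events[[1]], "seizure_event")) {
    events <- stats::setNames(list(events), ep$record_id[1])
  }
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_len(nrow(ep))) {
    truth <- as.character(ep$label[i]); guess <- pr[i]
    if (truth == "SEIZURE" && guess == "SEIZURE") tp <- tp + 1
    if (truth == "SEIZURE" && guess != "SEIZURE") fn <- fn + 1
    if (truth == "NONSEIZURE" && guess == "SEIZURE") fp <- fp + 1
    if (truth == "NONSEIZURE" && guess != "SEIZURE") tn <- tn + 1
  }
  nev <- 0; det <- 0; lat <- c()
  for (rid in names(events)) for (ev in events[[rid]]) {
    nev <- nev + 1
    best <- Inf
    for (i in seq_len(nrow(ep))) {
      if (ep$record_id[i] == rid && ep$label[i] == "SEIZURE" &&
          pr[i] == "SEIZURE" &&
          ep$start_s[i] >= ev$onset_s && ep$end_s[i] <= ev$offset_s) {
        best <- min(best, ep$end_s[i] - ev$onset_s)
      }
    }
    if (is.finite(best)) { det <- det + 1; lat <- c(lat, best) }
  }
  list(
    seizure_sensitivity = if (nev > 0) 100 * det / nev else NA_real_,
    epoch_sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    fpr_per_hour = if (tn + fp > 0) fp / ((tn + fp) * epoch_s / 3600) else NA_real_,
    mean_latency_s = if (det > 0) mean(lat) else NA_real_
  )
}

# random labeled epoch layout + predictions for metric cross-checks:
# events are epoch-aligned and at least two epochs long
random_prediction_case <- function(seed, n_epochs = 60, epoch_s = 4) {
  set.seed(seed)
  start_s <- (seq_len(n_epochs) - 1) * epoch_s
  end_s <- start_s + epoch_s
  label <- rep("NONSEIZURE", n_epochs)
  events <- list()
  k <- 1
  while (k + 3 <= n_epochs) {
    if (stats::runif(1) < 0.15) {
      len <- sample(2:3, 1)
      label[k:(k + len - 1)] <- "SEIZURE"
      events[[length(events) + 1]] <-
        seizure_event(start_s[k], end_s[k + len - 1])
      k <- k + len + 1
    } else k <- k + 1
  }
  label[sample(which(label == "NONSEIZURE"), 2)] <- "MIXED"
  epochs <- data.frame(epoch = seq_len(n_epochs), start_s = start_s,
                       end_s = end_s,
                       label = factor(label, levels = c("NONSEIZURE", "SEIZURE", "MIXED")))
  pred <- factor(sample(c("NONSEIZURE", "SEIZURE"), n_epochs, replace = TRUE,
                        prob = c(0.8, 0.2)),
                 levels = c("NONSEIZURE", "SEIZURE"))
  list(epochs = epochs, events = events, pred = pred, epoch_s = epoch_s)
}
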