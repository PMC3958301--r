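# Seizure detection: per-epoch SVM classification (second-order polynomial
# kernel), leave-one-record-out cross-validation, and event/epoch metrics.

#' Labeled per-epoch feature set of one record
#'
#' Bundles the feature matrix of a record with its epoch labels and event
#' annotations; the unit consumed by [loro_cv()].
#'
#' @param record an [eeg_record()].
#' @param N epoch length in samples.
#' @param feature extractor name (see [feature_matrix()]).
#' @param w sub-window width for `nlacc`.
#' @param features optional precomputed `n_epochs x n_channels` matrix (e.g.
#'   after transmission simulation); must match the record's epoch count.
#' @return object of class `feature_set`.
#' @export
make_feature_set <- function(record, N = 512, feature = "nlacc", w = 15,
                             features = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  epochs <- segment_and_label(record, N)
  if (is.null(features)) {
    features <- feature_matrix(record, N, feature, w)
  }
  stopifnot(nrow(features) == nrow(epochs))
  structure(list(features = features, epochs = epochs,
                 record_id = record$record_id, events = record$events,
                 fs = record$fs, N = as.integer(N),
                 epoch_s = N / record$fs, feature = feature),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s': %d epochs x %d channels (%s), %d seizure epoch(s)>\n",
              x$record_id, nrow(x$features), ncol(x$features), x$feature,
              sum(x$epochs$label == "SEIZURE")))
  invisible(x)
}

#' SVM classifier specification
#'
#' The kernel is fixed to a second-order polynomial; regularization,
#' kernel offset/scale, and class weighting are tunable.
#'
#' @param cost soft-margin constant C (default 1).
#' @param coef0 polynomial kernel offset (default 1).
#' @param gamma polynomial kernel scale; default `1/n_features` at fit time.
#' @param class_weights `"inverse"` (inverse class frequency, default) or
#'   `"none"`.
#' @return object of class `classifier_spec` (field `degree` fixed at 2).
#' @export
classifier_spec <- function(cost = 1, coef0 = 1, gamma = NULL,
                            class_weights = c("inverse", "none")) {
  class_weights <- match.arg(class_weights)
  stopifnot(cost > 0)
  structure(list(kernel = "polynomial", degree = 2L, cost = cost,
                 coef0 = coef0, gamma = gamma, class_weights = class_weights),
            class = "classifier_spec")
}

detect_levels <- c("NONSEIZURE", "SEIZURE")

#' Train the seizure/non-seizure SVM
#'
#' Fits a soft-margin SVM with a second-order polynomial kernel on z-score
#' standardized features; standardization statistics come from the training
#' split only and are stored with the model. Deterministic given inputs.
#'
#' @param x `n_epochs x n_features` numeric matrix (MIXED epochs excluded).
#' @param y labels, coercible to a factor with levels NONSEIZURE/SEIZURE;
#'   both classes must be present.
#' @param spec a [classifier_spec()].
#' @return object of class `seizure_svm`.
#' @export
train_detector <- function(x, y, spec = classifier_spec()) {
  stopifnot(is.matrix(x))
  y <- factor(as.character(y), levels = detect_levels)
  if (any(is.na(y))) stop("labels must be NONSEIZURE or SEIZURE")
  if (length(unique(y)) < 2) {
    stop("training set contains a single class; cannot fit a classifier")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  gamma <- if (is.null(spec$gamma)) 1 / ncol(x) else spec$gamma
  wts <- if (spec$class_weights == "inverse") {
    tb <- table(y)
    w <- as.numeric(sum(tb) / (2 * tb)); names(w) <- names(tb); w
  } else NULL
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "polynomial",
                    degree = spec$degree, coef0 = spec$coef0, gamma = gamma,
                    cost = spec$cost, class.weights = wts, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_,
                 levels = detect_levels, spec = spec, n_features = ncol(x)),
            class = "seizure_svm")
}

#' Predict epoch labels
#'
#' @param model a `seizure_svm` from [train_detector()].
#' @param x feature matrix with the training dimensionality.
#' @return factor of NONSEIZURE/SEIZURE, one per row.
#' @export
predict_detector <- function(model, x) {
  stopifnot(inherits(model, "seizure_svm"), is.matrix(x))
  if (ncol(x) != model$n_features) {
    stop("feature dimensionality ", ncol(x), " does not match training (",
         model$n_features, ")")
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  factor(as.character(stats::predict(model$fit, xs)), levels = detect_levels)
}

#' Leave-one-record-out cross-validation
#'
#' Each record of the subject is withheld once as the test set while a model
#' is trained on the MIXED-excluded epochs of all other records; predictions
#' are therefore out-of-sample for every epoch. Training rows are ordered
#' canonically (record id, then epoch), so results do not depend on the
#' order of `sets`. Folds whose training data contain a single class are
#' skipped with a warning and yield NA predictions.
#'
#' @param sets list of [make_feature_set()] objects (>= 2 records of one
#'   subject).
#' @param spec a [classifier_spec()].
#' @return object of class `loro_result`: data.frame with columns
#'   `record_id`, `epoch`, `start_s`, `end_s`, `label`, `predicted`, plus
#'   attributes `events` (named per record), `epoch_s`, `skipped`.
#' @export
loro_cv <- function(sets, spec = classifier_spec()) {
  stopifnot(length(sets) >= 2,
            all(vapply(sets, inherits, logical(1), "feature_set")))
  ids <- vapply(sets, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) stop("record ids must be unique")
  ord <- order(ids)
  sets <- sets[ord]; ids <- ids[ord]
  epoch_s <- unique(vapply(sets, `[[`, numeric(1), "epoch_s"))
  if (length(epoch_s) != 1) stop("all records must share the epoch size")

  skipped <- character(0)
  out <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    train_sets <- sets[-k]
    xtr <- do.call(rbind, lapply(train_sets, function(s) {
      s$features[s$epochs$label != "MIXED", , drop = FALSE]
    }))
    ytr <- unlist(lapply(train_sets, function(s) {
      as.character(s$epochs$label[s$epochs$label != "MIXED"])
    }))
    test <- sets[[k]]
    pred <- factor(rep(NA_character_, nrow(test$features)),
                   levels = detect_levels)
    if (length(unique(ytr)) < 2) {
      warning("fold for record '", ids[k],
              "' has single-class training data; skipped")
      skipped <- c(skipped, ids[k])
    } else {
      model <- train_detector(xtr, ytr, spec)
      pred <- predict_detector(model, test$features)
    }
    out[[k]] <- data.frame(record_id = ids[k], epoch = test$epochs$epoch,
                           start_s = test$epochs$start_s,
                           end_s = test$epochs$end_s,
                           label = test$epochs$label, predicted = pred)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  events <- lapply(sets, `[[`, "events")
  names(events) <- ids
  structure(res, events = events, epoch_s = epoch_s, skipped = skipped,
            class = c("loro_result", "data.frame"))
}

#' Detection metrics from per-epoch predictions
#'
#' Computes the five study metrics from predictions over labeled epochs.
#' MIXED epochs are excluded from every count. Definitions:
#' \itemize{
#'   \item seizure sensitivity: percentage of annotated seizure events
#'     during which at least one epoch is correctly labeled seizure;
#'   \item epoch sensitivity: percentage of seizure epochs correctly
#'     classified;
#'   \item specificity: percentage of non-seizure epochs correctly
#'     classified;
#'   \item false positive rate: falsely detected seizure epochs per hour of
#'     non-seizure recording time;
#'   \item latency: seconds from event onset to the end of the first seizure
#'     epoch within the event that is correctly labeled, averaged over
#'     detected events only (NA when no event is detected).
#' }
#'
#' @param predictions factor of NONSEIZURE/SEIZURE, one per epoch row.
#' @param epochs data.frame with columns `label`, `start_s`, `end_s` and,
#'   for multi-record evaluation, `record_id` (see [segment_and_label()] and
#'   [loro_cv()]).
#' @param events list of [seizure_event()] (single record) or a named list
#'   of such lists keyed by record id.
#' @param epoch_duration_s epoch duration in seconds.
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(predictions, epochs, events, epoch_duration_s) {
  stopifnot(length(predictions) == nrow(epochs), epoch_duration_s > 0)
  predictions <- factor(as.character(predictions), levels = detect_levels)
  if (is.null(epochs$record_id)) epochs$record_id <- "record"
  if (length(events) > 0 && inherits(events[[1]], "seizure_event")) {
    events <- stats::setNames(list(events), epochs$record_id[1])
  }

  keep <- epochs$label != "MIXED" & !is.na(predictions)
  ep <- epochs[keep, , drop = FALSE]
  pr <- predictions[keep]

  is_seiz <- ep$label == "SEIZURE"
  pred_seiz <- pr == "SEIZURE"
  tp <- sum(is_seiz & pred_seiz)
  fn <- sum(is_seiz & !pred_seiz)
  fp <- sum(!is_seiz & pred_seiz)
  tn <- sum(!is_seiz & !pred_seiz)

  # event-level bookkeeping
  n_events <- 0L; detected <- 0L; latencies <- numeric(0)
  for (rid in names(events)) {
    for (ev in events[[rid]]) {
      n_events <- n_events + 1L
      inside <- ep$record_id == rid & is_seiz &
        ep$start_s >= ev$onset_s - 1e-9 & ep$end_s <= ev$offset_s + 1e-9
      hit <- inside & pred_seiz
      if (any(hit)) {
        detected <- detected + 1L
        latencies <- c(latencies, min(ep$end_s[hit]) - ev$onset_s)
      }
    }
  }

  n_seiz <- tp + fn
  n_nonseiz <- tn + fp
  structure(list(
    seizure_sensitivity = if (n_events > 0) 100 * detected / n_events else NA_real_,
    epoch_sensitivity = if (n_seiz > 0) 100 * tp / n_seiz else NA_real_,
    specificity = if (n_nonseiz > 0) 100 * tn / n_nonseiz else NA_real_,
    fpr_per_hour = if (n_nonseiz > 0) {
      fp / (n_nonseiz * epoch_duration_s / 3600)
    } else NA_real_,
    mean_latency_s = if (detected > 0) mean(latencies) else NA_real_,
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn,
                  detected_events = detected, total_events = n_events)
  ), class = "metrics_report")
}

#' Metrics of a cross-validation result
#'
#' @param result a `loro_result` from [loro_cv()].
#' @return a `metrics_report` (see [compute_metrics()]).
#' @export
loro_metrics <- function(result) {
  stopifnot(inherits(result, "loro_result"))
  compute_metrics(result$predicted, as.data.frame(result),
                  attr(result, "events"), attr(result, "epoch_s"))
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v, unit = "") if (is.na(v)) "undefined" else sprintf("%.2f%s", v, unit)
  cat("Seizure detection metrics\n")
  cat(sprintf("  seizure sensitivity : %s (%d/%d events)\n",
              fmt(x$seizure_sensitivity, "%"),
              x$counts$detected_events, x$counts$total_events))
  cat(sprintf("  epoch sensitivity   : %s (%d/%d epochs)\n",
              fmt(x$epoch_sensitivity, "%"), x$counts$tp,
              x$counts$tp + x$counts$fn))
  cat(sprintf("  specificity         : %s\n", fmt(x$specificity, "%")))
  cat(sprintf("  false positive rate : %s\n", fmt(x$fpr_per_hour, "/h")))
  cat(sprintf("  mean latency        : %s\n", fmt(x$mean_latency_s, " s")))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(seizure_sensitivity = x$seizure_sensitivity,
             epoch_sensitivity = x$epoch_sensitivity,
             specificity = x$specificity,
             fpr_per_hour = x$fpr_per_hour,
             mean_latency_s = x$mean_latency_s)
}
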