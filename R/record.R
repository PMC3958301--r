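#' Seizure event annotation
#'
#' A single annotated seizure, in seconds from the start of the record.
#' Onset/offset are stored at 1-second resolution (integer seconds), the
#' resolution of clinical summary annotation files.
#'
#' @param onset_s onset, seconds from record start (`0 <= onset_s < offset_s`).
#' @param offset_s offset, seconds from record start.
#' @return an object of class `seizure_event`.
#' @export
#' @examples
#' seizure_event(120, 180)
seizure_event <- function(onset_s, offset_s) {
  onset_s <- as.numeric(onset_s)
  offset_s <- as.numeric(offset_s)
  if (length(onset_s) != 1 || length(offset_s) != 1 ||
      is.na(onset_s) || is.na(offset_s)) {
    stop("onset_s and offset_s must be single non-missing numbers")
  }
  if (onset_s < 0 || onset_s >= offset_s) {
    stop("require 0 <= onset_s < offset_s (got ", onset_s, ", ", offset_s, ")")
  }
  structure(list(onset_s = onset_s, offset_s = offset_s),
            class = "seizure_event")
}

#' @export
print.seizure_event <- function(x, ...) {
  cat(sprintf("<seizure_event %g-%g s (%g s)>\n",
              x$onset_s, x$offset_s, x$offset_s - x$onset_s))
  invisible(x)
}

# sort events by onset and check pairwise non-overlap / bounds
validate_events <- function(events, duration_s) {
  if (length(events) == 0) return(list())
  stopifnot(all(vapply(events, inherits, logical(1), "seizure_event")))
  ord <- order(vapply(events, `[[`, numeric(1), "onset_s"))
  events <- events[ord]
  on <- vapply(events, `[[`, numeric(1), "onset_s")
  off <- vapply(events, `[[`, numeric(1), "offset_s")
  if (any(off > duration_s)) {
    stop("seizure event extends past the end of the record (duration ",
         duration_s, " s)")
  }
  if (length(events) > 1 && any(on[-1] < off[-length(off)])) {
    stop("seizure events overlap")
  }
  events
}

#' Multichannel EEG record
#'
#' The unit of analysis and of cross-validation: a fixed-rate multichannel
#' recording with zero or more non-overlapping seizure-event annotations.
#'
#' @param data numeric matrix, `n_channels x n_samples`. Amplitudes are in
#'   signal units and must be representable in a signed 16-bit range.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `n_channels`.
#' @param record_id identifier string.
#' @param events list of [seizure_event()] objects (sorted and validated).
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_names = NULL,
                       record_id = "record", events = list()) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  n_channels <- nrow(data)
  if (is.null(channel_names)) {
    channel_names <- sprintf("CH%02d", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels) {
    stop("length(channel_names) must equal nrow(data)")
  }
  duration_s <- ncol(data) / fs
  events <- validate_events(events, duration_s)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 record_id = record_id, events = events),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s': %d ch x %d samples @ %g Hz (%.1f s), %d seizure event(s)>\n",
              x$record_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, length(x$events)))
  invisible(x)
}

#' @export
summary.eeg_record <- function(object, ...) {
  d <- object$data
  cat(sprintf("EEG record '%s'\n", object$record_id))
  cat(sprintf("  channels : %d (%s%s)\n", nrow(d),
              paste(utils::head(object$channel_names, 4), collapse = ", "),
              if (nrow(d) > 4) ", ..." else ""))
  cat(sprintf("  samples  : %d @ %g Hz = %.1f s\n", ncol(d), object$fs,
              ncol(d) / object$fs))
  cat(sprintf("  amplitude: [%.1f, %.1f], sd %.2f\n",
              min(d), max(d), stats::sd(d)))
  if (length(object$events)) {
    for (ev in object$events) {
      cat(sprintf("  seizure  : %g-%g s\n", ev$onset_s, ev$offset_s))
    }
  } else cat("  seizure  : none\n")
  invisible(object)
}

#' Record duration in seconds
#' @param record an [eeg_record()].
#' @return duration in seconds.
#' @export
record_duration_s <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  ncol(record$data) / record$fs
}
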