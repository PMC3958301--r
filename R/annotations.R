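# Plain-text seizure annotation files in the style of clinical summary
# listings: one block per record giving the file name, the number of
# seizures, and per-seizure start/end times in whole seconds.

#' Write seizure annotations for a record
#'
#' Event times are written at 1-second resolution (the resolution of the
#' source format); non-integer times are floored (onset) / ceiled (offset)
#' so the annotated interval never shrinks.
#'
#' @param record an [eeg_record()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  lines <- c(
    sprintf("File Name: %s.edf", record$record_id),
    sprintf("Number of Seizures in File: %d", length(record$events))
  )
  for (i in seq_along(record$events)) {
    ev <- record$events[[i]]
    lines <- c(lines,
               sprintf("Seizure %d Start Time: %d seconds", i, floor(ev$onset_s)),
               sprintf("Seizure %d End Time: %d seconds", i, ceiling(ev$offset_s)))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_annotation_block <- function(lines, path) {
  grab <- function(pattern, line) {
    m <- regmatches(line, regexec(pattern, line))[[1]]
    if (length(m) < 2) {
      stop("malformed annotation line in ", path, ": '", line, "'")
    }
    m[2]
  }
  nline <- grep("^Number of Seizures", lines, value = TRUE)
  if (length(nline) != 1) {
    stop("annotation block in ", path, " lacks a 'Number of Seizures' line")
  }
  n <- as.integer(grab("Number of Seizures in File:\\s*([0-9]+)\\s*$", nline))
  events <- vector("list", n)
  for (i in seq_len(n)) {
    sline <- grep(sprintf("^Seizure %d Start Time", i), lines, value = TRUE)
    eline <- grep(sprintf("^Seizure %d End Time", i), lines, value = TRUE)
    if (length(sline) != 1 || length(eline) != 1) {
      stop("annotation block in ", path, " lacks start/end lines for seizure ", i)
    }
    on <- as.numeric(grab("Start Time:\\s*([0-9]+)\\s*seconds", sline))
    off <- as.numeric(grab("End Time:\\s*([0-9]+)\\s*seconds", eline))
    events[[i]] <- seizure_event(on, off)
  }
  # normalize: sorted by onset regardless of file order
  events[order(vapply(events, `[[`, numeric(1), "onset_s"))]
}

#' Read seizure annotations for a single record
#'
#' Parses one annotation block and returns its events sorted by onset.
#' Malformed lines raise an error naming the offending line.
#'
#' @param path annotation text file.
#' @return list of [seizure_event()], sorted by onset.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- grep("^File Name:", lines)
  if (length(blocks) > 1) {
    stop(path, " contains ", length(blocks),
         " record blocks; use read_summary() for subject-level files")
  }
  parse_annotation_block(lines, path)
}

#' Read a subject-level summary file with one block per record
#'
#' @param path summary text file containing one or more record blocks, each
#'   starting with a `File Name:` line.
#' @return named list (by record file name, without extension) of event lists.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^File Name:", lines)
  if (length(starts) == 0) stop("no 'File Name:' blocks in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    name <- sub("^File Name:\\s*", "", block[1])
    name <- sub("\\.edf$", "", trimws(name))
    out[[name]] <- parse_annotation_block(block, path)
  }
  out
}
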