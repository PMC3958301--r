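# Minimal European Data Format (EDF) I/O: 16-bit integer signals, one-second
# data records, identity physical/digital scaling. Covers what multichannel
# scalp-EEG archives use; no EDF+ annotations (events travel in plain-text
# summary files, see read_annotations()).

edf_field <- function(x, width) {
  s <- format(x)[1]
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

#' Write an EEG record to an EDF file
#'
#' Samples are rounded to integer digital values in the signed 16-bit range
#' (clipped if outside); physical and digital ranges are identical, so the
#' round trip is exact to within one quantization step. The record duration
#' must be a whole number of seconds. Seizure annotations are not stored in
#' the EDF file; pair with [write_annotations()].
#'
#' @param record an [eeg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  n <- ncol(record$data)
  if (fs != round(fs) || n %% fs != 0) {
    stop("write_edf requires an integer sampling rate and a whole number of seconds")
  }
  ns <- nrow(record$data)
  ndr <- n %/% fs

  dig <- round(record$data)
  clipped <- sum(dig > 32767 | dig < -32768)
  if (clipped > 0) {
    warning(clipped, " sample(s) clipped to the signed 16-bit range")
    dig[dig > 32767] <- 32767
    dig[dig < -32768] <- -32768
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field(paste("Startdate 01.01.2000", record$record_id), 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(ndr, 8),
    edf_field(1, 8),
    edf_field(ns, 4),
    paste(vapply(record$channel_names, edf_field, character(1), width = 16),
          collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),       # transducer
    paste(rep(edf_field("uV", 8), ns), collapse = ""),      # physical dim
    paste(rep(edf_field(-32768, 8), ns), collapse = ""),    # physical min
    paste(rep(edf_field(32767, 8), ns), collapse = ""),     # physical max
    paste(rep(edf_field(-32768, 8), ns), collapse = ""),    # digital min
    paste(rep(edf_field(32767, 8), ns), collapse = ""),     # digital max
    paste(rep(edf_field("", 80), ns), collapse = ""),       # prefiltering
    paste(rep(edf_field(fs, 8), ns), collapse = ""),        # samples/record
    paste(rep(edf_field("", 32), ns), collapse = "")        # reserved
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  # data records: per record, each signal's fs samples consecutively
  arr <- array(t(dig), dim = c(fs, ndr, ns))          # sample x record x signal
  out <- as.integer(aperm(arr, c(1, 3, 2)))           # sample, signal, record
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' @param path EDF file path.
#' @param events optional list of [seizure_event()] to attach (EDF itself
#'   carries no annotations; see [read_annotations()]).
#' @return an [eeg_record()] (events empty unless supplied).
#' @export
read_edf <- function(path, events = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256 || trimws(substr(fixed, 1, 8)) != "0") {
    stop("not an EDF file (bad version field): ", path)
  }
  record_id <- trimws(substr(fixed, 89, 168))
  record_id <- sub("^Startdate \\S+ ?", "", record_id)
  if (record_id == "") record_id <- basename(path)
  hdr_bytes <- as.integer(trimws(substr(fixed, 185, 192)))
  ndr <- as.integer(trimws(substr(fixed, 237, 244)))
  rec_dur <- as.numeric(trimws(substr(fixed, 245, 252)))
  ns <- as.integer(trimws(substr(fixed, 253, 256)))
  if (is.na(ns) || ns < 1 || is.na(ndr) || ndr < 1 ||
      is.na(hdr_bytes) || hdr_bytes != 256 * (ns + 1)) {
    stop("malformed EDF header: ", path)
  }
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  take <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, character(1))
  }
  labels <- take(0, 16)
  pmin <- as.numeric(take(ns * (16 + 80 + 8), 8))
  pmax <- as.numeric(take(ns * (16 + 80 + 8 + 8), 8))
  dmin <- as.numeric(take(ns * (16 + 80 + 8 + 8 + 8), 8))
  dmax <- as.numeric(take(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(take(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  if (length(unique(spr)) != 1) {
    stop("read_edf supports a single common sampling rate; got ",
         paste(unique(spr), collapse = ", "))
  }
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = ndr * ns * spr[1], size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) != ndr * ns * spr[1]) stop("truncated EDF data: ", path)
  arr <- array(raw, dim = c(spr[1], ns, ndr))
  data <- matrix(0, ns, ndr * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns)) {
    data[i, ] <- as.numeric(arr[, i, ]) * gain[i] + pmin[i] - dmin[i] * gain[i]
  }
  eeg_record(data, fs, channel_names = labels, record_id = record_id,
             events = events)
}
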