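# End-to-end orchestration of the three transmission branches:
#   raw        : encode -> channel -> decode -> server-side features -> detect
#   compressed : compress -> encode -> channel -> decode -> reconstruct ->
#                features -> detect
#   features   : sensor-side features -> encode -> channel -> decode -> detect

#' Simulate raw-EEG transmission of a record
#'
#' 16-bit uniform encoding of every sample at the ADC full scale, i.i.d. bit
#' flips at `ber`, decoding. Returns the record as received at the server.
#'
#' @param record an [eeg_record()].
#' @param ber bit error rate.
#' @param seed channel seed.
#' @param full_scale ADC full scale (default 32768).
#' @return an [eeg_record()] with received samples.
#' @export
transmit_raw <- function(record, ber, seed = 1, full_scale = 32768) {
  spec <- quantizer_for("raw", full_scale = full_scale)
  stream <- encode_stream(as.vector(record$data), spec)
  stream <- corrupt_stream(stream, ber, seed)
  rx <- matrix(decode_stream(stream, spec), nrow(record$data))
  out <- record
  out$data <- rx
  out
}

#' Simulate feature transmission of a record
#'
#' Applies 16-bit encoding, channel corruption and decoding to a per-epoch
#' feature matrix (one value per channel per epoch, the N:1 reduction).
#'
#' @param features `n_epochs x n_channels` matrix of clean feature values.
#' @param ber bit error rate.
#' @param seed channel seed.
#' @param spec feature [quantizer_spec()]; see [quantizer_for()] — the range
#'   is calibration metadata transmitted error-free.
#' @return received feature matrix (same shape).
#' @export
transmit_features <- function(features, ber, seed = 1, spec) {
  stream <- encode_stream(as.vector(features), spec)
  stream <- corrupt_stream(stream, ber, seed)
  matrix(decode_stream(stream, spec), nrow(features), ncol(features))
}

#' Simulate compressed-EEG transmission of a record
#'
#' Epoch-wise compressive sensing of every channel with one shared sparse
#' binary matrix, 16-bit encoding of the measurements (full scale `d` times
#' the ADC range — the exact bound for a sum of `d` samples), channel
#' corruption, decoding, and server-side reconstruction. With `cr <= 1` no
#' compression is applied and the raw path is used.
#'
#' @param record an [eeg_record()].
#' @param N epoch length in samples.
#' @param cr compression ratio `N/M` (>= 1).
#' @param ber bit error rate.
#' @param seed seed for the measurement matrix and the channel.
#' @param params reconstruction [cs_params()].
#' @param d ones per matrix column.
#' @param full_scale ADC full scale.
#' @return an [eeg_record()] whose epoch-covered samples are the
#'   reconstruction; trailing samples beyond the last complete epoch are
#'   zeroed.
#' @export
transmit_compressed <- function(record, N = 512, cr = 4, ber = 0, seed = 1,
                                params = cs_params(), d = 4,
                                full_scale = 32768) {
  if (cr <= 1) return(transmit_raw(record, ber, seed, full_scale))
  M <- cr_to_m(N, cr)
  phi <- cs_matrix(M, N, d = d, seed = substream_seed(seed, "phi"))
  n_ch <- nrow(record$data)
  n_ep <- ncol(record$data) %/% N
  if (n_ep == 0) stop("record shorter than one epoch")
  used <- seq_len(n_ep * N)
  # columns: epoch-major within channel, channels concatenated
  X <- do.call(cbind, lapply(seq_len(n_ch), function(ch) {
    matrix(record$data[ch, used], nrow = N)
  }))
  Y <- cs_compress(X, phi)
  spec <- quantizer_for("measurements", d = d, full_scale = full_scale)
  stream <- encode_stream(as.vector(Y), spec)
  stream <- corrupt_stream(stream, ber, substream_seed(seed, "chan"))
  Yrx <- matrix(decode_stream(stream, spec), M)
  rec_fit <- cs_reconstruct(Yrx, phi, params)
  out <- record
  out$data <- matrix(0, n_ch, ncol(record$data))
  for (ch in seq_len(n_ch)) {
    cols <- ((ch - 1) * n_ep + 1):(ch * n_ep)
    out$data[ch, used] <- as.vector(rec_fit$xhat[, cols])
  }
  out
}

#' Experiment configuration
#'
#' @param approaches subset of `c("raw", "compressed", "features")`.
#' @param feature extractor used for detection (default `"nlacc"`).
#' @param N_sweep epoch sizes in samples (default 512; the study also sweeps
#'   384..896).
#' @param cr_sweep compression ratios for the compressed branch (default 4).
#' @param ber_sweep bit error rates (default `c(0, 1e-5, 1e-4, 1e-3, 1e-2)`).
#' @param generator a [gen_config()] for synthetic subjects.
#' @param n_records records per subject.
#' @param classifier a [classifier_spec()].
#' @param cs a [cs_params()] for reconstruction.
#' @param w NLACC sub-window width.
#' @param seed master seed; every grid point derives its own substream.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(approaches = c("raw", "compressed", "features"),
                              feature = "nlacc", N_sweep = 512, cr_sweep = 4,
                              ber_sweep = c(0, 1e-5, 1e-4, 1e-3, 1e-2),
                              generator = gen_config(), n_records = 3,
                              classifier = classifier_spec(),
                              cs = cs_params(), w = 15, seed = 1) {
  approaches <- match.arg(approaches, c("raw", "compressed", "features"),
                          several.ok = TRUE)
  stopifnot(length(N_sweep) >= 1, length(ber_sweep) >= 1,
            length(cr_sweep) >= 1, n_records >= 2)
  structure(list(approaches = approaches, feature = feature,
                 N_sweep = N_sweep, cr_sweep = cr_sweep,
                 ber_sweep = ber_sweep, generator = generator,
                 n_records = as.integer(n_records), classifier = classifier,
                 cs = cs, w = w, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; a
#' `generator:` section mirrors [gen_config()].
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  raw$generator <- NULL
  gen <- if (is.null(gen_args)) gen_config() else do.call(gen_config, gen_args)
  do.call(experiment_config, c(raw, list(generator = gen)))
}

# received feature sets for all records under one approach / grid point
branch_feature_sets <- function(records, approach, feature, N, w, cr, ber,
                                cs_par, seed) {
  clean <- lapply(records, feature_matrix, N = N, feature = feature, w = w)
  if (approach == "features") {
    # feature full scale: calibration metadata shared for the subject
    spec <- quantizer_for("features", reference = unlist(clean))
    return(lapply(seq_along(records), function(r) {
      rx <- transmit_features(clean[[r]], ber,
                              substream_seed(seed, "feat", r), spec)
      make_feature_set(records[[r]], N, feature, w, features = rx)
    }))
  }
  lapply(seq_along(records), function(r) {
    rec_rx <- if (approach == "raw") {
      transmit_raw(records[[r]], ber, substream_seed(seed, "raw", r))
    } else {
      transmit_compressed(records[[r]], N, cr, ber,
                          seed = substream_seed(seed, "cs", r),
                          params = cs_par)
    }
    rec_rx$events <- records[[r]]$events
    make_feature_set(rec_rx, N, feature, w)
  })
}

#' Run the full transmission-strategy experiment
#'
#' Generates (or takes) one synthetic subject, then for every approach and
#' every grid point (epoch size x compression ratio x bit error rate) runs
#' the corresponding branch end-to-end, evaluates the detector with
#' leave-one-record-out cross-validation, and records the five detection
#' metrics together with per-epoch transmission byte/packet accounting.
#' Grid points that fail are logged and skipped; the run continues.
#'
#' @param config an [experiment_config()].
#' @param records optional list of [eeg_record()] overriding generation.
#' @param out_dir optional directory; when given, metrics CSV and a JSON run
#'   manifest are written there.
#' @return object of class `seizure_experiment`: `metrics` (one data.frame
#'   row per grid point), `config`, `manifest`.
#' @export
run_experiment <- function(config, records = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()["elapsed"]
  if (is.null(records)) {
    gen <- config$generator
    gen$seed <- substream_seed(config$seed, "subject")
    records <- generate_subject(gen, config$n_records)
  }
  n_ch <- nrow(records[[1]]$data)
  rows <- list()
  for (approach in config$approaches) {
    crs <- if (approach == "compressed") config$cr_sweep else 1
    for (N in config$N_sweep) {
      for (cr in crs) {
        for (ber in config$ber_sweep) {
          pt_seed <- substream_seed(config$seed, approach, N, cr, ber)
          row <- tryCatch({
            sets <- branch_feature_sets(records, approach, config$feature,
                                        N, config$w, cr, ber, config$cs,
                                        pt_seed)
            met <- loro_metrics(loro_cv(sets, config$classifier))
            M <- if (approach == "compressed" && cr > 1) cr_to_m(N, cr) else N
            payload <- bytes_per_epoch(approach, n_ch, N, M)
            acct <- packetize_account(payload)
            cbind(data.frame(approach = approach, feature = config$feature,
                             N = N, cr = cr, ber = ber,
                             bytes_per_epoch = payload,
                             packets_per_epoch = acct$n_packets,
                             air_bytes_per_epoch = acct$total_bytes),
                  as.data.frame(met))
          }, error = function(e) {
            message("grid point (", approach, ", N=", N, ", CR=", cr,
                    ", BER=", ber, ") failed: ", conditionMessage(e))
            NULL
          })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  metrics <- do.call(rbind, rows)
  manifest <- list(
    config_hash = substream_seed(config$seed, paste(deparse(config), collapse = "")),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("seizlink")),
    n_records = length(records),
    record_ids = vapply(records, `[[`, character(1), "record_id"),
    elapsed_s = unname(proc.time()["elapsed"] - t0),
    outputs = character(0)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mpath <- file.path(out_dir, "metrics.csv")
    utils::write.csv(metrics, mpath, row.names = FALSE)
    jpath <- file.path(out_dir, "manifest.json")
    manifest$outputs <- c(mpath, jpath)
    jsonlite::write_json(manifest, jpath, auto_unbox = TRUE, digits = NA)
  }
  structure(list(metrics = metrics, config = config, manifest = manifest),
            class = "seizure_experiment")
}

#' @export
print.seizure_experiment <- function(x, ...) {
  cat(sprintf("<seizure_experiment: %d grid point(s), %d record(s), seed %d>\n",
              nrow(x$metrics), x$manifest$n_records, x$manifest$seed))
  print(x$metrics[, c("approach", "N", "cr", "ber", "seizure_sensitivity",
                      "specificity", "fpr_per_hour", "air_bytes_per_epoch")],
        row.names = FALSE)
  invisible(x)
}

# windowed-sinc low-pass FIR for integer-factor decimation
decimate_lowpass <- function(x, factor, taps = 63) {
  fc <- 0.5 / factor                     # cycles/sample cutoff (Nyquist of target)
  n <- seq(-(taps - 1) / 2, (taps - 1) / 2)
  h <- 2 * fc * sinc_fun(2 * fc * n) * (0.54 + 0.46 * cos(2 * pi * n / (taps - 1)))
  h <- h / sum(h)
  y <- stats::filter(c(x, rep(0, (taps - 1) / 2)), h, sides = 2)
  y <- as.numeric(y)[((taps - 1) / 2 + 1):(length(x) + (taps - 1) / 2)]
  y[is.na(y)] <- 0
  y
}

sinc_fun <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Load a directory of EDF records with summary annotations
#'
#' Replication path for archival scalp-EEG data: reads every `.edf` file,
#' attaches seizure events from either per-record `<id>-summary.txt` files or
#' a single subject-level `*summary.txt` with one block per record, and
#' decimates to `target_fs` (anti-alias low-pass, integer factor) if needed.
#' Records without annotations are loaded with no events and flagged with a
#' warning; mismatched channel counts across records are an error.
#'
#' @param record_dir directory of EDF (+ summary text) files.
#' @param target_fs target sampling rate (default 128 Hz).
#' @return list of [eeg_record()] (possibly empty, with a warning).
#' @export
load_chbmit <- function(record_dir, target_fs = 128) {
  edfs <- sort(list.files(record_dir, "\\.edf$", full.names = TRUE))
  if (length(edfs) == 0) {
    warning("no EDF files in ", record_dir)
    return(list())
  }
  summaries <- list.files(record_dir, "summary\\.txt$", full.names = TRUE)
  subject_events <- list()
  for (s in summaries) subject_events <- c(subject_events, read_summary(s))
  records <- lapply(edfs, function(p) {
    id <- sub("\\.edf$", "", basename(p))
    rec <- read_edf(p)
    ev <- subject_events[[id]]
    if (is.null(ev)) {
      warning("no annotations found for record '", id, "'; assuming none")
      ev <- list()
    }
    rec$record_id <- id
    if (rec$fs > target_fs) {
      k <- rec$fs / target_fs
      if (k != round(k)) stop("cannot decimate ", rec$fs, " Hz to ", target_fs)
      dat <- t(apply(rec$data, 1, decimate_lowpass, factor = k))
      rec$data <- dat[, seq(1, ncol(dat), by = k), drop = FALSE]
      rec$fs <- target_fs
    }
    rec$events <- validate_events(ev, ncol(rec$data) / rec$fs)
    rec
  })
  n_ch <- vapply(records, function(r) nrow(r$data), integer(1))
  if (length(unique(n_ch)) > 1) {
    stop("mismatched channel counts across records: ",
         paste(unique(n_ch), collapse = ", "))
  }
  records
}
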