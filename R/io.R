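#' Read an EDF/EDF+ recording
#'
#' Minimal reader for the European Data Format: 256-byte ASCII global
#' header, per-signal headers, then contiguous data records of little-endian
#' 16-bit integers which are mapped to physical units via the per-signal
#' calibration fields. Channels recorded at different rates are resampled
#' to the maximum rate with a warning. Annotation streams of EDF+ files
#' (label "EDF Annotations") are skipped.
#'
#' @param path Path to the EDF file.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- hdr(8)
  if (!identical(version, "0")) stop("not an EDF file (version '", version,
                                     "'): ", path)
  hdr(80); hdr(80); hdr(8); hdr(8)             # patient, recording, date, time
  hdr(8)                                       # header bytes
  hdr(44)                                      # reserved
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header in ", path)
  field <- function(n) vapply(seq_len(ns), function(i) hdr(n), "")
  labels <- field(16)
  field(80)                                    # transducer
  field(8)                                     # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                    # prefiltering
  spr <- as.integer(field(8))                  # samples per record
  field(32)                                    # reserved
  keep <- labels != "EDF Annotations"
  sig <- lapply(seq_len(ns), function(i) numeric(0))
  raw_all <- vector("list", ns)
  for (i in seq_len(ns)) raw_all[[i]] <- matrix(0L, spr[i], n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i]) stop("truncated EDF data in ", path)
      raw_all[[i]][, r] <- v
    }
  }
  fs_all <- spr / rec_dur
  fs <- max(fs_all[keep])
  chans <- which(keep)
  out <- matrix(0, length(chans), round(n_rec * rec_dur * fs))
  for (j in seq_along(chans)) {
    i <- chans[j]
    dig <- as.numeric(raw_all[[i]])
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- (dig - dig_min[i]) * scale + phys_min[i]
    if (fs_all[i] != fs) {
      warning("channel '", labels[i], "' at ", fs_all[i],
              " Hz resampled to ", fs, " Hz")
      phys <- resample_to_250(phys, fs_all[i], fs_out = fs)
    }
    out[j, seq_along(phys)] <- phys
  }
  raw_recording(out, fs, labels[chans])
}

#' Write a recording to EDF
#'
#' Minimal single-rate EDF writer (16-bit, one-second data records),
#' the counterpart of [read_edf()]; used for fixtures and for exporting
#' synthetic data.
#'
#' @param recording A [raw_recording()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  x <- recording$samples
  fs <- recording$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("recording shorter than one data record (1 s)")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  phys_max <- max(1, ceiling(max(abs(x))))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    writeChar(formatC(s, width = -n), con, eos = NULL)
  }
  pad("0", 8); pad("X X X X", 80); pad("Startdate X X X X", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44); pad(n_rec, 8); pad("1", 8); pad(ns, 4)
  for (l in recording$channel_labels) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(-phys_max, 8)
  for (i in seq_len(ns)) pad(phys_max, 8)
  for (i in seq_len(ns)) pad(-32767, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(fs, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- x[i, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round(seg / phys_max * 32767))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an annotation CSV
#'
#' Expects the 4-column dialect `channel,start_time,stop_time,label`
#' (times in seconds from the start of the recording). Labels are
#' upper-cased; labels outside [artifact_classes()] are kept but flagged in
#' the `unknown_labels` attribute. Extra columns (as found in corpus-style
#' exports) are tolerated and dropped.
#'
#' @param path CSV path.
#' @return Data frame with columns channel, start_time, stop_time, label.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "start_time", "stop_time", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns ", paste(need, collapse = ","))
  df <- df[, need]
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      s <- suppressWarnings(as.numeric(df$start_time[i]))
      e <- suppressWarnings(as.numeric(df$stop_time[i]))
      if (is.na(s) || is.na(e))
        stop("malformed annotation at line ", i + 1, ": non-numeric time")
      if (s < 0) stop("malformed annotation at line ", i + 1,
                      ": negative start time")
      if (e <= s) stop("malformed annotation at line ", i + 1,
                       ": stop_time <= start_time")
    }
    df$start_time <- as.numeric(df$start_time)
    df$stop_time <- as.numeric(df$stop_time)
    df$label <- toupper(df$label)
  }
  unknown <- setdiff(unique(df$label), artifact_classes())
  if (length(unknown))
    warning("labels outside the class vocabulary: ",
            paste(unknown, collapse = ", "))
  attr(df, "unknown_labels") <- unknown
  df
}

#' @rdname read_annotations
#' @param annotations Data frame to write.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("channel", "start_time", "stop_time",
                                   "label")], path, row.names = FALSE)
  invisible(path)
}

#' Dataset cache
#'
#' Single-file serialized container with the layout: `signals`
#' (segments x samples), `labels`, and attributes `fs`, `duration_s`,
#' `class_vocabulary`, `snr_db`, `seed` plus a config fingerprint.
#'
#' @param dataset A `labeled_dataset`.
#' @param path Destination path.
#' @return `write_dataset_cache`: invisibly `path`;
#'   `read_dataset_cache`: the `labeled_dataset`.
#' @export
write_dataset_cache <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  obj <- list(signals = dataset$segments, labels = dataset$labels,
              attrs = list(fs = dataset$fs, duration_s = dataset$duration_s,
                           class_vocabulary = dataset$class_vocabulary,
                           snr_db = dataset$snr_db, seed = dataset$seed),
              fingerprint = config_fingerprint(list(
                fs = dataset$fs, duration_s = dataset$duration_s,
                seed = dataset$seed)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_dataset_cache
#' @export
read_dataset_cache <- function(path) {
  if (!file.exists(path)) stop("cache file not found: ", path)
  obj <- readRDS(path)
  structure(list(segments = obj$signals, labels = obj$labels,
                 class_vocabulary = obj$attrs$class_vocabulary,
                 fs = obj$attrs$fs, duration_s = obj$attrs$duration_s,
                 snr_db = obj$attrs$snr_db, seed = obj$attrs$seed),
            class = "labeled_dataset")
}

#' Export a dataset as EDF plus annotation CSV
#'
#' Concatenates all segments on a single channel and writes matching
#' interval annotations, so the preprocessing path can be exercised on
#' synthetic data end to end.
#'
#' @param dataset A `labeled_dataset`.
#' @param edf_path,csv_path Output paths.
#' @param channel Channel label to use.
#' @return Invisibly, `edf_path`.
#' @export
export_dataset_edf <- function(dataset, edf_path, csv_path,
                               channel = "FP1-F7") {
  sig <- as.numeric(t(dataset$segments))
  rec <- raw_recording(matrix(sig, nrow = 1), dataset$fs, channel)
  write_edf(rec, edf_path)
  n <- nrow(dataset$segments)
  ann <- data.frame(channel = channel,
                    start_time = (seq_len(n) - 1) * dataset$duration_s,
                    stop_time = seq_len(n) * dataset$duration_s,
                    label = dataset$labels)
  write_annotations(ann, csv_path)
  invisible(edf_path)
}

#' Run configuration
#'
#' Nested configuration with every tunable of the pipeline; round-trips
#' losslessly through JSON. Unknown keys are rejected by name.
#'
#' @param ... Overrides as nested lists, e.g.
#'   `training = list(batch_size = 16)`.
#' @return A `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    synth = list(classes = setdiff(artifact_classes(), c("SHIV", "BACKGROUND")),
                 per_class = 400L, duration_s = 4, fs = 250L, snr_db = 10,
                 seed = 0L),
    preprocess = list(seconds = 4, min_seconds = 4, resample = TRUE,
                      bandpass = TRUE, notch = TRUE, standardize = TRUE,
                      leads = default_leads()),
    tfr = list(window_len = 250L, overlap = 200L, log_scale = TRUE),
    model = unclass(model_config()),
    training = unclass(train_config()),
    provenance = list(package_version = "0.1.0", seed = 0L))
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param cfg A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- default_run_config()
  for (sec in names(raw)) {
    if (!sec %in% names(ref)) stop("unknown config section: ", sec)
    for (key in names(raw[[sec]])) {
      if (!key %in% names(ref[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      ref[[sec]][[key]] <- raw[[sec]][[key]]
    }
  }
  ref
}
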