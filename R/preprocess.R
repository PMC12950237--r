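#' Rational polyphase resampling to 250 Hz
#'
#' Resamples a signal from `fs_in` to 250 Hz by the reduced rational factor
#' L/M (125/128 for the canonical 256 Hz input): the signal is first
#' low-pass filtered at the target Nyquist, upsampled by zero insertion
#' (factor L), convolved with a Kaiser-windowed-sinc anti-aliasing low-pass,
#' and decimated by M. The convolution is evaluated in polyphase form so the
#' zero-stuffed intermediate is never materialized. Output length is
#' `round(N * L / M)`.
#'
#' @param x Numeric signal vector.
#' @param fs_in Input sampling rate in Hz (canonically 256).
#' @param fs_out Target rate in Hz (default 250).
#'
#' @return Numeric vector at `fs_out` Hz.
#' @export
resample_to_250 <- function(x, fs_in, fs_out = 250) {
  if (fs_in <= 0) stop("fs_in must be > 0")
  if (fs_out <= 0) stop("fs_out must be > 0")
  if (fs_in == fs_out) return(x)
  g <- gcd(round(fs_out), round(fs_in))
  L <- round(fs_out) / g
  M <- round(fs_in) / g
  # Pre-filter at the target Nyquist when downsampling (redundant with the
  # anti-alias FIR but keeps the two stages independently testable).
  if (fs_out < fs_in) x <- fir_lowpass_zerophase(x, fs_in, fs_out / 2)
  resample_poly(x, L, M)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

# Zero-phase FIR low-pass (Hamming windowed sinc, centered convolution).
# 81 taps keep the edge transient well inside 50 output samples at 256 Hz.
fir_lowpass_zerophase <- function(x, fs, f_cut, taps = 81L) {
  m <- (taps - 1) / 2
  k <- -m:m
  h <- 2 * f_cut / fs * sinc(2 * f_cut / fs * k) * as.numeric(signal::hamming(taps))
  h <- h / sum(h)
  centered_conv(x, h)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Linear convolution keeping the central length(x) samples (zero padding).
centered_conv <- function(x, h) {
  m <- (length(h) - 1) / 2
  y <- stats::convolve(x, rev(h), type = "open")
  y[(m + 1):(m + length(x))]
}

# filtfilt with odd-symmetric reflect padding at both ends; suppresses the
# start-up transients of the raw forward-backward pass
filtfilt_pad <- function(flt, x, fs, pad_s = 3) {
  np <- min(length(x) - 1, round(pad_s * fs))
  if (np < 2) return(signal::filtfilt(flt, x))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(np + 1):(np + length(x))]
}

# Polyphase rational resampler: upsample by L, Kaiser FIR, decimate by M.
# FIR length 10 * max(L, M) (rounded up to a multiple of 2L + 1 so the
# filter is symmetric); each polyphase branch is normalized to unit DC gain.
resample_poly <- function(x, L, M) {
  n <- length(x)
  n_out <- round(n * L / M)
  if (L == 1 && M == 1) return(x)
  half <- ceiling(10 * max(L, M) / (2 * L)) * L
  k <- -half:half                      # taps at the upsampled rate
  fc <- 1 / (2 * max(L, M))            # cutoff: the smaller Nyquist
  h <- 2 * fc * sinc(2 * fc * k) * as.numeric(signal::kaiser(length(k), 8.6))
  h <- h * L
  # normalize each polyphase branch (phase = tap index mod L) to sum 1
  phase <- ((k %% L) + L) %% L
  for (p0 in 0:(L - 1)) {
    s <- sum(h[phase == p0])
    if (abs(s) > 1e-12) h[phase == p0] <- h[phase == p0] / s
  }
  delay <- half                        # group delay at the upsampled rate
  m_idx <- 0:(n_out - 1)
  centers <- m_idx * M + delay
  j_hi <- floor(centers / L)
  y <- numeric(n_out)
  r_max <- ceiling(length(h) / L)
  for (r in 0:r_max) {
    j <- j_hi - r
    tap <- centers - j * L + 1         # 1-based tap index
    ok <- j >= 0 & j < n & tap >= 1 & tap <= length(h)
    if (!any(ok)) next
    y[ok] <- y[ok] + h[tap[ok]] * x[j[ok] + 1]
  }
  y
}

#' Band-pass filter, 0.5--80 Hz
#'
#' Zero-phase Butterworth band-pass implemented as a cascade of an order-4
#' high-pass at 0.5 Hz and an order-4 low-pass at 80 Hz, each applied
#' forward--backward with [signal::filtfilt] (effective order 8, zero phase
#' distortion).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must exceed 160 so 80 Hz is below Nyquist.
#'
#' @return Filtered signal, same length.
#' @export
bandpass_0p5_80 <- function(x, fs) {
  if (fs <= 160) stop("fs must be > 160 (80 Hz must be below Nyquist)")
  hp <- signal::butter(4, 0.5 / (fs / 2), type = "high")
  lp <- signal::butter(4, 80 / (fs / 2), type = "low")
  filtfilt_pad(lp, filtfilt_pad(hp, x, fs), fs)
}

#' 50 Hz notch filter
#'
#' Second-order IIR notch at 50 Hz with quality factor `q`, applied
#' zero-phase (forward--backward).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (> 100).
#' @param q Quality factor (default 30).
#'
#' @return Filtered signal, same length.
#' @export
notch_50 <- function(x, fs, q = 30) {
  if (fs <= 100) stop("fs must be > 100 (50 Hz must be below Nyquist)")
  w0 <- 2 * pi * 50 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  filtfilt_pad(flt, x, fs)
}

#' A raw multi-channel recording
#'
#' @param samples Channels x time numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of electrode-pair names (bipolar
#'   montage), one per row of `samples`.
#'
#' @return A `raw_recording` list.
#' @export
raw_recording <- function(samples, fs, channel_labels) {
  samples <- as.matrix(samples)
  if (fs <= 0) stop("fs must be > 0")
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per row required")
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "raw_recording")
}

#' Extract annotated artifact intervals from a recording
#'
#' Returns, for each annotation of duration at least `min_seconds`, the
#' corresponding per-channel sample span. Sample indexing is 0-based and
#' half-open: span = `[floor(start_s * fs), floor(stop_s * fs))`.
#' Annotations referencing channels absent from the recording are skipped
#' with a warning.
#'
#' @param recording A [raw_recording()].
#' @param annotations Data frame with columns `channel`, `start_time`,
#'   `stop_time`, `label` (times in seconds), as returned by
#'   [read_annotations()].
#' @param min_seconds Minimum annotation duration to keep (default 4).
#'
#' @return List of elements, each with `signal`, `label`, `channel`,
#'   `start_s`, `stop_s`.
#' @export
extract_labeled_intervals <- function(recording, annotations,
                                      min_seconds = 4) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (a$stop_time - a$start_time < min_seconds) next
    ch <- match(a$channel, recording$channel_labels)
    if (is.na(ch)) {
      warning("annotation ", i, " references missing channel '", a$channel,
              "'; skipped")
      next
    }
    i0 <- floor(a$start_time * fs)       # 0-based, half-open
    i1 <- floor(a$stop_time * fs)
    i1 <- min(i1, ncol(recording$samples))
    if (i1 - i0 < 1) next
    out[[length(out) + 1]] <- list(
      signal = recording$samples[ch, (i0 + 1):i1],
      label = toupper(a$label), channel = a$channel,
      start_s = a$start_time, stop_s = a$stop_time)
  }
  out
}

#' Split a signal into fixed-length non-overlapping segments
#'
#' Consecutive windows of exactly `seconds * fs` samples from the start of
#' the signal; any trailing remainder is dropped.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param seconds Window length in seconds (1, 2, 4 or 5 in the reference
#'   protocol; any positive value giving at least one sample is accepted).
#'
#' @return List of numeric vectors, each of length `seconds * fs`.
#' @export
segment_signal <- function(x, fs, seconds = 4) {
  win <- floor(seconds * fs)
  if (win < 1) stop("seconds * fs must be >= 1")
  k <- floor(length(x) / win)
  lapply(seq_len(k), function(i) x[((i - 1) * win + 1):(i * win)])
}

#' Per-segment z-score standardization
#'
#' Subtracts the mean and divides by the standard deviation (guarded below
#' `1e-8`). Applied after segmentation; on by default throughout the
#' training pipeline because unscaled microvolt inputs destabilize
#' optimization.
#'
#' @param x Numeric segment.
#' @return Standardized segment.
#' @export
zscore_segment <- function(x) {
  (x - mean(x)) / max(stats::sd(x), 1e-8)
}

#' Default frontal / fronto-temporal lead set
#'
#' The bipolar leads used for automatism-style artifact extraction.
#' @return Character vector.
#' @export
default_leads <- function() c("FP1-F7", "FP2-F8", "FP1-F3", "FP2-F4")

#' Full preprocessing pipeline for one recording
#'
#' Order-fixed composition: resample to 250 Hz, 0.5--80 Hz band-pass, 50 Hz
#' notch, annotation-driven interval extraction, fixed-length segmentation
#' and (optionally) per-segment z-scoring. Each filtering stage can be
#' switched off.
#'
#' @param recording A [raw_recording()].
#' @param annotations Annotation data frame (see
#'   [extract_labeled_intervals()]).
#' @param seconds Segment length in seconds.
#' @param min_seconds Minimum annotation duration.
#' @param leads Restrict to these channel labels (`NULL` = all).
#' @param resample,bandpass,notch,standardize Stage switches.
#'
#' @return A `labeled_dataset` (see [generate_dataset()]) at 250 Hz.
#' @export
preprocess_recording <- function(recording, annotations, seconds = 4,
                                 min_seconds = 4, leads = NULL,
                                 resample = TRUE, bandpass = TRUE,
                                 notch = TRUE, standardize = TRUE) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  samples <- recording$samples
  if (!is.null(leads)) {
    keep <- recording$channel_labels %in% leads
    samples <- samples[keep, , drop = FALSE]
    recording <- raw_recording(samples, fs, recording$channel_labels[keep])
  }
  target_fs <- if (resample) 250 else fs
  proc <- matrix(0, nrow = nrow(recording$samples),
                 ncol = if (resample)
                   round(ncol(recording$samples) * 250 / fs)
                 else ncol(recording$samples))
  for (ch in seq_len(nrow(recording$samples))) {
    y <- recording$samples[ch, ]
    if (resample && fs != 250) y <- resample_to_250(y, fs)
    if (bandpass) y <- bandpass_0p5_80(y, target_fs)
    if (notch) y <- notch_50(y, target_fs)
    if (any(!is.finite(y))) stop("non-finite values after filtering channel ",
                                 recording$channel_labels[ch])
    proc[ch, seq_along(y)] <- y
  }
  rec250 <- raw_recording(proc, target_fs, recording$channel_labels)
  spans <- extract_labeled_intervals(rec250, annotations, min_seconds)
  segs <- list(); labs <- character(0)
  for (sp in spans) {
    for (w in segment_signal(sp$signal, target_fs, seconds)) {
      segs[[length(segs) + 1]] <- if (standardize) zscore_segment(w) else w
      labs <- c(labs, sp$label)
    }
  }
  seg_mat <- if (length(segs)) do.call(rbind, segs) else
    matrix(0, 0, floor(seconds * target_fs))
  structure(list(segments = seg_mat, labels = labs,
                 class_vocabulary = sort(unique(labs)), fs = target_fs,
                 duration_s = seconds, snr_db = NA_real_, seed = NA_integer_),
            class = "labeled_dataset")
}
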