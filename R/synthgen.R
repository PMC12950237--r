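#' @useDynLib eegartifacts, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Supported artifact class vocabulary
#'
#' The seven artifact classes plus \code{"BACKGROUND"} (artifact-free EEG).
#' \code{EYEM} eye movement, \code{BLINK} stereotyped blinking, \code{CHEW}
#' ordinary chewing, \code{RC} rhythmic (ictal automatism) chewing,
#' \code{MUSC} sustained muscle activity, \code{ELEC} electrode faults,
#' \code{SHIV} shivering.
#'
#' @return Character vector of class labels.
#' @export
artifact_classes <- function() {
  c("CHEW", "MUSC", "ELEC", "EYEM", "SHIV", "RC", "BLINK", "BACKGROUND")
}

# Default event/burst repetition rate (Hz) per class.
default_rate_hz <- function(class_label) {
  switch(class_label,
    EYEM = 1.0, BLINK = 2.0, CHEW = 1.5, RC = 2.0, SHIV = 1.0,
    0)
}

# Nominal peak amplitudes in microvolts (free parameters of the generator).
default_amplitude_uv <- function(class_label) {
  switch(class_label,
    EYEM = 150, BLINK = 150, CHEW = 80, RC = 80, MUSC = 80,
    ELEC = 300, SHIV = 60, BACKGROUND = 15,
    stop("unknown class label: ", class_label))
}

#' Parameters for one synthetic EEG segment
#'
#' @param class_label One of [artifact_classes()].
#' @param duration_s Segment duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (> 0).
#' @param snr_db Artifact-to-background power ratio in dB.
#' @param rate_hz Event/burst repetition rate in Hz; `NULL` uses the
#'   class-specific default.
#' @param amplitude_uv Nominal peak amplitude in microvolts; `NULL` uses the
#'   class default.
#' @param seed Integer random seed; identical parameters (including seed)
#'   yield bit-identical segments.
#'
#' @return A `synth_params` list.
#' @export
synth_params <- function(class_label, duration_s = 4, fs = 250, snr_db = 10,
                         rate_hz = NULL, amplitude_uv = NULL, seed = 0L) {
  class_label <- toupper(class_label)
  if (!class_label %in% artifact_classes())
    stop("unknown class label: ", class_label)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  if (is.null(rate_hz)) rate_hz <- default_rate_hz(class_label)
  if (rate_hz < 0) stop("rate_hz must be >= 0")
  if (is.null(amplitude_uv)) amplitude_uv <- default_amplitude_uv(class_label)
  structure(list(class_label = class_label, duration_s = duration_s, fs = fs,
                 snr_db = snr_db, rate_hz = rate_hz,
                 amplitude_uv = amplitude_uv, seed = as.integer(seed)),
            class = "synth_params")
}

#' Synthetic background EEG (1/f noise plus alpha rhythm)
#'
#' Pink (1/f power) noise with an optional 8--12 Hz oscillatory component,
#' standardized to zero mean and unit variance.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling frequency in Hz.
#' @param alpha_power Fraction of total power assigned to the 8--12 Hz band
#'   component (0 = pure pink noise).
#' @param seed Integer seed.
#'
#' @return Numeric vector of `duration_s * fs` samples.
#' @export
background_eeg <- function(duration_s, fs, alpha_power = 0.3, seed = 0L) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  n <- floor(duration_s * fs)
  if (n < 1) stop("duration_s * fs must be >= 1")
  with_seed(seed, {
    pink <- spectral_noise(n, fs, function(f) 1 / pmax(f, fs / n))
    alpha <- spectral_noise(n, fs, function(f) as.numeric(f >= 8 & f <= 12))
    x <- sqrt(max(1 - alpha_power, 0)) * standardize(pink)
    if (alpha_power > 0) x <- x + sqrt(alpha_power) * standardize(alpha)
    standardize(x)
  })
}

# Gaussian noise with power spectral density shaped by psd_fun(f);
# constructed in the frequency domain so the spectrum is exact.
spectral_noise <- function(n, fs, psd_fun) {
  nfft <- n
  f <- seq(0, fs / 2, length.out = floor(nfft / 2) + 1)
  gain <- sqrt(pmax(psd_fun(f), 0))
  gain[1] <- 0 # no DC
  # Hermitian-symmetric spectrum from white Gaussian half-spectrum
  half <- complex(real = stats::rnorm(length(f)),
                  imaginary = stats::rnorm(length(f))) * gain
  half[1] <- 0
  if (nfft %% 2 == 0) half[length(half)] <- complex(real = Re(half[length(half)]))
  spec <- c(half, Conj(rev(half[2:(length(half) - (1 - nfft %% 2))])))
  Re(stats::fft(spec, inverse = TRUE)) / nfft
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(x - mean(x))
  (x - mean(x)) / s
}

# Evaluate expr with a temporary, restorable RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate one labeled synthetic artifact segment
#'
#' Produces a single-channel waveform whose temporal and spectral morphology
#' follows the class taxonomy: slow 0.5--2 Hz half-sine deflections (EYEM),
#' stereotyped biphasic blink transients in 1--3 Hz trains (BLINK), 20--60 Hz
#' EMG bursts with jittered (CHEW) or strictly periodic (RC) onsets,
#' sustained broadband 20--80 Hz muscle noise (MUSC), electrode
#' steps/pops/dropouts (ELEC) and ~10 Hz shiver bursts (SHIV), superimposed
#' on 1/f background EEG at the requested signal-to-background ratio.
#'
#' @param params A [synth_params()] object.
#'
#' @return Numeric vector of `duration_s * fs` samples (nominal microvolts)
#'   with attributes `label` and `fs`.
#' @export
generate_artifact_segment <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  n <- floor(p$duration_s * p$fs)
  bg_rms <- default_amplitude_uv("BACKGROUND")
  bg <- background_eeg(p$duration_s, p$fs, alpha_power = 0.3,
                       seed = p$seed) * bg_rms
  x <- with_seed(p$seed + 1L, {
    if (p$class_label == "BACKGROUND") {
      bg
    } else if (p$class_label == "ELEC") {
      # Electrode faults transform the trace rather than adding to it.
      elec_artifact(bg, n, p)
    } else {
      art <- switch(p$class_label,
        EYEM = eyem_wave(n, p),
        BLINK = blink_wave(n, p),
        CHEW = emg_bursts(n, p, jitter_frac = 0.30),
        RC = emg_bursts(n, p, jitter_frac = 0.00),
        MUSC = band_noise(n, p$fs, 20, 80),
        SHIV = shiver_wave(n, p))
      bg + scale_to_snr(art, bg, p$snr_db)
    }
  })
  attr(x, "label") <- p$class_label
  attr(x, "fs") <- p$fs
  x
}

scale_to_snr <- function(art, bg, snr_db) {
  pa <- mean(art^2)
  if (pa < 1e-20) return(art)
  art * sqrt(mean(bg^2) / pa * 10^(snr_db / 10))
}

# 0.5-2 Hz half-sine deflections with random polarity and short gaps.
eyem_wave <- function(n, p) {
  fs <- p$fs
  x <- numeric(n)
  i <- 1 + floor(stats::runif(1, 0, 0.2) * fs)
  while (i <= n) {
    f <- stats::runif(1, 0.5, 2)           # deflection = half period at f
    len <- max(3L, round(fs / (2 * f)))
    idx <- i:min(n, i + len - 1)
    x[idx] <- sample(c(-1, 1), 1) * p$amplitude_uv *
      sin(pi * (seq_along(idx) - 1) / (len - 1))
    i <- i + len + floor(stats::runif(1, 0.05, 0.3) * fs)
  }
  x
}

# Stereotyped biphasic transient (200-400 ms) repeated in a 1-3 Hz train.
blink_wave <- function(n, p) {
  fs <- p$fs
  rate <- min(max(p$rate_hz, 1), 3)
  dur <- stats::runif(1, 0.2, 0.4)         # one duration, stereotyped train
  len <- max(5L, round(dur * fs))
  t <- seq(0, 1, length.out = len)
  proto <- sin(2 * pi * t) * exp(-3 * t)   # biphasic, decaying
  proto <- proto / max(abs(proto)) * p$amplitude_uv
  x <- numeric(n)
  onsets <- round(seq(from = stats::runif(1, 0, 0.2) * fs, to = n - len,
                      by = fs / rate))
  for (o in onsets[onsets >= 0]) {
    idx <- (o + 1):min(n, o + len)
    x[idx] <- x[idx] + proto[seq_along(idx)]
  }
  x
}

# 20-60 Hz band-limited EMG bursts; onset jitter distinguishes CHEW from RC.
emg_bursts <- function(n, p, jitter_frac) {
  fs <- p$fs
  rate <- if (p$rate_hz > 0) p$rate_hz else 1.5
  period <- fs / rate
  burst_len <- max(5L, round(0.3 * fs))
  carrier <- band_noise(n, fs, 20, 60)
  env <- numeric(n)
  k <- 0
  repeat {
    onset <- round(k * period +
                     stats::runif(1, -jitter_frac, jitter_frac) * period)
    if (onset > n - 2) break
    idx <- max(1, onset + 1):min(n, onset + burst_len)
    w <- sin(pi * (seq_along(idx) - 0.5) / burst_len)^2 # smooth burst window
    env[idx] <- pmax(env[idx], w)
    k <- k + 1
  }
  carrier * env
}

# Gaussian noise band-limited to [f_lo, f_hi] via exact spectral masking.
band_noise <- function(n, fs, f_lo, f_hi) {
  spectral_noise(n, fs, function(f) as.numeric(f >= f_lo & f <= f_hi))
}

# ~10 Hz sinusoidal bursts over the background.
shiver_wave <- function(n, p) {
  fs <- p$fs
  f0 <- stats::runif(1, 9, 11)
  rate <- if (p$rate_hz > 0) p$rate_hz else 1
  period <- fs / rate
  burst_len <- max(5L, round(0.5 * fs))
  env <- numeric(n)
  k <- 0
  repeat {
    onset <- round(k * period)
    if (onset > n - 2) break
    idx <- (onset + 1):min(n, onset + burst_len)
    env[idx] <- pmax(env[idx], sin(pi * (seq_along(idx) - 0.5) / burst_len)^2)
    k <- k + 1
  }
  sin(2 * pi * f0 * (0:(n - 1)) / fs + stats::runif(1, 0, 2 * pi)) * env
}

# Electrode artifact: step, pop (impulses), or flat-line dropout.
elec_artifact <- function(bg, n, p) {
  subtype <- sample(c("step", "pop", "dropout"), 1)
  a <- p$amplitude_uv
  if (subtype == "step") {
    at <- floor(stats::runif(1, 0.2, 0.8) * n)
    bg + c(numeric(at), rep(sample(c(-a, a), 1), n - at))
  } else if (subtype == "pop") {
    k <- sample(2:5, 1)
    at <- sort(sample.int(n - 3, k))
    x <- bg
    for (i in at) {
      w <- sample(2:5, 1)
      idx <- i:min(n, i + w - 1)
      x[idx] <- x[idx] + sample(c(-a, a), 1) * exp(-(seq_along(idx) - 1))
    }
    x
  } else {
    i0 <- floor(stats::runif(1, 0.1, 0.5) * n)
    len <- floor(stats::runif(1, 0.3, 0.5) * n)
    x <- bg
    x[i0:min(n, i0 + len)] <- x[i0] * 0.01
    x
  }
}

#' Generate a labeled synthetic dataset
#'
#' Deterministically generates `class_counts[l]` segments for every requested
#' class. Per-segment seeds are derived by hashing the master seed with the
#' class and the within-class index, so a subset of classes or indices is
#' reproducible independently of the rest.
#'
#' @param class_counts Named integer vector, e.g. `c(CHEW = 400, MUSC = 400)`.
#' @param duration_s,fs,snr_db,seed As in [synth_params()].
#'
#' @return A `labeled_dataset` list with elements `segments`
#'   (matrix, segments x samples), `labels` (character), `class_vocabulary`
#'   (ordered labels defining the integer encoding), `fs`, `duration_s`,
#'   `snr_db` and `seed`.
#' @export
generate_dataset <- function(class_counts, duration_s = 4, fs = 250,
                             snr_db = 10, seed = 0L) {
  labs <- names(class_counts)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("class_counts must be a named vector")
  labs <- toupper(labs)
  bad <- setdiff(labs, artifact_classes())
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  n_samp <- floor(duration_s * fs)
  total <- sum(class_counts)
  segments <- matrix(0, nrow = total, ncol = n_samp)
  labels <- character(total)
  row <- 1L
  for (ci in seq_along(labs)) {
    class_id <- match(labs[ci], artifact_classes())
    for (idx in seq_len(class_counts[ci])) {
      p <- synth_params(labs[ci], duration_s, fs, snr_db,
                        seed = segment_seed(seed, class_id, idx))
      segments[row, ] <- generate_artifact_segment(p)
      labels[row] <- labs[ci]
      row <- row + 1L
    }
  }
  structure(list(segments = segments, labels = labels,
                 class_vocabulary = labs, fs = fs, duration_s = duration_s,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "labeled_dataset")
}

# Order-stable per-segment seed: integer hash of (master, class, index),
# kept in [0, 2^31).
segment_seed <- function(master, class_index, index) {
  h <- (as.double(master) %% 2147483647) * 2654435761
  h <- (h + class_index * 40503 + index * 2654435769) %% 2147483647
  as.integer(h)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d segments x %d samples @%g Hz (%g s)\n",
              nrow(x$segments), ncol(x$segments), x$fs, x$duration_s))
  print(table(factor(x$labels, levels = x$class_vocabulary)))
  invisible(x)
}
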