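#' STFT magnitude spectrogram of a segment
#'
#' Hamming-windowed, one-sided short-time Fourier transform with window
#' length `window_len` samples and hop `window_len - overlap`. No centering
#' or padding is applied, so a segment of `L` samples yields exactly
#' `floor((L - window_len) / (window_len - overlap)) + 1` frames and
#' `window_len / 2 + 1` frequency bins. With `log_scale`, magnitudes are
#' compressed as `log(1 + |X|)` (standard for spectrogram-CNN inputs).
#'
#' The canonical configuration (250-sample Hamming window, overlap 200,
#' 4 s segment at 250 Hz) gives a 126 x 16 spectrogram with 1 Hz bin
#' spacing.
#'
#' @param x Numeric segment (length >= `window_len`).
#' @param fs Sampling rate in Hz.
#' @param window_len Window length in samples (default 250).
#' @param overlap Overlap between consecutive windows in samples
#'   (default 200; must be < `window_len`).
#' @param log_scale Apply `log(1 + magnitude)` compression (default TRUE).
#'
#' @return A `spectrogram` object: list with `values` (bins x frames,
#'   non-negative before the optional log), `freq_axis` (Hz), `time_axis`
#'   (seconds, frame centers), `window_len`, `overlap`, `fs`.
#' @export
stft_spectrogram <- function(x, fs = 250, window_len = 250L, overlap = 200L,
                             log_scale = TRUE) {
  window_len <- as.integer(window_len)
  overlap <- as.integer(overlap)
  if (overlap >= window_len) stop("overlap must be < window_len")
  L <- length(x)
  if (L < window_len)
    stop("segment length (", L, ") shorter than window_len (", window_len, ")")
  hop <- window_len - overlap
  n_frames <- (L - window_len) %/% hop + 1L
  n_bins <- window_len %/% 2L + 1L
  w <- as.numeric(signal::hamming(window_len))
  vals <- matrix(0, n_bins, n_frames)
  for (j in seq_len(n_frames)) {
    seg <- x[((j - 1L) * hop + 1L):((j - 1L) * hop + window_len)]
    vals[, j] <- Mod(stats::fft(seg * w)[1:n_bins])
  }
  if (log_scale) vals <- log1p(vals)
  structure(list(values = vals,
                 freq_axis = (0:(n_bins - 1L)) * fs / window_len,
                 time_axis = ((seq_len(n_frames) - 1L) * hop +
                                window_len / 2) / fs,
                 window_len = window_len, overlap = overlap, fs = fs),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames, 0-%g Hz, window %d/overlap %d\n",
              nrow(x$values), ncol(x$values), max(x$freq_axis),
              x$window_len, x$overlap))
  invisible(x)
}

#' Write spectrograms to CSV for inspection
#'
#' One CSV per segment (`spectrogram_<i>.csv`, bins x frames).
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if needed).
#' @param ... Passed to [stft_spectrogram()].
#' @return Invisibly, the file paths written.
#' @export
dump_spectrograms <- function(dataset, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(dataset$segments))
  for (i in seq_len(nrow(dataset$segments))) {
    sp <- stft_spectrogram(dataset$segments[i, ], fs = dataset$fs, ...)
    paths[i] <- file.path(dir, sprintf("spectrogram_%04d.csv", i))
    utils::write.table(sp$values, paths[i], sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
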