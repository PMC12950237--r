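# Independent oracles used across the suite. These are deliberately written
# from first principles (plain FFTs, floor arithmetic, brute-force counting)
# so they never share code with the implementation they check.

rms <- function(x) sqrt(mean(x^2))

# Welch power spectral density via averaged Hamming-windowed periodograms.
oracle_welch <- function(x, fs, nfft = 256) {
  nfft <- min(nfft, length(x))
  hop <- floor(nfft / 2)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  p <- rowMeans(vapply(starts, function(s) {
    seg <- x[s:(s + nfft - 1)] * win
    Mod(stats::fft(seg)[1:(nfft / 2 + 1)])^2
  }, numeric(nfft / 2 + 1)))
  list(freq = (0:(nfft / 2)) * fs / nfft, power = p)
}

# Fraction of total (non-DC) Welch power inside [f_lo, f_hi].
oracle_band_fraction <- function(x, fs, f_lo, f_hi) {
  w <- oracle_welch(x, fs)
  keep <- w$freq > 0
  sum(w$power[keep & w$freq >= f_lo & w$freq <= f_hi]) / sum(w$power[keep])
}

# Log-log slope of the Welch PSD over [f_lo, f_hi] by least squares.
oracle_psd_slope <- function(x, fs, f_lo = 1, f_hi = 40) {
  w <- oracle_welch(x, fs, nfft = 512)
  keep <- w$freq >= f_lo & w$freq <= f_hi
  unname(stats::coef(stats::lm(log(w$power[keep]) ~ log(w$freq[keep])))[2])
}

# Smoothed rectified envelope (moving average of |x|, 100 ms window).
oracle_envelope <- function(x, fs) {
  k <- max(1, round(0.1 * fs))
  as.numeric(stats::filter(abs(x), rep(1 / k, k), sides = 2))
}

# Lag (s) of the maximum envelope autocorrelation in [min_lag, max_lag].
oracle_env_acf_peak <- function(x, fs, min_lag = 0.25, max_lag = 1.0) {
  env <- oracle_envelope(x, fs)
  env <- env[!is.na(env)]
  a <- stats::acf(env, lag.max = round(max_lag * fs), plot = FALSE)$acf[, 1, 1]
  lags <- (seq_along(a) - 1) / fs
  keep <- lags >= min_lag
  lags[keep][which.max(a[keep])]
}

# Height of the max envelope autocorrelation in a lag window.
oracle_env_acf_height <- function(x, fs, min_lag = 0.25, max_lag = 1.0) {
  env <- oracle_envelope(x, fs)
  env <- env[!is.na(env)]
  a <- stats::acf(env, lag.max = round(max_lag * fs), plot = FALSE)$acf[, 1, 1]
  lags <- (seq_along(a) - 1) / fs
  max(a[lags >= min_lag])
}

# Rule-based artifact classifier built only on the band-power / envelope /
# discontinuity signatures that define the synthetic taxonomy. Used to show
# the generated classes are separable (hence learnable).
oracle_classify_segment <- function(x, fs) {
  dx <- diff(x)
  jump <- max(abs(dx)) / (stats::median(abs(dx)) + 1e-12)
  win <- max(2, round(0.3 * fs))
  nwin <- floor(length(x) / win)
  roll_sd <- vapply(seq_len(nwin), function(i)
    stats::sd(x[((i - 1) * win + 1):(i * win)]), 0)
  if (jump > 40 || min(roll_sd) < 0.02 * stats::sd(x)) return("ELEC")
  f_alpha <- oracle_band_fraction(x, fs, 8, 12)
  f_hi <- oracle_band_fraction(x, fs, 20, 80)
  f_lo <- oracle_band_fraction(x, fs, 0.5, 4)
  if (f_alpha > 0.40) return("SHIV")
  if (f_hi > 0.45) {
    env <- oracle_envelope(x, fs)
    env <- env[!is.na(env)]
    if (stats::sd(env) / mean(env) < 0.35) return("MUSC")
    return(if (oracle_env_acf_height(x, fs) > 0.5) "RC" else "CHEW")
  }
  if (f_lo > 0.30) {
    # blink trains are periodic transients; eye movements are aperiodic
    return(if (oracle_env_acf_height(x, fs) > 0.6) "BLINK" else "EYEM")
  }
  "BACKGROUND"
}

# Per-stage floor arithmetic for the conv chains (independent shape oracle).
oracle_out_len <- function(n, k, s) floor((n - k) / s) + 1

oracle_td_chain <- function(L) {
  t0 <- oracle_out_len(L, 8, 4)
  t0p <- oracle_out_len(t0, 4, 2)
  t1c <- oracle_out_len(t0p, 4, 2)
  T <- oracle_out_len(t1c, 2, 1)
  list(T = T, T1 = T - 2, T3 = 2 * T + (T - 2))
}

oracle_tfd_chain <- function(bins, frames) {
  h1 <- bins; w1 <- oracle_out_len(frames, 3, 1)      # conv (1,3)
  h2 <- h1 - 1; w2 <- w1 - 1                          # pool (2,2) s1
  h3 <- oracle_out_len(h2, 3, 1); w3 <- w2            # conv (3,1)
  hout <- h3 - 1; wout <- w3 - 1                      # pool (2,2) s1
  t2 <- (hout - 2) * (wout - 2)                       # conv (3,3)
  list(Hout = hout, Wout = wout, HW = hout * wout, T2 = t2,
       T4 = 2 * hout * wout + t2)
}

# small labeled dataset shared by trainer tests (two pure tones + noise)
make_tone_dataset <- function(n_per_class = 20, seconds = 4, fs = 250,
                              freqs = c(5, 40), seed = 42) {
  n <- seconds * fs
  set.seed(seed)
  labs <- rep(c("A", "B"), each = n_per_class)
  t <- (0:(n - 1)) / fs
  segs <- t(vapply(seq_along(labs), function(i) {
    f <- freqs[1 + (labs[i] == "B")]
    sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) +
      0.3 * stats::rnorm(n)
  }, numeric(n)))
  structure(list(segments = segs, labels = labs,
                 class_vocabulary = c("A", "B"), fs = fs,
                 duration_s = seconds, snr_db = NA, seed = seed),
            class = "labeled_dataset")
}
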