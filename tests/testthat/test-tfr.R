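test_that("canonical 4 s configuration yields a 126 x 16 spectrogram", {
  sp <- stft_spectrogram(stats::rnorm(1000), fs = 250)
  expect_equal(dim(sp$values), c(126, 16))
  expect_equal(sp$freq_axis[1], 0)
  expect_equal(sp$freq_axis[2] - sp$freq_axis[1], 1)  # fs/window = 1 Hz
  expect_equal(max(sp$freq_axis), 125)
  expect_true(all(diff(sp$freq_axis) > 0))
})

test_that("zero input gives a zero magnitude spectrogram", {
  sp <- stft_spectrogram(numeric(1000), fs = 250, log_scale = FALSE)
  expect_true(all(sp$values == 0))
})

test_that("a 10 Hz tone peaks at the 10 Hz bin in every frame", {
  t <- (0:999) / 250
  sp <- stft_spectrogram(sin(2 * pi * 10 * t), fs = 250, log_scale = FALSE)
  peaks <- apply(sp$values, 2, which.max)
  expect_true(all(sp$freq_axis[peaks] == 10))
})

test_that("frame count follows the floor law for many lengths", {
  for (L in c(250, 251, 300, 500, 999, 1000, 1250)) {
    sp <- stft_spectrogram(stats::rnorm(L), fs = 250)
    expect_equal(ncol(sp$values), (L - 250) %/% 50 + 1, info = paste("L =", L))
    expect_equal(nrow(sp$values), 126)
  }
  expect_error(stft_spectrogram(stats::rnorm(100), fs = 250), "shorter")
  expect_error(stft_spectrogram(stats::rnorm(1000), overlap = 250),
               "overlap")
})

test_that("magnitudes are non-negative and monotone under input scaling", {
  x <- stats::rnorm(1000)
  a <- stft_spectrogram(x, fs = 250, log_scale = FALSE)$values
  b <- stft_spectrogram(3 * x, fs = 250, log_scale = FALSE)$values
  expect_true(all(a >= 0))
  expect_true(all(b >= a - 1e-12))
})

test_that("magnitudes agree with an independent windowed-FFT oracle", {
  set.seed(9)
  x <- stats::rnorm(600)
  sp <- stft_spectrogram(x, fs = 250, log_scale = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:249) / 249)     # Hamming, symmetric
  for (j in seq_len(ncol(sp$values))) {
    seg <- x[((j - 1) * 50 + 1):((j - 1) * 50 + 250)]
    ref <- Mod(stats::fft(seg * w)[1:126])
    expect_equal(sp$values[, j], ref, tolerance = 1e-12)
  }
  # and with the signal package's spectrogram on the shared grid (specgram
  # drops the Nyquist bin and counts trailing frames differently)
  sg <- signal::specgram(x, n = 250, Fs = 250, window = signal::hamming(250),
                         overlap = 200)
  M <- Mod(sg$S)
  expect_equal(M, sp$values[seq_len(nrow(M)), seq_len(ncol(M))],
               tolerance = 1e-10, ignore_attr = TRUE)
})
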