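test_that("rational resampler honours the 125/128 length law and passes DC", {
  x <- rep(1, 2560)
  y <- resample_to_250(x, 256)
  expect_length(y, 2500)                      # round(N * 125/128)
  core <- y[51:(length(y) - 50)]
  expect_lt(max(abs(core - 1)), 1e-6)         # unity DC gain
  expect_error(resample_to_250(x, -1), "fs_in")
})

test_that("resampling preserves a 10 Hz tone's frequency", {
  t <- (0:(2560 * 4 - 1)) / 256               # 40 s at 256 Hz
  x <- sin(2 * pi * 10 * t)
  y <- resample_to_250(x, 256)
  spec <- Mod(stats::fft(y))[1:(length(y) / 2)]
  f_peak <- (which.max(spec) - 1) * 250 / length(y)
  expect_lt(abs(f_peak - 10), 0.1)
  # amplitude essentially preserved in the pass-band
  expect_equal(stats::sd(y), stats::sd(x), tolerance = 0.02)
})

test_that("band-pass keeps 10 Hz, removes DC, attenuates 100 Hz by 20 dB", {
  fs <- 250
  t <- (0:(fs * 8 - 1)) / fs
  mid <- (fs * 2):(fs * 6)          # steady-state portion
  tone10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_0p5_80(tone10, fs)
  gain_db <- 20 * log10(rms(y10[mid]) / rms(tone10[mid]))
  expect_lt(abs(gain_db), 1)
  ydc <- bandpass_0p5_80(rep(5, fs * 8), fs)
  expect_lt(abs(mean(ydc)), 0.05)
  tone100 <- sin(2 * pi * 100 * t)
  y100 <- bandpass_0p5_80(tone100, fs)
  att_db <- -20 * log10(rms(y100[mid]) / rms(tone100[mid]))
  expect_gte(att_db, 20)
  expect_error(bandpass_0p5_80(tone10, 120), "fs")
})

test_that("notch removes 50 Hz, spares 10 Hz, and is linear at zero", {
  fs <- 250
  t <- (0:(fs * 8 - 1)) / fs
  mid <- (fs * 2):(fs * 6)
  tone50 <- sin(2 * pi * 50 * t)
  y50 <- notch_50(tone50, fs)
  att_db <- -20 * log10(rms(y50[mid]) / rms(tone50[mid]))
  expect_gte(att_db, 30)
  tone10 <- sin(2 * pi * 10 * t)
  y10 <- notch_50(tone10, fs)
  expect_lt(abs(20 * log10(rms(y10[mid]) / rms(tone10[mid]))), 1)
  expect_equal(notch_50(numeric(500), fs), numeric(500))
  expect_error(notch_50(tone10, 90), "fs")
})

test_that("interval extraction applies the duration threshold and indexing", {
  rec <- raw_recording(matrix(seq_len(5000), nrow = 2, byrow = TRUE),
                       fs = 250, channel_labels = c("FP1-F7", "FP2-F8"))
  ann <- data.frame(channel = c("FP1-F7", "FP2-F8", "FP1-F7"),
                    start_time = c(2.0, 1.0, 0.0),
                    stop_time = c(9.0, 4.5, 6.0),
                    label = c("chew", "musc", "eyem"))
  got <- extract_labeled_intervals(rec, ann, min_seconds = 4)
  expect_length(got, 2)                       # 3.5 s interval dropped
  expect_length(got[[1]]$signal, 1750)        # (9-2) * 250
  expect_equal(got[[1]]$label, "CHEW")
  expect_equal(got[[1]]$signal[1], rec$samples[1, 501])  # floor(2*250), 0-based
  expect_equal(vapply(got, function(g) g$channel, ""),
               c("FP1-F7", "FP1-F7"))
  ann_bad <- data.frame(channel = "T3-T5", start_time = 0, stop_time = 5,
                        label = "musc")
  expect_warning(out <- extract_labeled_intervals(rec, ann_bad, 4),
                 "missing channel")
  expect_length(out, 0)
})

test_that("segmentation yields exact non-overlapping windows", {
  x <- seq_len(1750)
  segs <- segment_signal(x, 250, 4)
  expect_length(segs, 1)
  expect_length(segs[[1]], 1000)
  expect_length(segment_signal(seq_len(750), 250, 4), 0)
  x2 <- seq_len(2500)
  segs2 <- segment_signal(x2, 250, 4)
  expect_identical(unlist(segs2), x2[1:2000])  # prefix identity
  expect_error(segment_signal(x, 250, 0), "seconds")
})

test_that("full pipeline composes deterministically on a synthetic record", {
  counts <- c(MUSC = 2L, EYEM = 2L)
  ds <- generate_dataset(counts, duration_s = 8, fs = 250, snr_db = 15,
                         seed = 3)
  tmp_edf <- tempfile(fileext = ".edf")
  tmp_csv <- tempfile(fileext = ".csv")
  export_dataset_edf(ds, tmp_edf, tmp_csv)
  rec <- read_edf(tmp_edf)
  ann <- read_annotations(tmp_csv)
  out1 <- preprocess_recording(rec, ann, seconds = 4, min_seconds = 4,
                               resample = FALSE)
  out2 <- preprocess_recording(rec, ann, seconds = 4, min_seconds = 4,
                               resample = FALSE)
  # 4 annotated 8 s intervals -> 2 windows each
  expect_equal(nrow(out1$segments), 8)
  expect_identical(out1$segments, out2$segments)
  expect_true(all(is.finite(out1$segments)))
  # z-scored by default
  expect_lt(max(abs(rowMeans(out1$segments))), 1e-8)
  expect_equal(apply(out1$segments, 1, stats::sd), rep(1, 8),
               tolerance = 1e-6)
})
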