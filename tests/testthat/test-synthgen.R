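test_that("background EEG is seeded, sized and 1/f-shaped", {
  a <- background_eeg(4, 250, 0.3, seed = 7)
  b <- background_eeg(4, 250, 0.3, seed = 7)
  expect_identical(a, b)
  expect_length(background_eeg(4, 250, 0, seed = 1), 1000)
  expect_lt(abs(mean(a)), 1e-8)
  expect_equal(stats::sd(a), 1, tolerance = 1e-6)
  # pure pink noise: log-log PSD slope near -1 over 1-40 Hz
  slope <- oracle_psd_slope(background_eeg(30, 250, 0, seed = 1), 250)
  expect_gt(slope, -1.6)
  expect_lt(slope, -0.4)
  expect_error(background_eeg(0, 250), "duration")
  expect_error(background_eeg(4, -1), "fs")
})

test_that("artifact classes carry their defining spectral signatures", {
  hi <- function(cl, seed = 3, rate = NULL)
    generate_artifact_segment(synth_params(cl, 4, 250, snr_db = 20,
                                           rate_hz = rate, seed = seed))
  # MUSC: broadband 20-80 Hz power dominates
  expect_gte(oracle_band_fraction(hi("MUSC"), 250, 20, 80), 0.6)
  # EYEM: slow deflections, power below 4 Hz dominates
  expect_gte(oracle_band_fraction(hi("EYEM"), 250, 0, 4), 0.5)
  # SHIV: narrowband near 10 Hz
  expect_gte(oracle_band_fraction(hi("SHIV"), 250, 8, 12), 0.4)
  # RC at 2 Hz: envelope autocorrelation peaks at 0.5 s (within 10%)
  lag <- oracle_env_acf_peak(hi("RC", rate = 2.0), 250, min_lag = 0.25,
                             max_lag = 0.8)
  expect_gte(lag, 0.45)
  expect_lte(lag, 0.55)
  expect_error(synth_params("NOTACLASS"), "unknown class")
})

test_that("identical parameters give identical segments, seeds differ", {
  p <- synth_params("CHEW", 4, 250, 10, seed = 11)
  expect_identical(generate_artifact_segment(p),
                   generate_artifact_segment(p))
  p2 <- synth_params("CHEW", 4, 250, 10, seed = 12)
  expect_false(identical(as.numeric(generate_artifact_segment(p)),
                         as.numeric(generate_artifact_segment(p2))))
})

test_that("generate_dataset conserves counts and is order-stable", {
  counts <- stats::setNames(rep(4L, 6),
                            c("CHEW", "MUSC", "ELEC", "EYEM", "RC", "BLINK"))
  ds <- generate_dataset(counts, 4, 250, 10, seed = 5)
  expect_equal(nrow(ds$segments), 24)
  expect_equal(ncol(ds$segments), 1000)
  expect_equal(unname(table(ds$labels)[names(counts)]),
               unname(counts), ignore_attr = TRUE)
  ds2 <- generate_dataset(counts, 4, 250, 10, seed = 5)
  expect_identical(ds$segments, ds2$segments)
  ds3 <- generate_dataset(counts, 4, 250, 10, seed = 6)
  expect_false(identical(ds$segments, ds3$segments))
  # per-segment seeds derive from (master, class, index): a subset request
  # reproduces the same waveforms
  sub <- generate_dataset(counts[c("MUSC", "EYEM")], 4, 250, 10, seed = 5)
  expect_equal(sub$segments[1, ], ds$segments[5, ])
  expect_error(generate_dataset(c(CHEW = -1)), "non-negative")
  expect_error(generate_dataset(c(XX = 3)), "unknown class")
})

test_that("a band-power decision rule separates the classes at 10 dB", {
  classes <- c("CHEW", "MUSC", "ELEC", "EYEM", "RC", "BLINK", "SHIV")
  counts <- stats::setNames(rep(8L, length(classes)), classes)
  ds <- generate_dataset(counts, 4, 250, snr_db = 10, seed = 1)
  pred <- vapply(seq_len(nrow(ds$segments)),
                 function(i) oracle_classify_segment(ds$segments[i, ], 250),
                 "")
  expect_gte(mean(pred == ds$labels), 0.9)
})
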