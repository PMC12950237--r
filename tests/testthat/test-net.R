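ref_model <- function(...) {
  build_model(model_config(segment_seconds = 4, num_classes = 6, seed = 1,
                           ...))
}

test_that("every stage obeys the floor-arithmetic shape law (4 s input)", {
  m <- ref_model()
  set.seed(2)
  st <- forward_stages(m, stats::rnorm(1000))
  td <- oracle_td_chain(1000)
  tfd <- oracle_tfd_chain(126, 16)
  expect_equal(nrow(st$F_conv1da), td$T)          # 59
  expect_equal(nrow(st$F_trans1), td$T)
  expect_equal(nrow(st$F_conv1db), td$T1)         # 57
  expect_equal(nrow(st$F_td), td$T3)              # 175
  expect_equal(nrow(st$F_conv2da), tfd$HW)        # 1464
  expect_equal(nrow(st$F_conv2db), tfd$T2)        # 1200
  expect_equal(nrow(st$F_tfd), tfd$T4)            # 4128
  expect_equal(nrow(fuse_total(st$F_td, st$F_tfd)), td$T3 + tfd$T4)  # 4303
  expect_true(all(vapply(
    st[c("F_conv1da", "F_trans1", "F_conv1db", "F_td", "F_conv2da",
         "F_conv2db", "F_tfd")],
    ncol, 0L) == 40))
  d <- model_dims(m)
  expect_equal(d$Hout, tfd$Hout)
  expect_equal(d$Wout, tfd$Wout)
})

test_that("1 s and 2 s configurations follow the same per-stage oracle", {
  m1 <- build_model(model_config(segment_seconds = 1, num_classes = 6))
  expect_equal(model_dims(m1)$T, oracle_td_chain(250)$T)     # 12
  m2 <- build_model(model_config(segment_seconds = 2, num_classes = 6))
  expect_equal(model_dims(m2)$T, oracle_td_chain(500)$T)
  st <- forward_stages(m2, stats::rnorm(500))
  expect_equal(nrow(st$F_conv1da), oracle_td_chain(500)$T)
})

test_that("transformer encoding preserves shape and is permutation-equivariant", {
  m <- ref_model()
  set.seed(5)
  F <- matrix(stats::rnorm(8 * 40), 8, 40)
  out <- transformer_encode(m, F, branch = "td")
  expect_equal(dim(out), c(8, 40))
  perm <- sample(8)
  out_perm <- transformer_encode(m, F[perm, ], branch = "td")
  expect_equal(out_perm, out[perm, ], tolerance = 1e-5)
  # same property for the time-frequency branch weights
  out2 <- transformer_encode(m, F, branch = "tfd")
  expect_equal(transformer_encode(m, F[perm, ], branch = "tfd"),
               out2[perm, ], tolerance = 1e-5)
  expect_error(transformer_encode(m, matrix(0, 8, 39)), "d_model")
})

test_that("attention weight rows are probability distributions", {
  m <- ref_model()
  set.seed(6)
  F <- matrix(stats::rnorm(12 * 40), 12, 40)
  for (l in c(0L, 3L, 5L)) {
    P <- attention_probs(m, F, branch = "td", layer = l)
    expect_equal(dim(P), c(12, 12, 5))
    expect_true(all(P >= 0))
    expect_equal(apply(P, c(1, 3), sum),
                 matrix(1, 12, 5), tolerance = 1e-5)
  }
})

test_that("deep-local convolutions shrink the sequence as configured", {
  m <- ref_model()
  set.seed(7)
  F <- matrix(stats::rnorm(59 * 40), 59, 40)
  out <- conv1d_b(m, F)
  expect_equal(dim(out), c(57, 40))
  expect_error(conv1d_b(m, F[1:2, ]), "at least 3")
  sp <- matrix(abs(stats::rnorm(126 * 16)), 126, 16)
  got <- conv2d_a(m, sp)
  expect_equal(got$Hout, 122)
  expect_equal(got$Wout, 12)
  expect_equal(dim(got$F), c(1464, 40))
  out2 <- conv2d_b(m, got$F, got$Hout, got$Wout)
  expect_equal(dim(out2), c(1200, 40))
  expect_error(conv2d_b(m, got$F[1:100, ], 122, 12), "Hout")
})

test_that("zero input at initialization propagates to uniform probabilities", {
  m <- ref_model()
  st <- forward_stages(m, numeric(1000))
  expect_true(all(st$F_conv1da == 0))
  expect_true(all(st$F_conv2da == 0))
  expect_equal(as.numeric(st$probs), rep(1 / 6, 6), tolerance = 1e-6)
  # zero spectrogram through the 2-D stack alone
  z <- conv2d_a(m, matrix(0, 126, 16))
  expect_true(all(z$F == 0))
})

test_that("fusion concatenates along the sequence axis with channel mixing", {
  m <- ref_model()
  set.seed(8)
  fa <- matrix(stats::rnorm(59 * 40), 59, 40)
  ftr <- matrix(stats::rnorm(59 * 40), 59, 40)
  fb <- matrix(stats::rnorm(57 * 40), 57, 40)
  ftd <- fuse_domain(m, fa, ftr, fb, domain = "td")
  expect_equal(dim(ftd), c(175, 40))              # 2T + T1
  # kernel-1 conv preserves arbitrary lengths
  expect_equal(nrow(fuse_domain(m, fa[1:5, ], ftr[1:3, ], fb[1:2, ])), 10)
  ftfd <- matrix(stats::rnorm(4128 * 40), 4128, 40)
  tot <- fuse_total(ftd, ftfd)
  expect_equal(nrow(tot), 4303)
  expect_identical(tot[1:175, ], ftd)             # time-domain block first
  expect_error(fuse_total(ftd, ftfd[, 1:39]), "channel mismatch")
  expect_error(fuse_total(ftd, ftfd[0, , drop = FALSE]), "empty")
})

test_that("classifier softmax is a proper, shift-invariant distribution", {
  m <- ref_model()
  set.seed(9)
  F <- matrix(stats::rnorm(4303 * 40), 4303, 40)
  out <- classify(m, F)
  expect_equal(sum(out$p), 1, tolerance = 1e-6)
  expect_true(all(out$p >= 0 & out$p <= 1))
  # p is the softmax of z (hence invariant to a constant logit shift)
  expect_equal(as.numeric(out$p),
               as.numeric(exp(out$z) / sum(exp(out$z))), tolerance = 1e-5)
  expect_error(classify(m, F[1:100, ]), "width")
})

test_that("weighted fusion returns convex weights and a 40-wide output", {
  m <- build_model(model_config(segment_seconds = 4, num_classes = 6,
                                fusion_strategy = "weighted_cnn", seed = 2))
  set.seed(10)
  fa <- matrix(stats::rnorm(59 * 40), 59, 40)
  ftr <- matrix(stats::rnorm(59 * 40), 59, 40)
  fb <- matrix(stats::rnorm(57 * 40), 57, 40)
  got <- weighted_fusion(m, fa, ftr, fb, mode = "weighted")
  expect_equal(sum(got$weights), 1, tolerance = 1e-6)
  expect_equal(dim(got$F), c(1, 40))
  # identical groups get equal weights; weighted sum returns the pooled vec
  same <- fa
  got2 <- weighted_fusion(m, same, same, same, mode = "weighted")
  expect_equal(as.numeric(got2$weights), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(as.numeric(got2$F), colMeans(same), tolerance = 1e-5)
  # output width independent of input lengths, both modes
  got3 <- weighted_fusion(m, fa[1:9, ], ftr[1:30, ], fb, mode = "weighted_cnn")
  expect_equal(dim(got3$F), c(1, 40))
})

test_that("parameter counts sit in the expected range and nest by variant", {
  counts <- vapply(
    c("cnn", "cnn_tf", "cnn_tf_fusion", "cnn_tf_cnn_fusion", "full"),
    function(v) param_count(build_model(
      model_config(segment_seconds = 4, num_classes = 6, variant = v))), 0)
  expect_true(all(diff(counts) > 0))              # strictly nested
  expect_gte(counts["full"], 4e6)
  expect_lte(counts["full"], 4e7)
  # parameters grow with segment length
  by_len <- vapply(c(2, 4, 5), function(s) param_count(build_model(
    model_config(segment_seconds = s, num_classes = 6))), 0)
  expect_true(all(diff(by_len) > 0))
})

test_that("initialization is seed-deterministic and checkpoints round-trip", {
  cfg <- model_config(segment_seconds = 4, num_classes = 6, seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  set.seed(11)
  x <- matrix(stats::rnorm(2 * 1000), 2, 1000)
  expect_identical(predict_proba(m1, x), predict_proba(m2, x))
  cfg2 <- cfg
  cfg2$seed <- 4L
  m3 <- build_model(cfg2)
  expect_false(identical(predict_proba(m1, x), predict_proba(m3, x)))
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(m1, tmp, class_vocabulary = LETTERS[1:6])
  ck <- load_checkpoint(tmp)
  expect_identical(predict_proba(ck$model, x), predict_proba(m1, x))
  expect_equal(ck$class_vocabulary, LETTERS[1:6])
})

test_that("analytic gradients match finite differences along a random direction", {
  for (v in c("cnn_tf_cnn_fusion", "full")) {
    cfg <- model_config(segment_seconds = 4, num_classes = 3, variant = v,
                        seed = 3)
    m <- build_model(cfg)
    set.seed(31)
    B <- 2
    x <- matrix(stats::rnorm(1000 * B), 1000, B)
    sp <- array(0, dim = c(126, 16, B))
    for (b in 1:B) sp[, , b] <- stft_spectrogram(x[, b])$values
    y <- c(0L, 2L)
    lg <- eegartifacts:::cpp_net_loss_grads(m$ptr, x, sp, y, TRUE)
    params <- eegartifacts:::cpp_net_get_params(m$ptr)
    dirs <- lapply(params, function(w)
      matrix(stats::rnorm(length(w)), nrow(w), ncol(w)))
    nrm <- sqrt(sum(vapply(dirs, function(d) sum(d^2), 0)))
    dirs <- lapply(dirs, function(d) d / nrm)
    gd <- sum(mapply(function(g, d) sum(g * d), lg$grads[names(params)],
                     dirs))
    eps <- 0.05
    loss_at <- function(t) {
      eegartifacts:::cpp_net_set_params(m$ptr, mapply(
        function(w, d) w + t * d, params, dirs, SIMPLIFY = FALSE))
      eegartifacts:::cpp_net_loss_grads(m$ptr, x, sp, y, TRUE)$loss
    }
    fd <- (loss_at(eps) - loss_at(-eps)) / (2 * eps)
    expect_equal(gd, fd, tolerance = 0.02, info = v)
  }
})
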