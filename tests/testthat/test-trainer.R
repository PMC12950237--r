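test_that("stratified 5-fold splits are disjoint, covering and balanced", {
  labels <- rep(c("A", "B", "C"), each = 20)
  sp <- stratified_kfold(labels, k = 5, seed = 1)
  expect_setequal(unique(sp$fold), 0:4)
  # disjoint + covering is implied by a fold index per sample; check sizes
  expect_equal(unname(table(sp$fold)), rep(12, 5), ignore_attr = TRUE)
  # per class, per fold: 20/5 = 4 exactly
  for (cl in c("A", "B", "C"))
    expect_equal(unname(table(sp$fold[labels == cl])), rep(4, 5),
                 ignore_attr = TRUE)
  # 8:2 train:test per fold
  expect_equal(sum(sp$fold != 0) / sum(sp$fold == 0), 4)
  expect_identical(sp, stratified_kfold(labels, k = 5, seed = 1))
  expect_error(stratified_kfold(c("A", "A", "B"), k = 5), "at least k")
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(2)
  for (i in 1:20) {
    p <- stats::runif(4)
    p <- p / sum(p)
    y <- diag(4)[sample(4, 1), ]
    expect_gte(cross_entropy(y, p), 0)
  }
  expect_error(cross_entropy(c(1, 0), c(1, 0, 0)), "length")
})

test_that("metrics match hand-computed confusion counts", {
  counts <- data.frame(class = "X", TP = 8, TN = 9, FP = 1, FN = 2)
  m <- metrics_from_counts(counts)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 16 / 19)
})

test_that("metrics equal a brute-force recount on random predictions", {
  set.seed(3)
  truth <- sample(0:3, 200, replace = TRUE)
  pred <- ifelse(stats::runif(200) < 0.7, truth, sample(0:3, 200, TRUE))
  counts <- confusion_counts(truth, pred, classes = 0:3)
  m <- metrics_from_counts(counts)
  for (k in 0:3) {
    tp <- sum(truth == k & pred == k)
    tn <- sum(truth != k & pred != k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    expect_equal(counts$TP[k + 1], tp)
    expect_equal(counts$TN[k + 1] + counts$FP[k + 1] + counts$FN[k + 1] +
                   counts$TP[k + 1], 200)
    expect_equal(m$accuracy[k + 1], (tp + tn) / 200)
    expect_equal(m$recall[k + 1], tp / (tp + fn))
    expect_equal(m$f1[k + 1], 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("perfect predictions give metrics of exactly 1", {
  truth <- rep(0:2, each = 5)
  m <- metrics_from_counts(confusion_counts(truth, truth, classes = 0:2))
  expect_true(all(m$accuracy == 1 & m$recall == 1 & m$f1 == 1))
})

test_that("zero-denominator metrics warn and report 0", {
  # class 2 never occurs in truth or prediction -> recall undefined
  counts <- confusion_counts(c(0, 0, 1), c(0, 1, 1), classes = 0:2)
  w <- testthat::capture_warnings(m <- metrics_from_counts(counts))
  expect_true(any(grepl("zero denominator", w)))  # recall and F1 both warn
  expect_equal(m$recall[3], 0)
  expect_equal(m$f1[3], 0)
})

test_that("training separates two pure tones within a few epochs", {
  ds <- make_tone_dataset(n_per_class = 20)
  mcfg <- model_config(segment_seconds = 4, num_classes = 2,
                       variant = "cnn", seed = 0)
  tcfg <- train_config(batch_size = 8, max_epochs = 20,
                       early_stop_patience = Inf, seed = 0)
  data <- prepare_training_data(ds, mcfg)
  model <- build_model(mcfg)
  fit <- train(model, data, train_idx = seq_len(40), cfg = tcfg)
  expect_true(all(is.finite(fit$history$train_loss)))
  # training accuracy reaches 1 on this linearly separable task
  final <- evaluate(fit$model, data, seq_len(40))
  expect_equal(final$overall_accuracy, 1.0)
  # seeded rerun is bit-identical
  model2 <- build_model(mcfg)
  fit2 <- train(model2, data, train_idx = seq_len(40), cfg = tcfg)
  expect_identical(fit$history, fit2$history)
})

test_that("mean accuracy degrades when artifacts sink below the background", {
  classes <- c("MUSC", "EYEM", "SHIV")
  acc_at_snr <- function(snr) {
    mean(vapply(0:2, function(s) {
      ds <- generate_dataset(stats::setNames(rep(10L, 3), classes),
                             duration_s = 4, fs = 250, snr_db = snr,
                             seed = s)
      mcfg <- model_config(segment_seconds = 4, num_classes = 3,
                           variant = "cnn", seed = s)
      tcfg <- train_config(batch_size = 8, max_epochs = 8,
                           early_stop_patience = Inf, seed = s)
      data <- prepare_training_data(ds, mcfg)
      split <- stratified_kfold(ds$labels, k = 5, seed = s)
      fit <- train(build_model(mcfg), data, which(split$fold != 0), tcfg)
      evaluate(fit$model, data, which(split$fold == 0))$overall_accuracy
    }, 0))
  }
  expect_lt(acc_at_snr(-5), acc_at_snr(10))
})

test_that("run_ablation reports one row per variant/fusion/seed cell", {
  ds <- make_tone_dataset(n_per_class = 10)
  mcfg <- model_config(segment_seconds = 4, num_classes = 2,
                       variant = "cnn", seed = 0)
  tcfg <- train_config(batch_size = 8, max_epochs = 3,
                       early_stop_patience = Inf, seed = 0)
  abl <- run_ablation(ds, variants = c("cnn", "cnn_tf"),
                      train_cfg = tcfg, seeds = 0:1, base_model_cfg = mcfg)
  expect_equal(nrow(abl), 4)
  expect_setequal(abl$variant, c("cnn", "cnn_tf"))
  expect_true(all(abl$test_accuracy >= 0 & abl$test_accuracy <= 1))
})

test_that("run_cv aggregates fold metrics arithmetically", {
  ds <- make_tone_dataset(n_per_class = 15)
  mcfg <- model_config(segment_seconds = 4, num_classes = 2,
                       variant = "cnn", seed = 0)
  tcfg <- train_config(batch_size = 8, max_epochs = 6,
                       early_stop_patience = Inf, seed = 0)
  cv <- run_cv(ds, mcfg, tcfg, k = 5)
  expect_length(cv$fold_reports, 5)
  accs <- vapply(cv$fold_reports, function(r) r$overall_accuracy, 0)
  expect_equal(unname(cv$aggregate$overall_accuracy["mean"]), mean(accs))
  expect_equal(unname(cv$aggregate$overall_accuracy["sd"]), stats::sd(accs))
  # every fold tests exactly 20% of the data
  expect_true(all(vapply(cv$fold_reports, function(r) r$n, 0) == 6))
})
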