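#' Training configuration
#'
#' Adam optimizer settings and loop controls. Defaults follow the reference
#' protocol: learning rate 2e-4, beta1 0.9, beta2 0.999, batch size 200,
#' up to 100 epochs with early stopping (patience 10) on the loss of an
#' internal validation split (10% of the training portion).
#'
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decays (in (0, 1)).
#' @param batch_size Mini-batch size (>= 1); batches larger than the
#'   training split are truncated to it.
#' @param max_epochs Maximum epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (`Inf` disables early stopping).
#' @param val_fraction Fraction of the training split held out for early
#'   stopping.
#' @param seed Seed for shuffling and the validation split.
#'
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 200L, max_epochs = 100L,
                         early_stop_patience = 10L, val_fraction = 0.1,
                         seed = 0L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("beta1 and beta2 must be in (0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Seeded stratified k-fold split
#'
#' Deterministic stratified partition: within every class the (seeded)
#' shuffled indices are dealt round-robin to folds, so per-class counts
#' across folds differ by at most 1. With `k = 5` each fold's train:test
#' ratio is exactly 8:2.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#'
#' @return A `split_plan`: list with `fold` (0-based fold index per sample)
#'   and `k`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 0L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least k samples; short: ",
         paste(names(counts)[counts < k], collapse = ", "))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (seq_along(idx) - 1L) %% k
    }
  })
  structure(list(fold = fold, k = as.integer(k)), class = "split_plan")
}

#' Cross-entropy loss
#'
#' `-sum(y * log(p))` with `p` clamped to `[1e-12, 1]`.
#'
#' @param y_onehot One-hot (or soft) target vector.
#' @param p Predicted probability vector of the same length.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(y_onehot, p) {
  if (length(y_onehot) != length(p)) stop("length mismatch")
  -sum(y_onehot * log(pmin(pmax(p, 1e-12), 1)))
}

#' Prepare a dataset for training
#'
#' Z-scores every segment and precomputes its STFT spectrogram once (the
#' network consumes both representations), and encodes labels as 0-based
#' integers against the dataset's class vocabulary.
#'
#' @param dataset A `labeled_dataset`.
#' @param model_cfg The [model_config()] the data will be fed to.
#' @return A `training_data` list with `x` (n x L), `spec`
#'   (bins x frames x n or a stub for time-domain-only variants), `y`
#'   (0-based integers), `vocab`.
#' @export
prepare_training_data <- function(dataset, model_cfg) {
  x <- t(apply(dataset$segments, 1, zscore_segment))
  y <- match(dataset$labels, dataset$class_vocabulary) - 1L
  if (anyNA(y)) stop("labels outside the class vocabulary")
  spec <- if (model_cfg$variant == "full") {
    d0 <- stft_spectrogram(x[1, ], fs = dataset$fs)$values
    sp <- array(0, dim = c(nrow(d0), ncol(d0), nrow(x)))
    sp[, , 1] <- d0
    if (nrow(x) > 1)
      for (i in 2:nrow(x))
        sp[, , i] <- stft_spectrogram(x[i, ], fs = dataset$fs)$values
    sp
  } else array(0, dim = c(1, 1, nrow(x)))
  structure(list(x = x, spec = spec, y = y,
                 vocab = dataset$class_vocabulary),
            class = "training_data")
}

# forward probabilities for a subset, chunked to bound memory
eval_probs <- function(model, data, idx, chunk = 16L) {
  out <- matrix(0, length(idx), model$config$num_classes)
  for (i0 in seq(1, length(idx), by = chunk)) {
    take <- idx[i0:min(length(idx), i0 + chunk - 1)]
    out[i0:(i0 + length(take) - 1), ] <-
      cpp_net_forward(model$ptr, t(data$x[take, , drop = FALSE]),
                      data$spec[, , take, drop = FALSE])
  }
  out
}

mean_ce <- function(probs, y) {
  mean(vapply(seq_along(y),
              function(i) -log(max(probs[i, y[i] + 1], 1e-12)), 0))
}

#' Train a model
#'
#' Minimizes mean cross-entropy with Adam over seeded, shuffled mini-batches.
#' A stratification-free `val_fraction` of the training indices is held out;
#' training stops early when its loss has not improved for
#' `early_stop_patience` epochs, and the best-validation-loss weights are
#' restored.
#'
#' @param model An `lgnet_model` (trained in place; also returned).
#' @param data A `training_data` object.
#' @param train_idx Integer indices (1-based) of the training samples.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#'
#' @return List with `model` and `history` (data frame: epoch, train_loss,
#'   train_acc, val_loss, val_acc).
#' @export
train <- function(model, data, train_idx, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(data, "training_data"))
  if (length(train_idx) < 2) stop("empty or degenerate training set")
  n_val <- max(1L, round(cfg$val_fraction * length(train_idx)))
  val_idx <- with_seed(cfg$seed + 131L,
                       sample(train_idx, n_val))
  fit_idx <- setdiff(train_idx, val_idx)
  bs <- min(cfg$batch_size, length(fit_idx))
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best_loss <- Inf; best_params <- NULL; best_buffers <- NULL; wait <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- with_seed(cfg$seed + 1000L * epoch, sample(fit_idx))
    tl <- 0; ta <- 0; nb <- 0
    for (i0 in seq(1, length(order_idx), by = bs)) {
      take <- order_idx[i0:min(length(order_idx), i0 + bs - 1)]
      res <- cpp_net_train_batch(
        model$ptr, t(data$x[take, , drop = FALSE]),
        data$spec[, , take, drop = FALSE], data$y[take],
        cfg$learning_rate, cfg$beta1, cfg$beta2, 1e-8)
      if (!is.finite(res$loss)) stop("non-finite training loss at epoch ",
                                     epoch)
      tl <- tl + res$loss; ta <- ta + res$acc; nb <- nb + 1
    }
    vp <- eval_probs(model, data, val_idx)
    vl <- mean_ce(vp, data$y[val_idx])
    va <- mean(max.col(vp) - 1L == data$y[val_idx])
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   train_acc = ta / nb, val_loss = vl,
                                   val_acc = va))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, tl / nb, ta / nb, vl, va))
    if (vl < best_loss - 1e-6) {
      best_loss <- vl; wait <- 0L
      best_params <- cpp_net_get_params(model$ptr)
      best_buffers <- cpp_net_get_buffers(model$ptr)
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  if (!is.null(best_params)) {
    cpp_net_set_params(model$ptr, best_params)
    cpp_net_set_buffers(model$ptr, best_buffers)
  }
  list(model = model, history = hist)
}

#' One-vs-rest confusion counts
#'
#' @param truth,pred Integer or character class vectors of equal length.
#' @param classes Class vocabulary (defaults to the union of values).
#' @return Data frame with one row per class: TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  do.call(rbind, lapply(classes, function(cl) {
    data.frame(class = cl,
               TP = sum(truth == cl & pred == cl),
               TN = sum(truth != cl & pred != cl),
               FP = sum(truth != cl & pred == cl),
               FN = sum(truth == cl & pred != cl))
  }))
}

#' Per-class metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Recall = TP/(TP+FN),
#' F1 = 2TP/(2TP+FP+FN), each one-vs-rest; zero-denominator metrics are
#' reported as 0 with a warning.
#'
#' @param counts Data frame from [confusion_counts()].
#' @return Data frame with accuracy, recall and f1 per class.
#' @export
metrics_from_counts <- function(counts) {
  safe_div <- function(num, den, what, cl) {
    ifelse(den > 0, num / pmax(den, 1), {
      if (any(den == 0))
        warning("zero denominator for ", what, " (class ",
                paste(cl[den == 0], collapse = ", "), "); reported as 0")
      0
    })
  }
  data.frame(class = counts$class,
             accuracy = (counts$TP + counts$TN) /
               (counts$TP + counts$TN + counts$FP + counts$FN),
             recall = safe_div(counts$TP, counts$TP + counts$FN, "recall",
                               counts$class),
             f1 = safe_div(2 * counts$TP,
                           2 * counts$TP + counts$FP + counts$FN, "F1",
                           counts$class))
}

#' Evaluate a model on a subset of a dataset
#'
#' Argmax predictions (ties broken toward the lowest class index), one-vs-
#' rest confusion counts and per-class accuracy/recall/F1 with macro
#' averages.
#'
#' @param model An `lgnet_model`.
#' @param data A `training_data` object.
#' @param idx 1-based indices of the evaluation samples.
#' @param fold Optional fold id recorded in the report.
#' @return An `eval_report` list: `per_class` data frame, `macro` named
#'   vector, `overall_accuracy` (fraction of correctly labeled samples),
#'   `n`, `fold`, `fingerprint`.
#' @export
evaluate <- function(model, data, idx, fold = NA_integer_) {
  if (length(idx) < 1) stop("empty evaluation mask")
  probs <- eval_probs(model, data, idx)
  pred <- max.col(probs, ties.method = "first") - 1L
  truth <- data$y[idx]
  counts <- confusion_counts(truth, pred, classes = seq_along(data$vocab) - 1L)
  counts$class <- data$vocab[counts$class + 1L]
  per_class <- metrics_from_counts(counts)
  structure(list(per_class = per_class,
                 macro = c(accuracy = mean(per_class$accuracy),
                           recall = mean(per_class$recall),
                           f1 = mean(per_class$f1)),
                 overall_accuracy = mean(pred == truth),
                 counts = counts, n = length(idx), fold = fold,
                 fingerprint = config_fingerprint(model$config)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d fold=%s overall accuracy %.3f\n", x$n,
              x$fold, x$overall_accuracy))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("macro: accuracy %.3f recall %.3f f1 %.3f\n",
              x$macro["accuracy"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Trains one freshly initialized model per fold (weights seeded from
#' `model_cfg$seed + fold`), evaluates on that fold's held-out 20%, and
#' aggregates per-fold macro metrics as mean and SD.
#'
#' @param dataset A `labeled_dataset`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param folds Optional subset of folds to run (0-based ids), e.g. `0L`
#'   to re-run a single fold; defaults to all.
#' @param verbose Print progress.
#'
#' @return A `cv_report` list: `fold_reports`, `aggregate` (mean/sd of
#'   macro metrics and overall accuracy), `histories`, `split`.
#' @export
run_cv <- function(dataset, model_cfg, train_cfg, k = 5L, folds = NULL,
                   verbose = FALSE) {
  data <- prepare_training_data(dataset, model_cfg)
  split <- stratified_kfold(dataset$labels, k = k, seed = train_cfg$seed)
  if (is.null(folds)) folds <- 0:(k - 1)
  fold_reports <- list(); histories <- list()
  for (f in folds) {
    test_idx <- which(split$fold == f)
    train_idx <- which(split$fold != f)
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f
    tcfg_f <- train_cfg
    tcfg_f$seed <- train_cfg$seed + f
    model <- build_model(cfg_f)
    fit <- train(model, data, train_idx, tcfg_f, verbose = verbose)
    rep <- evaluate(fit$model, data, test_idx, fold = f)
    fold_reports[[as.character(f)]] <- rep
    histories[[as.character(f)]] <- fit$history
    if (verbose)
      message(sprintf("fold %d: overall accuracy %.3f (epochs run: %d)", f,
                      rep$overall_accuracy, nrow(fit$history)))
  }
  agg_of <- function(get) {
    v <- vapply(fold_reports, get, 0)
    c(mean = mean(v), sd = stats::sd(v))
  }
  structure(list(
    fold_reports = fold_reports,
    aggregate = list(
      overall_accuracy = agg_of(function(r) r$overall_accuracy),
      accuracy = agg_of(function(r) r$macro["accuracy"]),
      recall = agg_of(function(r) r$macro["recall"]),
      f1 = agg_of(function(r) r$macro["f1"])),
    histories = histories, split = split), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<cv_report> %d folds | overall acc %.3f +- %.3f | macro acc %.3f recall %.3f f1 %.3f\n",
              length(x$fold_reports), a$overall_accuracy["mean"],
              a$overall_accuracy["sd"], a$accuracy["mean"],
              a$recall["mean"], a$f1["mean"]))
  invisible(x)
}

#' Ablation / fusion-strategy comparison
#'
#' Trains the requested variants on a single seeded 8:2 stratified split
#' (one model per variant per seed) and reports test accuracy per run.
#'
#' @param dataset A `labeled_dataset`.
#' @param variants Character vector of [model_config()] variants.
#' @param fusion_strategies Fusion strategies crossed with `variant="full"`.
#' @param train_cfg A [train_config()].
#' @param seeds Integer vector of seeds; results are averaged over them.
#' @param base_model_cfg Template configuration.
#'
#' @return Data frame: variant, fusion, seed, test accuracy, macro f1.
#' @export
run_ablation <- function(dataset, variants = c("cnn", "full"),
                         fusion_strategies = "concat_cnn",
                         train_cfg = train_config(),
                         seeds = 0L, base_model_cfg = NULL) {
  if (is.null(base_model_cfg))
    base_model_cfg <- model_config(
      segment_seconds = dataset$duration_s, fs = dataset$fs,
      num_classes = length(dataset$class_vocabulary))
  combos <- do.call(rbind, lapply(variants, function(v) {
    fs <- if (v == "full") fusion_strategies else "concat_cnn"
    data.frame(variant = v, fusion = fs)
  }))
  out <- NULL
  for (i in seq_len(nrow(combos))) {
    cfg <- base_model_cfg
    cfg$variant <- combos$variant[i]
    cfg$fusion_strategy <- combos$fusion[i]
    data <- prepare_training_data(dataset, cfg)
    for (s in seeds) {
      split <- stratified_kfold(dataset$labels, k = 5L, seed = s)
      test_idx <- which(split$fold == 0L)   # one 8:2 split
      train_idx <- which(split$fold != 0L)
      cfg$seed <- s
      tcfg <- train_cfg
      tcfg$seed <- s
      model <- build_model(cfg)
      fit <- train(model, data, train_idx, tcfg)
      rep <- evaluate(fit$model, data, test_idx)
      out <- rbind(out, data.frame(
        variant = cfg$variant, fusion = cfg$fusion_strategy, seed = s,
        test_accuracy = rep$overall_accuracy,
        macro_f1 = unname(rep$macro["f1"])))
    }
  }
  out
}
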