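#' Model configuration
#'
#' All architectural hyperparameters of the dual-branch network. Defaults
#' follow the reference configuration: two-stage 1-D conv stack
#' (1->16, k=8, s=4; 16->40, k=4, s=2 with batch-norm, ELU and max-pooling),
#' two-stage 2-D conv stack over the spectrogram ((1,3) then (3,1) kernels
#' with (2,2) stride-1 pooling), two independent 6-layer/5-head/40-dim
#' pre-norm transformer encoders, deep-local 40->40 convolutions (kernel 3
#' resp. (3,3)), kernel-1 per-domain fusion convolutions, and a
#' 128-wide ELU/dropout classifier head.
#'
#' @param segment_seconds Segment length in seconds (1, 2, 4 or 5).
#' @param fs Sampling rate in Hz.
#' @param num_classes Number of output classes (m >= 2).
#' @param variant Ablation variant: `"cnn"` (time-domain conv stack only),
#'   `"cnn_tf"` (+ transformer), `"cnn_tf_fusion"` (+ shallow/global
#'   concatenation), `"cnn_tf_cnn_fusion"` (+ deep-local features and
#'   kernel-1 fusion; still time-domain only) or `"full"` (both domains).
#' @param fusion_strategy `"concat_cnn"` (concatenate along the sequence
#'   axis, then a kernel-1 convolution), `"weighted"` (MLP-attention
#'   weighted sum of pooled group vectors) or `"weighted_cnn"` (weighted sum
#'   followed by a kernel-1 convolution).
#' @param num_layers,num_heads,d_model Transformer encoder shape (the two
#'   branches share the shape but have separate weights).
#' @param ffn_width Feed-forward hidden width in each encoder layer.
#' @param positional_encoding `"none"` (default) or `"sinusoidal"`.
#' @param classifier_hidden Classifier hidden width.
#' @param dropout Dropout rate on the classifier hidden layer.
#' @param conv2d_text_order If `TRUE`, swap the two 2-D kernels to
#'   (3,1)-first order.
#' @param seed Integer seed controlling weight initialization (and dropout).
#'
#' @return A `model_config` list.
#' @export
model_config <- function(segment_seconds = 4, fs = 250, num_classes = 6,
                         variant = c("full", "cnn", "cnn_tf",
                                     "cnn_tf_fusion", "cnn_tf_cnn_fusion"),
                         fusion_strategy = c("concat_cnn", "weighted",
                                             "weighted_cnn"),
                         num_layers = 6, num_heads = 5, d_model = 40,
                         ffn_width = 160,
                         positional_encoding = c("none", "sinusoidal"),
                         classifier_hidden = 128, dropout = 0.5,
                         conv2d_text_order = FALSE, seed = 0L) {
  variant <- match.arg(variant)
  fusion_strategy <- match.arg(fusion_strategy)
  positional_encoding <- match.arg(positional_encoding)
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (d_model %% num_heads != 0)
    stop("d_model must be divisible by num_heads")
  structure(list(segment_seconds = segment_seconds, fs = as.integer(fs),
                 num_classes = as.integer(num_classes), variant = variant,
                 fusion_strategy = fusion_strategy,
                 num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 d_model = as.integer(d_model),
                 ffn_width = as.integer(ffn_width),
                 positional_encoding = positional_encoding,
                 classifier_hidden = as.integer(classifier_hidden),
                 dropout = dropout,
                 conv2d_text_order = isTRUE(conv2d_text_order),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build a model from a configuration
#'
#' Instantiates the network with deterministic, seed-controlled
#' initialization (fan-in-scaled uniform weights, zero biases, unit
#' batch-norm scale).
#'
#' @param cfg A [model_config()].
#' @return An `lgnet_model` object.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  ptr <- cpp_net_create(cfg)
  structure(list(ptr = ptr, config = cfg, dims = cpp_net_dims(ptr)),
            class = "lgnet_model")
}

#' @export
print.lgnet_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<lgnet_model> variant=%s fusion=%s %gs@%dHz classes=%d\n",
              x$config$variant, x$config$fusion_strategy,
              x$config$segment_seconds, x$config$fs, x$config$num_classes))
  cat(sprintf("  T=%d T1=%d T3=%d | spect %dx%d -> Hout*Wout=%d T2=%d T4=%d | fused %d\n",
              d$T, d$T1, d$T3, d$spec_bins, d$spec_frames, d$Hout * d$Wout,
              d$T2, d$T4, d$TF))
  cat(sprintf("  trainable parameters: %s\n",
              format(param_count(x), big.mark = ",")))
  invisible(x)
}

#' Trainable parameter count
#' @param model An `lgnet_model`.
#' @return Numeric scalar.
#' @export
param_count <- function(model) {
  cpp_net_param_count(model$ptr)
}

#' Stage dimensions of a model
#'
#' Sequence lengths produced by each stage: `T` (shallow 1-D features), `T1`
#' (deep-local 1-D), `T3` (fused time-domain), `Hout`/`Wout`/`T2`/`T4`
#' (2-D analogues) and `TF = T3 + T4` (total fused length).
#'
#' @param model An `lgnet_model`.
#' @return Named list of integer dimensions.
#' @export
model_dims <- function(model) model$dims

# --- spec-level operations (single segment, inference mode) -----------------

#' Shallow time-domain feature extraction (CONV1Da)
#'
#' Two 1-D convolution stages with batch normalization, ELU and max-pooling,
#' mapping a raw segment of `L` samples to a `T x 40` feature sequence.
#'
#' @param model An `lgnet_model`.
#' @param x Numeric segment of exactly `segment_seconds * fs` samples.
#' @return `T x 40` matrix.
#' @export
conv1d_a <- function(model, x) {
  L <- model$dims$L
  if (length(x) != L)
    stop("input must have exactly ", L, " samples for this configuration")
  forward_stages(model, x)$F_conv1da
}

#' Transformer encoding of a feature sequence
#'
#' Runs one branch's pre-norm multi-head self-attention encoder
#' (6 layers x 5 heads, embedding 40, softmax(QK^T/sqrt(d_k))V attention)
#' over an arbitrary-length sequence. Output shape equals input shape.
#'
#' @param model An `lgnet_model` (variant with a transformer).
#' @param F `T x 40` feature sequence.
#' @param branch `"td"` (time-domain weights) or `"tfd"`.
#' @return `T x 40` matrix.
#' @export
transformer_encode <- function(model, F, branch = c("td", "tfd")) {
  branch <- match.arg(branch)
  cpp_transformer_encode(model$ptr, branch, as.matrix(F))
}

#' Attention probabilities of one encoder layer
#'
#' @param model An `lgnet_model`.
#' @param F `T x 40` input sequence.
#' @param branch `"td"` or `"tfd"`; @param layer 0-based layer index.
#' @return `T x T x heads` array of row-stochastic attention weights.
#' @export
attention_probs <- function(model, F, branch = c("td", "tfd"), layer = 0L) {
  branch <- match.arg(branch)
  cpp_attention_probs(model$ptr, branch, as.integer(layer), as.matrix(F))
}

#' Deep-local time-domain features (CONV1Db)
#'
#' Kernel-3 40->40 convolution with batch-norm and ELU over the transformer
#' output; sequence length shrinks by 2.
#'
#' @param model An `lgnet_model` with deep-local layers.
#' @param F `T x 40` sequence (T >= 3).
#' @return `(T-2) x 40` matrix.
#' @export
conv1d_b <- function(model, F) {
  cpp_op_conv1d_b(model$ptr, as.matrix(F))
}

#' Shallow time-frequency features (CONV2Da)
#'
#' Two 2-D convolution stages over the spectrogram; the resulting
#' `40 x Hout x Wout` map is flattened row-major over (Hout, Wout) into an
#' `(Hout*Wout) x 40` sequence.
#'
#' @param model An `lgnet_model` with a time-frequency branch.
#' @param spec A [stft_spectrogram()] or a bins x frames matrix.
#' @return List with `F` (`(Hout*Wout) x 40`), `Hout`, `Wout`.
#' @export
conv2d_a <- function(model, spec) {
  v <- if (inherits(spec, "spectrogram")) spec$values else as.matrix(spec)
  cpp_op_conv2d_a(model$ptr, v)
}

#' Deep-local time-frequency features (CONV2Db)
#'
#' Unflattens the sequence to `40 x Hout x Wout`, applies a (3,3) 40->40
#' convolution with batch-norm and ELU, and re-flattens.
#'
#' @param model An `lgnet_model` with a time-frequency branch.
#' @param F `(Hout*Wout) x 40` sequence.
#' @param Hout,Wout Spatial dimensions of the unflattened map.
#' @return `T2 x 40` matrix.
#' @export
conv2d_b <- function(model, F, Hout, Wout) {
  cpp_op_conv2d_b(model$ptr, as.matrix(F), as.integer(Hout),
                  as.integer(Wout))
}

#' Per-domain feature fusion (concatenate + kernel-1 convolution)
#'
#' Concatenates shallow, global and deep-local feature sequences along the
#' sequence axis and mixes channels at every position with a kernel-1
#' convolution.
#'
#' @param model An `lgnet_model` with fusion parameters.
#' @param fa,ftr,fb The three `* x 40` feature sequences.
#' @param domain `"td"` or `"tfd"` (selects the fusion weights).
#' @return `(Ta+Ttr+Tb) x 40` matrix.
#' @export
fuse_domain <- function(model, fa, ftr, fb, domain = c("td", "tfd")) {
  domain <- match.arg(domain)
  cpp_op_fuse_domain(model$ptr, domain, as.matrix(fa), as.matrix(ftr),
                     as.matrix(fb))
}

#' Total fusion: concatenate both domains
#'
#' Time-domain block first; pure concatenation along the sequence axis.
#'
#' @param ftd,ftfd `T3 x 40` and `T4 x 40` feature sequences.
#' @return `(T3+T4) x 40` matrix.
#' @export
fuse_total <- function(ftd, ftfd) {
  ftd <- as.matrix(ftd); ftfd <- as.matrix(ftfd)
  if (nrow(ftfd) < 1 || nrow(ftd) < 1) stop("empty fusion operand")
  if (ncol(ftd) != ncol(ftfd)) stop("channel mismatch in fuse_total")
  rbind(ftd, ftfd)
}

#' MLP-attention weighted fusion
#'
#' Mean-pools each feature group to a 40-vector, scores the three pooled
#' vectors with a shared two-layer perceptron, softmax-normalizes the
#' scores into weights, and returns the weighted combination
#' (optionally passed through a kernel-1 convolution for
#' `mode = "weighted_cnn"`).
#'
#' @param model An `lgnet_model` built with a weighted `fusion_strategy`.
#' @param fa,ftr,fb The three `* x 40` feature sequences.
#' @param mode `"weighted"` or `"weighted_cnn"`.
#' @param domain `"td"` or `"tfd"`.
#' @return List with `F` (`1 x 40`) and `weights` (length 3, sums to 1).
#' @export
weighted_fusion <- function(model, fa, ftr, fb,
                            mode = c("weighted", "weighted_cnn"),
                            domain = c("td", "tfd")) {
  mode <- match.arg(mode)
  domain <- match.arg(domain)
  cpp_op_weighted_fusion(model$ptr, domain, as.matrix(fa), as.matrix(ftr),
                         as.matrix(fb), mode)
}

#' Classification head
#'
#' Flattens the fused feature sequence, applies a hidden fully connected
#' layer with ELU and dropout, a final linear layer to m logits, and
#' softmax.
#'
#' @param model An `lgnet_model`.
#' @param F Feature sequence matching the configured flattened width.
#' @return List with `z` (logits, `1 x m`) and `p` (probabilities).
#' @export
classify <- function(model, F) {
  cpp_op_classify(model$ptr, as.matrix(F))
}

#' All intermediate stage outputs for one segment
#'
#' @param model An `lgnet_model`.
#' @param x Raw segment (`segment_seconds * fs` samples, ideally z-scored).
#' @return Named list of stage matrices plus `logits` and `probs`.
#' @export
forward_stages <- function(model, x) {
  sp <- segment_spec_array(model, matrix(as.numeric(x), nrow = 1))
  cpp_net_stages(model$ptr, matrix(as.numeric(x), ncol = 1), sp)
}

#' Class probabilities for a batch of segments
#'
#' @param model An `lgnet_model`.
#' @param segments Matrix (segments x samples); z-scoring is applied.
#' @param chunk Segments processed per internal batch.
#' @return Matrix (segments x num_classes) of probabilities.
#' @export
predict_proba <- function(model, segments, chunk = 16L) {
  segments <- as.matrix(segments)
  n <- nrow(segments)
  out <- matrix(0, n, model$config$num_classes)
  for (i0 in seq(1, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1)
    xs <- t(apply(segments[idx, , drop = FALSE], 1, zscore_segment))
    sp <- segment_spec_array(model, xs)
    out[idx, ] <- cpp_net_forward(model$ptr, t(xs), sp)
  }
  out
}

# spectrogram array (bins x frames x batch) for a matrix of z-scored rows
segment_spec_array <- function(model, xs) {
  if (model$config$variant != "full")
    return(array(0, dim = c(1, 1, nrow(xs))))
  d <- model$dims
  sp <- array(0, dim = c(d$spec_bins, d$spec_frames, nrow(xs)))
  for (i in seq_len(nrow(xs)))
    sp[, , i] <- stft_spectrogram(xs[i, ], fs = model$config$fs)$values
  sp
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights, batch-norm running statistics, the
#' full [model_config()] and the class vocabulary; loading reconstructs a
#' model with identical inference behaviour.
#'
#' @param model An `lgnet_model`.
#' @param path Destination file.
#' @param class_vocabulary Optional character vector stored alongside.
#' @return `save_checkpoint`: invisibly, `path`. `load_checkpoint`: a list
#'   with elements `model` and `class_vocabulary`.
#' @export
save_checkpoint <- function(model, path, class_vocabulary = NULL) {
  obj <- list(config = model$config,
              params = cpp_net_get_params(model$ptr),
              buffers = cpp_net_get_buffers(model$ptr),
              class_vocabulary = class_vocabulary,
              seed = model$config$seed,
              fingerprint = config_fingerprint(model$config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config)
  cpp_net_set_params(model$ptr, obj$params)
  cpp_net_set_buffers(model$ptr, obj$buffers)
  list(model = model, class_vocabulary = obj$class_vocabulary)
}

# short deterministic fingerprint of any config-like list
config_fingerprint <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
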