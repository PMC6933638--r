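#' Training configuration
#'
#' @param epochs Maximum training epochs (default 50).
#' @param batch_size Mini-batch size; `NULL` takes the spec's default
#'   (32 struct / 64 one-hot).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param seed Integer seed governing weight init, batch shuffling and
#'   dropout.
#' @param patience Early stopping: stop when the epoch training loss has not
#'   improved by `min_delta` for this many epochs (default 5).
#' @param min_delta Minimum loss improvement counted by `patience`.
#' @param verbose Print the loss each epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = NULL,
                         learning_rate = 0.001, seed = 1L, patience = 5L,
                         min_delta = 1e-4, verbose = FALSE) {
  stopifnot(epochs >= 1, is.null(batch_size) || batch_size >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 patience = as.integer(patience), min_delta = min_delta,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# spec inferred from an encoded dataset when the caller does not supply one
default_spec_for <- function(encoded, classes) {
  if (encoded$kind == "onehot") {
    onehot_cnn_spec(classes = classes, input_len = encoded$L)
  } else {
    struct_cnn_spec(classes = classes, input_len = encoded$L,
                    channels = if (encoded$kind == "mixed") 2L else 1L)
  }
}

#' Train a CNN classifier on an encoded dataset
#'
#' Minimizes the softmax cross-entropy with Adam over shuffled mini-batches.
#' Training is deterministic given `config$seed` (single-threaded BLAS).
#'
#' @param encoded An `encoded_dataset` from [encode_dataset()].
#' @param spec Optional `cnn_spec`; defaults to the published architecture
#'   for the dataset's encoding kind, sized to its `L` and class count.
#' @param config A [train_config()].
#' @return A `trained_classifier`: list with `model`, `spec`, `label_map`,
#'   `history` (per-epoch mean training loss), `encoding` metadata and the
#'   default rejection `threshold` (0.977).
#' @export
train_cnn <- function(encoded, spec = NULL, config = train_config()) {
  labels <- encoded$labels
  n <- length(encoded$inputs)
  if (n == 0L) stop("empty dataset")
  classes <- length(encoded$label_index)
  if (classes < 2L) stop("training needs at least two classes")
  if (is.null(spec)) spec <- default_spec_for(encoded, classes)
  if (spec$classes != classes) {
    stop("spec has ", spec$classes, " classes but dataset has ", classes)
  }
  if ((spec$kind == "onehot") != (encoded$kind == "onehot")) {
    stop("spec kind and encoding kind disagree")
  }
  batch <- if (is.null(config$batch_size)) spec$batch_size else
    as.integer(config$batch_size)
  lr <- if (is.null(config$learning_rate)) spec$learning_rate else
    config$learning_rate

  model <- build_cnn(spec, seed = config$seed)
  weights <- model$weights
  state <- adam_state(weights)
  set.seed(config$seed + 1L)
  Y <- diag(classes)[labels + 1L, , drop = FALSE]

  idx_list <- if (spec$kind == "onehot") {
    lapply(spec$filter_widths, function(w) onehot_im2col_idx(spec$input_len, w))
  }

  history <- numeric(0)
  best <- Inf
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = batch)) {
      take <- perm[start:min(start + batch - 1L, n)]
      step <- if (spec$kind == "onehot") {
        onehot_batch_step(encoded$inputs[take], Y[take, , drop = FALSE],
                          weights, spec, idx_list)
      } else {
        struct_batch_step(encoded$inputs[take], Y[take, , drop = FALSE],
                          weights, spec)
      }
      upd <- adam_step(weights, step$grads, state, lr)
      weights <- upd$weights
      state <- upd$state
      epoch_loss <- epoch_loss + step$loss * length(take)
    }
    epoch_loss <- epoch_loss / n
    history <- c(history, epoch_loss)
    if (config$verbose) {
      message(sprintf("epoch %d  loss %.5f", epoch, epoch_loss))
    }
    if (epoch_loss < best - config$min_delta) {
      best <- epoch_loss
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$weights <- weights
  structure(list(model = model, spec = spec,
                 label_map = encoded$label_index, history = history,
                 encoding = list(kind = encoded$kind, T = encoded$T,
                                 ordered = encoded$ordered, L = encoded$L),
                 threshold = 0.977, config = config),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("trained_classifier:", x$spec$kind, "CNN,",
      length(x$label_map), "classes,", length(x$history),
      "epochs, final loss", signif(utils::tail(x$history, 1), 4), "\n")
  invisible(x)
}

# ---- batched training steps ------------------------------------------------

onehot_batch_step <- function(inputs, Y, weights, spec, idx_list) {
  B <- length(inputs)
  widths <- spec$filter_widths
  k <- spec$kernels_per_width
  Gb <- onehot_stack(inputs)
  fw <- lapply(seq_along(widths), function(wi) {
    w <- widths[wi]
    onehot_fwd_width(Gb, weights[[paste0("Wconv", w)]],
                     weights[[paste0("bconv", w)]], idx_list[[wi]])
  })
  F <- do.call(cbind, lapply(fw, function(f) relu(f$mx)))
  keep <- 1 - spec$dropout
  Din <- matrix(stats::runif(length(F)) < keep, nrow(F)) / keep
  Fd <- F * Din
  Z1 <- sweep_bias(Fd %*% weights$Wd1, weights$bd1)
  H1 <- relu(Z1)
  D1 <- matrix(stats::runif(length(H1)) < keep, nrow(H1)) / keep
  H1d <- H1 * D1
  logits <- sweep_bias(H1d %*% weights$Wout, weights$bout)
  S <- softmax_rows(logits)
  loss <- -mean(log(pmax(rowSums(S * Y), 1e-12)))
  dlog <- (S - Y) / B
  grads <- list(Wout = crossprod(H1d, dlog), bout = colSums(dlog))
  dH1 <- (dlog %*% t(weights$Wout)) * D1 * (Z1 > 0)
  grads$Wd1 <- crossprod(Fd, dH1)
  grads$bd1 <- colSums(dH1)
  dF <- (dH1 %*% t(weights$Wd1)) * Din
  # route pooled-feature gradients back through global max + relu to the
  # convolution weights
  for (wi in seq_along(widths)) {
    w <- widths[wi]
    cols <- ((wi - 1L) * k + 1L):(wi * k)
    g <- dF[, cols, drop = FALSE] * (fw[[wi]]$mx > 0)
    bw <- onehot_bwd_width(Gb, idx_list[[wi]], fw[[wi]]$arg, g)
    grads[[paste0("Wconv", w)]] <- bw$dW
    grads[[paste0("bconv", w)]] <- bw$db
  }
  list(loss = loss, grads = grads)
}

struct_batch_step <- function(inputs, Y, weights, spec) {
  B <- length(inputs)
  fw <- lapply(inputs, function(g) struct_conv_fwd(as_input_array(g), weights))
  F <- do.call(rbind, lapply(fw, `[[`, "flat"))
  keep <- 1 - spec$dropout
  Z1 <- sweep_bias(F %*% weights$Wd1, weights$bd1)
  H1 <- relu(Z1)
  D1 <- matrix(stats::runif(length(H1)) < keep, nrow(H1)) / keep
  H1d <- H1 * D1
  Z2 <- sweep_bias(H1d %*% weights$Wd2, weights$bd2)
  H2 <- relu(Z2)
  D2 <- matrix(stats::runif(length(H2)) < keep, nrow(H2)) / keep
  H2d <- H2 * D2
  logits <- sweep_bias(H2d %*% weights$Wout, weights$bout)
  S <- softmax_rows(logits)
  loss <- -mean(log(pmax(rowSums(S * Y), 1e-12)))
  dlog <- (S - Y) / B
  grads <- list(Wout = crossprod(H2d, dlog), bout = colSums(dlog))
  dH2 <- (dlog %*% t(weights$Wout)) * D2 * (Z2 > 0)
  grads$Wd2 <- crossprod(H1d, dH2)
  grads$bd2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(weights$Wd2)) * D1 * (Z1 > 0)
  grads$Wd1 <- crossprod(F, dH1)
  grads$bd1 <- colSums(dH1)
  dF <- dH1 %*% t(weights$Wd1)
  k2 <- spec$conv_kernels[2]
  dWc1 <- array(0, dim(weights$Wconv1)); dbc1 <- numeric(ncol(weights$Wconv1))
  dWc2 <- array(0, dim(weights$Wconv2)); dbc2 <- numeric(k2)
  for (s in seq_len(B)) {
    f <- fw[[s]]
    dP2 <- dF[s, ]
    dim(dP2) <- dim(f$pool2$out)
    dA2 <- maxpool2_bwd(f$pool2, dP2)
    h2 <- dim(dA2)[1]
    dZ2 <- matrix(dA2, h2 * h2, k2) * f$relu2
    dWc2 <- dWc2 + crossprod(f$X2, dZ2)
    dbc2 <- dbc2 + colSums(dZ2)
    dX2 <- dZ2 %*% t(weights$Wconv2)
    dP1 <- col2im_2x2(dX2, dim(f$pool1$out)[1], dim(f$pool1$out)[2],
                      ncol(weights$Wconv1))
    dA1 <- maxpool2_bwd(f$pool1, dP1)
    h1 <- dim(dA1)[1]
    dZ1 <- matrix(dA1, h1 * h1, ncol(weights$Wconv1)) * f$relu1
    dWc1 <- dWc1 + crossprod(f$X1, dZ1)
    dbc1 <- dbc1 + colSums(dZ1)
  }
  grads$Wconv1 <- dWc1; grads$bconv1 <- dbc1
  grads$Wconv2 <- dWc2; grads$bconv2 <- dbc2
  list(loss = loss, grads = grads)
}

# ---- inference -------------------------------------------------------------

#' Softmax probabilities for encoded inputs
#'
#' Forward pass without dropout (inverted dropout needs no rescaling at test
#' time). Rows sum to 1.
#'
#' @param classifier A `trained_classifier`.
#' @param encoded An `encoded_dataset` encoded identically to training.
#' @return Numeric matrix, one row per sequence, one column per class
#'   (columns named by family).
#' @export
predict_softmax <- function(classifier, encoded) {
  spec <- classifier$spec
  if (encoded$kind != classifier$encoding$kind) {
    stop("encoding mismatch: model trained on ", classifier$encoding$kind,
         ", inputs are ", encoded$kind)
  }
  if (encoded$L != classifier$encoding$L) {
    stop("padded length mismatch: model expects L = ", classifier$encoding$L)
  }
  weights <- classifier$model$weights
  if (spec$kind == "onehot") {
    idx_list <- lapply(spec$filter_widths,
                       function(w) onehot_im2col_idx(spec$input_len, w))
    chunks <- split(seq_along(encoded$inputs),
                    ceiling(seq_along(encoded$inputs) / 128))
    F <- do.call(rbind, lapply(chunks, function(take) {
      Gb <- onehot_stack(encoded$inputs[take])
      do.call(cbind, lapply(seq_along(spec$filter_widths), function(wi) {
        w <- spec$filter_widths[wi]
        relu(onehot_fwd_width(Gb, weights[[paste0("Wconv", w)]],
                              weights[[paste0("bconv", w)]],
                              idx_list[[wi]])$mx)
      }))
    }))
    H1 <- relu(sweep_bias(F %*% weights$Wd1, weights$bd1))
    logits <- sweep_bias(H1 %*% weights$Wout, weights$bout)
  } else {
    F <- do.call(rbind, lapply(encoded$inputs, function(g) {
      struct_conv_fwd(as_input_array(g), weights)$flat
    }))
    H1 <- relu(sweep_bias(F %*% weights$Wd1, weights$bd1))
    H2 <- relu(sweep_bias(H1 %*% weights$Wd2, weights$bd2))
    logits <- sweep_bias(H2 %*% weights$Wout, weights$bout)
  }
  S <- softmax_rows(logits)
  colnames(S) <- names(classifier$label_map)[order(classifier$label_map)]
  rownames(S) <- encoded$ids
  S
}

# argmax class ids (0-based), ties broken toward the lowest class id
argmax_class <- function(S) {
  max.col(S, ties.method = "first") - 1L
}

#' Evaluate a classifier on an encoded test set
#'
#' Predictions are the softmax argmax (no rejection). Per-class precision,
#' recall and F-score use TP/(TP+FP), TP/(TP+FN) and their harmonic mean;
#' zero denominators yield 0 so the macro F-score stays defined.
#'
#' @param classifier A `trained_classifier`.
#' @param encoded Test `encoded_dataset`; its labels must all be classes the
#'   model was trained on.
#' @return An `eval_report`: list with `accuracy`, `per_class` data frame
#'   (family, TP, FP, FN, precision, recall, fscore) and `macro_fscore`.
#' @export
evaluate_cnn <- function(classifier, encoded) {
  if (!all(names(encoded$label_index) %in% names(classifier$label_map))) {
    stop("test set contains families unseen in training")
  }
  # map test labels into the model's class ids
  truth <- unname(classifier$label_map[
    names(encoded$label_index)[match(encoded$labels,
                                     encoded$label_index)]])
  S <- predict_softmax(classifier, encoded)
  pred <- argmax_class(S)
  eval_report(truth, pred, classifier$label_map)
}

# confusion-based report over 0-based class ids
eval_report <- function(truth, pred, label_map) {
  classes <- sort(unname(label_map))
  fam <- names(label_map)[order(label_map)]
  tp <- fp <- fn <- integer(length(classes))
  for (ci in seq_along(classes)) {
    c0 <- classes[ci]
    tp[ci] <- sum(truth == c0 & pred == c0)
    fp[ci] <- sum(truth != c0 & pred == c0)
    fn[ci] <- sum(truth == c0 & pred != c0)
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  fscore <- ifelse(precision + recall > 0,
                   2 * precision * recall / (precision + recall), 0)
  structure(list(
    accuracy = mean(truth == pred),
    per_class = data.frame(family = fam, TP = tp, FP = fp, FN = fn,
                           precision = precision, recall = recall,
                           fscore = fscore, stringsAsFactors = FALSE),
    macro_fscore = mean(fscore)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.4f, macro F-score %.4f (%d classes)\n",
              x$accuracy, x$macro_fscore, nrow(x$per_class)))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits every class as evenly as possible into `k` disjoint, exhaustive
#' folds (deterministic under `config$seed`), trains on k-1 folds and
#' evaluates on the held-out fold.
#'
#' @param encoded An `encoded_dataset` covering the full dataset.
#' @param k Number of folds (default 5).
#' @param spec Optional `cnn_spec` passed to [train_cnn()].
#' @param config A [train_config()].
#' @return List of `k` `eval_report`s, with the fold assignment in
#'   attribute `folds`.
#' @export
kfold_cv <- function(encoded, k = 5L, spec = NULL, config = train_config()) {
  if (k < 2L) stop("k must be at least 2")
  folds <- stratified_folds(encoded$labels, k, seed = config$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_encoded(encoded, folds != f)
    te <- subset_encoded(encoded, folds == f)
    fit <- train_cnn(tr, spec = spec, config = config)
    reports[[f]] <- evaluate_cnn(fit, te)
  }
  attr(reports, "folds") <- folds
  reports
}

# per-class round-robin fold assignment after a seeded shuffle
stratified_folds <- function(labels, k, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (c0 in unique(labels)) {
    members <- which(labels == c0)
    if (length(members) < k) {
      stop("class ", c0, " has fewer than k = ", k, " members")
    }
    folds[sample(members)] <- rep_len(seq_len(k), length(members))
  }
  folds
}

# restrict an encoded_dataset to a logical/integer index
subset_encoded <- function(encoded, idx) {
  out <- encoded
  out$inputs <- encoded$inputs[idx]
  out$labels <- encoded$labels[idx]
  out$seq_len <- encoded$seq_len[idx]
  out$ids <- encoded$ids[idx]
  out
}
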