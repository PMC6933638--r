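#' Specification of the structure-matrix CNN
#'
#' The architecture used for the probability, pair and mixed matrices: two
#' valid (no-padding) 2x2 convolutions with 64 and 128 filters, each followed
#' by window-2 stride-2 floor max pooling, then fully connected layers of
#' 256 and 128 ReLU units (dropout 0.5 after each) and a softmax output.
#' With the default input size 200 the feature-map trace is
#' 200 -> 199 -> 99 -> 98 -> 49.
#'
#' @param classes Number of output classes (>= 2).
#' @param input_len Side length of the square input (default 200).
#' @param channels 1 for probability/pair, 2 for mixed.
#' @param conv_kernels Filters in the two convolution stages.
#' @param fc_units Units in the two hidden dense stages.
#' @param dropout Dropout rate after each hidden dense stage.
#' @param learning_rate,batch_size Adam learning rate and mini-batch size.
#' @return A `struct_cnn_spec`.
#' @export
struct_cnn_spec <- function(classes, input_len = 200L, channels = 1L,
                            conv_kernels = c(64L, 128L),
                            fc_units = c(256L, 128L), dropout = 0.5,
                            learning_rate = 0.001, batch_size = 32L) {
  stopifnot(classes >= 2, channels %in% c(1L, 2L),
            length(conv_kernels) == 2L, length(fc_units) == 2L)
  spec <- structure(list(kind = "struct", input_len = as.integer(input_len),
                         channels = as.integer(channels),
                         conv_kernels = as.integer(conv_kernels),
                         fc_units = as.integer(fc_units), dropout = dropout,
                         learning_rate = learning_rate,
                         batch_size = as.integer(batch_size),
                         classes = as.integer(classes)),
                    class = c("struct_cnn_spec", "cnn_spec"))
  struct_shape_trace(spec)  # validates the input is large enough
  spec
}

# feature-map sizes through conv/pool stages; errors when a stage collapses
struct_shape_trace <- function(spec) {
  L <- spec$input_len
  h1 <- L - 1L
  p1 <- h1 %/% 2L
  h2 <- p1 - 1L
  p2 <- h2 %/% 2L
  if (h1 < 1L || p1 < 1L || h2 < 1L || p2 < 1L) {
    stop("input_len ", L,
         " too small for two valid 2x2 convolutions with floor pooling")
  }
  c(conv1 = h1, pool1 = p1, conv2 = h2, pool2 = p2)
}

#' Specification of the one-hot CNN
#'
#' A single convolution stage with several filter widths applied in parallel
#' to the L x 4 one-hot matrix (valid convolution spanning all 4 base
#' columns), global max pooling per filter, concatenation, dropout 0.7, one
#' dense ReLU stage of 1024 units, dropout 0.7, and a softmax output.
#'
#' @param classes Number of output classes (>= 2).
#' @param input_len Padded sequence length (default 200).
#' @param filter_widths Convolution filter widths (default 2,4,...,16).
#' @param kernels_per_width Filters per width (default 512).
#' @param fc_units Units in the single hidden dense stage (default 1024).
#' @param dropout Dropout rate (default 0.7).
#' @param learning_rate,batch_size Adam learning rate and mini-batch size.
#' @return A `onehot_cnn_spec`.
#' @export
onehot_cnn_spec <- function(classes, input_len = 200L,
                            filter_widths = seq(2L, 16L, 2L),
                            kernels_per_width = 512L, fc_units = 1024L,
                            dropout = 0.7, learning_rate = 0.001,
                            batch_size = 64L) {
  stopifnot(classes >= 2, length(fc_units) == 1L, kernels_per_width >= 1)
  if (any(filter_widths > input_len)) {
    stop("filter width exceeds input length ", input_len)
  }
  structure(list(kind = "onehot", input_len = as.integer(input_len),
                 filter_widths = as.integer(filter_widths),
                 kernels_per_width = as.integer(kernels_per_width),
                 fc_units = as.integer(fc_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 classes = as.integer(classes)),
            class = c("onehot_cnn_spec", "cnn_spec"))
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(x$kind, "CNN spec: input", x$input_len, "->", x$classes, "classes,",
      format(count_parameters(x), big.mark = ","), "trainable parameters\n")
  invisible(x)
}

#' Closed-form trainable parameter count
#'
#' Sums the weights and biases of every convolution and dense stage of a
#' spec analytically (dropout and pooling contribute nothing). With the
#' published hyperparameters this reproduces the printed totals: 4,485,255
#' for the one-hot model over 135 classes and 78,748,399 for the
#' structure-matrix model over 47 classes. The count always equals
#' [n_parameters()] of the built model.
#'
#' @param spec A `struct_cnn_spec` or `onehot_cnn_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  if (inherits(spec, "struct_cnn_spec")) {
    tr <- struct_shape_trace(spec)
    k <- spec$conv_kernels
    flat <- tr["pool2"]^2 * k[2]
    conv <- (2 * 2 * spec$channels * k[1] + k[1]) +
            (2 * 2 * k[1] * k[2] + k[2])
    dense <- (flat * spec$fc_units[1] + spec$fc_units[1]) +
             (spec$fc_units[1] * spec$fc_units[2] + spec$fc_units[2])
    out <- spec$fc_units[2] * spec$classes + spec$classes
    return(as.integer(conv + dense + out))
  }
  if (inherits(spec, "onehot_cnn_spec")) {
    k <- spec$kernels_per_width
    conv <- sum(spec$filter_widths * 4 * k + k)
    pooled <- length(spec$filter_widths) * k
    dense <- pooled * spec$fc_units + spec$fc_units
    out <- spec$fc_units * spec$classes + spec$classes
    return(as.integer(conv + dense + out))
  }
  stop("not a cnn_spec")
}

#' Build an untrained CNN from a spec
#'
#' Initializes all weights (Glorot uniform, zero biases) deterministically
#' under `seed` and returns a model handle whose reported parameter count
#' ([n_parameters()]) can be cross-checked against [count_parameters()].
#'
#' @param spec A `cnn_spec`.
#' @param seed Integer RNG seed for weight initialization.
#' @return A `cnn_model`: list with `spec` and `weights`.
#' @export
build_cnn <- function(spec, seed = 1L) {
  set.seed(seed)
  if (inherits(spec, "struct_cnn_spec")) {
    tr <- struct_shape_trace(spec)
    k <- spec$conv_kernels
    flat <- as.integer(tr["pool2"]^2 * k[2])
    weights <- list(
      Wconv1 = glorot(4 * spec$channels, k[1]),
      bconv1 = numeric(k[1]),
      Wconv2 = glorot(4 * k[1], k[2]),
      bconv2 = numeric(k[2]),
      Wd1 = glorot(flat, spec$fc_units[1]),
      bd1 = numeric(spec$fc_units[1]),
      Wd2 = glorot(spec$fc_units[1], spec$fc_units[2]),
      bd2 = numeric(spec$fc_units[2]),
      Wout = glorot(spec$fc_units[2], spec$classes),
      bout = numeric(spec$classes))
  } else if (inherits(spec, "onehot_cnn_spec")) {
    k <- spec$kernels_per_width
    weights <- list()
    for (w in spec$filter_widths) {
      weights[[paste0("Wconv", w)]] <- glorot(4 * w, k)
      weights[[paste0("bconv", w)]] <- numeric(k)
    }
    pooled <- length(spec$filter_widths) * k
    weights$Wd1 <- glorot(pooled, spec$fc_units)
    weights$bd1 <- numeric(spec$fc_units)
    weights$Wout <- glorot(spec$fc_units, spec$classes)
    weights$bout <- numeric(spec$classes)
  } else {
    stop("not a cnn_spec")
  }
  structure(list(spec = spec, weights = weights), class = "cnn_model")
}

#' Trainable parameter count reported by a built model
#'
#' The sum of the lengths of every weight and bias array actually allocated
#' in the model — the engine-side counterpart of the closed-form
#' [count_parameters()].
#'
#' @param model A `cnn_model` or `trained_classifier`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "trained_classifier")) model <- model$model
  as.integer(sum(vapply(model$weights, length, numeric(1))))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("cnn_model (", x$spec$kind, "): ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}
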