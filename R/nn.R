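# Minimal deterministic CNN engine: valid convolutions via im2col + BLAS
# matrix products, floor max pooling, inverted dropout, Adam. All state is
# plain R arrays so models are portable and training is reproducible from a
# single RNG seed.

# ---- primitives -----------------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# im2col for a 2x2 valid convolution over an H x W x C array.
# Rows index windows column-major over (row, col); columns index
# (dr, dc, channel) with dr fastest.
im2col_2x2 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  h <- H - 1L; w <- W - 1L
  out <- array(0, c(h, w, 2L, 2L, C))
  for (a in 1:2) for (b in 1:2) {
    out[, , a, b, ] <- x[a:(h + a - 1L), b:(w + b - 1L), , drop = FALSE]
  }
  dim(out) <- c(h * w, 4L * C)
  out
}

# scatter-add inverse of im2col_2x2
col2im_2x2 <- function(dcol, H, W, C) {
  h <- H - 1L; w <- W - 1L
  dim(dcol) <- c(h, w, 2L, 2L, C)
  dx <- array(0, c(H, W, C))
  for (a in 1:2) for (b in 1:2) {
    dx[a:(h + a - 1L), b:(w + b - 1L), ] <-
      dx[a:(h + a - 1L), b:(w + b - 1L), , drop = FALSE] + dcol[, , a, b, ]
  }
  dx
}

# 2x2 stride-2 max pooling with floor semantics; returns pooled array and
# the four winner masks (first-wins tie break) needed for the backward pass.
maxpool2_fwd <- function(x) {
  d <- dim(x)
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L; C <- d[3]
  r1 <- seq.int(1L, 2L * ho, 2L); r2 <- r1 + 1L
  c1 <- seq.int(1L, 2L * wo, 2L); c2 <- c1 + 1L
  s11 <- x[r1, c1, , drop = FALSE]; s21 <- x[r2, c1, , drop = FALSE]
  s12 <- x[r1, c2, , drop = FALSE]; s22 <- x[r2, c2, , drop = FALSE]
  m <- pmax(s11, s21, s12, s22)
  m1 <- s11 == m
  m2 <- s21 == m & !m1
  m3 <- s12 == m & !m1 & !m2
  m4 <- s22 == m & !m1 & !m2 & !m3
  list(out = m, masks = list(m1, m2, m3, m4), H = d[1], W = d[2], C = C)
}

maxpool2_bwd <- function(pool, dout) {
  ho <- dim(dout)[1]; wo <- dim(dout)[2]
  r1 <- seq.int(1L, 2L * ho, 2L); r2 <- r1 + 1L
  c1 <- seq.int(1L, 2L * wo, 2L); c2 <- c1 + 1L
  dx <- array(0, c(pool$H, pool$W, pool$C))
  dx[r1, c1, ] <- dout * pool$masks[[1]]
  dx[r2, c1, ] <- dx[r2, c1, , drop = FALSE] + dout * pool$masks[[2]]
  dx[r1, c2, ] <- dx[r1, c2, , drop = FALSE] + dout * pool$masks[[3]]
  dx[r2, c2, ] <- dx[r2, c2, , drop = FALSE] + dout * pool$masks[[4]]
  dx
}

# Glorot-uniform weight init (the usual framework default)
glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# add a bias row-vector to every row of a matrix
sweep_bias <- function(m, b) m + rep(b, each = nrow(m))

# ---- Adam optimizer -------------------------------------------------------

adam_state <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  # fold both bias corrections into the step size (epsilon-hat variant)
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (k in names(weights)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    weights[[k]] <- weights[[k]] -
      lr_t * state$m[[k]] / (sqrt(state$v[[k]]) + eps)
  }
  list(weights = weights, state = state)
}

# ---- one-hot architecture forward/backward --------------------------------

# index matrix mapping windows of width w over an L x 4 one-hot grid
# (column-major) to im2col rows; columns ordered (offset, base), offset
# fastest, matching the conv weight row layout.
onehot_im2col_idx <- function(L, w) {
  windows <- L - w + 1L
  o <- rep(seq_len(w), times = 4L)            # offset within window
  b <- rep(seq_len(4L), each = w)             # base column
  idx <- outer(seq_len(windows) - 1L, o + (b - 1L) * L, `+`)
  storage.mode(idx) <- "integer"
  idx
}

# flatten a list of L x 4 grids into one (4L) x n matrix so a whole batch
# can be convolved with a single matrix product per filter width
onehot_stack <- function(inputs) {
  matrix(unlist(inputs, use.names = FALSE), length(inputs[[1]]),
         length(inputs))
}

# batched convolution + global max pool for one filter width.
# Gb: (4L) x B stacked grids. Returns pre-relu max values and argmax window
# (each B x k, leftmost window wins ties).
onehot_fwd_width <- function(Gb, W, bias, idx) {
  windows <- nrow(idx)
  B <- ncol(Gb)
  L4 <- nrow(Gb)
  k <- ncol(W)
  idx_big <- idx[rep(seq_len(windows), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * L4, each = windows)
  X <- matrix(Gb[idx_big], windows * B, ncol(idx))
  A <- X %*% W
  dim(A) <- c(windows, B * k)          # layout: window, sample, filter
  # the per-filter bias is constant over windows, so pool first, add after
  ai <- max.col(t(A), ties.method = "first")
  cur <- A[cbind(ai, seq_len(B * k))]
  mx <- matrix(cur, B, k)
  mx <- mx + rep(bias, each = B)
  list(mx = mx, arg = matrix(ai, B, k))
}

# gradient of the conv weights/bias of one width through global max + relu.
# g: B x k upstream gradient already masked by the relu at the max.
onehot_bwd_width <- function(Gb, idx, arg, g) {
  B <- ncol(Gb)
  L4 <- nrow(Gb)
  k <- ncol(g)
  bvec <- rep_len(seq_len(B), B * k)
  idx_sel <- idx[as.vector(arg), , drop = FALSE] + (bvec - 1L) * L4
  Xsel <- matrix(Gb[idx_sel], B * k, ncol(idx))
  Xsel <- Xsel * as.vector(g)
  dim(Xsel) <- c(B, k, ncol(idx))
  list(dW = t(colSums(Xsel)), db = colSums(g))
}

# ---- struct architecture forward (single sample) --------------------------

struct_conv_fwd <- function(x, weights) {
  X1 <- im2col_2x2(x)
  Z1 <- sweep_bias(X1 %*% weights$Wconv1, weights$bconv1)
  R1 <- relu(Z1)
  h1 <- dim(x)[1] - 1L
  A1 <- R1; dim(A1) <- c(h1, h1, ncol(Z1))
  pool1 <- maxpool2_fwd(A1)
  X2 <- im2col_2x2(pool1$out)
  Z2 <- sweep_bias(X2 %*% weights$Wconv2, weights$bconv2)
  R2 <- relu(Z2)
  h2 <- dim(pool1$out)[1] - 1L
  A2 <- R2; dim(A2) <- c(h2, h2, ncol(Z2))
  pool2 <- maxpool2_fwd(A2)
  list(X1 = X1, relu1 = Z1 > 0, pool1 = pool1,
       X2 = X2, relu2 = Z2 > 0, pool2 = pool2,
       flat = as.vector(pool2$out))
}

# as 3D array regardless of channel count
as_input_array <- function(grid) {
  if (length(dim(grid)) == 2L) dim(grid) <- c(dim(grid), 1L)
  grid
}
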