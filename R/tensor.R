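# Low-level tensor primitives for the network.
#
# Feature maps are dense arrays with dim c(C, H, W, B): channels vary fastest,
# batch slowest. Convolutions use im2col built by looping over the (at most
# kh*kw) kernel offsets with strided slice copies, so the heavy lifting is one
# BLAS matmul per layer. Every op has a matching backward used by the trainer.
# Output sizes follow the floor convention o = (n + 2p - k) %/% s + 1.

#' Exact-erf Gaussian Error Linear Unit
#'
#' Elementwise `GeLU(x) = x/2 * (1 + erf(x / sqrt(2)))`, evaluated through the
#' Gaussian CDF (`erf(x/sqrt(2)) = 2*pnorm(x) - 1`), i.e. the exact form rather
#' than the tanh approximation.
#'
#' @param x numeric vector or array.
#' @return Array of the same shape as `x`.
#' @examples
#' gelu(c(-1, 0, 1))
#' @export
gelu <- function(x) {
  stopifnot(is.numeric(x))
  x * stats::pnorm(x)
}

# d/dx gelu(x) = Phi(x) + x phi(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- padding -------------------------------------------------------------

pad_spatial <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

crop_spatial <- function(x, p, h, w) {
  if (p == 0) return(x)
  x[, (p + 1):(p + h), (p + 1):(p + w), , drop = FALSE]
}

conv_out_size <- function(n, k, stride, pad) {
  o <- (n + 2 * pad - k) %/% stride + 1
  if (o < 1) stop("spatial size ", n, " too small for kernel ", k)
  o
}

# ---- dense convolution ---------------------------------------------------

# Weights are stored flat: W is (C_out) x (C_in*kh*kw), column blocks ordered
# by kernel offset (kj outer, ki inner), channels fastest within a block.

conv2d_init <- function(c_in, c_out, k) {
  fan_in <- c_in * k * k
  list(W = matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = c_out),
       b = numeric(c_out), ksize = k)
}

im2col <- function(xp, k, stride, oh, ow) {
  d <- dim(xp)
  cin <- d[1]; b <- d[4]
  p <- matrix(0, cin * k * k, oh * ow * b)
  idx <- 0L
  for (kj in seq_len(k)) {
    cols <- kj + stride * (0:(ow - 1))
    for (ki in seq_len(k)) {
      rows <- ki + stride * (0:(oh - 1))
      p[(idx * cin + 1):((idx + 1) * cin), ] <-
        xp[, rows, cols, , drop = FALSE]
      idx <- idx + 1L
    }
  }
  p
}

conv2d_forward <- function(par, x, stride = 1, pad = 0) {
  d <- dim(x)
  k <- par$ksize
  cin <- ncol(par$W) / (k * k)
  if (d[1] != cin)
    stop("conv2d: expected ", cin, " input channels, got ", d[1])
  oh <- conv_out_size(d[2], k, stride, pad)
  ow <- conv_out_size(d[3], k, stride, pad)
  xp <- pad_spatial(x, pad)
  p <- im2col(xp, k, stride, oh, ow)
  y <- par$W %*% p + par$b
  list(out = array(y, c(nrow(par$W), oh, ow, d[4])),
       cache = list(p = p, in_dim = d, stride = stride, pad = pad, k = k))
}

conv2d_backward <- function(par, cache, dy) {
  d <- cache$in_dim
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  od <- dim(dy)
  dym <- matrix(dy, od[1])
  dW <- dym %*% t(cache$p)
  db <- rowSums(dym)
  dp <- crossprod(par$W, dym)                       # (cin*k*k) x (oh*ow*b)
  cin <- d[1]
  dxp <- array(0, c(cin, d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  idx <- 0L
  for (kj in seq_len(k)) {
    cols <- kj + stride * (0:(od[3] - 1))
    for (ki in seq_len(k)) {
      rows <- ki + stride * (0:(od[2] - 1))
      contrib <- array(dp[(idx * cin + 1):((idx + 1) * cin), ],
                       c(cin, od[2], od[3], od[4]))
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + contrib
      idx <- idx + 1L
    }
  }
  list(dpar = list(W = dW, b = db),
       dx = crop_spatial(dxp, pad, d[2], d[3]))
}

# ---- depthwise convolution ----------------------------------------------

# One k x k filter per channel (channel-preserving spatial mixing); this is
# the convolutional Q/K/V projection of the encoder. W is C x (k*k).

dwconv_init <- function(c_in, k) {
  list(W = matrix(stats::rnorm(c_in * k * k, sd = sqrt(2 / (k * k))),
                  nrow = c_in),
       b = numeric(c_in), ksize = k)
}

dwconv_forward <- function(par, x, stride = 1, pad = 1) {
  d <- dim(x)
  k <- par$ksize
  if (d[1] != nrow(par$W))
    stop("dwconv: expected ", nrow(par$W), " channels, got ", d[1])
  oh <- conv_out_size(d[2], k, stride, pad)
  ow <- conv_out_size(d[3], k, stride, pad)
  xp <- pad_spatial(x, pad)
  y <- array(0, c(d[1], oh, ow, d[4]))
  idx <- 0L
  for (kj in seq_len(k)) {
    cols <- kj + stride * (0:(ow - 1))
    for (ki in seq_len(k)) {
      idx <- idx + 1L
      y <- y + xp[, rows <- ki + stride * (0:(oh - 1)), cols, , drop = FALSE] *
        par$W[, idx]
    }
  }
  y <- y + par$b
  list(out = y, cache = list(xp = xp, in_dim = d, stride = stride, pad = pad,
                             k = k))
}

dwconv_backward <- function(par, cache, dy) {
  d <- cache$in_dim
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  od <- dim(dy)
  cin <- d[1]
  dW <- matrix(0, cin, k * k)
  db <- rowSums(matrix(dy, cin))
  dxp <- array(0, dim(cache$xp))
  idx <- 0L
  for (kj in seq_len(k)) {
    cols <- kj + stride * (0:(od[3] - 1))
    for (ki in seq_len(k)) {
      idx <- idx + 1L
      rows <- ki + stride * (0:(od[2] - 1))
      slice <- cache$xp[, rows, cols, , drop = FALSE]
      dW[, idx] <- rowSums(matrix(dy * slice, cin))
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] +
        dy * par$W[, idx]
    }
  }
  list(dpar = list(W = dW, b = db),
       dx = crop_spatial(dxp, pad, d[2], d[3]))
}

# ---- max pooling ---------------------------------------------------------

maxpool_forward <- function(x, k = 3, stride = 2, pad = 1) {
  d <- dim(x)
  oh <- conv_out_size(d[2], k, stride, pad)
  ow <- conv_out_size(d[3], k, stride, pad)
  xp <- pad_spatial(x, pad, value = -Inf)
  best <- array(-Inf, c(d[1], oh, ow, d[4]))
  arg <- array(0L, c(d[1], oh, ow, d[4]))
  idx <- 0L
  for (kj in seq_len(k)) {
    cols <- kj + stride * (0:(ow - 1))
    for (ki in seq_len(k)) {
      idx <- idx + 1L
      rows <- ki + stride * (0:(oh - 1))
      slice <- xp[, rows, cols, , drop = FALSE]
      upd <- slice > best
      best[upd] <- slice[upd]
      arg[upd] <- idx
    }
  }
  list(out = best, cache = list(arg = arg, in_dim = d, k = k,
                                stride = stride, pad = pad))
}

maxpool_backward <- function(cache, dy) {
  d <- cache$in_dim
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  od <- dim(dy)
  dxp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  idx <- 0L
  for (kj in seq_len(k)) {
    cols <- kj + stride * (0:(od[3] - 1))
    for (ki in seq_len(k)) {
      idx <- idx + 1L
      rows <- ki + stride * (0:(od[2] - 1))
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] +
        dy * (cache$arg == idx)
    }
  }
  crop_spatial(dxp, pad, d[2], d[3])
}

# ---- layer normalization (over channels at each spatial position) --------

layernorm_init <- function(c_in) list(gamma = rep(1, c_in),
                                      beta = numeric(c_in))

layernorm_forward <- function(par, x, eps = 1e-5) {
  d <- dim(x)
  cin <- d[1]
  xm <- matrix(x, cin)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = cin)
  sd_ <- sqrt(colMeans(xc * xc) + eps)
  xhat <- xc / rep(sd_, each = cin)
  y <- par$gamma * xhat + par$beta
  list(out = array(y, d), cache = list(xhat = xhat, sd = sd_, dimx = d))
}

layernorm_backward <- function(par, cache, dy) {
  d <- cache$dimx
  cin <- d[1]
  dym <- matrix(dy, cin)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * par$gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(m1, each = cin) - xhat * rep(m2, each = cin)) /
    rep(cache$sd, each = cin)
  list(dpar = list(gamma = dgamma, beta = dbeta), dx = array(dx, d))
}

# ---- batch normalization (per channel over space and batch) --------------

batchnorm_init <- function(c_in) {
  list(gamma = rep(1, c_in), beta = numeric(c_in))
}

batchnorm_state_init <- function(c_in) {
  list(mean = numeric(c_in), var = rep(1, c_in), count = 0L)
}

batchnorm_forward <- function(par, state, x, train, momentum = 0.1,
                              eps = 1e-5) {
  d <- dim(x)
  cin <- d[1]
  xm <- matrix(x, cin)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
    state$count <- state$count + 1L
  } else {
    if (state$count == 0L) {
      # untrained model: fall back to batch statistics so a forward pass is
      # still well-defined (running stats stay untouched)
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu * mu
      v[v < 0] <- 0
    } else {
      mu <- state$mean
      v <- state$var
    }
  }
  sd_ <- sqrt(v + eps)
  xhat <- (xm - mu) / sd_
  y <- par$gamma * xhat + par$beta
  list(out = array(y, d), state = state,
       cache = list(xhat = xhat, sd = sd_, dimx = d, train = train))
}

batchnorm_backward <- function(par, cache, dy) {
  d <- cache$dimx
  cin <- d[1]
  dym <- matrix(dy, cin)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * par$gamma
  if (cache$train) {
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  } else {
    dx <- dxhat / cache$sd
  }
  list(dpar = list(gamma = dgamma, beta = dbeta), dx = array(dx, d))
}

# ---- linear layer --------------------------------------------------------

linear_init <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_out * d_in, sd = sqrt(2 / d_in)), d_out),
       b = numeric(d_out))
}

linear_forward <- function(par, x) {
  # x: d_in x B
  list(out = par$W %*% x + par$b, cache = list(x = x))
}

linear_backward <- function(par, cache, dy) {
  list(dpar = list(W = dy %*% t(cache$x), b = rowSums(dy)),
       dx = crossprod(par$W, dy))
}

# ---- softmax over rows ---------------------------------------------------

softmax_rows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

softmax_rows_backward <- function(a, da) {
  a * (da - rowSums(a * da))
}

# ---- pixel shuffle -------------------------------------------------------

#' Pixel-shuffle rearrangement
#'
#' Rearranges a `(c*f^2) x h x w` feature map (per batch element) into a
#' `c x (f*h) x (f*w)` map. The operation is a pure permutation of values:
#' nothing is interpolated, created or lost.
#'
#' @param x array with dim `c(C, H, W, B)`; `C` must be divisible by `f^2`.
#' @param f integer upsampling factor per side.
#' @return Array with dim `c(C/f^2, f*H, f*W, B)`.
#' @export
pixel_shuffle <- function(x, f) {
  d <- dim(x)
  if (length(d) != 4) stop("pixel_shuffle expects a C x H x W x B array")
  if (d[1] %% (f * f) != 0)
    stop("channel count ", d[1], " not divisible by f^2 = ", f * f)
  c2 <- d[1] %/% (f * f)
  dim(x) <- c(c2, f, f, d[2], d[3], d[4])
  y <- aperm(x, c(1, 2, 4, 3, 5, 6))
  dim(y) <- c(c2, f * d[2], f * d[3], d[4])
  y
}

pixel_unshuffle <- function(y, f) {
  d <- dim(y)
  h <- d[2] %/% f; w <- d[3] %/% f
  dim(y) <- c(d[1], f, h, f, w, d[4])
  x <- aperm(y, c(1, 2, 4, 3, 5, 6))
  dim(x) <- c(d[1] * f * f, h, w, d[4])
  x
}

# ---- bilinear sampling / resizing ---------------------------------------

# Sample a single-channel matrix at fractional 0-based (x, y) coordinates
# with border replication.
bilinear_sample <- function(mat, xs, ys) {
  h <- nrow(mat); w <- ncol(mat)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  v00 <- mat[cbind(y0 + 1, x0 + 1)]
  v01 <- mat[cbind(y0 + 1, x1 + 1)]
  v10 <- mat[cbind(y1 + 1, x0 + 1)]
  v11 <- mat[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Bilinear resize of a matrix or image array
#'
#' @param img matrix `H x W` or array `H x W x C` with values on any scale.
#' @param out_h,out_w target size in pixels.
#' @return Resized matrix or array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  one <- function(mat) {
    h <- nrow(mat); w <- ncol(mat)
    if (h == out_h && w == out_w) return(mat)
    xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
    ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
    grid_x <- rep(xs, each = out_h)
    grid_y <- rep(ys, times = out_w)
    matrix(bilinear_sample(mat, grid_x, grid_y), out_h, out_w)
  }
  if (is.matrix(img)) return(one(img))
  d <- dim(img)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- one(img[, , ch])
  out
}
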