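# Numerical primitives: convolutions, pooling, normalizations, GeLU, pixel
# shuffle and resizing, each checked against a direct oracle and (where it
# has a backward) against finite differences.

naive_conv <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  cin <- d[1]
  co <- nrow(W)
  oh <- (d[2] + 2 * pad - k) %/% stride + 1
  ow <- (d[3] + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(cin, d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out <- array(0, c(co, oh, ow, d[4]))
  for (bi in seq_len(d[4])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    patch <- xp[, (i - 1) * stride + seq_len(k),
                (j - 1) * stride + seq_len(k), bi]
    # column order of W: offset (kj outer, ki inner), channels fastest
    vec <- as.vector(aperm(array(patch, c(cin, k, k)), c(1, 2, 3)))
    out[, i, j, bi] <- W %*% vec + b
  }
  out
}

test_that("dense convolution matches a direct sliding-window oracle", {
  set.seed(11)
  x <- rand_fm(2, 5, 5, 2, seed = 11)
  par <- ferpcvt:::conv2d_init(2, 3, 3)
  for (cfgs in list(c(1, 1), c(2, 1), c(1, 0))) {
    got <- ferpcvt:::conv2d_forward(par, x, cfgs[1], cfgs[2])$out
    want <- naive_conv(x, par$W, par$b, 3, cfgs[1], cfgs[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("depthwise convolution equals dense convolution with a
           channel-diagonal kernel", {
  set.seed(12)
  x <- rand_fm(3, 6, 6, 2, seed = 12)
  dpar <- ferpcvt:::dwconv_init(3, 3)
  # embed the per-channel filters into a block-diagonal dense kernel
  W <- matrix(0, 3, 3 * 9)
  for (off in 1:9) for (ch in 1:3)
    W[ch, (off - 1) * 3 + ch] <- dpar$W[ch, off]
  cpar <- list(W = W, b = dpar$b, ksize = 3)
  got <- ferpcvt:::dwconv_forward(dpar, x, 1, 1)$out
  want <- ferpcvt:::conv2d_forward(cpar, x, 1, 1)$out
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("max pooling matches a direct oracle and halves the side", {
  x <- rand_fm(2, 8, 8, 1, seed = 13)
  got <- ferpcvt:::maxpool_forward(x, 3, 2, 1)$out
  expect_identical(dim(got), c(2L, 4L, 4L, 1L))
  xp <- array(-Inf, c(2, 10, 10, 1))
  xp[, 2:9, 2:9, ] <- x
  for (i in 1:4) for (j in 1:4) for (ch in 1:2) {
    expect_equal(got[ch, i, j, 1],
                 max(xp[ch, (2 * i - 1):(2 * i + 1),
                        (2 * j - 1):(2 * j + 1), 1]))
  }
  # pooling a constant map preserves the constant
  const <- array(3.5, c(2, 8, 8, 1))
  expect_true(all(ferpcvt:::maxpool_forward(const)$out == 3.5))
})

test_that("backward passes agree with finite differences", {
  set.seed(14)
  x <- rand_fm(2, 6, 6, 2, seed = 14)
  proj <- rand_fm(3, 3, 3, 2, seed = 15)   # random projection to a scalar

  par <- ferpcvt:::conv2d_init(2, 3, 3)
  f <- function(xx) sum(ferpcvt:::conv2d_forward(par, xx, 2, 1)$out * proj)
  fw <- ferpcvt:::conv2d_forward(par, x, 2, 1)
  bw <- ferpcvt:::conv2d_backward(par, fw$cache, proj)
  ent <- sample(length(x), 6)
  expect_equal(bw$dx[ent], num_grad_entries(f, x, ent), tolerance = 1e-6)
  fW <- function(ww) {
    p2 <- par; p2$W <- ww
    sum(ferpcvt:::conv2d_forward(p2, x, 2, 1)$out * proj)
  }
  entw <- sample(length(par$W), 6)
  expect_equal(bw$dpar$W[entw], num_grad_entries(fW, par$W, entw),
               tolerance = 1e-6)

  dpar <- ferpcvt:::dwconv_init(2, 3)
  proj2 <- rand_fm(2, 6, 6, 2, seed = 16)
  g <- function(xx) sum(ferpcvt:::dwconv_forward(dpar, xx, 1, 1)$out * proj2)
  fw2 <- ferpcvt:::dwconv_forward(dpar, x, 1, 1)
  bw2 <- ferpcvt:::dwconv_backward(dpar, fw2$cache, proj2)
  expect_equal(bw2$dx[ent], num_grad_entries(g, x, ent), tolerance = 1e-6)

  lpar <- ferpcvt:::layernorm_init(2)
  h <- function(xx) sum(ferpcvt:::layernorm_forward(lpar, xx)$out * proj2)
  fw3 <- ferpcvt:::layernorm_forward(lpar, x)
  bw3 <- ferpcvt:::layernorm_backward(lpar, fw3$cache, proj2)
  expect_equal(bw3$dx[ent], num_grad_entries(h, x, ent), tolerance = 1e-5)

  bpar <- ferpcvt:::batchnorm_init(2)
  bst <- ferpcvt:::batchnorm_state_init(2)
  k <- function(xx)
    sum(ferpcvt:::batchnorm_forward(bpar, bst, xx, TRUE)$out * proj2)
  fw4 <- ferpcvt:::batchnorm_forward(bpar, bst, x, TRUE)
  bw4 <- ferpcvt:::batchnorm_backward(bpar, fw4$cache, proj2)
  expect_equal(bw4$dx[ent], num_grad_entries(k, x, ent), tolerance = 1e-5)

  pproj <- proj2[, 1:3, 1:3, , drop = FALSE]
  mp <- function(xx) sum(ferpcvt:::maxpool_forward(xx, 3, 2, 1)$out * pproj)
  fw5 <- ferpcvt:::maxpool_forward(x, 3, 2, 1)
  bw5 <- ferpcvt:::maxpool_backward(fw5$cache, pproj)
  expect_equal(bw5[ent], num_grad_entries(mp, x, ent), tolerance = 1e-6)
})

test_that("GeLU uses the exact error-function form", {
  expect_equal(gelu(0), 0)
  # independent oracle: 0.5 x (1 + erf(x / sqrt(2)))
  oracle <- if (requireNamespace("pracma", quietly = TRUE)) {
    function(x) 0.5 * x * (1 + pracma::erf(x / sqrt(2)))
  } else {
    function(x) 0.5 * x * (1 + 2 * stats::pnorm(x * sqrt(2) / sqrt(2)) - 1)
  }
  xs <- c(-4, -1, -0.5, 0.3, 1, 2, 5)
  expect_equal(gelu(xs), oracle(xs), tolerance = 1e-12)
  expect_equal(round(gelu(1), 6), 0.841345)
  expect_lt(abs(gelu(10) - 10) / 10, 1e-6)     # x for large x
  # distinguishable from the tanh approximation at moderate x
  tanh_approx <- function(x)
    0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
  expect_gt(max(abs(gelu(xs) - tanh_approx(xs))), 1e-5)
})

test_that("pixel shuffle is a value-preserving bijection", {
  x <- rand_fm(16, 3, 3, 2, seed = 17)
  y <- pixel_shuffle(x, 2)
  expect_identical(dim(y), c(4L, 6L, 6L, 2L))
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  expect_equal(ferpcvt:::pixel_unshuffle(y, 2), x)
  expect_error(pixel_shuffle(rand_fm(6, 2, 2, 1), 2), "divisible")
  # the published head geometry: 576 x 4 x 4 -> 4 x 48 x 48 under f = 12
  z <- rand_fm(576, 4, 4, 1, seed = 18)
  zs <- pixel_shuffle(z, 12)
  expect_identical(dim(zs), c(4L, 48L, 48L, 1L))
  expect_equal(sort(as.vector(zs)), sort(as.vector(z)))
})

test_that("bilinear resize is exact on constants and at identity scale", {
  m <- matrix(runif(36), 6, 6)
  expect_equal(resize_bilinear(m, 6, 6), m)
  expect_true(all(abs(resize_bilinear(matrix(2, 5, 5), 9, 9) - 2) < 1e-12))
  r <- resize_bilinear(m, 12, 12)
  expect_identical(dim(r), c(12L, 12L))
  expect_true(min(r) >= min(m) - 1e-12 && max(r) <= max(m) + 1e-12)
})
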