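# The PCVT network: construction, module shape contracts, classifier-head
# algebra, determinism and gradient flow.

test_that("configuration invariants are enforced with descriptive errors", {
  expect_error(stage_config(1, 10, 4), "divisible")
  expect_error(model_config(input_size = 100), "multiple of patch_size")
  expect_error(model_config(patch_size = 16), "2\\^\\(2 \\+ r\\)")
  expect_error(model_config(stages = list(stage_config(1, 100, 4)),
                            pixel_shuffle_factor = 12), "divisible")
  expect_error(model_config(d_class = 1), "d_class")
  expect_error(model_config(stages = list(stage_config(1, 192, 8),
                                          stage_config(1, 576, 7))),
               "divisible")
  expect_silent(validate_model_config(tiny_cfg()))
})

test_that("initialization is deterministic under the seed", {
  m1 <- build_model(tiny_cfg(), seed = 5)
  m2 <- build_model(tiny_cfg(), seed = 5)
  m3 <- build_model(tiny_cfg(), seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

ref7 <- reference_config("raf-db")
ref_model <- build_model(ref7$model, seed = 1, vocab = ref7$vocab,
                         head = "valc")

test_that("convolutional patch embedding reproduces the reference geometry", {
  x <- array(runif(3 * 128 * 128 * 2), c(3, 128, 128, 2))
  h <- cpe_forward(ref_model, x)
  expect_identical(dim(h), c(64L, 16L, 16L, 2L))
  # batch dimension preserved for any b
  h1 <- cpe_forward(ref_model, x[, , , 1, drop = FALSE])
  expect_identical(dim(h1), c(64L, 16L, 16L, 1L))
  expect_equal(h1, h[, , , 1, drop = FALSE], tolerance = 1e-12)
  expect_error(cpe_forward(ref_model, array(0, c(3, 64, 64, 1))),
               "does not match")
  # doubling the Block Scaling repeats halves once more from the same stem
  cfg2 <- model_config(patch_size = 16, r = 2,
                       stages = list(stage_config(1, 192, 8)),
                       pixel_shuffle_factor = 4, condense_channels = 24,
                       d_class = 7)
  m2 <- build_model(cfg2, seed = 1)
  h2 <- cpe_forward(m2, x)
  expect_identical(dim(h2), c(64L, 8L, 8L, 2L))
})

test_that("Block Scaling divides the side by 2^repeats, channels unchanged", {
  fm <- rand_fm(64, 32, 32, 1, seed = 21)
  out1 <- block_scaling(fm, repeats = 1)
  expect_identical(dim(out1), c(64L, 16L, 16L, 1L))
  out2 <- block_scaling(fm, repeats = 2)
  expect_identical(dim(out2), c(64L, 8L, 8L, 1L))
  expect_error(block_scaling(rand_fm(8, 7, 7, 1), 1), "divisible")
})

test_that("encoder blocks preserve shape and emit normalized attention", {
  tm <- build_model(tiny_cfg(), seed = 3)
  fm <- rand_fm(8, 4, 4, 2, seed = 22)
  eb <- encoder_block(tm, fm, stage = 1, block = 1)
  expect_identical(dim(eb$out), dim(fm))
  expect_identical(dim(eb$attention), c(16L, 16L, 2L, 2L))
  sums <- apply(eb$attention, c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(eb$attention >= 0))
})

test_that("zeroing attention-value and feed-forward weights reduces a block
           to two stacked layer normalizations", {
  tm <- build_model(tiny_cfg(), seed = 4)
  bp <- tm$params$stages[[1]]$blocks[[1]]
  bp$v$W[] <- 0; bp$v$b[] <- 0
  bp$ff2$W[] <- 0; bp$ff2$b[] <- 0
  tm$params$stages[[1]]$blocks[[1]] <- bp
  fm <- rand_fm(8, 4, 4, 2, seed = 23)
  got <- encoder_block(tm, fm, 1, 1)$out
  # independent oracle: plain channel-wise standardization composed twice
  ln_oracle <- function(x, gamma, beta, eps = 1e-5) {
    d <- dim(x)
    xm <- matrix(x, d[1])
    mu <- colMeans(xm)
    sd_ <- sqrt(colMeans(xm^2) - mu^2 + eps)
    array(gamma * sweep(sweep(xm, 2, mu), 2, sd_, "/") + beta, d)
  }
  want <- ln_oracle(ln_oracle(fm, bp$ln1$gamma, bp$ln1$beta),
                    bp$ln2$gamma, bp$ln2$beta)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("pyramid stages reproduce the reference output sizes", {
  fm1 <- rand_fm(64, 16, 16, 1, seed = 24)
  s1 <- ptf_stage(ref_model, fm1, stage = 1)
  expect_identical(dim(s1$out), c(192L, 8L, 8L, 1L))
  expect_length(s1$attention, 2)            # l = 2 blocks
  fm2 <- rand_fm(192, 8, 8, 1, seed = 25)
  s2 <- ptf_stage(ref_model, fm2, stage = 2)
  expect_identical(dim(s2$out), c(576L, 4L, 4L, 1L))
  expect_length(s2$attention, 4)            # l = 4 blocks
  # block combined pooling alone: conv to d0 then halving
  expect_identical(dim(block_combined_pooling(ref_model, fm1, 1)),
                   c(192L, 8L, 8L, 1L))
  expect_identical(dim(block_combined_pooling(ref_model, fm2, 2)),
                   c(576L, 4L, 4L, 1L))
})

test_that("pixel shuffle + condense maps the final stage back to the token
           grid with the configured channels", {
  fm <- rand_fm(576, 4, 4, 2, seed = 26)
  out <- pixel_shuffle_condense(ref_model, fm)
  expect_identical(dim(out), c(4820L, 4L, 4L, 2L))
})

test_that("channel mean and batch sharing satisfy their averaging algebra", {
  fm <- array(0, c(2, 3, 3, 2))
  fm[1, , , ] <- 1; fm[2, , , ] <- 3
  expect_true(all(channel_mean(fm) == 2))
  expect_true(all(channel_mean(array(7, c(5, 2, 2, 1))) == 7))
  # linearity
  a <- rand_fm(4, 3, 3, 2, seed = 27); b <- rand_fm(4, 3, 3, 2, seed = 28)
  expect_equal(channel_mean(2.5 * a + b),
               2.5 * channel_mean(a) + channel_mean(b), tolerance = 1e-12)
  # batch sharing equals the batch mean of channel means
  fm2 <- array(0, c(2, 2, 2, 2))
  fm2[, , , 1] <- 2; fm2[, , , 2] <- 4
  expect_true(all(batch_sharing(fm2) == 3))
  one <- rand_fm(3, 2, 2, 1, seed = 29)
  expect_equal(batch_sharing(one), channel_mean(one)[, , 1],
               tolerance = 1e-12)
  perm <- fm2[, , , c(2, 1)]
  expect_equal(batch_sharing(perm), batch_sharing(fm2), tolerance = 1e-12)
})

test_that("the classifier head combines V-A-like and neutral features as
           specified", {
  tm <- build_model(tiny_cfg(d_class = 4), seed = 9)
  fm <- rand_fm(16, 2, 2, 3, seed = 30)
  # w_AD = 0: no cross-sample effect in train mode
  tm0 <- tm
  tm0$params$valc$wad <- 0
  s1 <- valc_forward(tm0, fm, mode = "train")
  fm_perturbed <- fm
  fm_perturbed[, , , 2] <- fm_perturbed[, , , 2] + 5
  s2 <- valc_forward(tm0, fm_perturbed, mode = "train")
  expect_equal(s1[1, ], s2[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s1[2, ], s2[2, ])))
  # identical batch elements: combined = (1 + w_AD) * channel-mean path
  same <- fm
  same[, , , 2] <- same[, , , 1]; same[, , , 3] <- same[, , , 1]
  scores <- valc_forward(tm, same, mode = "train")
  vp <- tm$params$valc
  cond <- ferpcvt:::conv2d_forward(vp$condense, pixel_shuffle(same, 2),
                                   stride = 2, pad = 0)$out
  cm <- as.vector(channel_mean(cond)[, , 1])
  expected_logits <- vp$fc$W %*% ((1 + vp$wad) * cm) + vp$fc$b
  expect_equal(scores[1, ], as.vector(1 / (1 + exp(-expected_logits))),
               tolerance = 1e-10)
  expect_true(all(scores > 0 & scores < 1))
  # eval before any training step must refuse
  expect_error(valc_forward(tm, fm, mode = "eval"), "neutral baseline")
})

test_that("full forward matches the configured class count and is
           deterministic in eval mode", {
  x <- array(runif(3 * 128 * 128 * 2), c(3, 128, 128, 2))
  fw <- model_forward(ref_model, x, mode = "train")
  expect_identical(ncol(fw$scores), 7L)
  expect_true(all(fw$scores > 0 & fw$scores < 1))
  trained <- fw$model
  e1 <- model_forward(trained, x[, , , 1, drop = FALSE])
  e2 <- model_forward(trained, x[, , , 1, drop = FALSE])
  expect_identical(e1$scores, e2$scores)
  # argmax under sigmoid equals argmax under softmax (monotone in logits)
  soft <- ferpcvt:::softmax_cols(e1$logits)
  expect_identical(which.max(e1$scores[1, ]), which.max(soft[, 1]))
})

test_that("eval-mode scores are independent of batch composition", {
  tm <- build_model(tiny_cfg(d_class = 8), seed = 2,
                    vocab = emotion_vocabulary("private8"))
  x <- array(runif(3 * 32 * 32 * 4), c(3, 32, 32, 4))
  tm <- model_forward(tm, x, mode = "train")$model   # sets running state
  alone <- model_forward(tm, x[, , , 2, drop = FALSE])$scores
  batched <- model_forward(tm, x)$scores
  expect_equal(alone[1, ], batched[2, ], tolerance = 1e-6)
})

test_that("one training step sends a nonzero gradient into every parameter
           group, including w_AD", {
  tm <- build_model(tiny_cfg(d_class = 3), seed = 8)
  x <- array(runif(3 * 32 * 32 * 3), c(3, 32, 32, 3))
  fw <- ferpcvt:::fwd_model(tm, x, train = TRUE, keep = TRUE)
  ce <- ferpcvt:::cross_entropy(fw$logits, c(1L, 2L, 3L))
  grads <- ferpcvt:::bwd_model(tm, fw$cache, ce$dlogits)
  gl <- ferpcvt:::flatten_params(grads)
  group <- sub("\\.[^.]+$", "", names(gl))
  gmax <- tapply(vapply(gl, function(g) max(abs(g)), numeric(1)), group, max)
  expect_true(all(gmax > 0))
  expect_gt(abs(grads$valc$wad), 0)
})

test_that("checkpoints round-trip the weights, state and vocabulary", {
  tm <- build_model(tiny_cfg(d_class = 8), seed = 2,
                    vocab = emotion_vocabulary("private8"))
  x <- array(runif(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  tm <- model_forward(tm, x, mode = "train")$model
  f <- tempfile(fileext = ".rds")
  save_checkpoint(tm, f, train_config = train_config(epochs = 1,
                                                     batch_size = 2))
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, tm$params)
  expect_identical(m2$vocab, tm$vocab)
  expect_equal(m2$state$neutral$value, tm$state$neutral$value)
  s1 <- model_forward(tm, x)$scores
  s2 <- model_forward(m2, x)$scores
  expect_identical(s1, s2)
  expect_error(load_checkpoint(tempfile()), "not found")
})

test_that("attention rollout: uniform attention gives a flat map and a
           hand-computed concentrated case reproduces", {
  # uniform single layer -> every token receives the same attention
  TT <- 16
  maps <- list(list(array(1 / TT, c(TT, TT, 1, 1))))
  heat <- attention_rollout(maps, input_size = 8)
  expect_identical(dim(heat), c(8L, 8L))
  expect_lt(diff(range(heat)), 1e-12)
  expect_error(attention_rollout(list()), "empty")
  # two 4-token layers: a swap permutation followed by attention fixed on
  # token 1. Rolled product rows: (.5,.5,0,0), (.5,.5,0,0), (.25,...),
  # (.25,...); received = (.375,.375,.125,.125) -> normalized (1,1,0,0).
  P <- matrix(0, 4, 4)
  P[1, 2] <- 1; P[2, 1] <- 1; P[3, 4] <- 1; P[4, 3] <- 1
  A2 <- matrix(0, 4, 4); A2[, 1] <- 1
  maps2 <- list(list(array(P, c(4, 4, 1, 1)), array(A2, c(4, 4, 1, 1))))
  heat2 <- attention_rollout(maps2, input_size = 2)
  expect_equal(heat2, matrix(c(1, 1, 0, 0), 2, 2), tolerance = 1e-12)
  # normalization contract on a generic map
  tm <- build_model(tiny_cfg(), seed = 12)
  x <- array(runif(3 * 32 * 32 * 1), c(3, 32, 32, 1))
  fw <- ferpcvt:::fwd_model(tm, x, train = TRUE, collect_attention = TRUE)
  h <- attention_rollout(fw$attention, input_size = 32)
  expect_equal(range(h), c(0, 1))
})
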