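# The PCVT network: convolutional patch embedding (CPE), pyramid transformer
# stages (PTF) and either the valence-arousal-like classifier (V-ALC) or a
# small flatten-MLP head for the backbone-only model.
#
# The network is implemented natively: every module has an explicit forward
# (returning a cache) and backward, so training needs no external framework.
# Parameters live in a nested list; gradients mirror its structure.

# ---- construction --------------------------------------------------------

stage_entry_channels <- function(cfg) {
  ch <- cfg$stem_channels
  out <- integer(length(cfg$stages))
  for (s in seq_along(cfg$stages)) {
    out[s] <- ch
    ch <- cfg$stages[[s]]$d0
  }
  out
}

#' Build a PCVT model
#'
#' Initialization is deterministic under `seed` (He-normal weights, unit
#' norm scales, `w_AD = 1`). The default reference configuration reproduces
#' the published stage shapes: 3 x 128 x 128 -> 64 x 16 x 16 (CPE)
#' -> 192 x 8 x 8 -> 576 x 4 x 4 (PTF) -> d_class scores.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for the initialization.
#' @param vocab class-name vector of length `d_class` (defaults to
#'   `class1..classK`).
#' @param head `"valc"` for the full model with the valence-arousal-like
#'   classifier; `"light"` for the backbone-only model with its small
#'   flatten head.
#' @return Object of class `pcvt_model`.
#' @export
build_model <- function(config, seed = 1, vocab = NULL,
                        head = c("valc", "light")) {
  head <- match.arg(head)
  validate_model_config(config)
  if (is.null(vocab)) vocab <- paste0("class", seq_len(config$d_class))
  if (length(vocab) != config$d_class)
    stop("vocabulary length ", length(vocab), " does not match d_class ",
         config$d_class)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  params <- list()
  params$cpe <- list(conv1 = conv2d_init(config$in_channels,
                                         config$stem_channels, 3))
  params$cpe$bs <- lapply(seq_len(config$r), function(i)
    list(c2 = conv2d_init(config$stem_channels, config$stem_channels, 2),
         c1 = conv2d_init(config$stem_channels, config$stem_channels, 1)))

  entry <- stage_entry_channels(config)
  params$stages <- vector("list", length(config$stages))
  state_stages <- vector("list", length(config$stages))
  for (s in seq_along(config$stages)) {
    st <- config$stages[[s]]
    ch <- entry[s]
    blocks <- lapply(seq_len(st$l), function(b)
      list(q = dwconv_init(ch, 3), k = dwconv_init(ch, 3),
           v = dwconv_init(ch, 3),
           ln1 = layernorm_init(ch),
           ff1 = conv2d_init(ch, ch %/% 2, 1),
           ff2 = conv2d_init(ch %/% 2, ch, 1),
           ln2 = layernorm_init(ch)))
    params$stages[[s]] <- list(blocks = blocks,
                               bcp = list(conv = conv2d_init(ch, st$d0, 3),
                                          bn = batchnorm_init(st$d0)))
    state_stages[[s]] <- list(bn = batchnorm_state_init(st$d0))
  }

  final_d0 <- config$stages[[length(config$stages)]]$d0
  final_side <- token_side(config, length(config$stages))
  feat_dim <- final_side * final_side
  if (head == "valc") {
    f <- config$pixel_shuffle_factor
    params$valc <- list(
      condense = conv2d_init(final_d0 %/% (f * f), config$condense_channels,
                             f),
      wad = 1.0,
      fc = linear_init(feat_dim, config$d_class))
  } else {
    params$head <- list(
      fc1 = linear_init(final_d0 * feat_dim, config$head_hidden),
      fc2 = linear_init(config$head_hidden, config$d_class))
  }

  state <- list(stages = state_stages,
                neutral = list(value = numeric(feat_dim), count = 0L,
                               momentum = 0.1))
  structure(list(config = config, vocab = vocab, head = head,
                 params = params, state = state, seed = as.integer(seed)),
            class = "pcvt_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.pcvt_model <- function(x, ...) {
  cfg <- x$config
  cat("PCVT model (", if (x$head == "valc") "V-ALC head" else "light head",
      ")\n", sep = "")
  cat("  input: ", cfg$in_channels, " x ", cfg$input_size, " x ",
      cfg$input_size, ", patch ", cfg$patch_size, ", ", length(cfg$stages),
      " pyramid stage(s)\n", sep = "")
  for (s in seq_along(cfg$stages)) {
    st <- cfg$stages[[s]]
    cat("  stage ", s, ": l=", st$l, " d0=", st$d0, " heads=", st$heads,
        "\n", sep = "")
  }
  cat("  classes: ", paste(x$vocab, collapse = ", "), "\n", sep = "")
  cat("  trainable parameters: ", count_params(x), "\n", sep = "")
  invisible(x)
}

# ---- parameter tree utilities -------------------------------------------

# leaves are numeric vectors/matrices/arrays; "ksize" entries are metadata
walk_params <- function(tree, fn, path = character()) {
  if (is.list(tree)) {
    nm <- names(tree)
    for (i in seq_along(tree)) {
      if (identical(nm[i], "ksize")) next
      lab <- if (is.null(nm) || is.na(nm[i]) || nm[i] == "")
        as.character(i) else nm[i]
      walk_params(tree[[i]], fn, c(path, lab))
    }
  } else if (is.numeric(tree)) {
    fn(path, tree)
  }
  invisible(NULL)
}

flatten_params <- function(tree) {
  out <- list()
  walk_params(tree, function(path, value) {
    out[[paste(path, collapse = ".")]] <<- value
  })
  out
}

#' Number of trainable parameters
#'
#' @param model a `pcvt_model`.
#' @return Integer count of trainable scalars.
#' @export
count_params <- function(model) {
  sum(vapply(flatten_params(model$params), length, numeric(1)))
}

# ---- forward / backward: CPE --------------------------------------------

cpe_fwd <- function(params, x, keep = FALSE) {
  c1 <- conv2d_forward(params$conv1, x, stride = 2, pad = 1)
  g <- gelu(c1$out)
  mp <- maxpool_forward(g, 3, 2, 1)
  h <- mp$out
  bs_caches <- vector("list", length(params$bs))
  for (i in seq_along(params$bs)) {
    d <- dim(h)
    if (d[2] %% 2 != 0 || d[3] %% 2 != 0)
      stop("Block Scaling needs even spatial size, got ", d[2], " x ", d[3])
    s2 <- conv2d_forward(params$bs[[i]]$c2, h, stride = 2, pad = 0)
    s1 <- conv2d_forward(params$bs[[i]]$c1, s2$out, stride = 1, pad = 0)
    bs_caches[[i]] <- if (keep) list(c2 = s2$cache, c1 = s1$cache) else NULL
    h <- s1$out
  }
  cache <- if (keep) list(c1 = c1$cache, pre_gelu = c1$out, mp = mp$cache,
                          bs = bs_caches) else NULL
  list(out = h, cache = cache)
}

cpe_bwd <- function(params, cache, dy) {
  g <- list()
  dh <- dy
  for (i in rev(seq_along(params$bs))) {
    b1 <- conv2d_backward(params$bs[[i]]$c1, cache$bs[[i]]$c1, dh)
    b2 <- conv2d_backward(params$bs[[i]]$c2, cache$bs[[i]]$c2, b1$dx)
    g$bs[[i]] <- list(c2 = b2$dpar, c1 = b1$dpar)
    dh <- b2$dx
  }
  dg <- maxpool_backward(cache$mp, dh)
  dpre <- dg * gelu_grad(cache$pre_gelu)
  b0 <- conv2d_backward(params$conv1, cache$c1, dpre)
  g$conv1 <- b0$dpar
  list(dpar = g, dx = b0$dx)
}

# ---- forward / backward: encoder block ----------------------------------

enc_fwd <- function(bp, x, heads, keep = FALSE) {
  d <- dim(x)
  C <- d[1]; TT <- d[2] * d[3]; B <- d[4]
  if (C %% heads != 0)
    stop("channel count ", C, " not divisible by heads = ", heads)
  dh <- C %/% heads
  qf <- dwconv_forward(bp$q, x); kf <- dwconv_forward(bp$k, x)
  vf <- dwconv_forward(bp$v, x)
  qa <- array(qf$out, c(C, TT, B))
  ka <- array(kf$out, c(C, TT, B))
  va <- array(vf$out, c(C, TT, B))
  attn_out <- array(0, c(C, TT, B))
  A_store <- array(0, c(TT, TT, heads, B))
  sc <- 1 / sqrt(dh)
  for (bi in seq_len(B)) {
    for (h in seq_len(heads)) {
      rows <- ((h - 1) * dh + 1):(h * dh)
      Q <- matrix(qa[rows, , bi], dh, TT)
      K <- matrix(ka[rows, , bi], dh, TT)
      V <- matrix(va[rows, , bi], dh, TT)
      A <- softmax_rows(crossprod(Q, K) * sc)
      attn_out[rows, , bi] <- V %*% t(A)
      A_store[, , h, bi] <- A
    }
  }
  res1 <- x + array(attn_out, d)
  l1 <- layernorm_forward(bp$ln1, res1)
  f1 <- conv2d_forward(bp$ff1, l1$out, 1, 0)
  gh <- gelu(f1$out)
  f2 <- conv2d_forward(bp$ff2, gh, 1, 0)
  res2 <- l1$out + f2$out
  l2 <- layernorm_forward(bp$ln2, res2)
  cache <- if (keep)
    list(q = qf$cache, k = kf$cache, v = vf$cache, qa = qa, ka = ka, va = va,
         A = A_store, ln1 = l1$cache, ff1 = f1$cache, pre_gelu = f1$out,
         ff2 = f2$cache, ln2 = l2$cache, dimx = d, heads = heads) else NULL
  list(out = l2$out, attention = A_store, cache = cache)
}

enc_bwd <- function(bp, cache, dy) {
  d <- cache$dimx
  C <- d[1]; TT <- d[2] * d[3]; B <- d[4]
  heads <- cache$heads
  dh <- C %/% heads
  sc <- 1 / sqrt(dh)
  l2b <- layernorm_backward(bp$ln2, cache$ln2, dy)
  dres2 <- l2b$dx
  f2b <- conv2d_backward(bp$ff2, cache$ff2, dres2)
  dpre <- f2b$dx * gelu_grad(cache$pre_gelu)
  f1b <- conv2d_backward(bp$ff1, cache$ff1, dpre)
  dln1 <- dres2 + f1b$dx
  l1b <- layernorm_backward(bp$ln1, cache$ln1, dln1)
  dres1 <- l1b$dx
  dattn <- array(dres1, c(C, TT, B))
  dqa <- array(0, c(C, TT, B)); dka <- dqa; dva <- dqa
  for (bi in seq_len(B)) {
    for (h in seq_len(heads)) {
      rows <- ((h - 1) * dh + 1):(h * dh)
      Q <- matrix(cache$qa[rows, , bi], dh, TT)
      K <- matrix(cache$ka[rows, , bi], dh, TT)
      V <- matrix(cache$va[rows, , bi], dh, TT)
      A <- cache$A[, , h, bi]
      dOut <- matrix(dattn[rows, , bi], dh, TT)
      dV <- dOut %*% A
      dA <- t(crossprod(V, dOut))
      dS <- softmax_rows_backward(A, dA) * sc
      dqa[rows, , bi] <- K %*% t(dS)
      dka[rows, , bi] <- Q %*% dS
      dva[rows, , bi] <- dV
    }
  }
  qb <- dwconv_backward(bp$q, cache$q, array(dqa, d))
  kb <- dwconv_backward(bp$k, cache$k, array(dka, d))
  vb <- dwconv_backward(bp$v, cache$v, array(dva, d))
  dx <- dres1 + qb$dx + kb$dx + vb$dx
  list(dpar = list(q = qb$dpar, k = kb$dpar, v = vb$dpar, ln1 = l1b$dpar,
                   ff1 = f1b$dpar, ff2 = f2b$dpar, ln2 = l2b$dpar),
       dx = dx)
}

# ---- forward / backward: block combined pooling -------------------------

bcp_fwd <- function(sp, bn_state, x, train, keep = FALSE) {
  cv <- conv2d_forward(sp$conv, x, stride = 1, pad = 1)
  mp <- maxpool_forward(cv$out, 3, 2, 1)
  bn <- batchnorm_forward(sp$bn, bn_state, mp$out, train)
  cache <- if (keep) list(conv = cv$cache, mp = mp$cache, bn = bn$cache)
           else NULL
  list(out = bn$out, state = bn$state, cache = cache)
}

bcp_bwd <- function(sp, cache, dy) {
  bnb <- batchnorm_backward(sp$bn, cache$bn, dy)
  dmp <- maxpool_backward(cache$mp, bnb$dx)
  cvb <- conv2d_backward(sp$conv, cache$conv, dmp)
  list(dpar = list(conv = cvb$dpar, bn = bnb$dpar), dx = cvb$dx)
}

# ---- forward / backward: heads ------------------------------------------

valc_fwd <- function(vp, neutral_state, x, train, keep = FALSE) {
  f <- attr(vp, "f")
  xs <- pixel_shuffle(x, f)
  cv <- conv2d_forward(vp$condense, xs, stride = f, pad = 0)
  dc <- dim(cv$out)
  cc <- dc[1]; P <- dc[2] * dc[3]; B <- dc[4]
  Fm <- matrix(colMeans(matrix(cv$out, cc)), P, B)   # channel mean per sample
  if (train) {
    neutral <- rowMeans(Fm)                          # batch sharing
    if (neutral_state$count == 0L) {
      neutral_state$value <- neutral
    } else {
      m <- neutral_state$momentum
      neutral_state$value <- (1 - m) * neutral_state$value + m * neutral
    }
    neutral_state$count <- neutral_state$count + 1L
  } else {
    if (neutral_state$count == 0L)
      stop("the neutral baseline has never been updated; ",
           "train the model or load a trained checkpoint before inference")
    neutral <- neutral_state$value
  }
  combined <- Fm + vp$wad * neutral
  fc <- linear_forward(vp$fc, combined)
  cache <- if (keep) list(conv = cv$cache, dimx = dim(x), dimc = dc,
                          Fm = Fm, neutral = neutral, fc = fc$cache,
                          train = train, f = f) else NULL
  list(logits = fc$out, embedding = combined, state = neutral_state,
       cache = cache)
}

valc_bwd <- function(vp, cache, dlogits) {
  fcb <- linear_backward(vp$fc, cache$fc, dlogits)
  dcomb <- fcb$dx
  B <- ncol(dcomb)
  dwad <- sum(dcomb * cache$neutral)
  dF <- dcomb
  if (cache$train) {
    dneutral <- vp$wad * rowSums(dcomb)
    dF <- dF + matrix(dneutral / B, nrow(dF), B)
  }
  dc <- cache$dimc
  cc <- dc[1]
  dcv <- array(rep(as.vector(dF) / cc, each = cc), dc)
  cvb <- conv2d_backward(vp$condense, cache$conv, dcv)
  dxs <- cvb$dx
  dx <- pixel_unshuffle(dxs, cache$f)
  list(dpar = list(condense = cvb$dpar, wad = dwad, fc = fcb$dpar), dx = dx)
}

light_fwd <- function(hp, x, keep = FALSE) {
  d <- dim(x)
  flat <- matrix(x, prod(d[1:3]), d[4])
  f1 <- linear_forward(hp$fc1, flat)
  gh <- gelu(f1$out)
  f2 <- linear_forward(hp$fc2, gh)
  cache <- if (keep) list(fc1 = f1$cache, pre_gelu = f1$out, fc2 = f2$cache,
                          dimx = d) else NULL
  list(logits = f2$out, embedding = gh, cache = cache)
}

light_bwd <- function(hp, cache, dlogits) {
  f2b <- linear_backward(hp$fc2, cache$fc2, dlogits)
  dpre <- f2b$dx * gelu_grad(cache$pre_gelu)
  f1b <- linear_backward(hp$fc1, cache$fc1, dpre)
  list(dpar = list(fc1 = f1b$dpar, fc2 = f2b$dpar),
       dx = array(f1b$dx, cache$dimx))
}

# ---- full model forward / backward --------------------------------------

standardize_images <- function(x) (x - 0.5) / 0.5

fwd_model <- function(model, images, train = FALSE, keep = FALSE,
                      collect_attention = FALSE) {
  cfg <- model$config
  d <- dim(images)
  if (length(d) != 4)
    stop("images must be a C x H x W x B array")
  if (d[1] != cfg$in_channels || d[2] != cfg$input_size ||
      d[3] != cfg$input_size)
    stop("input size ", d[1], " x ", d[2], " x ", d[3],
         " does not match the configured ", cfg$in_channels, " x ",
         cfg$input_size, " x ", cfg$input_size)
  if (any(!is.finite(images))) stop("images contain non-finite values")
  shapes <- list()
  xn <- standardize_images(images)
  shapes$input <- d[1:3]
  cpe <- cpe_fwd(model$params$cpe, xn, keep)
  h <- cpe$out
  shapes$cpe <- dim(h)[1:3]
  attention <- if (collect_attention || keep)
    vector("list", length(cfg$stages)) else NULL
  stage_caches <- vector("list", length(cfg$stages))
  for (s in seq_along(cfg$stages)) {
    st <- cfg$stages[[s]]
    blk_caches <- vector("list", st$l)
    blk_attn <- vector("list", st$l)
    for (b in seq_len(st$l)) {
      eb <- enc_fwd(model$params$stages[[s]]$blocks[[b]], h, st$heads, keep)
      h <- eb$out
      blk_attn[[b]] <- eb$attention
      blk_caches[[b]] <- eb$cache
    }
    bc <- bcp_fwd(model$params$stages[[s]]$bcp, model$state$stages[[s]]$bn,
                  h, train, keep)
    h <- bc$out
    model$state$stages[[s]]$bn <- bc$state
    stage_caches[[s]] <- list(blocks = blk_caches, bcp = bc$cache)
    if (!is.null(attention)) attention[[s]] <- blk_attn
    shapes[[paste0("ptf", s)]] <- dim(h)[1:3]
  }
  if (model$head == "valc") {
    vp <- model$params$valc
    attr(vp, "f") <- cfg$pixel_shuffle_factor
    hd <- valc_fwd(vp, model$state$neutral, h, train, keep)
    model$state$neutral <- hd$state
  } else {
    hd <- light_fwd(model$params$head, h, keep)
  }
  shapes$head <- c(1, nrow(hd$logits))
  list(logits = hd$logits, scores = t(sigmoid(hd$logits)),
       embedding = hd$embedding, attention = attention, shapes = shapes,
       model = model,
       cache = if (keep) list(cpe = cpe$cache, stages = stage_caches,
                              head = hd$cache) else NULL)
}

bwd_model <- function(model, cache, dlogits) {
  cfg <- model$config
  g <- list()
  if (model$head == "valc") {
    vp <- model$params$valc
    hb <- valc_bwd(vp, cache$head, dlogits)
    g$valc <- hb$dpar
  } else {
    hb <- light_bwd(model$params$head, cache$head, dlogits)
    g$head <- hb$dpar
  }
  dh <- hb$dx
  g$stages <- vector("list", length(cfg$stages))
  for (s in rev(seq_along(cfg$stages))) {
    st <- cfg$stages[[s]]
    bb <- bcp_bwd(model$params$stages[[s]]$bcp, cache$stages[[s]]$bcp, dh)
    dh <- bb$dx
    blocks_g <- vector("list", st$l)
    for (b in rev(seq_len(st$l))) {
      eb <- enc_bwd(model$params$stages[[s]]$blocks[[b]],
                    cache$stages[[s]]$blocks[[b]], dh)
      dh <- eb$dx
      blocks_g[[b]] <- eb$dpar
    }
    g$stages[[s]] <- list(blocks = blocks_g, bcp = bb$dpar)
  }
  cb <- cpe_bwd(model$params$cpe, cache$cpe, dh)
  g$cpe <- cb$dpar
  g
}

# ---- public forward wrappers --------------------------------------------

#' Run the full model on a batch of images
#'
#' Images are standardized internally (`(x - 0.5) / 0.5` per channel) before
#' the patch embedding. In `"train"` mode the neutral baseline is the
#' batch-shared feature and running statistics are updated; in `"eval"` mode
#' the stored running neutral baseline makes single-image prediction
#' well-defined and batch-size independent.
#'
#' @param model a `pcvt_model`.
#' @param images array `C x H x W x B` with values in `[0, 1]`.
#' @param mode `"eval"` or `"train"`.
#' @param collect_attention also return per-stage/block/head attention maps.
#' @return List with `scores` (`B x d_class` sigmoid confidences in (0, 1)),
#'   `logits`, `predicted` (integer class indices), `embedding` (features
#'   entering the final linear layer, one column per sample), `attention`
#'   (if requested), `shapes` (per-module output shapes) and `model` (with
#'   updated running state when `mode = "train"`).
#' @export
model_forward <- function(model, images, mode = c("eval", "train"),
                          collect_attention = FALSE) {
  mode <- match.arg(mode)
  out <- fwd_model(model, images, train = (mode == "train"),
                   keep = FALSE, collect_attention = collect_attention)
  out$predicted <- apply(out$scores, 1, which.max)
  out
}

#' Convolutional patch embedding
#'
#' Maps standardized images to the token feature map: a 3x3/stride-2
#' convolution into `stem_channels`, GeLU, 3x3/stride-2 max pooling, then
#' `r` Block Scaling repeats (2x2/stride-2 followed by 1x1 convolutions).
#' Position information is carried by the convolutions themselves; the model
#' has no positional-embedding table.
#'
#' @param model a `pcvt_model`.
#' @param images array `C x H x W x B` in `[0, 1]`.
#' @return Feature map of shape `stem_channels x (H/patch) x (W/patch) x B`.
#' @export
cpe_forward <- function(model, images) {
  d <- dim(images)
  cfg <- model$config
  if (is.null(d) || length(d) != 4)
    stop("images must be a C x H x W x B array")
  if (d[1] != cfg$in_channels || d[2] != cfg$input_size ||
      d[3] != cfg$input_size)
    stop("input size ", paste(d[1:3], collapse = " x "),
         " does not match the configured ", cfg$in_channels, " x ",
         cfg$input_size, " x ", cfg$input_size)
  cpe_fwd(model$params$cpe, standardize_images(images))$out
}

#' Block Scaling: strided convolution pairs halving the spatial size
#'
#' Each repeat applies a 2x2/stride-2 convolution followed by a 1x1
#' convolution, shortening the side to half; `repeats` applications divide
#' the side by `2^repeats` with channels unchanged.
#'
#' @param fm feature map `C x H x W x B`; `H`, `W` must be divisible by
#'   `2^repeats`.
#' @param repeats repeat count.
#' @param params optional list of per-repeat weights (`c2`, `c1` as used by
#'   the CPE); fresh seeded weights are drawn when omitted.
#' @param seed seed for fresh weights.
#' @return Feature map `C x H/2^repeats x W/2^repeats x B`.
#' @export
block_scaling <- function(fm, repeats = 1, params = NULL, seed = 1) {
  d <- dim(fm)
  if (d[2] %% 2^repeats != 0 || d[3] %% 2^repeats != 0)
    stop("spatial size ", d[2], " x ", d[3], " not divisible by 2^", repeats)
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- lapply(seq_len(repeats), function(i)
      list(c2 = conv2d_init(d[1], d[1], 2), c1 = conv2d_init(d[1], d[1], 1)))
  }
  h <- fm
  for (i in seq_len(repeats)) {
    h <- conv2d_forward(params[[i]]$c2, h, stride = 2, pad = 0)$out
    h <- conv2d_forward(params[[i]]$c1, h, stride = 1, pad = 0)$out
  }
  h
}

#' One Conv-TF encoder block
#'
#' Convolutional (depthwise 3x3) Q/K/V projections, multi-head self-attention
#' over the token grid, residual + layer normalization, a bottleneck
#' feed-forward (1x1 convolutions to `d/2` and back with GeLU between), and a
#' second residual + layer normalization. Shape-preserving.
#'
#' @param model a `pcvt_model`.
#' @param fm feature map matching the stage's entry channels.
#' @param stage,block stage and block indices.
#' @return List with `out` (same shape as `fm`) and `attention`
#'   (`T x T x heads x B`, rows summing to 1).
#' @export
encoder_block <- function(model, fm, stage = 1, block = 1) {
  st <- model$config$stages[[stage]]
  eb <- enc_fwd(model$params$stages[[stage]]$blocks[[block]], fm, st$heads)
  list(out = eb$out, attention = eb$attention)
}

#' Block Combined Pooling
#'
#' A 3x3 convolution expands the channel dimension to the stage's `d0`, a
#' 3x3/stride-2 max pooling halves the spatial side, and batch normalization
#' regularizes the output: `d_i x h x w -> d0 x h/2 x w/2`.
#'
#' @param model a `pcvt_model`.
#' @param fm feature map entering the pooling.
#' @param stage stage index.
#' @return Pooled feature map (eval-mode normalization statistics).
#' @export
block_combined_pooling <- function(model, fm, stage = 1) {
  bcp_fwd(model$params$stages[[stage]]$bcp,
          model$state$stages[[stage]]$bn, fm, train = FALSE)$out
}

#' One full pyramid-transformer stage
#'
#' `l` encoder blocks followed by one Block Combined Pooling.
#'
#' @param model a `pcvt_model`.
#' @param fm feature map entering the stage.
#' @param stage stage index.
#' @return List with `out` and `attention` (list over blocks).
#' @export
ptf_stage <- function(model, fm, stage = 1) {
  st <- model$config$stages[[stage]]
  attn <- vector("list", st$l)
  h <- fm
  for (b in seq_len(st$l)) {
    eb <- encoder_block(model, h, stage, b)
    h <- eb$out
    attn[[b]] <- eb$attention
  }
  list(out = block_combined_pooling(model, h, stage), attention = attn)
}

#' Pixel shuffle and condensing convolution of the classifier
#'
#' The final feature map is up-sampled `f`-fold per side by pixel shuffle (a
#' value-preserving permutation) and condensed by an `f x f`/stride-`f`
#' convolution back to the token grid, with `condense_channels` channels.
#'
#' @param model a `pcvt_model` with the V-ALC head.
#' @param fm final-stage feature map.
#' @return Condensed feature map `condense_channels x h x w x B`.
#' @export
pixel_shuffle_condense <- function(model, fm) {
  if (model$head != "valc")
    stop("pixel_shuffle_condense requires the V-ALC head")
  f <- model$config$pixel_shuffle_factor
  xs <- pixel_shuffle(fm, f)
  conv2d_forward(model$params$valc$condense, xs, stride = f, pad = 0)$out
}

#' Channel Mean: per-sample average over channels
#'
#' @param fm feature map `C x H x W x B`.
#' @return Array `H x W x B`: the one-dimensional (single-channel)
#'   valence-arousal-like feature per sample.
#' @export
channel_mean <- function(fm) {
  d <- dim(fm)
  array(colMeans(matrix(fm, d[1])), d[2:4])
}

#' Batch Sharing: average over channels and batch
#'
#' Identically the batch-mean of [channel_mean()]: a single neutral feature
#' shared by every sample in the batch.
#'
#' @param fm feature map `C x H x W x B`.
#' @return Matrix `H x W`.
#' @export
batch_sharing <- function(fm) {
  d <- dim(fm)
  cm <- channel_mean(fm)
  array(rowMeans(matrix(cm, d[2] * d[3])), d[2:3])
}

#' Valence-arousal-like classifier head
#'
#' The condensed map is reduced to the V-A-like feature (channel mean) and a
#' neutral feature (batch sharing during training; the stored running value
#' during evaluation); `combined = V-A-like + w_AD * neutral` flows through
#' the final linear layer and the per-class sigmoid.
#'
#' @param model a `pcvt_model` with the V-ALC head.
#' @param fm final-stage feature map (`d0 x h x w x B`).
#' @param mode `"eval"` or `"train"`.
#' @return `B x d_class` matrix of sigmoid confidences, strictly in (0, 1).
#' @export
valc_forward <- function(model, fm, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  vp <- model$params$valc
  attr(vp, "f") <- model$config$pixel_shuffle_factor
  hd <- valc_fwd(vp, model$state$neutral, fm, train = (mode == "train"))
  t(sigmoid(hd$logits))
}

# ---- checkpointing -------------------------------------------------------

#' Save a model checkpoint
#'
#' The checkpoint archives the weights (including `w_AD`), the running
#' neutral-baseline and normalization state, the model configuration, the
#' vocabulary and the seed, under a versioned schema.
#'
#' @param model a `pcvt_model`.
#' @param path output file (RDS).
#' @param train_config,history optional training metadata to store.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, train_config = NULL,
                            history = NULL) {
  obj <- list(schema_version = 1L, config = unclass(model$config),
              vocab = model$vocab, head = model$head, params = model$params,
              state = model$state, seed = model$seed,
              train_config = if (is.null(train_config)) NULL
                             else unclass(train_config),
              history = history)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return A `pcvt_model` (with `train_config` and `history` attributes when
#'   present in the checkpoint).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported checkpoint schema")
  cfg <- obj$config
  cfg$stages <- lapply(cfg$stages, function(s) stage_config(s$l, s$d0,
                                                            s$heads))
  cfg <- do.call(model_config, cfg[setdiff(names(cfg), "stages")] |>
                   c(list(stages = cfg$stages)))
  model <- structure(list(config = cfg, vocab = obj$vocab, head = obj$head,
                          params = obj$params, state = obj$state,
                          seed = obj$seed),
                     class = "pcvt_model")
  attr(model, "train_config") <- obj$train_config
  attr(model, "history") <- obj$history
  model
}
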