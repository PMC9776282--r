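# Training: AdamW with decoupled weight decay, cross-entropy loss on the
# raw scores (sigmoid is applied only when reporting confidences; argmax is
# unaffected), exponential per-epoch learning-rate decay, and seeded,
# fully deterministic CPU execution (initialization and data order).

softmax_cols <- function(logits) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  sweep(e, 2, colSums(e), "/")
}

cross_entropy <- function(logits, y) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B)
}

adamw_new <- function() {
  env <- new.env(parent = emptyenv())
  env$m <- list(); env$v <- list(); env$t <- 0L
  env
}

# one AdamW step over the whole parameter tree; grads mirrors params
adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, g, path) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        if (identical(nm[i], "ksize")) next
        named <- !is.null(nm) && !is.na(nm[i]) && nm[i] != ""
        lab <- if (named) nm[i] else as.character(i)
        gi <- if (named) g[[nm[i]]] else g[[i]]
        p[[i]] <- upd(p[[i]], gi, paste(path, lab, sep = "."))
      }
      return(p)
    }
    if (is.null(g)) stop("missing gradient for ", path)
    m <- opt$m[[path]]
    v <- opt$v[[path]]
    if (is.null(m)) { m <- 0 * p; v <- 0 * p }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    opt$m[[path]] <- m
    opt$v[[path]] <- v
    p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
  }
  upd(params, grads, "par")
}

# stratified index split; returns list(train, val)
stratified_split <- function(y, val_fraction) {
  if (val_fraction <= 0)
    return(list(train = seq_along(y), val = integer(0)))
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- floor(length(idx) * val_fraction)
    if (n_val > 0) val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Train a PCVT model
#'
#' Runs AdamW with the configured learning rate and exponential per-epoch
#' decay on minibatches of the (stratified-split) training data, updating
#' the batch-shared neutral baseline's running value at every step. The run
#' is bit-reproducible on CPU under the config seed.
#'
#' @param model a `pcvt_model` (freshly built or loaded).
#' @param data either `list(x = images C x H x W x B, y = labels)` (labels
#'   as class names or 1-based indices) or a manifest data frame / CSV path
#'   whose images are loaded at the configured input size.
#' @param config a [train_config()].
#' @param out_dir optional run directory receiving `history.csv` and
#'   `checkpoint.rds`.
#' @param verbose print per-epoch progress to stderr.
#' @return Object of class `pcvt_fit`: list with `model` (trained),
#'   `history` (data frame: epoch, lr, train_loss, train_acc, val_loss,
#'   val_acc) and `config`.
#' @export
train_model <- function(model, data, config = train_config(),
                        out_dir = NULL, verbose = FALSE) {
  data <- as_image_data(data, model)
  y <- data$y
  if (dim(data$x)[4] < 2 && config$batch_size >= 2)
    stop("training needs at least 2 samples (batch-shared neutral baseline)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  split <- stratified_split(y, config$val_split)
  opt <- adamw_new()
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- decayed_lr(config$lr, config$lr_decay, epoch - 1)
    idx <- sample(split$train)
    n_correct <- 0; loss_sum <- 0; n_seen <- 0
    for (start in seq(1, length(idx), by = config$batch_size)) {
      bidx <- idx[start:min(start + config$batch_size - 1, length(idx))]
      xb <- data$x[, , , bidx, drop = FALSE]
      if (isTRUE(config$augment_hflip)) {
        w <- dim(xb)[3]
        for (j in which(stats::runif(length(bidx)) < 0.5))
          xb[, , , j] <- xb[, , w:1, j]
      }
      yb <- y[bidx]
      fw <- fwd_model(model, xb, train = TRUE, keep = TRUE)
      model <- fw$model
      ce <- cross_entropy(fw$logits, yb)
      grads <- bwd_model(model, fw$cache, ce$dlogits)
      model$params <- adamw_step(model$params, grads, opt, lr,
                                 config$weight_decay)
      loss_sum <- loss_sum + ce$loss * length(bidx)
      n_correct <- n_correct + sum(apply(fw$logits, 2, which.max) == yb)
      n_seen <- n_seen + length(bidx)
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (length(split$val)) {
      ev <- eval_pass(model, data$x[, , , split$val, drop = FALSE],
                      y[split$val])
      val_loss <- ev$loss; val_acc <- ev$acc
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = loss_sum / n_seen,
                                train_acc = n_correct / n_seen,
                                val_loss = val_loss, val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.6f  loss %.4f  acc %.3f", epoch, lr,
                      loss_sum / n_seen, n_correct / n_seen))
  }
  history <- do.call(rbind, hist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    save_checkpoint(model, file.path(out_dir, "checkpoint.rds"),
                    train_config = config, history = history)
  }
  structure(list(model = model, history = history, config = config),
            class = "pcvt_fit")
}

eval_pass <- function(model, x, y, batch_size = 64) {
  B <- dim(x)[4]
  loss_sum <- 0; n_correct <- 0
  for (start in seq(1, B, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1, B)
    fw <- fwd_model(model, x[, , , bidx, drop = FALSE], train = FALSE)
    ce <- cross_entropy(fw$logits, y[bidx])
    loss_sum <- loss_sum + ce$loss * length(bidx)
    n_correct <- n_correct + sum(apply(fw$logits, 2, which.max) == y[bidx])
  }
  list(loss = loss_sum / B, acc = n_correct / B)
}

#' @export
print.pcvt_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat("PCVT fit: ", n, " epoch(s)\n", sep = "")
  cat(sprintf("  final train loss %.4f, train acc %.3f\n",
              x$history$train_loss[n], x$history$train_acc[n]))
  if (!is.na(x$history$val_acc[n]))
    cat(sprintf("  final val loss %.4f, val acc %.3f\n",
                x$history$val_loss[n], x$history$val_acc[n]))
  invisible(x)
}
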