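# Shared fixtures, built in code at test time.

# minimal valid architecture: 32-px input, one stage, tiny widths
tiny_cfg <- function(d_class = 3) {
  model_config(input_size = 32, patch_size = 8, r = 1, stem_channels = 8,
               stages = list(stage_config(1, 16, 2)),
               pixel_shuffle_factor = 2, condense_channels = 5,
               head_hidden = 6, d_class = d_class)
}

# in-memory synthetic dataset as a model-ready tensor
tiny_tensor_data <- function(n_per_class = 2, size = 64, seed = 7) {
  vocab <- emotion_vocabulary("private8")
  ds <- generate_dataset(n_per_class, render_spec(size = size), seed = seed)
  B <- nrow(ds$manifest)
  x <- array(0, c(3, size, size, B))
  for (i in seq_len(B)) x[, , , i] <- aperm(ds$images[[i]], c(3, 1, 2))
  list(x = x, y = match(ds$manifest$label, vocab), manifest = ds$manifest,
       images = ds$images, vocab = vocab)
}

rand_fm <- function(c, h, w, b, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(c * h * w * b), c(c, h, w, b))
}

# central-difference gradient of scalar-valued f at selected entries of x
num_grad_entries <- function(f, x, entries, eps = 1e-5) {
  vapply(entries, function(j) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# independent per-class metric computation by direct counting over the
# expanded (true, predicted) label pairs of a confusion matrix
brute_force_metrics <- function(cm) {
  k <- nrow(cm)
  true <- integer(0); pred <- integer(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    true <- c(true, rep.int(i, cm[i, j]))
    pred <- c(pred, rep.int(j, cm[i, j]))
  }
  out <- matrix(0, k, 5,
                dimnames = list(NULL, c("precision", "specificity",
                                        "sensitivity", "f1", "g_mean")))
  for (cl in seq_len(k)) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    tn <- sum(true != cl & pred != cl)
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    sp <- if (tn + fp > 0) tn / (tn + fp) else 0
    se <- if (tp + fn > 0) tp / (tp + fn) else 0
    out[cl, ] <- c(pr, sp, se,
                   if (pr + se > 0) 2 * pr * se / (pr + se) else 0,
                   sqrt(se * sp))
  }
  list(per_class = out,
       accuracy = if (length(true)) mean(true == pred) else 0)
}
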