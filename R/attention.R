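# Attention rollout: stacking the per-layer attention weights in depth order
# to locate the image regions the classifier attends to.

# spatial aggregation operator of a 3x3/stride-2/pad-1 max pooling, as a
# row-stochastic (coarse x fine) token matrix: each coarse token averages
# the fine tokens inside its pooling window
pool_operator <- function(fine_side) {
  coarse <- (fine_side + 2 - 3) %/% 2 + 1
  D <- matrix(0, coarse * coarse, fine_side * fine_side)
  for (cj in seq_len(coarse)) {
    for (ci in seq_len(coarse)) {
      rowi <- (cj - 1) * coarse + ci
      for (kj in -1:1) {
        for (ki in -1:1) {
          fi <- 2 * (ci - 1) + 1 + ki
          fj <- 2 * (cj - 1) + 1 + kj
          if (fi >= 1 && fi <= fine_side && fj >= 1 && fj <= fine_side)
            D[rowi, (fj - 1) * fine_side + fi] <- 1
        }
      }
    }
  }
  D / rowSums(D)
}

#' Attention rollout heat map
#'
#' Head-averaged attention matrices are identity-added, row-renormalized and
#' multiplied in depth order; across stages the pooling geometry aggregates
#' fine tokens into coarse ones. The column means of the rolled product give
#' the attention each input token receives, reshaped to the token grid,
#' bilinearly upsampled to the input resolution and min-max normalized to
#' `[0, 1]`.
#'
#' @param maps attention maps as returned by [model_forward()] with
#'   `collect_attention = TRUE`: a list over stages of lists over blocks of
#'   `T x T x heads x B` arrays.
#' @param input_size output heat-map side in pixels.
#' @param batch_index which batch element to visualize.
#' @return `input_size x input_size` matrix with minimum 0 and maximum 1.
#' @export
attention_rollout <- function(maps, input_size = 128, batch_index = 1) {
  if (is.null(maps) || length(maps) == 0 ||
      all(vapply(maps, length, integer(1)) == 0))
    stop("empty attention maps; run model_forward(collect_attention = TRUE)")
  rolled <- NULL
  for (s in seq_along(maps)) {
    for (b in seq_along(maps[[s]])) {
      A4 <- maps[[s]][[b]]
      d <- dim(A4)
      TT <- d[1]
      A <- matrix(0, TT, TT)
      for (h in seq_len(d[3])) A <- A + A4[, , h, batch_index]
      A <- A / d[3]
      Ahat <- 0.5 * (A + diag(TT))
      Ahat <- Ahat / rowSums(Ahat)
      if (is.null(rolled)) {
        rolled <- Ahat
      } else {
        if (ncol(Ahat) < nrow(rolled))    # entering a coarser stage
          rolled <- pool_operator(as.integer(sqrt(nrow(rolled)))) %*% rolled
        rolled <- Ahat %*% rolled
      }
    }
  }
  received <- colMeans(rolled)
  side <- as.integer(sqrt(length(received)))
  heat <- matrix(received, side, side)    # row i = y, col j = x (token grid)
  heat <- resize_bilinear(heat, input_size, input_size)
  rng <- range(heat)
  if (rng[2] > rng[1]) (heat - rng[1]) / (rng[2] - rng[1])
  else matrix(0, input_size, input_size)
}
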