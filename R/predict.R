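# Prediction, data loading and embedding export.

# Coerce data to list(x = C x H x W x B tensor in [0,1], y = 1-based indices
# or NULL, labels = character or NULL). Accepts a tensor list, a manifest
# data frame, or a manifest CSV path. Images are bilinearly resized to the
# configured input size when needed.
as_image_data <- function(data, model) {
  cfg <- model$config
  if (is.character(data) && length(data) == 1) data <- read_manifest(data)
  if (is.list(data) && !is.data.frame(data) && !is.null(data$x)) {
    y <- data$y
    if (is.character(y) || is.factor(y)) {
      y <- match(as.character(y), model$vocab)
      if (anyNA(y)) stop("label outside the model vocabulary")
    }
    return(list(x = data$x, y = y,
                labels = if (is.null(y)) NULL else model$vocab[y]))
  }
  if (!is.data.frame(data)) stop("unsupported data argument")
  if (nrow(data) == 0) stop("empty manifest")
  B <- nrow(data)
  x <- array(0, c(cfg$in_channels, cfg$input_size, cfg$input_size, B))
  resized <- 0L
  for (i in seq_len(B)) {
    img <- read_image(manifest_path(data, i))
    if (nrow(img) != cfg$input_size || ncol(img) != cfg$input_size) {
      img <- resize_bilinear(img, cfg$input_size, cfg$input_size)
      resized <- resized + 1L
    }
    x[, , , i] <- aperm(img, c(3, 1, 2))
  }
  if (resized > 0)
    message(resized, " image(s) resized to ", cfg$input_size, " x ",
            cfg$input_size)
  y <- NULL
  if (!is.null(data$label)) {
    y <- match(as.character(data$label), model$vocab)
    if (anyNA(y))
      stop("label outside the model vocabulary: ",
           paste(unique(data$label[is.na(y)]), collapse = ", "))
  }
  list(x = x, y = y, labels = if (is.null(y)) NULL else model$vocab[y])
}

#' Predict emotion labels and confidences
#'
#' Eval-mode prediction: per-image argmax label plus the full sigmoid
#' confidence vector. Results are independent of how images are batched.
#' Images whose size differs from the configured input are bilinearly
#' resized with a logged notice.
#'
#' @param model a trained `pcvt_model` (neutral baseline updated).
#' @param data a single image path, an image array (`H x W x 3` in `[0,1]`),
#'   a manifest data frame / CSV path, or `list(x = tensor)`.
#' @param batch_size prediction batch size.
#' @return Data frame with `label` and one confidence column per class.
#' @export
predict_emotions <- function(model, data, batch_size = 64) {
  if (is.character(data) && length(data) == 1 &&
      grepl("\\.(png|jpe?g|tiff?)$", data, ignore.case = TRUE)) {
    img <- read_image(data)
    cfg <- model$config
    if (nrow(img) != cfg$input_size || ncol(img) != cfg$input_size) {
      message("image resized to ", cfg$input_size, " x ", cfg$input_size)
      img <- resize_bilinear(img, cfg$input_size, cfg$input_size)
    }
    data <- list(x = array(aperm(img, c(3, 1, 2)),
                           c(dim(img)[3], nrow(img), ncol(img), 1)))
  } else if (is.array(data) && length(dim(data)) == 3) {
    cfg <- model$config
    if (nrow(data) != cfg$input_size || ncol(data) != cfg$input_size) {
      message("image resized to ", cfg$input_size, " x ", cfg$input_size)
      data <- resize_bilinear(data, cfg$input_size, cfg$input_size)
    }
    data <- list(x = array(aperm(data, c(3, 1, 2)),
                           c(dim(data)[3], nrow(data), ncol(data), 1)))
  }
  data <- as_image_data(data, model)
  B <- dim(data$x)[4]
  scores <- matrix(0, B, length(model$vocab),
                   dimnames = list(NULL, model$vocab))
  for (start in seq(1, B, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1, B)
    fw <- fwd_model(model, data$x[, , , bidx, drop = FALSE], train = FALSE)
    scores[bidx, ] <- fw$scores
  }
  out <- data.frame(label = model$vocab[apply(scores, 1, which.max)],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Export penultimate-layer embeddings
#'
#' Writes the features entering the final linear layer (the combined
#' valence-arousal-like + weighted-neutral feature for the V-ALC head), one
#' row per image, for external t-SNE or other visualization.
#'
#' @param model a trained `pcvt_model`.
#' @param data manifest data frame / CSV path or `list(x, y)`.
#' @param path optional CSV output path.
#' @param batch_size forward batch size.
#' @return Data frame with `emb_*` columns and `label` (when known).
#' @export
export_embeddings <- function(model, data, path = NULL, batch_size = 64) {
  data <- as_image_data(data, model)
  B <- dim(data$x)[4]
  emb <- NULL
  for (start in seq(1, B, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1, B)
    fw <- fwd_model(model, data$x[, , , bidx, drop = FALSE], train = FALSE)
    if (is.null(emb)) emb <- matrix(0, B, nrow(fw$embedding))
    emb[bidx, ] <- t(fw$embedding)
  }
  colnames(emb) <- paste0("emb_", seq_len(ncol(emb)))
  out <- as.data.frame(emb)
  if (!is.null(data$labels)) out$label <- data$labels
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
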