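# Eye-landmark face alignment.
#
# Coordinates are 0-based pixel coordinates, x rightward, y downward (the
# image frame used by standard image libraries). The aligning rotation is
# rigid, taken about the midpoint of the inter-ocular line, so that after the
# transform the two eyes sit on the same row.

#' Eye-landmark record
#'
#' @param xl,yl left-eye coordinates (pixels, 0-based, y downward).
#' @param xr,yr right-eye coordinates.
#' @param confidence detector confidence in `[0, 1]`.
#' @return Object of class `eye_landmarks`.
#' @export
eye_landmarks <- function(xl, yl, xr, yr, confidence = 1) {
  vals <- c(xl = xl, yl = yl, xr = xr, yr = yr)
  if (!all(is.finite(vals)))
    stop("invalid landmarks: coordinates must be finite")
  if (xl == xr && yl == yr)
    stop("invalid landmarks: left and right eye coincide")
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop("invalid landmarks: confidence must be in [0, 1]")
  structure(list(xl = unname(xl), yl = unname(yl), xr = unname(xr),
                 yr = unname(yr), confidence = unname(confidence)),
            class = "eye_landmarks")
}

#' Rotation angle of the inter-ocular line
#'
#' `theta = atan((yr - yl) / (xr - xl))`, the angle (radians) by which the
#' line joining the eyes deviates from horizontal in the y-down image frame.
#'
#' @param landmarks an [eye_landmarks()] object (or coercible list).
#' @return Angle in radians, in `(-pi/2, pi/2)`.
#' @examples
#' rotation_angle(eye_landmarks(0, 0, 10, 10))  # pi/4
#' @export
rotation_angle <- function(landmarks) {
  lm <- as_eye_landmarks(landmarks)
  if (lm$xr == lm$xl)
    stop("invalid landmarks: vertical eye axis (xr == xl)")
  atan((lm$yr - lm$yl) / (lm$xr - lm$xl))
}

as_eye_landmarks <- function(lm) {
  if (inherits(lm, "eye_landmarks")) return(lm)
  eye_landmarks(lm$xl, lm$yl, lm$xr, lm$yr,
                if (is.null(lm$confidence)) 1 else lm$confidence)
}

#' Rigid alignment about the eye midpoint
#'
#' Builds the rotation `A = [[cos t, sin t], [-sin t, cos t]]` and translation
#' `B` such that the eye midpoint `(xc, yc)` is a fixed point and the mapped
#' eyes are level. `M = [A | B]` acts on homogeneous pixel coordinates.
#'
#' @param landmarks an [eye_landmarks()] object.
#' @param theta rotation angle in radians; defaults to
#'   [rotation_angle()] of the landmarks.
#' @return Object of class `rigid_alignment` with fields `theta`, `A`, `B`,
#'   `M` and `center`.
#' @export
alignment_transform <- function(landmarks, theta = NULL) {
  lm <- as_eye_landmarks(landmarks)
  if (is.null(theta)) theta <- rotation_angle(lm)
  ct <- cos(theta); st <- sin(theta)
  xc <- (lm$xl + lm$xr) / 2
  yc <- (lm$yl + lm$yr) / 2
  A <- matrix(c(ct, -st, st, ct), 2, 2)     # rows: (ct, st), (-st, ct)
  B <- c((1 - ct) * xc - st * yc,
         st * xc + (1 - ct) * yc)
  structure(list(theta = theta, A = A, B = B, M = cbind(A, B),
                 center = c(xc, yc)),
            class = "rigid_alignment")
}

#' Apply a rigid alignment to points
#'
#' @param alignment a `rigid_alignment`.
#' @param points numeric vector `c(x, y)` or an `n x 2` matrix of 0-based
#'   pixel coordinates.
#' @return Mapped coordinates, same shape as the input.
#' @export
apply_alignment <- function(alignment, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1) else as.matrix(points)
  out <- t(alignment$A %*% t(p)) +
    matrix(alignment$B, nrow(p), 2, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Warp an image by a rigid alignment
#'
#' Every output pixel is sampled at the alignment-inverse source coordinate
#' with bilinear interpolation; coordinates falling outside the frame
#' replicate the border. The warped frame (same size as the input) is then
#' bilinearly resized to `output_size x output_size`.
#'
#' @param image `H x W` matrix or `H x W x C` array with values in `[0, 1]`.
#' @param alignment a `rigid_alignment` from [alignment_transform()].
#' @param output_size side of the square output in pixels; `NULL` keeps the
#'   input size.
#' @return Warped image array.
#' @export
warp_image <- function(image, alignment, output_size = NULL) {
  if (is.null(image) || length(image) == 0)
    stop("empty image")
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  # dest -> src: src = A^-1 (dest - B); A is a rotation so A^-1 = t(A)
  Ainv <- t(alignment$A)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  sx <- Ainv[1, 1] * (gx - alignment$B[1]) + Ainv[1, 2] * (gy - alignment$B[2])
  sy <- Ainv[2, 1] * (gx - alignment$B[1]) + Ainv[2, 2] * (gy - alignment$B[2])
  out <- array(0, d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- matrix(bilinear_sample(image[, , ch], sx, sy), h, w)
  if (!is.null(output_size) && (output_size != h || output_size != w)) {
    if (output_size < 1) stop("output_size must be positive")
    out <- resize_bilinear(out, output_size, output_size)
  }
  if (d[3] == 1) out <- out[, , 1] else out
}

# landmark coordinates after warp_image: rigid map, then the resize scaling
map_landmarks <- function(alignment, lm, in_h, in_w, out_size) {
  p <- apply_alignment(alignment, rbind(c(lm$xl, lm$yl), c(lm$xr, lm$yr)))
  sx <- out_size / in_w
  sy <- out_size / in_h
  # resize maps src coordinate s to (s + 0.5) * scale - 0.5
  p[, 1] <- (p[, 1] + 0.5) * sx - 0.5
  p[, 2] <- (p[, 2] + 0.5) * sy - 0.5
  p
}

#' Read a manifest CSV
#'
#' Manifests have the header `path,label,xl,yl,xr,yr,confidence` (extra
#' columns are preserved); `path` entries are relative to the manifest
#' location, which is recorded in the `base_dir` attribute.
#'
#' @param path CSV file path.
#' @return `data.frame` with a `base_dir` attribute.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "xl", "yl", "xr", "yr", "confidence")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  attr(m, "base_dir") <- dirname(normalizePath(path))
  m
}

#' Write a manifest CSV
#'
#' @param manifest data frame with the manifest columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

manifest_path <- function(manifest, i) {
  base <- attr(manifest, "base_dir")
  p <- manifest$path[i]
  if (!is.null(base) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
}

#' Read an 8-bit PNG face image
#'
#' Grayscale images are replicated to three channels; an alpha channel is
#' dropped. JPEG decoding is not available; convert JPEG inputs to PNG first.
#'
#' @param path image file path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    stop("JPEG decoding is not supported; convert ", basename(path),
         " to PNG")
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2) img <- img[, , 1, drop = FALSE]  # gray + alpha
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3L))
  img
}

#' Align all faces of a manifest
#'
#' Rows whose detector confidence falls below `min_confidence` are dropped
#' (and counted); the survivors are rotated so the eyes are level, resized,
#' written to `output_dir` as PNG, and re-listed with mapped landmarks.
#' Unreadable images or degenerate landmarks skip the row with a warning.
#'
#' @param manifest manifest data frame (see [read_manifest()]) or CSV path.
#' @param output_dir directory for aligned images and the new manifest.
#' @param min_confidence drop threshold on the confidence column.
#' @param output_size side of the square aligned output, pixels.
#' @return List with `manifest` (the aligned manifest data frame, also
#'   written to `output_dir/aligned_manifest.csv`), `dropped` (low-confidence
#'   count) and `skipped` (unreadable/degenerate count).
#' @export
align_manifest <- function(manifest, output_dir, min_confidence = 0.5,
                           output_size = 128) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- manifest$confidence >= min_confidence
  dropped <- sum(!keep)
  rows <- which(keep)
  out <- vector("list", length(rows))
  skipped <- 0L
  for (j in seq_along(rows)) {
    i <- rows[j]
    res <- tryCatch({
      img <- read_image(manifest_path(manifest, i))
      lm <- eye_landmarks(manifest$xl[i], manifest$yl[i],
                          manifest$xr[i], manifest$yr[i],
                          manifest$confidence[i])
      al <- alignment_transform(lm)
      warped <- warp_image(img, al, output_size)
      fn <- sprintf("aligned_%05d.png", i)
      png::writePNG(warped, file.path(output_dir, fn))
      p <- map_landmarks(al, lm, nrow(img), ncol(img), output_size)
      data.frame(path = fn, label = manifest$label[i],
                 xl = p[1, 1], yl = p[1, 2], xr = p[2, 1], yr = p[2, 2],
                 confidence = manifest$confidence[i],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("skipping row ", i, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else out[[j]] <- res
  }
  out <- out[!vapply(out, is.null, logical(1))]
  aligned <- if (length(out)) do.call(rbind, out) else
    data.frame(path = character(), label = character(), xl = numeric(),
               yl = numeric(), xr = numeric(), yr = numeric(),
               confidence = numeric(), stringsAsFactors = FALSE)
  write_manifest(aligned, file.path(output_dir, "aligned_manifest.csv"))
  attr(aligned, "base_dir") <- normalizePath(output_dir)
  list(manifest = aligned, dropped = dropped, skipped = skipped)
}
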