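# Seeded parametric generator of schematic, action-unit-driven face images.
#
# Faces are analytic 2D drawings (ellipses, bands and curves evaluated per
# pixel), not photorealistic renders: enough geometry for alignment,
# labeling, training dynamics and the package invariants to be exercised
# without any external dataset. Every AU that the FACS rules reference moves
# a visible drawing parameter, so the eight emotion classes are separable.

#' Rendering specification for synthetic faces
#'
#' @param size square image side in pixels (>= 32).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (intensity scale 0..1).
#' @param subject_variation scale of per-subject appearance variation (face
#'   aspect, skin tone, feature offsets); 0 makes all subjects identical.
#' @param illumination strength of the linear illumination gradient.
#' @param roll_range head-roll angles are drawn uniformly from
#'   `[-roll_range, roll_range]` radians (exercises alignment).
#' @return `render_spec` list.
#' @export
render_spec <- function(size = 128, noise_sd = 0.02, subject_variation = 1,
                        illumination = 0.15, roll_range = 0.17) {
  if (size < 32) stop("size must be at least 32")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(size = as.integer(size), noise_sd = noise_sd,
                 subject_variation = subject_variation,
                 illumination = illumination, roll_range = roll_range),
            class = "render_spec")
}

zero_au <- function() {
  stats::setNames(numeric(length(au_vocabulary())), au_vocabulary())
}

#' Draw action-unit intensities for an emotion label
#'
#' AUs required by the label's FACS rule get intensities in `[0.6, 1]`
#' (within-clause "/" alternatives chosen uniformly); all remaining AUs get
#' residual intensities in `[0, 0.15]`. Uses the current RNG state.
#'
#' @param label emotion name known to the rule table.
#' @param rules FACS rule table from [facs_rules()].
#' @return Named numeric vector over [au_vocabulary()], all in `[0, 1]`.
#' @export
emotion_to_au_intensities <- function(label, rules = facs_rules()) {
  if (!label %in% names(rules))
    stop("unknown emotion label: ", label)
  au <- zero_au()
  au[] <- stats::runif(length(au), 0, 0.15)
  for (clause in rules[[label]]) {
    pick <- if (length(clause) == 1) clause else sample(clause, 1)
    au[pick] <- stats::runif(1, 0.6, 1)
  }
  au
}

# per-subject appearance parameters; draws from the current RNG state
subject_appearance <- function(variation = 1) {
  list(aspect = 1 + 0.06 * variation * stats::rnorm(1),
       tone = 1 + 0.08 * variation * stats::rnorm(1),
       eye_dx = 0.015 * variation * stats::rnorm(1),
       eye_dy = 0.02 * variation * stats::rnorm(1),
       mouth_dy = 0.02 * variation * stats::rnorm(1))
}

# soft step: 0 below 0, 1 above w, linear between
soft_step <- function(d, w = 0.02) pmin(pmax(d / w, 0), 1)

#' Render one synthetic face
#'
#' Draws an elliptical face whose brows, eyes, nose/cheek shading and mouth
#' are controlled by the AU intensities (brow raise/lower by AU1/2/4, eye
#' openness by AU5/7/43, cheek raise AU6, nose wrinkle AU9, upper-lip raise
#' AU10, mouth curvature AU12/15, lip thinning AU23/24/28, jaw drop AU26,
#' downward head pitch AU54), applies head roll, an illumination gradient
#' and Gaussian noise, and returns the true eye-center landmarks.
#' Deterministic given the RNG state (and `roll`, if supplied).
#'
#' @param au named AU intensity vector (see [emotion_to_au_intensities()]).
#' @param spec a [render_spec()].
#' @param subject optional per-subject appearance list (`aspect`, `tone`,
#'   `eye_dx`, `eye_dy`, `mouth_dy`).
#' @param roll head-roll angle in radians; drawn from the spec's range when
#'   `NULL`.
#' @return List with `image` (`size x size x 3` array in `[0, 1]`) and
#'   `landmarks` (named vector `xl, yl, xr, yr`, 0-based pixel coordinates).
#' @export
render_face <- function(au, spec = render_spec(), subject = NULL,
                        roll = NULL) {
  full <- zero_au()
  full[names(au)] <- au
  if (any(full < 0 | full > 1)) stop("AU intensities must lie in [0, 1]")
  au <- full
  if (is.null(subject))
    subject <- list(aspect = 1, tone = 1, eye_dx = 0, eye_dy = 0,
                    mouth_dy = 0)
  if (is.null(roll)) roll <- stats::runif(1, -spec$roll_range,
                                          spec$roll_range)
  n <- spec$size
  ctr <- (n - 1) / 2
  half <- n / 2
  px <- rep(0:(n - 1), each = n)       # column-major: x constant per column
  py <- rep(0:(n - 1), times = n)
  dx <- px - ctr
  dy <- py - ctr
  cr <- cos(roll); sr <- sin(roll)
  u <- (dx * cr + dy * sr) / half
  v <- (-dx * sr + dy * cr) / half

  dv <- 0.24 * au["AU54"]              # head down: whole face shifts
  I <- rep(0.50, n * n)                # mid-gray backdrop

  face <- soft_step(1 - ((u / (0.64 * subject$aspect))^2 +
                           ((v - dv - 0.02) / 0.84)^2), 0.12)
  skin <- 0.78 * subject$tone
  I <- I * (1 - face) + face * skin

  # brows: straight bands between inner and outer anchor points
  brow_base <- -0.33 + dv
  for (s in c(-1, 1)) {
    u1 <- s * 0.12; u2 <- s * 0.40
    v1 <- brow_base + 0.16 * au["AU4"] - 0.18 * au["AU1"]   # inner end
    v2 <- brow_base + 0.06 * au["AU4"] - 0.16 * au["AU2"]   # outer end
    tt <- pmin(pmax((u - u1) / (u2 - u1), 0), 1)
    vline <- v1 + tt * (v2 - v1)
    in_u <- soft_step(0.145 - abs(u - s * 0.26), 0.02)
    m <- soft_step(0.048 - abs(v - vline), 0.035) * in_u * face
    I <- I * (1 - m) + m * 0.18
  }

  # eyes: ellipses whose height encodes openness; landmarks at the centers
  open_frac <- (0.45 + 0.55 * au["AU5"]) * (1 - au["AU43"]) *
    (1 - 0.35 * au["AU7"])
  ey <- 0.13 * open_frac + 0.008
  ex <- 0.16
  ve <- -0.16 + dv + subject$eye_dy
  for (s in c(-1, 1)) {
    ue <- s * 0.26 + subject$eye_dx
    eye <- soft_step(1 - ((u - ue) / ex)^2 - ((v - ve) / ey)^2, 0.10)
    I <- I * (1 - eye) + eye * 0.96
    pup <- soft_step(1 - ((u - ue) / 0.065)^2 - ((v - ve) / 0.065)^2, 0.15) *
      soft_step(open_frac - 0.25, 0.1)
    I <- I * (1 - pup) + pup * 0.08
    closed_w <- soft_step(au[["AU43"]] - 0.25, 0.3)
    patch <- soft_step(1 - ((u - ue) / ex)^2 - ((v - ve) / 0.09)^2, 0.10)
    I <- I * (1 - patch * closed_w) + patch * closed_w * 0.42
    lid <- soft_step(0.028 - abs(v - ve), 0.022) *
      soft_step(ex - abs(u - ue), 0.02) * closed_w
    I <- I * (1 - lid) + lid * 0.15
  }

  # brow lowering also shadows the glabella (area signal robust to roll)
  if (au["AU4"] > 0) {
    glab <- soft_step(1 - (u / 0.13)^2 - ((v - (-0.24 + dv)) / 0.10)^2, 0.15)
    I <- I - 0.45 * au["AU4"] * glab * face
  }

  # cheek raise: darker blobs under the eyes
  if (au["AU6"] > 0) {
    for (s in c(-1, 1)) {
      blob <- soft_step(1 - ((u - s * 0.30) / 0.20)^2 -
                          ((v - (0.10 + dv)) / 0.10)^2, 0.15)
      I <- I - 0.45 * au["AU6"] * blob * face
    }
  }

  # nose wrinkle: horizontal creases on the bridge
  if (au["AU9"] > 0) {
    for (vb in c(-0.10, -0.05)) {
      band <- soft_step(0.016 - abs(v - (vb + dv)), 0.014) *
        soft_step(0.13 - abs(u), 0.02)
      I <- I - 0.45 * au["AU9"] * band
    }
  }

  # upper-lip raise darkens the philtrum region
  if (au["AU10"] > 0) {
    phil <- soft_step(1 - (u / 0.11)^2 - ((v - (0.27 + dv)) / 0.07)^2, 0.15)
    I <- I - 0.30 * au["AU10"] * phil * face
  }

  # mouth: curvature from AU12/AU15, aperture from AU26, thinning AU23/24/28
  vm <- 0.40 + dv + subject$mouth_dy
  mw <- 0.22 * (1 + 0.25 * au["AU12"])
  curv <- 0.30 * au["AU12"] - 0.36 * au["AU15"]
  aperture <- 0.26 * au["AU26"]
  thick <- 0.040 * (1 - 0.70 * max(au["AU23"], au["AU24"], au["AU28"]))
  vmid <- vm - curv * (u / mw)^2
  in_mouth_u <- soft_step(mw - abs(u), 0.02)
  vu <- vmid - aperture / 2 - 0.09 * au["AU10"]
  vl <- vmid + aperture / 2
  for (vli in list(vu, vl)) {
    m <- soft_step(thick - abs(v - vli), 0.030) * in_mouth_u * face
    I <- I * (1 - m) + m * 0.25
  }
  # lip-corner action as area signals: raised dimple dots (AU12) above the
  # corners, drooping shadow blobs (AU15) below them
  for (s in c(-1, 1)) {
    if (au["AU12"] > 0) {
      dot <- soft_step(1 - ((u - s * (mw + 0.05)) / 0.075)^2 -
                         ((v - (vm - curv - 0.05)) / 0.075)^2, 0.15)
      I <- I - 0.35 * au["AU12"] * dot * face
    }
    if (au["AU15"] > 0) {
      droop <- soft_step(1 - ((u - s * (mw + 0.03)) / 0.085)^2 -
                           ((v - (vm + 0.10)) / 0.085)^2, 0.15)
      I <- I - 0.42 * au["AU15"] * droop * face
    }
  }
  if (aperture > 0.001) {
    interior <- soft_step(v - vu, 0.01) * soft_step(vl - v, 0.01) *
      soft_step(mw * 0.92 - abs(u), 0.02) *
      soft_step(aperture - 0.02, 0.02)
    I <- I * (1 - interior) + interior * 0.10
  }

  I <- I + spec$illumination * (dx / n)
  if (spec$noise_sd > 0) I <- I + stats::rnorm(n * n, 0, spec$noise_sd)
  I <- pmin(pmax(I, 0), 1)

  img <- array(0, c(n, n, 3))
  base <- matrix(I, n, n)               # [y + 1, x + 1]
  img[, , 1] <- base
  img[, , 2] <- base * 0.97
  img[, , 3] <- base * 0.93

  lms <- numeric(4)
  i <- 1
  for (s in c(-1, 1)) {
    ue <- s * 0.26 + subject$eye_dx
    lx <- ctr + (ue * cr - ve * sr) * half
    ly <- ctr + (ue * sr + ve * cr) * half
    lms[i] <- lx; lms[i + 1] <- ly
    i <- i + 2
  }
  names(lms) <- c("xl", "yl", "xr", "yr")
  list(image = img, landmarks = lms, roll = roll)
}

table1_private_counts <- function() {
  c(happy = 141, sad = 78, surprised = 62, angry = 44, neutral = 509,
    painful = 85, strained = 298, tired = 85)
}

#' Generate a seeded synthetic face dataset
#'
#' Renders AU-driven faces for every class of the 8-class rehabilitation
#' vocabulary, with per-subject appearance variation (subjects recur across
#' classes, as patients contribute several emotions), head roll, noise and
#' illumination. Fully reproducible from the seed.
#'
#' @param n_per_class images per class, or a named per-class count vector
#'   via `counts`.
#' @param spec a [render_spec()].
#' @param seed RNG seed; two runs with the same seed produce byte-identical
#'   manifests and images.
#' @param out_dir directory for PNG images and `manifest.csv`; when `NULL`
#'   images are returned in memory only.
#' @param counts optional named integer vector of per-class counts.
#' @param preset `"table1-private"` reproduces the class imbalance of the
#'   stroke-patient collection (minimum 44, maximum 509 samples; min/max
#'   ratio 0.0864).
#' @param n_subjects size of the simulated subject pool.
#' @return List with `manifest` (data frame: path, label, landmarks,
#'   confidence, subject, roll and the AU intensities used) and `images`
#'   (list of arrays when `out_dir` is `NULL`).
#' @export
generate_dataset <- function(n_per_class = 20, spec = render_spec(),
                             seed = 1, out_dir = NULL, counts = NULL,
                             preset = NULL, n_subjects = 10) {
  vocab <- emotion_vocabulary("private8")
  if (!is.null(preset)) {
    if (preset != "table1-private") stop("unknown preset: ", preset)
    counts <- table1_private_counts()
  }
  if (is.null(counts))
    counts <- stats::setNames(rep(as.integer(n_per_class), length(vocab)),
                              vocab)
  if (any(counts < 1)) stop("per-class counts must be >= 1")
  if (!all(names(counts) %in% vocab))
    stop("counts name unknown classes: ",
         paste(setdiff(names(counts), vocab), collapse = ", "))
  if (!is.null(out_dir) &&
      !dir.create(out_dir, showWarnings = FALSE, recursive = TRUE) &&
      !dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subjects <- lapply(seq_len(n_subjects), function(i)
    subject_appearance(spec$subject_variation))
  rules <- facs_rules()

  total <- sum(counts)
  rows <- vector("list", total)
  images <- if (is.null(out_dir)) vector("list", total) else NULL
  k <- 0L
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      k <- k + 1L
      sid <- sample.int(n_subjects, 1)
      au <- emotion_to_au_intensities(cls, rules)
      r <- render_face(au, spec, subjects[[sid]])
      fn <- sprintf("%s_%04d.png", cls, i)
      if (!is.null(out_dir)) {
        png::writePNG(r$image, file.path(out_dir, fn))
      } else {
        images[[k]] <- r$image
      }
      rows[[k]] <- data.frame(path = fn, label = cls,
                              xl = r$landmarks["xl"], yl = r$landmarks["yl"],
                              xr = r$landmarks["xr"], yr = r$landmarks["yr"],
                              confidence = stats::runif(1, 0.9, 1),
                              subject = sid, roll = r$roll,
                              t(au), row.names = NULL,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    attr(manifest, "base_dir") <- normalizePath(out_dir)
  }
  list(manifest = manifest, images = images, spec = spec, seed = seed)
}
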