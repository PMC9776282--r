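# Eye-landmark alignment: rotation angle, rigid transform, warping and
# manifest-level filtering.

test_that("rotation angle follows the y-down image convention", {
  expect_equal(rotation_angle(eye_landmarks(0, 0, 10, 0)), 0)
  expect_equal(rotation_angle(eye_landmarks(0, 0, 10, 10)), pi / 4)
  expect_equal(rotation_angle(eye_landmarks(0, 5, 10, 0)), atan(-0.5),
               tolerance = 1e-7)
  expect_equal(round(rotation_angle(eye_landmarks(0, 5, 10, 0)), 5),
               -0.46365)
})

test_that("degenerate landmarks are rejected with clear errors", {
  expect_error(eye_landmarks(3, 4, 3, 4), "coincide")
  expect_error(rotation_angle(eye_landmarks(5, 0, 5, 9)), "vertical")
  expect_error(eye_landmarks(0, NA, 1, 1), "finite")
  expect_error(eye_landmarks(0, 0, 1, 1, confidence = 1.5), "confidence")
})

test_that("the rigid transform is a proper rotation fixing the midpoint", {
  lm <- eye_landmarks(0, 0, 10, 10)
  al <- alignment_transform(lm)
  expect_equal(crossprod(al$A), diag(2), tolerance = 1e-12)
  expect_equal(det(al$A), 1, tolerance = 1e-12)
  expect_true(al$theta > -pi / 2 && al$theta < pi / 2)
  expect_equal(apply_alignment(al, al$center), al$center,
               tolerance = 1e-9)
  expect_equal(dim(al$M), c(2, 3))
  # homogeneous form: M applied to (xc, yc, 1)
  expect_equal(as.vector(al$M %*% c(al$center, 1)), al$center,
               tolerance = 1e-9)
})

test_that("theta = 0 gives the identity transform", {
  al <- alignment_transform(eye_landmarks(10, 30, 50, 30))
  expect_equal(al$A, diag(2))
  expect_equal(al$B, c(0, 0))
})

test_that("alignment levels the eyes and preserves rigid structure", {
  set.seed(41)
  for (i in 1:50) {
    lm <- eye_landmarks(runif(1, 0, 40), runif(1, 0, 100),
                        runif(1, 60, 100), runif(1, 0, 100))
    al <- alignment_transform(lm)
    p <- apply_alignment(al, rbind(c(lm$xl, lm$yl), c(lm$xr, lm$yr)))
    expect_lt(abs(p[1, 2] - p[2, 2]), 1e-6)           # levelled
    d0 <- sqrt((lm$xr - lm$xl)^2 + (lm$yr - lm$yl)^2)
    expect_equal(sqrt(sum((p[2, ] - p[1, ])^2)), d0, tolerance = 1e-6)
    # composing with the inverse rotation about the same midpoint
    inv <- alignment_transform(lm, theta = -al$theta)
    q <- apply_alignment(inv, apply_alignment(al, c(7, 13)))
    expect_equal(q, c(7, 13), tolerance = 1e-9)
    # idempotence: re-estimating the angle on mapped landmarks gives 0
    expect_lt(abs(atan((p[2, 2] - p[1, 2]) / (p[2, 1] - p[1, 1]))), 1e-6)
  }
})

test_that("identity warp at input size is pixel-identical", {
  set.seed(2)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  al <- alignment_transform(eye_landmarks(5, 10, 19, 10))  # level eyes
  expect_identical(dim(warp_image(img, al, 24)), dim(img))
  expect_equal(warp_image(img, al, 24), img)
  expect_error(warp_image(array(0, c(0, 0, 1)), al), "empty")
})

test_that("warping a rolled synthetic face levels the true eye landmarks", {
  set.seed(6)
  au <- emotion_to_au_intensities("neutral")
  rolled <- render_face(au, render_spec(noise_sd = 0.01), roll = 0.15)
  lm <- eye_landmarks(rolled$landmarks["xl"], rolled$landmarks["yl"],
                      rolled$landmarks["xr"], rolled$landmarks["yr"])
  al <- alignment_transform(lm)
  expect_equal(al$theta, 0.15, tolerance = 1e-6)
  w <- warp_image(rolled$image, al, 128)
  expect_identical(dim(w), c(128L, 128L, 3L))
  p <- ferpcvt:::map_landmarks(al, lm, 128, 128, 128)
  expect_lt(abs(p[1, 2] - p[2, 2]), 1e-6)
  # an unrolled render of the same face puts its eyes on the same row
  set.seed(6)
  au2 <- emotion_to_au_intensities("neutral")
  flat <- render_face(au2, render_spec(noise_sd = 0.01), roll = 0)
  expect_lt(abs(p[1, 2] - flat$landmarks["yl"]), 1)
  expect_lt(abs(p[2, 2] - flat$landmarks["yr"]), 1)
})

test_that("align_manifest filters, counts and writes aligned outputs", {
  src <- file.path(tempdir(), "synth_align_src")
  ds <- generate_dataset(2, render_spec(size = 48), seed = 9, out_dir = src)
  m <- ds$manifest[1:10, ]
  m$confidence <- c(rep(0.9, 7), rep(0.2, 3))
  attr(m, "base_dir") <- src
  out <- file.path(tempdir(), "synth_align_out")
  res <- align_manifest(m, out, min_confidence = 0.5, output_size = 48)
  expect_equal(res$dropped, 3)
  expect_equal(nrow(res$manifest), 7)
  expect_true(all(file.exists(file.path(out, res$manifest$path))))
  expect_true(file.exists(file.path(out, "aligned_manifest.csv")))
  # threshold 0 retains everything
  res0 <- align_manifest(m, file.path(tempdir(), "aa0"), 0, 48)
  expect_equal(res0$dropped, 0)
  expect_equal(nrow(res0$manifest), 10)
  # threshold 1 with all confidences < 1: empty output, no error
  res1 <- align_manifest(m, file.path(tempdir(), "aa1"), 1.0, 48)
  expect_equal(nrow(res1$manifest), 0)
  expect_equal(res1$dropped, 10)
})

test_that("unreadable files are skipped with a warning, not a crash", {
  src <- file.path(tempdir(), "synth_align_bad")
  ds <- generate_dataset(1, render_spec(size = 48), seed = 10,
                         out_dir = src)
  m <- ds$manifest[1:3, ]
  m$path[2] <- "does_not_exist.png"
  attr(m, "base_dir") <- src
  expect_warning(
    res <- align_manifest(m, file.path(tempdir(), "aab"), 0.5, 48),
    "skipping")
  expect_equal(res$skipped, 1)
  expect_equal(nrow(res$manifest), 2)
})

test_that("manifest round-trips through CSV with required columns", {
  m <- data.frame(path = "a.png", label = "happy", xl = 1, yl = 2, xr = 3,
                  yr = 2, confidence = 0.9)
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_equal(m2$label, "happy")
  expect_error(read_manifest(tempfile()), "not found")
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(path = "a", label = "b"), bad,
                   row.names = FALSE)
  expect_error(read_manifest(bad), "missing columns")
})
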