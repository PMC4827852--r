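# minimal hand-built Gaussian pyramid holding one octave of copies of `img`
fake_gaussian_pyramid <- function(img, n_levels = 6) {
  cfg <- scale_space_config()
  structure(list(octaves = list(lapply(seq_len(n_levels), function(i) img)),
                 level_sigmas = list(cfg$base_sigma * cfg$k^(0:(n_levels - 1))),
                 config = cfg),
            class = "gaussian_pyramid")
}

ramp_keypoint <- function(x = 32, y = 32, sigma = 1.6, orientation = NA_real_) {
  data.frame(x = x, y = y, sigma = sigma, octave = 0L, level = 2L,
             x_pix = as.integer(round(x)), y_pix = as.integer(round(y)),
             dog_value = 0.1, orientation = orientation)
}

test_that("gradients follow the central-difference magnitude/orientation", {
  w <- 32; h <- 24
  gx <- compute_gradients(matrix(rep(seq_len(w) / w, each = h), h, w))
  expect_equal(gx$magnitude[5, 10], 2 / w, tolerance = 1e-12)
  expect_equal(gx$orientation[5, 10], 0)
  gy <- compute_gradients(matrix(rep(seq_len(h) / h, w), h, w))
  expect_equal(gy$magnitude[10, 5], 2 / h, tolerance = 1e-12)
  expect_equal(gy$orientation[10, 5], pi / 2)
  gc <- compute_gradients(matrix(0.7, h, w))
  expect_true(all(gc$magnitude == 0))
  expect_true(all(gc$orientation == 0))   # atan2(0, 0) convention
})

test_that("a pure ramp produces one oriented keypoint at the ramp direction", {
  img <- matrix(rep(seq_len(64) / 64, each = 64), 64, 64)
  gp <- fake_gaussian_pyramid(img)
  ok <- assign_orientations(ramp_keypoint(), gp)
  expect_equal(nrow(ok), 1L)
  bin_width <- 2 * pi / 36
  expect_lt(min(abs(c(ok$orientation, ok$orientation - 2 * pi))), bin_width)
})

test_that("secondary peaks within 80% of the highest spawn extra keypoints", {
  # continuous piecewise-linear image: gradient (a, 0) above the fold and
  # (a, b) below it, giving two orientation populations of equal extent
  # whose histogram-peak ratio is a / sqrt(a^2 + b^2)
  two_pop <- function(b, a = 0.01, n = 64, c = 32) {
    xs <- matrix(seq_len(n), n, n, byrow = TRUE)
    ys <- matrix(seq_len(n), n, n)
    a * xs + b * pmax(ys - c, 0)
  }
  # ratio 0.85 >= 0.80: both orientations reported
  b_hi <- 0.01 * tan(acos(0.85))
  n_hi <- nrow(assign_orientations(
    ramp_keypoint(), fake_gaussian_pyramid(two_pop(b_hi))))
  expect_equal(n_hi, 2L)
  # ratio 0.50 < 0.80: only the dominant orientation survives
  b_lo <- 0.01 * tan(acos(0.50))
  n_lo <- nrow(assign_orientations(
    ramp_keypoint(), fake_gaussian_pyramid(two_pop(b_lo))))
  expect_equal(n_lo, 1L)
})

test_that("dominant orientation tracks a 30-degree patch rotation", {
  skip_if_not_installed("EBImage")
  base <- blob_image(65, 65, cbind(c(33, 45), c(33, 33)), blob_sigma = 4)
  rot <- EBImage::rotate(EBImage::Image(t(base)), -30,
                         output.dim = c(65, 65), bg.col = 0.1)
  rot <- t(EBImage::imageData(rot))
  gp_a <- build_gaussian_pyramid(base)
  gp_b <- build_gaussian_pyramid(rot)
  kp <- ramp_keypoint(x = 33, y = 33, sigma = 3)
  oa <- assign_orientations(kp, gp_a)
  ob <- assign_orientations(kp, gp_b)
  bin_width <- 2 * pi / 36
  d <- abs(oa$orientation[1] - ob$orientation[1])
  d <- min(d %% (2 * pi), 2 * pi - d %% (2 * pi))
  expect_lt(abs(d - pi / 6), bin_width)
})

test_that("descriptors are 128-long, unit-norm, and degenerate on flat patches", {
  img <- blob_grid_image()
  f <- sift_features(img)
  expect_gt(nrow(f$keypoints), 0)
  expect_equal(ncol(f$descriptors), 128L)
  norms <- sqrt(rowSums(f$descriptors^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_true(all(f$descriptors >= 0))
  # flat patch: all-zero descriptor
  gp_flat <- fake_gaussian_pyramid(matrix(0.5, 64, 64))
  d0 <- compute_descriptor(ramp_keypoint(orientation = 0), gp_flat)
  expect_equal(d0, rep(0, 128))
})

test_that("descriptors are invariant to brightness offset and contrast scale", {
  img <- blob_grid_image()
  kp <- detect_keypoints(img)[1, ]
  gp1 <- build_gaussian_pyramid(img)
  okp <- assign_orientations(kp, gp1)[1, ]
  d1 <- compute_descriptor(okp, gp1)
  d_off <- compute_descriptor(okp, build_gaussian_pyramid(img + 0.1))
  expect_equal(d_off, d1, tolerance = 1e-10)
  d_scale <- compute_descriptor(okp, build_gaussian_pyramid(img * 0.55))
  expect_lt(max(abs(d_scale - d1)), 1e-6)
})

test_that("pre-normalization descriptor mass matches deposited gradient mass", {
  img <- blob_grid_image()
  gp <- build_gaussian_pyramid(img)
  k0 <- detect_keypoints(img)
  k0 <- k0[k0$octave == 0L, ][1, ]
  kp <- assign_orientations(k0, gp)[1, ]
  raw <- compute_descriptor(kp, gp, raw = TRUE)
  expect_length(raw, 128L)
  # independent accounting: weighted magnitude of each sample, times its
  # spatial trilinear coverage of the 4x4 grid (orientation bins always
  # conserve mass by circular wrap)
  oc <- list(x = kp$x, y = kp$y, sigma = kp$sigma)  # octave 0 keypoint
  local_sigmas <- gp$config$base_sigma * gp$config$k^(0:5)
  glevel <- which.min(abs(local_sigmas - oc$sigma))
  gf <- compute_gradients(gp$octaves[[1]][[glevel]])
  offs <- (1:16 - 8.5) * oc$sigma
  u <- rep(offs, times = 16); v <- rep(offs, each = 16)
  ct <- cos(kp$orientation); st <- sin(kp$orientation)
  sx <- oc$x + ct * u - st * v
  sy <- oc$y + st * u + ct * v
  cover1d <- function(cc) {
    c0 <- floor(cc); f <- cc - c0
    (if (c0 >= 0 && c0 < 4) 1 - f else 0) +
      (if (c0 + 1 >= 0 && c0 + 1 < 4) f else 0)
  }
  cu <- u / (4 * oc$sigma) + 1.5
  cv <- v / (4 * oc$sigma) + 1.5
  total <- 0
  for (i in seq_along(u)) {
    # bilinear gradient sample, written out independently
    x <- sx[i]; y <- sy[i]
    if (x < 1 || x > ncol(img) || y < 1 || y > nrow(img)) next
    x0 <- min(floor(x), ncol(img) - 1); y0 <- min(floor(y), nrow(img) - 1)
    fx <- x - x0; fy <- y - y0
    gxv <- (1-fx)*(1-fy)*gf$gx[y0, x0] + fx*(1-fy)*gf$gx[y0, x0+1] +
      (1-fx)*fy*gf$gx[y0+1, x0] + fx*fy*gf$gx[y0+1, x0+1]
    gyv <- (1-fx)*(1-fy)*gf$gy[y0, x0] + fx*(1-fy)*gf$gy[y0, x0+1] +
      (1-fx)*fy*gf$gy[y0+1, x0] + fx*fy*gf$gy[y0+1, x0+1]
    m <- sqrt(gxv^2 + gyv^2)
    wgt <- exp(-(u[i]^2 + v[i]^2) / (2 * (8 * oc$sigma)^2)) * m
    total <- total + wgt * cover1d(cu[i]) * cover1d(cv[i])
  }
  expect_equal(sum(raw), total, tolerance = 1e-6)
})

test_that("descriptor survives an exact 90-degree rotation of the scene", {
  img <- make_phantom(phantom_config(height = 160, width = 160,
                                     n_vertebrae = 4, curvature_amp = 6))
  rot90 <- t(apply(img, 2, rev))              # exact rotation, no resampling
  fa <- sift_features(img)
  fb <- sift_features(rot90)
  # map a keypoint of img to rotated coordinates and find its counterpart
  n <- nrow(img)
  cosims <- c()
  for (i in seq_len(min(15, nrow(fa$keypoints)))) {
    xa <- fa$keypoints$x[i]; ya <- fa$keypoints$y[i]
    # (x, y) -> (n + 1 - y, x) under this array rotation
    xr <- n + 1 - ya; yr <- xa
    d <- sqrt((fb$keypoints$x - xr)^2 + (fb$keypoints$y - yr)^2)
    j <- which.min(d)
    if (d[j] > 1) next
    cosims <- c(cosims, sum(fa$descriptors[i, ] * fb$descriptors[j, ]))
  }
  expect_gte(length(cosims), 5)
  expect_gte(median(cosims), 0.8)
})
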