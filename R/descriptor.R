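#' Orientation / descriptor configuration
#'
#' @param hist_bins bins of the orientation histogram (10 degrees each by
#'   default).
#' @param window_radius_factor orientation window radius in multiples of the
#'   Gaussian weighting scale.
#' @param weight_sigma_factor Gaussian weighting scale in multiples of the
#'   keypoint scale.
#' @param peak_fraction secondary histogram peaks at least this fraction of
#'   the highest peak spawn additional oriented keypoints.
#' @return A list of class `orientation_config`.
#' @export
orientation_config <- function(hist_bins = 36L, window_radius_factor = 3,
                               weight_sigma_factor = 1.5,
                               peak_fraction = 0.8) {
  stopifnot(hist_bins >= 4L, peak_fraction > 0, peak_fraction <= 1)
  structure(list(hist_bins = as.integer(hist_bins),
                 window_radius_factor = window_radius_factor,
                 weight_sigma_factor = weight_sigma_factor,
                 peak_fraction = peak_fraction),
            class = "orientation_config")
}

#' Gradient magnitude and orientation of a Gaussian level
#'
#' Central differences `L(x+1, y) - L(x-1, y)` and `L(x, y+1) - L(x, y-1)`
#' (border pixels use reflected neighbors), magnitude as their Euclidean
#' norm, orientation as the two-argument arctangent mapped to `[0, 2*pi)`.
#' A zero gradient gets orientation 0 by convention.
#'
#' @param level numeric matrix (a Gaussian pyramid level), at least 3x3.
#' @return List with `magnitude`, `orientation`, and the raw difference
#'   fields `gx`, `gy` (used for interpolated descriptor sampling).
#' @export
compute_gradients <- function(level) {
  n <- nrow(level); m <- ncol(level)
  stopifnot(n >= 3L, m >= 3L)
  ixp <- reflect_index(2:(m + 1L), m); ixm <- reflect_index(0:(m - 1L), m)
  iyp <- reflect_index(2:(n + 1L), n); iym <- reflect_index(0:(n - 1L), n)
  gx <- level[, ixp, drop = FALSE] - level[, ixm, drop = FALSE]
  gy <- level[iyp, , drop = FALSE] - level[iym, , drop = FALSE]
  list(magnitude = sqrt(gx^2 + gy^2),
       orientation = atan2(gy, gx) %% (2 * pi),
       gx = gx, gy = gy)
}

# Gaussian level whose octave-local blur is nearest sigma_oct
nearest_gaussian_level <- function(gp, sigma_oct) {
  n_levels <- length(gp$octaves[[1L]])
  local_sigmas <- gp$config$base_sigma * gp$config$k^(0:(n_levels - 1L))
  which.min(abs(local_sigmas - sigma_oct))
}

gradient_cache <- function(gp) {
  env <- new.env(parent = emptyenv())
  function(octave, level) {
    key <- paste0(octave, ":", level)
    if (is.null(env[[key]]))
      env[[key]] <- compute_gradients(gp$octaves[[octave + 1L]][[level]])
    env[[key]]
  }
}

kp_octave_coords <- function(kp) {
  s <- 2^kp$octave
  list(x = (kp$x - 1) / s + 1, y = (kp$y - 1) / s + 1,
       sigma = kp$sigma / s)
}

#' Assign gradient orientations to a keypoint
#'
#' Builds a 36-bin histogram of gradient orientations from samples within a
#' window of radius `window_radius_factor` times the Gaussian weighting
#' scale (`weight_sigma_factor * sigma`) around the keypoint, each sample
#' weighted by its gradient magnitude times a Gaussian of that scale. The
#' highest histogram peak and every local peak within `peak_fraction` of it
#' yield one oriented keypoint each; peak positions are refined by parabolic
#' interpolation over the three surrounding bins.
#'
#' @param kp one-row keypoint data frame from [detect_keypoints()].
#' @param gp the Gaussian pyramid the keypoint was detected in.
#' @param config an [orientation_config()].
#' @param grad optional precomputed gradient accessor (internal).
#' @return Keypoint data frame with 0 or more rows (0 when the window falls
#'   outside the image or carries no gradient energy).
#' @export
assign_orientations <- function(kp, gp, config = orientation_config(),
                                grad = NULL) {
  oc <- kp_octave_coords(kp)
  glevel <- nearest_gaussian_level(gp, oc$sigma)
  gf <- if (is.null(grad)) compute_gradients(gp$octaves[[kp$octave + 1L]][[glevel]])
        else grad(kp$octave, glevel)
  n <- nrow(gf$magnitude); m <- ncol(gf$magnitude)
  sig_w <- config$weight_sigma_factor * oc$sigma
  r <- max(1L, as.integer(round(config$window_radius_factor * sig_w)))
  xc <- as.integer(round(oc$x)); yc <- as.integer(round(oc$y))
  xs <- max(1L, xc - r):min(m, xc + r)
  ys <- max(1L, yc - r):min(n, yc + r)
  if (length(xs) == 0L || length(ys) == 0L) return(empty_keypoints())
  dx <- outer(rep(1, length(ys)), xs - oc$x)
  dy <- outer(ys - oc$y, rep(1, length(xs)))
  w <- exp(-(dx^2 + dy^2) / (2 * sig_w^2)) * gf$magnitude[ys, xs]
  theta <- gf$orientation[ys, xs]
  nb <- config$hist_bins
  bin <- (as.integer(floor(theta / (2 * pi / nb))) %% nb) + 1L
  h <- numeric(nb)
  sums <- rowsum(as.numeric(w), bin)
  h[as.integer(rownames(sums))] <- sums
  if (max(h) <= 0) return(empty_keypoints())

  left <- h[c(nb, seq_len(nb - 1L))]
  right <- h[c(seq_len(nb)[-1L], 1L)]
  is_peak <- h > left & h >= right
  keep <- which(is_peak & h >= config$peak_fraction * max(h))
  if (length(keep) == 0L) keep <- which.max(h)
  out <- kp[rep(1L, length(keep)), ]
  bw <- 2 * pi / nb
  for (j in seq_along(keep)) {
    i <- keep[j]
    hl <- left[i]; hc <- h[i]; hr <- right[i]
    denom <- hl - 2 * hc + hr
    delta <- if (abs(denom) > 1e-12) 0.5 * (hl - hr) / denom else 0
    out$orientation[j] <- ((i - 1 + 0.5 + delta) * bw) %% (2 * pi)
  }
  rownames(out) <- NULL
  out
}

bilinear_sample <- function(mat, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- nrow(mat); m <- ncol(mat)
  inside <- x >= 1 & x <= m & y >= 1 & y <= n
  xc <- pmin(pmax(x, 1), m); yc <- pmin(pmax(y, 1), n)
  x0 <- pmin(floor(xc), m - 1L); y0 <- pmin(floor(yc), n - 1L)
  fx <- xc - x0; fy <- yc - y0
  v <- (1 - fx) * (1 - fy) * mat[cbind(y0, x0)] +
       fx * (1 - fy) * mat[cbind(y0, x0 + 1)] +
       (1 - fx) * fy * mat[cbind(y0 + 1, x0)] +
       fx * fy * mat[cbind(y0 + 1, x0 + 1)]
  v * inside
}

#' Compute the 128-element SIFT descriptor of an oriented keypoint
#'
#' Samples the gradient field of the keypoint's Gaussian level on a 16x16
#' grid spaced by the keypoint scale, rotated to the keypoint orientation.
#' Sample orientations are taken relative to the keypoint orientation and
#' magnitudes weighted by a Gaussian of half the window width (so every
#' spatial cell of the 4x4 grid carries mass); weighted magnitudes
#' are distributed trilinearly over a 4x4 grid of spatial cells times 8
#' orientation bins. The flattened 128-vector is normalized to unit length,
#' clipped at `clip` and renormalized, making it invariant to affine
#' intensity changes and robust to local gradient bursts.
#'
#' @param kp one-row oriented keypoint (finite `orientation`).
#' @param gp the Gaussian pyramid.
#' @param clip ceiling applied to normalized entries before renormalization.
#' @param grad optional precomputed gradient accessor (internal).
#' @param raw return the accumulated histogram mass before normalization
#'   and clipping (diagnostic).
#' @return Numeric vector of length 128; all zeros when the support carries
#'   no gradient energy (degenerate patch).
#' @export
compute_descriptor <- function(kp, gp, clip = 0.2, grad = NULL, raw = FALSE) {
  stopifnot(is.finite(kp$orientation))
  oc <- kp_octave_coords(kp)
  glevel <- nearest_gaussian_level(gp, oc$sigma)
  gf <- if (is.null(grad)) compute_gradients(gp$octaves[[kp$octave + 1L]][[glevel]])
        else grad(kp$octave, glevel)

  n_cells <- 4L; n_ori <- 8L; n_samp <- 16L
  step <- oc$sigma
  offs <- (seq_len(n_samp) - (n_samp + 1) / 2) * step   # -7.5s .. 7.5s
  u <- rep(offs, times = n_samp)                        # along orientation
  v <- rep(offs, each = n_samp)
  ct <- cos(kp$orientation); st <- sin(kp$orientation)
  sx <- oc$x + ct * u - st * v
  sy <- oc$y + st * u + ct * v

  gxs <- bilinear_sample(gf$gx, sx, sy)
  gys <- bilinear_sample(gf$gy, sx, sy)
  mag <- sqrt(gxs^2 + gys^2)
  ori <- (atan2(gys, gxs) - kp$orientation) %% (2 * pi)

  sig_w <- (n_samp / 2) * step          # half the descriptor window width
  w <- exp(-(u^2 + v^2) / (2 * sig_w^2)) * mag

  # continuous cell coordinates in [ -0.375, 3.375 ] and orientation bins
  cu <- u / (n_samp / n_cells * step) + (n_cells - 1) / 2
  cv <- v / (n_samp / n_cells * step) + (n_cells - 1) / 2
  ob <- ori / (2 * pi / n_ori)

  desc <- numeric(n_cells * n_cells * n_ori)
  c0 <- floor(cu); r0 <- floor(cv); o0 <- floor(ob)
  fc <- cu - c0; fr <- cv - r0; fo <- ob - o0
  for (dc in 0:1) for (dr in 0:1) for (do_ in 0:1) {
    cc <- c0 + dc; rr <- r0 + dr; oo <- (o0 + do_) %% n_ori
    wt <- w * (if (dc) fc else 1 - fc) * (if (dr) fr else 1 - fr) *
      (if (do_) fo else 1 - fo)
    ok <- cc >= 0 & cc < n_cells & rr >= 0 & rr < n_cells & wt > 0
    if (!any(ok)) next
    idx <- (rr[ok] * n_cells + cc[ok]) * n_ori + oo[ok] + 1L
    sums <- rowsum(wt[ok], idx)
    ii <- as.integer(rownames(sums))
    desc[ii] <- desc[ii] + sums
  }
  if (raw) return(desc)
  nrm <- sqrt(sum(desc^2))
  if (nrm <= 0) return(desc)
  desc <- pmin(desc / nrm, clip)
  desc / sqrt(sum(desc^2))
}

#' Detect, orient, and describe SIFT features
#'
#' Convenience pipeline combining [detect_keypoints()],
#' [assign_orientations()] and [compute_descriptor()] with shared pyramids
#' and cached gradient fields. Keypoints with degenerate (all-zero)
#' descriptors are dropped.
#'
#' @param image normalized image plane.
#' @param ss_config a [scale_space_config()].
#' @param det_config a [detection_config()].
#' @param orient_config an [orientation_config()].
#' @return List with `keypoints` (data frame, one row per oriented keypoint)
#'   and `descriptors` (matrix with one 128-element row per keypoint).
#' @export
sift_features <- function(image, ss_config = scale_space_config(),
                          det_config = detection_config(),
                          orient_config = orientation_config()) {
  gp <- build_gaussian_pyramid(image, ss_config)
  dog <- build_dog_pyramid(gp)
  kp <- detect_keypoints(image, ss_config, det_config,
                         pyramids = list(gaussian = gp, dog = dog))
  grad <- gradient_cache(gp)
  rows <- list(); descs <- list()
  for (i in seq_len(nrow(kp))) {
    oriented <- assign_orientations(kp[i, ], gp, orient_config, grad = grad)
    for (j in seq_len(nrow(oriented))) {
      d <- compute_descriptor(oriented[j, ], gp, grad = grad)
      if (sum(d) <= 0) next
      rows[[length(rows) + 1L]] <- oriented[j, ]
      descs[[length(descs) + 1L]] <- d
    }
  }
  if (length(rows) == 0L)
    return(list(keypoints = empty_keypoints(),
                descriptors = matrix(numeric(), 0L, 128L)))
  out_kp <- do.call(rbind, rows)
  rownames(out_kp) <- NULL
  list(keypoints = out_kp, descriptors = do.call(rbind, descs))
}
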