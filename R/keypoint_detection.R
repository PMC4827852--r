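#' Keypoint detection configuration
#'
#' @param contrast_threshold minimum absolute interpolated DoG value for a
#'   keypoint on a `[0, 1]`-normalized image. The default 0.03 discards
#'   low-contrast extrema.
#' @param edge_gamma maximum allowed ratio of principal curvatures; a
#'   candidate is kept only if `Tr(H)^2 / Det(H) <= (gamma + 1)^2 / gamma`
#'   for the 2-D spatial Hessian `H` of the DoG level.
#' @param max_interp_steps maximum re-centering iterations during sub-pixel
#'   localization.
#' @param offset_limit per-axis offset (pixels / levels) beyond which the
#'   quadratic fit is re-centered on the nearest sample.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(contrast_threshold = 0.03, edge_gamma = 10,
                             max_interp_steps = 5L, offset_limit = 0.5) {
  stopifnot(contrast_threshold > 0, edge_gamma >= 1, max_interp_steps >= 1L)
  structure(list(contrast_threshold = contrast_threshold,
                 edge_gamma = edge_gamma,
                 max_interp_steps = as.integer(max_interp_steps),
                 offset_limit = offset_limit),
            class = "detection_config")
}

#' Find discrete DoG extrema
#'
#' Scans every interior DoG level for samples that are strictly greater or
#' strictly smaller than all 26 neighbors: 8 at the same scale plus 9 in each
#' adjacent scale. Ties are rejected, so constant regions produce no
#' candidates. Only interior levels and a 1-px interior border are scanned.
#'
#' @param dog a [build_dog_pyramid()] result with at least 3 levels per
#'   octave.
#' @return Data frame with columns `octave` (0-based), `level` (1-based DoG
#'   level index), `y`, `x` (1-based sample coordinates within the octave).
#' @export
detect_extrema <- function(dog) {
  stopifnot(inherits(dog, "dog_pyramid"))
  if (any(lengths(dog$octaves) < 3L))
    stop("extrema detection needs >= 3 DoG levels per octave")
  out <- list()
  for (o in seq_along(dog$octaves)) {
    levels <- dog$octaves[[o]]
    n <- nrow(levels[[1L]]); m <- ncol(levels[[1L]])
    if (n < 3L || m < 3L) next
    ry <- 2:(n - 1L); rx <- 2:(m - 1L)
    for (l in 2:(length(levels) - 1L)) {
      center <- levels[[l]][ry, rx, drop = FALSE]
      is_max <- matrix(TRUE, length(ry), length(rx))
      is_min <- is_max
      for (dl in -1:1) {
        lev <- levels[[l + dl]]
        for (dy in -1:1) for (dx in -1:1) {
          if (dl == 0L && dy == 0L && dx == 0L) next
          nb <- lev[ry + dy, rx + dx, drop = FALSE]
          is_max <- is_max & (center > nb)
          is_min <- is_min & (center < nb)
          if (!any(is_max) && !any(is_min)) break
        }
      }
      hit <- which(is_max | is_min, arr.ind = TRUE)
      if (nrow(hit) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          octave = o - 1L, level = l,
          y = hit[, 1L] + 1L, x = hit[, 2L] + 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(octave = integer(), level = integer(),
                      y = integer(), x = integer()))
  do.call(rbind, out)
}

dog_gradient <- function(d1, d2, d3, y, x) {
  c(gx = (d2[y, x + 1L] - d2[y, x - 1L]) / 2,
    gy = (d2[y + 1L, x] - d2[y - 1L, x]) / 2,
    gs = (d3[y, x] - d1[y, x]) / 2)
}

dog_hessian3 <- function(d1, d2, d3, y, x) {
  v <- d2[y, x]
  dxx <- d2[y, x + 1L] - 2 * v + d2[y, x - 1L]
  dyy <- d2[y + 1L, x] - 2 * v + d2[y - 1L, x]
  dss <- d3[y, x] - 2 * v + d1[y, x]
  dxy <- (d2[y + 1L, x + 1L] - d2[y + 1L, x - 1L] -
          d2[y - 1L, x + 1L] + d2[y - 1L, x - 1L]) / 4
  dxs <- (d3[y, x + 1L] - d3[y, x - 1L] -
          d1[y, x + 1L] + d1[y, x - 1L]) / 4
  dys <- (d3[y + 1L, x] - d3[y - 1L, x] -
          d1[y + 1L, x] + d1[y - 1L, x]) / 4
  matrix(c(dxx, dxy, dxs,
           dxy, dyy, dys,
           dxs, dys, dss), 3L, 3L)
}

#' Refine a candidate extremum to sub-pixel accuracy
#'
#' Fits the local 3-D quadratic model of the DoG (second-order Taylor
#' expansion in `x`, `y` and scale, with finite-difference gradient and
#' Hessian) and solves for the offset where its derivative vanishes. If any
#' offset component exceeds `offset_limit` the fit is re-centered on the
#' nearest sample, up to `max_interp_steps` times. The interpolated value
#' `D + grad' * offset / 2` must reach `contrast_threshold` in magnitude.
#'
#' @param candidate one row of [detect_extrema()] output (or a list with
#'   `octave`, `level`, `y`, `x`).
#' @param dog the DoG pyramid the candidate came from.
#' @param config a [detection_config()].
#' @return A one-row keypoint data frame (columns `x`, `y`, `sigma`,
#'   `octave`, `level`, `x_pix`, `y_pix`, `dog_value`, `orientation`), or
#'   `NULL` when the candidate is rejected (singular Hessian, runaway
#'   iteration, out of bounds, or low contrast).
#' @export
localize_keypoint <- function(candidate, dog, config = detection_config()) {
  o <- candidate$octave + 1L
  l <- as.integer(candidate$level)
  y <- as.integer(candidate$y); x <- as.integer(candidate$x)
  levels <- dog$octaves[[o]]
  n <- nrow(levels[[1L]]); m <- ncol(levels[[1L]])
  nl <- length(levels)
  off <- c(0, 0, 0)
  for (step in seq_len(config$max_interp_steps)) {
    if (l < 2L || l > nl - 1L || y < 2L || y > n - 1L ||
        x < 2L || x > m - 1L) return(NULL)
    d1 <- levels[[l - 1L]]; d2 <- levels[[l]]; d3 <- levels[[l + 1L]]
    g <- dog_gradient(d1, d2, d3, y, x)
    h <- dog_hessian3(d1, d2, d3, y, x)
    if (!is.finite(rcond(h)) || rcond(h) < 1e-10) return(NULL)
    off <- as.numeric(solve(h, -g))  # (dx, dy, ds)
    if (all(abs(off) <= config$offset_limit)) break
    x <- x + as.integer(round(off[1L]))
    y <- y + as.integer(round(off[2L]))
    l <- l + as.integer(round(off[3L]))
    if (step == config$max_interp_steps) return(NULL)
  }
  if (any(abs(off) > config$offset_limit + 0.5)) return(NULL)
  d2 <- levels[[l]]
  g <- dog_gradient(levels[[l - 1L]], d2, levels[[l + 1L]], y, x)
  dog_value <- d2[y, x] + 0.5 * sum(g * off)
  if (abs(dog_value) < config$contrast_threshold) return(NULL)
  cfg <- dog$config
  scale_mult <- 2^(candidate$octave)
  data.frame(
    x = (x + off[1L] - 1) * scale_mult + 1,
    y = (y + off[2L] - 1) * scale_mult + 1,
    sigma = cfg$base_sigma * cfg$k^(l - 1L + off[3L]) * scale_mult,
    octave = candidate$octave, level = l,
    x_pix = x, y_pix = y,
    dog_value = dog_value, orientation = NA_real_)
}

#' Edge-response test on the 2-D spatial Hessian
#'
#' Keypoints along edges have one large and one small principal curvature;
#' with eigenvalues `alpha >= beta` and `gamma = alpha / beta`, the ratio
#' `Tr(H)^2 / Det(H) = (gamma + 1)^2 / gamma` grows with the curvature
#' imbalance. A candidate is accepted iff `Det(H) > 0` and the ratio is at
#' most `(edge_gamma + 1)^2 / edge_gamma`. The ratio is invariant to
#' rescaling the DoG, so the test is contrast-free.
#'
#' @param candidate a list or row with `octave`, `level`, `y`, `x` (use
#'   `y_pix` / `x_pix` from a localized keypoint).
#' @param dog the DoG pyramid.
#' @param config a [detection_config()].
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
edge_response_ok <- function(candidate, dog, config = detection_config()) {
  o <- candidate$octave + 1L
  d2 <- dog$octaves[[o]][[as.integer(candidate$level)]]
  y <- if (!is.null(candidate$y_pix)) as.integer(candidate$y_pix)
       else as.integer(candidate$y)
  x <- if (!is.null(candidate$x_pix)) as.integer(candidate$x_pix)
       else as.integer(candidate$x)
  v <- d2[y, x]
  dxx <- d2[y, x + 1L] - 2 * v + d2[y, x - 1L]
  dyy <- d2[y + 1L, x] - 2 * v + d2[y - 1L, x]
  dxy <- (d2[y + 1L, x + 1L] - d2[y + 1L, x - 1L] -
          d2[y - 1L, x + 1L] + d2[y - 1L, x - 1L]) / 4
  tr <- dxx + dyy
  det <- dxx * dyy - dxy^2
  g <- config$edge_gamma
  det > 0 && tr^2 / det <= (g + 1)^2 / g
}

empty_keypoints <- function() {
  data.frame(x = numeric(), y = numeric(), sigma = numeric(),
             octave = integer(), level = integer(),
             x_pix = integer(), y_pix = integer(),
             dog_value = numeric(), orientation = numeric())
}

#' Detect SIFT keypoints in an image
#'
#' Full detection pipeline: Gaussian and DoG pyramids, 26-neighbor extrema
#' scan, sub-pixel localization with the contrast test, and the
#' edge-response test. Every returned keypoint passed both filters.
#'
#' @param image normalized image plane (matrix, values in `[0, 1]`).
#' @param ss_config a [scale_space_config()].
#' @param det_config a [detection_config()].
#' @param pyramids optional precomputed list with elements `gaussian` and
#'   `dog` (to share pyramids with descriptor computation).
#' @return Keypoint data frame (possibly 0-row); `orientation` is `NA` until
#'   assigned by [assign_orientations()].
#' @export
detect_keypoints <- function(image, ss_config = scale_space_config(),
                             det_config = detection_config(),
                             pyramids = NULL) {
  if (is.null(pyramids)) {
    gp <- build_gaussian_pyramid(image, ss_config)
    dog <- build_dog_pyramid(gp)
  } else {
    gp <- pyramids$gaussian; dog <- pyramids$dog
  }
  cand <- detect_extrema(dog)
  if (nrow(cand) == 0L) return(empty_keypoints())
  kps <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kp <- localize_keypoint(cand[i, ], dog, det_config)
    if (is.null(kp)) next
    if (!edge_response_ok(kp, dog, det_config)) next
    kps[[i]] <- kp
  }
  kps <- kps[!vapply(kps, is.null, logical(1L))]
  if (length(kps) == 0L) return(empty_keypoints())
  kp <- do.call(rbind, kps)
  # one keypoint per refined scale-space cell (re-centering can merge)
  key <- paste(kp$octave, kp$level, kp$y_pix, kp$x_pix)
  kp <- kp[!duplicated(key), ]
  rownames(kp) <- NULL
  kp
}
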