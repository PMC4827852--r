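#' Scale-space configuration
#'
#' Parameters of the Gaussian scale space. The scale family is
#' `sigma(o, i) = base_sigma * k^i * 2^o` with `k = 2^(1/scales_per_octave)`;
#' each octave holds `scales_per_octave + 3` Gaussian levels so that every
#' difference-of-Gaussians (DoG) level used for extrema detection has both
#' scale neighbors.
#'
#' @param base_sigma blur of the first pyramid level, in pixels.
#' @param scales_per_octave number of DoG levels probed per octave doubling.
#' @param n_octaves number of octaves, or `NULL` to take as many as keep the
#'   smallest octave at least 16 px per axis.
#' @param assumed_blur blur already present in the input image, in pixels.
#' @return A list of class `scale_space_config`.
#' @export
scale_space_config <- function(base_sigma = 1.6, scales_per_octave = 3L,
                               n_octaves = NULL, assumed_blur = 0.5) {
  stopifnot(base_sigma > 0, scales_per_octave >= 1L,
            is.null(n_octaves) || n_octaves >= 1L,
            assumed_blur >= 0, assumed_blur < base_sigma)
  structure(list(base_sigma = base_sigma,
                 scales_per_octave = as.integer(scales_per_octave),
                 k = 2^(1 / scales_per_octave),
                 n_octaves = n_octaves,
                 assumed_blur = assumed_blur),
            class = "scale_space_config")
}

#' Sampled 1-D Gaussian kernel
#'
#' Truncated at 5 standard deviations (truncation mass below 6e-7, so the
#' Gaussian semigroup property holds to 1e-6 per pixel) and renormalized to
#' unit sum so convolution preserves constants.
#'
#' @param sigma standard deviation in pixels.
#' @return Numeric vector of odd length `2*ceiling(5*sigma) + 1`.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(5 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# half-sample symmetric fold of arbitrary indices into 1..n (pattern
# cba|abc|cba); preserves the image sum under a normalized kernel
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

convolve_axis <- function(x, kern, margin) {
  r <- (length(kern) - 1L) %/% 2L
  n <- dim(x)[margin]
  idx <- reflect_index((1L - r):(n + r), n)
  p <- if (margin == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
  out <- 0
  for (j in seq_along(kern)) {
    sl <- (j - 1L) + seq_len(n)
    out <- out + kern[j] *
      (if (margin == 1L) p[sl, , drop = FALSE] else p[, sl, drop = FALSE])
  }
  out
}

#' Gaussian-blur an image plane
#'
#' Separable convolution with a truncated, normalized Gaussian; boundaries
#' are handled by half-sample symmetric reflection, which preserves both
#' constants and the image mean.
#'
#' @param x numeric matrix.
#' @param sigma blur standard deviation in pixels; `sigma <= 0` returns `x`.
#' @return Blurred matrix of the same dimensions.
#' @export
blur_plane <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  convolve_axis(convolve_axis(x, k, 1L), k, 2L)
}

downsample2 <- function(x) {
  x[seq(1L, nrow(x), by = 2L), seq(1L, ncol(x), by = 2L), drop = FALSE]
}

#' Build the Gaussian scale-space pyramid
#'
#' Level `(o, i)` carries absolute blur `base_sigma * k^i * 2^o`. Blurs are
#' applied incrementally (`sigma_inc = sqrt(target^2 - current^2)`) so the
#' composed blur follows the absolute schedule; each octave after the first
#' starts from the level with doubled blur, downsampled by 2 per axis.
#' Octaves that would fall below 16 px in either axis are omitted.
#'
#' @param image normalized image plane (matrix).
#' @param config a [scale_space_config()].
#' @return Object of class `gaussian_pyramid`: `octaves` (list of lists of
#'   matrices) and `level_sigmas` (absolute blur per level).
#' @export
build_gaussian_pyramid <- function(image, config = scale_space_config()) {
  image <- as_image_plane(image)
  if (min(dim(image)) < 16L) stop("image must be at least 16 px per axis")
  s <- config$scales_per_octave
  k <- config$k
  n_levels <- s + 3L
  max_oct <- max(1L, floor(log2(min(dim(image)) / 16)) + 1L)
  n_oct <- if (is.null(config$n_octaves)) max_oct
           else min(config$n_octaves, max_oct)

  octaves <- vector("list", n_oct)
  level_sigmas <- vector("list", n_oct)
  base <- blur_plane(image, sqrt(config$base_sigma^2 - config$assumed_blur^2))
  for (o in seq_len(n_oct) - 1L) {
    levels <- vector("list", n_levels)
    levels[[1L]] <- base
    # octave-local sigma of level i is base_sigma * k^i
    for (i in seq_len(n_levels - 1L)) {
      sig_inc <- config$base_sigma * sqrt(k^(2 * i) - k^(2 * (i - 1)))
      levels[[i + 1L]] <- blur_plane(levels[[i]], sig_inc)
    }
    octaves[[o + 1L]] <- levels
    level_sigmas[[o + 1L]] <- config$base_sigma * k^(0:(n_levels - 1L)) * 2^o
    base <- downsample2(levels[[s + 1L]])  # octave-local sigma 2*base_sigma
  }
  structure(list(octaves = octaves, level_sigmas = level_sigmas,
                 config = config),
            class = "gaussian_pyramid")
}

#' @export
print.gaussian_pyramid <- function(x, ...) {
  cat(sprintf("<gaussian_pyramid> %d octave(s), %d level(s) each\n",
              length(x$octaves), length(x$octaves[[1L]])))
  invisible(x)
}

#' Build the difference-of-Gaussians pyramid
#'
#' Each DoG level is the element-wise difference of adjacent Gaussian levels,
#' `D(x, y, sigma) = L(x, y, k * sigma) - L(x, y, sigma)`; its nominal scale
#' is the blur of the lower level.
#'
#' @param gp a [build_gaussian_pyramid()] result.
#' @return Object of class `dog_pyramid` with one fewer level per octave.
#' @export
build_dog_pyramid <- function(gp) {
  stopifnot(inherits(gp, "gaussian_pyramid"))
  if (any(lengths(gp$octaves) < 2L)) stop("each octave needs >= 2 levels")
  octaves <- lapply(gp$octaves, function(levels) {
    lapply(seq_len(length(levels) - 1L),
           function(i) levels[[i + 1L]] - levels[[i]])
  })
  level_sigmas <- lapply(gp$level_sigmas, function(s) s[-length(s)])
  structure(list(octaves = octaves, level_sigmas = level_sigmas,
                 config = gp$config),
            class = "dog_pyramid")
}
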