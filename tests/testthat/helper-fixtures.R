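# Fixtures built in code; no binary files.

# image with isotropic Gaussian blobs at given centers (x, y)
blob_image <- function(height, width, centers, blob_sigma = 3,
                       amp = 0.7, bg = 0.1) {
  img <- matrix(bg, height, width)
  xg <- matrix(seq_len(width), height, width, byrow = TRUE)
  yg <- matrix(seq_len(height), height, width)
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-((xg - centers[i, 1])^2 + (yg - centers[i, 2])^2) /
                             (2 * blob_sigma^2))
  }
  pmin(img, 1)
}

# regular 3x3 grid of well-separated blobs
blob_grid_image <- function(size = 128, spacing = 40, blob_sigma = 3) {
  pos <- seq(size / 2 - spacing, size / 2 + spacing, by = spacing)
  centers <- as.matrix(expand.grid(x = pos, y = pos))
  blob_image(size, size, centers, blob_sigma = blob_sigma)
}

# hand-built DoG pyramid object from a list of equally sized level matrices
fake_dog_pyramid <- function(levels, base_sigma = 1.6, s = 3) {
  cfg <- scale_space_config(base_sigma = base_sigma, scales_per_octave = s)
  structure(list(octaves = list(levels),
                 level_sigmas = list(base_sigma * cfg$k^(seq_along(levels) - 1)),
                 config = cfg),
            class = "dog_pyramid")
}

# separable quadratic DoG patch peaking at offset (ox, oy, os) from the
# central sample, with peak value `peak`
quadratic_dog_levels <- function(n = 9, n_levels = 3, ox = 0, oy = 0, os = 0,
                                 peak = 0.1, curv = c(0.01, 0.01, 0.01)) {
  ctr <- (n + 1) / 2
  lvl_ctr <- (n_levels + 1) / 2
  lapply(seq_len(n_levels), function(l) {
    m <- matrix(0, n, n)
    for (y in seq_len(n)) for (x in seq_len(n)) {
      m[y, x] <- peak - curv[1] * (x - ctr - ox)^2 -
        curv[2] * (y - ctr - oy)^2 - curv[3] * (l - lvl_ctr - os)^2
    }
    m
  })
}

# 3x3 spatial patch embedded in a flat 3-level pyramid, with prescribed
# second derivatives Dxx, Dyy, Dxy at the center of the middle level
curvature_patch_levels <- function(dxx, dyy, dxy, n = 5) {
  ctr <- (n + 1) / 2
  m <- matrix(0, n, n)
  for (y in seq_len(n)) for (x in seq_len(n)) {
    u <- x - ctr; v <- y - ctr
    m[y, x] <- 0.5 * dxx * u^2 + 0.5 * dyy * v^2 + dxy * u * v
  }
  list(matrix(0, n, n), m, matrix(0, n, n))
}

# exhaustive 26-neighbor brute-force extrema scan (independent oracle)
brute_force_extrema <- function(dog) {
  out <- list()
  for (o in seq_along(dog$octaves)) {
    levels <- dog$octaves[[o]]
    n <- nrow(levels[[1]]); m <- ncol(levels[[1]])
    for (l in 2:(length(levels) - 1)) {
      for (y in 2:(n - 1)) for (x in 2:(m - 1)) {
        v <- levels[[l]][y, x]
        nb <- numeric(0)
        for (dl in -1:1) for (dy in -1:1) for (dx in -1:1) {
          if (dl == 0 && dy == 0 && dx == 0) next
          nb <- c(nb, levels[[l + dl]][y + dy, x + dx])
        }
        if (all(v > nb) || all(v < nb))
          out[[length(out) + 1]] <- data.frame(octave = as.integer(o - 1),
                                               level = as.integer(l),
                                               y = as.integer(y),
                                               x = as.integer(x))
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(octave = integer(), level = integer(),
                      y = integer(), x = integer()))
  do.call(rbind, out)
}

# small smooth random test image (seeded), values in [0, 1]
smooth_random_image <- function(n, seed, blur = 2) {
  img <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  img <- blur_plane(img, blur)
  normalize_intensity(img)
}

# crop-shift: the phantom viewed through a window moved by (dx, dy);
# exact integer translation with identical content in the common region
shifted_crop <- function(img, dx, dy, margin) {
  n <- nrow(img); m <- ncol(img)
  img[(1 + margin + dy):(n - margin + dy),
      (1 + margin + dx):(m - margin + dx)]
}

# masked NMSE of a stitched sequence's central-slice canvas vs the phantom
sequence_canvas_nmse <- function(res, phantom, slice = 1) {
  canvas <- res$slices[[slice]]$canvas
  cov <- res$slices[[slice]]$coverage
  t1 <- res$segment_transforms[[1]]
  rows <- seq_len(nrow(phantom)) + round(t1$dy)
  cols <- seq_len(ncol(phantom)) + round(t1$dx)
  ok_r <- rows >= 1 & rows <= nrow(canvas)
  ok_c <- cols >= 1 & cols <= ncol(canvas)
  nmse(phantom[ok_r, ok_c], canvas[rows[ok_r], cols[ok_c]],
       mask = cov[rows[ok_r], cols[ok_c]])
}
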