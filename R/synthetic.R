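#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards, so generators are pure functions of their configs.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Spine phantom configuration
#'
#' Geometry and contrast of the synthetic sagittal spine phantom: a curved
#' column of bright vertebral bodies separated by darker intervertebral
#' discs, a spinal-cord band behind the column, over dark background.
#' Intensities are in normalized `[0, 1]` units.
#'
#' @param height,width phantom size in pixels (`height >= 128`).
#' @param n_vertebrae number of vertebral bodies along the column.
#' @param vertebra_intensity,disc_intensity,cord_intensity,background
#'   structure intensities in `[0, 1]`.
#' @param curvature_amp lateral sinusoidal curvature of the column, pixels.
#' @param texture_sd SD of intra-structure intensity jitter (0 for
#'   piecewise-constant structures).
#' @param tissue_amp amplitude (SD) of the smooth two-scale soft-tissue
#'   intensity field overlaid on the whole image; set 0 for bare geometry.
#' @param seed integer RNG seed.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(height = 700L, width = 256L, n_vertebrae = 12L,
                           vertebra_intensity = 0.85, disc_intensity = 0.35,
                           cord_intensity = 0.40, background = 0.30,
                           curvature_amp = 10, texture_sd = 0.02,
                           tissue_amp = 0.18, seed = 1L) {
  ints <- c(vertebra_intensity, disc_intensity, cord_intensity, background)
  stopifnot(height >= 128L, width >= 32L, n_vertebrae >= 1L,
            all(ints >= 0 & ints <= 1), texture_sd >= 0, tissue_amp >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_vertebrae = as.integer(n_vertebrae),
                 vertebra_intensity = vertebra_intensity,
                 disc_intensity = disc_intensity,
                 cord_intensity = cord_intensity, background = background,
                 curvature_amp = curvature_amp, texture_sd = texture_sd,
                 tissue_amp = tissue_amp, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic spine phantom
#'
#' Deterministic given the config seed. Vertebral bodies alternate with
#' disc gaps along a sinusoidally curved midline; the cord band runs the
#' full column length. Every structure edge and corner supplies gradient
#' features for keypoint detection.
#'
#' @param config a [phantom_config()].
#' @param n_slices number of slices; above 1, each slice adds independent
#'   seeded intensity jitter of SD `slice_jitter_sd`, emulating
#'   co-registered multi-slice acquisition.
#' @param slice_jitter_sd per-slice additive noise SD.
#' @return A single image plane (matrix) when `n_slices = 1`, otherwise a
#'   [slice_stack()].
#' @export
make_phantom <- function(config = phantom_config(), n_slices = 1L,
                         slice_jitter_sd = 0) {
  h <- config$height; w <- config$width
  nv <- config$n_vertebrae
  ys <- seq_len(h)
  x_mid <- w / 2 + config$curvature_amp * sin(2 * pi * ys / h)
  cord_gap <- max(3L, round(w * 0.02))
  cord_width <- max(4L, round(w * 0.035))

  # vertebral bodies grow craniocaudally (cervical small, lumbar large),
  # which also keeps the column aperiodic for feature matching
  top <- round(0.04 * h); bottom <- h - round(0.04 * h)
  span <- bottom - top + 1L
  grow <- seq(0.65, 1.35, length.out = nv)
  edges <- top + round(span * c(0, cumsum(grow)) / sum(grow))
  vert_frac <- 0.72                       # rest of each block is disc gap
  body_id <- integer(h)                   # 0 = not a vertebral body row
  row_in_column <- logical(h)
  for (i in seq_len(nv)) {
    b0 <- edges[i]; bn <- edges[i + 1L] - 1L
    b1 <- b0 + round(vert_frac * (bn - b0 + 1L)) - 1L
    body_id[b0:b1] <- i
    row_in_column[b0:bn] <- TRUE
  }
  halfwidth_row <- round(w * (0.075 + 0.06 * (ys - top) / span))

  base <- with_seed(config$seed, {
    body_gain <- 1 + stats::runif(nv, -0.12, 0.12)   # marrow-signal spread
    img <- matrix(config$background, h, w)
    xg <- matrix(seq_len(w), h, w, byrow = TRUE)
    xm <- matrix(x_mid, h, w)
    in_column_band <- abs(xg - xm) <= matrix(halfwidth_row, h, w)
    body_rows <- matrix(body_id > 0L, h, w)
    col_rows <- matrix(row_in_column, h, w)
    img[in_column_band & col_rows & !body_rows] <- config$disc_intensity
    vert_val <- matrix(config$vertebra_intensity *
                         c(1, body_gain)[body_id + 1L], h, w)
    sel <- in_column_band & body_rows
    img[sel] <- vert_val[sel]
    cord_lo <- xm + matrix(halfwidth_row, h, w) + cord_gap
    in_cord <- xg >= cord_lo & xg < cord_lo + cord_width & col_rows
    img[in_cord] <- config$cord_intensity
    if (config$tissue_amp > 0) {
      # smooth two-scale random field emulating soft-tissue signal
      tis <- 0
      for (s in c(2, 6)) {
        t1 <- blur_plane(matrix(stats::rnorm(h * w), h, w), s)
        tis <- tis + t1 / stats::sd(t1)
      }
      img <- img + tis / stats::sd(tis) * config$tissue_amp
    }
    if (config$texture_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, sd = config$texture_sd), h, w)
    pmin(pmax(img, 0), 1)
  })
  if (n_slices == 1L) return(as_image_plane(base, source_id = "phantom"))
  planes <- with_seed(config$seed + 1L, lapply(seq_len(n_slices), function(s) {
    p <- base
    if (slice_jitter_sd > 0)
      p <- pmin(pmax(p + matrix(stats::rnorm(h * w, sd = slice_jitter_sd),
                                h, w), 0), 1)
    p
  }))
  slice_stack(planes, segment_label = "other")
}

segment_labels <- function(n) {
  base <- c("C", "T", "L")
  c(base, rep("other", max(0L, n - 3L)))[seq_len(n)]
}

#' Split a phantom into overlapping segments with known ground truth
#'
#' Cuts the phantom into `n_segments` vertical (head-to-foot) bands sharing
#' exactly `overlap_px` rows between neighbors, emulating separate
#' cervical/thoracic/lumbar fields of view. Optional integer lateral jitter
#' (table shift between acquisitions), per-segment multiplicative gain
#' (coil sensitivity) and per-pixel additive Gaussian noise are applied
#' after cutting and recorded so the true inter-segment transforms remain
#' known.
#'
#' @param phantom image plane or [slice_stack()].
#' @param n_segments number of segments (>= 2).
#' @param overlap_px shared rows between neighbors (>= 1).
#' @param jitter_px maximum absolute lateral integer jitter per segment.
#' @param gains per-segment gain factors (scalar recycled).
#' @param noise_sd additive Gaussian noise SD (per pixel, per slice).
#' @param seed integer RNG seed for jitter and noise.
#' @return List of class `segment_set`: `segments` (list of
#'   [slice_stack()]s), `true_offsets` (data frame of per-adjacent-pair
#'   `(dx, dy)` mapping segment i+1 coordinates into segment i's frame),
#'   `row_starts`, `jitter`, `overlap_px`, `gains`, `noise_sd`, `seed`.
#' @export
split_overlapping <- function(phantom, n_segments = 3L, overlap_px = 56L,
                              jitter_px = 0L, gains = 1, noise_sd = 0,
                              seed = 1L) {
  if (!inherits(phantom, "slice_stack")) phantom <- slice_stack(phantom)
  h <- nrow(phantom$planes[[1L]]); w <- ncol(phantom$planes[[1L]])
  n <- as.integer(n_segments)
  stopifnot(n >= 2L, overlap_px >= 1L, jitter_px >= 0L, noise_sd >= 0)
  gains <- rep_len(gains, n)
  seg_h_ideal <- (h + (n - 1L) * overlap_px) / n
  if (seg_h_ideal - overlap_px <= 0)
    stop("overlap too large to tile: non-positive stride between segments")
  if (seg_h_ideal < 64) stop("overlap too large to tile: segment height < 64 px")
  ends <- vapply(seq_len(n), function(i)
    round(i * seg_h_ideal - (i - 1L) * overlap_px), numeric(1L))
  starts <- c(1L, as.integer(ends[-n] - overlap_px + 1L))
  ends <- as.integer(ends)
  if (any(ends - starts + 1L < 64L)) stop("overlap too large to tile")

  margin <- as.integer(jitter_px)
  jit <- with_seed(seed, c(0L, if (n > 1L && margin > 0L)
    sample(-margin:margin, n - 1L, replace = TRUE) else rep(0L, n - 1L)))
  cols <- lapply(jit, function(j) (1L + margin + j):(w - margin + j))

  segments <- with_seed(seed + 1L, lapply(seq_len(n), function(i) {
    planes <- lapply(phantom$planes, function(p) {
      seg <- p[starts[i]:ends[i], cols[[i]], drop = FALSE] * gains[i]
      if (noise_sd > 0)
        seg <- seg + matrix(stats::rnorm(length(seg), sd = noise_sd),
                            nrow(seg), ncol(seg))
      pmin(pmax(seg, 0), 1)
    })
    slice_stack(planes, segment_label = segment_labels(n)[i])
  }))
  true_offsets <- data.frame(
    pair = paste(seq_len(n - 1L), 2:n, sep = "-"),
    dx = as.numeric(jit[-1L] - jit[-n]),
    dy = as.numeric(starts[-1L] - starts[-n]))
  structure(list(segments = segments, true_offsets = true_offsets,
                 row_starts = starts, jitter = jit,
                 overlap_px = as.integer(overlap_px), gains = gains,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 phantom_dim = c(h, w)),
            class = "segment_set")
}

#' True pairwise transforms of a segment set
#' @param segment_set a [split_overlapping()] result.
#' @return List of [spine_transform()]s, one per adjacent pair, mapping
#'   segment i+1 coordinates into segment i's frame.
#' @export
true_transforms <- function(segment_set) {
  lapply(seq_len(nrow(segment_set$true_offsets)), function(i)
    spine_transform(dx = segment_set$true_offsets$dx[i],
                    dy = segment_set$true_offsets$dy[i]))
}

#' Stitch a segment set with its known ground-truth transforms
#'
#' Bypasses matching entirely: composes the segments using the recorded
#' true offsets. With unit gains and no noise this reproduces the phantom
#' region the segments cover.
#'
#' @param segment_set a [split_overlapping()] result.
#' @param blend passed to [stitch_pair()].
#' @param slice which slice to stitch (default: central).
#' @return A [stitch_pair()]-style result for the requested slice.
#' @export
stitch_with_true_offsets <- function(segment_set, blend = "feather",
                                     slice = NULL) {
  segs <- segment_set$segments
  ci <- if (is.null(slice)) central_slice_index(length(segs[[1L]]$planes))
        else slice
  tts <- true_transforms(segment_set)
  res <- NULL
  canvas <- segs[[1L]]$planes[[ci]]
  coverage <- matrix(TRUE, nrow(canvas), ncol(canvas))
  acc <- spine_transform(0, 0)        # segment-1 frame -> current canvas
  for (j in 2:length(segs)) {
    t_into_canvas <- compose_spine_transforms(
      acc, Reduce(compose_spine_transforms, tts[seq_len(j - 1L)]))
    res <- stitch_pair(canvas, segs[[j]]$planes[[ci]], t_into_canvas, blend,
                       coverage_a = coverage)
    canvas <- res$canvas
    coverage <- res$coverage
    acc <- compose_spine_transforms(res$transforms$a, acc)
  }
  res
}

#' Pairwise translations implied by a stitched sequence
#'
#' Converts the per-segment canvas transforms of [stitch_sequence()] into
#' relative translations between adjacent segments, directly comparable to
#' the `true_offsets` of [split_overlapping()].
#'
#' @param seq_result a [stitch_sequence()] result.
#' @return Data frame with `dx`, `dy` per adjacent pair.
#' @export
recovered_offsets <- function(seq_result) {
  st <- seq_result$segment_transforms
  n <- length(st)
  if (n < 2L) return(data.frame(dx = numeric(), dy = numeric()))
  do.call(rbind, lapply(2:n, function(j) {
    rel <- compose_spine_transforms(invert_spine_transform(st[[j - 1L]]),
                                    st[[j]])
    data.frame(dx = rel$dx, dy = rel$dy)
  }))
}
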