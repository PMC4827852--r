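#' Corresponding point pairs between two images
#'
#' Holds matched coordinates driving transform estimation: manual picks
#' (mPTP) or automatic SIFT matches (aPTP).
#'
#' @param points_a,points_b data frames with columns `x`, `y` (pixel
#'   coordinates in each image), equal row counts, at least 1 row.
#' @param source `"manual"` or `"automatic"`.
#' @return An object of class `point_pair_set`.
#' @export
point_pair_set <- function(points_a, points_b,
                           source = c("manual", "automatic")) {
  source <- match.arg(source)
  points_a <- as.data.frame(points_a); points_b <- as.data.frame(points_b)
  stopifnot(all(c("x", "y") %in% names(points_a)),
            all(c("x", "y") %in% names(points_b)))
  if (nrow(points_a) != nrow(points_b) || nrow(points_a) < 1L)
    stop("point sets must have equal length >= 1")
  structure(list(points_a = points_a, points_b = points_b, source = source),
            class = "point_pair_set")
}

#' Geometric transform between segment coordinate frames
#'
#' Maps coordinates of a moving image into a reference frame:
#' `p_ref = scale * R(rotation) * p_mov + (dx, dy)`. The translation model
#' fixes `rotation = 0`, `scale = 1`.
#'
#' @param dx,dy translation in pixels.
#' @param rotation rotation in radians (similarity model only).
#' @param scale isotropic scale factor, `> 0`.
#' @param model `"translation"` or `"similarity"`.
#' @return An object of class `spine_transform`.
#' @export
spine_transform <- function(dx = 0, dy = 0, rotation = 0, scale = 1,
                            model = c("translation", "similarity")) {
  model <- match.arg(model)
  stopifnot(scale > 0, is.finite(dx), is.finite(dy))
  if (model == "translation" && (rotation != 0 || scale != 1))
    stop("translation model must have rotation 0 and scale 1")
  structure(list(dx = unname(dx), dy = unname(dy),
                 rotation = unname(rotation), scale = unname(scale),
                 model = model),
            class = "spine_transform")
}

#' @export
print.spine_transform <- function(x, ...) {
  cat(sprintf("<spine_transform %s> dx=%.3f dy=%.3f rot=%.4f scale=%.4f\n",
              x$model, x$dx, x$dy, x$rotation, x$scale))
  invisible(x)
}

#' Apply a transform to coordinates
#' @param transform a [spine_transform()].
#' @param x,y coordinate vectors in the moving frame.
#' @return List with transformed `x`, `y` in the reference frame.
#' @export
apply_spine_transform <- function(transform, x, y) {
  ct <- cos(transform$rotation); st <- sin(transform$rotation)
  s <- transform$scale
  list(x = s * (ct * x - st * y) + transform$dx,
       y = s * (st * x + ct * y) + transform$dy)
}

#' Invert a transform
#' @param transform a [spine_transform()].
#' @return The inverse [spine_transform()].
#' @export
invert_spine_transform <- function(transform) {
  s <- 1 / transform$scale
  r <- -transform$rotation
  ct <- cos(r); st <- sin(r)
  spine_transform(dx = -s * (ct * transform$dx - st * transform$dy),
                  dy = -s * (st * transform$dx + ct * transform$dy),
                  rotation = if (transform$model == "translation") 0 else r,
                  scale = if (transform$model == "translation") 1 else s,
                  model = transform$model)
}

# t_after applied after t_first
compose_spine_transforms <- function(t_after, t_first) {
  p0 <- apply_spine_transform(t_after,
                              t_first$dx, t_first$dy)
  model <- if (t_after$model == "translation" &&
               t_first$model == "translation") "translation" else "similarity"
  spine_transform(dx = p0$x, dy = p0$y,
                  rotation = if (model == "translation") 0
                             else (t_after$rotation + t_first$rotation),
                  scale = if (model == "translation") 1
                          else t_after$scale * t_first$scale,
                  model = model)
}

#' Estimate the inter-segment transform from point pairs
#'
#' Translation: component-wise median of the displacement vectors
#' `points_a - points_b`, robust to isolated mismatches. Similarity:
#' least-squares rigid-plus-scale (Procrustes) fit via the SVD of the
#' demeaned cross-covariance.
#'
#' @param pairs a [point_pair_set()].
#' @param model `"translation"` (>= 1 pair) or `"similarity"` (>= 2 pairs).
#' @return A [spine_transform()] mapping image-b coordinates into image-a's
#'   frame, with per-pair fit `residuals` attached as an attribute.
#' @export
estimate_transform <- function(pairs,
                               model = c("translation", "similarity")) {
  model <- match.arg(model)
  a <- pairs$points_a; b <- pairs$points_b
  n <- nrow(a)
  if (model == "translation") {
    tr <- spine_transform(dx = stats::median(a$x - b$x),
                          dy = stats::median(a$y - b$y),
                          model = "translation")
  } else {
    if (n < 2L) stop("similarity model needs at least 2 point pairs")
    ca <- colMeans(a[c("x", "y")]); cb <- colMeans(b[c("x", "y")])
    ad <- sweep(as.matrix(a[c("x", "y")]), 2L, ca)
    bd <- sweep(as.matrix(b[c("x", "y")]), 2L, cb)
    h <- crossprod(bd, ad)                        # 2x2 cross-covariance
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot_mat <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    s <- sum(diag(diag(c(1, d)) %*% diag(sv$d))) / sum(bd^2)
    if (!is.finite(s) || s <= 0) stop("degenerate point configuration")
    rot <- atan2(rot_mat[2L, 1L], rot_mat[1L, 1L])
    t_vec <- ca - s * as.numeric(rot_mat %*% cb)
    tr <- spine_transform(dx = t_vec[1L], dy = t_vec[2L], rotation = rot,
                          scale = s, model = "similarity")
  }
  fit <- apply_spine_transform(tr, b$x, b$y)
  attr(tr, "residuals") <- sqrt((fit$x - a$x)^2 + (fit$y - a$y)^2)
  tr
}

feather_profile <- function(coord, size) {
  pmax(pmin(coord, size + 1 - coord), 0)
}

#' Stitch two image planes with a known transform
#'
#' Renders both images onto the bounding-box canvas of image a and the
#' transformed image b (background 0). Non-overlap pixels are copied;
#' overlap pixels are combined per `blend`: `"feather"` weights each source
#' by its distance to the segment edge (weights normalized to sum 1),
#' `"average"` uses equal weights, `"overwrite"` lets image b win. Image b
#' is resampled bilinearly, so integer translations are exact.
#'
#' @param img_a reference image plane.
#' @param img_b moving image plane.
#' @param transform a [spine_transform()] mapping b coordinates into a's
#'   frame.
#' @param blend `"feather"`, `"average"`, or `"overwrite"`.
#' @param coverage_a optional logical matrix marking which pixels of
#'   `img_a` hold valid data (when `img_a` is itself a stitched mosaic,
#'   its canvas padding must not blend into the new overlap); `NULL`
#'   treats all of `img_a` as valid.
#' @return Object of class `stitch_result`: `canvas` (matrix), `transforms`
#'   (per-input [spine_transform()] into canvas coordinates), `coverage`
#'   (logical matrix, `TRUE` where at least one segment contributes --
#'   the valid-data mask for agreement statistics), `overlap_mask`
#'   (`TRUE` where both contribute), and `weights` (the two normalized
#'   weight maps).
#' @export
stitch_pair <- function(img_a, img_b, transform,
                        blend = c("feather", "average", "overwrite"),
                        coverage_a = NULL) {
  blend <- match.arg(blend)
  if (!all(is.finite(unlist(transform[c("dx", "dy", "rotation", "scale")]))))
    stop("degenerate (non-finite) transform")
  na <- nrow(img_a); ma <- ncol(img_a)
  nb <- nrow(img_b); mb <- ncol(img_b)
  corners <- apply_spine_transform(transform,
                                   c(1, mb, 1, mb), c(1, 1, nb, nb))
  x0 <- floor(min(1, corners$x)); x1 <- ceiling(max(ma, corners$x))
  y0 <- floor(min(1, corners$y)); y1 <- ceiling(max(na, corners$y))
  w_can <- x1 - x0 + 1L; h_can <- y1 - y0 + 1L

  # image a: integer placement at canvas offset (1 - x0, 1 - y0)
  va <- matrix(0, h_can, w_can); wa <- va
  rows_a <- (1 - y0 + 1):(na - y0 + 1)
  cols_a <- (1 - x0 + 1):(ma - x0 + 1)
  va[rows_a, cols_a] <- img_a
  wa_src <- if (blend == "feather")
    outer(feather_profile(seq_len(na), na), feather_profile(seq_len(ma), ma),
          pmin) else matrix(1, na, ma)
  if (!is.null(coverage_a)) wa_src <- wa_src * coverage_a
  wa[rows_a, cols_a] <- wa_src

  # image b: inverse-map every canvas pixel and sample bilinearly
  ax <- matrix(x0:x1, h_can, w_can, byrow = TRUE)
  ay <- matrix(y0:y1, h_can, w_can)
  inv <- invert_spine_transform(transform)
  bcoord <- apply_spine_transform(inv, ax, ay)
  bx <- bcoord$x; by <- bcoord$y
  valid_b <- bx >= 1 & bx <= mb & by >= 1 & by <= nb
  vb <- matrix(bilinear_sample(img_b, bx, by), h_can, w_can)
  wb <- if (blend == "feather")
    matrix(pmin(feather_profile(bx, mb), feather_profile(by, nb)),
           h_can, w_can) * valid_b
  else matrix(as.numeric(valid_b), h_can, w_can)

  present_a <- wa > 0
  if (blend == "overwrite") wa[valid_b] <- 0
  tot <- wa + wb
  canvas <- ifelse(tot > 0, (wa * va + wb * vb) / pmax(tot, .Machine$double.eps), 0)

  offset_t <- spine_transform(dx = 1 - x0, dy = 1 - y0)
  structure(list(
    canvas = canvas,
    transforms = list(a = offset_t,
                      b = compose_spine_transforms(offset_t, transform)),
    coverage = present_a | (wb > 0),
    overlap_mask = present_a & valid_b,
    weights = list(a = ifelse(tot > 0, wa / pmax(tot, .Machine$double.eps), 0),
                   b = ifelse(tot > 0, wb / pmax(tot, .Machine$double.eps), 0))),
    class = "stitch_result")
}

#' Index of the central slice
#'
#' For `n` slices (1-based), the lower middle: `floor((n - 1) / 2) + 1`, so
#' 6-slice stacks use slice 3 and 5-slice stacks the exact middle.
#'
#' @param n_slices number of slices.
#' @return Integer slice index.
#' @export
central_slice_index <- function(n_slices) {
  stopifnot(n_slices >= 1L)
  as.integer(floor((n_slices - 1) / 2) + 1L)
}

as_stack_list <- function(segments) {
  lapply(segments, function(s) if (inherits(s, "slice_stack")) s
                               else slice_stack(s))
}

#' Stitch an ordered sequence of spine segments
#'
#' Sequential accumulation mirroring cervical-thoracic-lumbar acquisition:
#' the first two segments are stitched, then each further segment is
#' stitched onto the growing mosaic. Correspondences per adjacent pair come
#' either from SIFT matching (aPTP, `mode = "aptp"`) or from supplied point
#' pairs (mPTP). For multi-slice stacks the transform is estimated on the
#' central slice only and applied unchanged to every slice.
#'
#' @param segments ordered list of [slice_stack()]s (or matrices); all
#'   stacks must share the slice count.
#' @param mode `"aptp"` (automatic) or `"mptp"` (manual).
#' @param pairs_list for mPTP, a list with one [point_pair_set()] per
#'   adjacent pair (pair i maps segment i+1 onto the mosaic-so-far, in the
#'   mosaic's canvas coordinates).
#' @param model,blend passed to [estimate_transform()] / [stitch_pair()].
#' @param match_cfg a [match_config()]; aPTP fails a pair when fewer than
#'   `min_matches` correspondences survive filtering.
#' @param ss_config,det_config,orient_config SIFT settings for aPTP.
#' @return List of class `stitch_sequence_result`: `slices` (one
#'   [stitch_pair()] result per slice), `segment_transforms` (per input
#'   segment into the final canvas), `pair_transforms` (per adjacent pair,
#'   in the mosaic frame at estimation time), and `central_index`.
#' @export
stitch_sequence <- function(segments, mode = c("aptp", "mptp"),
                            pairs_list = NULL,
                            model = "translation", blend = "feather",
                            match_cfg = match_config(),
                            ss_config = scale_space_config(),
                            det_config = detection_config(),
                            orient_config = orientation_config()) {
  mode <- match.arg(mode)
  segments <- as_stack_list(segments)
  if (length(segments) < 1L) stop("need at least one segment")
  n_slices <- vapply(segments, function(s) length(s$planes), integer(1L))
  if (length(unique(n_slices)) != 1L)
    stop("mismatched slice counts across segments: ",
         paste(n_slices, collapse = ", "))
  ci <- central_slice_index(n_slices[1L])

  canvases <- segments[[1L]]$planes
  coverages <- lapply(canvases, function(p) matrix(TRUE, nrow(p), ncol(p)))
  seg_transforms <- list(spine_transform(0, 0))
  pair_transforms <- list()
  if (length(segments) == 1L) {
    slices <- lapply(canvases, function(p)
      structure(list(canvas = p,
                     transforms = list(a = spine_transform(0, 0)),
                     coverage = matrix(TRUE, nrow(p), ncol(p)),
                     overlap_mask = matrix(FALSE, nrow(p), ncol(p)),
                     weights = NULL), class = "stitch_result"))
    return(structure(list(slices = slices,
                          segment_transforms = seg_transforms,
                          pair_transforms = pair_transforms,
                          central_index = ci),
                     class = "stitch_sequence_result"))
  }

  if (mode == "mptp" &&
      (is.null(pairs_list) || length(pairs_list) < length(segments) - 1L))
    stop("mPTP mode needs one point-pair set per adjacent segment pair")

  slices <- NULL
  for (j in 2:length(segments)) {
    ref_central <- canvases[[ci]]
    tgt_central <- segments[[j]]$planes[[ci]]
    pair_name <- sprintf("pair %d-%d", j - 1L, j)
    if (mode == "aptp") {
      mm <- match_images(ref_central, tgt_central, config = match_cfg,
                         ss_config = ss_config, det_config = det_config,
                         orient_config = orient_config)
      if (is.null(mm$pairs) || !isTRUE(attr(mm$matches, "enough")))
        stop(sprintf("%s: %d matches < min_matches %d", pair_name,
                     nrow(mm$matches), match_cfg$min_matches))
      pairs <- mm$pairs
    } else {
      pairs <- pairs_list[[j - 1L]]
    }
    tr <- estimate_transform(pairs, model = model)
    pair_transforms[[j - 1L]] <- tr

    slices <- mapply(function(canvas, plane, cov)
                       stitch_pair(canvas, plane, tr, blend, coverage_a = cov),
                     canvases, segments[[j]]$planes, coverages,
                     SIMPLIFY = FALSE)
    coverages <- lapply(slices, `[[`, "coverage")
    offset_t <- slices[[ci]]$transforms$a
    seg_transforms <- lapply(seg_transforms, function(t0)
      compose_spine_transforms(offset_t, t0))
    seg_transforms[[j]] <- slices[[ci]]$transforms$b
    canvases <- lapply(slices, `[[`, "canvas")
  }
  structure(list(slices = slices, segment_transforms = seg_transforms,
                 pair_transforms = pair_transforms, central_index = ci),
            class = "stitch_sequence_result")
}

#' Propagate a central-slice transform across two stacks
#'
#' Applies one transform -- estimated on the central slice -- unchanged to
#' every slice index of two equal-length stacks.
#'
#' @param stack_a,stack_b [slice_stack()]s with equal slice counts.
#' @param central_transform a [spine_transform()] (b into a's frame).
#' @param blend passed to [stitch_pair()].
#' @return List of [stitch_pair()] results, one per slice.
#' @export
propagate_to_slices <- function(stack_a, stack_b, central_transform,
                                blend = "feather") {
  if (length(stack_a$planes) != length(stack_b$planes))
    stop("stacks have unequal slice counts")
  mapply(function(a, b) stitch_pair(a, b, central_transform, blend),
         stack_a$planes, stack_b$planes, SIMPLIFY = FALSE)
}
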