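#' Matching configuration
#'
#' @param ratio_threshold maximum nearest / second-nearest distance ratio
#'   (Lowe's ratio test); set to 1 to disable.
#' @param mutual require the match to be each keypoint's nearest neighbor in
#'   both directions.
#' @param min_matches minimum surviving correspondences for a pair of images
#'   to be considered matched.
#' @return A list of class `match_config`.
#' @export
match_config <- function(ratio_threshold = 0.8, mutual = TRUE,
                         min_matches = 4L) {
  stopifnot(ratio_threshold > 0, ratio_threshold <= 1, min_matches >= 1L)
  structure(list(ratio_threshold = ratio_threshold, mutual = mutual,
                 min_matches = as.integer(min_matches)),
            class = "match_config")
}

#' Euclidean distance between descriptor vectors
#'
#' The matching metric: square root of the sum of squared component
#' differences, generalized from the planar two-point distance to the
#' 128-dimensional descriptor space.
#'
#' @param u,v numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("descriptor lengths differ")
  sqrt(sum((u - v)^2))
}

# exact all-pairs Euclidean distance matrix (rows of a vs rows of b)
descriptor_cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Match descriptor sets by nearest Euclidean distance
#'
#' Each keypoint in `set_a` is paired with its nearest neighbor in `set_b`
#' (exact all-pairs search; distance ties broken by the lower index in
#' `set_b`). Matches are filtered by the ratio test and, optionally, by
#' mutual nearest-neighbor consistency. Degenerate all-zero descriptors are
#' excluded up front.
#'
#' @param set_a,set_b descriptor matrices (one descriptor per row).
#' @param config a [match_config()].
#' @return Data frame with columns `idx_a`, `idx_b`, `distance`, `ratio`
#'   (ratio is `NA` when `set_b` has a single usable descriptor). Fewer than
#'   `min_matches` rows signal pair-match failure to the caller; an
#'   attribute `enough` carries that verdict.
#' @export
match_descriptors <- function(set_a, set_b, config = match_config()) {
  if (!is.matrix(set_a)) set_a <- matrix(set_a, nrow = 1L)
  if (!is.matrix(set_b)) set_b <- matrix(set_b, nrow = 1L)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L)
    stop("both descriptor sets must be nonempty")
  if (ncol(set_a) != ncol(set_b)) stop("descriptor lengths differ")
  ok_a <- which(rowSums(set_a^2) > 0)
  ok_b <- which(rowSums(set_b^2) > 0)
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      distance = numeric(), ratio = numeric())
  if (length(ok_a) == 0L || length(ok_b) == 0L)
    return(structure(empty, enough = FALSE))
  d <- descriptor_cross_distances(set_a[ok_a, , drop = FALSE],
                                  set_b[ok_b, , drop = FALSE])
  nn <- apply(d, 1L, which.min)                 # ties -> lower index
  # recompute the retained distances directly (the expansion-based matrix
  # carries ~1e-8 rounding; identical descriptors must give exactly 0)
  sa <- set_a[ok_a, , drop = FALSE]; sb <- set_b[ok_b, , drop = FALSE]
  nn_dist <- vapply(seq_len(nrow(d)), function(i)
    sqrt(sum((sa[i, ] - sb[nn[i], ])^2)), numeric(1L))
  ratio <- rep(NA_real_, nrow(d))
  if (ncol(d) >= 2L) {
    second <- vapply(seq_len(nrow(d)), function(i) min(d[i, -nn[i]]),
                     numeric(1L))
    ratio <- ifelse(second > 0, nn_dist / second,
                    ifelse(nn_dist == 0, 0, 1))
  }
  keep <- is.na(ratio) | ratio <= config$ratio_threshold
  if (config$mutual) {
    nn_back <- apply(d, 2L, which.min)
    keep <- keep & (nn_back[nn] == seq_len(nrow(d)))
  }
  res <- data.frame(idx_a = ok_a[keep], idx_b = ok_b[nn[keep]],
                    distance = nn_dist[keep], ratio = ratio[keep])
  res <- res[order(res$distance, res$idx_a), ]
  rownames(res) <- NULL
  structure(res, enough = nrow(res) >= config$min_matches)
}

#' Match two images end to end
#'
#' Runs [sift_features()] on both images and [match_descriptors()] on the
#' results, returning matched keypoint coordinates ready for transform
#' estimation.
#'
#' @param img_a,img_b normalized image planes.
#' @param config a [match_config()].
#' @param ... passed to [sift_features()].
#' @return List with `matches` (data frame), `keypoints_a`, `keypoints_b`,
#'   and `pairs` (a [point_pair_set()] of matched coordinates,
#'   `source = "automatic"`).
#' @export
match_images <- function(img_a, img_b, config = match_config(), ...) {
  fa <- sift_features(img_a, ...)
  fb <- sift_features(img_b, ...)
  if (nrow(fa$keypoints) == 0L || nrow(fb$keypoints) == 0L)
    stop("no usable keypoints in at least one image")
  m <- match_descriptors(fa$descriptors, fb$descriptors, config)
  pairs <- NULL
  if (nrow(m) > 0L)
    pairs <- point_pair_set(
      data.frame(x = fa$keypoints$x[m$idx_a], y = fa$keypoints$y[m$idx_a]),
      data.frame(x = fb$keypoints$x[m$idx_b], y = fb$keypoints$y[m$idx_b]),
      source = "automatic")
  list(matches = m, keypoints_a = fa$keypoints, keypoints_b = fb$keypoints,
       pairs = pairs)
}

#' Serialize matches to JSON
#' @param matches data frame from [match_descriptors()].
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
write_matches_json <- function(matches, path) {
  jsonlite::write_json(as.list(as.data.frame(matches)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
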