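#' Validate and coerce a 2-D grayscale image plane
#'
#' An image plane is a plain numeric matrix with rows indexed by `y` and
#' columns by `x` (1-based, pixel centers at integer coordinates). Planes
#' entering keypoint detection must be at least 16 px in each dimension and
#' normalized to `[0, 1]`.
#'
#' @param x numeric matrix (or 2-D array) of pixel intensities.
#' @param source_id optional free-text provenance, stored as an attribute.
#' @return A numeric matrix with attribute `source_id`.
#' @export
as_image_plane <- function(x, source_id = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) x <- collapse_channels(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("an image plane must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x)))
    stop("image plane contains non-finite values")
  if (!is.null(source_id)) attr(x, "source_id") <- source_id
  x
}

collapse_channels <- function(x) {
  # color -> grayscale by channel mean; alpha (4th channel) ignored
  nc <- dim(x)[3L]
  if (nc >= 3L) (x[, , 1L] + x[, , 2L] + x[, , 3L]) / 3 else x[, , 1L]
}

#' Min-max normalize intensities to [0, 1]
#'
#' A constant (zero-range) input maps to all zeros; normalizing an already
#' normalized plane is the identity.
#'
#' @param x numeric matrix or array of intensities.
#' @param lo,hi optional range to normalize against (defaults to the data
#'   range); used by [normalize_stack()] to keep slices on a shared scale.
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(x, lo = min(x), hi = max(x)) {
  if (hi - lo <= 0) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Construct a slice stack
#'
#' An ordered set of co-registered image planes covering one spine segment
#' (cervical, thoracic or lumbar). All planes must share dimensions.
#'
#' @param planes list of image planes (numeric matrices), or one matrix.
#' @param segment_label one of `"C"`, `"T"`, `"L"`, `"other"`.
#' @param slice_spacing slice spacing in mm (metadata only).
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(planes, segment_label = "other",
                        slice_spacing = NA_real_) {
  if (is.matrix(planes)) planes <- list(planes)
  if (length(planes) < 1L) stop("a slice stack needs at least one plane")
  planes <- lapply(planes, as_image_plane)
  d <- dim(planes[[1L]])
  ok <- vapply(planes, function(p) identical(dim(p), d), logical(1L))
  if (!all(ok)) stop("all planes in a stack must share dimensions")
  segment_label <- match.arg(segment_label, c("C", "T", "L", "other"))
  structure(list(planes = planes, segment_label = segment_label,
                 slice_spacing = slice_spacing),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$planes[[1L]])
  cat(sprintf("<slice_stack> segment %s: %d slice(s) of %d x %d px\n",
              x$segment_label, length(x$planes), d[1L], d[2L]))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) length(x$planes)

#' Normalize a whole stack to [0, 1] with one shared min-max
#'
#' Per-stack (not per-slice) normalization keeps slices mutually consistent,
#' which the contrast threshold of keypoint detection assumes.
#'
#' @param stack a [slice_stack()].
#' @return The stack with all planes normalized against the stack-wide range.
#' @export
normalize_stack <- function(stack) {
  lo <- min(vapply(stack$planes, min, numeric(1L)))
  hi <- max(vapply(stack$planes, max, numeric(1L)))
  stack$planes <- lapply(stack$planes, normalize_intensity, lo = lo, hi = hi)
  stack
}

stack_extensions <- c(png = "png", jpeg = "jpe?g", tiff = "tiff?")

read_plane_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png         = png::readPNG(file),
    jpg         = ,
    jpeg        = jpeg::readJPEG(file),
    tif         = ,
    tiff        = tiff::readTIFF(file),
    stop("unreadable format '", ext, "' for ", file)
  )
  as_image_plane(img, source_id = basename(file))
}

#' Read a segment stack from image files
#'
#' Reads a single PNG/JPEG/TIFF file or a directory of them (one file per
#' slice, ordered lexicographically by filename), collapses color channels,
#' and min-max normalizes intensities over the whole stack.
#'
#' @param path a file or a directory of same-size image files.
#' @param format_hint `"auto"` (by extension) or one of `"png"`, `"jpeg"`,
#'   `"tiff"`.
#' @param segment_label passed to [slice_stack()].
#' @return A [slice_stack()] with all intensities in `[0, 1]`.
#' @export
read_stack <- function(path, format_hint = c("auto", "png", "jpeg", "tiff"),
                       segment_label = "other") {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) {
    pat <- if (format_hint == "auto") paste0("\\.(", paste(stack_extensions, collapse = "|"), ")$")
           else paste0("\\.(", stack_extensions[[format_hint]], ")$")
    files <- sort(list.files(path, pattern = pat, full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no image files found under ", path)
  } else files <- path
  planes <- lapply(files, read_plane_file)
  dims <- vapply(planes, dim, integer(2L))
  if (ncol(dims) > 1L && any(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L]))
    stop("inconsistent plane dimensions within series at ", path)
  normalize_stack(slice_stack(planes, segment_label = segment_label))
}

#' Write a (stitched) stack to image files
#'
#' PNG is written at 8 bits, TIFF at 16 bits (lossless round trip within the
#' quantization step of the bit depth), JPEG is lossy. Multi-slice stacks go
#' to `slice_01.<ext>`, `slice_02.<ext>`, ... under `path` (created if
#' needed); single-plane stacks may target one file directly.
#'
#' @param stack a [slice_stack()] with values in `[0, 1]`.
#' @param path output file (single slice) or directory.
#' @param format one of `"png"`, `"jpeg"`, `"tiff"`.
#' @return Invisibly, the written file paths.
#' @export
write_stitched <- function(stack, path, format = c("png", "jpeg", "tiff")) {
  format <- match.arg(format)
  if (!inherits(stack, "slice_stack")) stack <- slice_stack(stack)
  if (length(stack$planes) == 0L) stop("empty stack")
  ext <- c(png = "png", jpeg = "jpg", tiff = "tif")[[format]]
  single_file <- length(stack$planes) == 1L && nzchar(tools::file_ext(path))
  if (single_file) {
    files <- path
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(path, sprintf("slice_%02d.%s",
                                     seq_along(stack$planes), ext))
  }
  for (i in seq_along(stack$planes)) {
    p <- pmin(pmax(stack$planes[[i]], 0), 1)
    switch(format,
      png  = png::writePNG(p, target = files[[i]]),
      jpeg = jpeg::writeJPEG(p, target = files[[i]], quality = 0.95),
      tiff = tiff::writeTIFF(p, where = files[[i]], bits.per.sample = 16L)
    )
  }
  invisible(files)
}

#' Serialize keypoints (and descriptors) to JSON
#'
#' @param keypoints keypoint data frame from [detect_keypoints()].
#' @param path output JSON file.
#' @param descriptors optional matrix of 128-element descriptor rows.
#' @return Invisibly, `path`.
#' @export
write_keypoints_json <- function(keypoints, path, descriptors = NULL) {
  rec <- as.list(keypoints)
  if (!is.null(descriptors)) {
    stopifnot(nrow(descriptors) == nrow(keypoints))
    rec$descriptor <- apply(descriptors, 1L, identity, simplify = FALSE)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read keypoints (and descriptors) from JSON
#'
#' @param path JSON file written by [write_keypoints_json()].
#' @return A list with `keypoints` (data frame) and `descriptors` (matrix or
#'   `NULL`).
#' @export
read_keypoints_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  desc <- NULL
  if (!is.null(rec$descriptor)) {
    desc <- rec$descriptor
    if (is.list(desc)) desc <- do.call(rbind, desc)
    desc <- matrix(as.numeric(t(desc)), nrow = length(rec$x), byrow = TRUE)
    rec$descriptor <- NULL
  }
  list(keypoints = as.data.frame(rec), descriptors = desc)
}

#' Read manual point pairs from JSON
#'
#' The mPTP (manual point-to-point) input: a JSON list of records with fields
#' `xa, ya, xb, yb` giving corresponding points in two images' pixel
#' coordinates.
#'
#' @param path JSON file.
#' @return A [point_pair_set()] with `source = "manual"`.
#' @export
read_point_pairs_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("xa", "ya", "xb", "yb")
  if (!all(need %in% names(rec)))
    stop("point-pair JSON must contain fields xa, ya, xb, yb")
  point_pair_set(data.frame(x = rec$xa, y = rec$ya),
                 data.frame(x = rec$xb, y = rec$yb),
                 source = "manual")
}

#' Serialize a transform to JSON
#' @param transform a [spine_transform()].
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a transform from JSON
#' @param path JSON file written by [write_transform_json()].
#' @return A [spine_transform()].
#' @export
read_transform_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  spine_transform(dx = rec$dx, dy = rec$dy, rotation = rec$rotation,
                  scale = rec$scale, model = rec$model)
}
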