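#' Normalized mean square error between two images
#'
#' `sum((ref - test)^2) / sum(ref^2)` over all (optionally masked) pixels.
#' Identical images give 0; an all-zero test image gives 1.
#'
#' @param reference,test numeric matrices (or vectors) of equal shape.
#' @param mask optional logical array restricting the comparison, e.g. to
#'   the intersection of both images' valid-data regions.
#' @return Non-negative scalar.
#' @export
nmse <- function(reference, test, mask = NULL) {
  if (!identical(dim(reference), dim(test)) ||
      length(reference) != length(test))
    stop("reference and test shapes differ")
  if (!is.null(mask)) {
    reference <- reference[mask]; test <- test[mask]
  }
  denom <- sum(reference^2)
  if (denom <= 0) stop("all-zero reference")
  sum((reference - test)^2) / denom
}

#' Pearson correlation and coefficient of determination
#'
#' Product-moment correlation of paired intensities with its two-sided
#' p-value, plus the R-squared of the least-squares line (the squared
#' correlation of the paired observations).
#'
#' @param reference,test equal-length numeric data (matrices are
#'   flattened).
#' @param mask optional logical selector.
#' @return List with `r`, `p_value`, `r_squared`, `n`.
#' @export
pearson_agreement <- function(reference, test, mask = NULL) {
  x <- as.numeric(reference); y <- as.numeric(test)
  if (length(x) != length(y)) stop("lengths differ")
  if (!is.null(mask)) { x <- x[mask]; y <- y[mask] }
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in at least one input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       r_squared = unname(ct$estimate)^2, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences `test - reference`, their mean and sample standard deviation
#' (n - 1 denominator), limits of agreement at mean +/- 1.96 SD, and the
#' fraction of differences outside the limits (about 5% for normal
#' differences).
#'
#' @param reference_values,test_values equal-length numeric vectors.
#' @return List of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `limits` (length-2), `outlier_fraction`, `n`, and the `differences` /
#'   `means` used (for plotting).
#' @export
bland_altman <- function(reference_values, test_values) {
  x <- as.numeric(reference_values); y <- as.numeric(test_values)
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 2L) stop("need at least 2 paired observations")
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  lim <- c(m - 1.96 * s, m + 1.96 * s)
  structure(list(mean_diff = m, sd_diff = s, limits = lim,
                 outlier_fraction = mean(d < lim[1L] | d > lim[2L]),
                 n = length(d), differences = d, means = (x + y) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g +/- %.4g (limits %.4g, %.4g), n = %d\n",
              x$mean_diff, x$sd_diff, x$limits[1L], x$limits[2L], x$n))
  invisible(x)
}

#' Full agreement report for a reference/test image pair
#'
#' Combines [nmse()], [pearson_agreement()] and [bland_altman()] over the
#' pixels of one image pair.
#'
#' @param reference,test numeric matrices of equal shape.
#' @param mask optional logical matrix; comparisons are restricted to
#'   `TRUE` pixels (e.g. the intersection of valid-data masks so background
#'   padding does not inflate agreement).
#' @return List of class `agreement_report` with `nmse`, `pearson_r`,
#'   `p_value`, `r_squared`, `ba_mean_diff`, `ba_sd_diff`, `ba_limits`,
#'   `outlier_fraction`, `n`.
#' @export
agreement_report <- function(reference, test, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(reference))
  nm <- nmse(reference, test, mask)
  pe <- pearson_agreement(reference, test, mask)
  ba <- bland_altman(as.numeric(reference)[mask], as.numeric(test)[mask])
  structure(list(nmse = nm, pearson_r = pe$r, p_value = pe$p_value,
                 r_squared = pe$r_squared, ba_mean_diff = ba$mean_diff,
                 ba_sd_diff = ba$sd_diff, ba_limits = ba$limits,
                 outlier_fraction = ba$outlier_fraction, n = pe$n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("Agreement (n = %d):\n",
                     "  NMSE      %.4g  (sum sq. error / sum sq. reference)\n",
                     "  Pearson r %.4f  (p = %.3g), R^2 = %.4f\n",
                     "  Bland-Altman %.4g +/- %.4g, limits (%.4g, %.4g)\n"),
              x$n, x$nmse, x$pearson_r, x$p_value, x$r_squared,
              x$ba_mean_diff, x$ba_sd_diff, x$ba_limits[1L], x$ba_limits[2L]))
  invisible(x)
}

#' Slice-wise and pooled agreement between two stacks
#'
#' Computes a pixelwise [agreement_report()] per slice plus a pooled report
#' over the per-slice mean signal intensities (one observation per slice,
#' matching slice-level summaries of whole stitched images).
#'
#' @param ref_stack,test_stack [slice_stack()]s of equal slice counts and
#'   shapes.
#' @param mask optional logical matrix applied to every slice.
#' @return List with `per_slice` (list of reports), `pooled_means`
#'   (Bland-Altman over slice means when >= 2 slices, plus Pearson when
#'   >= 3), and `slice_means` (data frame).
#' @export
compare_slicewise <- function(ref_stack, test_stack, mask = NULL) {
  if (!inherits(ref_stack, "slice_stack")) ref_stack <- slice_stack(ref_stack)
  if (!inherits(test_stack, "slice_stack")) test_stack <- slice_stack(test_stack)
  if (length(ref_stack$planes) != length(test_stack$planes))
    stop("unequal slice counts")
  per_slice <- mapply(agreement_report, ref_stack$planes, test_stack$planes,
                      MoreArgs = list(mask = mask), SIMPLIFY = FALSE)
  mean_of <- function(p) if (is.null(mask)) mean(p) else mean(p[mask])
  mr <- vapply(ref_stack$planes, mean_of, numeric(1L))
  mt <- vapply(test_stack$planes, mean_of, numeric(1L))
  pooled <- list()
  if (length(mr) >= 2L) pooled$bland_altman <- bland_altman(mr, mt)
  if (length(mr) >= 3L && stats::sd(mr) > 0 && stats::sd(mt) > 0)
    pooled$pearson <- pearson_agreement(mr, mt)
  list(per_slice = per_slice, pooled_means = pooled,
       slice_means = data.frame(slice = seq_along(mr),
                                ref_mean = mr, test_mean = mt))
}

#' Bland-Altman plot
#' @param ba a [bland_altman()] result.
#' @return A ggplot object: differences vs means, with the mean-difference
#'   line (solid) and the +/- 1.96 SD limits (dotted).
#' @export
plot_bland_altman <- function(ba) {
  df <- data.frame(pair_mean = ba$means, difference = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = pair_mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$mean_diff) +
    ggplot2::geom_hline(yintercept = ba$limits, linetype = "dotted") +
    ggplot2::labs(x = "Mean of pair", y = "Difference (test - reference)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Signal-intensity agreement scatter plot
#' @param reference,test equal-length numeric data.
#' @return A ggplot object: test vs reference intensities with the identity
#'   line and the least-squares fit.
#' @export
plot_agreement <- function(reference, test) {
  df <- data.frame(reference = as.numeric(reference),
                   test = as.numeric(test))
  ggplot2::ggplot(df, ggplot2::aes(x = reference, y = test)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.6) +
    ggplot2::labs(x = "Reference intensity", y = "Test intensity",
                  title = "Signal-intensity agreement") +
    ggplot2::theme_minimal()
}
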