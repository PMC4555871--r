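# MFI -> surface-density calibration: background-subtracted mean
# fluorescence intensity and the through-origin linear fit
# (density per counting area = slope x MFI).

#' Estimate the image background level
#'
#' Median of a user-designated empty region when given, otherwise the
#' image-wide 10th percentile.
#'
#' @param image Numeric matrix.
#' @param empty_region Optional: a logical mask into `image`, or a numeric
#'   matrix/vector of blank-field pixel values (e.g. a control frame).
#' @param probs Quantile used in the fallback (default 0.1).
#' @return Scalar background level in counts.
#' @export
estimate_background <- function(image, empty_region = NULL, probs = 0.1) {
  if (is.null(empty_region))
    return(unname(stats::quantile(as.numeric(image), probs = probs)))
  if (is.logical(empty_region)) {
    stopifnot(all(dim(empty_region) == dim(image)))
    if (!any(empty_region)) stop("empty background region", call. = FALSE)
    return(stats::median(image[empty_region]))
  }
  stats::median(as.numeric(empty_region))
}

#' Background-subtracted mean fluorescence intensity
#'
#' Mean pixel value inside the ROI minus the background estimate, clamped
#' at 0.
#'
#' @param image Numeric matrix.
#' @param roi `c(x, y, w, h)` in pixels, or `NULL` for the whole frame.
#' @param background Scalar background in counts; when `NULL` it is
#'   estimated with [estimate_background()] (image-wide 10th percentile).
#'   For dense surfaces pass a blank-field estimate instead.
#'
#' @return MFI in counts (scalar, >= 0), with the background used attached
#'   as attribute `background`.
#' @export
compute_mfi <- function(image, roi = NULL, background = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(roi)) {
    vals <- as.numeric(image)
  } else {
    roi <- roi_check(roi, image)
    vals <- as.numeric(image[roi[["y"]]:(roi[["y"]] + roi[["h"]] - 1),
                             roi[["x"]]:(roi[["x"]] + roi[["w"]] - 1)])
  }
  if (is.null(background)) background <- estimate_background(image)
  out <- max(0, mean(vals) - background)
  attr(out, "background") <- background
  out
}

#' Fit the through-origin MFI -> density calibration
#'
#' Least squares with no intercept: `slope = sum(x*y) / sum(x^2)` for
#' points (MFI, molecules per counting area). R-squared is computed
#' against the through-origin model with the total sum of squares taken
#' about zero (the convention consistent with a no-intercept fit).
#'
#' @param points Data frame with columns `mfi` and `count` (molecules per
#'   counting area); at least 3 points, MFI not all zero.
#' @param counting_area Counting area in um^2 the counts refer to
#'   (default 473.1).
#'
#' @return An object of class `density_calibration`: `slope` (molecules
#'   per counting area per MFI unit), `r_squared`, `counting_area`,
#'   `n_points`.
#' @export
fit_calibration <- function(points, counting_area = 473.1) {
  stopifnot(is.data.frame(points),
            all(c("mfi", "count") %in% names(points)))
  x <- as.numeric(points$mfi)
  y <- as.numeric(points$count)
  if (length(x) < 3L)
    stop("need at least 3 calibration points", call. = FALSE)
  if (all(x == 0))
    stop("degenerate fit: all MFI values are zero", call. = FALSE)
  if (counting_area <= 0)
    stop("`counting_area` must be positive", call. = FALSE)
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  structure(
    list(slope = slope,
         r_squared = 1 - ss_res / ss_tot,
         counting_area = counting_area,
         n_points = length(x)),
    class = "density_calibration"
  )
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf(
    "<density_calibration> density per %.1f um^2 = %.3f x MFI (R^2 = %.4f, n = %d)\n",
    x$counting_area, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert MFI to surface density
#'
#' `density = slope * MFI / counting_area`, in molecules per um^2.
#'
#' @param mfi MFI value(s) in counts, >= 0.
#' @param cal A [fit_calibration()] result.
#' @return Surface density in molecules per um^2.
#' @export
mfi_to_density <- function(mfi, cal) {
  stopifnot(inherits(cal, "density_calibration"))
  if (!is.numeric(mfi) || any(is.na(mfi)) || any(mfi < 0))
    stop("`mfi` must be non-negative", call. = FALSE)
  as.numeric(mfi) * cal$slope / cal$counting_area
}
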