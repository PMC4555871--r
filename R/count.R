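# Single-molecule counting and microcluster quantification.

roi_check <- function(roi, image) {
  roi <- as.numeric(roi)
  if (length(roi) != 4L)
    stop("`roi` must be c(x, y, w, h) in pixels", call. = FALSE)
  names(roi) <- c("x", "y", "w", "h")
  if (roi[["w"]] <= 0 || roi[["h"]] <= 0)
    stop("`roi` has zero area", call. = FALSE)
  if (roi[["x"]] < 1 || roi[["y"]] < 1 ||
      roi[["x"]] + roi[["w"]] - 1 > ncol(image) ||
      roi[["y"]] + roi[["h"]] - 1 > nrow(image))
    stop("`roi` extends beyond the image", call. = FALSE)
  roi
}

in_roi <- function(x, y, roi) {
  x >= roi[["x"]] - 0.5 & x < roi[["x"]] + roi[["w"]] - 0.5 &
    y >= roi[["y"]] - 0.5 & y < roi[["y"]] + roi[["h"]] - 0.5
}

# Fit all candidates and return one row per candidate with quality flags.
fit_candidates <- function(image, cands, params, noise_sd) {
  if (nrow(cands) == 0L) {
    out <- spot_fit_row(fit_gaussian_2d(matrix(0, 16, 16), c(8, 8), params))
    return(out[0L, ])
  }
  rows <- vector("list", nrow(cands))
  srange <- params$sigma_range * params$psf_sigma_px
  for (i in seq_len(nrow(cands))) {
    f <- fit_gaussian_2d(image, c(cands$x[i], cands$y[i]), params)
    r <- spot_fit_row(f)
    if (r$converged &&
        (r$sigma < srange[1L] || r$sigma > srange[2L] ||
         r$amplitude < params$amp_min_k * noise_sd))
      r$flag <- "quality"
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  # fits that drifted onto the same emitter (near-identical centres):
  # keep the brighter one
  ok <- which(out$flag == "ok")
  if (length(ok) > 1L) {
    ord <- ok[order(out$amplitude[ok], decreasing = TRUE)]
    kept_x <- kept_y <- numeric(0)
    for (i in ord) {
      if (length(kept_x) &&
          min((kept_x - out$x0[i])^2 + (kept_y - out$y0[i])^2) < 0.25) {
        out$flag[i] <- "duplicate"
      } else {
        kept_x <- c(kept_x, out$x0[i]); kept_y <- c(kept_y, out$y0[i])
      }
    }
  }
  out
}

# Palm-probability correction for unresolvable near-neighbours: under a
# homogeneous Poisson process at density lambda, the chance a molecule is
# the local representative within merge radius s is (1 - exp(-m)) / m with
# m = lambda * pi * s^2, so observed ~ lambda * (1 - exp(-m)) / m. Invert
# numerically for lambda.
correct_overlap_density <- function(density_obs, s_um) {
  if (density_obs <= 0 || s_um <= 0) return(density_obs)
  g <- function(lam) {
    m <- lam * pi * s_um^2
    lam * (if (m < 1e-9) 1 else (1 - exp(-m)) / m) - density_obs
  }
  stats::uniroot(g, c(density_obs * 0.999, density_obs * 20),
                 extendInt = "upX", tol = 1e-10)$root
}

#' Count single molecules in a region of interest
#'
#' Detects candidates over the full image, fits each with a 2D Gaussian,
#' applies the quality filters (convergence, sigma within
#' `sigma_range * psf_sigma_px`, amplitude above `amp_min_k` noise SDs),
#' and counts accepted fits whose centre lies in the ROI. The density
#' optionally includes a documented overlap (near-neighbour merging)
#' correction with merge radius equal to the non-maximum-suppression
#' separation.
#'
#' @param image Numeric matrix.
#' @param roi `c(x, y, w, h)` in 1-based pixels, within the image.
#' @param optics An [optics_model()] (pixel size and PSF width).
#' @param params A [detection_params()]; defaults match `optics`.
#' @param overlap_correct Apply the Palm overlap correction to the density.
#'
#' @return A list of class `spot_count`: `count` (accepted fits in the
#'   ROI), `density` (molecules/um^2, corrected when requested),
#'   `density_raw`, `area_um2`, and `spots` (per-candidate fit table with
#'   flags and an `in_roi` column).
#' @export
count_spots <- function(image, roi, optics, params = NULL,
                        overlap_correct = TRUE) {
  stopifnot(inherits(optics, "optics_model"))
  roi <- roi_check(roi, image)
  if (is.null(params)) params <- detection_params_for(optics)
  cands <- detect_candidates(image, params)
  noise_sd <- attr(cands, "noise_sd")
  spots <- fit_candidates(image, cands, params, noise_sd)
  spots$in_roi <- spots$flag == "ok" & in_roi(spots$x0, spots$y0, roi)
  count <- sum(spots$in_roi)
  area <- roi[["w"]] * roi[["h"]] * optics$pixel_size^2
  density_raw <- count / area
  density <- if (isTRUE(overlap_correct))
    correct_overlap_density(density_raw,
                            merge_radius_px(params) * optics$pixel_size)
  else density_raw
  structure(
    list(count = count, density = density, density_raw = density_raw,
         area_um2 = area, roi = roi, spots = spots,
         noise_sd = noise_sd),
    class = "spot_count"
  )
}

#' @export
print.spot_count <- function(x, ...) {
  cat(sprintf(
    "<spot_count> %d spots in %.1f um^2: %.3f molecules/um^2 (raw %.3f)\n",
    x$count, x$area_um2, x$density, x$density_raw))
  invisible(x)
}

#' Quantify microclusters inside a synapse mask
#'
#' Detects and 2D-Gaussian-fits every microcluster whose candidate pixel
#' lies in the mask; the integrated fluorescence intensity
#' (`2 pi A sigma^2`) is the cluster volume proxy. Clusters whose fit
#' window leaves the image or crosses the mask border are flagged
#' (`"border"` / `"mask_edge"`) and excluded from the accepted set but
#' reported in the returned table.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same shape, non-empty.
#' @param params A [detection_params()]; microclusters are wider than
#'   single molecules, so a `psf_sigma_px` ~1.5x the PSF is typical.
#'
#' @return Data frame of per-cluster fits (flag `"ok"` marks accepted
#'   clusters), with attribute `n_excluded`.
#' @export
quantify_clusters <- function(image, mask, params = detection_params()) {
  stopifnot(is.matrix(image), is.logical(mask),
            all(dim(mask) == dim(image)))
  if (!any(mask))
    stop("`mask` is empty", call. = FALSE)
  cands <- detect_candidates(image, params)
  noise_sd <- attr(cands, "noise_sd")
  if (nrow(cands) > 0L)
    cands <- cands[mask[cbind(cands$y, cands$x)], , drop = FALSE]
  spots <- fit_candidates(image, cands, params, noise_sd)
  # fits whose window includes out-of-mask pixels sit on the synapse rim
  h <- params$fit_halfwidth
  for (i in seq_len(nrow(spots))) {
    if (spots$flag[i] != "ok") next
    xs <- (round(spots$x0[i]) - h):(round(spots$x0[i]) + h)
    ys <- (round(spots$y0[i]) - h):(round(spots$y0[i]) + h)
    if (any(xs < 1L) || any(xs > ncol(mask)) || any(ys < 1L) ||
        any(ys > nrow(mask)) || !all(mask[ys, xs]))
      spots$flag[i] <- "mask_edge"
  }
  attr(spots, "n_excluded") <- sum(spots$flag != "ok")
  spots
}
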