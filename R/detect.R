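# Spot detection: difference-of-Gaussians bandpass, robust thresholding,
# local maxima with non-maximum suppression.

# Edge-renormalised 1-D Gaussian blur operator as a dense band matrix;
# blurring a constant image returns the same constant, including at edges.
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  K <- matrix(0, n, n)
  for (d in -r:r) {
    w <- stats::dnorm(d, sd = sigma)
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- w
  }
  K / rowSums(K)
}

# Separable Gaussian blur of a matrix image.
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  Kr <- blur_matrix(nrow(image), sigma)
  Kc <- blur_matrix(ncol(image), sigma)
  Kr %*% image %*% t(Kc)
}

# Difference-of-Gaussians bandpass; zero response to constant offsets.
bandpass_dog <- function(image, sigma_small, sigma_large) {
  gaussian_blur(image, sigma_small) - gaussian_blur(image, sigma_large)
}

#' Detection and fitting parameters
#'
#' @param psf_sigma_px Expected spot Gaussian sigma in pixels.
#' @param threshold_k Detection threshold in multiples of the robust noise
#'   SD (MAD) of the bandpassed image.
#' @param min_separation Minimum candidate separation in pixels
#'   (non-maximum suppression radius).
#' @param fit_halfwidth Half-width of the square fit window in pixels;
#'   default `max(3, ceiling(3 * psf_sigma_px))`, always >= 2 PSF sigma.
#' @param dog_scales Bandpass Gaussian sigmas `c(small, large)` in pixels.
#' @param max_iter Maximum fit iterations.
#' @param tol Fit convergence tolerance.
#' @param sigma_range Quality filter: accepted fitted sigma as multiples of
#'   `psf_sigma_px`.
#' @param amp_min_k Quality filter: minimum amplitude in multiples of the
#'   robust noise SD.
#'
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(psf_sigma_px = 1,
                             threshold_k = 5,
                             min_separation = 2,
                             fit_halfwidth = NULL,
                             dog_scales = psf_sigma_px * c(1, 3),
                             max_iter = 200L,
                             tol = 1e-8,
                             sigma_range = c(0.5, 3),
                             amp_min_k = 3) {
  if (is.null(fit_halfwidth))
    fit_halfwidth <- max(3L, ceiling(3 * psf_sigma_px))
  stopifnot(psf_sigma_px > 0, threshold_k > 0, min_separation >= 1,
            fit_halfwidth >= 2 * psf_sigma_px, length(dog_scales) == 2L,
            dog_scales[1L] < dog_scales[2L], sigma_range[1L] < sigma_range[2L])
  structure(
    list(psf_sigma_px = psf_sigma_px, threshold_k = threshold_k,
         min_separation = min_separation,
         fit_halfwidth = as.integer(fit_halfwidth),
         dog_scales = dog_scales, max_iter = as.integer(max_iter),
         tol = tol, sigma_range = sigma_range, amp_min_k = amp_min_k),
    class = "detection_params"
  )
}

#' Detection parameters matched to an optics model
#'
#' @param optics An [optics_model()].
#' @param ... Overrides passed to [detection_params()].
#' @export
detection_params_for <- function(optics, ...) {
  detection_params(psf_sigma_px = psf_sigma_px(optics), ...)
}

# Noise SD of a bandpassed image from the negative half of the deviation
# distribution: spots only push pixels upward, so the lower half is
# signal-free even on crowded fields (MAD equivalent under symmetric noise).
robust_noise_sd <- function(dog) {
  dev <- as.numeric(dog) - stats::median(as.numeric(dog))
  neg <- dev[dev <= 0]
  if (length(neg) == 0L) return(0)
  1.4826 * stats::median(abs(neg))
}

# Two-point resolution of the detection pipeline: the smallest separation
# (in pixels) at which two equal noiseless spots still yield two local
# maxima after the bandpass and non-maximum suppression. A deterministic
# property of the detector configuration (PSF width, DoG scales, NMS
# separation), found by bisection on rendered spot pairs; used as the
# merge radius of the overlap correction.
merge_radius_px <- local({
  cache <- new.env(parent = emptyenv())
  resolved <- function(d, params) {
    # average over sub-pixel phases of the pair centre
    n <- 41L
    for (phase in c(0, 0.25)) {
      c0 <- (n + 1) / 2 + phase
      img <- render_spots(c(n, n), c(c0 - d / 2, c0 + d / 2), c(c0, c0),
                          1000, params$psf_sigma_px)
      dog <- bandpass_dog(img, params$dog_scales[1L],
                          params$dog_scales[2L])
      is_max <- dog > max(dog) * 0.05
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        is_max <- is_max & dog >= shift_pad(dog, dr, dc)
      }
      idx <- which(is_max)
      ys <- (idx - 1L) %% n + 1L
      xs <- (idx - 1L) %/% n + 1L
      # NMS-thinned maxima count (ties within min_separation collapse)
      ord <- order(dog[idx], decreasing = TRUE)
      xs <- xs[ord]; ys <- ys[ord]
      kx <- ky <- numeric(0)
      for (i in seq_along(xs)) {
        if (length(kx) == 0L ||
            min((kx - xs[i])^2 + (ky - ys[i])^2) >=
            params$min_separation^2) {
          kx <- c(kx, xs[i]); ky <- c(ky, ys[i])
        }
      }
      if (length(kx) < 2L) return(FALSE)
    }
    TRUE
  }
  function(params) {
    key <- paste(params$psf_sigma_px, params$dog_scales[1L],
                 params$dog_scales[2L], params$min_separation, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    lo <- params$min_separation
    hi <- 8 * params$psf_sigma_px
    if (resolved(lo, params)) hi <- lo
    else while (!resolved(hi, params)) hi <- hi * 1.5
    while (hi - lo > 0.05) {
      mid <- (lo + hi) / 2
      if (resolved(mid, params)) hi <- mid else lo <- mid
    }
    cache[[key]] <- hi
    hi
  }
})

# Shifted copy of a matrix, padding with -Inf (for maximum comparisons).
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Detect candidate spots
#'
#' Local maxima of the bandpassed (difference-of-Gaussians) image exceeding
#' `threshold_k` robust noise SDs, thinned by non-maximum suppression at
#' `min_separation` (ties and merges keep the brighter candidate).
#' Constant offsets do not affect the result.
#'
#' @param image Numeric matrix, finite values.
#' @param params A [detection_params()].
#'
#' @return Data frame with integer pixel coordinates `x` (column), `y`
#'   (row) and the bandpassed `value`, ordered by decreasing value. The
#'   robust noise SD is attached as attribute `noise_sd`.
#' @export
detect_candidates <- function(image, params = detection_params()) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(image)))
    stop("`image` must be finite", call. = FALSE)
  dog <- bandpass_dog(image, params$dog_scales[1L], params$dog_scales[2L])
  noise <- robust_noise_sd(dog)
  empty <- data.frame(x = integer(0), y = integer(0), value = numeric(0))
  attr(empty, "noise_sd") <- noise
  if (noise == 0) return(empty)
  thr <- params$threshold_k * noise
  is_max <- dog > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & dog >= shift_pad(dog, dr, dc)
  }
  idx <- which(is_max)
  if (length(idx) == 0L) return(empty)
  ys <- (idx - 1L) %% nrow(dog) + 1L
  xs <- (idx - 1L) %/% nrow(dog) + 1L
  vals <- dog[idx]
  ord <- order(vals, decreasing = TRUE)
  xs <- xs[ord]; ys <- ys[ord]; vals <- vals[ord]
  keep <- logical(length(xs))
  kx <- ky <- numeric(0)
  min_sep2 <- params$min_separation^2
  for (i in seq_along(xs)) {
    if (length(kx) == 0L ||
        min((kx - xs[i])^2 + (ky - ys[i])^2) >= min_sep2) {
      keep[i] <- TRUE
      kx <- c(kx, xs[i]); ky <- c(ky, ys[i])
    }
  }
  out <- data.frame(x = xs[keep], y = ys[keep], value = vals[keep])
  attr(out, "noise_sd") <- noise
  out
}
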