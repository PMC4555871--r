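# Imaging models: microscope/camera description and the isotype
# force-response model used by the synthetic-data generators.

#' TIRF optics and camera model
#'
#' Defaults emulate the experimental geometry: 512 x 512 frames and a pixel
#' size of 0.16 um so a 136 x 136-pixel counting ROI is ~473.6 um^2,
#' matching the ~473.1 um^2 counting area; PSF sigma 0.15 um for a
#' high-NA (1.49) oil objective. The camera is an EMCCD surrogate: Poisson
#' shot noise on signal photons, a fixed offset and Gaussian read noise
#' (gain 1); pixel values are floored at 0.
#'
#' @param pixel_size um per pixel.
#' @param psf_sigma PSF Gaussian sigma in um.
#' @param frame_shape Frame dimensions `c(rows, cols)` in pixels.
#' @param photons_per_molecule Expected photons collected per molecule.
#' @param background_offset Camera offset in counts.
#' @param read_noise_sd Gaussian read noise SD in counts.
#'
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(pixel_size = 0.16,
                         psf_sigma = 0.15,
                         frame_shape = c(512L, 512L),
                         photons_per_molecule = 2000,
                         background_offset = 100,
                         read_noise_sd = 10) {
  stopifnot(pixel_size > 0, psf_sigma > 0, length(frame_shape) == 2L,
            all(frame_shape >= 8), photons_per_molecule > 0,
            background_offset >= 0, read_noise_sd >= 0)
  structure(
    list(pixel_size = pixel_size,
         psf_sigma = psf_sigma,
         frame_shape = as.integer(frame_shape),
         photons_per_molecule = photons_per_molecule,
         background_offset = background_offset,
         read_noise_sd = read_noise_sd),
    class = "optics_model"
  )
}

psf_sigma_px <- function(optics) optics$psf_sigma / optics$pixel_size

frame_area_um2 <- function(optics)
  prod(optics$frame_shape) * optics$pixel_size^2

#' Centred square counting ROI
#'
#' @param optics An [optics_model()].
#' @param size_px ROI edge in pixels (default 136, ~473.6 um^2 at 0.16 um
#'   pixels).
#' @return `c(x, y, w, h)` in 1-based pixel coordinates.
#' @export
counting_roi <- function(optics, size_px = 136L) {
  size_px <- as.integer(size_px)
  stopifnot(all(optics$frame_shape >= size_px))
  x <- (optics$frame_shape[2L] - size_px) %/% 2L + 1L
  y <- (optics$frame_shape[1L] - size_px) %/% 2L + 1L
  c(x = x, y = y, w = size_px, h = size_px)
}

roi_area_um2 <- function(roi, optics) roi[["w"]] * roi[["h"]] * optics$pixel_size^2

#' Isotype force-response model
#'
#' Encodes the three-level step response of IgM-type receptors over the
#' sensor force panel and the force-independent (flat, high) response of
#' IgG/IgE-type receptors. Tail-swapped chimeras follow the tail: GGM
#' (IgG body, IgM tail) is force-dependent like IgM; MMG (IgM body, IgG
#' tail) is flat like IgG. Per-cell accumulation plateaus are drawn as
#' Normal(level mean, cv * level mean) truncated at 0, in arbitrary
#' accumulation units; level means default to 1 : 2 : 3.5 (low : medium :
#' high) with CV 25%. Non-conjugated control tethers give baseline-only
#' responses.
#'
#' @param isotype One of `"IgM"`, `"IgG"`, `"IgE"`, `"GGM"`, `"MMG"`.
#' @param level_means Named vector `c(low=, medium=, high=)`, arbitrary
#'   units; must be increasing.
#' @param level_cv Coefficient of variation of the per-cell plateau.
#' @param baseline Mean accumulation for non-conjugated control tethers.
#' @param tau Accumulation time constant in seconds:
#'   A(t) = plateau * (1 - exp(-t / tau)).
#' @param force_bands Optional data frame `(max_force, level)` mapping
#'   forces to levels; defaults by isotype (force-dependent: <=16 pN low,
#'   <=43 pN medium, above high; force-independent: all high).
#'
#' @return An object of class `response_model`.
#' @export
response_model <- function(isotype = c("IgM", "IgG", "IgE", "GGM", "MMG"),
                           level_means = c(low = 1, medium = 2, high = 3.5),
                           level_cv = 0.25,
                           baseline = 0.2,
                           tau = 120,
                           force_bands = NULL) {
  isotype <- match.arg(isotype)
  stopifnot(all(c("low", "medium", "high") %in% names(level_means)),
            level_means[["low"]] < level_means[["medium"]],
            level_means[["medium"]] < level_means[["high"]],
            level_cv >= 0, baseline >= 0, tau > 0)
  force_dependent <- isotype %in% c("IgM", "GGM")
  if (is.null(force_bands)) {
    force_bands <- if (force_dependent) {
      data.frame(max_force = c(16, 43, Inf),
                 level = c("low", "medium", "high"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(max_force = Inf, level = "high", stringsAsFactors = FALSE)
    }
  }
  stopifnot(all(force_bands$level %in% names(level_means)))
  structure(
    list(isotype = isotype,
         level_means = level_means,
         level_cv = level_cv,
         baseline = baseline,
         tau = tau,
         force_bands = force_bands,
         force_dependent = force_dependent),
    class = "response_model"
  )
}

#' Response level implied by (isotype, sensor)
#'
#' @param response A [response_model()].
#' @param sensor A [tgt_sensor()]; non-conjugated sensors map to
#'   `"baseline"`.
#' @return `"baseline"`, `"low"`, `"medium"` or `"high"`.
#' @export
response_level <- function(response, sensor) {
  stopifnot(inherits(response, "response_model"),
            inherits(sensor, "tgt_sensor"))
  if (!sensor$np_conjugated) return("baseline")
  bands <- response$force_bands
  bands$level[which(sensor$mean_rupture_force <= bands$max_force)[1L]]
}

level_mean <- function(response, level) {
  if (level == "baseline") response$baseline else
    unname(response$level_means[[level]])
}

draw_plateaus <- function(response, level, n) {
  m <- level_mean(response, level)
  if (m == 0) return(rep(0, n))
  rnorm_trunc0(n, mean = m, sd = response$level_cv * m)
}
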