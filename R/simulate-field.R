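# Synthetic single-molecule TIRF fields and the incubation-concentration ->
# surface-density curve.

# Expected photon image for point emitters. Positions are continuous pixel
# coordinates (pixel j spans [j-0.5, j+0.5)); per-pixel intensities are the
# exact integral of the Gaussian PSF over the pixel (separable erf form).
render_spots <- function(shape, x_px, y_px, photons, sigma_px) {
  img <- matrix(0, nrow = shape[1L], ncol = shape[2L])
  n <- length(x_px)
  if (n == 0L) return(img)
  photons <- rep_len(photons, n)
  sigma_px <- rep_len(sigma_px, n)
  r <- ceiling(4 * max(sigma_px)) + 1L
  for (i in seq_len(n)) {
    cx <- x_px[i]; cy <- y_px[i]
    ix <- max(1L, floor(cx) - r):min(shape[2L], floor(cx) + r)
    iy <- max(1L, floor(cy) - r):min(shape[1L], floor(cy) + r)
    if (ix[1L] > ix[length(ix)] || iy[1L] > iy[length(iy)]) next
    fx <- stats::pnorm(ix + 0.5, cx, sigma_px[i]) -
      stats::pnorm(ix - 0.5, cx, sigma_px[i])
    fy <- stats::pnorm(iy + 0.5, cy, sigma_px[i]) -
      stats::pnorm(iy - 0.5, cy, sigma_px[i])
    img[iy, ix] <- img[iy, ix] + photons[i] * (fy %o% fx)
  }
  img
}

# Camera model: Poisson shot noise on the expected signal photons, fixed
# offset, Gaussian read noise; counts floored at 0.
apply_camera_noise <- function(expected_signal, optics) {
  shape <- dim(expected_signal)
  shot <- matrix(stats::rpois(length(expected_signal),
                              lambda = as.numeric(expected_signal)),
                 nrow = shape[1L], ncol = shape[2L])
  img <- shot + optics$background_offset
  if (optics$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = optics$read_noise_sd),
                        nrow = shape[1L], ncol = shape[2L])
  pmax(img, 0)
}

#' Simulate a sparse single-molecule TIRF field
#'
#' Molecule positions follow a homogeneous spatial Poisson process at the
#' requested surface density; each molecule is rendered as a
#' diffraction-limited 2D Gaussian PSF, then Poisson shot noise, camera
#' offset and Gaussian read noise are applied.
#'
#' @param density Molecules per um^2 (>= 0).
#' @param optics An [optics_model()].
#' @param seed Optional integer; same seed gives bit-identical output.
#'
#' @return A list of class `molecule_field` with `image` (counts),
#'   `expected` (noise-free expected signal photons per pixel) and `truth`
#'   (`n`, positions `x_um`/`y_um` from the field origin, and
#'   `photons` per molecule), plus `density` and `optics`.
#' @export
simulate_molecule_field <- function(density, optics = optics_model(),
                                    seed = NULL) {
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0)
    stop("`density` must be a non-negative scalar", call. = FALSE)
  stopifnot(inherits(optics, "optics_model"))
  with_seed(seed, {
    w_um <- optics$frame_shape[2L] * optics$pixel_size
    h_um <- optics$frame_shape[1L] * optics$pixel_size
    n <- stats::rpois(1L, density * w_um * h_um)
    x_um <- stats::runif(n, 0, w_um)
    y_um <- stats::runif(n, 0, h_um)
    photons <- rep(optics$photons_per_molecule, n)
    expected <- render_spots(optics$frame_shape,
                             x_um / optics$pixel_size + 0.5,
                             y_um / optics$pixel_size + 0.5,
                             photons, psf_sigma_px(optics))
    image <- apply_camera_noise(expected, optics)
    structure(
      list(image = image,
           expected = expected,
           truth = list(n = n, x_um = x_um, y_um = y_um, photons = photons),
           density = density,
           optics = optics),
      class = "molecule_field"
    )
  })
}

#' Surface density at a given incubation concentration
#'
#' Monotone (Hyman-filtered cubic) interpolation through the measured
#' anchor points 2 -> 0.3, 5 -> 4.0, 10 -> 19.0 and 50 -> 29.0 nM ->
#' molecules/um^2, with 0 -> 0; concentrations beyond 50 nM saturate at
#' 29.0.
#'
#' @param concentration Incubation concentration(s) in nM, >= 0.
#' @return Surface density in molecules per um^2.
#' @export
coating_density <- function(concentration) {
  if (!is.numeric(concentration) || any(is.na(concentration)) ||
      any(concentration < 0))
    stop("`concentration` must be non-negative", call. = FALSE)
  conc <- c(0, 2, 5, 10, 50)
  dens <- c(0, 0.3, 4.0, 19.0, 29.0)
  f <- stats::splinefun(conc, dens, method = "hyman")
  out <- ifelse(concentration >= 50, 29.0, pmax(0, f(concentration)))
  unname(out)
}
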