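# 2D Gaussian spot fitting: symmetric single-sigma Gaussian plus constant
# background, least squares over a square window.

#' Fit a 2D Gaussian to a spot
#'
#' Least-squares fit of `b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 s^2))`
#' over a `(2h+1) x (2h+1)` window centred on `center`. Windows clipped by
#' the image border are flagged (`flag = "border"`, `converged = FALSE`)
#' and carry no parameter estimates. Non-converged or singular fits return
#' `converged = FALSE`.
#'
#' @param image Numeric matrix.
#' @param center Integer pixel coordinates `c(x, y)` (column, row).
#' @param params A [detection_params()]; `fit_halfwidth`, `max_iter`,
#'   `tol` and `psf_sigma_px` (starting sigma) are used.
#'
#' @return A list of class `spot_fit`: `x0`, `y0` (sub-pixel, full-image
#'   coordinates), `amplitude`, `sigma`, `background`,
#'   `integrated_intensity` (= 2 pi A sigma^2), `residual_norm`,
#'   `converged`, `flag`.
#' @export
fit_gaussian_2d <- function(image, center, params = detection_params()) {
  stopifnot(is.matrix(image))
  cx <- as.numeric(center[[1L]])
  cy <- as.numeric(center[[2L]])
  h <- params$fit_halfwidth
  failed <- function(flag) {
    structure(list(x0 = NA_real_, y0 = NA_real_, amplitude = NA_real_,
                   sigma = NA_real_, background = NA_real_,
                   integrated_intensity = NA_real_,
                   residual_norm = NA_real_, converged = FALSE,
                   flag = flag),
              class = "spot_fit")
  }
  xi <- round(cx); yi <- round(cy)
  if (xi - h < 1L || xi + h > ncol(image) || yi - h < 1L ||
      yi + h > nrow(image))
    return(failed("border"))
  xs <- (xi - h):(xi + h)
  ys <- (yi - h):(yi + h)
  z <- image[ys, xs]
  dat <- data.frame(
    z = as.numeric(z),
    x = rep(xs, each = length(ys)),
    y = rep(ys, times = length(xs))
  )
  # moment-based starting values; background from the window rim
  rim <- c(z[1L, ], z[nrow(z), ], z[, 1L], z[, ncol(z)])
  b0 <- stats::median(rim)
  a0 <- max(max(z) - b0, 1e-6)
  w <- pmax(dat$z - b0, 0)
  if (sum(w) > 0) {
    x0s <- sum(w * dat$x) / sum(w)
    y0s <- sum(w * dat$y) / sum(w)
  } else {
    x0s <- xi; y0s <- yi
  }
  s0 <- params$psf_sigma_px
  fit <- tryCatch(
    stats::nls(
      z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = dat,
      start = list(b = b0, A = a0, x0 = x0s, y0 = y0s, s = s0),
      algorithm = "port",
      # the centre stays near the candidate pixel so neighbouring spots in
      # the window cannot capture the fit
      lower = c(b = -Inf, A = 0, x0 = xi - 1.5, y0 = yi - 1.5, s = 0.2),
      upper = c(b = Inf, A = Inf, x0 = xi + 1.5, y0 = yi + 1.5,
                s = 4 * h),
      control = stats::nls.control(maxiter = params$max_iter,
                                   tol = params$tol, warnOnly = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    # fall back to unconstrained quasi-Newton on the sum of squares
    sse <- function(p) {
      mu <- p[1L] + p[2L] *
        exp(-((dat$x - p[3L])^2 + (dat$y - p[4L])^2) / (2 * p[5L]^2))
      sum((dat$z - mu)^2)
    }
    op <- tryCatch(
      stats::optim(c(b0, a0, x0s, y0s, s0), sse, method = "BFGS",
                   control = list(maxit = params$max_iter,
                                  reltol = params$tol)),
      error = function(e) NULL)
    if (is.null(op) || op$convergence != 0L || op$par[5L] <= 0 ||
        op$par[2L] < 0)
      return(failed("not_converged"))
    p <- op$par
    res_norm <- sqrt(op$value)
    est <- c(b = p[1L], A = p[2L], x0 = p[3L], y0 = p[4L],
             s = abs(p[5L]))
  } else {
    est <- stats::coef(fit)
    res_norm <- sqrt(sum(stats::residuals(fit)^2))
  }
  structure(
    list(x0 = unname(est[["x0"]]), y0 = unname(est[["y0"]]),
         amplitude = unname(est[["A"]]), sigma = unname(est[["s"]]),
         background = unname(est[["b"]]),
         integrated_intensity = 2 * pi * unname(est[["A"]]) *
           unname(est[["s"]])^2,
         residual_norm = res_norm, converged = TRUE, flag = "ok"),
    class = "spot_fit"
  )
}

#' @export
print.spot_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<spot_fit> not converged (%s)\n", x$flag))
  } else {
    cat(sprintf(
      "<spot_fit> (%.2f, %.2f) A=%.1f sigma=%.2f b=%.1f FI=%.1f\n",
      x$x0, x$y0, x$amplitude, x$sigma, x$background,
      x$integrated_intensity))
  }
  invisible(x)
}

spot_fit_row <- function(f) {
  data.frame(x0 = f$x0, y0 = f$y0, amplitude = f$amplitude,
             sigma = f$sigma, background = f$background,
             integrated_intensity = f$integrated_intensity,
             residual_norm = f$residual_norm, converged = f$converged,
             flag = f$flag, stringsAsFactors = FALSE)
}
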