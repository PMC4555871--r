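# Shared fixtures: small optics and hand-rendered images, all generated in
# code at test time.

small_optics <- function(...) {
  optics_model(frame_shape = c(160L, 160L), ...)
}

cell_optics <- function(...) {
  optics_model(frame_shape = c(96L, 96L), ...)
}

# Exact point-sampled Gaussian image (the fit model itself).
gaussian_image <- function(n, A, x0, y0, sigma, b) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  b + A * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2))
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Truth positions (px) of a simulated field, and how many fall in a ROI.
truth_px <- function(field) {
  ps <- field$optics$pixel_size
  list(x = field$truth$x_um / ps + 0.5, y = field$truth$y_um / ps + 0.5)
}

truth_in_roi <- function(field, roi) {
  t <- truth_px(field)
  sum(t$x >= roi[["x"]] - 0.5 & t$x < roi[["x"]] + roi[["w"]] - 0.5 &
        t$y >= roi[["y"]] - 0.5 & t$y < roi[["y"]] + roi[["h"]] - 0.5)
}
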