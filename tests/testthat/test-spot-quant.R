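test_that("candidate detection finds well-separated spots and nothing else", {
  expect_error(detect_candidates(matrix(numeric(0), 0, 0)), "non-empty")
  expect_equal(nrow(detect_candidates(matrix(5, 64, 64))), 0L)

  # 50 spots on a jittered grid at SNR ~10
  op <- optics_model(frame_shape = c(128L, 128L), photons_per_molecule = 800)
  set.seed(3)
  gx <- rep(seq(12, 117, by = 15), each = 8)[1:50] + runif(50, -2, 2)
  gy <- rep(seq(12, 117, by = 15), times = 8)[1:50] + runif(50, -2, 2)
  expected <- tgtforce:::render_spots(c(128L, 128L), gx, gy, 800,
                                      tgtforce:::psf_sigma_px(op))
  set.seed(4)
  img <- tgtforce:::apply_camera_noise(expected, op)
  params <- detection_params_for(op)
  cands <- detect_candidates(img, params)
  d_true <- vapply(seq_len(nrow(cands)), function(i)
    min(sqrt((cands$x[i] - gx)^2 + (cands$y[i] - gy)^2)), 1)
  expect_gte(sum(d_true <= 2), 49L)
  expect_lte(sum(d_true > 2), 1L)

  # determinism and offset invariance
  expect_identical(cands, detect_candidates(img, params))
  shifted <- detect_candidates(img + 500, params)
  expect_identical(cands[, c("x", "y")], shifted[, c("x", "y")])
})

test_that("noiseless 2D Gaussian fits are exact and FI matches the pixel sum", {
  img <- gaussian_image(41, A = 1000, x0 = 21.3, y0 = 20.6, sigma = 2,
                        b = 100)
  params <- detection_params(psf_sigma_px = 2)
  f <- fit_gaussian_2d(img, c(21, 21), params)
  expect_true(f$converged)
  expect_equal(f$amplitude, 1000, tolerance = 1e-6)
  expect_equal(f$sigma, 2, tolerance = 1e-6)
  expect_equal(f$x0, 21.3, tolerance = 1e-6)
  expect_equal(f$y0, 20.6, tolerance = 1e-6)
  expect_equal(f$background, 100, tolerance = 1e-6)
  # discrete-sum oracle: FI equals the background-subtracted pixel sum
  expect_equal(f$integrated_intensity, sum(img - 100), tolerance = 0.005)

  # integrated intensity is invariant to the background level
  f2 <- fit_gaussian_2d(img + 250, c(21, 21), params)
  expect_equal(f2$integrated_intensity, f$integrated_intensity,
               tolerance = 1e-6)
})

test_that("fitting is translation-equivariant and flags clipped windows", {
  img <- gaussian_image(41, A = 500, x0 = 18.4, y0 = 19.2, sigma = 1.5,
                        b = 50)
  params <- detection_params(psf_sigma_px = 1.5)
  f <- fit_gaussian_2d(img, c(18, 19), params)
  shifted <- matrix(50, 41, 41)
  shifted[8:41, 6:41] <- img[1:34, 1:36]  # shift by (+5 x, +7 y)
  fs <- fit_gaussian_2d(shifted, c(23, 26), params)
  expect_equal(fs$x0 - f$x0, 5, tolerance = 1e-6)
  expect_equal(fs$y0 - f$y0, 7, tolerance = 1e-6)
  expect_equal(fs$amplitude, f$amplitude, tolerance = 1e-6)

  fb <- fit_gaussian_2d(img, c(2, 2), params)
  expect_false(fb$converged)
  expect_equal(fb$flag, "border")
})

test_that("amplitude estimates are unbiased under Poisson noise (Monte Carlo)", {
  op <- optics_model(frame_shape = c(21L, 21L), photons_per_molecule = 800,
                     read_noise_sd = 5)
  ex <- tgtforce:::render_spots(c(21L, 21L), 11.2, 10.7, 800,
                                tgtforce:::psf_sigma_px(op))
  params <- detection_params_for(op)
  # reference: the noiseless fit of the same pixel-integrated spot
  a_ref <- fit_gaussian_2d(ex + op$background_offset, c(11, 11),
                           params)$amplitude
  amps <- vapply(1:200, function(k) {
    im <- with_seed_test(k, tgtforce:::apply_camera_noise(ex, op))
    fit_gaussian_2d(im, c(11, 11), params)$amplitude
  }, 1)
  expect_lt(abs(mean(amps) / a_ref - 1), 0.02)
})

test_that("counting is calibrated at low density and offset-invariant", {
  op <- small_optics()
  roi <- counting_roi(op, 136L)
  empty <- simulate_molecule_field(0, op, seed = 2)
  cs0 <- count_spots(empty$image, roi, op)
  expect_equal(cs0$count, 0L)
  expect_equal(cs0$density, 0)
  expect_error(count_spots(empty$image, c(10, 10, 0, 5), op), "zero area")

  # pooled recovery at the sparse single-molecule density (scaled replicates)
  ratios <- vapply(1:8, function(s) {
    f <- simulate_molecule_field(0.3, op, seed = 40 + s)
    cs <- count_spots(f$image, roi, op)
    cs$density * cs$area_um2 / truth_in_roi(f, roi)
  }, 1)
  expect_lt(abs(mean(ratios) - 1), 0.05)

  # adding a constant offset does not change the count
  f <- simulate_molecule_field(0.3, op, seed = 77)
  c1 <- count_spots(f$image, roi, op)
  c2 <- count_spots(f$image + 300, roi, op)
  expect_equal(c1$count, c2$count)
})

test_that("microcluster FI quantification scales and respects the mask", {
  # two clusters, the second at twice the amplitude -> FI ratio 2
  img <- matrix(100, 64, 64) +
    tgtforce:::render_spots(c(64L, 64L), c(20, 44), c(32, 32),
                            c(1000, 2000), 1.5)
  mask <- matrix(TRUE, 64, 64)
  params <- detection_params(psf_sigma_px = 1.5)
  cl <- quantify_clusters(img, mask, params)
  ok <- cl[cl$flag == "ok", ]
  ok <- ok[order(ok$x0), ]
  expect_equal(nrow(ok), 2L)
  expect_equal(ok$integrated_intensity[2] / ok$integrated_intensity[1], 2,
               tolerance = 0.02)

  # a cluster at the mask border is excluded and reported
  mask2 <- matrix(FALSE, 64, 64)
  mask2[, 1:21] <- TRUE  # boundary cuts through the first cluster window
  cl2 <- quantify_clusters(img, mask2, params)
  expect_true(any(cl2$flag == "mask_edge"))
  expect_equal(sum(cl2$flag == "ok"), 0L)
  expect_gte(attr(cl2, "n_excluded"), 1L)
  expect_error(quantify_clusters(img, matrix(FALSE, 64, 64), params),
               "empty")
})

test_that("high-force synapse frames carry brighter microclusters than low-force", {
  op <- cell_optics()
  resp <- response_model("IgM")
  params <- detection_params(
    psf_sigma_px = 1.5 * tgtforce:::psf_sigma_px(op))
  mean_fi <- function(pos, s0) {
    per_frame <- vapply(1:6, function(k) {
      tl <- simulate_cell_timelapse(resp, tgt_sensor(pos), 600, 600,
                                    optics = op, seed = s0 + k)
      fr <- tl$stack[, , 2L]
      seg <- segment_contact(fr, op$pixel_size)
      cl <- quantify_clusters(fr, seg$mask, params)
      fi <- cl$integrated_intensity[cl$flag == "ok"]
      if (length(fi)) mean(fi) else NA_real_
    }, 1)
    mean(per_frame, na.rm = TRUE)
  }
  expect_gt(mean_fi(21, 600), mean_fi(1, 700))
})
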