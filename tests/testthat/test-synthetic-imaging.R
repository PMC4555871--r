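test_that("molecule fields have Poisson-consistent truth and conserve photons", {
  # scaled-down frame (64 px = 104.9 um^2) so 30 replicates stay fast
  op <- optics_model(frame_shape = c(64L, 64L))
  area <- 64^2 * op$pixel_size^2
  dens <- 4.0
  n <- vapply(1:30, function(s)
    simulate_molecule_field(dens, op, seed = 100 + s)$truth$n, 1L)
  lambda <- dens * area
  se <- sqrt(lambda / 30)
  expect_lt(abs(mean(n) - lambda), 3 * se)

  # expected-photon conservation before noise (up to edge spill)
  f <- simulate_molecule_field(0.5, op, seed = 9)
  expect_lt(sum(f$expected), f$truth$n * op$photons_per_molecule + 1e-6)
  expect_gt(sum(f$expected), 0.95 * f$truth$n * op$photons_per_molecule)
  expect_true(all(f$image >= 0))
})

test_that("empty fields are background-only and seeds give bit-identical frames", {
  op <- optics_model(frame_shape = c(64L, 64L))
  f0 <- simulate_molecule_field(0, op, seed = 1)
  expect_equal(f0$truth$n, 0L)
  expect_equal(mean(f0$image), op$background_offset, tolerance = 0.01)

  fa <- simulate_molecule_field(1, op, seed = 5)
  fb <- simulate_molecule_field(1, op, seed = 5)
  expect_identical(fa$image, fb$image)
  fc <- simulate_molecule_field(1, op, seed = 6)
  expect_false(identical(fa$image, fc$image))

  expect_error(simulate_molecule_field(-1, op), "non-negative")
})

test_that("coating density reproduces the printed anchors and is monotone", {
  expect_equal(coating_density(0), 0)
  expect_equal(coating_density(2), 0.3)
  expect_equal(coating_density(5), 4.0)
  expect_equal(coating_density(10), 19.0)
  expect_equal(coating_density(50), 29.0)
  expect_equal(coating_density(100), 29.0)  # saturates past the last anchor
  grid <- coating_density(seq(0, 60, by = 0.1))
  expect_true(all(diff(grid) >= -1e-12))
  expect_error(coating_density(-1), "non-negative")
})

test_that("time-lapse frame counts and degenerate inputs follow the contract", {
  resp <- response_model("IgM")
  s <- tgt_sensor(21)
  tl <- simulate_cell_timelapse(resp, s, duration = 600, interval = 4,
                                seed = 1, render = FALSE)
  expect_equal(nrow(tl$truth), 151L)  # floor(600/4) + 1
  expect_equal(tl$truth$time[2] - tl$truth$time[1], 4)
  expect_error(simulate_cell_timelapse(resp, s, duration = 0, interval = 4),
               "positive")
  expect_error(simulate_cell_timelapse(resp, s, duration = 2, interval = 4),
               "positive")
})

test_that("control tethers give baseline-only traces", {
  resp <- response_model("IgM")
  nc <- tgt_sensor(21, np_conjugated = FALSE)
  accs <- vapply(1:20, function(s) {
    tl <- simulate_cell_timelapse(resp, nc, duration = 600, interval = 60,
                                  seed = 300 + s, render = FALSE)
    tail(tl$truth$accumulation, 1L)
  }, 1)
  # final accumulation sits at the baseline level, far below "low"
  expect_lt(mean(accs), resp$level_means[["low"]] / 2)
  expect_equal(mean(accs), resp$baseline, tolerance = 0.25)
})

test_that("IgM truth plateaus rank 56 > 43 > 12 pN across seeded cells", {
  resp <- response_model("IgM")
  plat <- function(pos, s0) vapply(1:50, function(k)
    simulate_cell_timelapse(resp, tgt_sensor(pos), 600, 60,
                            seed = s0 + k, render = FALSE)$plateau, 1)
  p12 <- plat(1, 1000)
  p43 <- plat(11, 2000)
  p56 <- plat(21, 3000)
  expect_lt(t_test_two_tailed(p56, p43)$p, 0.001)
  expect_gt(mean(p56), mean(p43))
  expect_gt(mean(p43), mean(p12))
  expect_lt(t_test_two_tailed(p43, p12)$p, 0.001)
})

test_that("condition panels carry the isotype force-response structure", {
  panel <- build_sensor_panel()
  igm <- simulate_condition_panel(response_model("IgM"), panel, 40,
                                  seed = 11)
  expect_equal(nrow(igm$truth), 320L)
  # exactly three distinct level means in the IgM truth
  expect_setequal(unique(igm$truth$level), c("low", "medium", "high"))
  lv <- tapply(igm$truth$level, igm$truth$force, unique)
  expect_identical(as.vector(lv[c("12", "16")]), c("low", "low"))
  expect_identical(as.vector(lv[c("23", "33", "43")]),
                   rep("medium", 3L))
  expect_identical(as.vector(lv[c("50", "54", "56")]), rep("high", 3L))

  # IgG/IgE: one level across all forces (zero spread in truth means)
  igg <- simulate_condition_panel(response_model("IgG"), panel, 40,
                                  seed = 12)
  expect_setequal(unique(igg$truth$level), "high")
  ige <- simulate_condition_panel(response_model("IgE"), panel, 5, seed = 13)
  expect_setequal(unique(ige$truth$level), "high")

  # tail-swap chimeras follow the tail
  expect_true(response_model("GGM")$force_dependent)
  expect_false(response_model("MMG")$force_dependent)

  expect_error(simulate_condition_panel(response_model("IgM"), list(), 10),
               "at least one sensor")
  expect_error(simulate_condition_panel(response_model("IgM"), panel, 0),
               ">= 1")
})

test_that("rendered stacks are deterministic given the seed", {
  resp <- response_model("IgM")
  s <- tgt_sensor(21)
  op <- optics_model(frame_shape = c(48L, 48L))
  a <- simulate_cell_timelapse(resp, s, 60, 20, optics = op, seed = 4)
  b <- simulate_cell_timelapse(resp, s, 60, 20, optics = op, seed = 4)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth, b$truth)
})
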