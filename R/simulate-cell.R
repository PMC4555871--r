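# Synthetic B-cell synapse images: endpoint frames and time-lapses whose
# microcluster content and contact area follow the isotype response model.

#' Rendering parameters for synthetic synapse frames
#'
#' Converts accumulation units into photons and um^2. The contact footprint
#' is a disk whose area is `area_baseline + area_per_unit * A(t)`; a
#' fraction of the synapse photons is spread uniformly over the disk
#' (diffuse membrane signal), the rest is split over discrete microclusters
#' (Gaussians slightly wider than the PSF) whose count grows with A(t).
#'
#' @param photons_per_unit Expected photons per accumulation unit per frame.
#' @param diffuse_fraction Fraction of synapse photons in the diffuse pool.
#' @param clusters_per_unit Microcluster count scale; the count grows as
#'   `clusters_per_unit * sqrt(A(t))`, so per-cluster brightness grows as
#'   `sqrt(A(t))` - stronger activation gives both more and brighter
#'   clusters.
#' @param cluster_sigma_factor Cluster Gaussian sigma as a multiple of the
#'   PSF sigma.
#' @param cluster_min_sep_px Minimum centre-to-centre cluster spacing in
#'   pixels (keeps clusters individually resolvable).
#' @param area_baseline Contact area at zero accumulation (um^2).
#' @param area_per_unit Contact-area gain per accumulation unit (um^2).
#' @return A list of class `synapse_render_params`.
#' @export
synapse_render_params <- function(photons_per_unit = 3e4,
                                  diffuse_fraction = 0.7,
                                  clusters_per_unit = 8,
                                  cluster_sigma_factor = 1.5,
                                  cluster_min_sep_px = 3,
                                  area_baseline = 3,
                                  area_per_unit = 12) {
  stopifnot(photons_per_unit > 0, diffuse_fraction >= 0,
            diffuse_fraction <= 1, clusters_per_unit >= 0,
            cluster_sigma_factor >= 1, cluster_min_sep_px >= 0,
            area_baseline >= 0, area_per_unit >= 0)
  structure(as.list(environment()), class = "synapse_render_params")
}

n_clusters_for <- function(rp, accumulation) {
  as.integer(max(0, round(rp$clusters_per_unit * sqrt(max(accumulation, 0)))))
}

# One rendered synapse frame. `cluster_xy_unit` are fixed unit-disk
# positions so clusters persist coherently across a time-lapse.
render_synapse_frame <- function(accumulation, area_um2, optics, rp,
                                 cluster_xy_unit) {
  shape <- optics$frame_shape
  ps <- optics$pixel_size
  cx <- (shape[2L] + 1) / 2
  cy <- (shape[1L] + 1) / 2
  radius_px <- sqrt(area_um2 / pi) / ps
  xs <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  ys <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  disk <- (xs - cx)^2 + (ys - cy)^2 <= radius_px^2
  total <- rp$photons_per_unit * accumulation
  expected <- matrix(0, shape[1L], shape[2L])
  npx <- sum(disk)
  if (npx > 0L && total > 0) {
    expected[disk] <- rp$diffuse_fraction * total / npx
    n_cl <- min(nrow(cluster_xy_unit), n_clusters_for(rp, accumulation))
    if (n_cl > 0L) {
      # clusters sit inside the disk, one PSF width off the rim, spaced by
      # cluster_min_sep_px (inventory order, so time-lapses are coherent)
      r_eff <- max(radius_px - 2 * psf_sigma_px(optics), 0.5 * radius_px)
      cand_x <- cx + cluster_xy_unit[, 1L] * r_eff
      cand_y <- cy + cluster_xy_unit[, 2L] * r_eff
      cl_x <- cl_y <- numeric(0)
      for (i in seq_along(cand_x)) {
        if (length(cl_x) >= n_cl) break
        if (length(cl_x) == 0L ||
            min((cl_x - cand_x[i])^2 + (cl_y - cand_y[i])^2) >=
            rp$cluster_min_sep_px^2) {
          cl_x <- c(cl_x, cand_x[i]); cl_y <- c(cl_y, cand_y[i])
        }
      }
      expected <- expected + render_spots(
        shape, cl_x, cl_y,
        photons = (1 - rp$diffuse_fraction) * total / length(cl_x),
        sigma_px = rp$cluster_sigma_factor * psf_sigma_px(optics))
    }
  }
  list(expected = expected, image = apply_camera_noise(expected, optics))
}

# Fixed inventory of unit-disk cluster positions (area-uniform).
draw_cluster_inventory <- function(n_max) {
  r <- sqrt(stats::runif(n_max))
  th <- stats::runif(n_max, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

#' Simulate a single-cell synapse time-lapse
#'
#' The cell's accumulation follows saturating growth
#' `A(t) = plateau * (1 - exp(-t / tau))` with the plateau drawn from the
#' response level implied by (isotype, sensor force, NP conjugation);
#' control (non-conjugated) tethers give baseline-only traces. Contact
#' area and microcluster count grow with A(t) as configured in
#' [synapse_render_params()].
#'
#' @param response A [response_model()].
#' @param sensor A [tgt_sensor()].
#' @param duration Total time in s (> 0, >= `interval`).
#' @param interval Frame interval in s (> 0); frame count is
#'   `floor(duration / interval) + 1` (t = 0 included).
#' @param optics An [optics_model()]; small frames (e.g. 96 x 96) keep the
#'   rendering fast.
#' @param seed Optional integer seed.
#' @param render_params A [synapse_render_params()].
#' @param render `FALSE` skips pixel rendering and returns truth only.
#'
#' @return A list of class `cell_timelapse` with `stack` (rows x cols x
#'   frames array, or `NULL` when `render = FALSE`) and `truth`: a data
#'   frame (frame, time, accumulation, area_um2, n_clusters) plus the
#'   drawn `plateau`, `level` and condition metadata.
#' @export
simulate_cell_timelapse <- function(response, sensor, duration, interval,
                                    optics = optics_model(frame_shape = c(96L, 96L)),
                                    seed = NULL,
                                    render_params = synapse_render_params(),
                                    render = TRUE) {
  stopifnot(inherits(response, "response_model"),
            inherits(sensor, "tgt_sensor"),
            inherits(optics, "optics_model"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(interval) ||
      interval <= 0 || duration < interval)
    stop("`duration` and `interval` must be positive with duration >= interval",
         call. = FALSE)
  rp <- render_params
  with_seed(seed, {
    times <- seq(0, by = interval, length.out = floor(duration / interval) + 1L)
    level <- response_level(response, sensor)
    plateau <- draw_plateaus(response, level, 1L)
    acc <- plateau * (1 - exp(-times / response$tau))
    area <- rp$area_baseline + rp$area_per_unit * acc
    n_cl <- vapply(acc, function(a) n_clusters_for(rp, a), integer(1L))
    # 3x oversampled inventory so min-separation thinning can still reach
    # the target count
    inventory <- draw_cluster_inventory(max(3L * max(n_cl), 1L))
    stack <- NULL
    if (isTRUE(render)) {
      stack <- array(0, dim = c(optics$frame_shape, length(times)))
      for (k in seq_along(times)) {
        fr <- render_synapse_frame(acc[k], area[k], optics, rp, inventory)
        stack[, , k] <- fr$image
      }
    }
    structure(
      list(stack = stack,
           truth = data.frame(frame = seq_along(times), time = times,
                              accumulation = acc, area_um2 = area,
                              n_clusters = n_cl),
           plateau = plateau, level = level,
           sensor_id = sensor$id, force = sensor$mean_rupture_force,
           np_conjugated = sensor$np_conjugated,
           isotype = response$isotype,
           interval = interval, optics = optics,
           render_params = rp),
      class = "cell_timelapse"
    )
  })
}

#' Simulate per-cell endpoint frames over a sensor panel
#'
#' For each sensor, draws `n_cells` per-cell accumulation plateaus from the
#' response model and (optionally) renders the endpoint synapse frame after
#' `duration` seconds of saturating growth.
#'
#' @param response A [response_model()].
#' @param panel Non-empty list of [tgt_sensor()] objects.
#' @param n_cells Cells per sensor (>= 1).
#' @param optics An [optics_model()].
#' @param seed Optional integer seed.
#' @param duration Endpoint time in s (default 600, i.e. the 10-min course).
#' @param render_params A [synapse_render_params()].
#' @param render Render pixel frames (`TRUE`) or produce ground truth only.
#'
#' @return A list of class `condition_panel` with `truth` (one row per
#'   cell: cell, sensor_id, force, np_conjugated, level, plateau,
#'   accumulation, area_um2) and `frames` (list of matrices parallel to
#'   the truth rows, or `NULL`).
#' @export
simulate_condition_panel <- function(response, panel, n_cells,
                                     optics = optics_model(frame_shape = c(96L, 96L)),
                                     seed = NULL, duration = 600,
                                     render_params = synapse_render_params(),
                                     render = FALSE) {
  stopifnot(inherits(response, "response_model"))
  if (length(panel) == 0L)
    stop("`panel` must contain at least one sensor", call. = FALSE)
  if (!is.numeric(n_cells) || n_cells < 1L)
    stop("`n_cells` must be >= 1", call. = FALSE)
  n_cells <- as.integer(n_cells)
  rp <- render_params
  with_seed(seed, {
    rows <- list()
    frames <- if (isTRUE(render)) list() else NULL
    idx <- 0L
    for (s in panel) {
      level <- response_level(response, s)
      plateaus <- draw_plateaus(response, level, n_cells)
      acc <- plateaus * (1 - exp(-duration / response$tau))
      area <- rp$area_baseline + rp$area_per_unit * acc
      for (j in seq_len(n_cells)) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          cell = idx, sensor_id = s$id, force = s$mean_rupture_force,
          np_conjugated = s$np_conjugated, level = level,
          plateau = plateaus[j], accumulation = acc[j],
          area_um2 = area[j], stringsAsFactors = FALSE)
        if (isTRUE(render)) {
          inv <- draw_cluster_inventory(
            max(1L, 3L * n_clusters_for(rp, acc[j])))
          frames[[idx]] <- render_synapse_frame(acc[j], area[j], optics,
                                                rp, inv)$image
        }
      }
    }
    structure(
      list(truth = do.call(rbind, rows), frames = frames,
           isotype = response$isotype, duration = duration,
           optics = optics, render_params = rp),
      class = "condition_panel"
    )
  })
}
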