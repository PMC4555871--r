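# Synapse quantification: contact-area segmentation and per-frame
# accumulation metrics (background-subtracted MFI and total FI).

# Otsu's threshold on a numeric sample (maximises between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- graphics::hist(x, breaks = seq(rng[1L], rng[2L],
                                      length.out = nbins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Connected-component labelling of a logical mask (4-connectivity),
# run-based two-pass with union-find.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nlab <- 0L
  prev <- NULL  # matrix: start, end, label (runs of previous column)
  for (cc in seq_len(nc)) {
    col <- mask[, cc]
    if (!any(col)) { prev <- NULL; next }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    cur <- matrix(0L, length(idx), 3L)
    for (j in seq_along(idx)) {
      s <- starts[idx[j]]; e <- ends[idx[j]]
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab <- nlab
      labels[s:e, cc] <- lab
      if (!is.null(prev)) {
        touching <- which(prev[, 1L] <= e & prev[, 2L] >= s)
        for (k in touching) {
          ra <- find_root(lab); rb <- find_root(prev[k, 3L])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
      cur[j, ] <- c(s, e, lab)
    }
    prev <- cur
  }
  if (nlab == 0L) return(labels)
  roots <- vapply(seq_len(nlab), find_root, integer(1L))
  compact <- match(roots, sort(unique(roots)))
  nz <- labels > 0L
  labels[nz] <- compact[labels[nz]]
  labels
}

#' Segment the cell contact footprint
#'
#' Otsu's threshold on the Gaussian-smoothed frame, keeping the largest
#' connected component. A contrast guard returns an empty mask when the
#' putative foreground does not stand out from the background (blank
#' frames): foreground-background separation below
#' `min_contrast_k` x robust background noise.
#'
#' @param image Numeric matrix.
#' @param pixel_size um per pixel (for the area).
#' @param smooth_sigma Smoothing Gaussian sigma in pixels (default 1).
#' @param threshold Fixed threshold in counts; `NULL` uses Otsu.
#' @param min_contrast_k Contrast guard multiplier (default 3; for pure
#'   noise the Otsu split separates the halves of the noise distribution
#'   by ~1.6 SD, so requiring 3 robust SDs rejects blank frames).
#'
#' @return A list of class `contact_segmentation`: logical `mask`,
#'   `area_um2`, `threshold`.
#' @export
segment_contact <- function(image, pixel_size, smooth_sigma = 1,
                            threshold = NULL, min_contrast_k = 3) {
  stopifnot(is.matrix(image), pixel_size > 0)
  sm <- gaussian_blur(image, smooth_sigma)
  if (diff(range(sm)) <= 1e-9 * max(1, abs(mean(sm)))) {
    # flat frame: nothing to segment
    return(structure(
      list(mask = matrix(FALSE, nrow(image), ncol(image)), area_um2 = 0,
           threshold = if (is.null(threshold)) max(sm) else threshold),
      class = "contact_segmentation"))
  }
  thr <- if (is.null(threshold)) otsu_threshold(sm) else threshold
  mask <- sm > thr
  if (any(mask) && !all(mask) && is.null(threshold)) {
    contrast <- mean(sm[mask]) - mean(sm[!mask])
    noise <- stats::mad(sm)
    if (noise > 0 && contrast < min_contrast_k * noise)
      mask[] <- FALSE
  }
  if (all(mask)) mask[] <- FALSE  # degenerate: no background at all
  if (any(mask)) {
    labels <- label_components(mask)
    sizes <- tabulate(labels[labels > 0L])
    mask <- labels == which.max(sizes)
  }
  structure(
    list(mask = mask, area_um2 = sum(mask) * pixel_size^2,
         threshold = thr),
    class = "contact_segmentation"
  )
}

as_frame_list <- function(stack) {
  if (is.list(stack)) return(stack)
  if (is.array(stack) && length(dim(stack)) == 3L)
    return(lapply(seq_len(dim(stack)[3L]), function(k) stack[, , k]))
  if (is.matrix(stack)) return(list(stack))
  stop("`stack` must be a matrix, 3-D array or list of matrices",
       call. = FALSE)
}

#' Per-frame synapse accumulation metrics
#'
#' For each frame, background-subtracted MFI and total FI inside the mask
#' plus the mask area. The per-frame background defaults to the median of
#' a border band (frame edge, width `border_px`) outside the mask.
#'
#' @param stack 3-D array (rows x cols x frames) or list of matrices.
#' @param masks List of logical masks, one per frame (e.g. from
#'   [segment_contact()]).
#' @param interval Frame interval in s.
#' @param pixel_size um per pixel.
#' @param background Scalar background in counts; `NULL` estimates per
#'   frame from the border band.
#' @param border_px Border band width in pixels (default 5).
#'
#' @return A data frame of class `synapse_trace` with columns `frame`,
#'   `time`, `contact_area`, `synapse_mfi`, `synapse_total_fi`.
#' @export
accumulation_metrics <- function(stack, masks, interval, pixel_size,
                                 background = NULL, border_px = 5L) {
  frames <- as_frame_list(stack)
  if (length(masks) != length(frames))
    stop("`masks` must have one mask per frame", call. = FALSE)
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    mk <- masks[[k]]
    if (inherits(mk, "contact_segmentation")) mk <- mk$mask
    stopifnot(is.logical(mk), all(dim(mk) == dim(fr)))
    bg <- background
    if (is.null(bg)) {
      band <- matrix(FALSE, nrow(fr), ncol(fr))
      b <- min(border_px, floor(min(dim(fr)) / 4))
      band[c(seq_len(b), nrow(fr) - seq_len(b) + 1L), ] <- TRUE
      band[, c(seq_len(b), ncol(fr) - seq_len(b) + 1L)] <- TRUE
      band <- band & !mk
      bg <- if (any(band)) stats::median(fr[band]) else
        stats::median(as.numeric(fr))
    }
    npx <- sum(mk)
    total <- if (npx > 0L) sum(fr[mk] - bg) else 0
    rows[[k]] <- data.frame(
      frame = k, time = (k - 1L) * interval,
      contact_area = npx * pixel_size^2,
      synapse_mfi = if (npx > 0L) total / npx else 0,
      synapse_total_fi = total)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("synapse_trace", "data.frame")
  attr(out, "interval") <- interval
  out
}

#' Segment and quantify a whole time-lapse
#'
#' Convenience wrapper: per-frame [segment_contact()] (independent frames,
#' no tracking) followed by [accumulation_metrics()].
#'
#' @inheritParams accumulation_metrics
#' @param ... Passed to [segment_contact()].
#' @return A `synapse_trace` data frame; the masks are attached as
#'   attribute `masks`.
#' @export
quantify_timelapse <- function(stack, interval, pixel_size,
                               background = NULL, ...) {
  frames <- as_frame_list(stack)
  masks <- lapply(frames, segment_contact, pixel_size = pixel_size, ...)
  tr <- accumulation_metrics(frames, masks, interval, pixel_size,
                             background = background)
  attr(tr, "masks") <- masks
  tr
}

#' Fit a saturating-growth plateau to a trace
#'
#' Least-squares fit of `A * (1 - exp(-t / tau))` to a trace column.
#'
#' @param trace A `synapse_trace` (or any data frame with `time`).
#' @param value Column to fit (default `"synapse_total_fi"`).
#' @return A list with `plateau`, `tau` and `converged`.
#' @export
fit_plateau <- function(trace, value = "synapse_total_fi") {
  t <- trace$time
  y <- trace[[value]]
  a0 <- max(y)
  if (a0 <= 0) return(list(plateau = 0, tau = NA_real_, converged = FALSE))
  fit <- tryCatch(
    stats::nls(y ~ A * (1 - exp(-t / tau)),
               start = list(A = a0, tau = max(t) / 5),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(plateau = NA_real_, tau = NA_real_,
                                converged = FALSE))
  co <- stats::coef(fit)
  list(plateau = unname(co[["A"]]), tau = unname(co[["tau"]]),
       converged = TRUE)
}

#' Per-condition endpoint summary (mean, SEM, n)
#'
#' @param cells Data frame of per-cell measurements.
#' @param value Name of the value column to summarise.
#' @param by Name of the condition column (default `"condition"`).
#' @return Data frame with `condition`, `n`, `mean`, `sem`
#'   (SD/sqrt(n); `NA` when n = 1). Empty conditions (unused factor
#'   levels) are dropped with a warning.
#' @export
summarize_endpoint <- function(cells, value, by = "condition") {
  stopifnot(is.data.frame(cells), value %in% names(cells),
            by %in% names(cells))
  f <- cells[[by]]
  if (is.factor(f) && any(table(f) == 0L)) {
    warning("dropping empty condition(s): ",
            paste(levels(f)[table(f) == 0L], collapse = ", "))
    f <- droplevels(f)
  }
  groups <- split(cells[[value]], f)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(condition = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
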