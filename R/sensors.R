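# NP-TGT sensor panel: printed strand sequences, the biotin-position ->
# rupture-force map, rupture-force distributions and tether survival.

# Both strands 21 nt, written 5'->3'. The ligand strand carries the NP hapten
# through a 3' amine; the anchor strand carries the biotin whose position
# sets the rupture geometry (unzipping vs shearing) and hence the force.
TGT_LIGAND_STRAND <- "CACAGCACGGAGGCACGACAC"
TGT_ANCHOR_STRAND <- "GTGTCGTGCCTCCGTGCTGTG"

TGT_BIOTIN_POSITIONS <- c(1L, 2L, 4L, 7L, 11L, 15L, 18L, 21L)
TGT_RUPTURE_FORCES   <- c(12, 16, 23, 33, 43, 50, 54, 56)

TGT_FWHM_UNZIPPING <- 5
TGT_FWHM_SHEARING  <- 15

# FWHM = 2*sqrt(2*log(2)) * sigma for a Gaussian
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Single-stranded DNA sequence with an optional modification
#'
#' @param bases Character scalar over the strict alphabet ACGT, read 5' to 3'.
#' @param modification One of `"none"`, `"NP_3prime"` (hapten conjugate at the
#'   3' amine) or `"biotin"` (biotin at base `biotin_position`).
#' @param biotin_position 1-based base index from the 5' end; required when
#'   `modification = "biotin"`.
#'
#' @return An object of class `strand_sequence`.
#' @export
strand_sequence <- function(bases,
                            modification = c("none", "NP_3prime", "biotin"),
                            biotin_position = NA_integer_) {
  modification <- match.arg(modification)
  if (!is.character(bases) || length(bases) != 1L || nchar(bases) == 0L)
    stop("`bases` must be a non-empty character scalar", call. = FALSE)
  bases <- toupper(bases)
  if (grepl("[^ACGT]", bases))
    stop("invalid sequence: alphabet is strictly ACGT", call. = FALSE)
  if (modification == "biotin") {
    biotin_position <- as.integer(biotin_position)
    if (is.na(biotin_position) || biotin_position < 1L ||
        biotin_position > nchar(bases))
      stop("`biotin_position` must lie in [1, strand length]", call. = FALSE)
  } else {
    biotin_position <- NA_integer_
  }
  structure(
    list(bases = bases, modification = modification,
         biotin_position = biotin_position),
    class = "strand_sequence"
  )
}

strand_bases <- function(x) {
  if (inherits(x, "strand_sequence")) return(x$bases)
  if (is.character(x) && length(x) == 1L) {
    x <- toupper(x)
    if (nchar(x) == 0L || grepl("[^ACGT]", x))
      stop("invalid sequence: alphabet is strictly ACGT", call. = FALSE)
    return(x)
  }
  stop("expected a `strand_sequence` or a character scalar", call. = FALSE)
}

# Modifications are metadata only and never alter complementarity.
reverse_complement <- function(bases) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(bases, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Construct one NP-TGT sensor
#'
#' The biotin position on the anchor strand fixes the rupture geometry and
#' the mean rupture force through the printed one-to-one map: positions
#' 1, 2, 4, 7, 11, 15, 18, 21 give 12, 16, 23, 33, 43, 50, 54, 56 pN.
#' Positions 1-2 (forces 12 and 16 pN) pull in the unzipping geometry
#' (FWHM 5 pN); the remaining positions default to shearing (FWHM 15 pN).
#' The rupture mode of intermediate positions can be overridden.
#'
#' @param biotin_position One of 1, 2, 4, 7, 11, 15, 18, 21.
#' @param np_conjugated `FALSE` builds the hapten-free negative-control
#'   tether ("NC"): same DNA, no ligand.
#' @param rupture_mode `"unzipping"` or `"shearing"`; default from position.
#' @param id Optional label; a descriptive one is generated when `NULL`.
#'
#' @return An object of class `tgt_sensor` with fields `id`,
#'   `ligand_strand`, `anchor_strand`, `biotin_position`,
#'   `mean_rupture_force` (pN), `rupture_mode`, `fwhm` (pN),
#'   `np_conjugated`.
#' @export
tgt_sensor <- function(biotin_position, np_conjugated = TRUE,
                       rupture_mode = NULL, id = NULL) {
  biotin_position <- as.integer(biotin_position)
  idx <- match(biotin_position, TGT_BIOTIN_POSITIONS)
  if (is.na(idx))
    stop("`biotin_position` must be one of ",
         paste(TGT_BIOTIN_POSITIONS, collapse = ", "), call. = FALSE)
  force_pn <- TGT_RUPTURE_FORCES[idx]
  if (is.null(rupture_mode))
    rupture_mode <- if (biotin_position <= 2L) "unzipping" else "shearing"
  rupture_mode <- match.arg(rupture_mode, c("unzipping", "shearing"))
  fwhm <- if (rupture_mode == "unzipping") TGT_FWHM_UNZIPPING else
    TGT_FWHM_SHEARING
  if (is.null(id))
    id <- sprintf("TGT_%02dpN%s", force_pn,
                  if (np_conjugated) "" else "_NC")
  structure(
    list(
      id = id,
      ligand_strand = strand_sequence(
        TGT_LIGAND_STRAND,
        modification = if (np_conjugated) "NP_3prime" else "none"),
      anchor_strand = strand_sequence(TGT_ANCHOR_STRAND, "biotin",
                                      biotin_position),
      biotin_position = biotin_position,
      mean_rupture_force = force_pn,
      rupture_mode = rupture_mode,
      fwhm = fwhm,
      np_conjugated = isTRUE(np_conjugated)
    ),
    class = "tgt_sensor"
  )
}

#' @export
print.tgt_sensor <- function(x, ...) {
  cat(sprintf(
    "<tgt_sensor> %s: %g pN (%s, FWHM %g pN), biotin @%d, %s\n",
    x$id, x$mean_rupture_force, x$rupture_mode, x$fwhm,
    x$biotin_position,
    if (x$np_conjugated) "NP-conjugated" else "no NP (control)"))
  invisible(x)
}

#' Build the 8-sensor NP-TGT force panel
#'
#' @param include_control Append the 56 pN tether without NP conjugation
#'   (the negative control, "NC") after the 8 NP-conjugated sensors.
#'
#' @return A list of [tgt_sensor()] objects in ascending force order
#'   (class `tgt_panel`).
#' @export
build_sensor_panel <- function(include_control = FALSE) {
  panel <- lapply(TGT_BIOTIN_POSITIONS, tgt_sensor)
  if (isTRUE(include_control))
    panel <- c(panel, list(tgt_sensor(21L, np_conjugated = FALSE)))
  structure(panel, class = "tgt_panel")
}

#' @method as.data.frame tgt_panel
#' @export
as.data.frame.tgt_panel <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) data.frame(
    id = s$id,
    biotin_position = s$biotin_position,
    mean_rupture_force = s$mean_rupture_force,
    rupture_mode = s$rupture_mode,
    fwhm = s$fwhm,
    np_conjugated = s$np_conjugated,
    stringsAsFactors = FALSE
  )))
}

#' @export
print.tgt_panel <- function(x, ...) {
  cat(sprintf("<tgt_panel> %d sensors\n", length(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Check whether two strands anneal into a duplex
#'
#' Compares strand `a` position by position against the reverse complement
#' of strand `b` (both read 5' to 3'), aligned end to end. Mismatch
#' positions are 1-based indices along `a`.
#'
#' @param a,b Strands (`strand_sequence` or plain ACGT character scalars).
#'
#' @return A list with `is_fully_complementary`, `duplex_length`
#'   (min of the strand lengths) and `mismatch_positions`.
#' @export
check_duplex <- function(a, b) {
  sa <- strand_bases(a)
  sb_rc <- reverse_complement(strand_bases(b))
  va <- strsplit(sa, "", fixed = TRUE)[[1]]
  vb <- strsplit(sb_rc, "", fixed = TRUE)[[1]]
  len <- min(length(va), length(vb))
  mism <- which(va[seq_len(len)] != vb[seq_len(len)])
  list(
    is_fully_complementary = length(mism) == 0L &&
      length(va) == length(vb),
    duplex_length = len,
    mismatch_positions = as.integer(mism)
  )
}

#' Sample rupture forces from a sensor's distribution
#'
#' The rupture threshold is modelled as Gaussian with mean equal to the
#' sensor's nominal force and sigma = FWHM / (2 sqrt(2 log 2)), truncated
#' at 0 pN (negligible mass for the panel's forces).
#'
#' @param sensor A [tgt_sensor()].
#' @param n Number of draws (>= 0).
#' @param seed Optional integer; draws are reproducible given the seed and
#'   the caller's RNG stream is left untouched.
#'
#' @return Numeric vector of `n` forces in pN.
#' @export
sample_rupture_forces <- function(sensor, n, seed = NULL) {
  stopifnot(inherits(sensor, "tgt_sensor"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("`n` must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  mu <- sensor$mean_rupture_force
  sd <- sensor$fwhm * FWHM_TO_SIGMA
  with_seed(seed, rnorm_trunc0(n, mu, sd))
}

#' Probability that a tether survives an applied force
#'
#' P(rupture threshold > applied force) under the sensor's truncated
#' Gaussian rupture distribution. Non-increasing in the applied force.
#'
#' @param sensor A [tgt_sensor()].
#' @param applied_force Force(s) in pN, >= 0.
#'
#' @return Probabilities in `[0, 1]`, same length as `applied_force`.
#' @export
survival_probability <- function(sensor, applied_force) {
  stopifnot(inherits(sensor, "tgt_sensor"))
  if (!is.numeric(applied_force) || any(is.na(applied_force)) ||
      any(applied_force < 0))
    stop("`applied_force` must be non-negative", call. = FALSE)
  mu <- sensor$mean_rupture_force
  sd <- sensor$fwhm * FWHM_TO_SIGMA
  # survival of N(mu, sd) truncated at 0
  upper <- stats::pnorm(applied_force, mu, sd, lower.tail = FALSE)
  total <- stats::pnorm(0, mu, sd, lower.tail = FALSE)
  pmin(1, upper / total)
}

#' Full width at half maximum of a sample, from a fine histogram
#'
#' Bins the sample at `binwidth`, smooths the counts with a boxcar whose
#' length scales with the sample spread (stabilises the peak estimate),
#' interpolates the two half-maximum crossings linearly, and removes the
#' broadening introduced by the bin and the boxcar
#' (`(binwidth^2 + (smooth_bins * binwidth)^2) / 12` in variance; the
#' deconvolution is exact for a Gaussian peak and second-order for smooth
#' unimodal densities).
#'
#' @param x Numeric sample (length > 10).
#' @param binwidth Histogram bin width (default 0.05, in the sample's units).
#' @param smooth_bins Odd boxcar length in bins; `NULL` (default) picks
#'   ~0.25 sample SDs, at least 5 bins; 1 disables smoothing.
#'
#' @return The FWHM estimate (scalar).
#' @export
estimate_fwhm <- function(x, binwidth = 0.05, smooth_bins = NULL) {
  if (length(x) <= 10L) stop("need more than 10 observations", call. = FALSE)
  if (is.null(smooth_bins)) {
    smooth_bins <- max(5L, as.integer(round(0.25 * stats::sd(x) / binwidth)))
    if (smooth_bins %% 2L == 0L) smooth_bins <- smooth_bins + 1L
  }
  breaks <- seq(floor(min(x) / binwidth) * binwidth - binwidth,
                ceiling(max(x) / binwidth) * binwidth + binwidth,
                by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- as.numeric(h$counts)
  mids <- h$mids
  if (smooth_bins > 1L) {
    counts <- as.numeric(stats::filter(counts,
                                       rep(1 / smooth_bins, smooth_bins),
                                       sides = 2))
    keep <- !is.na(counts)
    counts <- counts[keep]
    mids <- mids[keep]
  }
  ipk <- which.max(counts)
  half <- counts[ipk] / 2
  below_l <- which(counts[seq_len(ipk)] < half)
  below_r <- which(counts[ipk:length(counts)] < half)
  if (length(below_l) == 0L || length(below_r) == 0L)
    stop("half-maximum crossings not bracketed by the sample", call. = FALSE)
  l <- max(below_l)                      # last bin below half, left side
  r <- ipk + min(below_r) - 1L           # first bin below half, right side
  x_left <- mids[l] + (half - counts[l]) * (mids[l + 1L] - mids[l]) /
    (counts[l + 1L] - counts[l])
  x_right <- mids[r - 1L] + (half - counts[r - 1L]) * (mids[r] - mids[r - 1L]) /
    (counts[r] - counts[r - 1L])
  raw <- x_right - x_left
  broadening <- (binwidth^2 + (smooth_bins * binwidth)^2) / 12
  sigma2_raw <- (raw * FWHM_TO_SIGMA)^2
  if (sigma2_raw > broadening)
    sqrt(sigma2_raw - broadening) / FWHM_TO_SIGMA
  else raw
}
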