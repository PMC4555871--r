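# Condition comparisons (two-tailed t-tests) and the multi-threshold
# grouping of the force panel into statistically distinct response levels.

#' Two-tailed t-test between two conditions
#'
#' Welch's unequal-variance t-test by default (robust to unequal group
#' variances; identical to the pooled Student test when variances match).
#' `var_equal = TRUE` gives the pooled-variance variant.
#'
#' @param a,b Numeric samples, each with n >= 2 and not both of zero
#'   variance.
#' @param var_equal Use the pooled-variance Student test.
#'
#' @return One-row data frame: `n1`, `n2`, `mean_a`, `mean_b`,
#'   `mean_diff` (a - b), `t`, `df`, `p`.
#' @export
t_test_two_tailed <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both samples have zero variance", call. = FALSE)
  tt <- stats::t.test(a, b, alternative = "two.sided",
                      var.equal = var_equal)
  data.frame(n1 = length(a), n2 = length(b),
             mean_a = mean(a), mean_b = mean(b),
             mean_diff = mean(a) - mean(b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' All pairwise condition comparisons
#'
#' Two-tailed t-tests for every condition pair (the cross-comparison
#' strategy). Raw p-values are reported unadjusted, with Holm-adjusted
#' values alongside for transparency. Per-pair failures (n < 2, zero
#' variance) are flagged, not fatal.
#'
#' @param samples Named list of numeric samples (>= 2 conditions).
#' @param var_equal Use pooled-variance Student tests.
#'
#' @return Data frame with one row per pair: `a`, `b`, `n1`, `n2`,
#'   `mean_diff`, `t`, `df`, `p`, `p_holm`, `ok`.
#' @export
cross_compare <- function(samples, var_equal = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            !is.null(names(samples)))
  nms <- names(samples)
  pairs <- utils::combn(nms, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    na <- pairs[1L, i]; nb <- pairs[2L, i]
    res <- tryCatch(
      t_test_two_tailed(samples[[na]], samples[[nb]], var_equal),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(a = na, b = nb, n1 = length(samples[[na]]),
                        n2 = length(samples[[nb]]), mean_diff = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        ok = FALSE, stringsAsFactors = FALSE))
    data.frame(a = na, b = nb, n1 = res$n1, n2 = res$n2,
               mean_diff = res$mean_diff, t = res$t, df = res$df,
               p = res$p, ok = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  out$p_holm[out$ok] <- stats::p.adjust(out$p[out$ok], method = "holm")
  out[, c("a", "b", "n1", "n2", "mean_diff", "t", "df", "p", "p_holm",
          "ok")]
}

#' Group force-panel sensors into response levels
#'
#' Agglomerative sweep in ascending force order: each sensor is compared
#' (two-tailed t-test) against the pooled samples of the current group and
#' starts a new group when it differs significantly. Groups are therefore
#' contiguous in force.
#'
#' By default the per-boundary significance level is Bonferroni-corrected
#' to `alpha / (k - 1)` over the `k - 1` sweep tests, so the family-wise
#' probability of a spurious split under a flat (single-level) response is
#' ~`alpha`; `boundary_adjust = "none"` uses `alpha` at every boundary.
#'
#' @param samples Named list of numeric samples, names convertible to the
#'   sensor forces in pN (each n >= 2; duplicate forces are an error).
#' @param alpha Family-wise significance level (default 0.05).
#' @param boundary_adjust `"bonferroni"` (default) or `"none"`.
#' @param var_equal Use pooled-variance Student tests.
#'
#' @return An object of class `threshold_grouping`: `table` (force,
#'   group, n, mean), `n_groups`, `alpha`, `alpha_boundary`,
#'   `boundary_p` (p-value at each force boundary).
#' @export
group_force_levels <- function(samples, alpha = 0.05,
                               boundary_adjust = c("bonferroni", "none"),
                               var_equal = FALSE) {
  boundary_adjust <- match.arg(boundary_adjust)
  stopifnot(is.list(samples), !is.null(names(samples)))
  forces <- suppressWarnings(as.numeric(names(samples)))
  if (any(is.na(forces)))
    stop("sample names must be sensor forces (pN)", call. = FALSE)
  if (anyDuplicated(forces))
    stop("duplicate sensor forces", call. = FALSE)
  if (any(vapply(samples, length, 1L) < 2L))
    stop("each sensor needs n >= 2 cells", call. = FALSE)
  ord <- order(forces)
  forces <- forces[ord]
  samples <- samples[ord]
  k <- length(samples)
  alpha_b <- if (boundary_adjust == "bonferroni" && k > 1L)
    alpha / (k - 1L) else alpha
  group <- integer(k)
  group[1L] <- 1L
  pool <- samples[[1L]]
  boundary_p <- rep(NA_real_, max(k - 1L, 0L))
  for (i in seq_len(k)[-1L]) {
    p <- t_test_two_tailed(samples[[i]], pool, var_equal)$p
    boundary_p[i - 1L] <- p
    if (p < alpha_b) {
      group[i] <- group[i - 1L] + 1L
      pool <- samples[[i]]
    } else {
      group[i] <- group[i - 1L]
      pool <- c(pool, samples[[i]])
    }
  }
  structure(
    list(table = data.frame(
           force = forces, group = group,
           n = vapply(samples, length, 1L),
           mean = vapply(samples, mean, 1)),
         n_groups = max(group), alpha = alpha, alpha_boundary = alpha_b,
         boundary_p = boundary_p),
    class = "threshold_grouping"
  )
}

#' @export
print.threshold_grouping <- function(x, ...) {
  cat(sprintf(
    "<threshold_grouping> %d group(s) at alpha = %g (per-boundary %g)\n",
    x$n_groups, x$alpha, x$alpha_boundary))
  print(x$table, row.names = FALSE)
  invisible(x)
}
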