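# Global fragmentation analysis: the per-length fragment fraction profile
# over 90-410 bp, z-scored against the healthy control panel, and the
# short-fragment (90-150 bp) enrichment call.

#' Global fragment-length profile
#'
#' The fraction of fragments at each length from 90 to 410 bp; fragments
#' outside the range are excluded from the denominator.
#'
#' @param x a `FragmentSet`, or an integer vector of fragment lengths.
#' @param range length support (default 90:410).
#' @return a `LengthProfile` data.frame (length, fraction) with attributes
#'   `n_in_range` and `n_out_of_range`.
#' @export
length_profile <- function(x, range = 90:410) {
  lens <- if (is.data.frame(x)) x$length else as.integer(x)
  in_range <- lens >= min(range) & lens <= max(range)
  if (!any(in_range)) stop("no fragments within the profile length range")
  counts <- tabulate(lens[in_range] - min(range) + 1L, nbins = length(range))
  out <- data.frame(length = range, fraction = counts / sum(counts))
  attr(out, "n_in_range") <- sum(in_range)
  attr(out, "n_out_of_range") <- sum(!in_range)
  class(out) <- c("LengthProfile", "data.frame")
  out
}

#' Per-length z-scores of a profile against the control panel
#'
#' @param profile a `LengthProfile`.
#' @param panel a `ControlPanel` (see [build_panel()]).
#' @param leave_one_out index of the panel member the profile belongs to,
#'   or `NULL` (default) for a non-panel sample; panel members are always
#'   compared to the other controls only.
#' @return data.frame (length, fraction, z).
#' @export
length_zscores <- function(profile, panel, leave_one_out = NULL) {
  stats <- panel$length
  if (!identical(as.integer(profile$length), as.integer(stats$length))) {
    stop("length range mismatch between profile and panel")
  }
  if (is.null(leave_one_out)) {
    m <- stats$mean
    s <- stats$sd
  } else {
    m <- panel$length_loo_mean[, leave_one_out]
    s <- panel$length_loo_sd[, leave_one_out]
  }
  z <- (profile$fraction - m) / s
  if (any(s == 0)) {
    warning(sum(s == 0), " length(s) with zero panel SD; z set to 0")
    z[s == 0] <- 0
  }
  data.frame(length = profile$length, fraction = profile$fraction, z = z)
}

#' Short-fragment fraction of a length profile
#' @param profile a `LengthProfile`.
#' @param window short-fragment window, default `c(90, 150)`.
#' @return scalar fraction.
#' @export
short_fraction <- function(profile, window = c(90, 150)) {
  sum(profile$fraction[profile$length >= window[1L] &
                         profile$length <= window[2L]])
}

#' Global fragmentation ctDNA call
#'
#' The sample's short-fragment (90-150 bp) fraction is z-scored against
#' the panel, and called positive when the z exceeds a threshold
#' calibrated so that at most `1 - specificity` of the panel's own
#' leave-one-out z-scores exceed it.
#'
#' @param profile a `LengthProfile`.
#' @param panel a `ControlPanel`.
#' @param specificity target specificity of the calibrated threshold.
#' @param leave_one_out panel index when calling a panel member.
#' @return a `GlobalCall`: list(short_fraction, zscore, threshold,
#'   positive).
#' @export
call_global <- function(profile, panel, specificity = 0.95,
                        leave_one_out = NULL) {
  if (panel$n < 20) {
    warning("panel has fewer than 20 controls; calibrated quantile unstable")
  }
  sf <- short_fraction(profile, panel$short_window)
  if (is.null(leave_one_out)) {
    z <- (sf - mean(panel$short_frac)) / stats::sd(panel$short_frac)
    loo_z <- panel$short_frac_loo_z
  } else {
    i <- leave_one_out
    others <- panel$short_frac[-i]
    z <- (sf - mean(others)) / stats::sd(others)
    loo_z <- panel$short_frac_loo_z[-i]
  }
  thr <- calibrate_threshold(loo_z, specificity)
  structure(list(short_fraction = sf, zscore = z, threshold = thr,
                 positive = is.finite(z) && z > thr),
            class = "GlobalCall")
}

#' Two-group comparison by Mann-Whitney U with Bonferroni adjustment
#'
#' Two-sided Mann-Whitney U test: exact when both groups have at most 7
#' values and there are no ties, otherwise the normal approximation with
#' mid-ranks and continuity correction.  The Bonferroni-adjusted p-value
#' is `min(1, p * n_tests)`.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param n_tests number of tests in the family (default 1).
#' @return list(u, p, p_adjusted, method).
#' @export
#' @examples
#' cohort_compare(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided p = 0.1
cohort_compare <- function(group_a, group_b, n_tests = 1L) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must contain at least one value")
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- length(group_a) <= 7 && length(group_b) <= 7 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_tests),
       method = if (use_exact) "exact" else "normal_approx")
}
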