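# Regional fragmentation: the ratio of short (90-150 bp) to long
# (151-220 bp) fragments (S/L ratio) in 100 kb bins, z-scored against the
# control panel, with SCNA regions masked and arm-level significance
# testing.

new_sl_profile <- function(bins, short, long) {
  out <- as.data.frame(bins)
  out$short <- as.numeric(short)
  out$long <- as.numeric(long)
  out$ratio <- ifelse(out$long > 0, out$short / out$long, NA_real_)
  out$masked <- FALSE
  for (a in c("bin_size", "chrom_sizes")) attr(out, a) <- attr(bins, a)
  class(out) <- c("SLProfile", "data.frame")
  out
}

#' Short/long fragment-ratio profile in 100 kb bins
#'
#' @param x a `FragmentSet` or a `SyntheticSample` (which carries
#'   precomputed 100 kb short/long counts).
#' @param bins 100 kb `GenomeBins` (required for a `FragmentSet`).
#' @param short_window,long_window inclusive length windows; the defaults
#'   are 90-150 bp and 151-220 bp.
#' @return an `SLProfile` data.frame: bins plus short, long, ratio
#'   (`NA` where the long count is 0) and a masked flag.
#' @export
sl_profile <- function(x, bins = NULL, short_window = c(90, 150),
                       long_window = c(151, 220)) {
  UseMethod("sl_profile")
}

#' @export
sl_profile.FragmentSet <- function(x, bins = NULL, short_window = c(90, 150),
                                   long_window = c(151, 220)) {
  stopifnot(!is.null(bins))
  s <- count_in_bins(x, bins, short_window)
  l <- count_in_bins(x, bins, long_window)
  new_sl_profile(bins, s$count, l$count)
}

#' @export
sl_profile.SyntheticSample <- function(x, bins = NULL,
                                       short_window = c(90, 150),
                                       long_window = c(151, 220)) {
  new_sl_profile(x$counts100_short, x$counts100_short$count,
                 x$counts100_long$count)
}

#' Remove a GC trend from the S/L ratios
#'
#' Residualizes the per-bin ratio against a local regression on GC,
#' preserving the profile mean.  Skipped with a warning when fewer than 50
#' bins have a defined ratio.
#'
#' @param profile an `SLProfile`.
#' @param gc per-bin GC fractions; defaults to the profile's `gc` column.
#' @return the profile with detrended ratios.
#' @export
gc_smooth <- function(profile, gc = profile$gc) {
  ok <- is.finite(profile$ratio) & is.finite(gc)
  if (sum(ok) < 50) {
    warning("fewer than 50 defined bins; GC smoothing skipped")
    return(profile)
  }
  fit <- stats::loess(profile$ratio[ok] ~ gc[ok], span = 0.75, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  fitted <- stats::predict(fit, newdata = gc[ok])
  profile$ratio[ok] <- profile$ratio[ok] - fitted + mean(profile$ratio[ok])
  profile
}

#' Z-score an S/L profile against the control panel
#'
#' `z = (ratio - panel mean) / panel SD` per bin with a defined,
#' unmasked ratio.  Panel members are compared to the other controls only
#' (leave-one-out).  By default the z-scores are then centered on the
#' sample's genome-wide median: sample-level coherent shifts of the S/L
#' ratio (between-individual variation in overall fragment size, which is
#' the global feature's signal) would otherwise displace every arm at
#' once, and the arm-level test is meant to detect regional
#' redistribution, not overall shift.
#'
#' @param profile an `SLProfile`.
#' @param panel a `ControlPanel`.
#' @param leave_one_out panel column index for a panel member, or `NULL`.
#' @param center subtract the sample's median z (default TRUE).
#' @return the profile with a `z` column.
#' @export
sl_zscores <- function(profile, panel, leave_one_out = NULL,
                       center = TRUE) {
  st <- panel$sl
  if (nrow(st$bins) != nrow(profile) ||
      !all(st$bins$chrom == profile$chrom & st$bins$start == profile$start)) {
    stop("bin set mismatch between profile and panel")
  }
  if (is.null(leave_one_out)) {
    m <- st$mean
    s <- st$sd
  } else {
    m <- panel$sl_loo_mean[, leave_one_out]
    s <- panel$sl_loo_sd[, leave_one_out]
  }
  z <- (profile$ratio - m) / s
  z[!is.finite(z)] <- NA_real_
  z[profile$masked] <- NA_real_
  if (center) z <- z - stats::median(z, na.rm = TRUE)
  profile$z <- z
  profile
}

#' Mask bins affected by called SCNAs
#'
#' Regionally enriched ctDNA over copy-number-altered regions biases the
#' S/L ratio, so such regions are excluded from regional testing.  In
#' `"arm"` mode (default) every bin of an arm harboring a called SCNA is
#' masked; `"bin"` mode masks only bins overlapping a called segment.
#'
#' @param profile an `SLProfile`.
#' @param scna_calls a data.frame of called SCNA segments
#'   (chrom/start/end, e.g. from [call_scna()]); `NULL` or empty masks
#'   nothing.
#' @param mode `"arm"` or `"bin"`.
#' @return the profile with an updated `masked` flag (masking only ever
#'   adds to existing masks).
#' @export
mask_scna <- function(profile, scna_calls, mode = c("arm", "bin")) {
  mode <- match.arg(mode)
  if (is.null(scna_calls) || nrow(scna_calls) == 0) return(profile)
  hit <- IRanges::overlapsAny(df_to_granges(profile),
                              df_to_granges(scna_calls))
  if (mode == "arm") {
    arms <- unique(profile$arm_label[hit])
    hit <- profile$arm_label %in% arms
  }
  profile$masked <- profile$masked | hit
  if (!is.null(profile$z)) profile$z[profile$masked] <- NA_real_
  profile
}

#' Arm-level regional fragmentation ctDNA call
#'
#' Per chromosome arm, the sample's bin z-scores are compared to the
#' pooled leave-one-out bin z-scores of the panel controls on that arm by
#' a two-sided Mann-Whitney U test; p-values are Bonferroni-adjusted over
#' the tested arms.  The sample is ctDNA-positive when at least one arm is
#' significant at `alpha`.  Arms with fewer than `min_bins` usable bins
#' (e.g. acrocentric p arms, or arms fully masked by SCNAs) are skipped
#' and reduce the Bonferroni denominator.
#'
#' @param profile an `SLProfile` with a `z` column ([sl_zscores()]).
#' @param panel a `ControlPanel`.
#' @param arms arms to test; defaults to all arms in the profile.
#' @param alpha significance level on adjusted p-values.
#' @param min_bins minimum usable bins per tested arm (default 5).
#' @param exclude_panel_member panel column index to drop from the pooled
#'   control z (when calling a panel member).
#' @return a `RegionalCall`: list with `per_arm` data.frame,
#'   `significant_arms`, `n_tested`, `positive` (`NA` when no arm is
#'   testable).
#' @export
regional_call <- function(profile, panel, arms = NULL, alpha = 0.05,
                          min_bins = 5L, exclude_panel_member = NULL) {
  stopifnot(!is.null(profile$z))
  arms <- arms %||% unique(profile$arm_label)
  loo_z <- panel$sl_loo_z
  if (!is.null(exclude_panel_member)) {
    loo_z <- loo_z[, -exclude_panel_member, drop = FALSE]
  }
  rows <- lapply(arms, function(a) {
    idx <- which(profile$arm_label == a & !profile$masked &
                   is.finite(profile$z))
    if (length(idx) < min_bins) return(NULL)
    ctrl <- as.vector(loo_z[idx, ])
    ctrl <- ctrl[is.finite(ctrl)]
    if (length(ctrl) < min_bins) return(NULL)
    wt <- suppressWarnings(
      stats::wilcox.test(profile$z[idx], ctrl, alternative = "two.sided",
                         exact = FALSE, correct = TRUE))
    data.frame(arm = a, n_bins = length(idx), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(structure(list(per_arm = NULL, significant_arms = character(),
                          n_tested = 0L, alpha = alpha, positive = NA),
                     class = "RegionalCall"))
  }
  per_arm <- do.call(rbind, rows)
  per_arm$p_adjusted <- pmin(1, per_arm$p * nrow(per_arm))
  per_arm$significant <- per_arm$p_adjusted < alpha
  structure(list(per_arm = per_arm,
                 significant_arms = per_arm$arm[per_arm$significant],
                 n_tested = nrow(per_arm), alpha = alpha,
                 positive = any(per_arm$significant)),
            class = "RegionalCall")
}
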