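# The control panel ("panel of normals"): per-length, per-bin and per-set
# summary statistics from healthy control samples, the reference for every
# z-score and calibrated threshold in the pipeline.  Panel members are
# always assessed leave-one-out (each control compared to the remaining
# controls), which gives the null score distributions the thresholds are
# calibrated on.

# LOO z of each element of a vector against the remaining elements.
loo_z_vector <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    (x[i] - mean(x[-i])) / stats::sd(x[-i])
  }, 0)
}

#' Build a control panel from healthy samples
#'
#' @param samples list of `SyntheticSample` objects (tumor fraction 0),
#'   or, for real data, a list of lists each carrying `lengths`,
#'   `counts50_short`, `counts100_short`, `counts100_long`, `dips`.
#' @param what which components to compute: any of `"lengths"`, `"sl"`,
#'   `"scna"`, `"dips"`.  The SCNA component (leave-one-out log2
#'   normalization + CBS of every control) dominates build time.
#' @param short_window short-fragment window (default `c(90, 150)`;
#'   `c(100, 150)` is accepted for the alternative bound).
#' @param length_range global profile support (default 90:410).
#' @param cbs_alpha,cbs_n_perm CBS parameters for segmenting the panel.
#' @param confidence,threshold_family passed to [derive_thresholds()].
#' @param seed seed for the CBS permutation streams.
#' @return a `ControlPanel` list; see Details in the package vignette.
#' @export
build_panel <- function(samples, what = c("lengths", "sl", "scna", "dips"),
                        short_window = c(90, 150), length_range = 90:410,
                        cbs_alpha = 0.01, cbs_n_perm = 2000L,
                        confidence = 0.95,
                        threshold_family = "genome", seed = 1L) {
  n <- length(samples)
  stopifnot(n >= 3)
  panel <- list(n = n, short_window = short_window,
                provenance = list(what = what, confidence = confidence,
                                  threshold_family = threshold_family,
                                  cbs_alpha = cbs_alpha,
                                  cbs_n_perm = cbs_n_perm, seed = seed))
  class(panel) <- "ControlPanel"

  if ("lengths" %in% what) {
    profs <- lapply(samples, function(s) length_profile(s$lengths,
                                                        length_range))
    frac <- vapply(profs, `[[`, numeric(length(length_range)), "fraction")
    loo <- loo_stats(frac)
    panel$length <- data.frame(length = length_range,
                               mean = rowMeans(frac),
                               sd = apply(frac, 1L, stats::sd))
    panel$length_loo_mean <- loo$mean
    panel$length_loo_sd <- loo$sd
    panel$short_frac <- vapply(profs, short_fraction, 0,
                               window = short_window)
    panel$short_frac_loo_z <- loo_z_vector(panel$short_frac)
  }

  if ("sl" %in% what) {
    profs <- lapply(samples, function(s) {
      suppressWarnings(gc_smooth(sl_profile(s)))
    })
    ratio <- vapply(profs, `[[`, numeric(nrow(profs[[1L]])), "ratio")
    loo <- loo_stats(ratio)
    panel$sl <- list(bins = profs[[1L]][c("chrom", "start", "end", "arm",
                                          "arm_label")],
                     mean = rowMeans(ratio),
                     sd = apply(ratio, 1L, stats::sd))
    panel$sl_loo_mean <- loo$mean
    panel$sl_loo_sd <- loo$sd
    loo_z <- (ratio - loo$mean) / loo$sd
    # center each control like sl_zscores() centers a sample
    panel$sl_loo_z <- sweep(loo_z, 2L,
                            apply(loo_z, 2L, stats::median, na.rm = TRUE))
  }

  if ("scna" %in% what) {
    counts <- vapply(samples, function(s)
      as.numeric(s$counts50_short$count),
      numeric(nrow(samples[[1L]]$counts50_short)))
    bins50 <- samples[[1L]]$counts50_short
    corrected <- vapply(seq_len(n), function(i)
      gc_correct_values(counts[, i], bins50$gc), numeric(nrow(counts)))
    scaled <- sweep(corrected, 2L,
                    apply(corrected, 2L, stats::median, na.rm = TRUE), "/")
    loo <- loo_stats(scaled)
    panel$counts50 <- list(
      bins = as.data.frame(bins50)[c("chrom", "start", "end", "arm",
                                     "arm_label", "gc")],
      mean = rowMeans(scaled),
      sd = apply(scaled, 1L, stats::sd))
    panel$counts50_loo_mean <- loo$mean

    # leave-one-out log2 profiles of every control, segmented by CBS;
    # the pooled segment means give the chromosome thresholds
    cbs_seeds <- derive_seeds(seed, n)
    seg_list <- lapply(seq_len(n), function(i) {
      prof <- bins50
      l2 <- log2(scaled[, i] / loo$mean[, i])
      l2[counts[, i] == 0 | !is.finite(l2)] <- NA_real_
      prof$log2 <- l2
      segs <- segment_cbs(prof, alpha = cbs_alpha, n_perm = cbs_n_perm,
                          seed = cbs_seeds[i])
      segs$control <- i
      segs
    })
    panel$control_segments <- do.call(rbind, seg_list)
    panel$thresholds <- derive_thresholds(panel$control_segments,
                                          confidence = confidence,
                                          family = threshold_family)
  }

  if ("dips" %in% what) {
    set_names <- names(samples[[1L]]$dips)
    area <- vapply(samples, function(s)
      vapply(s$dips, `[[`, 0, "dip_area"), numeric(length(set_names)))
    depth <- vapply(samples, function(s)
      vapply(s$dips, `[[`, 0, "dip_depth"), numeric(length(set_names)))
    panel$dips <- data.frame(set = set_names,
                             area_mean = rowMeans(area),
                             area_sd = apply(area, 1L, stats::sd),
                             depth_mean = rowMeans(depth),
                             depth_sd = apply(depth, 1L, stats::sd),
                             stringsAsFactors = FALSE)
    panel$dip_loo_z <- stats::setNames(lapply(seq_along(set_names),
      function(k) loo_z_vector(area[k, ])), set_names)
  }

  panel
}

#' Print a ControlPanel summary
#' @param x a `ControlPanel`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.ControlPanel <- function(x, ...) {
  cat("ControlPanel:", x$n, "controls; components:",
      paste(intersect(c("length", "sl", "counts50", "dips"), names(x)),
            collapse = ", "), "\n")
  invisible(x)
}
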