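# Coverage-dip analysis over chromatin region sets.
#
# Transcriptionally active (nucleosome-depleted) regions shed fewer cfDNA
# fragments, so sequencing coverage dips there.  Tumor-derived cfDNA
# deepens the dips over regions active in the tumor's tissue of origin.
# Profiles are built on a fixed grid: a length-normalized central window
# flanked by 20 kb on each side, all in 500 bp position bins, averaged
# over the regions of a set and normalized to flank mean 1.

# Shared constructor: normalizes the flank baseline and computes metrics.
# `central_cell_bp` is the genomic width one central grid cell represents
# (region span / central_bins after length normalization); dip_area is
# the deficit integrated over the central window in relative-coverage x
# kb units.
new_dip_profile <- function(set_name, mean_cov, flank_bins, central_bins,
                            bin_width = 500, n_regions = NA_integer_,
                            region_matrix = NULL, regions = NULL,
                            central_cell_bp = bin_width) {
  n_bins <- 2L * flank_bins + central_bins
  stopifnot(length(mean_cov) == n_bins)
  central <- seq(flank_bins + 1L, flank_bins + central_bins)
  flank <- setdiff(seq_len(n_bins), central)
  fl_mean <- mean(mean_cov[flank], na.rm = TRUE)
  if (is.finite(fl_mean) && fl_mean > 0) mean_cov <- mean_cov / fl_mean
  structure(list(
    set_name = set_name,
    bin_width = bin_width,
    flank_bins = flank_bins,
    central_bins = central_bins,
    central_cell_bp = central_cell_bp,
    grid = data.frame(position_bin = seq_len(n_bins) - flank_bins - 1L,
                      central = seq_len(n_bins) %in% central,
                      mean_cov = mean_cov),
    dip_depth = mean(mean_cov[flank], na.rm = TRUE) -
      mean(mean_cov[central], na.rm = TRUE),
    dip_area = sum(1 - mean_cov[central], na.rm = TRUE) *
      central_cell_bp / 1000,
    n_regions = n_regions,
    region_matrix = region_matrix,
    regions = regions), class = "DipProfile")
}

#' Build a coverage-dip profile for one region set
#'
#' Averages relative coverage around the regions of a set on a common
#' grid: each region's span is length-normalized to `central_bins`
#' positions and flanked by `flank` bp split into `bin`-width position
#' bins.  The averaged profile is normalized so the flank mean is 1;
#' `dip_depth` is the flank-minus-central mean coverage and `dip_area` the
#' summed coverage deficit below the flank baseline over the central
#' window (in relative-coverage x kb units).
#'
#' @param coverage a coverage track: data.frame chrom/start/end/cov
#'   (0-based half-open intervals at resolution <= `bin`).
#' @param region_set data.frame chrom/start/end of regions (one set).
#' @param flank flank width in bp on each side (default 20000).
#' @param bin position-bin width in bp (default 500).
#' @param central_bins number of grid positions the region span is scaled
#'   to (default 20).
#' @param set_name label for the set.
#' @return a `DipProfile` (keeps the per-region matrix for bias
#'   correction).
#' @export
build_dip_profile <- function(coverage, region_set, flank = 20000L,
                              bin = 500L, central_bins = 20L,
                              set_name = "region_set") {
  if (is.null(region_set) || nrow(region_set) == 0) {
    stop("empty region set")
  }
  flank_bins <- as.integer(flank / bin)
  n_bins <- 2L * flank_bins + central_bins
  n_reg <- nrow(region_set)

  # grid cell coordinates for every region x position bin
  cell_list <- lapply(seq_len(n_reg), function(i) {
    rs <- region_set$start[i]
    re <- region_set$end[i]
    len <- re - rs
    left <- seq(rs - flank, rs - bin, by = bin)
    cen_edges <- rs + len * (0:central_bins) / central_bins
    right <- seq(re, re + flank - bin, by = bin)
    data.frame(chrom = region_set$chrom[i],
               start = c(left, utils::head(cen_edges, -1L), right),
               end = c(left + bin, cen_edges[-1L], right + bin),
               region = i, pos = seq_len(n_bins))
  })
  cells <- do.call(rbind, cell_list)
  cells$start <- pmax(cells$start, 0)

  cell_gr <- df_to_granges(cells)
  track_gr <- df_to_granges(coverage)
  ov <- GenomicRanges::findOverlaps(cell_gr, track_gr)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(cell_gr)[S4Vectors::queryHits(ov)],
    IRanges::ranges(track_gr)[S4Vectors::subjectHits(ov)]))
  covv <- coverage$cov[S4Vectors::subjectHits(ov)]
  num <- rowsum(w * covv, S4Vectors::queryHits(ov))
  den <- rowsum(w, S4Vectors::queryHits(ov))
  cell_cov <- rep(NA_real_, nrow(cells))
  cell_cov[as.integer(rownames(num))] <- num / den

  mat <- matrix(cell_cov[order(cells$region, cells$pos)],
                nrow = n_reg, ncol = n_bins, byrow = TRUE)
  cell_bp <- mean(region_set$end - region_set$start) / central_bins
  new_dip_profile(set_name, colMeans(mat, na.rm = TRUE), flank_bins,
                  central_bins, bin_width = bin, n_regions = n_reg,
                  region_matrix = mat, regions = region_set,
                  central_cell_bp = cell_bp)
}

#' Correct a dip profile for copy-number and GC bias
#'
#' Regions overlapping called SCNA segments are either rescaled by the
#' CN-implied coverage factor `2^segment_log2` (restoring the diploid
#' baseline) or excluded from the averaging.  Optionally the averaged
#' profile is residualized against a per-position GC covariate by local
#' regression (mean preserved).
#'
#' @param profile a `DipProfile` built with [build_dip_profile()] (the
#'   per-region matrix is required for SCNA handling).
#' @param gc optional numeric GC fraction per position bin.
#' @param scna_segments optional `SegmentTable` of called SCNAs (from
#'   [call_scna()] / [segment_cbs()]), columns chrom/start/end/mean_log2.
#' @param mode `"rescale"` (default) or `"exclude"`.
#' @return a corrected `DipProfile`.
#' @export
correct_dip_bias <- function(profile, gc = NULL, scna_segments = NULL,
                             mode = c("rescale", "exclude")) {
  mode <- match.arg(mode)
  mat <- profile$region_matrix
  regions <- profile$regions
  if (!is.null(scna_segments) && nrow(scna_segments) &&
      !is.null(mat) && !is.null(regions)) {
    ov <- GenomicRanges::findOverlaps(df_to_granges(regions),
                                      df_to_granges(scna_segments))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (mode == "rescale") {
      for (k in seq_along(qh)) {
        mat[qh[k], ] <- mat[qh[k], ] / 2^scna_segments$mean_log2[sh[k]]
      }
    } else {
      keep <- setdiff(seq_len(nrow(mat)), unique(qh))
      if (!length(keep)) stop("all regions excluded by SCNA overlap")
      mat <- mat[keep, , drop = FALSE]
      regions <- regions[keep, , drop = FALSE]
    }
  }
  mean_cov <- if (!is.null(mat)) colMeans(mat, na.rm = TRUE)
              else profile$grid$mean_cov
  if (!is.null(gc)) {
    stopifnot(length(gc) == length(mean_cov))
    m0 <- mean(mean_cov, na.rm = TRUE)
    corrected <- gc_correct_values(mean_cov, gc)
    mean_cov <- corrected * m0 / mean(corrected, na.rm = TRUE)
  }
  new_dip_profile(profile$set_name, mean_cov, profile$flank_bins,
                  profile$central_bins, bin_width = profile$bin_width,
                  n_regions = if (!is.null(mat)) nrow(mat) else profile$n_regions,
                  region_matrix = mat, regions = regions,
                  central_cell_bp = profile$central_cell_bp %||% profile$bin_width)
}

#' Chromatin-based ctDNA call over multiple region sets
#'
#' For each region set the sample's dip area is z-scored against the
#' control panel (leave-one-out statistics for panel members); a set is
#' significant when its z exceeds the one-sided prediction threshold
#' `qt(1 - alpha_per_set, n - 1) * sqrt(1 + 1/n)` -- the t-based bound
#' that keeps the per-set false-positive rate at `alpha_per_set` when
#' the panel mean and SD are themselves estimates.  The sample is ctDNA-positive when at
#' least `min_sets` sets are significant -- the two-set rule that
#' restores >= 95% specificity (a single-set rule lets through
#' occasional single-set excursions in healthy samples).
#'
#' @param profiles named list of `DipProfile` for one sample (>= 2 sets).
#' @param panel a `ControlPanel` with a `dips` component
#'   (see [build_panel()]).
#' @param alpha_per_set per-set one-sided significance level.
#' @param min_sets minimum number of significant sets for positivity.
#' @return a `ChromatinCall`: list with `per_set` data.frame (set,
#'   dip_depth, dip_area, z_depth, z_area, threshold, significant),
#'   `n_significant`, `positive`.
#' @export
chromatin_call <- function(profiles, panel, alpha_per_set = 0.05,
                           min_sets = 2L) {
  if (length(profiles) < 2L) stop("at least two region sets are required")
  stats <- panel$dips
  sets <- names(profiles)
  missing <- setdiff(sets, stats$set)
  if (length(missing)) {
    stop("panel has no dip statistics for set(s): ",
         paste(missing, collapse = ", "))
  }
  thr <- stats::qt(1 - alpha_per_set, df = panel$n - 1) *
    sqrt(1 + 1 / panel$n)
  rows <- lapply(sets, function(nm) {
    p <- profiles[[nm]]
    s <- stats[stats$set == nm, ]
    z_area <- (p$dip_area - s$area_mean) / s$area_sd
    z_depth <- (p$dip_depth - s$depth_mean) / s$depth_sd
    data.frame(set = nm, dip_depth = p$dip_depth, dip_area = p$dip_area,
               z_depth = z_depth, z_area = z_area, threshold = thr,
               significant = is.finite(z_area) & z_area > thr,
               stringsAsFactors = FALSE)
  })
  per_set <- do.call(rbind, rows)
  n_sig <- sum(per_set$significant)
  structure(list(per_set = per_set, n_significant = n_sig,
                 min_sets = min_sets,
                 positive = n_sig >= min_sets),
            class = "ChromatinCall")
}
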