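# Genome-wide SCNA calling on short (90-150 bp) fragment counts in 50 kb
# bins: GC correction, panel normalization, circular binary segmentation
# (CBS) with merging disabled, chromosome-specific limit-of-blank (LOB)
# thresholds, and genome-wide plus focal calls.

#' GC-correct and panel-normalize binned counts to a log2 ratio profile
#'
#' Counts are residualized against GC by local regression, scaled to
#' sample median 1, divided by the panel's per-bin expected value, and
#' log2-transformed.  Zero-count bins (and bins without a panel
#' expectation) are undefined.
#'
#' @param counts `BinnedCounts` of short-fragment counts in 50 kb bins.
#' @param panel a `ControlPanel` with a `counts50` component.
#' @param gc per-bin GC; defaults to the `gc` column of `counts`.
#' @param leave_one_out panel column index when normalizing a panel
#'   member (its own counts are removed from the panel expectation).
#' @return a `Log2Profile` data.frame: the bins plus `log2` (NA where
#'   undefined).
#' @export
log2_normalize <- function(counts, panel, gc = counts$gc,
                           leave_one_out = NULL) {
  pb <- panel$counts50
  if (nrow(pb$bins) != nrow(counts) ||
      !all(pb$bins$chrom == counts$chrom & pb$bins$start == counts$start)) {
    stop("bin set mismatch between counts and panel")
  }
  expected <- if (is.null(leave_one_out)) pb$mean
              else panel$counts50_loo_mean[, leave_one_out]
  corrected <- gc_correct_values(as.numeric(counts$count), gc)
  med <- stats::median(corrected[counts$count > 0], na.rm = TRUE)
  scaled <- corrected / med
  l2 <- log2(scaled / expected)
  l2[counts$count == 0 | !is.finite(l2)] <- NA_real_
  out <- as.data.frame(counts)
  out$log2 <- l2
  for (a in c("bin_size", "chrom_sizes")) attr(out, a) <- attr(counts, a)
  class(out) <- c("Log2Profile", "data.frame")
  out
}

#' Segment a log2 profile by circular binary segmentation
#'
#' Recursive change-point search: within each segment the maximal
#' circular t-statistic over all arcs is tested against `n_perm`
#' permutations; a split is accepted at permutation p < `alpha` and the
#' resulting sub-segments are searched recursively.  Merging of adjacent
#' segments is disabled by default (`merge_threshold = 0`); a positive
#' threshold would re-merge neighbors whose means differ by less than it.
#' Undefined bins are dropped before segmentation; segments are
#' contiguous over the defined bins of each chromosome.
#'
#' @param profile a `Log2Profile` (or any bins data.frame with a `log2`
#'   column).
#' @param alpha permutation significance level per split (default 0.01).
#' @param n_perm permutations per split test (default 10000; early
#'   stopping once a split can no longer reach significance).
#' @param merge_threshold 0 disables post-hoc merging.
#' @param seed RNG seed making the permutation test, and hence the
#'   segment table, bit-reproducible.
#' @param min_width minimum segment width in bins (default 2).
#' @return a `SegmentTable` data.frame: chrom, start, end, n_bins,
#'   mean_log2; the attribute `bin_segment` maps every profile row to its
#'   segment id (NA for undefined bins).
#' @export
segment_cbs <- function(profile, alpha = 0.01, n_perm = 10000L,
                        merge_threshold = 0, seed = NULL, min_width = 2L) {
  with_seed(seed, {
    seg_id <- rep(NA_integer_, nrow(profile))
    segs <- list()
    next_id <- 1L
    for (ch in unique(profile$chrom)) {
      rows <- which(profile$chrom == ch & is.finite(profile$log2))
      if (!length(rows)) next
      x <- profile$log2[rows]
      bounds <- cbs_recurse(x, alpha, as.integer(n_perm),
                            as.integer(min_width))
      if (merge_threshold > 0 && nrow(bounds) > 1L) {
        bounds <- merge_segments(x, bounds, merge_threshold)
      }
      for (k in seq_len(nrow(bounds))) {
        idx <- rows[bounds$from[k]:bounds$to[k]]
        segs[[next_id]] <- data.frame(
          chrom = ch,
          start = profile$start[idx[1L]],
          end = profile$end[idx[length(idx)]],
          n_bins = length(idx),
          mean_log2 = mean(profile$log2[idx]),
          stringsAsFactors = FALSE)
        seg_id[idx] <- next_id
        next_id <- next_id + 1L
      }
    }
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    attr(out, "bin_segment") <- seg_id
    attr(out, "params") <- list(alpha = alpha, n_perm = n_perm,
                                merge_threshold = merge_threshold,
                                min_width = min_width, seed = seed)
    class(out) <- c("SegmentTable", "data.frame")
    out
  })
}

# Recursive split search on one chromosome; returns data.frame(from, to)
# of 1-based inclusive bounds into x.
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2L * min_width || stats::sd(x) < 1e-12) {
    return(data.frame(from = 1L, to = n))
  }
  res <- cbs_split(x, alpha, n_perm, min_width)
  if (!res$significant) return(data.frame(from = 1L, to = n))
  i <- res$i  # arc is x[(i+1)..j]
  j <- res$j
  parts <- list()
  if (i > 0L) parts <- c(parts, list(c(1L, i)))
  parts <- c(parts, list(c(i + 1L, j)))
  if (j < n) parts <- c(parts, list(c(j + 1L, n)))
  out <- lapply(parts, function(p) {
    sub <- cbs_recurse(x[p[1L]:p[2L]], alpha, n_perm, min_width)
    sub$from <- sub$from + p[1L] - 1L
    sub$to <- sub$to + p[1L] - 1L
    sub
  })
  do.call(rbind, out)
}

merge_segments <- function(x, bounds, threshold) {
  repeat {
    if (nrow(bounds) < 2L) return(bounds)
    means <- vapply(seq_len(nrow(bounds)), function(k)
      mean(x[bounds$from[k]:bounds$to[k]]), 0)
    d <- abs(diff(means))
    if (!length(d) || min(d) >= threshold) return(bounds)
    k <- which.min(d)
    bounds$to[k] <- bounds$to[k + 1L]
    bounds <- bounds[-(k + 1L), , drop = FALSE]
  }
}

#' Chromosome-specific limit-of-blank calling thresholds
#'
#' From the segment-mean log2 values of the segmented control panel, per
#' chromosome: `LOB_gain = mean + z * SD`, `LOB_loss = mean - z * SD`.
#' With `family = "genome"` (default) the confidence is interpreted per
#' sample: z is Bonferroni-adjusted over the 2 x K chromosome tails a
#' genome-wide screen tests, so ~(1 - confidence) of healthy samples
#' carry any call at all.  `family = "chromosome"` applies the classical
#' per-measurement limit of blank (z = 1.645 at 95%) to each chromosome
#' separately.
#'
#' @param control_segments data.frame with columns `chrom` and
#'   `mean_log2` (and, if available, `start`/`end`), pooling the CBS
#'   segment means of the panel controls.
#' @param confidence coverage of the blank interval (default 0.95).
#' @param family `"genome"` or `"chromosome"` (see above).
#' @param min_segments chromosomes with fewer control segments fall back
#'   to the pooled genome-wide mean/SD, with a warning.
#' @param min_size segments shorter than this (bp) are excluded from the
#'   blank distribution, matching the size restriction of [call_scna()]:
#'   with merging disabled, CBS occasionally emits short spurious
#'   segments whose means are extreme by selection, and these would
#'   otherwise inflate the blank SD.
#' @return a `ChromThresholds` data.frame: chrom, lob_loss, lob_gain,
#'   n_segments.
#' @export
derive_thresholds <- function(control_segments, confidence = 0.95,
                              family = c("genome", "chromosome"),
                              min_segments = 20L, min_size = 2e6) {
  family <- match.arg(family)
  if (!is.null(control_segments$start) && !is.null(control_segments$end)) {
    keep <- (control_segments$end - control_segments$start) >= min_size
    if (any(keep)) control_segments <- control_segments[keep, , drop = FALSE]
  }
  chroms <- unique(control_segments$chrom)
  k_tails <- 2L * length(chroms)
  z <- if (family == "genome") {
    stats::qnorm(1 - (1 - confidence) / k_tails)
  } else {
    stats::qnorm(confidence)
  }
  pooled_m <- mean(control_segments$mean_log2)
  pooled_s <- stats::sd(control_segments$mean_log2)
  rows <- lapply(chroms, function(ch) {
    v <- control_segments$mean_log2[control_segments$chrom == ch]
    if (length(v) < min_segments) {
      warning("chromosome ", ch, " has ", length(v),
              " control segments; using genome-wide threshold")
      m <- pooled_m
      s <- pooled_s
    } else {
      m <- mean(v)
      s <- stats::sd(v)
    }
    data.frame(chrom = ch,
               lob_loss = min(m - z * s, -1e-6),
               lob_gain = max(m + z * s, 1e-6),
               n_segments = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(confidence = confidence, family = family,
                                  z = z, n_controls_segments =
                                    nrow(control_segments))
  class(out) <- c("ChromThresholds", "data.frame")
  out
}

#' Call genome-wide SCNAs from a segment table
#'
#' A segment is a gain when its mean log2 exceeds the chromosome's
#' `LOB_gain`, a loss when below `LOB_loss`; all other segments are
#' neutral and not reported.  Only segments spanning at least `min_size`
#' are eligible: genome-wide SCNAs are arm-scale events, and with
#' merging disabled CBS occasionally emits short spurious segments whose
#' means are extreme by construction (the maximal-arc selection);
#' sub-`min_size` events are the domain of [call_focal()], which demands
#' independent evidence (census overlap and a neighbor-delta above the
#' LOB, or a three-copy amplitude).
#'
#' @param segments a `SegmentTable`.
#' @param thresholds a `ChromThresholds`.
#' @param min_size minimum segment span in bp (default 2 Mb).
#' @return an `SCNACall` data.frame: the called segments plus
#'   `direction` (`"gain"`/`"loss"`).
#' @export
call_scna <- function(segments, thresholds, min_size = 2e6) {
  miss <- setdiff(unique(segments$chrom), thresholds$chrom)
  if (length(miss)) {
    stop("no thresholds for chromosome(s): ", paste(miss, collapse = ", "))
  }
  idx <- match(segments$chrom, thresholds$chrom)
  big <- (segments$end - segments$start) >= min_size
  direction <- ifelse(segments$mean_log2 > thresholds$lob_gain[idx], "gain",
                      ifelse(segments$mean_log2 < thresholds$lob_loss[idx],
                             "loss", "neutral"))
  direction[!big] <- "neutral"
  out <- segments[direction != "neutral", , drop = FALSE]
  out$direction <- direction[direction != "neutral"]
  rownames(out) <- NULL
  class(out) <- c("SCNACall", "data.frame")
  out
}

#' Call focal SCNAs and focal amplifications
#'
#' A segment is a focal SCNA when it spans less than `max_span` (20 Mb),
#' overlaps between 1 and `max_genes` (100) cancer-census genes, and its
#' mean log2 differs from the mean of the neighboring `neighbor_window`
#' (20 Mb, bin-weighted over flanking segments, one-sided at chromosome
#' ends) by more than the chromosome's LOB in the corresponding
#' direction.  Independently, a segment whose log2 exceeds its neighbors
#' by at least `amp_delta` (0.58, ~ three copies) is a focal
#' amplification even without census overlap; by default the span limit
#' is not imposed on this rule (`strict_span = FALSE`).
#'
#' @param segments a `SegmentTable`.
#' @param thresholds a `ChromThresholds`.
#' @param census cancer gene census data.frame chrom/start/end/gene.
#' @param max_span focal size limit in bp.
#' @param neighbor_window flank width in bp for the neighbor mean.
#' @param amp_delta log2 excess defining a focal amplification.
#' @param max_genes maximum census genes overlapped.
#' @param strict_span also require `< max_span` for the amplification
#'   rule.
#' @return a `FocalCall` data.frame: chrom, start, end, size,
#'   mean_log2, neighbor_delta, census_gene_count, kind
#'   (`"focal_gain"`, `"focal_loss"`, `"focal_amplification"`).
#' @export
call_focal <- function(segments, thresholds, census, max_span = 20e6,
                       neighbor_window = 20e6, amp_delta = 0.58,
                       max_genes = 100L, strict_span = FALSE) {
  miss <- setdiff(unique(segments$chrom), thresholds$chrom)
  if (length(miss)) {
    stop("no thresholds for chromosome(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(segments) == 0) {
    return(structure(data.frame(), class = c("FocalCall", "data.frame")))
  }
  bad_census <- setdiff(unique(segments$chrom), unique(census$chrom))
  # census need not cover every chromosome, but must share the namespace
  if (length(bad_census) == length(unique(segments$chrom))) {
    stop("census chromosome names do not match segments")
  }
  n_genes <- GenomicRanges::countOverlaps(df_to_granges(segments),
                                          df_to_granges(census))
  rows <- lapply(seq_len(nrow(segments)), function(k) {
    seg <- segments[k, ]
    others <- segments[segments$chrom == seg$chrom &
                         seq_len(nrow(segments)) != k, , drop = FALSE]
    side_mean <- function(win_start, win_end) {
      if (win_end <= win_start || nrow(others) == 0) return(NA_real_)
      ov_w <- pmax(0, pmin(others$end, win_end) -
                     pmax(others$start, win_start))
      use <- ov_w > 0
      if (!any(use)) return(NA_real_)
      w <- others$n_bins[use] * ov_w[use] / (others$end[use] -
                                               others$start[use])
      sum(w * others$mean_log2[use]) / sum(w)
    }
    left <- side_mean(seg$start - neighbor_window, seg$start)
    right <- side_mean(seg$end, seg$end + neighbor_window)
    neighbor <- mean(c(left, right), na.rm = TRUE)
    delta <- seg$mean_log2 - neighbor
    size <- seg$end - seg$start
    thr <- thresholds[thresholds$chrom == seg$chrom, ]
    kind <- NA_character_
    if (is.finite(delta)) {
      if (delta >= amp_delta && (!strict_span || size < max_span)) {
        kind <- "focal_amplification"
      } else if (size < max_span && n_genes[k] >= 1L &&
                 n_genes[k] <= max_genes) {
        if (delta > thr$lob_gain) kind <- "focal_gain"
        else if (delta < thr$lob_loss) kind <- "focal_loss"
      }
    }
    if (is.na(kind)) return(NULL)
    data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
               size = size, mean_log2 = seg$mean_log2,
               neighbor_delta = delta, census_gene_count = n_genes[k],
               kind = kind, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  class(out) <- c("FocalCall", "data.frame")
  out
}

#' Write a segment table in SEG format
#' @param segments SegmentTable.
#' @param sample_id sample label (first SEG column).
#' @param path output path.
#' @export
write_seg <- function(segments, sample_id, path) {
  df <- data.frame(sample = sample_id, chrom = segments$chrom,
                   start = segments$start, end = segments$end,
                   n_bins = segments$n_bins, log2 = segments$mean_log2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
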