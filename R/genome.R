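#' Tile a genome into fixed-size bins with arm labels and exclusions
#'
#' Produces the contiguous, non-overlapping bin grid underlying all
#' read-depth and fragmentation analyses.  Coordinates are 0-based,
#' half-open (BED convention) throughout the package.  Each chromosome is
#' tiled from 0 in steps of `bin_size`; the final bin may be shorter.  Bins
#' are labelled `p` or `q` by comparing the bin midpoint with the centromere
#' position, and bins overlapping any exclusion interval (ENCODE-blacklist
#' style regions, assembly gaps) are dropped.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), or a
#'   two-column data.frame (chrom, size) as read from a `.chrom.sizes` file.
#' @param bin_size bin width in bp (50000 for SCNA calling, 100000 for
#'   regional fragmentation).
#' @param arm_table data.frame with columns `chrom` and `centromere` (bp
#'   position splitting the p and q arm).  Every chromosome in
#'   `chrom_sizes` must be present.
#' @param exclusions optional list of interval data.frames
#'   (chrom/start/end, 0-based half-open) or `GRanges`; bins overlapping any
#'   interval are removed (any-overlap rule).
#' @return A `GenomeBins` data.frame with columns chrom, start, end, arm and
#'   attributes `bin_size` and `chrom_sizes`.
#' @export
#' @examples
#' gb <- tile_genome(c(chrT = 120000), 50000,
#'                   data.frame(chrom = "chrT", centromere = 60000))
#' nrow(gb)  # 3 bins, last of length 20000
tile_genome <- function(chrom_sizes, bin_size, arm_table, exclusions = NULL) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2L]]),
                                   as.character(chrom_sizes[[1L]]))
  }
  stopifnot(bin_size > 0, length(chrom_sizes) > 0)
  missing_arm <- setdiff(names(chrom_sizes), arm_table$chrom)
  if (length(missing_arm)) {
    stop("no centromere position for chromosome(s): ",
         paste(missing_arm, collapse = ", "))
  }
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    cen <- arm_table$centromere[match(ch, arm_table$chrom)]
    mids <- (starts + ends) / 2
    data.frame(chrom = ch, start = starts, end = ends,
               arm = ifelse(mids < cen, "p", "q"),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  bins$arm_label <- paste0(sub("^chr", "", bins$chrom), bins$arm)
  structure_bins <- function(b) {
    rownames(b) <- NULL
    attr(b, "bin_size") <- bin_size
    attr(b, "chrom_sizes") <- chrom_sizes
    class(b) <- c("GenomeBins", "data.frame")
    b
  }
  bins <- structure_bins(bins)
  if (!is.null(exclusions)) bins <- apply_exclusions(bins, exclusions)
  bins
}

#' Remove fragments or bins overlapping exclusion intervals
#'
#' Any-overlap rule: an item is removed if it overlaps any interval of any
#' exclusion set by at least one base.  Removal counts are reported via a
#' message and recorded in the `n_excluded` attribute.
#'
#' @param items a `FragmentSet` or `GenomeBins` (or any chrom/start/end
#'   data.frame with 0-based half-open coordinates).
#' @param exclusions a single interval set or a list of them; each either a
#'   chrom/start/end data.frame or a `GRanges`.
#' @return object of the same type with overlapping rows removed.
#' @export
apply_exclusions <- function(items, exclusions) {
  if (is.null(exclusions) || (is.list(exclusions) && !length(exclusions)) ||
      (is.data.frame(exclusions) && !nrow(exclusions))) {
    return(items)
  }
  if (is.data.frame(exclusions) || methods::is(exclusions, "GRanges")) {
    exclusions <- list(exclusions)
  }
  gr_list <- lapply(exclusions, function(e) {
    if (methods::is(e, "GRanges")) e else df_to_granges(e)
  })
  excl <- suppressWarnings(do.call(c, gr_list))
  items_gr <- df_to_granges(items)
  excl_chroms <- unique(as.character(GenomicRanges::seqnames(excl)))
  shared <- intersect(excl_chroms, unique(items$chrom))
  if (!length(shared) && length(excl) > 0 && nrow(items) > 0) {
    stop("chromosome name mismatch between items (",
         paste(utils::head(unique(items$chrom), 3), collapse = ","),
         ") and exclusions (",
         paste(utils::head(excl_chroms, 3), collapse = ","), ")")
  }
  hits <- IRanges::overlapsAny(items_gr, excl)
  out <- items[!hits, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("bin_size", "chrom_sizes", "sample_id", "provenance")) {
    if (!is.null(attr(items, a))) attr(out, a) <- attr(items, a)
  }
  attr(out, "n_excluded") <- sum(hits)
  class(out) <- class(items)
  out
}

#' Annotate bins with GC content
#'
#' Computes the per-bin GC fraction either from a reference sequence source
#' (a named `DNAStringSet`/character vector of chromosome sequences) or from
#' a supplied per-bin GC table.  N bases are excluded from the denominator.
#'
#' @param bins a `GenomeBins` object.
#' @param reference named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences, or a numeric vector with one GC value per bin.
#' @return the bins with a `gc` column (fraction in `[0, 1]`, `NA` for
#'   all-N bins).
#' @export
gc_annotate <- function(bins, reference) {
  if (is.numeric(reference)) {
    stopifnot(length(reference) == nrow(bins))
    bins$gc <- as.numeric(reference)
    return(bins)
  }
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  gc <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    if (!ch %in% names(reference)) {
      stop("reference has no sequence for chromosome ", ch)
    }
    seq <- reference[[ch]]
    idx <- which(bins$chrom == ch)
    if (any(bins$end[idx] > length(seq))) {
      stop("bin beyond reference length on ", ch)
    }
    v <- Biostrings::Views(seq, start = bins$start[idx] + 1L,
                           end = bins$end[idx])
    freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    denom <- rowSums(freq)
    gc[idx] <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
  }
  bins$gc <- gc
  bins
}

#' Write genome bins (with optional counts) to a TSV file
#' @param bins GenomeBins, possibly carrying gc/count columns.
#' @param path output file.
#' @export
write_bins_tsv <- function(bins, path) {
  utils::write.table(as.data.frame(bins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
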