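#' Load cfDNA fragments from a BAM file or a fragment interval table
#'
#' Reads paired-end fragment records and applies the standard cfDNA
#' filters: mapping quality at least `min_mapq` (default 30) and removal of
#' duplicate fragments (identical chrom, start, end).  For BAM input only
#' proper pairs are used and each template is counted once (via its
#' first-in-pair read); the fragment is the outer template span.  BAM
#' 1-based positions are converted to the package-wide 0-based half-open
#' convention.  Table input is a TSV/BED with columns chrom, start, end and
#' optionally mapq (assumed already 0-based half-open).
#'
#' @param source path to a coordinate-sorted indexed BAM, or to a TSV/BED
#'   fragment table, or a data.frame with columns chrom, start, end
#'   (optionally mapq).
#' @param min_mapq minimum mapping quality retained (default 30).
#' @param dedup collapse duplicate (chrom, start, end) fragments (default
#'   TRUE).
#' @param sample_id optional sample label; defaults to the file basename.
#' @return A `FragmentSet`: data.frame with columns chrom, start, end,
#'   length, mapq, carrying `sample_id` and `provenance` attributes.
#' @export
load_fragments <- function(source, min_mapq = 30L, dedup = TRUE,
                           sample_id = NULL) {
  if (is.character(source)) {
    if (!file.exists(source)) stop("cannot read fragment source: ", source)
    sample_id <- sample_id %||% sub("\\.(bam|bed|tsv|txt)(\\.gz)?$", "",
                                    basename(source), ignore.case = TRUE)
    if (grepl("\\.bam$", source, ignore.case = TRUE)) {
      df <- read_bam_fragments(source)
    } else {
      df <- read_fragment_table(source)
    }
  } else if (is.data.frame(source)) {
    df <- source
    if (is.null(df$mapq)) df$mapq <- rep(60L, nrow(df))
    sample_id <- sample_id %||% "sample"
  } else {
    stop("cannot read fragment source of class ", class(source)[1L])
  }

  n_nonpos <- sum(df$end <= df$start)
  if (n_nonpos > 0) {
    warning(n_nonpos, " non-positive-length fragment(s) skipped")
    df <- df[df$end > df$start, , drop = FALSE]
  }
  df <- df[df$mapq >= min_mapq, , drop = FALSE]
  if (isTRUE(dedup)) {
    df <- df[!duplicated(df[c("chrom", "start", "end")]), , drop = FALSE]
  }
  df$length <- df$end - df$start
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end",
                                                "length", "mapq")]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  attr(df, "provenance") <- list(min_mapq = min_mapq, dedup = dedup,
                                 n_skipped_nonpositive = n_nonpos)
  class(df) <- c("FragmentSet", "data.frame")
  df
}

# Outer template spans of proper pairs, one record per template: the
# leftmost mate of an FR pair carries TLEN > 0, so keeping isize > 0 counts
# each template exactly once and gives fragment = [pos-1, pos-1+isize).
read_bam_fragments <- function(path) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("rname", "pos", "isize", "mapq"))
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  keep <- !is.na(res$isize) & !is.na(res$pos) & res$isize > 0L
  start <- res$pos[keep] - 1L
  data.frame(chrom = as.character(res$rname[keep]),
             start = as.integer(start),
             end = as.integer(start + res$isize[keep]),
             mapq = as.integer(ifelse(is.na(res$mapq[keep]), 0L,
                                      res$mapq[keep])),
             stringsAsFactors = FALSE)
}

read_fragment_table <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("cannot parse fragment table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mapq = integer()))
  }
  # allow a header line
  if (!is.numeric(df[[2L]])) {
    names(df) <- as.character(unlist(df[1L, ]))
    df <- df[-1L, , drop = FALSE]
    df[[2L]] <- as.numeric(df[[2L]])
    df[[3L]] <- as.numeric(df[[3L]])
    if (ncol(df) >= 4L) df[[4L]] <- as.numeric(df[[4L]])
  }
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  out$mapq <- if (ncol(df) >= 4L) as.integer(df[[4L]]) else 60L
  out
}

#' Count fragments in genome bins by midpoint, with a length window
#'
#' Each fragment is assigned to the single bin containing its midpoint;
#' fragments whose length falls outside `length_window` (inclusive bounds)
#' or whose midpoint falls in no retained bin are not counted.
#'
#' @param frags a `FragmentSet`.
#' @param bins a `GenomeBins` object.
#' @param length_window `c(min, max)` in bp, or `"all"` for no length
#'   filter.  The standard windows are `c(90, 150)` (short) and
#'   `c(151, 220)` (long).
#' @return A `BinnedCounts` object: the bins with a `count` column and
#'   attributes `length_window`, `n_assigned`, `n_unassigned`.
#' @export
count_in_bins <- function(frags, bins, length_window = "all") {
  if (is.numeric(length_window)) {
    stopifnot(length(length_window) == 2L)
    keep <- frags$length >= length_window[1L] & frags$length <= length_window[2L]
    frags <- frags[keep, , drop = FALSE]
  }
  counts <- integer(nrow(bins))
  n_assigned <- 0L
  if (nrow(frags) > 0 && nrow(bins) > 0) {
    mid <- floor((frags$start + frags$end) / 2)
    mid_gr <- GenomicRanges::GRanges(frags$chrom,
                                     IRanges::IRanges(mid + 1L, mid + 1L))
    hits <- GenomicRanges::findOverlaps(mid_gr, df_to_granges(bins),
                                        select = "first")
    ok <- !is.na(hits)
    tab <- tabulate(hits[ok], nbins = nrow(bins))
    counts <- as.integer(tab)
    n_assigned <- sum(ok)
  }
  out <- bins
  out$count <- counts
  attr(out, "length_window") <- length_window
  attr(out, "n_assigned") <- n_assigned
  attr(out, "n_unassigned") <- nrow(frags) - n_assigned
  class(out) <- unique(c("BinnedCounts", class(bins)))
  out
}

#' Write a FragmentSet as a 4-column TSV (chrom, start, end, mapq)
#' @param frags FragmentSet.
#' @param path output path.
#' @export
write_fragments_tsv <- function(frags, path) {
  utils::write.table(frags[c("chrom", "start", "end", "mapq")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
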