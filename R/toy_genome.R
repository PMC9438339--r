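#' A deterministic desk-scale toy genome
#'
#' A synthetic 22-autosome genome (~99 Mb total) used by the cohort
#' generator and the test suite.  Non-acrocentric chromosomes have 2.5 Mb p
#' and q arms; chr13, 14, 15, 21 and 22 have short 0.3 Mb p arms, so that
#' (as for real acrocentric chromosomes) their p arms drop out of arm-level
#' testing and 39 usable autosome arms remain.  The genome carries a
#' deterministic smooth GC landscape over 0.30-0.60, a small exclusion list
#' emulating blacklist/gap regions, six toy chromatin region sets and a toy
#' cancer gene census.  Everything is generated in code; none of it derives
#' from a real assembly.
#'
#' @param arm_bp length of a standard chromosome arm in bp.
#' @param acro_p_bp length of an acrocentric p arm in bp.
#' @return a `ToyGenome` list with elements `chrom_sizes`, `arm_table`,
#'   `exclusions`, `region_sets`, `census`, and the GC field function
#'   `gc_at(chrom, pos)`.
#' @export
toy_genome <- function(arm_bp = 2.5e6, acro_p_bp = 3e5) {
  chroms <- paste0("chr", 1:22)
  acro <- paste0("chr", c(13, 14, 15, 21, 22))
  p_len <- ifelse(chroms %in% acro, acro_p_bp, arm_bp)
  sizes <- stats::setNames(p_len + arm_bp, chroms)
  arm_table <- data.frame(chrom = chroms, centromere = p_len,
                          stringsAsFactors = FALSE)
  offsets <- stats::setNames(cumsum(c(0, unname(sizes)[-length(sizes)])),
                             chroms)

  gc_at <- function(chrom, pos) {
    g <- offsets[chrom] + pos
    gc <- 0.45 + 0.08 * sin(2 * pi * g / 1.7e6) +
      0.04 * sin(2 * pi * g / 4.3e5)
    pmin(pmax(gc, 0.30), 0.60)
  }

  # fixed pseudo-blacklist: one 120 kb region on every third chromosome
  excl_chroms <- chroms[seq(3, 22, by = 3)]
  exclusions <- data.frame(
    chrom = excl_chroms,
    start = 0.7e6 + 1e5 * seq_along(excl_chroms),
    end = 0.7e6 + 1e5 * seq_along(excl_chroms) + 1.2e5,
    stringsAsFactors = FALSE)

  region_sets <- toy_region_sets(chroms, sizes)
  census <- toy_census(chroms, sizes)

  structure(list(chrom_sizes = sizes, arm_table = arm_table,
                 exclusions = exclusions, region_sets = region_sets,
                 census = census, gc_at = gc_at, offsets = offsets),
            class = "ToyGenome")
}

# Six named region sets, 40 regions of 2 kb each, deterministically placed.
toy_region_sets <- function(chroms, sizes) {
  set_names <- c("chromhmm_enhancers", "hic_gained_enhancers",
                 "yap_taz_gained", "yap_taz_conserved", "crc_tss",
                 "universal_dhs")
  sets <- lapply(seq_along(set_names), function(s) {
    idx <- seq_len(40L)
    ch <- chroms[(idx * 5L + s) %% length(chroms) + 1L]
    start <- (0.35e6 + 47000 * idx + 31000 * s) %% (sizes[ch] - 5e4)
    df <- data.frame(chrom = ch, start = round(start),
                     end = round(start) + 2000L, stringsAsFactors = FALSE)
    df[order(df$chrom, df$start), ]
  })
  stats::setNames(sets, set_names)
}

# Toy cancer gene census: 80 named genes of 60 kb, some densely clustered.
toy_census <- function(chroms, sizes) {
  idx <- seq_len(80L)
  ch <- chroms[(idx * 7L) %% length(chroms) + 1L]
  start <- (0.5e6 + 61000 * idx) %% (sizes[ch] - 1e5)
  data.frame(chrom = ch, start = round(start), end = round(start) + 60000L,
             gene = sprintf("TOYG%02d", idx), stringsAsFactors = FALSE)
}

#' Tile a toy genome and annotate GC
#'
#' Convenience wrapper over [tile_genome()] + [gc_annotate()] using the toy
#' genome's deterministic GC field and exclusion list.
#'
#' @param genome a `ToyGenome`.
#' @param bin_size bin width in bp.
#' @param exclude apply the genome's exclusion list (default TRUE).
#' @return a `GenomeBins` with a `gc` column.
#' @export
toy_bins <- function(genome, bin_size, exclude = TRUE) {
  bins <- tile_genome(genome$chrom_sizes, bin_size, genome$arm_table,
                      exclusions = if (exclude) genome$exclusions)
  mids <- (bins$start + bins$end) / 2
  bins$gc <- unname(genome$gc_at(bins$chrom, mids))
  bins
}
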