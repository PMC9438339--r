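# Fragment loading, genome tiling, exclusions, bin counting, GC.

test_that("tile_genome produces the expected bin grid with arm labels", {
  arm <- data.frame(chrom = "chrT", centromere = 60000)
  gb <- tile_genome(c(chrT = 100000), 50000, arm)
  expect_equal(nrow(gb), 2L)
  expect_equal(gb$end - gb$start, c(50000, 50000))

  gb3 <- tile_genome(c(chrT = 120000), 50000, arm)
  expect_equal(nrow(gb3), 3L)
  expect_equal(gb3$end[3] - gb3$start[3], 20000)
  # arm by midpoint vs centromere at 60 kb: mids 25k, 75k, 110k
  expect_equal(gb3$arm, c("p", "q", "q"))

  expect_error(tile_genome(c(chrT = 1e5, chrU = 1e5), 5e4, arm), "chrU")
})

test_that("tiling is complete: bins plus exclusions cover each chromosome", {
  f <- toy_fixture()
  g <- f$genome
  bins_all <- tile_genome(g$chrom_sizes, 5e4, g$arm_table)
  for (ch in names(g$chrom_sizes)) {
    b <- bins_all[bins_all$chrom == ch, ]
    expect_equal(b$start, c(0, utils::head(b$end, -1)))  # no gap, no overlap
    expect_equal(b$end[nrow(b)], unname(g$chrom_sizes[ch]))
  }
  # excluded bins are exactly those overlapping an exclusion interval
  kept <- toy_bins(g, 5e4)
  dropped <- bins_all[!paste(bins_all$chrom, bins_all$start) %in%
                        paste(kept$chrom, kept$start), ]
  ex <- g$exclusions
  overlaps_excl <- function(b) any(ex$chrom == b[["chrom"]] &
                                     ex$start < as.numeric(b[["end"]]) &
                                     ex$end > as.numeric(b[["start"]]))
  expect_true(all(apply(dropped, 1L, overlaps_excl)))
})

test_that("apply_exclusions follows the any-overlap rule and is idempotent", {
  bins <- tile_genome(c(chr1 = 2e5), 5e4,
                      data.frame(chrom = "chr1", centromere = 1e5))
  expect_identical(apply_exclusions(bins, list()), bins)

  # one-base overlap at the boundary removes the bin
  ex <- data.frame(chrom = "chr1", start = 49999, end = 60000)
  out <- apply_exclusions(bins, ex)
  expect_equal(out$start, c(100000, 150000))

  # adjacent (touching, half-open) interval does not remove the first bin
  ex2 <- data.frame(chrom = "chr1", start = 50000, end = 60000)
  out2 <- apply_exclusions(bins, ex2)
  expect_true(any(out2$start == 0))
  expect_false(any(out2$start == 50000))

  expect_error(apply_exclusions(bins, data.frame(chrom = "1", start = 0,
                                                 end = 10)),
               "mismatch")

  # random bins vs random exclusions equals the quadratic oracle
  withr::with_seed(42, {
    rb <- data.frame(chrom = sample(c("chrA", "chrB"), 100, TRUE),
                     start = sample.int(1e6, 100))
    rb$end <- rb$start + sample.int(5e4, 100)
    rx <- data.frame(chrom = sample(c("chrA", "chrB"), 15, TRUE),
                     start = sample.int(1e6, 15))
    rx$end <- rx$start + sample.int(1e5, 15)
  })
  got <- apply_exclusions(rb, rx)
  keep_oracle <- vapply(seq_len(nrow(rb)), function(i) {
    !any(rx$chrom == rb$chrom[i] & rx$start < rb$end[i] &
           rx$end > rb$start[i])
  }, TRUE)
  expect_equal(nrow(got), sum(keep_oracle))
  expect_equal(got$start, rb$start[keep_oracle])
  expect_identical(apply_exclusions(got, rx)$start, got$start)  # idempotent
})

test_that("load_fragments filters, deduplicates and records provenance", {
  empty <- load_fragments(data.frame(chrom = character(), start = integer(),
                                     end = integer()))
  expect_equal(nrow(empty), 0L)

  three <- data.frame(chrom = "chr1", start = c(100, 100, 100),
                      end = c(250, 250, 250), mapq = 60L)
  expect_equal(nrow(load_fragments(three)), 1L)
  expect_equal(nrow(load_fragments(three, dedup = FALSE)), 3L)

  mixed <- data.frame(chrom = "chr1", start = 1:6 * 100,
                      end = 1:6 * 100 + 150, mapq = c(60, 10, 35, 29, 30, 0))
  fs <- load_fragments(mixed, min_mapq = 30)
  expect_equal(nrow(fs), 3L)
  expect_true(all(fs$mapq >= 30))
  expect_equal(fs$length, fs$end - fs$start)

  neg <- data.frame(chrom = "chr1", start = c(100, 500), end = c(250, 400),
                    mapq = 60L)
  expect_warning(out <- load_fragments(neg), "skipped")
  expect_equal(nrow(out), 1L)

  # filter idempotence: re-filtering the filtered set changes nothing
  again <- load_fragments(as.data.frame(fs), min_mapq = 30)
  expect_equal(again$start, fs$start)
})

test_that("BAM fragments are proper-pair template spans with MAPQ filter", {
  skip_if_not_installed("Rsamtools")
  pos <- seq(1000, by = 2000, length.out = 10)
  tlen <- rep(c(150L, 180L), 5)
  mapq <- c(60L, 60L, 10L, 60L, 60L, 10L, 60L, 60L, 60L, 60L)
  bam <- write_pair_bam(pos, tlen, mapq)
  fs <- load_fragments(bam, min_mapq = 30)
  expect_equal(nrow(fs), 8L)
  expect_equal(sort(fs$start), sort(pos[mapq >= 30] - 1L))
  expect_equal(sort(fs$length), sort(tlen[mapq >= 30]))
})

test_that("count_in_bins assigns by midpoint with inclusive length bounds", {
  bins <- tile_genome(c(chr1 = 2e5), 5e4,
                      data.frame(chrom = "chr1", centromere = 1e5))
  f1 <- load_fragments(data.frame(chrom = "chr1", start = 100, end = 250,
                                  mapq = 60L))
  expect_equal(sum(count_in_bins(f1, bins, c(90, 150))$count), 1L)
  f2 <- load_fragments(data.frame(chrom = "chr1", start = 100, end = 251,
                                  mapq = 60L))
  expect_equal(sum(count_in_bins(f2, bins, c(90, 150))$count), 0L)

  # 1000 random fragments equal the brute-force midpoint oracle
  frags <- load_fragments(make_fragment_df(1000, max_pos = 1.9e5,
                                           seed = 7), dedup = FALSE)
  bc <- count_in_bins(frags, bins, c(90, 150))
  oracle <- integer(nrow(bins))
  for (i in seq_len(nrow(frags))) {
    len <- frags$length[i]
    if (len < 90 || len > 150) next
    mid <- floor((frags$start[i] + frags$end[i]) / 2)
    k <- which(bins$start <= mid & mid < bins$end)
    if (length(k)) oracle[k] <- oracle[k] + 1L
  }
  expect_equal(bc$count, oracle)
  # conservation: total counted = in-window fragments with midpoint in bins
  expect_equal(sum(bc$count), sum(oracle))
  expect_equal(attr(bc, "n_assigned") + attr(bc, "n_unassigned"),
               sum(frags$length >= 90 & frags$length <= 150))
})

test_that("gc_annotate counts G+C over non-N bases", {
  bins <- tile_genome(c(chrT = 40), 20,
                      data.frame(chrom = "chrT", centromere = 20))
  expect_equal(gc_annotate(bins, c(chrT = strrep("A", 40)))$gc, c(0, 0))
  expect_equal(gc_annotate(bins, c(chrT = strrep("GC", 20)))$gc, c(1, 1))

  withr::with_seed(3, {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE), collapse = "")
  })
  got <- gc_annotate(bins, c(chrT = seq))$gc
  chars <- strsplit(seq, "")[[1]]
  for (k in 1:2) {
    sub <- chars[(bins$start[k] + 1):bins$end[k]]
    expect_equal(got[k], sum(sub %in% c("G", "C")) / sum(sub != "N"))
  }

  short_ref <- c(chrT = strrep("A", 30))
  expect_error(gc_annotate(bins, short_ref), "beyond reference")

  # numeric per-bin table path
  expect_equal(gc_annotate(bins, c(0.4, 0.5))$gc, c(0.4, 0.5))
})
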