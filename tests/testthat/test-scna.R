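# Log2 normalization, limit-of-blank thresholds, genome-wide and focal
# SCNA calling.

# A minimal panel mock for unit tests of log2_normalize: flat expectation.
mock_count_panel <- function(bins, expected = NULL) {
  list(counts50 = list(bins = as.data.frame(bins)[c("chrom", "start", "end")],
                       mean = expected %||% rep(1, nrow(bins))))
}

flat_counts <- function(n = 300, count = 100) {
  bins <- tile_genome(stats::setNames(n * 5e4, "chr1"), 5e4,
                      data.frame(chrom = "chr1", centromere = n * 2.5e4))
  bins$gc <- rep(seq(0.35, 0.55, length.out = 50), length.out = n)
  bins$count <- rep(count, n)
  class(bins) <- c("BinnedCounts", class(bins))
  bins
}

test_that("log2_normalize is ~0 at the panel expectation and log2(1.5) at 1.5x", {
  counts <- flat_counts()
  prof <- log2_normalize(counts, mock_count_panel(counts))
  expect_lt(max(abs(prof$log2)), 0.02)

  up <- counts
  up$count[1:100] <- 150  # "arm" at 1.5x; sample median still 100
  prof2 <- suppressWarnings(log2_normalize(up, mock_count_panel(up)))
  expect_equal(mean(prof2$log2[1:100]), log2(1.5), tolerance = 0.05)

  z <- counts
  z$count[5] <- 0
  expect_true(is.na(log2_normalize(z, mock_count_panel(z))$log2[5]))

  expect_error(log2_normalize(counts[-1, ], mock_count_panel(counts)),
               "mismatch")
})

test_that("log2_normalize removes an injected GC trend", {
  counts <- flat_counts()
  withr::with_seed(6, {
    trend <- exp(1.5 * (counts$gc - 0.45))
    counts$count <- as.integer(round(100 * trend *
                                       exp(rnorm(nrow(counts), 0, 0.05))))
  })
  prof <- log2_normalize(counts, mock_count_panel(counts))
  expect_lt(abs(cor(prof$log2, counts$gc, use = "complete.obs")), 0.05)
})

test_that("derive_thresholds implements both LOB families", {
  # chromosome family: classical per-measurement limit of blank
  withr::with_seed(10, {
    segs <- data.frame(chrom = rep("chr1", 200),
                       mean_log2 = rnorm(200, 0, 1))
  })
  segs$mean_log2 <- (segs$mean_log2 - mean(segs$mean_log2)) /
    sd(segs$mean_log2) * 0.05  # exact mean 0, SD 0.05
  thr <- derive_thresholds(segs, confidence = 0.95, family = "chromosome")
  expect_equal(thr$lob_gain, qnorm(0.95) * 0.05, tolerance = 1e-6)
  expect_equal(thr$lob_gain, 0.0823, tolerance = 1e-3)
  expect_equal(thr$lob_loss, -thr$lob_gain, tolerance = 1e-6)

  # genome family widens by the Bonferroni z over chromosome tails
  segs2 <- rbind(segs, transform(segs, chrom = "chr2"))
  thr2 <- derive_thresholds(segs2, confidence = 0.95, family = "genome")
  expect_equal(thr2$lob_gain[1], qnorm(1 - 0.05 / 4) * 0.05,
               tolerance = 1e-6)

  # degenerate panel: all segment means zero -> thresholds collapse to ~0
  seg0 <- data.frame(chrom = rep("chr1", 50), mean_log2 = 0)
  thr0 <- derive_thresholds(seg0, family = "chromosome")
  expect_lt(thr0$lob_gain, 1e-5)
  expect_gt(thr0$lob_loss, -1e-5)

  # sparse chromosomes fall back to the genome-wide pool with a warning
  sparse <- rbind(segs, data.frame(chrom = "chr9",
                                   mean_log2 = c(0.01, -0.01)))
  expect_warning(thr3 <- derive_thresholds(sparse, family = "chromosome"),
                 "chr9")
  expect_equal(thr3$lob_gain[thr3$chrom == "chr9"],
               thr3$lob_gain[thr3$chrom == "chr1"], tolerance = 0.02)

  # thresholds are a pure function of the persisted panel segments
  expect_identical(derive_thresholds(segs, family = "chromosome"),
                   derive_thresholds(segs, family = "chromosome"))
})

test_that("call_scna applies chromosome thresholds to large segments", {
  thr <- structure(data.frame(chrom = "chr1", lob_loss = -0.08,
                              lob_gain = 0.08, n_segments = 55),
                   class = c("ChromThresholds", "data.frame"))
  segs <- data.frame(chrom = "chr1",
                     start = c(0, 3e6, 6e6, 9e6),
                     end = c(3e6, 6e6, 9e6, 9.5e6),
                     n_bins = c(60, 60, 60, 10),
                     mean_log2 = c(0.02, 0.20, -0.30, 0.90))
  calls <- call_scna(segs, thr)
  expect_equal(calls$direction, c("gain", "loss"))
  expect_equal(calls$start, c(3e6, 6e6))
  # the 0.9 segment is below min_size -> not a genome-wide call
  expect_false(9e6 %in% calls$start)
  # within-threshold segments are never called
  expect_equal(nrow(call_scna(segs[1, ], thr)), 0L)
  expect_error(call_scna(transform(segs, chrom = "chrX"), thr), "chrX")
})

test_that("call_focal implements the census and amplification rules", {
  thr <- structure(data.frame(chrom = "chr8", lob_loss = -0.08,
                              lob_gain = 0.08, n_segments = 55),
                   class = c("ChromThresholds", "data.frame"))
  census <- data.frame(chrom = "chr8",
                       start = seq(41e6, by = 2e5, length.out = 50),
                       end = seq(41e6, by = 2e5, length.out = 50) + 1e5,
                       gene = paste0("G", 1:50))

  # 10 Mb segment, 50 census genes, neighbor delta 0.3 > LOB -> focal gain
  segs <- data.frame(chrom = "chr8",
                     start = c(0e6, 40e6, 50e6),
                     end = c(40e6, 50e6, 140e6),
                     n_bins = c(800, 200, 1800),
                     mean_log2 = c(0.0, 0.3, 0.0))
  fc <- call_focal(segs, thr, census)
  expect_equal(nrow(fc), 1L)
  expect_equal(fc$kind, "focal_gain")
  expect_equal(fc$census_gene_count, 45)
  expect_equal(fc$neighbor_delta, 0.3, tolerance = 1e-6)

  # 25 Mb segment: no gene-based focal call
  wide <- data.frame(chrom = "chr8",
                     start = c(0e6, 40e6, 65e6),
                     end = c(40e6, 65e6, 140e6),
                     n_bins = c(800, 500, 1500),
                     mean_log2 = c(0.0, 0.3, 0.0))
  expect_equal(nrow(call_focal(wide, thr, census)), 0L)

  # 5 Mb segment, no census genes, delta 0.60 >= 0.58 -> amplification
  amp <- data.frame(chrom = "chr8",
                    start = c(0e6, 10e6, 15e6),
                    end = c(10e6, 15e6, 140e6),
                    n_bins = c(200, 100, 2500),
                    mean_log2 = c(0.0, 0.6, 0.0))
  fa <- call_focal(amp, thr, census)
  expect_equal(fa$kind, "focal_amplification")
  expect_equal(fa$census_gene_count, 0)

  expect_error(call_focal(transform(segs, chrom = "chr9"),
                          transform(thr, chrom = "chr9"),
                          census), "census")
})

test_that("panel thresholds flag tumor arms and spare fresh controls", {
  sp <- study_panel()
  panel <- sp$panel
  f <- toy_fixture()

  expect_true(all(panel$thresholds$lob_gain > 0))
  expect_true(all(panel$thresholds$lob_loss < 0))

  # tau = 0.10: the seven truth arms are recovered
  truth <- c("7p", "8q", "13q", "20q", "8p", "17p", "18q")
  for (k in 1:3) {
    s <- tumor_samples(1, tau = 0.10, seed = 880 + k)[[1]]
    res <- run_scna_pipeline(s, panel, seed = 890 + k)
    hit_arms <- unique(f$bins50$arm_label[
      IRanges::overlapsAny(lifecna:::df_to_granges(f$bins50),
                           lifecna:::df_to_granges(res$calls))])
    expect_gte(length(intersect(truth, hit_arms)), 6L)
    dirs <- res$calls$direction[match(c("7p", "17p"),
      sapply(seq_len(nrow(res$calls)), function(i) {
        ov <- f$bins50$chrom == res$calls$chrom[i] &
          f$bins50$start >= res$calls$start[i] &
          f$bins50$end <= res$calls$end[i]
        names(sort(table(f$bins50$arm_label[ov]), decreasing = TRUE))[1]
      }))]
    expect_equal(dirs, c("gain", "loss"))
  }

  # fresh controls rarely carry any genome-wide call
  fp <- vapply(seq_along(ctrl <- fresh_controls(40, seed = 870)),
               function(i) {
    nrow(run_scna_pipeline(ctrl[[i]], panel, seed = 950 + i)$calls) > 0
  }, TRUE)
  expect_lte(mean(fp), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 40))
})

test_that("detection of truth arms is monotone in tumor fraction", {
  sp <- study_panel()
  f <- toy_fixture()
  truth_bins <- f$bins50$arm_label %in% c("7p", "8q", "13q", "20q",
                                          "8p", "17p", "18q")
  n_called <- vapply(c(0.01, 0.05, 0.10), function(tau) {
    hits <- vapply(seq_len(3), function(k) {
      s <- tumor_samples(1, tau = tau, seed = 7000 + 10 * k +
                           round(1000 * tau))[[1]]
      res <- run_scna_pipeline(s, sp$panel, seed = 7500 + k)
      sum(unique(f$bins50$arm_label[
        IRanges::overlapsAny(lifecna:::df_to_granges(f$bins50),
                             lifecna:::df_to_granges(res$calls))]) %in%
          c("7p", "8q", "13q", "20q", "8p", "17p", "18q"))
    }, 0)
    mean(hits)
  }, 0)
  expect_true(all(diff(n_called) >= 0))
  expect_gte(n_called[3], 6)
})
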