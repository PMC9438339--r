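# The synthetic cohort generator: copy-number scaling, overdispersion,
# dilution series, region profiles, reproducibility.

test_that("tumor profiles validate their inputs", {
  expect_error(tumor_profile(tumor_fraction = 1.2), "\\[0, 1\\]")
  expect_error(tumor_profile(arm_states = c(3, 1)), "named")
  f <- toy_fixture()
  bad_focal <- data.frame(chrom = "chr1", start = 4e6, end = 9e6, cn = 4)
  expect_error(simulate_sample(profile = tumor_profile(
    focal_events = bad_focal, tumor_fraction = 0.1), genome = f$genome,
    seed = 1, bins50 = f$bins50, bins100 = f$bins100), "bounds")
})

test_that("cn_by_bin maps arm states and focal events onto bins", {
  f <- toy_fixture()
  prof <- tumor_profile(arm_states = c("8q" = 3),
                        focal_events = data.frame(chrom = "chr8",
                                                  start = 1e6, end = 1.4e6,
                                                  cn = 6),
                        tumor_fraction = 0.5)
  cn <- cn_by_bin(prof, f$bins50)
  expect_true(all(cn[f$bins50$arm_label == "8q"] == 3))
  foc <- f$bins50$chrom == "chr8" & f$bins50$start < 1.4e6 &
    f$bins50$end > 1e6
  expect_true(all(cn[foc] == 6))
  expect_true(all(cn[f$bins50$chrom == "chr3"] == 2))
})

test_that("all-fragment counts scale as 1 + tau*(CN/2 - 1)", {
  f <- toy_fixture()
  cases <- list(list(tau = 1, cn = 4, expected = 1),          # log2(2)
                list(tau = 0.1, cn = 3, expected = log2(1.05)))
  for (cs in cases) {
    ratios <- vapply(1:6, function(k) {
      prof <- tumor_profile(arm_states = c("5q" = cs$cn),
                            tumor_fraction = cs$tau)
      s_t <- simulate_sample(profile = prof, genome = f$genome,
                             seed = 9000 + k, bins50 = f$bins50,
                             bins100 = f$bins100, n_lengths = 1000)
      s_0 <- simulate_sample(profile = tumor_profile(), genome = f$genome,
                             seed = 9000 + k, bins50 = f$bins50,
                             bins100 = f$bins100, n_lengths = 1000)
      arm <- f$bins50$arm_label == "5q"
      mean(s_t$counts50_all$count[arm]) / mean(s_0$counts50_all$count[arm])
    }, 0)
    expect_equal(mean(log2(ratios)), cs$expected, tolerance = 0.04)
  }
  # tau = 0: no arm deviates in expectation
  s0a <- simulate_sample(profile = tumor_profile(), genome = f$genome,
                         seed = 1, bins50 = f$bins50, bins100 = f$bins100,
                         n_lengths = 1000)
  s0b <- simulate_sample(profile = tumor_profile(), genome = f$genome,
                         seed = 2, bins50 = f$bins50, bins100 = f$bins100,
                         n_lengths = 1000)
  arm <- f$bins50$arm_label == "5q"
  r <- mean(s0a$counts50_all$count[arm]) / mean(s0b$counts50_all$count[arm])
  expect_lt(abs(log2(r)), 0.25)  # depth jitter + counting noise only
})

test_that("bin counts are overdispersed (variance >= mean)", {
  f <- toy_fixture()
  s <- simulate_sample(profile = tumor_profile(), genome = f$genome,
                       seed = 31, bins50 = f$bins50, bins100 = f$bins100,
                       n_lengths = 1000)
  # compare within a narrow GC stratum so the mean is near-constant
  idx <- abs(f$bins50$gc - 0.45) < 0.01
  x <- s$counts50_all$count[idx]
  expect_gt(var(x) / mean(x), 1.5)
})

test_that("control panels are all-healthy and bit-reproducible", {
  f <- toy_fixture()
  p1 <- simulate_control_panel(5, seed = 77, genome = f$genome,
                               n_lengths = 2000)
  p2 <- simulate_control_panel(5, seed = 77, genome = f$genome,
                               n_lengths = 2000)
  expect_length(p1, 5L)
  expect_true(all(vapply(p1, function(s) s$truth$tumor_fraction, 0) == 0))
  expect_identical(p1[[3]]$counts50_short$count,
                   p2[[3]]$counts50_short$count)
  expect_identical(p1[[3]]$lengths, p2[[3]]$lengths)
  # distinct member seeds produce distinct data
  expect_false(identical(p1[[1]]$lengths, p1[[2]]$lengths))
})

test_that("panel summaries converge with panel size", {
  f <- toy_fixture()
  pa <- simulate_control_panel(20, seed = 501, genome = f$genome,
                               n_lengths = 1000)
  pb <- simulate_control_panel(20, seed = 502, genome = f$genome,
                               n_lengths = 1000)
  ma <- rowMeans(vapply(pa, function(s) as.numeric(s$counts50_short$count),
                        numeric(nrow(f$bins50))))
  mb <- rowMeans(vapply(pb, function(s) as.numeric(s$counts50_short$count),
                        numeric(nrow(f$bins50))))
  # two independent 20-sample panels estimate the same per-bin expectation:
  # the systematic bin-to-bin structure (GC bias, fragmentation landscape)
  # is shared, and per-bin disagreement is at the sqrt(2) * CV/sqrt(20)
  # sampling scale (~5%)
  expect_gt(cor(ma, mb), 0.6)
  expect_lt(mean(abs(ma - mb) / ((ma + mb) / 2)), 0.08)
  expect_lt(abs(mean(ma) / mean(mb) - 1), 0.05)
})

test_that("dilution series varies only tau with distinct replicate seeds", {
  f <- toy_fixture()
  dil <- dilution_series(taus = c(0.005, 0.01, 0.025, 0.05, 0.10),
                         replicates = 1, seed = 55, genome = f$genome,
                         n_lengths = 5000)
  expect_length(dil, 5L)
  arm_states <- lapply(dil, function(s) s$truth$arm_states)
  expect_true(all(vapply(arm_states, identical, TRUE, arm_states[[1]])))
  taus <- vapply(dil, function(s) s$truth$tumor_fraction, 0)
  expect_equal(unname(taus), c(0.005, 0.01, 0.025, 0.05, 0.10))

  # expected short-fragment fraction follows the mixture blend, and the
  # expected gained-arm enrichment is monotone in tau
  sf <- vapply(dil, function(s) {
    mean(s$lengths >= 90 & s$lengths <= 150)
  }, 0)
  expected <- vapply(taus, function(tau) mixture_window_fraction(
    blend_mixtures(healthy_mixture(), tumor_mixture(), tau), c(90, 150)), 0)
  expect_true(all(abs(sf - expected) < 0.02))
  # expected gained-arm enrichment is monotone in tau: averaged over
  # replicates at well-separated fractions (single replicates cannot
  # resolve 0.5% vs 1% tau against counting noise)
  gained <- f$bins50$arm_label %in% c("7p", "8q", "13q", "20q")
  rel_at <- function(tau) {
    reps <- dilution_series(taus = tau, replicates = 3, seed = 66,
                            genome = f$genome, n_lengths = 1000)
    mean(vapply(reps, function(s)
      mean(s$counts50_short$count[gained]) / mean(s$counts50_short$count),
      0))
  }
  rel <- vapply(c(0.005, 0.025, 0.10), rel_at, 0)
  expect_true(all(diff(rel) > 0))
})

test_that("region profiles follow the tau * dip_depth_scale contract", {
  null_p <- simulate_region_profiles(tau = 0, seed = 3)
  expect_named(null_p, c("chromhmm_enhancers", "hic_gained_enhancers",
                         "yap_taz_gained", "yap_taz_conserved", "crc_tss",
                         "universal_dhs"))
  expect_lt(abs(null_p$crc_tss$dip_depth), 0.02)

  full <- simulate_region_profiles(tau = 1, dip_depth_scale = 0.3, seed = 4)
  central <- full$crc_tss$grid$mean_cov[full$crc_tss$grid$central]
  expect_equal(mean(central), 0.7, tolerance = 0.02)

  # Monte-Carlo: measured dip depth within 3 SE of tau * scale
  reps <- vapply(1:200, function(k) {
    simulate_region_profiles("crc_tss", tau = 0.2, dip_depth_scale = 0.3,
                             seed = 5000 + k)[[1]]$dip_depth
  }, 0)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.06), 3 * se + 1e-4)

  expect_error(simulate_region_profiles(character(0), tau = 0),
               "non-empty")
})

test_that("a sample is identical given identical parameters and seed", {
  f <- toy_fixture()
  a <- simulate_sample(profile = crc_tumor_profile(0.05), genome = f$genome,
                       seed = 12345, bins50 = f$bins50, bins100 = f$bins100,
                       n_lengths = 2000)
  b <- simulate_sample(profile = crc_tumor_profile(0.05), genome = f$genome,
                       seed = 12345, bins50 = f$bins50, bins100 = f$bins100,
                       n_lengths = 2000)
  expect_identical(a$counts50_short$count, b$counts50_short$count)
  expect_identical(a$counts100_long$count, b$counts100_long$count)
  expect_identical(a$lengths, b$lengths)
  expect_identical(vapply(a$dips, `[[`, 0, "dip_area"),
                   vapply(b$dips, `[[`, 0, "dip_area"))
})
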