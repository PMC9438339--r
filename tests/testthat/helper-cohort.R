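# Shared fixtures, built once per test run and cached.  The "study
# panel" mirrors the reference-set conditions (55 healthy controls at
# ~6x-equivalent depth); several suites reuse it because building it
# (leave-one-out normalization + CBS of every control) is the expensive
# step.

.fixtures <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixtures$genome)) {
    .fixtures$genome <- toy_genome()
    .fixtures$bins50 <- toy_bins(.fixtures$genome, 5e4)
    .fixtures$bins100 <- toy_bins(.fixtures$genome, 1e5)
  }
  .fixtures
}

study_panel <- function() {
  if (is.null(.fixtures$panel)) {
    f <- toy_fixture()
    .fixtures$controls <- simulate_control_panel(55, seed = 101,
                                                 genome = f$genome)
    .fixtures$panel <- suppressWarnings(
      build_panel(.fixtures$controls, seed = 102))
  }
  list(panel = .fixtures$panel, controls = .fixtures$controls)
}

# fresh healthy samples, never part of the panel
fresh_controls <- function(n, seed) {
  f <- toy_fixture()
  seeds <- withr::with_seed(seed, sample.int(1e8, n))
  lapply(seeds, function(sd)
    simulate_sample(profile = tumor_profile(), genome = f$genome, seed = sd,
                    bins50 = f$bins50, bins100 = f$bins100))
}

tumor_samples <- function(n, tau, seed) {
  f <- toy_fixture()
  seeds <- withr::with_seed(seed, sample.int(1e8, n))
  lapply(seeds, function(sd)
    simulate_sample(profile = crc_tumor_profile(tau), genome = f$genome,
                    seed = sd, bins50 = f$bins50, bins100 = f$bins100))
}

run_scna_pipeline <- function(s, panel, seed) {
  prof <- log2_normalize(s$counts50_short, panel)
  segs <- segment_cbs(prof, seed = seed)
  list(profile = prof, segments = segs,
       calls = call_scna(segs, panel$thresholds))
}

# a plain fragment table for genome_io tests
make_fragment_df <- function(n, chrom = "chr1", max_pos = 4.9e6,
                             lengths = NULL, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE)
    len <- if (is.null(lengths)) sample(90:410, n, replace = TRUE)
           else rep_len(lengths, n)
    data.frame(chrom = chrom, start = start, end = start + len,
               mapq = 60L, stringsAsFactors = FALSE)
  })
}
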