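#' Describe a synthetic tumor
#'
#' A tumor profile fixes the copy-number state per chromosome arm, optional
#' focal events, the tumor fraction tau of the sample's cfDNA, and the
#' relative coverage reduction the tumor imposes at active chromatin
#' region sets.
#'
#' @param arm_states named numeric vector of copy numbers keyed by arm
#'   label (e.g. `c("8q" = 3, "17p" = 1)`); unlisted arms are diploid.
#' @param focal_events optional data.frame chrom/start/end/cn of focal
#'   events overriding the arm state.
#' @param tumor_fraction tau in `[0, 1]`.
#' @param dip_depth_scale relative central coverage reduction at fully
#'   tumor-derived cfDNA over active region sets (default 0.3).
#' @return a `TumorProfile`.
#' @export
tumor_profile <- function(arm_states = numeric(0), focal_events = NULL,
                          tumor_fraction = 0, dip_depth_scale = 0.3) {
  if (!is.numeric(tumor_fraction) || tumor_fraction < 0 || tumor_fraction > 1) {
    stop("tumor_fraction must lie in [0, 1]")
  }
  if (length(arm_states) && (is.null(names(arm_states)) ||
                             any(!nzchar(names(arm_states))))) {
    stop("arm_states must be a named vector of copy numbers")
  }
  if (any(arm_states < 0)) stop("copy numbers must be nonnegative")
  structure(list(arm_states = arm_states, focal_events = focal_events,
                 tumor_fraction = tumor_fraction,
                 dip_depth_scale = dip_depth_scale),
            class = "TumorProfile")
}

#' Default CRC-like tumor profile
#'
#' Canonical colorectal arm events: gains of 7p, 8q, 13q and 20q, losses of
#' 8p, 17p and 18q.
#'
#' @param tumor_fraction tau in `[0, 1]`.
#' @param dip_depth_scale see [tumor_profile()].
#' @return a `TumorProfile`.
#' @export
crc_tumor_profile <- function(tumor_fraction, dip_depth_scale = 0.3) {
  tumor_profile(
    arm_states = c("7p" = 3, "8q" = 3, "13q" = 3, "20q" = 3,
                   "8p" = 1, "17p" = 1, "18q" = 1),
    tumor_fraction = tumor_fraction,
    dip_depth_scale = dip_depth_scale)
}

#' Copy number per bin implied by a tumor profile
#' @param profile a `TumorProfile`.
#' @param bins a `GenomeBins` (with `arm_label`).
#' @return numeric copy number per bin.
#' @export
cn_by_bin <- function(profile, bins) {
  cn <- rep(2, nrow(bins))
  if (length(profile$arm_states)) {
    hit <- match(bins$arm_label, names(profile$arm_states))
    cn[!is.na(hit)] <- profile$arm_states[hit[!is.na(hit)]]
  }
  fe <- profile$focal_events
  if (!is.null(fe) && nrow(fe)) {
    ov <- GenomicRanges::findOverlaps(df_to_granges(bins), df_to_granges(fe))
    cn[S4Vectors::queryHits(ov)] <- fe$cn[S4Vectors::subjectHits(ov)]
  }
  cn
}

# Smooth unimodal GC bias curve over the gc range, mean-normalized.
# The default width gives ~25% depletion at the GC extremes of the toy
# genome, the order of magnitude of real library-preparation GC bias.
gc_bias_curve <- function(gc, center = 0.45, width = 0.2) {
  b <- exp(-(gc - center)^2 / (2 * width^2))
  b / mean(b)
}

# Deterministic per-bin fragmentation landscape (chromatin-like variation
# of the local short-fragment propensity); absorbed by the panel means.
bin_frag_factor <- function(genome, bins) {
  mids <- genome$offsets[bins$chrom] + (bins$start + bins$end) / 2
  sin(2 * pi * mids / 0.9e6)
}

#' Arm-level chromatin signature of the simulated tumor
#'
#' Tumor-derived cfDNA carries the chromatin profile of its tissue of
#' origin, so its short-fragment propensity differs between chromosome
#' arms (some arms shed shorter, others longer fragments than healthy
#' cfDNA).  The toy tumor's signature is a fixed deterministic value in
#' `[-1, 1]` per arm; it is what the regional fragmentation analysis
#' detects after sample-level centering.
#'
#' @param bins a `GenomeBins` (for its `arm_label` column).
#' @return numeric vector, one signature value per bin.
#' @export
tumor_arm_signature <- function(bins) {
  arms <- sort(unique(bins$arm_label))
  sig <- stats::setNames(sin(1.7 * seq_along(arms)), arms)
  unname(sig[bins$arm_label])
}

#' Simulate one synthetic cfDNA sample
#'
#' Generates the per-sample data products the pipeline consumes: fragment
#' lengths, short-fragment (90-150 bp) and all-fragment counts in 50 kb
#' bins, short and long (151-220 bp) counts in 100 kb bins, and coverage
#' profiles over the genome's region sets.  Expected bin counts follow
#' `depth * gc_bias(gc) * (1 + tau * (CN/2 - 1))`, drawn from a negative
#' binomial (variance >= mean).  Fragment lengths come from the healthy /
#' tumor mixture blended by tau; the short-fragment share of each bin
#' additionally reflects the locally elevated tumor content of gained
#' regions, so short-fragment counts amplify copy-number signal as they do
#' in real cfDNA.
#'
#' @param depth_equiv expected total fragments per 50 kb bin in a neutral
#'   diploid bin; 1800 corresponds to ~6x coverage at 167 bp fragments.
#' @param profile a `TumorProfile`.
#' @param genome a `ToyGenome` (default [toy_genome()]).
#' @param seed RNG seed; a sample is bit-reproducible given
#'   (parameters, seed).
#' @param n_lengths number of fragment lengths drawn for the global
#'   profile.
#' @param healthy,tumor length mixtures (defaults [healthy_mixture()],
#'   [tumor_mixture()]).
#' @param nb_size negative-binomial size (dispersion) for 50 kb counts.
#' @param nb_size_sl negative-binomial size for 100 kb short/long counts.
#' @param depth_jitter_sd,gc_center_sd,shoulder_sd between-sample
#'   variability: log-normal depth factor, GC bias center jitter, and
#'   healthy sub-nucleosomal shoulder-weight jitter.
#' @param bins50,bins100 optional precomputed bin grids (for speed when
#'   simulating many samples).
#' @param sample_id optional label.
#' @return a `SyntheticSample` list: `lengths`, `counts50_short`,
#'   `counts50_all`, `counts100_short`, `counts100_long`, `dips`, `truth`,
#'   `seed`, `sample_id`.
#' @export
simulate_sample <- function(depth_equiv = 1800, profile = tumor_profile(),
                            genome = toy_genome(), seed = NULL,
                            n_lengths = 1e5,
                            healthy = healthy_mixture(),
                            tumor = tumor_mixture(),
                            nb_size = 50, nb_size_sl = 200,
                            depth_jitter_sd = 0.05, gc_center_sd = 0.008,
                            shoulder_sd = 0.005,
                            bins50 = NULL, bins100 = NULL,
                            sample_id = NULL) {
  stopifnot(depth_equiv > 0)
  tau <- profile$tumor_fraction
  fe <- profile$focal_events
  if (!is.null(fe) && nrow(fe)) {
    bad <- fe$end > genome$chrom_sizes[fe$chrom] | fe$start < 0
    if (any(bad)) stop("focal event(s) outside chromosome bounds")
  }
  if (is.null(bins50)) bins50 <- toy_bins(genome, 5e4)
  if (is.null(bins100)) bins100 <- toy_bins(genome, 1e5)

  with_seed(seed, {
    depth_factor <- exp(stats::rnorm(1, 0, depth_jitter_sd))
    gc_center <- 0.45 + stats::rnorm(1, 0, gc_center_sd)
    shoulder <- max(0, 0.06 + stats::rnorm(1, 0, shoulder_sd))
    healthy_s <- healthy_mixture(shoulder_weight = shoulder)

    p_short_h <- mixture_window_fraction(healthy_s, c(90, 150))
    p_long_h <- mixture_window_fraction(healthy_s, c(151, 220))
    p_short_t <- mixture_window_fraction(tumor, c(90, 150))
    p_long_t <- mixture_window_fraction(tumor, c(151, 220))

    draw_track <- function(bins, scale_bp, fraction, size) {
      cn <- cn_by_bin(profile, bins)
      total_scale <- 1 - tau + tau * cn / 2        # DNA quantity
      w_local <- ifelse(total_scale > 0,
                        tau * (cn / 2) / total_scale, 0)  # local tumor share
      g <- bin_frag_factor(genome, bins)
      h <- tumor_arm_signature(bins)  # tumor tissue-of-origin chromatin
      frac <- switch(fraction,
        all = 1,
        short = ((1 - w_local) * p_short_h +
                   w_local * p_short_t * (1 + 0.25 * h)) * (1 + 0.10 * g),
        long = ((1 - w_local) * p_long_h +
                  w_local * p_long_t * (1 - 0.05 * h)) * (1 - 0.02 * g))
      mu <- depth_factor * depth_equiv * scale_bp / 5e4 *
        gc_bias_curve(bins$gc, center = gc_center) * total_scale * frac
      out <- bins
      out$count <- stats::rnbinom(nrow(bins), mu = mu, size = size)
      class(out) <- unique(c("BinnedCounts", class(bins)))
      out
    }

    counts50_short <- draw_track(bins50, 5e4, "short", nb_size)
    counts50_all <- draw_track(bins50, 5e4, "all", nb_size)
    counts100_short <- draw_track(bins100, 1e5, "short", nb_size_sl)
    counts100_long <- draw_track(bins100, 1e5, "long", nb_size_sl)

    lengths <- simulate_lengths(n_lengths, blend_mixtures(healthy_s, tumor, tau))

    dips <- simulate_region_profiles(names(genome$region_sets), tau,
                                     profile$dip_depth_scale)

    structure(list(sample_id = sample_id %||% "synthetic",
                   seed = seed, truth = profile,
                   lengths = lengths,
                   counts50_short = counts50_short,
                   counts50_all = counts50_all,
                   counts100_short = counts100_short,
                   counts100_long = counts100_long,
                   dips = dips),
              class = "SyntheticSample")
  })
}

#' Simulate a panel of healthy control samples
#'
#' All samples have tumor fraction 0; per-sample seeds are derived
#' deterministically from the master seed, so the panel is bit-reproducible.
#'
#' @param n_samples number of controls (default 55).
#' @param depth_equiv see [simulate_sample()].
#' @param seed master seed.
#' @param genome a `ToyGenome`.
#' @param ... further arguments passed to [simulate_sample()].
#' @return list of `SyntheticSample` objects.
#' @export
simulate_control_panel <- function(n_samples = 55, depth_equiv = 1800,
                                   seed = NULL, genome = toy_genome(), ...) {
  stopifnot(n_samples >= 3)
  seeds <- derive_seeds(seed %||% 1L, n_samples)
  bins50 <- toy_bins(genome, 5e4)
  bins100 <- toy_bins(genome, 1e5)
  lapply(seq_len(n_samples), function(i) {
    simulate_sample(depth_equiv = depth_equiv, profile = tumor_profile(),
                    genome = genome, seed = seeds[i],
                    bins50 = bins50, bins100 = bins100,
                    sample_id = sprintf("control_%02d", i), ...)
  })
}

#' Simulate an in silico dilution series
#'
#' One tumor profile mixed at a ladder of tumor fractions, several
#' replicates per fraction with distinct seeds.
#'
#' @param tumor_params a `TumorProfile` whose arm states, focal events and
#'   dip scale define the tumor (its own tumor_fraction is ignored), or
#'   NULL for the default CRC profile.
#' @param taus tumor fractions, default `c(0.005, 0.01, 0.025, 0.05, 0.10)`.
#' @param replicates replicates per tumor fraction.
#' @param seed master seed.
#' @param genome a `ToyGenome`.
#' @param ... passed to [simulate_sample()].
#' @return list of `SyntheticSample`, named `tau<frac>_rep<i>`.
#' @export
dilution_series <- function(tumor_params = NULL,
                            taus = c(0.005, 0.01, 0.025, 0.05, 0.10),
                            replicates = 1, seed = NULL,
                            genome = toy_genome(), ...) {
  stopifnot(all(taus > 0), all(taus < 1), replicates >= 1)
  base <- tumor_params %||% crc_tumor_profile(tumor_fraction = taus[1L])
  grid <- expand.grid(rep = seq_len(replicates), tau = taus)
  seeds <- derive_seeds(seed %||% 1L, nrow(grid))
  bins50 <- toy_bins(genome, 5e4)
  bins100 <- toy_bins(genome, 1e5)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    prof <- tumor_profile(arm_states = base$arm_states,
                          focal_events = base$focal_events,
                          tumor_fraction = grid$tau[i],
                          dip_depth_scale = base$dip_depth_scale)
    simulate_sample(profile = prof, genome = genome, seed = seeds[i],
                    bins50 = bins50, bins100 = bins100,
                    sample_id = sprintf("tau%g_rep%d", grid$tau[i],
                                        grid$rep[i]), ...)
  })
  stats::setNames(out, vapply(out, `[[`, "", "sample_id"))
  }

#' Simulate coverage-dip profiles over chromatin region sets
#'
#' Produces per-set averaged relative-coverage profiles on the standard
#' grid (500 bp bins, 20 kb flanks around a length-normalized central
#' window).  Central bins of a set with tumor response `r` have expected
#' relative coverage `1 - tau * dip_depth_scale * r`; flank bins have
#' expectation 1; noise is independent per position bin.  The five
#' CRC-active sets respond fully (response 1); universal DHS responds
#' at half strength (response 0.5).
#'
#' @param region_sets character vector of set names (>= 2), or a named
#'   list of interval sets whose names are used.
#' @param tau tumor fraction in `[0, 1]`.
#' @param dip_depth_scale tumor coverage reduction at `tau = 1`.
#' @param seed optional RNG seed.
#' @param flank_bins,central_bins grid geometry (40 + 20 + 40 bins of
#'   500 bp by default).
#' @param noise_sd per-position-bin noise SD of the averaged profile.
#' @return named list of `DipProfile` objects (see [build_dip_profile()]).
#' @export
simulate_region_profiles <- function(region_sets = c(
                                       "chromhmm_enhancers",
                                       "hic_gained_enhancers",
                                       "yap_taz_gained",
                                       "yap_taz_conserved",
                                       "crc_tss", "universal_dhs"),
                                     tau = 0, dip_depth_scale = 0.3,
                                     seed = NULL,
                                     flank_bins = 40L, central_bins = 20L,
                                     noise_sd = 0.008) {
  if (is.list(region_sets)) region_sets <- names(region_sets)
  if (!length(region_sets)) stop("region_sets must be non-empty")
  stopifnot(tau >= 0, tau <= 1)
  response <- c(chromhmm_enhancers = 1, hic_gained_enhancers = 1,
                yap_taz_gained = 1, yap_taz_conserved = 1,
                crc_tss = 1, universal_dhs = 0.5)
  with_seed(seed, {
    out <- lapply(region_sets, function(nm) {
      r <- unname(response[nm]) %||% 1
      if (is.na(r)) r <- 1
      n_bins <- 2L * flank_bins + central_bins
      central <- seq(flank_bins + 1L, flank_bins + central_bins)
      mean_cov <- rep(1, n_bins)
      mean_cov[central] <- 1 - tau * dip_depth_scale * r
      mean_cov <- mean_cov + stats::rnorm(n_bins, 0, noise_sd)
      new_dip_profile(nm, mean_cov, flank_bins, central_bins,
                      bin_width = 500, n_regions = NA_integer_)
    })
    stats::setNames(out, region_sets)
  })
}
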