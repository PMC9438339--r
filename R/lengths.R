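#' Define a cfDNA fragment-length mixture
#'
#' Fragment lengths are modelled as a discrete mixture over 50-500 bp of
#' Gaussian components (a mode, a spread and a weight each), with an
#' optional sawtooth modulation below the mono-nucleosomal peak emulating
#' the ~10.4 bp periodicity of nuclease cleavage on the nucleosome.
#'
#' @param components data.frame (or matrix) with columns `mode`, `spread`,
#'   `weight`; weights must sum to 1 and modes lie in 50-500 bp.  A
#'   component with `spread = 0` is a point mass.
#' @param periodicity_amp amplitude of the sawtooth modulation applied to
#'   the mixture density at lengths at or below `periodicity_below`
#'   (0 disables it).
#' @param periodicity_period modulation period in bp (default 10.4).
#' @param periodicity_below lengths at or below this are modulated; the
#'   phase is anchored so the modulation peaks here (default 167).
#' @param range integer support of the discretized mixture.
#' @return a `LengthMixture` object.
#' @export
length_mixture <- function(components, periodicity_amp = 0,
                           periodicity_period = 10.4,
                           periodicity_below = 167L,
                           range = 50:500) {
  components <- as.data.frame(components)
  stopifnot(all(c("mode", "spread", "weight") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-8 || any(components$weight < 0)) {
    stop("mixture weights must be nonnegative and sum to 1")
  }
  if (any(components$mode < 50 | components$mode > 500)) {
    stop("mixture modes must lie in [50, 500] bp")
  }
  structure(list(components = components,
                 periodicity = list(amp = periodicity_amp,
                                    period = periodicity_period,
                                    below = periodicity_below),
                 range = as.integer(range)),
            class = "LengthMixture")
}

#' Default healthy cfDNA length mixture
#'
#' Mono-nucleosomal peak at 167 bp (DNA around one nucleosome plus linker),
#' a sub-nucleosomal shoulder near 145 bp carrying the 10.4 bp sawtooth,
#' and a di-nucleosomal component near 334 bp.
#'
#' @param shoulder_weight weight of the sub-nucleosomal shoulder; its
#'   default (0.06) sets the healthy short-fragment (90-150 bp) fraction.
#' @return a `LengthMixture`.
#' @export
healthy_mixture <- function(shoulder_weight = 0.06) {
  stopifnot(shoulder_weight >= 0, shoulder_weight <= 0.5)
  length_mixture(
    data.frame(mode = c(167, 145, 334),
               spread = c(6, 18, 25),
               weight = c(0.9 - shoulder_weight, shoulder_weight, 0.10)),
    periodicity_amp = 0.25)
}

#' Default tumor-derived cfDNA length mixture
#'
#' Same components as [healthy_mixture()] with a much larger share of the
#' sub-nucleosomal shoulder, so tumor fragments are enriched between 90 and
#' 150 bp.  The effect size is an assumption of the generator (chosen so
#' that a 10% tumor fraction is unambiguously detectable against the
#' control panel while 0.1% is not), not an estimate from data.
#'
#' @param shoulder_weight weight of the sub-nucleosomal shoulder
#'   (default 0.40).
#' @return a `LengthMixture`.
#' @export
tumor_mixture <- function(shoulder_weight = 0.40) {
  stopifnot(shoulder_weight >= 0, shoulder_weight <= 0.9)
  length_mixture(
    data.frame(mode = c(167, 145, 334),
               spread = c(6, 18, 25),
               weight = c(0.9 - shoulder_weight, shoulder_weight, 0.10)),
    periodicity_amp = 0.25)
}

#' Discretized probability mass function of a length mixture
#'
#' @param mixture a `LengthMixture`.
#' @return data.frame with columns `length` and `p` (sums to 1).
#' @export
mixture_pmf <- function(mixture) {
  stopifnot(inherits(mixture, "LengthMixture"))
  lens <- mixture$range
  p <- numeric(length(lens))
  for (i in seq_len(nrow(mixture$components))) {
    comp <- mixture$components[i, ]
    if (comp$spread <= 0) {
      d <- as.numeric(lens == round(comp$mode))
    } else {
      d <- stats::dnorm(lens, comp$mode, comp$spread)
      d <- d / sum(d)
    }
    p <- p + comp$weight * d
  }
  per <- mixture$periodicity
  if (per$amp > 0) {
    mod_idx <- lens <= per$below
    p[mod_idx] <- p[mod_idx] *
      (1 + per$amp * cos(2 * pi * (per$below - lens[mod_idx]) / per$period))
  }
  data.frame(length = lens, p = p / sum(p))
}

#' Mean and variance implied by a length mixture
#'
#' Closed-form moments of the discretized mixture, used as the independent
#' reference for Monte-Carlo checks of the sampler.
#' @param mixture a `LengthMixture`.
#' @return named numeric vector `c(mean, var)`.
#' @export
mixture_moments <- function(mixture) {
  pmf <- mixture_pmf(mixture)
  m <- sum(pmf$length * pmf$p)
  v <- sum((pmf$length - m)^2 * pmf$p)
  c(mean = m, var = v)
}

#' Fraction of mixture mass in a length window (inclusive bounds)
#' @param mixture a `LengthMixture`.
#' @param window `c(min, max)` bp, default the short window 90-150.
#' @return scalar probability.
#' @export
mixture_window_fraction <- function(mixture, window = c(90, 150)) {
  pmf <- mixture_pmf(mixture)
  sum(pmf$p[pmf$length >= window[1L] & pmf$length <= window[2L]])
}

#' Simulate cfDNA fragment lengths
#'
#' Draws `n` lengths from the discretized mixture.  With the healthy
#' default and large `n` the empirical mode is 167 bp.
#'
#' @param n number of fragments.
#' @param mixture a `LengthMixture` (default [healthy_mixture()]).
#' @param seed optional RNG seed for reproducibility.
#' @return integer vector of lengths (bp).
#' @export
#' @examples
#' x <- simulate_lengths(1e4, healthy_mixture(), seed = 1)
#' table(x)[which.max(table(x))]
simulate_lengths <- function(n, mixture = healthy_mixture(), seed = NULL) {
  stopifnot(n > 0)
  pmf <- mixture_pmf(mixture)
  with_seed(seed, {
    idx <- sample.int(nrow(pmf), size = n, replace = TRUE, prob = pmf$p)
    as.integer(pmf$length[idx])
  })
}

#' Blend two length mixtures by a tumor fraction
#'
#' Returns the mixture of a healthy and a tumor component with weights
#' `(1 - tau)` and `tau`, the length distribution of a sample whose cfDNA
#' carries tumor fraction `tau`.
#' @param healthy,tumor `LengthMixture` objects with identical support.
#' @param tau tumor fraction in `[0, 1]`.
#' @return a `LengthMixture` (represented by its blended components).
#' @export
blend_mixtures <- function(healthy, tumor, tau) {
  stopifnot(tau >= 0, tau <= 1)
  comp <- rbind(
    transform(healthy$components, weight = weight * (1 - tau)),
    transform(tumor$components, weight = weight * tau))
  length_mixture(comp,
                 periodicity_amp = healthy$periodicity$amp,
                 periodicity_period = healthy$periodicity$period,
                 periodicity_below = healthy$periodicity$below,
                 range = healthy$range)
}
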