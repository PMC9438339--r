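---
title: "Untargeted ctDNA detection from low-coverage cfDNA WGS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted ctDNA detection from low-coverage cfDNA WGS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tumors shed DNA into plasma. This circulating tumor DNA (ctDNA) is a minority
component — commonly below 5% — of the total cell-free DNA (cfDNA), most of
which comes from hematopoietic turnover. Detecting that minority component
from ~6x whole-genome sequencing, without knowing the tumor's mutations,
relies on physical and regulatory differences between tumor-derived and
background cfDNA:

* **Global fragmentation.** Healthy cfDNA peaks at ~167 bp (DNA wrapped
  around one nucleosome plus linker) with a ~10 bp sawtooth below the peak.
  Tumor-derived fragments are shorter, enriching the 90–150 bp window.
* **Regional fragmentation.** The ratio of short (90–150 bp) to long
  (151–220 bp) fragments per 100 kb bin — the S/L ratio — reflects the
  chromatin of the cells of origin and shifts regionally when ctDNA is
  present.
* **Chromatin dip coverage.** Coverage dips over nucleosome-depleted, active
  regulatory regions. Tumor-specific active region sets (enhancers, TSS)
  dip more deeply when ctDNA is present.
* **Somatic copy number alterations (SCNAs).** Arm-level gains and losses
  shift read depth; restricting to 90–150 bp fragments enriches for ctDNA
  and amplifies the shift.

Every signal is calibrated against a panel of healthy controls (the
reference set, 55 controls in the default study conditions), and panel
members are always assessed leave-one-out — each control against the
remaining controls — which supplies the null score distributions that
thresholds are derived from.

# Per-feature models

## Global fragmentation

`length_profile()` computes the fraction of fragments at each length from
90 to 410 bp (out-of-range fragments leave the denominator).
`call_global()` z-scores the sample's short-fragment (90–150 bp) fraction
against the panel and calls ctDNA when the z exceeds the smallest threshold
under which at most 5% of the panel's own leave-one-out z-scores would have
been called — a 95%-specificity calibration. The underlying sources never
state a named test for this per-sample call; the calibrated threshold is
this package's choice, consistent with the 95%-specificity anchoring used
everywhere else in the workflow.

`cohort_compare()` provides the cohort-level two-group machinery: a
two-sided Mann–Whitney U test, exact when both groups have at most 7 values
without ties, otherwise the mid-rank normal approximation with continuity
correction, with Bonferroni adjustment `min(1, p * n_tests)`.

## Regional fragmentation

`sl_profile()` counts short and long fragments per 100 kb bin (midpoint
assignment, inclusive bounds); bins with zero long count are undefined.
`gc_smooth()` residualizes the ratio against GC by local regression
(loess, span 0.75, degree 2, robust fitting), preserving the mean.
`sl_zscores()` standardizes each bin against the panel's per-bin mean and
SD, then **centers the sample's z-scores on their genome-wide median**.
The centering is a deliberate design choice: overall fragment size varies
between individuals, which shifts every bin's S/L ratio coherently; that
coherent component is exactly what the global feature measures, while the
arm-level test is meant to detect regional *redistribution*. Without
centering, ordinary between-individual variation displaces all ~39 arms at
once and the arm test loses its specificity entirely. The panel's
leave-one-out z matrix is centered the same way.

`regional_call()` tests each arm by a two-sided Mann–Whitney U of the
sample's bin z-scores against the pooled leave-one-out bin z-scores of all
controls on that arm, Bonferroni-corrected over the tested arms (at most
39 usable autosome arms; acrocentric p arms with fewer than 5 usable bins
are skipped and shrink the correction denominator). One significant arm at
adjusted p < 0.05 makes the sample ctDNA-positive.

Two documented ambiguities are exposed as options rather than resolved
silently: the short-fragment window is 90–150 bp by default with a
`short_window` override (the alternative 100–150 bp bound appears in parts
of the literature), and `mask_scna()` supports both arm-level masking
(default) and bin-level masking of SCNA regions before regional testing.
Masking exists because ctDNA is regionally enriched over copy-number
gains, which would bias the fragmentation statistics; it only ever shrinks
the tested bin set.

## Chromatin dip coverage

`build_dip_profile()` averages relative coverage around the regions of a
set on a fixed grid: each region's span is length-normalized to 20 central
positions, flanked by 20 kb per side in 500 bp bins, and the averaged
profile is normalized to flank mean 1. Two metrics summarize the dip:
`dip_depth` (flank mean minus central mean) and `dip_area` (the deficit
integrated over the central window, in relative-coverage × kb). The area
drives the call; which of the two the original workflow used is not
documented, so both are computed and stored.

`correct_dip_bias()` compensates regionally enriched ctDNA: regions inside
called SCNA segments are rescaled by the CN-implied factor
`2^segment_log2` (or excluded), and an optional GC covariate is
residualized out. This is deliberately simpler than a trained
coverage-bias model; it is the documented contract of this package, not a
re-implementation of any external tool's bias machinery.

`chromatin_call()` z-scores each set's dip area against the panel and
declares a set significant when the z exceeds the one-sided t-based
prediction bound `qt(1 - alpha, n - 1) * sqrt(1 + 1/n)`, the threshold
that holds the per-set false-positive rate at `alpha` when the panel mean
and SD are estimates rather than known constants. The sample is
ctDNA-positive only when **at least two** region sets are significant.
The two-set rule is the specificity guard: with six sets each tested at
5%, a single-set rule would flag roughly a quarter of healthy samples,
while requiring two concordant sets keeps the expected specificity near
96%. Note that 95% is then a boundary, not a comfortable interior point:
a finite healthy cohort will land below it roughly half the time even
under perfect calibration, which is why the test suite checks the rule
against the one-sided binomial band around 95% rather than a hard cut.

## SCNA calling

`log2_normalize()` takes short-fragment counts in 50 kb bins, residualizes
GC by loess, scales the sample median to 1, divides by the panel's per-bin
expected value and takes log2. `segment_cbs()` is a from-scratch circular
binary segmentation: within each segment the maximal circular t-statistic
over all arcs is tested against permutations (default alpha 0.01, 10,000
permutations with early stopping, minimum width 2 bins) and significant
arcs split the segment recursively. **Merging of adjacent segments is
disabled by default** (`merge_threshold = 0`), matching the upstream
workflow's setting; a positive threshold re-joins neighbors whose means
differ by less than it. The permutation stream runs under a caller-set
seed, so segment tables are bit-reproducible.

`derive_thresholds()` turns the segmented panel into chromosome-specific
limits of blank (LOB): per chromosome, `mean ± z·SD` of control segment
means. Two interpretations of the confidence are offered. The default
(`family = "genome"`) reads 95% as *per-sample* confidence and
Bonferroni-adjusts z over the 2 × 22 chromosome tails a genome-wide screen
tests (z ≈ 3.1), so that only ~5% of healthy samples carry any call at
all. `family = "chromosome"` is the classical per-measurement LOB
(z = 1.645 at 95%); it is simple and textbook-correct per chromosome, but
44 simultaneous 5% tails would flag nearly every healthy genome, which is
incompatible both with this workflow's specificity target and with the
observed behavior of such screens on healthy controls. The genome-family
default is therefore a considered deviation, documented here.

`call_scna()` labels segments beyond the LOB as gains or losses — but only
segments spanning at least 2 Mb. This size floor is the companion to
disabled merging: CBS occasionally emits short spurious segments under
pure noise, and because the split statistic selects the *maximal* arc,
their means are extreme by construction; no mean-based threshold can
separate them from genuine low-amplitude events, but size can, since
genome-wide SCNAs are arm-scale. Sub-2 Mb events belong to
`call_focal()`, which demands independent evidence: a segment under 20 Mb
overlapping 1–100 cancer-census genes whose mean log2 differs from the
bin-weighted mean of the flanking 20 Mb by more than the chromosome LOB
(focal gain/loss), or a neighbor excess of at least 0.58 — the log2 of a
three-copy gain — which qualifies as a focal amplification even without
census overlap. Whether the amplification rule should also respect the
20 Mb limit is ambiguous in the sources; by default it does not, and a
`strict_span` flag imposes it.

## Machine-learning ensemble

`featurize()` builds two feature sets: the global per-length fraction
vector (321 features, rows sum to 1) and the regional mean bin-z per 5 Mb
window. Regional windows are nested **within chromosome arms** — a window
crossing the centromere would average biologically unrelated arms (on the
desk-scale genome it would even cancel opposite-signed arm signatures).
Windows without usable bins are imputed to 0 with a parallel indicator
column.

`bootstrap_cv()` runs the four classifier families — RBF-kernel SVM (cost
from {0.1, 1, 10} by an inner hold-out), random forest (500 trees),
one-hidden-layer feed-forward network (16 units, weight decay 0.05), and
binomial elastic net (alpha 0.5, lambda by inner CV) — for `n_iter`
iterations of stratified 5-fold cross-validation. Within each iteration
the training folds are bootstrap-resampled (stratified, with replacement,
to original size) and the untouched held-out fold is predicted, so every
sample receives exactly one out-of-fold probability per iteration; the
family with the best out-of-fold AUC wins the iteration and its
probabilities are stored. `train_meta()` stacks the two base classifiers'
per-sample mean out-of-fold probabilities in a logistic regression — the
meta-learner never sees in-fold output. `finalize_model()` fits the SVM on
the complete data and sets the decision threshold at the smallest score
that at most 5% of training controls exceed.

A caution that the test suite makes explicit: in-sample sensitivity of the
final models is dominated by memorization (a flexible SVM separates its
own training cohort almost perfectly), so any comparison between feature
sets is made on a held-out synthetic cohort at matched 95% specificity.
There the regional model retains most of its sensitivity while the global
model degrades — the qualitative ordering this architecture expects.

## Reporting

`assemble_report()` collects the per-feature (score, threshold, call)
triplets — SCNA, focal SCNA, global and regional fragmentation, chromatin
coverage, the three ML predictions, and an optional externally estimated
tumor fraction passed through unchanged — into one table; features not
computed are `NA` with a reason. The overall summary is
any-feature-positive and is labeled a convenience aggregate: the
individual feature calls remain the primary readout.
`trend_summary()` classifies each feature's trajectory across a patient's
timepoints as normalized (latest call negative after an earlier
positive), decreasing, increasing, or stable, and reports stepwise
directions alongside.

# The synthetic cohort generator

Real plasma WGS of the kind this pipeline targets is controlled-access;
the generator provides cohorts with the statistical structure the pipeline
assumes, so every stage is testable at desk scale.

**Genome.** `toy_genome()` builds a deterministic 22-autosome, ~99 Mb
genome: 2.5 Mb arms (0.3 Mb p arms on chr13/14/15/21/22, so the usual
acrocentric arms drop out of arm-level testing and 39 usable arms remain),
a smooth GC landscape over 0.30–0.60, a small exclusion list, six named
chromatin region sets and an 80-gene toy census. Nothing derives from a
real assembly; files shipped or written are synthetic by construction.

**Fragment lengths.** A discrete mixture over 50–500 bp: mono-nucleosomal
mode 167 bp (SD 6), a sub-nucleosomal shoulder at 145 bp (SD 18), and a
di-nucleosomal component at 334 bp, with a 10.4 bp sawtooth modulation
(amplitude 0.25) below the peak. The healthy shoulder weight is 0.06
(between-sample SD 0.005); the tumor mixture moves the shoulder weight to
0.40. A sample at tumor fraction tau draws from the (1−tau, tau) blend.
These effect sizes are generator assumptions, chosen once so that a 10%
tumor fraction is unambiguously detectable against the panel while 0.1%
is not; no published effect sizes exist for them.

**Counts.** Expected bin counts are
`depth × gc_bias(gc) × (1 − tau + tau·CN/2)`, drawn negative-binomially
(size 50 for 50 kb tracks, 200 for 100 kb short/long tracks; variance
always exceeds the mean). `depth_equiv = 1800` fragments per 50 kb bin
corresponds to ~6x coverage at 167 bp fragments. The GC bias curve is a
smooth unimodal bump (width 0.2, ~25% depletion at the GC extremes —
the order of real library-preparation bias). Between-sample variability:
log-normal depth factor (SD 0.05) and GC-center jitter (SD 0.008). The
short-fragment share of a bin mixes the healthy and tumor length
propensities by the bin's *local* tumor DNA content, so short-fragment
counts amplify copy-number signal exactly as they do in real cfDNA —
which also means the closed-form `log2(1 + tau·(CN/2 − 1))` expectation
holds for the all-fragment track and is tested there.

**Tumor regional signature.** Tumor-derived fragments carry an arm-level
chromatin signature (a fixed value in [−1, 1] per arm, amplitude 0.25 on
the tumor short-fragment propensity): some arms shed shorter, others
longer fragments than the healthy background, with arm-specific
directions. This is what the regional feature detects after centering.

**Dips.** `simulate_region_profiles()` draws per-set grid profiles with
central expectation `1 − tau·scale·response` (response 1 for the five
CRC-active sets, 0.5 for universal DHS; `dip_depth_scale` defaults to
0.3) and independent N(0, 0.008) noise per position bin.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence-level artifacts (mappability,
alignment error), correlated noise along the genome beyond the GC field,
age- or preanalytics-driven fragmentation differences (the
heparin-associated short-fragment excess after surgery, for instance),
subclonal heterogeneity, and any coupling between the count tracks and
the drawn fragment lengths (the 50 kb and 100 kb tracks of one sample are
drawn independently given the same expectations). Specificity and
sensitivity measured here are properties of the model under its own
assumptions.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere; BAM
  positions are converted on read; fragments map to bins by midpoint;
  length-window bounds are inclusive on both ends.
* Leave-one-out moments are computed in closed form from sums and sums of
  squares (no re-looping), with the unbiased SD over n−2 degrees of
  freedom; negative rounding residue is clamped at zero.
* Calibrated thresholds are order statistics: the smallest value with at
  most `(1 − specificity)·n` scores strictly above it; positivity is
  always *strictly greater than* the threshold.
* Zero-count bins, zero-long-count bins, zero panel SDs, all-masked arms
  and constant segments all have defined behavior (undefined/NA with a
  recorded reason, z = 0 with a warning, NA call, single segment).
* CBS permutations run under the R RNG, so `set.seed`/`seed =` control
  them; early stopping abandons a split test as soon as significance is
  unreachable, which changes nothing about the accept/reject decision.
* Sex chromosomes are absent from the toy genome and excluded from
  calling by design; the panel is mixed-sex in origin and no sex
  normalization is modeled.

# Problem sizes

The packaged study conditions are desk-scale by choice: a ~99 Mb genome
(1,959 retained 50 kb bins, 976 100 kb bins), 55-control panels, 100-null
specificity runs, 5-replicate dilution series, and ML cohorts of 134
cases / 63 controls with held-out evaluation on 90 samples. These sizes
keep every experiment reproducible on a laptop while preserving the
statistical structure (panel calibration, multiplicity burdens, binomial
bands) of the full-scale analysis.

# Known limitations

* The chromosome-specific thresholds of the original workflow are not
  public; the LOB construction here (genome-family confidence, 2 Mb size
  floor) is a reconstruction whose rationale is given above, not a copy.
* The per-set chromatin alpha of 0.05 caps expected two-set specificity
  near 96%; a stricter per-set test would move it higher, at a
  sensitivity cost.
* The regional arm test assumes exchangeability of bin z-scores within an
  arm between sample and pooled controls; strong within-arm
  autocorrelation in real data would make the Mann–Whitney p optimistic.
* ichorCNA-style tumor-fraction quantification is intentionally external:
  the report schema carries an optional tumor-fraction entry supplied by
  the user, and nothing in this package estimates it.
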