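# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb the session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive per-sample child seeds from one master seed (all < 2^31)
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Convert a chrom/start/end data.frame to GRanges (0-based half-open input)
#' @noRd
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Leave-one-out mean and SD per row of a matrix (columns = panel members)
#'
#' Returns list(mean, sd): matrices of the same shape where column j holds
#' the statistic computed over all columns except j.
#' @noRd
loo_stats <- function(x) {
  n <- ncol(x)
  stopifnot(n >= 3L)
  rs <- rowSums(x)
  rss <- rowSums(x^2)
  m <- (rs - x) / (n - 1)
  # sum of squares excluding column j, then unbiased variance over n-1 obs
  ss <- (rss - x^2) - (n - 1) * m^2
  ss[ss < 0] <- 0
  s <- sqrt(ss / (n - 2))
  list(mean = m, sd = s)
}

#' Smallest threshold such that at most (1 - specificity) of `scores` exceed it
#'
#' Used for every panel-calibrated cutoff: a value is "positive" when it is
#' strictly greater than the returned threshold.
#' @noRd
calibrate_threshold <- function(scores, specificity = 0.95) {
  scores <- scores[is.finite(scores)]
  stopifnot(length(scores) >= 3L, specificity > 0, specificity <= 1)
  k <- floor((1 - specificity) * length(scores))  # allowed exceedances
  sorted <- sort(scores, decreasing = TRUE)
  # threshold = (k+1)-th largest score: exactly k scores strictly exceed it
  sorted[k + 1L]
}

#' GC bias correction by local regression
#'
#' Fits a loess of values against GC fraction and rescales each value by
#' fitted/median(fitted), preserving the overall level.  Returns the input
#' unchanged (with a warning) when fewer than `min_points` finite pairs.
#' @noRd
gc_correct_values <- function(values, gc, span = 0.75, min_points = 50L) {
  ok <- is.finite(values) & is.finite(gc)
  if (sum(ok) < min_points) {
    warning("too few bins for GC correction; values returned unchanged")
    return(values)
  }
  fit <- stats::loess(values[ok] ~ gc[ok], span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  fitted <- stats::predict(fit, newdata = gc[ok])
  ref <- stats::median(fitted, na.rm = TRUE)
  out <- values
  adj <- fitted / ref
  adj[!is.finite(adj) | adj <= 0] <- 1
  out[ok] <- values[ok] / adj
  out
}

#' Rank-based ROC AUC (probability a case outscores a control)
#' @noRd
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Empirical mode of an integer vector
#' @noRd
int_mode <- function(x) {
  tab <- tabulate(x - min(x) + 1L)
  min(x) + which.max(tab) - 1L
}
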