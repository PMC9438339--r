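# Per-sample report combining all feature calls, and longitudinal trend
# summaries across timepoints of one patient.

report_entry <- function(score, threshold, call, reason = NA_character_) {
  data.frame(score = score, threshold = threshold, call = call,
             reason = reason, stringsAsFactors = FALSE)
}

# Convert a module call object into a (score, threshold, call) row.
as_report_entry <- function(x) {
  if (is.null(x)) {
    return(report_entry(NA_real_, NA_real_, "NA", "not computed"))
  }
  if (inherits(x, "GlobalCall")) {
    return(report_entry(x$zscore, x$threshold,
                        if (x$positive) "pos" else "neg"))
  }
  if (inherits(x, "RegionalCall")) {
    if (is.na(x$positive)) {
      return(report_entry(NA_real_, NA_real_, "NA", "no testable arm"))
    }
    return(report_entry(length(x$significant_arms), 0,
                        if (x$positive) "pos" else "neg"))
  }
  if (inherits(x, "ChromatinCall")) {
    return(report_entry(x$n_significant, x$min_sets - 1,
                        if (x$positive) "pos" else "neg"))
  }
  if (inherits(x, "SCNACall") || inherits(x, "FocalCall")) {
    return(report_entry(nrow(x), 0, if (nrow(x) > 0) "pos" else "neg"))
  }
  if (is.data.frame(x) && all(c("score", "positive") %in% names(x))) {
    # prediction of a FinalModel / MetaModel
    return(report_entry(x$score[1L], attr(x, "threshold") %||% NA_real_,
                        if (x$positive[1L]) "pos" else "neg"))
  }
  if (is.list(x) && all(c("score", "threshold") %in% names(x))) {
    call <- if (is.na(x$score)) "NA"
            else if (x$score > x$threshold) "pos" else "neg"
    return(report_entry(x$score, x$threshold, call,
                        x$reason %||% NA_character_))
  }
  stop("cannot convert object of class ", class(x)[1L], " to a report entry")
}

#' Assemble the per-sample ctDNA report
#'
#' Combines the per-feature calls into one table (the per-sample readout:
#' SCNAs, focal SCNAs, global and regional fragmentation, chromatin
#' coverage, the three ML predictions, and an optional externally
#' estimated tumor fraction).  Missing features are reported as `NA` with
#' a reason.  The overall summary is any-feature-positive -- a
#' convenience aggregate; the individual feature calls remain primary.
#'
#' @param sample_id sample label.
#' @param scna,focal,global,regional,chromatin call objects from the
#'   respective modules (`NULL` if not computed).
#' @param ml_global,ml_regional,ml_meta prediction rows
#'   (`predict()` output) or `NULL`.
#' @param tumor_fraction optional externally estimated tumor fraction
#'   passed through unchanged (list(score, threshold) or a number).
#' @param timepoint optional free-form timepoint label.
#' @return a `SampleReport`: list(sample_id, timepoint, table, positive,
#'   evidence).
#' @export
assemble_report <- function(sample_id, scna = NULL, focal = NULL,
                            global = NULL, regional = NULL,
                            chromatin = NULL, ml_global = NULL,
                            ml_regional = NULL, ml_meta = NULL,
                            tumor_fraction = NULL, timepoint = NULL) {
  inputs <- list(scna = scna, focal_scna = focal, global_frag = global,
                 regional_frag = regional, chromatin = chromatin,
                 ml_global = ml_global, ml_regional = ml_regional,
                 ml_meta = ml_meta)
  ids <- unlist(lapply(inputs, function(x) attr(x, "sample_id")))
  if (length(ids) && any(ids != sample_id)) {
    stop("conflicting sample ids: ", paste(unique(ids), collapse = ", "),
         " vs ", sample_id)
  }
  if (all(vapply(inputs, is.null, TRUE))) {
    stop("at least one feature must be computed")
  }
  rows <- lapply(inputs, as_report_entry)
  tbl <- do.call(rbind, rows)
  tbl <- cbind(feature = names(inputs), tbl)
  if (!is.null(tumor_fraction)) {
    tf <- if (is.numeric(tumor_fraction)) {
      list(score = tumor_fraction, threshold = NA_real_)
    } else tumor_fraction
    call <- if (is.na(tf$threshold %||% NA)) "NA"
            else if (tf$score > tf$threshold) "pos" else "neg"
    tbl <- rbind(tbl, cbind(feature = "tumor_fraction",
                            report_entry(tf$score, tf$threshold %||% NA_real_,
                                         call,
                                         if (call == "NA")
                                           "no threshold supplied"
                                         else NA_character_)))
  }
  rownames(tbl) <- NULL
  evidence <- tbl$feature[tbl$call == "pos"]
  structure(list(sample_id = sample_id, timepoint = timepoint, table = tbl,
                 positive = length(evidence) > 0, evidence = evidence),
            class = "SampleReport")
}

#' Print a SampleReport summary
#' @param x a `SampleReport`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.SampleReport <- function(x, ...) {
  cat("SampleReport for", x$sample_id,
      if (!is.null(x$timepoint)) paste0("(", x$timepoint, ")"), "\n")
  print(x$table, row.names = FALSE)
  cat("overall (any feature positive):",
      if (x$positive) "ctDNA POSITIVE" else "ctDNA negative", "\n")
  invisible(x)
}

#' Write a SampleReport as JSON
#' @param report a `SampleReport`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(sample_id = report$sample_id,
                            timepoint = report$timepoint,
                            features = report$table,
                            positive = report$positive,
                            evidence = report$evidence),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Per-feature trends across the timepoints of one patient
#'
#' For each feature: `"normalized"` when the latest call is negative
#' after an earlier positive; `"decreasing"` / `"increasing"` when the
#' score strictly declines / rises across consecutive timepoints;
#' otherwise `"stable"`; `NA` with fewer than two evaluable timepoints.
#'
#' @param series list of `SampleReport` objects of one patient, ordered
#'   in time.
#' @param timepoints optional numeric timestamps; an error is raised if
#'   they are not strictly increasing.
#' @return a `LongitudinalSeries`: list(trends, steps, features,
#'   sample_ids).
#' @export
trend_summary <- function(series, timepoints = NULL) {
  if (length(series) < 2L) stop("trends require at least two timepoints")
  if (!is.null(timepoints)) {
    if (any(diff(order(timepoints)) != 1) || any(diff(timepoints) <= 0)) {
      stop("timepoints must be strictly increasing")
    }
  }
  feats <- series[[1L]]$table$feature
  score_mat <- matrix(vapply(series, function(r)
    r$table$score[match(feats, r$table$feature)], numeric(length(feats))),
    nrow = length(feats))
  call_mat <- matrix(vapply(series, function(r)
    r$table$call[match(feats, r$table$feature)], character(length(feats))),
    nrow = length(feats))
  trend_one <- function(scores, calls) {
    ok <- !is.na(scores)
    if (sum(ok) < 2L) return(NA_character_)
    s <- scores[ok]
    cl <- calls[ok]
    if (cl[length(cl)] == "neg" && any(utils::head(cl, -1L) == "pos")) {
      return("normalized")
    }
    d <- diff(s)
    if (all(d < 0)) return("decreasing")
    if (all(d > 0)) return("increasing")
    "stable"
  }
  trends <- vapply(seq_along(feats), function(k)
    trend_one(score_mat[k, ], call_mat[k, ]), "")
  steps <- t(apply(score_mat, 1L, function(s) sign(diff(s))))
  structure(list(trends = stats::setNames(trends, feats),
                 steps = steps, features = feats,
                 sample_ids = vapply(series, `[[`, "", "sample_id")),
            class = "LongitudinalSeries")
}
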