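# Machine-learning ctDNA classification: global and regional fragmentation
# feature sets, bootstrap x cross-validation over four classifier
# families, a supervised logistic meta-learner stacked on out-of-fold
# predictions, and final SVM models thresholded at 95% training-control
# specificity.

#' Build a feature matrix from per-sample fragmentation data
#'
#' `feature_set = "global_frag"`: the per-length fragment fraction vector
#' over 90-410 bp (each row sums to 1).  `feature_set = "regional_frag"`:
#' the mean panel z-score of the 100 kb S/L bins within each 5 Mb genomic
#' window; windows without usable (defined, unmasked) bins are imputed to
#' 0 and flagged by a parallel indicator column.
#'
#' @param samples list of `SyntheticSample` objects, or a list of
#'   precomputed `LengthProfile` (global) / z-scored `SLProfile`
#'   (regional) objects.
#' @param feature_set `"global_frag"` or `"regional_frag"`.
#' @param panel a `ControlPanel` (required for regional features and for
#'   profiles not yet z-scored).
#' @param window regional aggregation window in bp (default 5 Mb).
#' @param labels optional 0/1 or factor labels stored alongside.
#' @return a `FeatureMatrix`: list(x, labels, feature_set).
#' @export
featurize <- function(samples, feature_set = c("global_frag",
                                               "regional_frag"),
                      panel = NULL, window = 5e6, labels = NULL) {
  feature_set <- match.arg(feature_set)
  rows <- lapply(samples, function(s) {
    if (feature_set == "global_frag") {
      prof <- if (inherits(s, "LengthProfile")) s
              else length_profile(s$lengths)
      stats::setNames(prof$fraction, paste0("len_", prof$length))
    } else {
      prof <- if (inherits(s, "SLProfile")) s
              else suppressWarnings(gc_smooth(sl_profile(s)))
      if (is.null(prof$z)) {
        stopifnot(!is.null(panel))
        prof <- sl_zscores(prof, panel)
      }
      # windows are nested within chromosome arms: a window crossing the
      # centromere would average biologically unrelated arms
      arm_start <- stats::ave(prof$start, prof$arm_label,
                              FUN = function(v) min(v))
      win <- paste0(prof$arm_label, "_w",
                    floor((prof$start - arm_start) / window))
      usable <- !prof$masked & is.finite(prof$z)
      wins <- unique(win)
      z_mean <- vapply(wins, function(w) {
        idx <- win == w & usable
        if (any(idx)) mean(prof$z[idx]) else 0
      }, 0)
      imputed <- vapply(wins, function(w) as.numeric(!any(win == w & usable)),
                        0)
      c(stats::setNames(z_mean, paste0("z_", wins)),
        stats::setNames(imputed, paste0("masked_", wins)))
    }
  })
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (!is.null(s$sample_id)) s$sample_id else paste0("s", i)
  }, "")
  structure(list(x = x, labels = labels, feature_set = feature_set),
            class = "FeatureMatrix")
}

# -- classifier families ------------------------------------------------

# Each fitter returns an object with a common predict_prob() route giving
# P(case).  Hyperparameters: SVM RBF with cost chosen on an inner
# hold-out from {0.1, 1, 10}; RF 500 trees; NN one hidden layer of 16
# units with weight decay; elastic net alpha = 0.5, lambda by inner CV.
fit_family <- function(family, x, y) {
  y <- factor(y, levels = c(0, 1))
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, .pad = x[, 1L])  # glmnet needs >= 2 columns
  model <- switch(family,
    svm = {
      costs <- c(0.1, 1, 10)
      if (length(y) >= 12) {
        hold <- stratified_split(y, frac = 1 / 3)
        aucs <- vapply(costs, function(cc) {
          # all-zero indicator columns trigger a harmless scaling warning
          m <- suppressWarnings(
            e1071::svm(x[!hold, , drop = FALSE], y[!hold],
                       kernel = "radial", cost = cc, probability = TRUE))
          rank_auc(predict_prob_svm(m, x[hold, , drop = FALSE]),
                   as.integer(y[hold] == "1"))
        }, 0)
        cost <- costs[which.max(aucs)]
      } else cost <- 1
      m <- suppressWarnings(e1071::svm(x, y, kernel = "radial", cost = cost,
                                       probability = TRUE))
      list(family = "svm", fit = m, cost = cost)
    },
    random_forest = {
      m <- ranger::ranger(x = as.data.frame(x), y = y, probability = TRUE,
                          num.trees = 500, num.threads = 1)
      list(family = "random_forest", fit = m)
    },
    feedforward_nn = {
      m <- nnet::nnet(x, as.integer(y == "1"), size = 16, decay = 0.05,
                      maxit = 200, MaxNWts = 50000, entropy = TRUE,
                      trace = FALSE)
      list(family = "feedforward_nn", fit = m)
    },
    elastic_net = {
      # small inner folds warn about class counts; expected at desk scale
      cv <- suppressWarnings(
        glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0.5,
                          nfolds = 3))
      list(family = "elastic_net", fit = cv)
    },
    stop("unknown classifier family: ", family))
  model$pad <- pad
  model
}

predict_prob_svm <- function(fit, x) {
  p <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
  as.numeric(p[, "1"])
}

predict_prob <- function(model, x) {
  if (isTRUE(model$pad)) x <- cbind(x, .pad = x[, 1L])
  switch(model$family,
    svm = predict_prob_svm(model$fit, x),
    random_forest =
      as.numeric(stats::predict(model$fit,
                                data = as.data.frame(x))$predictions[, "1"]),
    feedforward_nn = as.numeric(stats::predict(model$fit, x)),
    elastic_net = as.numeric(stats::predict(model$fit, newx = x,
                                            s = "lambda.min",
                                            type = "response")))
}

# logical vector marking a stratified random subset of ~frac per class
stratified_split <- function(y, frac) {
  hold <- rep(FALSE, length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    hold[sample(idx, max(1L, round(length(idx) * frac)))] <- TRUE
  }
  hold
}

# stratified fold ids 1..k
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

#' Bootstrap x cross-validated comparison of classifier families
#'
#' Per iteration: a stratified 5-fold split of the samples; for each
#' fold, the training folds are bootstrap-resampled (stratified, with
#' replacement, to their original size), each family is fitted on the
#' resample and predicts the untouched held-out fold.  The family with
#' the highest out-of-fold ROC AUC wins the iteration and its
#' out-of-fold probabilities are stored, so every sample receives exactly
#' one stored probability per iteration.
#'
#' @param features a `FeatureMatrix` or numeric matrix.
#' @param labels 0/1 vector (1 = case); at least 10 per class.
#' @param families subset of `c("svm", "random_forest",
#'   "feedforward_nn", "elastic_net")`.
#' @param n_iter bootstrap iterations (default 100).
#' @param folds CV folds (default 5).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return a `CVResult`: list(per_iteration, oof (n x n_iter matrix of
#'   stored probabilities), mean_oof, labels, families).
#' @export
bootstrap_cv <- function(features, labels,
                         families = c("svm", "random_forest",
                                      "feedforward_nn", "elastic_net"),
                         n_iter = 100L, folds = 5L, seed = NULL) {
  x <- if (inherits(features, "FeatureMatrix")) features$x else features
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  if (sum(y == 0L) < 10 || sum(y == 1L) < 10) {
    stop("need at least 10 samples per class")
  }
  yf <- factor(y, levels = c(0, 1))

  with_seed(seed, {
    oof <- matrix(NA_real_, nrow(x), n_iter)
    iters <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      fold_id <- stratified_folds(yf, folds)
      fam_oof <- matrix(NA_real_, nrow(x), length(families),
                        dimnames = list(NULL, families))
      for (f in seq_len(folds)) {
        tr <- which(fold_id != f)
        te <- which(fold_id == f)
        # stratified bootstrap of the training folds
        boot <- unlist(lapply(levels(yf), function(lv) {
          idx <- tr[yf[tr] == lv]
          sample(idx, length(idx), replace = TRUE)
        }))
        for (fam in families) {
          m <- fit_family(fam, x[boot, , drop = FALSE], y[boot])
          fam_oof[te, fam] <- predict_prob(m, x[te, , drop = FALSE])
        }
      }
      aucs <- apply(fam_oof, 2L, rank_auc, labels = y)
      best <- families[which.max(aucs)]
      oof[, it] <- fam_oof[, best]
      thr <- calibrate_threshold(fam_oof[y == 0L, best], 0.95)
      iters[[it]] <- data.frame(
        iter = it, best_family = best, auc = max(aucs),
        sens_at_95spec = mean(fam_oof[y == 1L, best] > thr))
    }
    structure(list(per_iteration = do.call(rbind, iters), oof = oof,
                   mean_oof = rowMeans(oof), labels = y,
                   families = families),
              class = "CVResult")
  })
}

#' Stack two cross-validated classifiers into a meta-learner
#'
#' Fits a logistic regression on the per-sample mean out-of-fold
#' probabilities of the global and regional base classifiers.  Only
#' out-of-fold predictions enter the fit, so the meta-learner never sees
#' a base model's in-fold output.
#'
#' @param cv_global,cv_regional `CVResult` objects over the same samples
#'   in the same order.
#' @param labels 0/1 vector.
#' @return a `MetaModel`: list(fit, threshold = NULL until calibrated).
#' @export
train_meta <- function(cv_global, cv_regional, labels) {
  y <- as.integer(labels)
  if (length(cv_global$mean_oof) != length(cv_regional$mean_oof) ||
      length(y) != length(cv_global$mean_oof)) {
    stop("sample mismatch between base CV results and labels")
  }
  df <- data.frame(y = y, p_global = cv_global$mean_oof,
                   p_regional = cv_regional$mean_oof)
  fit <- suppressWarnings(stats::glm(y ~ p_global + p_regional,
                                     family = stats::binomial(), data = df))
  score <- as.numeric(stats::predict(fit, type = "response"))
  thr <- calibrate_threshold(score[y == 0L], 0.95)
  structure(list(fit = fit, threshold = thr, scores = score, labels = y),
            class = "MetaModel")
}

#' Fit the final model on all data and calibrate its decision threshold
#'
#' The support vector machine is fitted on the complete data set; the
#' decision threshold is the smallest score such that at most
#' `1 - specificity` of the training controls exceed it.
#'
#' @param features `FeatureMatrix` or matrix.
#' @param labels 0/1 vector with at least 20 controls.
#' @param feature_set label recorded on the model.
#' @param specificity training-control specificity (default 0.95).
#' @param seed RNG seed.
#' @return a `FinalModel`: list(fit, threshold, feature_set,
#'   control_scores, feature_names).
#' @export
finalize_model <- function(features, labels, feature_set = "features",
                           specificity = 0.95, seed = NULL) {
  x <- if (inherits(features, "FeatureMatrix")) features$x else features
  y <- as.integer(labels)
  if (sum(y == 0L) < 20) warning("fewer than 20 controls; threshold unstable")
  with_seed(seed, {
    m <- fit_family("svm", x, y)
    scores <- predict_prob(m, x)
    thr <- calibrate_threshold(scores[y == 0L], specificity)
    structure(list(model = m, threshold = thr, feature_set = feature_set,
                   control_scores = scores[y == 0L],
                   feature_names = colnames(x)),
              class = "FinalModel")
  })
}

#' Score new samples with a final model
#'
#' @param object a `FinalModel`.
#' @param newdata `FeatureMatrix` or matrix with the model's features.
#' @param ... unused.
#' @return data.frame(score, positive); positive iff score > threshold.
#' @export
predict.FinalModel <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "FeatureMatrix")) newdata$x else newdata
  if (!is.matrix(x)) x <- matrix(x, nrow = 1,
                                 dimnames = list(NULL, object$feature_names))
  if (ncol(x) != length(object$feature_names)) {
    stop("feature dimension mismatch: model expects ",
         length(object$feature_names), " features, got ", ncol(x))
  }
  score <- predict_prob(object$model, x)
  data.frame(score = score, positive = score > object$threshold)
}

#' @export
predict.MetaModel <- function(object, newdata, ...) {
  stopifnot(all(c("p_global", "p_regional") %in% names(newdata)))
  score <- as.numeric(stats::predict(object$fit, newdata = newdata,
                                     type = "response"))
  data.frame(score = score, positive = score > object$threshold)
}
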