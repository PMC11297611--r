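# Repeated stratified k-fold cross-validation, the five performance
# metrics, and percentile bootstrap confidence intervals over pooled
# out-of-fold predictions.

#' Repeated stratified k-fold assignment
#'
#' Deals each class round-robin into k folds after a seeded shuffle, so
#' per-fold class counts differ by at most one from perfect stratification;
#' each repetition reshuffles with a distinct derived seed.
#'
#' @param labels 0/1 vector.
#' @param k fold count (default 4).
#' @param repeats number of repetitions.
#' @param seed integer seed.
#' @return integer matrix, patients x repetitions, entries in \code{1..k}.
#' @export
stratifiedKFold <- function(labels, k = 4L, repeats = 1L, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  for (cls in c(0L, 1L))
    if (sum(labels == cls) < k)
      stopf("class %d has fewer members (%d) than folds (%d)",
            cls, sum(labels == cls), k)
  out <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    withSeed(deriveSeed(seed, paste0("fold-rep-", r)), {
      for (cls in c(0L, 1L)) {
        idx <- sample(which(labels == cls))
        out[idx, r] <- rep_len(sample.int(k), length(idx))
      }
    })
  }
  out
}

#' Out-of-fold predictions (and Shapley values) under repeated CV
#'
#' For each repetition and fold: fit the Gaussian-kernel SVM on the training
#' rows restricted to the requested feature subset, score the held-out rows,
#' and (optionally) compute Kernel SHAP attributions for the held-out rows
#' against a background subsampled from that fold's training rows. Every
#' (patient, repetition) pair is scored exactly once.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param featureSubset character vector of feature names (non-empty).
#' @param hyper an \code{\link{svmHyperparams}}.
#' @param folds fold assignment from \code{\link{stratifiedKFold}}.
#' @param shapConfig a \code{\link{kernelShapConfig}}, or \code{NULL} to
#'   skip attribution.
#' @return list with \code{oof} (\code{data.frame}: \code{patient},
#'   \code{repetition}, \code{fold}, \code{score}, \code{pred},
#'   \code{label}) and, when attribution ran, \code{phi} (matrix aligned
#'   with the rows of \code{oof}) and \code{baseValues}.
#' @export
repeatedCVPredict <- function(cohort, featureSubset, hyper = svmHyperparams(),
                              folds, shapConfig = kernelShapConfig()) {
  if (length(featureSubset) == 0) stopf("feature subset is empty")
  X <- cohortMatrix(cohort)[, featureSubset, drop = FALSE]
  y <- cohortLabels(cohort)
  k <- max(folds)
  oof <- list(); phis <- list(); bases <- numeric()
  for (r in seq_len(ncol(folds))) {
    for (f in seq_len(k)) {
      test <- which(folds[, r] == f)
      train <- which(folds[, r] != f)
      if (length(unique(y[train])) < 2)
        stopf("degenerate training split (single class) in repetition %d fold %d", r, f)
      model <- fitSVM(X[train, , drop = FALSE], y[train], hyper)
      s <- decisionScores(model, X[test, , drop = FALSE])
      oof[[length(oof) + 1L]] <- data.frame(
        patient = rownames(X)[test], repetition = r, fold = f,
        score = s, pred = as.integer(s > 0), label = as.integer(y[test]),
        stringsAsFactors = FALSE)
      if (!is.null(shapConfig)) {
        cfg <- shapConfig
        cfg$seed <- deriveSeed(shapConfig$seed, sprintf("shap-r%d-f%d", r, f))
        sm <- shapMatrix(model, X[test, , drop = FALSE],
                         X[train, , drop = FALSE], cfg)
        phis[[length(phis) + 1L]] <- sm$phi
        bases <- c(bases, rep(sm$baseValue, length(test)))
      }
    }
  }
  out <- list(oof = do.call(rbind, oof))
  rownames(out$oof) <- NULL
  if (!is.null(shapConfig)) {
    out$phi <- do.call(rbind, phis)
    out$baseValues <- bases
  }
  out
}

aucMidrank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics pooled over out-of-fold predictions
#'
#' Precision TP/(TP+FP), sensitivity TP/(TP+FN), accuracy, F1, and AUC by
#' the Mann-Whitney statistic with midranks on the decision scores, pooled
#' over all repetitions. The positive class is the case label (1); the
#' decision threshold is a margin of 0.
#'
#' @param oof \code{data.frame} with columns \code{score}, \code{pred},
#'   \code{label} (as produced by \code{\link{repeatedCVPredict}}).
#' @return named list: \code{precision}, \code{sensitivity}, \code{f1},
#'   \code{accuracy}, \code{auc}. With no predicted positives, precision
#'   (and hence F1) is defined as 0 with a warning.
#' @export
computeMetrics <- function(oof) {
  if (length(unique(oof$label)) < 2)
    stopf("both classes must be present in the predictions")
  tp <- sum(oof$pred == 1 & oof$label == 1)
  fp <- sum(oof$pred == 1 & oof$label == 0)
  fn <- sum(oof$pred == 0 & oof$label == 1)
  tn <- sum(oof$pred == 0 & oof$label == 0)
  if (tp + fp == 0) {
    warning("no predicted positives: precision defined as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  sensitivity <- tp / (tp + fn)
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  list(precision = precision, sensitivity = sensitivity, f1 = f1,
       accuracy = (tp + tn) / nrow(oof),
       auc = aucMidrank(oof$score, oof$label))
}

#' Percentile bootstrap confidence interval for a pooled metric
#'
#' Cluster bootstrap over patients: each round resamples patient ids with
#' replacement, carries every resampled patient's predictions across all
#' repetitions (duplicates included), recomputes the metric, and reports the
#' 2.5th/97.5th percentiles. Rounds whose resample lacks a class are redrawn
#' (at most 1000 attempts each).
#'
#' @param oof pooled out-of-fold predictions (needs a \code{patient}
#'   column).
#' @param metric one of \code{"precision"}, \code{"sensitivity"},
#'   \code{"f1"}, \code{"accuracy"}, \code{"auc"}.
#' @param rounds bootstrap rounds (default 200).
#' @param seed integer seed.
#' @return list of class \code{metricCI}: \code{point}, \code{lower},
#'   \code{upper}, \code{rounds}.
#' @export
bootstrapCI <- function(oof, metric = c("precision", "sensitivity", "f1",
                                        "accuracy", "auc"),
                        rounds = 200L, seed = 1L) {
  metric <- match.arg(metric)
  if (rounds < 2) stopf("need at least 2 bootstrap rounds")
  point <- suppressWarnings(computeMetrics(oof)[[metric]])
  pats <- unique(oof$patient)
  byPatient <- split(seq_len(nrow(oof)), oof$patient)
  patLabel <- vapply(byPatient, function(i) oof$label[i[1]], numeric(1))
  stat <- withSeed(deriveSeed(seed, paste0("boot-", metric)), {
    vapply(seq_len(rounds), function(b) {
      for (attempt in seq_len(1000)) {
        take <- sample(pats, length(pats), replace = TRUE)
        if (length(unique(patLabel[take])) == 2) {
          idx <- unlist(byPatient[take], use.names = FALSE)
          return(suppressWarnings(computeMetrics(oof[idx, ])[[metric]]))
        }
      }
      stopf("could not draw a two-class bootstrap resample in 1000 attempts; cohort too small or single-class")
    }, numeric(1))
  })
  q <- unname(stats::quantile(stat, c(0.025, 0.975), na.rm = TRUE))
  structure(list(point = point, lower = q[1], upper = q[2],
                 rounds = as.integer(rounds)),
            class = "metricCI")
}
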