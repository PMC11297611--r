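# The contribution selection algorithm: backward elimination driven by
# mean absolute Shapley importance of a Gaussian-kernel SVM, one feature
# removed per iteration, every iteration scored by repeated stratified CV
# with bootstrap confidence intervals.

CSA_METRICS <- c("precision", "sensitivity", "f1", "accuracy", "auc")

#' Configuration of the contribution selection algorithm
#'
#' @param hyper an \code{\link{svmHyperparams}}.
#' @param k,repeats cross-validation folds and repetitions.
#' @param nCoalitions,backgroundSize Kernel SHAP budget (see
#'   \code{\link{kernelShapConfig}}).
#' @param bootstrapRounds bootstrap rounds per metric per iteration.
#' @param minFeatures smallest feature-set size to evaluate (default 1:
#'   the loop runs the full sweep down to a single feature).
#' @param seed master seed; folds, coalition sampling and bootstrap draw
#'   from named derived streams.
#' @return list of class \code{csaConfig}.
#' @export
csaConfig <- function(hyper = svmHyperparams(), k = 4L, repeats = 5L,
                      nCoalitions = "auto", backgroundSize = 16L,
                      bootstrapRounds = 200L, minFeatures = 1L, seed = 1L) {
  if (minFeatures < 1) stopf("minFeatures must be >= 1")
  structure(list(hyper = hyper, k = as.integer(k), repeats = as.integer(repeats),
                 nCoalitions = nCoalitions,
                 backgroundSize = as.integer(backgroundSize),
                 bootstrapRounds = as.integer(bootstrapRounds),
                 minFeatures = as.integer(minFeatures), seed = as.integer(seed)),
            class = "csaConfig")
}

csaIteration <- function(cohort, featureSet, config, folds) {
  shapCfg <- kernelShapConfig(config$nCoalitions, config$backgroundSize,
                              deriveSeed(config$seed, "shap"))
  cv <- repeatedCVPredict(cohort, featureSet, config$hyper, folds, shapCfg)
  metrics <- lapply(CSA_METRICS, function(m)
    bootstrapCI(cv$oof, m, rounds = config$bootstrapRounds,
                seed = deriveSeed(config$seed, paste0("boot-", length(featureSet)))))
  names(metrics) <- CSA_METRICS
  list(n_features = length(featureSet),
       feature_set = featureSet,
       importances = aggregateImportance(cv$phi),
       metrics = metrics,
       cv = cv)
}

#' Run the backward-elimination contribution selection algorithm
#'
#' Starting from all features, each iteration (i) computes held-out Kernel
#' SHAP attributions and cross-validated performance for the current
#' feature set, (ii) records per-feature mean absolute importance and the
#' five metrics with bootstrap CIs, and (iii) eliminates the feature with
#' the lowest importance (exact ties broken by lexicographically smallest
#' name), until \code{minFeatures} remain. A cohort with M features and
#' \code{minFeatures = 1} therefore evaluates exactly M models. Fully
#' deterministic given cohort, config and seed.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param config a \code{\link{csaConfig}}.
#' @param traceFile optional path: the trace table is (re)written after
#'   every completed iteration, so an interrupted run leaves a usable
#'   partial trace.
#' @param verbose print one progress line per iteration.
#' @return a \linkS4class{CSATrace}.
#' @seealso \code{\link{selectOptimal}}, \code{\link{explainFinal}}
#' @export
runCSA <- function(cohort, config = csaConfig(), traceFile = NULL,
                   verbose = FALSE) {
  stopifnot(is(cohort, "CohortExperiment"))
  featureSet <- sort(rownames(cohort), method = "radix")
  if (length(featureSet) < config$minFeatures)
    stopf("cohort has fewer features (%d) than minFeatures (%d)",
          length(featureSet), config$minFeatures)
  folds <- stratifiedKFold(cohortLabels(cohort), k = config$k,
                           repeats = config$repeats,
                           seed = deriveSeed(config$seed, "folds"))
  records <- list()
  repeat {
    rec <- csaIteration(cohort, featureSet, config, folds)
    rec$cv <- NULL
    if (length(featureSet) > config$minFeatures) {
      imp <- rec$importances
      ord <- order(imp, names(imp), method = "radix")
      rec$removed_feature <- names(imp)[ord[1]]
    }
    records[[length(records) + 1L]] <- rec
    if (verbose)
      message(sprintf("CSA: %4d features | auc %.3f | removed: %s",
                      rec$n_features, rec$metrics$auc$point,
                      rec$removed_feature %||% "-"))
    if (!is.null(traceFile)) {
      tmp <- new("CSATrace", records = records, provenance = list())
      utils::write.table(traceTable(tmp), traceFile, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (length(featureSet) <= config$minFeatures) break
    featureSet <- setdiff(featureSet, rec$removed_feature)
  }
  new("CSATrace", records = records,
      provenance = list(config = config[setdiff(names(config), "hyper")],
                        hyper = unclass(config$hyper),
                        n_patients = ncol(cohort),
                        n_features_start = nrow(cohort),
                        cohort_provenance = provenance(cohort)))
}

#' Select the optimal feature set from a CSA trace
#'
#' For each of the five metrics, the iteration record(s) attaining its
#' maximum point estimate count as winners of that metric (all tied records
#' win). The record winning the most metrics is selected; ties between
#' records are broken toward the fewest features. Comparison uses point
#' estimates only; confidence intervals are reported, not used for
#' selection.
#'
#' @param trace a \linkS4class{CSATrace}, or a list of iteration records.
#' @return list with \code{feature_set}, \code{record} (the winning
#'   iteration record), \code{wins} (metric names it won), and
#'   \code{metric_winners} (per metric, the n_features of all winning
#'   records).
#' @export
selectOptimal <- function(trace) {
  records <- if (is(trace, "CSATrace")) traceRecords(trace) else trace
  if (!length(records)) stopf("empty trace")
  eps <- 1e-12
  pts <- sapply(CSA_METRICS, function(m)
    vapply(records, function(r) r$metrics[[m]]$point, numeric(1)))
  pts <- matrix(pts, nrow = length(records),
                dimnames = list(NULL, CSA_METRICS))
  winners <- lapply(CSA_METRICS, function(m) {
    v <- pts[, m]
    which(v >= max(v) - eps)
  })
  names(winners) <- CSA_METRICS
  wins <- integer(length(records))
  for (w in winners) wins[w] <- wins[w] + 1L
  nf <- vapply(records, function(r) r$n_features, numeric(1))
  best <- which(wins == max(wins))
  best <- best[which.min(nf[best])]
  list(feature_set = records[[best]]$feature_set,
       record = records[[best]],
       wins = CSA_METRICS[vapply(CSA_METRICS, function(m)
         best %in% winners[[m]], logical(1))],
       metric_winners = lapply(winners, function(w) nf[w]))
}

#' Held-out explanation of a selected feature set
#'
#' Recomputes held-out Kernel SHAP attributions for the selected features
#' under the same repeated-CV scheme, and exports the two interpretation
#' tables: a beeswarm table (one row per patient x repetition, carrying each
#' feature's attribution \code{phi.<feature>}, its observed 0/1 value
#' \code{val.<feature>} and the base value) and a bar table of mean absolute
#' importance sorted descending (stable on ties).
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param featureSet character vector, subset of the cohort's features.
#' @param config a \code{\link{csaConfig}}.
#' @return list with \code{beeswarm} (\code{data.frame}, one row per
#'   patient x repetition), \code{importances} (\code{data.frame}:
#'   \code{feature}, \code{mean_abs_shap}), and \code{oof}.
#' @export
explainFinal <- function(cohort, featureSet, config = csaConfig()) {
  missing <- setdiff(featureSet, rownames(cohort))
  if (length(missing))
    stopf("feature(s) not in cohort: %s", paste(missing, collapse = ", "))
  folds <- stratifiedKFold(cohortLabels(cohort), k = config$k,
                           repeats = config$repeats,
                           seed = deriveSeed(config$seed, "folds"))
  shapCfg <- kernelShapConfig(config$nCoalitions, config$backgroundSize,
                              deriveSeed(config$seed, "shap"))
  cv <- repeatedCVPredict(cohort, featureSet, config$hyper, folds, shapCfg)
  X <- cohortMatrix(cohort)[, featureSet, drop = FALSE]
  bee <- data.frame(patient = cv$oof$patient, repetition = cv$oof$repetition,
                    base_value = cv$baseValues, stringsAsFactors = FALSE)
  for (j in seq_along(featureSet)) {
    bee[[paste0("phi.", featureSet[j])]] <- cv$phi[, j]
    bee[[paste0("val.", featureSet[j])]] <- X[cv$oof$patient, j]
  }
  rownames(bee) <- NULL
  imp <- aggregateImportance(cv$phi)
  ord <- order(-imp, names(imp), method = "radix")
  list(beeswarm = bee,
       importances = data.frame(feature = names(imp)[ord],
                                mean_abs_shap = unname(imp[ord]),
                                stringsAsFactors = FALSE),
       oof = cv$oof)
}
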