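#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Case-control cohort of binary problem-list features
#'
#' A \code{CohortExperiment} holds a patient cohort described by binarized
#' past-medical-history ("problem list") items: a strictly 0/1 incidence
#' matrix, a binary case/control label per patient, and free-text provenance.
#' It extends \linkS4class{SummarizedExperiment} with features as rows and
#' patients as columns, so the usual Bioconductor accessors
#' (\code{assay}, \code{colData}, subsetting with \code{[}) apply. Analysis
#' code consumes the transposed patient-by-feature view via
#' \code{\link{cohortMatrix}}.
#'
#' Validity requires: all assay entries in \{0, 1\}; unique feature names and
#' patient ids; a label column in \code{colData} with values in \{0, 1\}
#' (1 = case) containing at least one case and one control.
#'
#' @slot provenance free-text record of the generator configuration or the
#'   ingest source that produced the cohort.
#'
#' @seealso \code{\link{CohortExperiment}} (constructor),
#'   \code{\link{simulateCohort}}, \code{\link{binarizeProblemLists}}
#' @export
setClass("CohortExperiment",
  contains = "SummarizedExperiment",
  slots = c(provenance = "character")
)

setValidity("CohortExperiment", function(object) {
  m <- assay(object, "presence")
  msgs <- character()
  if (nrow(object) > 0 && ncol(object) > 0 && !isBinary(m))
    msgs <- c(msgs, "assay 'presence' must contain only 0/1 values")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "feature names must be unique")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "patient ids must be unique")
  if (!"label" %in% colnames(colData(object))) {
    msgs <- c(msgs, "colData must contain a 'label' column")
  } else {
    lab <- colData(object)$label
    if (!all(lab %in% c(0L, 1L)))
      msgs <- c(msgs, "labels must be 0 (control) or 1 (case)")
    if (ncol(object) > 0 && (sum(lab == 1L) < 1L || sum(lab == 0L) < 1L))
      msgs <- c(msgs, "cohort must contain at least one case and one control")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortExperiment from a patient-by-feature binary matrix
#'
#' @param matrix numeric or integer matrix, patients in rows and features in
#'   columns, entries strictly 0/1. Row names are patient ids, column names
#'   feature names; defaults (\code{P1..}, \code{F1..}) are supplied if
#'   missing.
#' @param labels integer/numeric vector of 0/1 labels (1 = case), one per
#'   patient row.
#' @param provenance free-text provenance string.
#' @param colData optional additional per-patient metadata
#'   (\code{data.frame} or \code{DataFrame}) merged into \code{colData};
#'   may carry continuous covariates such as age or serum titer.
#'
#' @return a \linkS4class{CohortExperiment}.
#' @examples
#' m <- matrix(c(1, 0, 1, 0, 0, 1, 1, 1), nrow = 4,
#'             dimnames = list(paste0("P", 1:4), c("gerd", "depression")))
#' ce <- CohortExperiment(m, labels = c(1, 1, 0, 0))
#' cohortLabels(ce)
#' @export
CohortExperiment <- function(matrix, labels, provenance = "unspecified",
                             colData = NULL) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("P", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix)) && ncol(matrix) > 0)
    colnames(matrix) <- paste0("F", seq_len(ncol(matrix)))
  if (length(labels) != nrow(matrix))
    stopf("length of labels (%d) must equal the number of patients (%d)",
          length(labels), nrow(matrix))
  cd <- DataFrame(label = as.integer(labels), row.names = rownames(matrix))
  if (!is.null(colData)) {
    extra <- as(colData, "DataFrame")
    for (nm in setdiff(colnames(extra), "label")) cd[[nm]] <- extra[[nm]]
  }
  storage.mode(matrix) <- "integer"
  new("CohortExperiment",
      SummarizedExperiment(assays = list(presence = t(matrix)), colData = cd),
      provenance = as.character(provenance))
}

#' @describeIn CohortExperiment patient-by-feature 0/1 matrix (the analysis
#'   orientation: patients in rows).
#' @param x a \code{CohortExperiment}.
#' @export
cohortMatrix <- function(x) {
  stopifnot(is(x, "CohortExperiment"))
  t(assay(x, "presence"))
}

#' @describeIn CohortExperiment integer 0/1 label per patient (1 = case),
#'   named by patient id.
#' @export
cohortLabels <- function(x) {
  stopifnot(is(x, "CohortExperiment"))
  structure(colData(x)$label, names = colnames(x))
}

#' @describeIn CohortExperiment patient identifiers.
#' @export
patientIds <- function(x) {
  stopifnot(is(x, "CohortExperiment"))
  colnames(x)
}

#' @describeIn CohortExperiment free-text provenance of the cohort.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "CohortExperiment"))
  x@provenance
}

#' @export
setMethod("show", "CohortExperiment", function(object) {
  lab <- colData(object)$label
  cat(sprintf(
    "CohortExperiment: %d patients (%d cases / %d controls) x %d features\n",
    ncol(object), sum(lab == 1L), sum(lab == 0L), nrow(object)))
  cat("provenance:", substr(object@provenance, 1, 70), "\n")
})

#' Shapley attribution of a single prediction
#'
#' Per-feature Shapley values \eqn{\phi_i} plus the base value
#' \eqn{\phi_0 = v(\emptyset)} (the mean model score over the background set)
#' for one explained instance. The efficiency axiom requires
#' \eqn{\phi_0 + \sum_i \phi_i} to equal the model score of the instance;
#' \code{\link{exactShapley}} guarantees it to 1e-9 and
#' \code{\link{kernelShap}} enforces it exactly through the constrained
#' regression.
#'
#' @slot phi named numeric vector of per-feature attributions.
#' @slot baseValue numeric scalar, mean background score.
#' @export
setClass("ShapVector",
  slots = c(phi = "numeric", baseValue = "numeric"))

setValidity("ShapVector", function(object) {
  if (length(object@baseValue) != 1L) return("baseValue must be a scalar")
  if (is.null(names(object@phi)) && length(object@phi) > 0)
    return("phi must be named by feature")
  TRUE
})

ShapVector <- function(phi, baseValue) new("ShapVector", phi = phi,
                                           baseValue = as.numeric(baseValue))

#' @describeIn ShapVector per-feature attributions.
#' @param x a \code{ShapVector}.
#' @export
shapValues <- function(x) { stopifnot(is(x, "ShapVector")); x@phi }

#' @describeIn ShapVector base value \eqn{\phi_0}.
#' @export
baseValue <- function(x) { stopifnot(is(x, "ShapVector")); x@baseValue }

#' @export
setMethod("show", "ShapVector", function(object) {
  cat(sprintf("ShapVector over %d features; base value %.4f; sum(phi) %.4f\n",
              length(object@phi), object@baseValue, sum(object@phi)))
  top <- head(object@phi[order(-abs(object@phi))], 5)
  for (nm in names(top)) cat(sprintf("  %-30s %+ .4f\n", nm, top[[nm]]))
})

#' Backward-elimination trace of the contribution selection algorithm
#'
#' Ordered record of every iteration of the CSA loop, from the full feature
#' set down to \code{minFeatures}. Each iteration record carries the feature
#' set, per-feature mean absolute Shapley importance, the five
#' cross-validated performance metrics with bootstrap confidence intervals,
#' and the feature eliminated at the end of the iteration (absent on the
#' final one). Consecutive feature sets are strictly nested.
#'
#' @slot records list of iteration records (see \code{\link{runCSA}}).
#' @slot provenance list echoing the configuration and seeds of the run.
#' @seealso \code{\link{runCSA}}, \code{\link{selectOptimal}},
#'   \code{\link{traceTable}}
#' @export
setClass("CSATrace", slots = c(records = "list", provenance = "list"))

setValidity("CSATrace", function(object) {
  ns <- vapply(object@records, function(r) r$n_features, numeric(1))
  if (length(ns) > 1 && any(diff(ns) != -1))
    return("iteration records must step down one feature at a time")
  TRUE
})

#' @describeIn CSATrace iteration records as a list.
#' @param x a \code{CSATrace}.
#' @export
traceRecords <- function(x) { stopifnot(is(x, "CSATrace")); x@records }

#' @describeIn CSATrace number of iteration records.
#' @export
setMethod("length", "CSATrace", function(x) length(x@records))

#' @export
setMethod("show", "CSATrace", function(object) {
  ns <- vapply(object@records, function(r) r$n_features, numeric(1))
  cat(sprintf("CSATrace: %d iterations (%d -> %d features)\n",
              length(ns), max(ns), min(ns)))
})

#' Flatten a CSA trace to one row per iteration
#'
#' @param trace a \linkS4class{CSATrace}.
#' @return \code{data.frame} with \code{n_features}, \code{removed_feature},
#'   and for each metric (precision, sensitivity, f1, accuracy, auc) the
#'   point estimate and 95\% bootstrap bounds
#'   (\code{<metric>}, \code{<metric>_lo}, \code{<metric>_hi}).
#' @export
traceTable <- function(trace) {
  stopifnot(is(trace, "CSATrace"))
  rows <- lapply(trace@records, function(r) {
    out <- list(n_features = r$n_features,
                removed_feature = r$removed_feature %||% NA_character_)
    for (m in names(r$metrics)) {
      ci <- r$metrics[[m]]
      out[[m]] <- ci$point
      out[[paste0(m, "_lo")]] <- ci$lower
      out[[paste0(m, "_hi")]] <- ci$upper
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
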