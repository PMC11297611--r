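# Cohort summary statistics: exact association tests and the formatted
# demographics table. Both tests are the primitives specified for this
# pipeline: Fisher by explicit hypergeometric enumeration, Welch from
# summary statistics (patient-level means are often all that is published).

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' Exact test of association in a 2x2 table with fixed margins. The
#' two-sided p-value follows the SPSS/R convention: the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table
#' (a relative tolerance of 1e-7 absorbs floating-point error). The
#' enumeration runs over the feasible range of cell \code{a}.
#'
#' @param a,b,c,d non-negative cell counts: \code{a} cases with the trait,
#'   \code{b} cases without, \code{c} controls with, \code{d} controls
#'   without.
#' @return list with \code{p_value}, plus \code{odds_table} (the input) for
#'   reporting. If a margin is zero (no patient has, or lacks, the trait, or
#'   a class is empty) the test is vacuous and \code{p_value = 1} with a
#'   warning.
#' @examples
#' fisherExactTwoSided(1, 22, 2, 23)$p_value   # 1.000
#' fisherExactTwoSided(12, 11, 7, 18)$p_value  # ~0.140
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("contingency counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  res <- list(table = counts)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate 2x2 margin: p-value defined as 1")
    res$p_value <- 1
    return(res)
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  pObs <- stats::dhyper(a, c1, n - c1, r1)
  res$p_value <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  res
}

#' Welch's two-sample t-test from group summaries
#'
#' Location test not assuming equal variances, computed from per-group mean,
#' standard deviation and size: \eqn{t = (\bar x_a - \bar x_b) /
#' \sqrt{s_a^2/n_a + s_b^2/n_b}} with Welch-Satterthwaite degrees of
#' freedom, two-sided p from the t distribution.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries; \code{sd >= 0},
#'   \code{n >= 2}.
#' @return list with \code{statistic} (t), \code{df}, \code{p_value}.
#' @examples
#' welchTFromSummary(54.3, 10.7, 23, 45.9, 21.6, 25)$p_value  # ~0.093
#' @export
welchTFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (nA < 2 || nB < 2) stopf("each group needs n >= 2")
  if (sdA < 0 || sdB < 0) stopf("standard deviations must be non-negative")
  va <- sdA^2 / nA; vb <- sdB^2 / nB
  if (va + vb == 0) {
    # zero variance in both groups: identical constants are a null result,
    # distinct constants an infinitely significant one
    if (meanA == meanB) return(list(statistic = 0, df = nA + nB - 2, p_value = 1))
    return(list(statistic = sign(meanA - meanB) * Inf, df = nA + nB - 2,
                p_value = 0))
  }
  t <- (meanA - meanB) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Welch's t-test from patient-level samples
#'
#' Identical to \code{\link{welchTFromSummary}} applied to the samples'
#' means and standard deviations.
#'
#' @param valuesA,valuesB numeric vectors, at least 2 values each.
#' @return as \code{\link{welchTFromSummary}}.
#' @export
welchTFromSamples <- function(valuesA, valuesB) {
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stopf("each group needs at least 2 values")
  welchTFromSummary(mean(valuesA), stats::sd(valuesA), length(valuesA),
                    mean(valuesB), stats::sd(valuesB), length(valuesB))
}

formatCount <- function(k, n) {
  pct <- if (n > 0) roundHalfUp(100 * k / n) else 0
  sprintf("%d/%d (%d)", k, n, pct)
}

#' Demographics-table summary of a cohort
#'
#' Builds the case-vs-control comparison table: binary variables (problem-
#' list features) are reported as \code{k/n (pct)} per class with a
#' two-sided Fisher exact p; continuous per-patient covariates from
#' \code{colData} are reported as \code{mean (SD)} with a Welch t p.
#' Percentages round half away from zero; p-values are additionally
#' formatted to 3 decimals in \code{p_display}.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param binaryVars character vector of feature names; default all features.
#' @param continuousVars character vector of \code{colData} column names
#'   (e.g. \code{"titer"}); default none.
#' @return \code{data.frame} with columns \code{variable}, \code{type},
#'   \code{cases}, \code{controls}, \code{p_value}, \code{p_display}.
#' @export
table1Report <- function(cohort, binaryVars = NULL, continuousVars = character()) {
  m <- cohortMatrix(cohort)
  lab <- cohortLabels(cohort)
  if (is.null(binaryVars)) binaryVars <- colnames(m)
  unknown <- setdiff(binaryVars, colnames(m))
  if (length(unknown))
    stopf("unknown binary variable(s): %s", paste(unknown, collapse = ", "))
  cd <- as.data.frame(colData(cohort))
  unknown <- setdiff(continuousVars, colnames(cd))
  if (length(unknown))
    stopf("unknown continuous variable(s): %s", paste(unknown, collapse = ", "))

  rows <- list()
  for (v in continuousVars) {
    x <- cd[[v]]
    res <- welchTFromSamples(x[lab == 1], x[lab == 0])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      cases = sprintf("%.1f (%.1f)", mean(x[lab == 1]), stats::sd(x[lab == 1])),
      controls = sprintf("%.1f (%.1f)", mean(x[lab == 0]), stats::sd(x[lab == 0])),
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  for (v in binaryVars) {
    kc <- sum(m[lab == 1, v]); nc <- sum(lab == 1)
    ku <- sum(m[lab == 0, v]); nu <- sum(lab == 0)
    res <- suppressWarnings(fisherExactTwoSided(kc, nc - kc, ku, nu - ku))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "binary",
      cases = formatCount(kc, nc), controls = formatCount(ku, nu),
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_display <- sprintf("%.3f", out$p_value)
  out
}
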