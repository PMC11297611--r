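#' Configuration for the synthetic problem-list cohort generator
#'
#' Assembles and validates the parameters that define a simulated
#' case-control cohort of binary past-medical-history features. Defaults
#' mirror the study conditions the package targets: 23 cases, 25 controls,
#' and 319 unique binarized problem-list items.
#'
#' @param nCases,nControls number of case / control patients.
#' @param nFeatures total number of binary features (columns).
#' @param informative \code{data.frame} with columns \code{name},
#'   \code{prevCases}, \code{prevControls} describing planted discriminative
#'   features (class-specific Bernoulli prevalences); \code{NULL} for none.
#' @param noisePrevalenceSampler function \code{n -> n} prevalences in
#'   \eqn{[0,1]} used to draw one background prevalence per non-informative
#'   feature, shared by both classes. Default \code{rbeta(n, 0.6, 5)}
#'   (median about 0.08), matching the sparsity of real problem lists.
#' @param titerLognormal optional list with \code{meanlogCases},
#'   \code{sdlogCases}, \code{meanlogControls}, \code{sdlogControls}:
#'   per-class lognormal parameters for a cosmetic per-patient serum-titer
#'   covariate written to \code{colData$titer}.
#' @param correlationBlocks optional list of blocks, each a list with
#'   \code{features} (integer indices of non-informative columns) and
#'   \code{rho} (probability that a feature copies the block's shared latent
#'   Bernoulli draw instead of its own). Off by default; real problem lists
#'   co-occur, independent features are the documented default.
#' @param seed integer seed; the cohort is bit-reproducible from it.
#'
#' @return validated list of class \code{cohortConfig}.
#' @seealso \code{\link{simulateCohort}}
#' @export
cohortConfig <- function(nCases = 23L, nControls = 25L, nFeatures = 319L,
                         informative = NULL,
                         noisePrevalenceSampler = function(n) stats::rbeta(n, 0.6, 5),
                         titerLognormal = NULL,
                         correlationBlocks = NULL,
                         seed = 1L) {
  chkCount <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x))
      stopf("configuration error: '%s' must be a positive integer count", nm)
  }
  chkCount(nCases, "nCases"); chkCount(nControls, "nControls")
  if (length(nFeatures) != 1L || is.na(nFeatures) || nFeatures < 0 ||
      nFeatures != as.integer(nFeatures))
    stopf("configuration error: 'nFeatures' must be a non-negative integer")
  if (!is.null(informative)) {
    informative <- as.data.frame(informative, stringsAsFactors = FALSE)
    need <- c("name", "prevCases", "prevControls")
    if (!all(need %in% colnames(informative)))
      stopf("configuration error: 'informative' needs columns %s",
            paste(need, collapse = ", "))
    pr <- c(informative$prevCases, informative$prevControls)
    if (any(is.na(pr)) || any(pr < 0) || any(pr > 1))
      stopf("configuration error: informative prevalences must lie in [0,1]")
    if (anyDuplicated(informative$name))
      stopf("configuration error: informative feature names must be unique")
    if (nrow(informative) > nFeatures)
      stopf("configuration error: more informative features (%d) than 'nFeatures' (%d)",
            nrow(informative), nFeatures)
  }
  if (!is.function(noisePrevalenceSampler))
    stopf("configuration error: 'noisePrevalenceSampler' must be a function")
  structure(list(nCases = as.integer(nCases), nControls = as.integer(nControls),
                 nFeatures = as.integer(nFeatures), informative = informative,
                 noisePrevalenceSampler = noisePrevalenceSampler,
                 titerLognormal = titerLognormal,
                 correlationBlocks = correlationBlocks,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Simulate a case-control cohort of binary problem-list features
#'
#' Samples a patient-by-feature 0/1 matrix feature-wise Bernoulli:
#' planted informative columns use class-specific prevalences; every other
#' column uses a single background prevalence drawn once from the
#' configured sampler and shared by cases and controls, so non-informative
#' columns carry no class signal by construction. Labels contain exactly
#' \code{nCases} ones. Identical config + seed gives a bit-identical cohort.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{CohortExperiment}; planted feature columns are
#'   named as configured, noise columns \code{noise_001, ...} (ordering:
#'   informative features first, then noise).
#' @examples
#' ce <- simulateCohort(cohortConfig(nCases = 5, nControls = 5,
#'                                   nFeatures = 8, seed = 7))
#' dim(cohortMatrix(ce))
#' @export
simulateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  withSeed(config$seed, {
    nPat <- config$nCases + config$nControls
    labels <- c(rep(1L, config$nCases), rep(0L, config$nControls))
    nInf <- if (is.null(config$informative)) 0L else nrow(config$informative)
    nNoise <- config$nFeatures - nInf
    fnames <- c(if (nInf) as.character(config$informative$name),
                if (nNoise) sprintf("noise_%03d", seq_len(nNoise)))
    m <- matrix(0L, nPat, config$nFeatures,
                dimnames = list(sprintf("P%03d", seq_len(nPat)), fnames))
    if (nInf) for (j in seq_len(nInf)) {
      p <- ifelse(labels == 1L, config$informative$prevCases[j],
                  config$informative$prevControls[j])
      m[, j] <- stats::rbinom(nPat, 1L, p)
    }
    if (nNoise) {
      bg <- config$noisePrevalenceSampler(nNoise)
      if (any(bg < 0) || any(bg > 1))
        stopf("configuration error: 'noisePrevalenceSampler' returned values outside [0,1]")
      for (j in seq_len(nNoise))
        m[, nInf + j] <- stats::rbinom(nPat, 1L, bg[j])
      if (!is.null(config$correlationBlocks)) {
        for (blk in config$correlationBlocks) {
          idx <- nInf + blk$features
          pBlk <- mean(bg[blk$features])
          latent <- stats::rbinom(nPat, 1L, pBlk)
          for (j in idx) {
            use <- stats::runif(nPat) < blk$rho
            m[use, j] <- latent[use]
          }
        }
      }
    }
    cd <- NULL
    if (!is.null(config$titerLognormal)) {
      tl <- config$titerLognormal
      titer <- ifelse(labels == 1L,
                      stats::rlnorm(nPat, tl$meanlogCases, tl$sdlogCases),
                      stats::rlnorm(nPat, tl$meanlogControls, tl$sdlogControls))
      cd <- data.frame(titer = titer, row.names = rownames(m))
    }
    CohortExperiment(m, labels,
                     provenance = sprintf(
                       "simulateCohort(nCases=%d, nControls=%d, nFeatures=%d, informative=%d, seed=%d)",
                       config$nCases, config$nControls, config$nFeatures, nInf,
                       config$seed),
                     colData = cd)
  })
}

canonicalizeItem <- function(item) tolower(trimws(item))

#' Binarize long-format problem-list records into a cohort
#'
#' Builds the patient-by-feature incidence matrix from raw problem-list
#' records: the vocabulary is the sorted set of canonical item names after
#' applying the optional consolidation map (lookup is case-folded and
#' whitespace-stripped; unmapped items keep their verbatim trimmed string),
#' and entry (patient, feature) is 1 iff the patient has at least one record
#' mapping to that feature (merged records combine by logical OR, e.g.
#' "depressive symptoms" and "major depressive disorder" both mapped to
#' "depression" yield one column). Patients present in \code{labels} but
#' without records appear as all-zero rows. Column order is lexicographic
#' (C locale) for deterministic downstream tie-breaking.
#'
#' @param records \code{data.frame} with columns \code{patient_id},
#'   \code{item} (verbatim problem-list entries; non-empty strings).
#' @param labels named 0/1 vector (names = patient ids), or a
#'   \code{data.frame} with columns \code{patient_id}, \code{label}.
#' @param consolidationMap optional named character vector mapping raw item
#'   strings to canonical names, or a \code{data.frame} with columns
#'   \code{item}, \code{canonical}.
#' @return a \linkS4class{CohortExperiment}.
#' @export
binarizeProblemLists <- function(records, labels, consolidationMap = NULL) {
  if (is.data.frame(labels)) {
    labels <- structure(labels$label, names = as.character(labels$patient_id))
  }
  if (!all(labels %in% c(0, 1)))
    stopf("ingest error: labels must be 0/1")
  if (is.data.frame(consolidationMap))
    consolidationMap <- structure(as.character(consolidationMap$canonical),
                                  names = as.character(consolidationMap$item))
  if (!is.null(consolidationMap))
    names(consolidationMap) <- canonicalizeItem(names(consolidationMap))
  pats <- names(labels)
  if (is.null(pats) || anyDuplicated(pats))
    stopf("ingest error: labels must be uniquely named by patient_id")

  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0) {
    if (any(!nzchar(trimws(records$patient_id))) ||
        any(!nzchar(trimws(records$item))))
      stopf("ingest error: empty patient_id or item string in records")
    unknown <- setdiff(unique(records$patient_id), pats)
    if (length(unknown))
      stopf("ingest error: record patient id(s) absent from labels: %s",
            paste(unknown, collapse = ", "))
  }

  mapItem <- function(item) {
    key <- canonicalizeItem(item)
    mapped <- !is.null(consolidationMap) & key %in% names(consolidationMap)
    out <- trimws(item)
    if (any(mapped)) out[mapped] <- consolidationMap[key[mapped]]
    out
  }
  canon <- if (nrow(records)) mapItem(records$item) else character()
  vocab <- sort(unique(canon), method = "radix")
  if (!is.null(consolidationMap) && nrow(records) > 0 && length(vocab) == 0)
    stopf("ingest error: consolidation map produced an empty vocabulary")
  if (length(vocab) == 0)
    warning("no problem-list records: cohort has zero feature columns")

  m <- matrix(0L, length(pats), length(vocab),
              dimnames = list(pats, vocab))
  if (nrow(records))
    m[cbind(match(records$patient_id, pats), match(canon, vocab))] <- 1L
  CohortExperiment(m, labels[pats],
                   provenance = sprintf(
                     "binarizeProblemLists(%d records, %d patients, %d items%s)",
                     nrow(records), length(pats), length(vocab),
                     if (is.null(consolidationMap)) "" else ", consolidated"))
}

#' Export a cohort to long-format problem-list records
#'
#' Inverse of \code{\link{binarizeProblemLists}} up to column order: one
#' record per (patient, feature) cell equal to 1.
#'
#' @param cohort a \linkS4class{CohortExperiment}.
#' @return \code{data.frame} with columns \code{patient_id}, \code{item}.
#' @export
cohortToProblemLists <- function(cohort) {
  m <- cohortMatrix(cohort)
  idx <- which(m == 1L, arr.ind = TRUE)
  data.frame(patient_id = rownames(m)[idx[, 1]],
             item = colnames(m)[idx[, 2]],
             stringsAsFactors = FALSE)[order(idx[, 1], idx[, 2]), ]
}

#' Read / write cohort matrices and problem-list TSV files
#'
#' Plain-TSV interchange. The matrix format has a header row, first column
#' \code{patient_id}, remaining columns feature names, cells 0/1; labels are
#' a two-column TSV \code{patient_id<TAB>label}; problem lists are
#' \code{patient_id<TAB>item}; consolidation maps are
#' \code{item<TAB>canonical}. Lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @param cohort a \linkS4class{CohortExperiment}.
#' @param labelsPath path to the labels TSV accompanying a matrix TSV.
#' @param hashComment optional string written as a leading \code{#} comment
#'   (used by the pipeline to stamp the configuration hash).
#' @return \code{readCohortMatrix} returns a \code{CohortExperiment};
#'   \code{readProblemLists} and \code{readConsolidationMap} return
#'   \code{data.frame}s; the writers return the path invisibly.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
readCohortMatrix <- function(path, labelsPath) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  lab <- utils::read.delim(labelsPath, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  miss <- setdiff(rownames(m), as.character(lab$patient_id))
  if (length(miss))
    stopf("ingest error: matrix patient id(s) absent from labels: %s",
          paste(miss, collapse = ", "))
  labv <- lab$label[match(rownames(m), as.character(lab$patient_id))]
  CohortExperiment(m, labv, provenance = sprintf("readCohortMatrix(%s)", path))
}

#' @rdname cohort-io
#' @export
writeCohortMatrix <- function(cohort, path, labelsPath = NULL,
                              hashComment = NULL) {
  m <- cohortMatrix(cohort)
  con <- file(path, "w")
  if (!is.null(hashComment)) writeLines(paste0("# ", hashComment), con)
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(labelsPath)) {
    con <- file(labelsPath, "w")
    if (!is.null(hashComment)) writeLines(paste0("# ", hashComment), con)
    utils::write.table(
      data.frame(patient_id = rownames(m), label = cohortLabels(cohort)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname cohort-io
#' @export
readProblemLists <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' @rdname cohort-io
#' @export
readConsolidationMap <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}
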