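# End-to-end experiment driver: simulate (or ingest) -> demographics table
# -> CSA sweep -> optimal-set selection -> held-out explanation, with every
# artifact stamped by a common configuration hash.

pipelineDefaults <- function() list(
  mode = "simulate",
  # simulate
  n_cases = 23L, n_controls = 25L, n_features = 319L,
  n_informative = 0L, informative_prev_cases = 0.65,
  informative_prev_controls = 0.10,
  # ingest
  matrix_path = NA_character_, labels_path = NA_character_,
  records_path = NA_character_, consolidation_path = NA_character_,
  # model / loop
  svm.C = 1, svm.gamma = "scale", svm.class_weight = "none",
  cv.k = 4L, cv.repeats = 5L,
  shap.n_coalitions = "auto", shap.background_size = 16L,
  bootstrap.rounds = 200L, csa.min_features = 1L,
  table1.continuous = character(),
  seed = 1L)

#' Read a flat key-value experiment configuration
#'
#' YAML file of scalar keys (see \code{\link{runExperiment}} for the list).
#' Unknown keys are hard errors; omitted keys take the documented defaults.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file.
#' @return named list of class \code{runConfig}.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineDefaults()
  supplied <- if (is.null(path)) list() else yaml::read_yaml(path)
  supplied[names(overrides)] <- overrides
  unknown <- setdiff(names(supplied), names(cfg))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(supplied)) cfg[[nm]] <- supplied[[nm]]
  if (!cfg$mode %in% c("simulate", "ingest"))
    stopf("mode must be 'simulate' or 'ingest'")
  hasIngest <- !is.na(cfg$matrix_path) || !is.na(cfg$records_path)
  if (cfg$mode == "simulate" && hasIngest)
    stopf("simulate mode must not set ingest paths")
  if (cfg$mode == "ingest" && !hasIngest)
    stopf("ingest mode needs matrix_path or records_path")
  structure(cfg, class = "runConfig")
}

buildCohort <- function(cfg) {
  if (cfg$mode == "simulate") {
    inf <- NULL
    if (cfg$n_informative > 0)
      inf <- data.frame(
        name = sprintf("planted_%02d", seq_len(cfg$n_informative)),
        prevCases = cfg$informative_prev_cases,
        prevControls = cfg$informative_prev_controls)
    simulateCohort(cohortConfig(
      nCases = cfg$n_cases, nControls = cfg$n_controls,
      nFeatures = cfg$n_features, informative = inf,
      seed = deriveSeed(cfg$seed, "cohort")))
  } else if (!is.na(cfg$matrix_path)) {
    readCohortMatrix(cfg$matrix_path, cfg$labels_path)
  } else {
    recs <- readProblemLists(cfg$records_path)
    labs <- utils::read.delim(cfg$labels_path, comment.char = "#",
                              stringsAsFactors = FALSE)
    cmap <- if (is.na(cfg$consolidation_path)) NULL
            else readConsolidationMap(cfg$consolidation_path)
    binarizeProblemLists(recs, labs, cmap)
  }
}

writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full experiment
#'
#' Builds (or ingests) the cohort, writes the demographics table, runs the
#' backward-elimination sweep, selects the optimal feature set and
#' recomputes its held-out explanation. Writes, under \code{outDir}:
#' \code{cohort_matrix.tsv} + \code{cohort_labels.tsv}, \code{table1.tsv},
#' \code{trace.tsv}, \code{selected.json}, \code{beeswarm.tsv},
#' \code{importances.tsv} and \code{provenance.json}. Every file carries the
#' configuration hash, so artifacts of one run can be matched; rerunning
#' with an identical config reproduces the outputs byte for byte.
#'
#' @param config a \code{runConfig} from \code{\link{readRunConfig}}.
#' @param outDir output directory (created if needed).
#' @param verbose progress logging.
#' @return (invisibly) list with the cohort, trace, selection and
#'   explanation objects.
#' @export
runExperiment <- function(config = readRunConfig(), outDir, verbose = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";"))

  cohort <- buildCohort(config)
  writeCohortMatrix(cohort, file.path(outDir, "cohort_matrix.tsv"),
                    file.path(outDir, "cohort_labels.tsv"),
                    hashComment = paste0("config_hash=", hash))
  cont <- config$table1.continuous
  if (length(cont) == 1 && (is.na(cont) || !nzchar(cont))) cont <- character()
  writeStamped(table1Report(cohort, continuousVars = cont),
               file.path(outDir, "table1.tsv"), hash)

  cc <- csaConfig(
    hyper = svmHyperparams(config$svm.C, config$svm.gamma, config$svm.class_weight),
    k = config$cv.k, repeats = config$cv.repeats,
    nCoalitions = config$shap.n_coalitions,
    backgroundSize = config$shap.background_size,
    bootstrapRounds = config$bootstrap.rounds,
    minFeatures = config$csa.min_features,
    seed = deriveSeed(config$seed, "csa"))
  trace <- runCSA(cohort, cc, traceFile = file.path(outDir, "trace.tsv"),
                  verbose = verbose)
  writeStamped(traceTable(trace), file.path(outDir, "trace.tsv"), hash)

  sel <- selectOptimal(trace)
  jsonlite::write_json(
    list(config_hash = hash,
         feature_set = sel$feature_set,
         n_features = sel$record$n_features,
         winning_metrics = sel$wins,
         metrics = lapply(sel$record$metrics, function(ci)
           list(point = ci$point, lower = ci$lower, upper = ci$upper)),
         provenance = trace@provenance),
    file.path(outDir, "selected.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)

  expl <- explainFinal(cohort, sel$feature_set, cc)
  writeStamped(expl$beeswarm, file.path(outDir, "beeswarm.tsv"), hash)
  writeStamped(expl$importances, file.path(outDir, "importances.tsv"), hash)

  jsonlite::write_json(
    list(config_hash = hash, config = unclass(config),
         package_version = as.character(utils::packageVersion("shapCSA")),
         cohort_provenance = provenance(cohort),
         n_patients = ncol(cohort), n_features = nrow(cohort)),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)

  invisible(list(cohort = cohort, trace = trace, selection = sel,
                 explanation = expl, config_hash = hash))
}
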