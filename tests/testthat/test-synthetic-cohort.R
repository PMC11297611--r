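test_that("default generator reproduces the target cohort shape", {
  ce <- simulateCohort(cohortConfig(seed = 5))
  m <- cohortMatrix(ce)
  expect_identical(dim(m), c(48L, 319L))
  expect_true(all(m %in% 0:1))
  expect_identical(sum(cohortLabels(ce)), 23L)
  expect_identical(sum(cohortLabels(ce) == 0), 25L)
})

test_that("generation is bit-reproducible from config + seed", {
  inf <- data.frame(name = "gerd", prevCases = 0.6, prevControls = 0.2)
  a <- simulateCohort(cohortConfig(nFeatures = 40, informative = inf, seed = 7))
  b <- simulateCohort(cohortConfig(nFeatures = 40, informative = inf, seed = 7))
  expect_identical(cohortMatrix(a), cohortMatrix(b))
  c <- simulateCohort(cohortConfig(nFeatures = 40, informative = inf, seed = 8))
  expect_false(identical(cohortMatrix(a), cohortMatrix(c)))
})

test_that("a fully penetrant planted feature equals the label vector", {
  ce <- simulateCohort(cohortConfig(
    nCases = 10, nControls = 10, nFeatures = 5,
    informative = data.frame(name = "hallmark", prevCases = 1, prevControls = 0),
    seed = 2))
  expect_identical(as.integer(cohortMatrix(ce)[, "hallmark"]),
                   as.integer(cohortLabels(ce)))
})

test_that("noise columns carry no class signal at large n", {
  ce <- simulateCohort(cohortConfig(nCases = 1000, nControls = 1000,
                                    nFeatures = 50, seed = 13))
  m <- cohortMatrix(ce); lab <- cohortLabels(ce)
  gap <- abs(colMeans(m[lab == 1, ]) - colMeans(m[lab == 0, ]))
  expect_lt(max(gap), 0.06)
})

test_that("empirical prevalence recovers the configured prevalence", {
  inf <- data.frame(name = paste0("p", 1:3),
                    prevCases = c(0.65, 0.3, 0.9),
                    prevControls = c(0.10, 0.3, 0.5))
  ce <- simulateCohort(cohortConfig(nCases = 1500, nControls = 1500,
                                    nFeatures = 40, informative = inf,
                                    seed = 21))
  m <- cohortMatrix(ce); lab <- cohortLabels(ce)
  for (j in 1:3) {
    for (cls in 0:1) {
      p <- if (cls == 1) inf$prevCases[j] else inf$prevControls[j]
      phat <- mean(m[lab == cls, inf$name[j]])
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1500) + 1e-9)
    }
  }
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohortConfig(nCases = 0), "nCases")
  expect_error(cohortConfig(nFeatures = 2,
    informative = data.frame(name = c("a", "b", "c"), prevCases = 0.5,
                             prevControls = 0.5)), "informative")
  expect_error(cohortConfig(informative = data.frame(
    name = "a", prevCases = 1.2, prevControls = 0.5)), "\\[0,1\\]")
})

test_that("consolidation merges synonyms into one OR-combined column", {
  recs <- data.frame(patient_id = c("A", "B"),
                     item = c("depressive symptoms", "Major Depressive Disorder"))
  map <- c("depressive symptoms" = "depression",
           "major depressive disorder" = "depression")
  ce <- binarizeProblemLists(recs, c(A = 1, B = 0, C = 0), map)
  expect_identical(rownames(ce), "depression")
  expect_identical(as.integer(cohortMatrix(ce)[, "depression"]),
                   c(1L, 1L, 0L))
})

test_that("binarization matches a hand-built incidence matrix, lexicographic columns", {
  recs <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p3"),
    item = c("gerd", "asthma", "joint pain", "asthma", "gerd", "hypothyroidism"))
  ce <- binarizeProblemLists(recs, c(p1 = 1, p2 = 0, p3 = 1))
  expect_identical(rownames(ce),
                   c("asthma", "gerd", "hypothyroidism", "joint pain"))
  expected <- matrix(c(1, 1, 0, 0,
                       0, 0, 0, 1,
                       1, 1, 1, 0), nrow = 3, byrow = TRUE,
                     dimnames = list(c("p1", "p2", "p3"),
                                     c("asthma", "gerd", "hypothyroidism", "joint pain")))
  expect_identical(cohortMatrix(ce), matrix(as.integer(expected), 3, 4,
                                            dimnames = dimnames(expected)))
})

test_that("labeled patients without records become all-zero rows; empty input warns", {
  recs <- data.frame(patient_id = "A", item = "gerd")
  ce <- binarizeProblemLists(recs, c(A = 1, B = 0))
  expect_identical(as.integer(cohortMatrix(ce)["B", ]), 0L)
  expect_warning(
    ce0 <- binarizeProblemLists(data.frame(patient_id = character(),
                                           item = character()),
                                c(A = 1, B = 0)),
    "zero feature")
  expect_identical(dim(cohortMatrix(ce0)), c(2L, 0L))
})

test_that("records for unlabeled patients are an ingest error listing the ids", {
  recs <- data.frame(patient_id = c("A", "ghost"), item = c("gerd", "gerd"))
  expect_error(binarizeProblemLists(recs, c(A = 1, B = 0)), "ghost")
})

test_that("export to long format and re-ingest round-trips the matrix", {
  ce <- simulateCohort(cohortConfig(nCases = 6, nControls = 6, nFeatures = 12,
                                    seed = 31))
  recs <- cohortToProblemLists(ce)
  back <- binarizeProblemLists(recs, cohortLabels(ce))
  common <- rownames(back)  # all-zero columns cannot survive the round trip
  expect_identical(cohortMatrix(back),
                   cohortMatrix(ce)[, common, drop = FALSE])
})

test_that("matrix TSV write/read round-trips through files", {
  dir <- withr::local_tempdir()
  ce <- simulateCohort(cohortConfig(nCases = 5, nControls = 5, nFeatures = 7,
                                    seed = 4))
  writeCohortMatrix(ce, file.path(dir, "m.tsv"), file.path(dir, "l.tsv"),
                    hashComment = "config_hash=test")
  back <- readCohortMatrix(file.path(dir, "m.tsv"), file.path(dir, "l.tsv"))
  expect_identical(cohortMatrix(back), cohortMatrix(ce))
  expect_identical(cohortLabels(back), cohortLabels(ce))
})

test_that("cohort validity rejects non-binary entries and single-class labels", {
  m <- matrix(c(0, 2, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("f", "g")))
  expect_error(CohortExperiment(m, c(1, 0)), "0/1")
  m2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("f", "g")))
  expect_error(CohortExperiment(m2, c(1, 1)), "control")
})
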