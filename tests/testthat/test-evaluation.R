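makeOOF <- function(pred, label, score = NULL, patient = NULL) {
  data.frame(patient = patient %||% paste0("P", seq_along(pred)),
             repetition = 1L, fold = 1L,
             score = score %||% ifelse(pred == 1, 1, -1),
             pred = pred, label = label, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stratified folds respect class balance at the target cohort shape", {
  lab <- c(rep(1, 23), rep(0, 25))
  folds <- stratifiedKFold(lab, k = 4, repeats = 3, seed = 10)
  for (r in 1:3) {
    for (f in 1:4) {
      cases <- sum(lab == 1 & folds[, r] == f)
      ctrls <- sum(lab == 0 & folds[, r] == f)
      expect_true(cases %in% 5:6)
      expect_true(ctrls %in% 6:7)
    }
  }
})

test_that("folds are forced and deterministic in the exact-division case", {
  lab <- rep(c(1, 0), each = 4)
  folds <- stratifiedKFold(lab, k = 4, repeats = 1, seed = 3)
  for (f in 1:4) {
    expect_identical(sum(lab == 1 & folds[, 1] == f), 1L)
    expect_identical(sum(lab == 0 & folds[, 1] == f), 1L)
  }
  expect_identical(folds, stratifiedKFold(lab, k = 4, repeats = 1, seed = 3))
  expect_error(stratifiedKFold(c(1, 1, 1, 0, 0, 0, 0), k = 4), "fewer members")
})

test_that("stratification tolerance holds across k on random labels", {
  set.seed(6)
  for (k in 2:5) {
    lab <- rbinom(40, 1, 0.4)
    lab[1:k] <- 1; lab[(k + 1):(2 * k)] <- 0
    folds <- stratifiedKFold(lab, k = k, repeats = 2, seed = k)
    for (r in 1:2) for (cls in 0:1) {
      counts <- tabulate(folds[lab == cls, r], k)
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("pooled metrics match hand arithmetic on an explicit confusion matrix", {
  # TP=3, FP=1, FN=2, TN=4
  oof <- makeOOF(pred = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                 label = c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0))
  m <- computeMetrics(oof)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 / 3)
})

test_that("perfect separated predictions score 1 on every metric; ties give AUC 0.5", {
  oof <- makeOOF(pred = c(1, 1, 0, 0), label = c(1, 1, 0, 0),
                 score = c(2, 1, -1, -2))
  m <- computeMetrics(oof)
  expect_equal(unlist(m), c(precision = 1, sensitivity = 1, f1 = 1,
                            accuracy = 1, auc = 1))
  flat <- makeOOF(pred = c(0, 0, 0, 0), label = c(1, 1, 0, 0),
                  score = rep(0.5, 4))
  expect_equal(suppressWarnings(computeMetrics(flat))$auc, 0.5)
  expect_warning(computeMetrics(flat), "no predicted positives")
})

test_that("AUC uses midranks and matches exhaustive pair counting", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    label <- c(1, 0, rbinom(n - 2, 1, 0.5))
    score <- sample(round(rnorm(n), 1))  # coarse scores force ties
    oof <- makeOOF(pred = as.integer(score > 0), label = label, score = score)
    expect_equal(computeMetrics(oof)$auc, bruteAUC(score, label),
                 tolerance = 1e-12)
    # invariance under a strictly monotone transform
    oof2 <- oof; oof2$score <- exp(oof$score)
    expect_equal(computeMetrics(oof2)$auc, computeMetrics(oof)$auc,
                 tolerance = 1e-12)
  }
})

test_that("a perfectly informative feature yields all-correct held-out predictions", {
  ce <- toyCohort()
  folds <- stratifiedKFold(cohortLabels(ce), k = 2, repeats = 2, seed = 1)
  cv <- repeatedCVPredict(ce, "sig", hyper = svmHyperparams(C = 10),
                          folds = folds, shapConfig = NULL)
  expect_identical(cv$oof$pred, cv$oof$label)
  expect_identical(nrow(cv$oof), 8L * 2L)  # n_patients x repeats
})

test_that("held-out SHAP rows align with the out-of-fold table", {
  ce <- toyCohort()
  folds <- stratifiedKFold(cohortLabels(ce), k = 2, repeats = 1, seed = 2)
  cv <- repeatedCVPredict(ce, c("sig", "n1"), folds = folds,
                          shapConfig = kernelShapConfig("all", seed = 2))
  expect_identical(dim(cv$phi), c(8L, 2L))
  expect_identical(length(cv$baseValues), 8L)
  # local accuracy against the held-out decision scores
  expect_equal(unname(rowSums(cv$phi) + cv$baseValues), cv$oof$score,
               tolerance = 1e-6)
})

test_that("pure-noise features give chance-level pooled AUC on a large cohort", {
  aucs <- vapply(1:5, function(s) {
    ce <- simulateCohort(cohortConfig(nCases = 100, nControls = 100,
                                      nFeatures = 15, seed = 100 + s))
    folds <- stratifiedKFold(cohortLabels(ce), k = 4, repeats = 1, seed = s)
    cv <- repeatedCVPredict(ce, rownames(ce), folds = folds, shapConfig = NULL)
    computeMetrics(cv$oof)$auc
  }, numeric(1))
  expect_true(all(aucs > 0.35 & aucs < 0.65))
})

test_that("bootstrap CIs are seed-deterministic and degenerate on perfect input", {
  oof <- makeOOF(pred = rep(c(1, 0), 10), label = rep(c(1, 0), 10))
  ci <- bootstrapCI(oof, "accuracy", rounds = 50, seed = 4)
  expect_identical(c(ci$lower, ci$point, ci$upper), c(1, 1, 1))
  set.seed(30)
  oof2 <- makeOOF(pred = rbinom(40, 1, 0.5), label = rep(c(1, 0), 20),
                  score = rnorm(40))
  a <- bootstrapCI(oof2, "auc", rounds = 100, seed = 9)
  b <- bootstrapCI(oof2, "auc", rounds = 100, seed = 9)
  expect_identical(a, b)
  expect_lte(a$lower, a$upper)
})

test_that("bootstrap interval width shrinks with cohort size", {
  inf <- data.frame(name = c("s1", "s2"), prevCases = 0.7, prevControls = 0.2)
  widthAt <- function(n, seed) {
    ce <- simulateCohort(cohortConfig(nCases = n / 2, nControls = n / 2,
                                      nFeatures = 10, informative = inf,
                                      seed = seed))
    folds <- stratifiedKFold(cohortLabels(ce), k = 4, repeats = 1, seed = seed)
    cv <- repeatedCVPredict(ce, rownames(ce), folds = folds, shapConfig = NULL)
    ci <- bootstrapCI(cv$oof, "accuracy", rounds = 200, seed = seed)
    ci$upper - ci$lower
  }
  wins <- sum(vapply(1:6, function(s) widthAt(400, s) < widthAt(48, s),
                     logical(1)))
  expect_gte(wins, 5)
})
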