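# Shared fixtures and independent brute-force oracles. Everything is built
# in code; no stored data.

# tiny deterministic cohort: 8 patients, 3 features, one perfectly
# informative column
toyCohort <- function() {
  m <- cbind(sig = c(1, 1, 1, 1, 0, 0, 0, 0),
             n1  = c(0, 1, 0, 1, 0, 1, 0, 1),
             n2  = c(1, 0, 0, 1, 1, 0, 0, 1))
  rownames(m) <- paste0("P", 1:8)
  CohortExperiment(m, labels = c(1, 1, 1, 1, 0, 0, 0, 0))
}

plantedCohort <- function(seed, nFeatures = 60, nPlanted = 4,
                          prevCases = 0.65, prevControls = 0.10,
                          nCases = 23, nControls = 25) {
  inf <- data.frame(name = sprintf("planted_%d", seq_len(nPlanted)),
                    prevCases = prevCases, prevControls = prevControls)
  simulateCohort(cohortConfig(nCases = nCases, nControls = nControls,
                              nFeatures = nFeatures, informative = inf,
                              seed = seed))
}

# hypergeometric two-sided p by direct factorial tabulation over every
# table with the observed margins (independent of stats::dhyper)
bruteFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  as_ <- max(0, c1 - r2):min(r1, c1)
  pt <- function(x) exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  probs <- vapply(as_, pt, numeric(1))
  sum(probs[probs <= pt(a) * (1 + 1e-7)])
}

# AUC by exhaustive case-control pair counting
bruteAUC <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  g <- 0
  for (s in cs) g <- g + sum(s > ct) + 0.5 * sum(s == ct)
  g / (length(cs) * length(ct))
}

# random small coalition game over binary features: linear + pairwise
# interaction score, random binary background
randomGame <- function(M, seed, nBackground = 3) {
  set.seed(seed)
  w <- rnorm(M)
  W2 <- matrix(rnorm(M * M, sd = 0.5), M, M); W2[lower.tri(W2, diag = TRUE)] <- 0
  score <- function(Z) as.numeric(Z %*% w + rowSums((Z %*% W2) * Z))
  fn <- paste0("f", seq_len(M))
  bg <- matrix(rbinom(nBackground * M, 1, 0.5), nBackground, M,
               dimnames = list(NULL, fn))
  x <- stats::setNames(rbinom(M, 1, 0.5), fn)
  valueFunction(score, x, bg)
}

efficiencyGap <- function(sv, vf) {
  vF <- vf$score(matrix(vf$x, 1, dimnames = list(NULL, vf$featureNames)))
  abs(baseValue(sv) + sum(shapValues(sv)) - as.numeric(vF))
}
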