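# Model-agnostic Shapley attribution: an exact enumeration oracle for small
# feature counts and a Kernel SHAP weighted-least-squares estimator for the
# general case. Absent features are marginalised interventionally over a
# background sample, so a coalition's value is the mean model score over
# hybrid rows (coalition features from the explained instance, the rest from
# each background row). Attributions are computed on the signed decision
# margin (identity link).

#' Interventional value function for Shapley attribution
#'
#' Bundles the model score, one explained instance and the background
#' reference rows into the coalition game \eqn{v(S)}: the average model
#' score over synthetic rows in which features in \eqn{S} take the explained
#' instance's values and the remaining features take each background row's
#' values. By construction \eqn{v(\emptyset)} is the mean background score
#' and \eqn{v(F)} the score of the instance itself.
#'
#' @param score function mapping a feature matrix to a numeric score vector,
#'   or a \code{trainedSVM} (scored via \code{\link{decisionScores}}).
#' @param x named numeric vector: the explained instance.
#' @param background matrix of reference rows (same feature columns as
#'   \code{x}); must be non-empty.
#' @return list of class \code{valueFunction}.
#' @export
valueFunction <- function(score, x, background) {
  if (inherits(score, "trainedSVM")) {
    model <- score
    score <- function(X) decisionScores(model, X)
  }
  stopifnot(is.function(score))
  if (!is.matrix(background)) background <- as.matrix(background)
  if (nrow(background) == 0) stopf("background set must be non-empty")
  if (is.null(names(x))) names(x) <- colnames(background)
  stopifnot(identical(names(x), colnames(background)))
  structure(list(score = score, x = x, background = background,
                 featureNames = names(x)),
            class = "valueFunction")
}

# Hybrid rows for a stack of coalition masks (nC x M) against the full
# background: returns (nC*B) x M, background-fastest within each coalition.
hybridRows <- function(x, background, Z) {
  B <- nrow(background); nC <- nrow(Z); M <- length(x)
  bgRep <- background[rep(seq_len(B), times = nC), , drop = FALSE]
  maskRep <- Z[rep(seq_len(nC), each = B), , drop = FALSE]
  xRep <- matrix(x, nrow = nC * B, ncol = M, byrow = TRUE)
  out <- bgRep * (1 - maskRep) + xRep * maskRep
  colnames(out) <- names(x)
  out
}

#' Value of one feature coalition
#'
#' @param vf a \code{\link{valueFunction}}.
#' @param S coalition: character vector of feature names or integer indices
#'   (possibly empty) of features taking the explained instance's values.
#' @return numeric scalar \eqn{v(S)}.
#' @export
coalitionValue <- function(vf, S) {
  stopifnot(inherits(vf, "valueFunction"))
  M <- length(vf$x)
  idx <- if (is.character(S)) match(S, vf$featureNames) else as.integer(S)
  if (anyNA(idx) || any(idx < 1) || any(idx > M))
    stopf("coalition contains unknown features")
  z <- matrix(0, 1, M); z[1, idx] <- 1
  mean(vf$score(hybridRows(vf$x, vf$background, z)))
}

shapleyWeightBySize <- function(M) {
  # w(s) = s! (M-1-s)! / M!  for |S| = s, s = 0..M-1 (marginal-contribution
  # weight in the Shapley sum), computed in log space for stability
  s <- 0:(M - 1)
  exp(lfactorial(s) + lfactorial(M - 1 - s) - lfactorial(M))
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all \eqn{2^M} coalitions and applies the Shapley formula
#' \eqn{\phi_i = \sum_{S \subseteq F \setminus \{i\}}
#' \frac{|S|!\,(M-|S|-1)!}{M!}\,[v(S \cup \{i\}) - v(S)]}. Serves as the
#' oracle against which the Kernel SHAP estimator is validated. Refuses
#' \eqn{M > 15}; use \code{\link{kernelShap}} beyond that.
#'
#' @param vf a \code{\link{valueFunction}}.
#' @return a \linkS4class{ShapVector}; efficiency holds to 1e-9.
#' @export
exactShapley <- function(vf) {
  stopifnot(inherits(vf, "valueFunction"))
  M <- length(vf$x)
  if (M > 15)
    stopf("exact enumeration limited to 15 features (2^M coalitions); use kernelShap()")
  nC <- 2L^M
  bits <- t(vapply(0:(nC - 1), function(k) as.integer(intToBits(k)[1:M]),
                   integer(M)))
  v <- rowMeans(matrix(vf$score(hybridRows(vf$x, vf$background, bits)),
                       nrow = nC, byrow = TRUE))
  sizes <- rowSums(bits)
  w <- shapleyWeightBySize(M)
  phi <- vapply(seq_len(M), function(i) {
    without <- which(bits[, i] == 0L)
    sum(w[sizes[without] + 1L] * (v[without + 2L^(i - 1L)] - v[without]))
  }, numeric(1))
  names(phi) <- vf$featureNames
  ShapVector(phi, baseValue = v[1])
}

#' Kernel SHAP sampling configuration
#'
#' @param nCoalitions \code{"auto"} (budget \eqn{2M + 512}, capped at the
#'   \eqn{2^M - 2} proper non-empty coalitions), \code{"all"} (full
#'   enumeration), or an explicit count. Coalitions are drawn stratified by
#'   size with the Shapley kernel mass
#'   \eqn{\pi(s) = (M-1)/(\binom{M}{s} s (M-s))}; sizes whose stratum fits
#'   the remaining budget are enumerated exhaustively.
#' @param backgroundSize number of background rows to retain (deterministic
#'   subsample by seed) when a larger reference set is supplied.
#' @param seed integer seed making the coalition sample reproducible.
#' @return list of class \code{kernelShapConfig}.
#' @export
kernelShapConfig <- function(nCoalitions = "auto", backgroundSize = 16L,
                             seed = 1L) {
  if (!(identical(nCoalitions, "auto") || identical(nCoalitions, "all") ||
        (is.numeric(nCoalitions) && nCoalitions >= 2)))
    stopf("nCoalitions must be \"auto\", \"all\" or a count >= 2")
  if (backgroundSize < 1) stopf("backgroundSize must be >= 1")
  structure(list(nCoalitions = nCoalitions,
                 backgroundSize = as.integer(backgroundSize),
                 seed = as.integer(seed)),
            class = "kernelShapConfig")
}

# Build the coalition design shared by all instances explained against the
# same model/background: masks Z (nC x M) and regression weights w.
sampleCoalitions <- function(M, nCoalitions, seed) {
  full <- 2^M - 2
  budget <- if (identical(nCoalitions, "all")) full
            else if (identical(nCoalitions, "auto")) min(2 * M + 512, full)
            else min(as.numeric(nCoalitions), full)
  sizes <- seq_len(M - 1)
  massBySize <- (M - 1) / (sizes * (M - sizes))     # total pi mass per size
  enumMask <- rep(FALSE, M - 1)
  if (budget >= full) {
    enumMask[] <- TRUE
  } else {
    # pair size s with its complement, most informative (smallest/largest
    # coalitions, highest kernel mass) first; enumerate whole strata while
    # they fit the budget
    left <- budget
    for (s0 in sort(unique(pmin(sizes, M - sizes)))) {
      grp <- unique(c(s0, M - s0))
      need <- sum(choose(M, grp))
      if (need > left) break
      enumMask[grp] <- TRUE
      left <- left - need
    }
  }
  Zs <- list(); ws <- list()
  for (s in sizes[enumMask]) {
    combs <- utils::combn(M, s)
    z <- matrix(0, ncol(combs), M)
    z[cbind(rep(seq_len(ncol(combs)), each = s), as.vector(combs))] <- 1
    Zs[[length(Zs) + 1L]] <- z
    ws[[length(ws) + 1L]] <- rep(massBySize[s] / choose(M, s), nrow(z))
  }
  remSizes <- sizes[!enumMask]
  if (length(remSizes)) {
    nLeft <- max(0, round(budget - sum(vapply(Zs, nrow, numeric(1)))))
    if (nLeft >= 1) {
      withSeed(seed, {
        pick <- sample(remSizes, nLeft, replace = TRUE,
                       prob = massBySize[remSizes])
        z <- matrix(0, nLeft, M)
        for (r in seq_len(nLeft))
          z[r, sample.int(M, pick[r])] <- 1
      })
      # collapse duplicate masks, weighting by multiplicity; the sampled
      # stratum shares the remaining kernel mass uniformly
      key <- apply(z, 1, paste, collapse = "")
      tab <- table(key)
      z <- z[!duplicated(key), , drop = FALSE]
      Zs[[length(Zs) + 1L]] <- z
      ws[[length(ws) + 1L]] <- sum(massBySize[remSizes]) *
        as.numeric(tab[apply(z, 1, paste, collapse = "")]) / nLeft
    }
  }
  Z <- do.call(rbind, Zs)
  list(Z = Z, w = do.call(c, ws))
}

# Solve the Shapley-kernel weighted least squares with the efficiency
# constraint eliminated into the design; minimum-norm solution (SVD
# pseudoinverse) when the sampled system is underdetermined. V is nC x R
# (coalition values for R explained instances).
solveKernelShap <- function(Z, w, V, v0, vF, featureNames) {
  M <- ncol(Z); R <- ncol(V)
  if (M == 1) {
    phi <- matrix(vF - v0, ncol = 1)
    colnames(phi) <- featureNames
    return(phi)
  }
  A <- Z[, -M, drop = FALSE] - Z[, M]
  sw <- sqrt(w)
  Aw <- A * sw
  Y <- (V - v0 - outer(Z[, M], vF - v0)) * sw
  sv <- svd(Aw)
  tol <- max(dim(Aw)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  phi <- rbind(beta, (vF - v0) - colSums(beta))
  rownames(phi) <- featureNames
  t(phi)
}

#' Kernel SHAP: Shapley values by weighted least squares
#'
#' Estimates Shapley values by regressing coalition values on coalition
#' membership under the Shapley kernel weights, with the efficiency
#' constraint \eqn{\sum_i \phi_i = v(F) - v(\emptyset)} enforced exactly by
#' eliminating one coefficient. Under full coalition enumeration the
#' solution equals the exact Shapley values; with a sampled design it is the
#' minimum-norm weighted-least-squares estimate, which remains defined (and
#' deterministic given the seed) even when fewer coalitions than features
#' are sampled.
#'
#' @param vf a \code{\link{valueFunction}}.
#' @param config a \code{\link{kernelShapConfig}}.
#' @return a \linkS4class{ShapVector}.
#' @export
kernelShap <- function(vf, config = kernelShapConfig()) {
  stopifnot(inherits(vf, "valueFunction"))
  res <- shapMatrix(vf$score, matrix(vf$x, 1, dimnames = list(NULL, vf$featureNames)),
                    vf$background, config)
  ShapVector(res$phi[1, ], res$baseValue)
}

#' Per-instance Shapley values for a matrix of explained rows
#'
#' Applies the Kernel SHAP estimator row-wise, sharing one coalition sample
#' and one background across all rows (the coalition design depends only on
#' the feature count and seed), so the model is evaluated in a single batch.
#'
#' @param score scoring function or \code{trainedSVM}.
#' @param X matrix of instances to explain (rows align with the output).
#' @param background reference rows; subsampled to
#'   \code{config$backgroundSize} deterministically by seed when larger.
#' @param config a \code{\link{kernelShapConfig}}.
#' @return list with \code{phi} (matrix, rows = instances, columns =
#'   features), \code{baseValue} (mean background score) and
#'   \code{featureNames}.
#' @export
shapMatrix <- function(score, X, background, config = kernelShapConfig()) {
  if (inherits(score, "trainedSVM")) {
    model <- score
    score <- function(Xs) decisionScores(model, Xs)
  }
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0) stopf("no instances to explain")
  if (!is.matrix(background)) background <- as.matrix(background)
  if (nrow(background) == 0) stopf("background set must be non-empty")
  M <- ncol(X)
  if (M < 1) stopf("need at least one feature")
  if (nrow(background) > config$backgroundSize) {
    keep <- withSeed(deriveSeed(config$seed, "background"),
                     sample.int(nrow(background), config$backgroundSize))
    background <- background[keep, , drop = FALSE]
  }
  v0 <- mean(score(background))
  vF <- as.numeric(score(X))
  if (M == 1) {
    phi <- matrix(vF - v0, ncol = 1, dimnames = list(NULL, colnames(X)))
    return(list(phi = phi, baseValue = v0, featureNames = colnames(X)))
  }
  des <- sampleCoalitions(M, config$nCoalitions, deriveSeed(config$seed, "coalitions"))
  nC <- nrow(des$Z); B <- nrow(background); R <- nrow(X)
  V <- matrix(NA_real_, nC, R)
  # batch the hybrid-row scoring; chunk explained rows to bound memory
  chunk <- max(1L, floor(2e6 / (nC * B)))
  for (start in seq(1L, R, by = chunk)) {
    rows <- start:min(start + chunk - 1L, R)
    synth <- do.call(rbind, lapply(rows, function(r)
      hybridRows(X[r, ], background, des$Z)))
    sc <- score(synth)
    for (k in seq_along(rows)) {
      block <- sc[((k - 1) * nC * B + 1):(k * nC * B)]
      V[, rows[k]] <- rowMeans(matrix(block, nrow = nC, byrow = TRUE))
    }
  }
  phi <- solveKernelShap(des$Z, des$w, V, v0, vF, colnames(X))
  list(phi = phi, baseValue = v0, featureNames = colnames(X))
}

#' Mean absolute Shapley importance per feature
#'
#' The ranking statistic of the backward-elimination loop and of the
#' importance bar chart: \eqn{\mathrm{imp}_i = \mathrm{mean}_r |\phi_{ri}|}
#' over explained instances, direction ignored. Exact ties are preserved
#' (elimination tie-breaking is the caller's concern).
#'
#' @param phi matrix of per-instance Shapley values (rows = instances), or
#'   the list returned by \code{\link{shapMatrix}}.
#' @return named numeric vector of importances.
#' @export
aggregateImportance <- function(phi) {
  if (is.list(phi) && !is.data.frame(phi)) phi <- phi$phi
  if (!is.matrix(phi)) phi <- as.matrix(phi)
  if (nrow(phi) == 0) stopf("no instances: cannot aggregate importances")
  colMeans(abs(phi))
}
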