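# Gaussian-kernel soft-margin SVM behind a minimal fit/score contract.
# The quadratic program is solved by libsvm via e1071; this file owns the
# hyperparameter resolution, the feature-name contract and the score sign
# convention (positive margin = case).

#' SVM hyperparameters
#'
#' @param C soft-margin penalty, positive.
#' @param gamma RBF width in \eqn{K(x,x') = \exp(-\gamma \|x-x'\|^2)}:
#'   a positive number, or \code{"scale"} to resolve
#'   \eqn{1 / (p \cdot \mathrm{Var}(X))} from the training matrix (the
#'   common default for unscaled binary features).
#' @param classWeight \code{"none"} or \code{"balanced"} (weights inversely
#'   proportional to class frequency). The target cohort is nearly balanced
#'   (23/25), so \code{"none"} is the default.
#' @return list of class \code{svmHyperparams}.
#' @export
svmHyperparams <- function(C = 1, gamma = "scale", classWeight = c("none", "balanced")) {
  classWeight <- match.arg(classWeight)
  if (!is.numeric(C) || C <= 0) stopf("C must be a positive real")
  if (!(identical(gamma, "scale") || (is.numeric(gamma) && gamma > 0)))
    stopf("gamma must be positive or \"scale\"")
  structure(list(C = C, gamma = gamma, classWeight = classWeight),
            class = "svmHyperparams")
}

resolveGamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else gamma
}

#' Fit a Gaussian-kernel SVM classifier
#'
#' Deterministic given (X, y, hyperparameters). Feature names are recorded
#' and enforced at scoring time.
#'
#' @param X numeric matrix, patients in rows, named feature columns;
#'   at least one column.
#' @param y 0/1 labels (1 = case), both classes present.
#' @param hyper an \code{\link{svmHyperparams}}.
#' @return object of class \code{trainedSVM} with the fitted state, the
#'   training feature names and the resolved hyperparameters.
#' @export
fitSVM <- function(X, y, hyper = svmHyperparams()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) == 0) stopf("cannot fit on zero features")
  if (is.null(colnames(X))) stopf("X must have feature (column) names")
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stopf("training labels contain a single class")
  gam <- resolveGamma(hyper$gamma, X)
  yf <- factor(ifelse(y == 1L, "case", "ctrl"), levels = c("case", "ctrl"))
  cw <- if (hyper$classWeight == "balanced") {
    tab <- table(yf); n <- length(yf)
    stats::setNames(n / (2 * as.numeric(tab)), names(tab))
  } else NULL
  fit <- e1071::svm(x = X, y = yf, kernel = "radial", cost = hyper$C,
                    gamma = gam, scale = FALSE, class.weights = cw,
                    probability = FALSE, fitted = FALSE)
  # libsvm's margin sign follows the order classes appear in the training
  # data; pin it so that positive always means "case"
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- !startsWith(colnames(dv)[1], "case")
  structure(list(fit = fit, featureNames = colnames(X), gamma = gam,
                 C = hyper$C, classWeight = hyper$classWeight, flip = flip),
            class = "trainedSVM")
}

#' Signed decision margins of a trained SVM
#'
#' Scores rows of \code{X}; the predicted label is 1 (case) iff the score is
#' strictly positive. Columns must carry the training feature names; a
#' matrix with the same names in a different order is realigned, any other
#' mismatch is a contract error naming the differing columns.
#'
#' @param model a \code{trainedSVM} from \code{\link{fitSVM}}.
#' @param X matrix to score.
#' @return numeric vector of signed margins, one per row of \code{X}.
#' @export
decisionScores <- function(model, X) {
  stopifnot(inherits(model, "trainedSVM"))
  if (!is.matrix(X)) X <- as.matrix(X)
  tn <- model$featureNames
  if (!identical(colnames(X), tn)) {
    if (setequal(colnames(X), tn) && !anyDuplicated(colnames(X))) {
      X <- X[, tn, drop = FALSE]
    } else {
      stopf("feature-name contract violated; missing: [%s], unexpected: [%s]",
            paste(setdiff(tn, colnames(X)), collapse = ", "),
            paste(setdiff(colnames(X), tn), collapse = ", "))
    }
  }
  if (nrow(X) == 0) return(numeric(0))
  dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  if (model$flip) s <- -s
  s
}
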