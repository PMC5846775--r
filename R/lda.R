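# Two-class linear discriminant analysis with pooled, ridge-regularized
# within-class covariance. Small fitted objects are plain lists, in the
# style of lm-like fits; the data containers of the package are S4.

#' Fit a two-class linear discriminant model
#'
#' Class means and pooled within-class covariance, with a ridge
#' \code{lambda = ridge * trace(S)/p} always added for small-sample
#' stability. Classification assigns the class with the larger discriminant
#' score (negative half Mahalanobis distance to the class mean plus log
#' prior); exact ties go to the first class in label order.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Two-class factor (or coercible), one label per row.
#' @param ridge Relative ridge regularization (default 1e-6); set to 0 to
#'   disable, in which case a singular covariance is an error.
#' @param priors Class prior probabilities (default equal).
#' @return An object of class \code{"ldaModel"}.
#' @examples
#' x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
#' fit <- ldaFit(x, c("a", "a", "a", "b", "b", "b"))
#' ldaPredict(fit, matrix(1.5))  # "b": past the midpoint of the means
#' @export
ldaFit <- function(x, labels, ridge = 1e-6, priors = c(0.5, 0.5)) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required")
  if (length(labels) != nrow(x))
    stop("one label per sample row is required")
  if (any(table(labels) < 2))
    stop("each class needs at least 2 samples")
  if (length(priors) != 2L || any(priors <= 0))
    stop("'priors' must be two positive probabilities")
  priors <- priors / sum(priors)
  lev <- levels(labels)
  core <- .ldaCore(x[labels == lev[1], , drop = FALSE],
                   x[labels == lev[2], , drop = FALSE], ridge)
  structure(list(levels = lev,
                 means = core$means,
                 sigmaInv = core$sigmaInv,
                 logPrior = log(priors),
                 features = colnames(x), p = ncol(x)),
            class = "ldaModel")
}

# Pooled-covariance core shared by ldaFit and the repeated-split loop.
.ldaCore <- function(x1, x2, ridge) {
  p <- ncol(x1)
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  c1 <- x1 - rep(m1, each = nrow(x1))
  c2 <- x2 - rep(m2, each = nrow(x2))
  S <- (crossprod(c1) + crossprod(c2)) / (nrow(x1) + nrow(x2) - 2)
  if (ridge > 0)
    S <- S + diag(ridge * sum(diag(S)) / p, p)
  R <- tryCatch(chol(S), error = function(e)
    stop("singular pooled covariance; increase 'ridge' to regularize",
         call. = FALSE))
  list(means = rbind(m1, m2, deparse.level = 0), sigmaInv = chol2inv(R))
}

.ldaScores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$p)
    stop("feature mismatch: model was fitted on ", model$p, " features")
  if (!is.null(model$features) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$features))
    stop("feature mismatch: column names differ from the fitted features")
  sc <- matrix(NA_real_, nrow(x), 2)
  for (k in 1:2) {
    d <- sweep(x, 2, model$means[k, ])
    sc[, k] <- -0.5 * rowSums((d %*% model$sigmaInv) * d) + model$logPrior[k]
  }
  sc
}

#' Predict classes from a fitted LDA model
#'
#' @param model An \code{"ldaModel"} from \code{\link{ldaFit}}.
#' @param x Samples x features matrix on the same features.
#' @return Factor of predicted class labels.
#' @export
ldaPredict <- function(model, x) {
  sc <- .ldaScores(model, x)
  factor(model$levels[ifelse(sc[, 2] > sc[, 1], 2L, 1L)],
         levels = model$levels)
}

#' Continuous discriminant score of a panel
#'
#' Difference of the two class discriminant scores (second class minus
#' first), a linear function of the features; larger values favour the
#' second class. This is the score fed to \code{\link{rocAuc}} for a
#' combined multi-protein classifier, and any strictly increasing
#' transform of it yields the same ROC curve. For a single-protein panel
#' the score is a monotone (affine) function of that protein's abundance.
#'
#' @param model An \code{"ldaModel"}.
#' @param x Samples x features matrix on the fitted features.
#' @return Numeric score per sample.
#' @export
panelScore <- function(model, x) {
  sc <- .ldaScores(model, x)
  sc[, 2] - sc[, 1]
}
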