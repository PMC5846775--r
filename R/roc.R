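# ROC analysis. The curve is built by a threshold sweep over the unique
# scores; the trapezoid area is identical (to numerical precision) to the
# Mann-Whitney pair-counting statistic, which is exposed separately as an
# independent computation route.

.binLabels <- function(labels, positive = NULL) {
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) != 2L)
    stop("both classes must be present in 'labels'")
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev) stop("'positive' is not a label level")
  labels == positive
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps the classification threshold over the unique scores (predicting
#' positive when \code{score >= threshold}) and integrates the resulting
#' sensitivity / 1-specificity curve by the trapezoid rule. With tied
#' scores the curve steps diagonally, so the trapezoid area equals the
#' Mann-Whitney pair count with half-weighted ties
#' (\code{\link{pairCountAuc}}). An AUC of 0.5 is a random classifier,
#' 1.0 a perfect one.
#'
#' @param scores Numeric classifier scores, larger = more positive-like.
#' @param labels Two-class labels.
#' @param positive Label treated as positive (default: second factor level).
#' @param classifier Description stored with the result.
#' @return A \linkS4class{RocCurve}.
#' @examples
#' aucValue(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)))  # 1: perfect separation
#' @export
rocAuc <- function(scores, labels, positive = NULL, classifier = "score") {
  pos <- .binLabels(labels, positive)
  if (length(scores) != length(pos))
    stop("'scores' and 'labels' must have equal length")
  if (anyNA(scores)) stop("missing scores are not allowed")
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call <- scores >= thr[i]
    sens[i] <- sum(call & pos) / nPos
    spec[i] <- sum(!call & !pos) / nNeg
  }
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  new("RocCurve",
      curve = data.frame(threshold = thr, sensitivity = sens,
                         specificity = spec),
      auc = auc, classifier = classifier)
}

#' Mann-Whitney pair-counting AUC
#'
#' The probability that a random positive sample scores above a random
#' negative one, with ties counted one half:
#' \code{(#(pos > neg) + 0.5 #(pos = neg)) / (nPos * nNeg)}, computed via
#' midranks. Serves as the independent route to the trapezoid AUC of
#' \code{\link{rocAuc}}.
#'
#' @inheritParams rocAuc
#' @return AUC as a single number in [0, 1].
#' @export
pairCountAuc <- function(scores, labels, positive = NULL) {
  pos <- .binLabels(labels, positive)
  if (length(scores) != length(pos))
    stop("'scores' and 'labels' must have equal length")
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
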