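# Exhaustive biomarker-panel search: all 2-5 protein subsets of the
# candidate proteases, each scored by mean LDA accuracy over repeated
# stratified random train/test splits.

#' Enumerate candidate panels
#'
#' All subsets of the candidates of size \code{kMin} to \code{kMax}, in
#' deterministic order: subset size ascending, then lexicographic in the
#' candidate order supplied.
#'
#' @param candidates Character vector of candidate ids (non-empty, unique).
#' @param kMin,kMax Smallest and largest panel size (default 2 and 5).
#' @return List of character vectors, one per panel.
#' @examples
#' length(enumerateSubsets(letters[1:8]))  # choose(8,2..5) = 210
#' @export
enumerateSubsets <- function(candidates, kMin = 2, kMax = 5) {
  if (length(candidates) == 0) stop("empty candidate set")
  if (anyDuplicated(candidates)) stop("duplicate candidate ids")
  if (kMin < 1 || kMin > kMax || kMax > length(candidates))
    stop("need 1 <= kMin <= kMax <= number of candidates")
  out <- list()
  for (k in seq(kMin, kMax)) {
    cmb <- utils::combn(candidates, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Repeated stratified random-split accuracy of one panel
#'
#' For each replicate the samples are split into a stratified training set
#' (fraction \code{trainFrac} of each class, at least 2 and at most
#' \code{n - 1} per class) and the remaining test set; an LDA model is
#' fitted on the training samples and the accuracy (proportion of correct
#' predictions) measured on the test samples. Seeded and reproducible.
#'
#' @param x Samples x features matrix, already restricted to the panel.
#' @param labels Two-class labels, one per sample.
#' @param nRep Number of replicates (default 100).
#' @param trainFrac Training fraction per class (default 2/3).
#' @param seed Integer seed or \code{NULL}.
#' @param ridge Ridge regularization passed to \code{\link{ldaFit}}.
#' @return List with \code{accuracies} (one value per replicate),
#'   \code{meanAccuracy} and \code{bestAccuracy}.
#' @export
repeatedSplitAccuracy <- function(x, labels, nRep = 100, trainFrac = 2 / 3,
                                  seed = NULL, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  assertScalarNumber(trainFrac, "trainFrac", lower = 1e-6, upper = 1)
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  k1 <- min(max(round(trainFrac * length(idx1)), 2L), length(idx1) - 1L)
  k2 <- min(max(round(trainFrac * length(idx2)), 2L), length(idx2) - 1L)
  if (k1 < 2 || k2 < 2)
    stop("too few samples for a stratified split with both classes in training")
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(nRep)
  isClass2 <- as.integer(labels) == 2L
  p <- ncol(x)
  n1 <- length(idx1)
  n2 <- length(idx2)
  diagIdx <- 1L + (seq_len(p) - 1L) * (p + 1L)
  for (r in seq_len(nRep)) {
    tr1 <- idx1[sample.int(n1, k1)]
    tr2 <- idx2[sample.int(n2, k2)]
    te <- seq_along(labels)[-c(tr1, tr2)]
    x1 <- x[tr1, , drop = FALSE]
    x2 <- x[tr2, , drop = FALSE]
    m1 <- .colMeans(x1, k1, p)
    m2 <- .colMeans(x2, k2, p)
    c1 <- x1 - rep(m1, each = k1)
    c2 <- x2 - rep(m2, each = k2)
    S <- (crossprod(c1) + crossprod(c2)) / (k1 + k2 - 2)
    if (ridge > 0)
      S[diagIdx] <- S[diagIdx] + ridge * sum(S[diagIdx]) / p
    # equal-prior LDA boundary as a weight vector: class 2 iff
    # w'x > w'(m1+m2)/2, ties to the first class (as in ldaPredict)
    w <- solve.default(S, m2 - m1)
    pred2 <- c(x[te, , drop = FALSE] %*% w) > sum(w * (m1 + m2)) / 2
    acc[r] <- mean(pred2 == isClass2[te])
  }
  list(accuracies = acc, meanAccuracy = mean(acc), bestAccuracy = max(acc))
}

#' Exhaustive panel search over candidate proteins
#'
#' Evaluates every \code{kMin}-\code{kMax} subset of the candidates by
#' repeated stratified split LDA accuracy and returns the ranked
#' leaderboard. Each panel draws its splits from its own seed substream, so
#' results do not depend on evaluation order.
#'
#' @param x Samples x proteins feature matrix (typically glog values of the
#'   two compared groups, samples in rows), or a normalized
#'   \linkS4class{ProteomeSet} together with \code{classes}.
#' @param labels Two-class labels (ignored for a \code{ProteomeSet}).
#' @param candidates Candidate protein ids (columns of \code{x}).
#' @param kMin,kMax Panel size range (default 2-5, capped at the number of
#'   candidates).
#' @param nRep Split replicates per panel (default 100).
#' @param trainFrac Training fraction (default 2/3).
#' @param seed Master seed for the split substreams.
#' @param classes For a \code{ProteomeSet}: the two groups to compare
#'   (default HC vs IBS).
#' @param ridge Ridge regularization for the LDA fits.
#' @return Ranked \code{data.frame} (see \code{\link{rankPanels}}) with one
#'   row per panel: \code{panel}, \code{size}, \code{meanAccuracy},
#'   \code{bestAccuracy}, \code{rank}.
#' @export
panelSearch <- function(x, labels = NULL, candidates, kMin = 2, kMax = 5,
                        nRep = 100, trainFrac = 2 / 3, seed = 1,
                        classes = c("HC", "IBS"), ridge = 1e-6) {
  if (is(x, "ProteomeSet")) {
    keep <- sampleGroups(x) %in% classes
    labels <- droplevels(factor(sampleGroups(x)[keep], levels = classes))
    x <- t(glogValues(x, base = 10)[, keep, drop = FALSE])
  }
  x <- as.matrix(x)
  missing <- setdiff(candidates, colnames(x))
  if (length(missing))
    stop("candidates absent from the feature matrix: ",
         paste(missing, collapse = ", "))
  kMax <- min(kMax, length(candidates))
  subsets <- enumerateSubsets(candidates, kMin, kMax)
  res <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    ids <- subsets[[i]]
    sub <- repeatedSplitAccuracy(
      x[, ids, drop = FALSE], labels, nRep = nRep, trainFrac = trainFrac,
      seed = substreamSeed(seed, paste(ids, collapse = "|")), ridge = ridge)
    res[[i]] <- data.frame(panel = paste(ids, collapse = "+"),
                           size = length(ids),
                           meanAccuracy = sub$meanAccuracy,
                           bestAccuracy = sub$bestAccuracy,
                           stringsAsFactors = FALSE)
  }
  rankPanels(do.call(rbind, res))
}

#' Rank evaluated panels
#'
#' Sorts by mean accuracy (descending), breaking ties by smaller panel
#' size, then lexicographically by the panel id string.
#'
#' @param results \code{data.frame} with columns \code{panel}, \code{size},
#'   \code{meanAccuracy} (and optionally more).
#' @return The same rows sorted, with a \code{rank} column added.
#' @export
rankPanels <- function(results) {
  if (NROW(results) < 1) stop("no panel results to rank")
  o <- order(-results$meanAccuracy, results$size, results$panel)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
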