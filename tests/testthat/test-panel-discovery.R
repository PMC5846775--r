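# Subset enumeration, LDA, repeated-split scoring, ranking and ROC.

test_that("subset enumeration counts and ordering are correct", {
  expect_length(enumerateSubsets(letters[1:8], 2, 5), 210)
  expect_length(enumerateSubsets(letters[1:3], 2, 2), 3)
  expect_length(enumerateSubsets(letters[1:8], 1, 8), 255)
  subs <- enumerateSubsets(c("a", "b", "c"), 2, 3)
  expect_identical(subs, list(c("a", "b"), c("a", "c"), c("b", "c"),
                              c("a", "b", "c")))
  expect_error(enumerateSubsets(character(0)), "empty")
  expect_error(enumerateSubsets(letters[1:3], 2, 5), "kMax")
})

test_that("one-dimensional LDA has the closed-form boundary", {
  # class means 0 and 2, pooled variance 1, equal priors -> boundary at 1
  x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  y <- factor(rep(c("a", "b"), each = 3))
  fit <- ldaFit(x, y, ridge = 0)
  expect_equal(as.character(ldaPredict(fit, matrix(1.5))), "b")
  expect_equal(as.character(ldaPredict(fit, matrix(0.5))), "a")
  # equidistant point: tie broken to the first class in label order
  expect_equal(as.character(ldaPredict(fit, matrix(1))), "a")
  expect_error(ldaFit(matrix(1, 4, 2), factor(c("a", "a", "b", "b")),
                      ridge = 0), "ridge")
})

test_that("a duplicated ridge-regularized feature leaves predictions unchanged", {
  cls <- separatedClasses(8, 8, p = 1, gap = 3, seed = 2)
  x1 <- cls$x
  x2 <- cbind(x1, x1[, 1, drop = FALSE])
  colnames(x2) <- c("f1", "f1b")
  f1 <- ldaFit(x1, cls$labels)
  f2 <- ldaFit(x2, cls$labels)
  grid1 <- matrix(seq(-3, 6, by = 0.25), ncol = 1)
  grid2 <- cbind(grid1, grid1)
  colnames(grid1) <- "f1"; colnames(grid2) <- c("f1", "f1b")
  expect_identical(ldaPredict(f1, grid1), ldaPredict(f2, grid2))
})

test_that("LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  cls <- separatedClasses(12, 12, p = 3, gap = 1.5, seed = 4)
  fit <- ldaFit(cls$x, cls$labels, ridge = 0)
  ref <- MASS::lda(cls$x, cls$labels, prior = c(0.5, 0.5))
  test <- matrix(rnorm(60, mean = 0.75), 20, 3,
                 dimnames = list(NULL, colnames(cls$x)))
  expect_identical(as.character(ldaPredict(fit, test)),
                   as.character(predict(ref, test)$class))
})

test_that("panel scores are monotone-invariant inputs to the ROC", {
  cls <- separatedClasses(10, 10, p = 2, gap = 1, seed = 5)
  fit <- ldaFit(cls$x, cls$labels)
  sc <- panelScore(fit, cls$x)
  a1 <- aucValue(rocAuc(sc, cls$labels))
  a2 <- aucValue(rocAuc(exp(2 * sc) + 5, cls$labels))
  expect_equal(a1, a2, tolerance = 1e-12)
  # affine-transformed features give identical predictions
  xa <- sweep(cls$x * 3.5, 2, c(10, -2), "+")
  fita <- ldaFit(xa, cls$labels)
  expect_identical(ldaPredict(fit, cls$x), ldaPredict(fita, xa))
  expect_error(panelScore(fit, cls$x[, 1, drop = FALSE]), "mismatch")
})

test_that("repeated splits are stratified, seeded and well calibrated", {
  cls <- separatedClasses(10, 12, p = 2, gap = 12, seed = 6)
  res <- repeatedSplitAccuracy(cls$x, cls$labels, nRep = 50, seed = 1)
  expect_equal(res$meanAccuracy, 1)
  expect_length(res$accuracies, 50)
  res2 <- repeatedSplitAccuracy(cls$x, cls$labels, nRep = 50, seed = 1)
  expect_identical(res$accuracies, res2$accuracies)
  # no signal: accuracy compatible with coin flipping
  set.seed(8)
  x0 <- matrix(rnorm(24 * 2), 24, 2)
  y0 <- factor(rep(c("a", "b"), 12))
  res0 <- repeatedSplitAccuracy(x0, y0, nRep = 100, seed = 2)
  expect_lt(abs(res0$meanAccuracy - 0.5), 0.1)
  expect_true(all(res0$accuracies >= 0 & res0$accuracies <= 1))
})

test_that("panel ranking breaks ties by size then id", {
  res <- data.frame(panel = c("a+b+c", "a+b", "d+e"), size = c(3, 2, 2),
                    meanAccuracy = c(0.9, 0.9, 0.95))
  rk <- rankPanels(res)
  expect_equal(rk$panel, c("d+e", "a+b", "a+b+c"))
  expect_equal(rk$rank, 1:3)
  one <- rankPanels(data.frame(panel = "x+y", size = 2, meanAccuracy = 0.7))
  expect_equal(one$rank, 1)
})

test_that("panel search is deterministic and order-independent", {
  ps <- vsnNormalize(smallProteome(seed = 31, nDifferential = 3,
                                   nProteases = 6,
                                   effectRange = c(0.5, 0.6),
                                   patternWeights = c(1, 0, 0, 0, 0, 0, 0)))
  cand <- groundTruth(ps)$proteaseIds
  lb1 <- panelSearch(ps, candidates = cand, kMax = 3, nRep = 20, seed = 5)
  lb2 <- panelSearch(ps, candidates = cand, kMax = 3, nRep = 20, seed = 5)
  expect_identical(lb1, lb2)
  # per-panel substreams: a panel's accuracy does not depend on which
  # other panels were evaluated
  lb3 <- panelSearch(ps, candidates = cand[1:3], kMin = 2, kMax = 2,
                     nRep = 20, seed = 5)
  shared <- intersect(lb1$panel, lb3$panel)
  expect_gt(length(shared), 0)
  expect_equal(lb1$meanAccuracy[match(shared, lb1$panel)],
               lb3$meanAccuracy[match(shared, lb3$panel)])
})

test_that("study-scale condition reaches study-scale top accuracy", {
  # 7 + 8 samples with strong planted three-protein signal: the search
  # reproduces a >= 0.95 top accuracy, echoing the printed 98%
  cfg <- synthProteomeConfig(nProteins = 200, nDifferential = 3,
                             effectRange = c(0.4, 0.5),
                             patternWeights = c(1, 0, 0, 0, 0, 0, 0),
                             nProteases = 8, seed = 61)
  ps <- vsnNormalize(simulateProteome(cfg))
  lb <- panelSearch(ps, candidates = groundTruth(ps)$proteaseIds, seed = 61)
  expect_gte(lb$meanAccuracy[1], 0.95)
})

test_that("trapezoid ROC matches brute-force pair counting", {
  expect_equal(aucValue(rocAuc(1:4, c(0, 0, 1, 1), positive = "1")), 1)
  expect_equal(aucValue(rocAuc(1:4, c(1, 0, 1, 0), positive = "1")), 0.25)
  expect_equal(aucValue(rocAuc(rep(1, 6), rep(c(0, 1), 3), positive = "1")),
               0.5)
  # brute-force oracle over all positive-negative pairs, with ties
  set.seed(9)
  for (i in 1:25) {
    sc <- sample(1:6, 30, replace = TRUE)
    lab <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    oracle <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
    expect_equal(aucValue(rocAuc(sc, lab, positive = "1")), oracle,
                 tolerance = 1e-12)
    expect_equal(pairCountAuc(sc, lab, positive = "1"), oracle,
                 tolerance = 1e-12)
    # label-swap symmetry
    expect_equal(aucValue(rocAuc(sc, lab, positive = "0")), 1 - oracle,
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- rnorm(40)
  lab <- rbinom(40, 1, 0.5)
  ours <- aucValue(rocAuc(sc, lab, positive = "1"))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the ROC curve runs monotonically from (0,0) to (1,1)", {
  set.seed(14)
  rc <- rocAuc(rnorm(30), rbinom(30, 1, 0.4), positive = "1")
  cv <- rocPoints(rc)
  expect_equal(cv$sensitivity[1], 0)
  expect_equal(1 - cv$specificity[1], 0)
  expect_equal(cv$sensitivity[nrow(cv)], 1)
  expect_equal(cv$specificity[nrow(cv)], 0)
  expect_true(all(diff(cv$sensitivity) >= 0))
  expect_true(all(diff(1 - cv$specificity) >= 0))
})

test_that("a combined panel scores at least as well as its best single", {
  aucsCombined <- aucsSingle <- numeric(8)
  for (s in 1:8) {
    cfg <- synthProteomeConfig(nProteins = 100,
                               groupSizes = c(HC = 15, IBS = 15, UC = 2),
                               nDifferential = 3,
                               effectRange = c(0.25, 0.3),
                               patternWeights = c(1, 0, 0, 0, 0, 0, 0),
                               nProteases = 3, seed = 70 + s)
    ps <- vsnNormalize(simulateProteome(cfg))
    ids <- groundTruth(ps)$differentialIds
    keep <- sampleGroups(ps) %in% c("HC", "IBS")
    labels <- droplevels(sampleGroups(ps)[keep])
    feats <- t(glogValues(ps, base = 10)[ids, keep, drop = FALSE])
    model <- ldaFit(feats, labels)
    aucsCombined[s] <- aucValue(rocAuc(panelScore(model, feats), labels,
                                       positive = "IBS"))
    aucsSingle[s] <- max(vapply(ids, function(id)
      aucValue(rocAuc(feats[, id], labels, positive = "IBS")), numeric(1)))
  }
  expect_gte(mean(aucsCombined - aucsSingle), 0)
})
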