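# Group model, empirical-Bayes moderation, BH adjustment and the
# abundance-pattern classification.

groupFactor <- factor(rep(c("HC", "IBS", "UC"), c(7, 8, 7)),
                      levels = c("HC", "IBS", "UC"))

test_that("the one-way fit reproduces hand-computed means and variances", {
  m <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 1)
  g <- factor(rep(c("HC", "IBS", "UC"), each = 2))
  fit <- fitGroupModel(m, g)
  expect_equal(unname(fit$means[1, ]), c(1, 2, 3))
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df, 3)
  # shift equivariance: adding a constant moves means, not variances
  fit2 <- fitGroupModel(m + 7, g)
  expect_equal(fit2$means, fit$means + 7)
  expect_equal(fit2$s2, fit$s2)
  expect_error(fitGroupModel(m, factor(c("a", "a", "a", "a", "a", "b"))),
               "fewer than 2")
})

test_that("residual variance equals the pooled within-group variance", {
  set.seed(10)
  m <- matrix(rnorm(30 * 22), 30, 22)
  fit <- fitGroupModel(m, groupFactor)
  oracle <- apply(m, 1, function(y) {
    mns <- tapply(y, groupFactor, mean)
    sum((y - mns[as.character(groupFactor)])^2) / (22 - 3)
  })
  expect_equal(unname(fit$s2), unname(oracle), tolerance = 1e-12)
})

test_that("moment-matching recovers planted variance hyperparameters", {
  set.seed(42)
  G <- 5000
  sigma2 <- 1 * 4 / rchisq(G, 4)
  s2 <- sigma2 * rchisq(G, 10) / 10
  eb <- ebayesModerate(s2, 10)
  expect_lt(abs(eb$d0 - 4) / 4, 0.15)
  expect_lt(abs(eb$s02 - 1), 0.15)
  # shrinkage bracketing: every moderated variance between s2 and s02
  expect_true(all(eb$s2Post >= pmin(s2, eb$s02) - 1e-12 &
                    eb$s2Post <= pmax(s2, eb$s02) + 1e-12))
})

test_that("moderation matches the independent reference implementation", {
  skip_if_not_installed("limma")
  set.seed(13)
  s2 <- rchisq(2000, 6) / 6 * (3 / rchisq(2000, 3))
  eb <- ebayesModerate(s2, 6)
  ff <- limma::fitFDist(s2, df1 = 6)
  expect_equal(eb$d0, ff$df2, tolerance = 1e-6)
  expect_equal(eb$s02, ff$scale, tolerance = 1e-6)
})

test_that("equal variances collapse to complete shrinkage", {
  eb <- ebayesModerate(rep(2.5, 50), 5)
  expect_identical(eb$d0, Inf)
  expect_equal(unname(eb$s2Post), rep(2.5, 50))
  expect_error(ebayesModerate(rep(0, 50), 5), "zero")
})

test_that("unmoderated statistics equal the classical ANOVA oracle", {
  set.seed(7)
  m <- matrix(rnorm(50 * 22), 50, 22)
  fit <- fitGroupModel(m, groupFactor)
  mt <- moderatedTests(fit$means, fit$n, fit$s2, fit$df)  # d0 = 0
  pOracle <- apply(m, 1, function(y) anova(lm(y ~ groupFactor))[1, "Pr(>F)"])
  expect_lt(max(abs(mt$pF - pOracle)), 1e-10)
  tOracle <- apply(m, 1, function(y) {
    mns <- tapply(y, groupFactor, mean)
    s2p <- sum((y - mns[as.character(groupFactor)])^2) / 19
    (mns[["IBS"]] - mns[["HC"]]) / sqrt(s2p * (1 / 7 + 1 / 8))
  })
  expect_lt(max(abs(mt$pT[, "IBS-vs-HC"] -
                      2 * pt(abs(tOracle), 19, lower.tail = FALSE))), 1e-10)
  # zero contrast gives t = 0, p = 1
  mConst <- matrix(rep(rnorm(22, sd = 0), 2), 2, 22) + 5
  fitC <- fitGroupModel(mConst + rnorm(44, sd = 1e-9), groupFactor)
  mtC <- moderatedTests(fitC$means, fitC$n, rep(1, 2), fitC$df)
  expect_lt(max(abs(mtC$t)), 1e-6)
  expect_gt(min(mtC$pT), 1 - 1e-5)
})

test_that("p-values are uniform under the null generator", {
  cfg <- synthProteomeConfig(nProteins = 2000, nDifferential = 0,
                             nProteases = 0, seed = 8)
  fit <- moderatedDE(vsnNormalize(simulateProteome(cfg)))
  expect_gt(ks.test(diffTable(fit)$pF, "punif")$p.value, 0.01)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(100)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("selectDifferential honours the threshold", {
  ps <- smallProteome(seed = 2)
  fit <- moderatedDE(vsnNormalize(ps))
  expect_setequal(selectDifferential(fit, 1), rownames(ps))
  sel <- selectDifferential(fit, 0.05)
  expect_true(all(diffTable(fit)[sel, "padjF"] < 0.05))
})

test_that("pattern classification reproduces the reference protease table", {
  tab <- referenceProteaseTable()
  expect_equal(nrow(tab), 17)
  cls <- classifyPattern(tab$ratioIbsHc, tab$pIbsHc, tab$ratioUcHc,
                         tab$pUcHc, tab$ratioIbsUc, tab$pIbsUc)
  # printed single rows
  expect_equal(cls[tab$name == "Elastase 3A"], "up-IBS-vs-both")
  expect_equal(cls[tab$name == "Cathepsin C"], "up-IBS-vs-HC-and-UC-vs-HC")
  expect_equal(cls[tab$name == "Cathepsin H"], "down-IBS-vs-UC-only")
  # full partition of the 17 rows
  counts <- table(factor(cls, levels = c(
    "up-IBS-vs-both", "up-IBS-vs-HC-and-UC-vs-HC", "up-IBS-vs-HC-only",
    "up-IBS-vs-UC-only", "down-IBS-vs-HC", "down-IBS-vs-HC-and-UC",
    "down-IBS-vs-UC-only", "other")))
  expect_equal(unname(as.integer(counts)), c(4, 1, 3, 2, 4, 2, 1, 0))
})

test_that("pattern class is a pure function of signs and significance", {
  # non-significant everywhere -> other, regardless of signs
  expect_equal(classifyPattern(0.5, 0.5, -0.2, 0.6, 0.4, 0.9), "other")
  # vectorization keeps row order
  cls <- classifyPattern(c(0.5, -0.5), c(0.01, 0.01), c(0, 0), c(1, 1),
                         c(0.4, -0.4), c(0.01, 0.01))
  expect_equal(cls, c("up-IBS-vs-both", "down-IBS-vs-HC-and-UC"))
})
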