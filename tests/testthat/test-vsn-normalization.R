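# Generalized-log normalization, z-scores, clustering and PCA.

test_that("glog transform has the arsinh limits", {
  expect_identical(glogTransform(0, 0, 1), 0)
  # approaches a logarithm (of 2x/b) for large arguments: < 1% relative
  # error from (x - a)/b = 10 upwards
  u <- c(10, 30, 100, 1e4)
  expect_true(all(abs(glogTransform(u) - log(2 * u)) / log(2 * u) < 0.01))
  # ratios turn into log differences at high intensity
  expect_equal(glogTransform(2e6, 0, 1500) - glogTransform(1e6, 0, 1500),
               log(2), tolerance = 1e-5)
  expect_error(glogTransform(1, 0, 0), "positive")
})

test_that("identical sample columns give identical calibrations", {
  set.seed(4)
  x <- matrix(rep(rlnorm(80, 8, 0.8), 4), ncol = 4)
  rownames(x) <- sprintf("P%03d", 1:80)
  ps <- vsnNormalize(ProteomeSet(x, group = c("HC", "HC", "IBS", "IBS")))
  cal <- vsnCalibration(ps)
  expect_equal(diff(range(cal$offset)), 0, tolerance = 1e-6 * mean(cal$scale))
  expect_equal(diff(range(cal$scale)) / mean(cal$scale), 0, tolerance = 1e-6)
  h <- glogValues(ps)
  expect_lt(max(abs(h - h[, 1])), 1e-8)
})

test_that("normalization stabilizes the variance the generator plants", {
  ps <- simulateProteome(synthProteomeConfig(nProteins = 500,
                                             nDifferential = 0,
                                             nProteases = 0, seed = 11))
  psn <- vsnNormalize(ps)
  h <- glogValues(psn)
  mu <- rowMeans(h)
  sds <- apply(h, 1, sd)
  dec <- cut(mu, quantile(mu, 0:10 / 10), include.lowest = TRUE)
  hRatio <- max(tapply(sds, dec, median)) / min(tapply(sds, dec, median))
  raw <- intensities(ps)
  rdec <- cut(rowMeans(raw), quantile(rowMeans(raw), 0:10 / 10),
              include.lowest = TRUE)
  rawRatio <- max(tapply(apply(raw, 1, sd), rdec, median)) /
    min(tapply(apply(raw, 1, sd), rdec, median))
  expect_lt(hRatio, 2)
  expect_gt(rawRatio, 10)
  # transformed sample distributions are aligned
  expect_lt(diff(range(apply(h, 2, median))), 0.2)
  expect_true(all(vsnCalibration(psn)$scale > 0))
})

test_that("scaling one sample is absorbed into its scale parameter", {
  ps <- simulateProteome(synthProteomeConfig(nProteins = 300,
                                             nDifferential = 0,
                                             nProteases = 0, seed = 21))
  m <- intensities(ps)
  h1 <- glogValues(vsnNormalize(ps))
  m2 <- m
  m2[, 3] <- m[, 3] * 2
  ps2 <- ProteomeSet(m2, group = as.character(sampleGroups(ps)))
  psn2 <- vsnNormalize(ps2)
  expect_equal(vsnCalibration(psn2)$scale[[3]] /
                 vsnCalibration(vsnNormalize(ps))$scale[[3]],
               2, tolerance = 0.1)
  d <- abs(h1 - glogValues(psn2))
  expect_lt(median(d), 0.05)
  expect_lt(max(d), 0.3)
})

test_that("degenerate inputs are rejected with diagnostics", {
  x <- matrix(rlnorm(40, 8), 10, 4, dimnames = list(paste0("P", 1:10), NULL))
  x[, 2] <- 5
  ps <- ProteomeSet(x, group = c("HC", "HC", "IBS", "IBS"))
  expect_error(vsnNormalize(ps), "constant sample")
  expect_error(vsnNormalize(ProteomeSet(x[1:5, ],
                                        group = c("HC", "HC", "IBS", "IBS"))),
               "at least 10 proteins")
})

test_that("per-protein z-scores standardize exactly", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 9))
  z <- zscoreByProtein(m)
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  mm <- rbind(a = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(zscoreByProtein(mm), "flat")
  expect_error(zscoreByProtein(m, "missing"), "unknown")
})

test_that("complete-linkage clustering matches the brute-force tree", {
  z <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("a", "b", "c"), NULL))
  cl <- hierarchicalCluster(z, cols = FALSE)
  expect_equal(cl$rowTree$height, c(1, 10))
  expect_equal(sort(cl$rowOrder), 1:3)
  # identical items merge at height zero
  z2 <- matrix(c(1, 1, 5), ncol = 1)
  cl2 <- hierarchicalCluster(z2, cols = FALSE)
  expect_equal(min(cl2$rowTree$height), 0)
  expect_true(all(diff(cl2$rowTree$height) >= 0))
  expect_error(hierarchicalCluster(matrix(c(1, NA), 2, 1)), "missing")
})

test_that("sample PCA is orthonormal with ordered variance fractions", {
  # collinear cloud: first component carries all variance
  line <- rbind(seq_len(20), 2 * seq_len(20))
  pc <- pcaSamples(line)
  expect_equal(pc$varExplained[1], 1, tolerance = 1e-12)
  set.seed(6)
  m <- matrix(rnorm(200), 10, 20)
  pc2 <- pcaSamples(m)
  expect_true(all(diff(pc2$varExplained) <= 1e-12))
  expect_equal(sum(pc2$varExplained), 1, tolerance = 1e-12)
  expect_equal(crossprod(pc2$loadings), diag(ncol(pc2$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # scores times loadings reconstruct the centred data
  recon <- pc2$scores %*% t(pc2$loadings)
  centred <- t(m) - rep(rowMeans(m), each = 20)
  expect_lt(max(abs(recon - centred)), 1e-8)
})
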