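# Variance-stabilizing normalization: per-sample affine calibration followed
# by a generalized-log (arsinh) transform, fitted by robust (least-trimmed)
# profile maximum likelihood under the additive-multiplicative error model.

#' Generalized-log (arsinh) transform
#'
#' \code{h(x) = arsinh((x - offset) / scale)}. For large positive arguments
#' \code{h(x1) - h(x2)} approaches \code{ln(x1) - ln(x2)}; near zero the
#' transform is linear, which is what stabilizes the variance of
#' additive-noise-dominated low intensities.
#'
#' @param x Numeric vector or matrix.
#' @param offset Per-sample additive calibration a_s (scalar, or one per
#'   column of \code{x}).
#' @param scale Per-sample scale calibration b_s (> 0).
#' @return Transformed values, same shape as \code{x}.
#' @examples
#' glogTransform(0, 0, 1)        # = arsinh(0) = 0
#' glogTransform(2e6, 0, 1) - glogTransform(1e6, 0, 1)  # ~ ln 2
#' @export
glogTransform <- function(x, offset = 0, scale = 1) {
  if (any(scale <= 0)) stop("'scale' must be positive")
  if (is.matrix(x)) {
    t <- sweep(x, 2, rep_len(offset, ncol(x)), "-")
    asinh(sweep(t, 2, rep_len(scale, ncol(x)), "/"))
  } else {
    asinh((x - offset) / scale)
  }
}

# Profiled negative log-likelihood and its analytic gradient, for the rows
# in the current trim set. Row means (the protein-level fit) are profiled
# out inside the objective; because residuals sum to zero per row, their
# derivative contribution vanishes.
.vsnObjective <- function(par, x) {
  n <- ncol(x)
  a <- par[seq_len(n)]
  b <- exp(par[n + seq_len(n)])
  t <- sweep(x, 2, a, "-")
  h <- asinh(sweep(t, 2, b, "/"))
  r <- h - rowMeans(h)
  D <- sweep(t^2, 2, b^2, "+")
  N <- length(x)
  out <- (N / 2) * log(max(sum(r^2), 1e-300)) + 0.5 * sum(log(D))
  if (!is.finite(out)) out <- 1e300
  out
}

.vsnGradient <- function(par, x) {
  n <- ncol(x)
  a <- par[seq_len(n)]
  b <- exp(par[n + seq_len(n)])
  t <- sweep(x, 2, a, "-")
  h <- asinh(sweep(t, 2, b, "/"))
  r <- h - rowMeans(h)
  D <- sweep(t^2, 2, b^2, "+")
  w <- 1 / sqrt(D)
  N <- length(x)
  rss <- sum(r^2)
  gradA <- (N / rss) * (-colSums(r * w)) - colSums(t * w^2)
  gradLogB <- (N / rss) * (-colSums(r * t * w)) +
    colSums(sweep(w^2, 2, b^2, "*"))
  c(gradA, gradLogB)
}

#' Variance-stabilizing normalization of a proteome
#'
#' Estimates per-sample calibration parameters (a_s, b_s) of the transform
#' \code{h(x) = arsinh((x - a_s)/b_s)} by maximum likelihood under the
#' additive-multiplicative error model, profiling out the per-protein means
#' and the common variance, with least-trimmed-squares robustness: after
#' each fit the 10\% of proteins with the largest residual sum of squares
#' are set aside and the fit repeated until the calibration stabilizes.
#' The transformed matrix is stored as assay \code{"glog"} and the
#' calibration in \code{metadata(x)$vsn}.
#'
#' @param x A \linkS4class{ProteomeSet} with >= 10 proteins, >= 2 samples
#'   and positive intensities.
#' @param trim Fraction of proteins excluded as outliers (default 0.1).
#' @param maxIter Maximum outer trimming iterations (default 50).
#' @param tol Convergence tolerance on the calibration change (default 1e-8).
#' @return The input object with assay \code{"glog"} and calibration
#'   metadata added; see \code{\link{glogValues}}, \code{\link{vsnCalibration}}.
#' @export
vsnNormalize <- function(x, trim = 0.1, maxIter = 50, tol = 1e-8) {
  stopifnot(is(x, "ProteomeSet"))
  m <- intensities(x)
  if (anyNA(m))
    stop("missing intensities are not supported by the calibration fit")
  if (nrow(m) < 10) stop("need at least 10 proteins")
  if (ncol(m) < 2) stop("need at least 2 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate constant sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  n <- ncol(m)
  a <- rep(0, n)
  b <- pmax(apply(m, 2, stats::quantile, 0.25), .Machine$double.eps)
  par <- c(a, log(b))
  keep <- seq_len(nrow(m))
  nKeep <- max(2L, ceiling((1 - trim) * nrow(m)))
  iter <- 0L
  converged <- FALSE
  fPrev <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    fit <- stats::optim(par, .vsnObjective, .vsnGradient,
                        x = m[keep, , drop = FALSE],
                        method = "L-BFGS-B",
                        lower = c(rep(-10 * max(m), n),
                                  rep(log(min(m[m > 0]) * 1e-8), n)),
                        upper = c(rep(10 * max(m), n),
                                  rep(log(max(m) * 1e4), n)),
                        control = list(maxit = 500, factr = 1e4))
    # offsets are only identified relative to the scale, so measure the
    # parameter change on the (a/b, log b) scale; the objective change is
    # a secondary stop against optimizer jitter on the flat offset ridge
    bNew <- exp(fit$par[n + seq_len(n)])
    delta <- max(abs(fit$par[seq_len(n)] - par[seq_len(n)]) / bNew,
                 abs(fit$par[n + seq_len(n)] - par[n + seq_len(n)]))
    fDelta <- abs(fPrev - fit$value) / (1 + abs(fit$value))
    fPrev <- fit$value
    par <- fit$par
    h <- glogTransform(m, par[seq_len(n)], bNew)
    rss <- rowSums((h - rowMeans(h))^2)
    keepNew <- order(rss)[seq_len(nKeep)]
    if (min(delta, fDelta) < tol && identical(sort(keepNew), sort(keep))) {
      converged <- TRUE
      break
    }
    keep <- keepNew
  }
  a <- par[seq_len(n)]
  b <- exp(par[n + seq_len(n)])
  if (any(!is.finite(b)) || any(b <= 0))
    stop("calibration fit failed: non-positive scale estimate (iterations: ",
         iter, ")")
  h <- glogTransform(m, a, b)
  dimnames(h) <- dimnames(m)
  assay(x, "glog", withDimnames = TRUE) <- h
  metadata(x)$vsn <- list(offset = structure(a, names = colnames(m)),
                          scale = structure(b, names = colnames(m)),
                          iterations = iter, converged = converged,
                          trimmedFraction = trim)
  validObject(x)
  x
}

#' Per-protein z-scores of normalized values
#'
#' Standardizes each selected protein row to mean 0 and sample (n-1)
#' standard deviation 1 across samples, the scale conventionally used for
#' clustered heatmaps.
#'
#' @param x A normalized \linkS4class{ProteomeSet} or a numeric matrix
#'   (proteins x samples).
#' @param proteins Optional character vector restricting the rows.
#' @return Matrix of z-scores, selected proteins x samples.
#' @export
zscoreByProtein <- function(x, proteins = NULL) {
  m <- if (is(x, "ProteomeSet")) glogValues(x) else as.matrix(x)
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, rownames(m))
    if (length(missing))
      stop("unknown proteins: ", paste(missing, collapse = ", "))
    m <- m[proteins, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("empty protein subset")
  if (ncol(m) < 2) stop("need at least 2 samples")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance protein(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  t(scale(t(m)))[, , drop = FALSE]
}

#' Complete-linkage hierarchical clustering of rows and columns
#'
#' Agglomerative clustering with Euclidean distance and complete linkage,
#' as used for the z-score heatmap of differential proteins.
#'
#' @param z Numeric matrix (no missing values).
#' @param rows,cols Cluster the rows / the columns (default both; a
#'   dimension with fewer than 2 items is skipped).
#' @return List with \code{rowTree}, \code{colTree} (objects of class
#'   \code{hclust} or \code{NULL}) and the corresponding \code{rowOrder},
#'   \code{colOrder} leaf permutations.
#' @export
hierarchicalCluster <- function(z, rows = TRUE, cols = TRUE) {
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z)))
    stop("input contains missing or non-finite values")
  out <- list(rowTree = NULL, colTree = NULL, rowOrder = NULL, colOrder = NULL)
  if (rows && nrow(z) >= 2) {
    out$rowTree <- stats::hclust(stats::dist(z, method = "euclidean"),
                                 method = "complete")
    out$rowOrder <- out$rowTree$order
  }
  if (cols && ncol(z) >= 2) {
    out$colTree <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                                 method = "complete")
    out$colOrder <- out$colTree$order
  }
  out
}

#' Principal component analysis of samples
#'
#' Centred (unscaled) PCA of the samples of a proteins-x-samples matrix.
#'
#' @param m Numeric matrix, features x samples (e.g. z-scores or glog
#'   values of the differential proteins).
#' @return List with \code{scores} (samples x components),
#'   \code{loadings} (features x components), \code{varExplained}
#'   (fractions, non-increasing) and \code{sdev}.
#' @export
pcaSamples <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2 || nrow(m) < 2)
    stop("need at least 2 samples and 2 features")
  if (anyNA(m)) stop("input contains missing values")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  list(scores = pc$x, loadings = pc$rotation,
       varExplained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}
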