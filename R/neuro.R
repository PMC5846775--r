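# Neurophysiology statistics: the neuroindex and Ca-neuroindex per
# ganglion, the nonparametric test battery (Kruskal-Wallis with Dunn's
# post-hoc and Bonferroni adjustment, paired Wilcoxon, Mann-Whitney), the
# antagonist percent inhibition and its Pearson correlation with protease
# abundance.

#' Neuroindex of a ganglion recording
#'
#' The product of the percentage of responding neurons and their mean spike
#' discharge frequency:
#' \code{100 * responders/neuronsTotal * mean(frequencies)}; zero when no
#' neuron responds. Reported without units.
#'
#' @param neuronsTotal Number of imaged neurons in the ganglion (> 0).
#' @param responders Number of responding neurons (0..neuronsTotal).
#' @param magnitudes Per-responder spike frequencies in Hz (vector of
#'   length \code{responders}), or a single pre-averaged mean frequency.
#' @return The neuroindex, a single non-negative number.
#' @examples
#' neuroindex(10, 8, rep(3.8, 8))  # 80% of 3.8 Hz -> 304
#' @export
neuroindex <- function(neuronsTotal, responders, magnitudes = numeric(0)) {
  assertScalarNumber(neuronsTotal, "neuronsTotal", lower = 1)
  assertScalarNumber(responders, "responders", lower = 0)
  if (responders > neuronsTotal)
    stop("more responders than neurons in the ganglion")
  if (responders == 0) return(0)
  if (!length(magnitudes) %in% c(1L, responders))
    stop("'magnitudes' must hold one frequency per responder (or one mean)")
  if (any(magnitudes < 0)) stop("spike frequencies must be >= 0")
  100 * responders / neuronsTotal * mean(magnitudes)
}

#' Ca-neuroindex of a calcium-imaging recording
#'
#' The calcium-imaging analogue of the neuroindex: the mean peak
#' intracellular calcium response (dF/F) of the responding neurons times
#' the percentage of responders, with the number of nicotine-responsive
#' cells as the 100\% reference.
#'
#' @param nicotineResponders Number of nicotine-responsive cells (> 0).
#' @param responders Number of cells responding to the stimulus.
#' @param magnitudes Per-responder peak dF/F values (or one mean).
#' @return The Ca-neuroindex, a single non-negative number.
#' @examples
#' caNeuroindex(8, 4, rep(2, 4))  # 50% responders at dF/F 2 -> 100
#' @export
caNeuroindex <- function(nicotineResponders, responders,
                         magnitudes = numeric(0)) {
  assertScalarNumber(nicotineResponders, "nicotineResponders", lower = 1)
  assertScalarNumber(responders, "responders", lower = 0)
  if (responders == 0) return(0)
  if (!length(magnitudes) %in% c(1L, responders))
    stop("'magnitudes' must hold one dF/F value per responder (or one mean)")
  if (any(magnitudes < 0)) stop("dF/F values must be >= 0")
  100 * responders / nicotineResponders * mean(magnitudes)
}

#' Neuroindex table of a ganglion recording data set
#'
#' Computes the per-ganglion neuroindex for a recording table (as produced
#' by \code{\link{simulateGanglia}} or read with
#' \code{\link{readGanglionCSV}}) and optionally aggregates to one value
#' per patient, the level at which between-group tests are run.
#'
#' @param recordings \code{data.frame} with columns \code{patient},
#'   \code{group}, \code{neuronsTotal}, \code{responders} and
#'   semicolon-joined \code{magnitudes}.
#' @param aggregate \code{"none"} for per-ganglion values,
#'   \code{"median"} (default for testing) or \code{"mean"} for one value
#'   per patient.
#' @return \code{data.frame} with \code{patient}, \code{group} and
#'   \code{neuroindex} (plus \code{ganglion} when not aggregated).
#' @export
neuroindexTable <- function(recordings,
                            aggregate = c("none", "median", "mean")) {
  aggregate <- match.arg(aggregate)
  mags <- lapply(strsplit(as.character(recordings$magnitudes), ";",
                          fixed = TRUE),
                 function(s) as.numeric(s[nzchar(s)]))
  ni <- vapply(seq_len(nrow(recordings)), function(i)
    neuroindex(recordings$neuronsTotal[i], recordings$responders[i],
               mags[[i]]), numeric(1))
  out <- data.frame(patient = recordings$patient, group = recordings$group,
                    ganglion = recordings$ganglion, neuroindex = ni,
                    stringsAsFactors = FALSE)
  if (aggregate == "none") return(out)
  fun <- if (aggregate == "median") stats::median else mean
  agg <- stats::aggregate(neuroindex ~ patient + group, data = out, FUN = fun)
  agg[order(agg$group, agg$patient), , drop = FALSE]
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based one-way analysis of variance across the groups (tie
#' corrected), followed by Dunn's all-pairwise z statistics from the mean
#' ranks with Bonferroni-adjusted p-values
#' (\code{p_adj = min(1, p * number of pairs)}).
#'
#' @param values Numeric response values.
#' @param groups Group labels, one per value (>= 2 non-empty groups).
#' @return List with \code{statistic} (H), \code{df}, \code{p.value} and
#'   \code{dunn}, a \code{data.frame} of pairwise \code{z}, \code{p} and
#'   \code{padj}.
#' @export
groupCompare <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (anyNA(values)) stop("missing values are not allowed")
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
  meanRank <- tapply(r, groups, mean)
  sizes <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(length(lev), 2)
  z <- numeric(ncol(pairs))
  cmp <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tieCorr) *
                 (1 / sizes[[i1]] + 1 / sizes[[i2]]))
    z[j] <- (meanRank[[i1]] - meanRank[[i2]]) / se
    cmp[j] <- paste(lev[i1], "vs", lev[i2])
  }
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value,
       dunn = data.frame(comparison = cmp, z = z, p = p,
                         padj = pmin(1, p * ncol(pairs)),
                         stringsAsFactors = FALSE))
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test of paired pre/post values; zero differences
#' are dropped (signed-rank convention), the exact null distribution is
#' used for up to 25 remaining pairs (when no ties) and the
#' continuity-corrected normal approximation otherwise. If all differences
#' are zero the result is flagged degenerate with p = 1.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param minPairs Minimum non-zero pairs required (default 5).
#' @return List with \code{statistic} (V), \code{p.value}, \code{n}
#'   (non-zero pairs) and \code{degenerate}.
#' @export
pairedCompare <- function(pre, post, minPairs = 5) {
  if (length(pre) != length(post)) stop("'pre' and 'post' must be paired")
  d <- post - pre
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(statistic = NA_real_, p.value = 1, n = 0L, degenerate = TRUE))
  if (length(nz) < minPairs)
    stop("fewer than ", minPairs, " non-zero paired differences")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = length(nz), degenerate = FALSE)
}

#' Mann-Whitney rank-sum comparison of two unpaired samples
#'
#' Two-sided test; exact for small tie-free samples, tie-corrected normal
#' approximation with continuity correction otherwise. The returned U is
#' the number of (a, b) pairs with a above b (ties half-weighted), so
#' \code{U(a, b) + U(b, a) = length(a) * length(b)}.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exactMax Largest per-sample size for the exact distribution.
#' @return List with \code{statistic} (U), \code{p.value}, and the sample
#'   sizes \code{nA}, \code{nB}.
#' @export
unpairedCompare <- function(a, b, exactMax = 50) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  exact <- length(a) <= exactMax && length(b) <= exactMax &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       nA = length(a), nB = length(b))
}

#' Percent inhibition of the neuroindex
#'
#' \code{100 * (pre - post) / pre}; negative when the post value exceeds
#' the baseline. Vectorized over paired values.
#'
#' @param pre Baseline neuroindex (> 0).
#' @param post Neuroindex under the antagonist / inhibitor.
#' @return Percent decrease per pair.
#' @examples
#' percentInhibition(158.3, 50.5)  # 68.1
#' @export
percentInhibition <- function(pre, post) {
  if (length(pre) != length(post)) stop("'pre' and 'post' must be paired")
  if (any(pre <= 0)) stop("percent inhibition is undefined for pre <= 0")
  100 * (pre - post) / pre
}

#' Pearson correlation of protease abundance with antagonist inhibition
#'
#' Standard Pearson correlation between per-patient protease abundance and
#' the antagonist-induced percent decrease of the neuroindex, with the
#' two-sided p-value from \code{t = r sqrt((n-2)/(1-r^2))}.
#'
#' @param abundance Per-patient abundance values (n >= 3, finite).
#' @param decrease Per-patient percent decrease, same length.
#' @return List with \code{r}, \code{p.value} and \code{n}.
#' @export
abundanceInhibitionCorrelation <- function(abundance, decrease) {
  if (length(abundance) != length(decrease))
    stop("'abundance' and 'decrease' must be paired")
  if (length(abundance) < 3) stop("need at least 3 patients")
  if (any(!is.finite(abundance)) || any(!is.finite(decrease)))
    stop("values must be finite")
  if (stats::sd(abundance) == 0 || stats::sd(decrease) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(abundance, decrease, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n = length(abundance))
}
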