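# Moderated differential abundance across the three sample groups:
# per-protein one-way least squares, empirical-Bayes variance shrinkage,
# moderated t/F statistics, BH false-discovery control and the
# abundance-pattern classification.

#' Per-protein one-way group model
#'
#' Ordinary least squares of each protein on the sample-group factor:
#' group means, pooled residual variance and residual degrees of freedom
#' \code{n - k}.
#'
#' @param x A normalized \linkS4class{ProteomeSet}, or a numeric matrix
#'   (proteins x samples) supplied together with \code{groups}.
#' @param groups Factor of group labels (ignored when \code{x} is a
#'   \code{ProteomeSet}).
#' @param base Log base for the returned means when \code{x} is a
#'   \code{ProteomeSet}: default 10, so contrasts read as log10 ratios.
#' @return List with \code{means} (proteins x groups), \code{s2} (residual
#'   variances), \code{df} (residual degrees of freedom) and \code{n}
#'   (samples per group).
#' @export
fitGroupModel <- function(x, groups = NULL, base = 10) {
  if (is(x, "ProteomeSet")) {
    groups <- sampleGroups(x)
    m <- glogValues(x, base = base)
  } else {
    m <- as.matrix(x)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  nPer <- table(groups)
  if (any(nPer < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(nPer)[nPer < 2], collapse = ", "))
  k <- nlevels(groups)
  means <- sapply(levels(groups), function(g)
    rowMeans(m[, groups == g, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(m), levels(groups)))
  rss <- rowSums((m - means[, as.character(groups), drop = FALSE])^2)
  df <- ncol(m) - k
  list(means = means, s2 = rss / df, df = df,
       n = structure(as.integer(nPer), names = names(nPer)))
}

# Newton inversion of the trigamma function, used to match the variance of
# log sample variances to a scaled-F marginal.
.trigammaInverse <- function(y, tol = 1e-8, maxIter = 50) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))   # trigamma(x) ~ 1/x^2 for small x
  if (y < 1e-6) return(1 / y)        # trigamma(x) ~ 1/x   for large x
  x <- 0.5 + 1 / y
  for (i in seq_len(maxIter)) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, deriv = 2)
    xNew <- x - step
    if (xNew <= 0) xNew <- x / 2
    if (abs(xNew - x) < tol * x) return(xNew)
    x <- xNew
  }
  stop("trigamma inversion did not converge (target ", format(y),
       ", last value ", format(x), ")")
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' moment-matching the marginal scaled-F distribution of the per-protein
#' sample variances (mean and variance of log s^2 with trigamma inversion),
#' then shrinks each variance to
#' \code{(d0 * s0^2 + df * s2) / (d0 + df)}. When the observed log-variance
#' spread is no larger than expected from chi-squared sampling alone, d0 is
#' infinite (capped at 1e6 for downstream arithmetic) and every moderated
#' variance equals the common value.
#'
#' @param s2 Per-protein residual variances (>= 10 values).
#' @param df Residual degrees of freedom (single value).
#' @param d0Cap Cap applied to an infinite d0 estimate.
#' @return List with \code{d0}, \code{s02}, \code{s2Post} and \code{dfTotal}
#'   (= \code{df + d0}, capped).
#' @export
ebayesModerate <- function(s2, df, d0Cap = 1e6) {
  if (length(s2) < 10)
    stop("need at least 10 proteins for stable hyperparameter estimation")
  assertScalarNumber(df, "df", lower = 1e-12)
  if (all(s2 == 0)) stop("all residual variances are zero")
  s2 <- pmax(s2, 1e-10 * stats::median(s2[s2 > 0]))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  d0Use <- min(d0, d0Cap)
  s2Post <- (d0Use * s02 + df * s2) / (d0Use + df)
  list(d0 = d0, s02 = s02, s2Post = s2Post,
       dfTotal = min(df + d0, d0Cap))
}

#' Moderated t and F tests for the three-group comparison
#'
#' Pairwise moderated t statistics (contrast of group means over its
#' standard error with the moderated variance, referred to a t distribution
#' on \code{df + d0} degrees of freedom) and the moderated overall F on the
#' \code{k - 1} df group effect, two-sided throughout.
#'
#' @param means Proteins x groups matrix of group means.
#' @param n Samples per group (named, matching \code{means} columns).
#' @param s2Post Moderated variances from \code{\link{ebayesModerate}}.
#' @param dfTotal Total degrees of freedom \code{df + d0}.
#' @return List with \code{contrasts} (proteins x pairs of mean
#'   differences), \code{t}, \code{pT} (two-sided), \code{f} and \code{pF}.
#' @export
moderatedTests <- function(means, n, s2Post, dfTotal) {
  k <- ncol(means)
  grps <- colnames(means)
  pairs <- utils::combn(k, 2)
  est <- matrix(NA_real_, nrow(means), ncol(pairs))
  tt <- est
  cn <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i2 <- pairs[2, j]; i1 <- pairs[1, j]
    # positive estimate = higher in the first-named group of "A-vs-B"
    est[, j] <- means[, i2] - means[, i1]
    se <- sqrt(s2Post * (1 / n[[grps[i1]]] + 1 / n[[grps[i2]]]))
    tt[, j] <- est[, j] / se
    cn[j] <- paste0(grps[i2], "-vs-", grps[i1])
  }
  colnames(est) <- colnames(tt) <- cn
  rownames(est) <- rownames(tt) <- rownames(means)
  pT <- 2 * stats::pt(abs(tt), df = dfTotal, lower.tail = FALSE)
  nVec <- as.numeric(n[grps])
  grand <- as.numeric(means %*% nVec) / sum(nVec)
  ssb <- rowSums(sweep((means - grand)^2, 2, nVec, "*"))
  f <- (ssb / (k - 1)) / s2Post
  pF <- stats::pf(f, df1 = k - 1, df2 = dfTotal, lower.tail = FALSE)
  list(contrasts = est, t = tt, pT = pT, f = f, pF = pF)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' \code{q_i = min over j with p_(j) >= p_(i) of m p_(j)/j}, clipped at 1;
#' a thin, input-checked wrapper around \code{stats::p.adjust}.
#'
#' @param p P-values in [0, 1].
#' @return Adjusted p-values, monotone in \code{p} and \code{>= p}.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify the abundance pattern of a protein
#'
#' Maps the three pairwise contrasts (IBS vs HC, UC vs HC, IBS vs UC) and
#' their p-values onto the eight pattern classes used for the protease
#' table: significance at \code{alpha} per contrast combined with the sign
#' of the estimate, checked in the order up-vs-both, up-vs-HC-with-UC-vs-HC,
#' up-vs-HC-only, up-vs-UC-only, then the mirrored down classes, else
#' \code{"other"}.
#'
#' @param ratioIbsHc,pIbsHc log10 ratio and p-value of IBS vs HC.
#' @param ratioUcHc,pUcHc log10 ratio and p-value of UC vs HC.
#' @param ratioIbsUc,pIbsUc log10 ratio and p-value of IBS vs UC.
#' @param alpha Per-contrast significance level (default 0.05).
#' @return Character vector of pattern class labels.
#' @export
classifyPattern <- function(ratioIbsHc, pIbsHc, ratioUcHc, pUcHc,
                            ratioIbsUc, pIbsUc, alpha = 0.05) {
  n <- length(ratioIbsHc)
  stopifnot(length(pIbsHc) == n, length(ratioUcHc) == n, length(pUcHc) == n,
            length(ratioIbsUc) == n, length(pIbsUc) == n)
  upHc <- pIbsHc < alpha & ratioIbsHc > 0
  dnHc <- pIbsHc < alpha & ratioIbsHc < 0
  upUc <- pIbsUc < alpha & ratioIbsUc > 0
  dnUc <- pIbsUc < alpha & ratioIbsUc < 0
  upUcHc <- pUcHc < alpha & ratioUcHc > 0
  out <- rep("other", n)
  out[dnUc & !dnHc & !upHc] <- "down-IBS-vs-UC-only"
  out[dnHc] <- "down-IBS-vs-HC"
  out[dnHc & dnUc] <- "down-IBS-vs-HC-and-UC"
  out[upUc & !upHc & !dnHc] <- "up-IBS-vs-UC-only"
  out[upHc] <- "up-IBS-vs-HC-only"
  out[upHc & upUcHc & !upUc] <- "up-IBS-vs-HC-and-UC-vs-HC"
  out[upHc & upUc] <- "up-IBS-vs-both"
  out
}

#' Moderated differential-abundance analysis
#'
#' The full per-protein workflow: one-way group fit on the glog (log10)
#' scale, empirical-Bayes variance moderation, moderated pairwise t and
#' overall F statistics, BH adjustment of the overall F p-values, and the
#' abundance-pattern classification. Pairwise p-values are reported
#' unadjusted, mirroring the reference protease table; the differential
#' selection (see \code{\link{selectDifferential}}) uses the BH-adjusted
#' overall F.
#'
#' @param x A normalized \linkS4class{ProteomeSet} with the three groups,
#'   or a numeric matrix plus \code{groups}.
#' @param groups Group factor when \code{x} is a matrix.
#' @param alpha Significance level for pattern classification (default 0.05).
#' @param priorDf \code{NULL} to estimate d0 empirically; 0 forces the
#'   classical (unmoderated) statistics.
#' @return A \linkS4class{ModeratedFit}.
#' @examples
#' ps <- simulateProteome(synthProteomeConfig(nProteins = 120,
#'                                            nDifferential = 20, seed = 1))
#' fit <- moderatedDE(vsnNormalize(ps))
#' head(selectDifferential(fit))
#' @export
moderatedDE <- function(x, groups = NULL, alpha = 0.05, priorDf = NULL) {
  fit <- fitGroupModel(x, groups = groups)
  if (is.null(priorDf)) {
    eb <- ebayesModerate(fit$s2, fit$df)
  } else {
    assertScalarNumber(priorDf, "priorDf", lower = 0)
    eb <- if (priorDf == 0) {
      list(d0 = 0, s02 = NA_real_, s2Post = fit$s2, dfTotal = fit$df)
    } else {
      s02 <- ebayesModerate(fit$s2, fit$df)$s02
      list(d0 = priorDf, s02 = s02,
           s2Post = (priorDf * s02 + fit$df * fit$s2) / (priorDf + fit$df),
           dfTotal = fit$df + priorDf)
    }
  }
  mt <- moderatedTests(fit$means, fit$n, eb$s2Post, eb$dfTotal)
  grps <- colnames(fit$means)
  pick <- function(m, a, b) {
    cn <- paste0(a, "-vs-", b)
    if (cn %in% colnames(m)) m[, cn] else -m[, paste0(b, "-vs-", a)]
  }
  pickP <- function(m, a, b) {
    cn <- paste0(a, "-vs-", b)
    if (cn %in% colnames(m)) m[, cn] else m[, paste0(b, "-vs-", a)]
  }
  if (!all(c("HC", "IBS", "UC") %in% grps))
    stop("moderatedDE expects the groups HC, IBS and UC")
  tab <- DataFrame(
    meanHC = fit$means[, "HC"], meanIBS = fit$means[, "IBS"],
    meanUC = fit$means[, "UC"],
    ratioIbsHc = pick(mt$contrasts, "IBS", "HC"),
    pIbsHc = pickP(mt$pT, "IBS", "HC"),
    ratioUcHc = pick(mt$contrasts, "UC", "HC"),
    pUcHc = pickP(mt$pT, "UC", "HC"),
    ratioIbsUc = pick(mt$contrasts, "IBS", "UC"),
    pIbsUc = pickP(mt$pT, "IBS", "UC"),
    fStat = mt$f, pF = mt$pF, padjF = bhAdjust(mt$pF),
    row.names = rownames(fit$means))
  tab$pattern <- classifyPattern(tab$ratioIbsHc, tab$pIbsHc, tab$ratioUcHc,
                                 tab$pUcHc, tab$ratioIbsUc, tab$pIbsUc,
                                 alpha = alpha)
  if (is(x, "ProteomeSet"))
    tab$protease <- isProtease(x)[rownames(tab)]
  new("ModeratedFit", table = tab, priorDf = as.numeric(eb$d0),
      priorVar = as.numeric(if (is.na(eb$s02)) 0 else eb$s02),
      residDf = as.numeric(fit$df), groupSizes = fit$n, alpha = alpha)
}

#' Select differential proteins at a given FDR
#'
#' @param fit A \linkS4class{ModeratedFit} (or its \code{diffTable}).
#' @param alpha FDR threshold on the BH-adjusted overall F p-value.
#' @return Character vector of protein ids with \code{padjF < alpha}.
#' @export
selectDifferential <- function(fit, alpha = 0.05) {
  tab <- if (is(fit, "ModeratedFit")) diffTable(fit) else fit
  rownames(tab)[!is.na(tab$padjF) & tab$padjF < alpha]
}

#' Reference protease contrast table
#'
#' The 17 differentially expressed proteases of the reference biopsy
#' supernatant study, with their printed log10 ratios and pairwise p-values
#' for IBS vs HC, UC vs HC and IBS vs UC, bundled as package data. The two
#' complement C3 entries share one UniProt id and are disambiguated with a
#' \code{.b} suffix.
#'
#' @return \code{data.frame} with columns \code{uniprot}, \code{name},
#'   \code{ratioIbsHc}, \code{pIbsHc}, \code{ratioUcHc}, \code{pUcHc},
#'   \code{ratioIbsUc}, \code{pIbsUc}.
#' @export
referenceProteaseTable <- function() {
  f <- system.file("extdata", "reference_protease_contrasts.tsv",
                   package = "ProteasePanel", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}
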