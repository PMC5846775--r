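#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' ProteomeSet: label-free protein abundances with sample groups
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a raw
#' label-free intensity matrix (assay \code{"intensity"}, proteins in rows,
#' samples in columns), a per-protein protease annotation flag in
#' \code{rowData}, and a per-sample group label (\code{HC}, \code{IBS},
#' \code{UC}) in \code{colData}. After \code{\link{vsnNormalize}} the object
#' additionally carries the assay \code{"glog"} and the fitted calibration
#' parameters in \code{metadata(x)$vsn}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{ProteomeSet}} (constructor),
#'   \code{\link{vsnNormalize}}, \code{\link{simulateProteome}}
#' @name ProteomeSet-class
#' @rdname ProteomeSet-class
#' @exportClass ProteomeSet
setClass("ProteomeSet", contains = "SummarizedExperiment")

setValidity("ProteomeSet", function(object) {
  msg <- character(0)
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  if (!"protease" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'protease' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate protein ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if ("intensity" %in% assayNames(object)) {
    x <- assay(object, "intensity")
    if (any(!is.na(x) & x <= 0))
      msg <- c(msg, "intensities must be positive (or NA for missing)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteomeSet
#'
#' @param intensity Numeric matrix of positive raw intensities, proteins x
#'   samples, with unique row and column names.
#' @param group Character or factor of sample group labels, one per column.
#' @param protease Logical per-protein protease annotation flag.
#' @param metadata Optional list stored in \code{metadata()}.
#' @return A \linkS4class{ProteomeSet}.
#' @examples
#' m <- matrix(rlnorm(40, 10), 10, 4,
#'             dimnames = list(paste0("P", 1:10), paste0("S", 1:4)))
#' ps <- ProteomeSet(m, group = c("HC", "HC", "IBS", "IBS"))
#' @export
ProteomeSet <- function(intensity, group,
                        protease = rep(FALSE, nrow(intensity)),
                        metadata = list()) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("P%04d", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("S%02d", seq_len(ncol(intensity)))
  if (length(group) != ncol(intensity))
    stop("'group' must have one label per sample")
  lev <- intersect(c("HC", "IBS", "UC"), unique(as.character(group)))
  if (length(lev) == 0L) lev <- unique(as.character(group))
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(group = factor(as.character(group), levels = lev),
                        row.names = colnames(intensity)),
    rowData = DataFrame(protease = as.logical(protease),
                        row.names = rownames(intensity)),
    metadata = metadata
  )
  new("ProteomeSet", se)
}

setMethod("show", "ProteomeSet", function(object) {
  cat(sprintf("ProteomeSet: %d proteins x %d samples\n",
              nrow(object), ncol(object)))
  tab <- table(colData(object)$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  proteases flagged: %d\n", sum(rowData(object)$protease)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(metadata(object)$vsn))
    cat(sprintf("  vsn calibration: fitted (%d iterations)\n",
                metadata(object)$vsn$iterations))
  if (!is.null(metadata(object)$groundTruth))
    cat(sprintf("  ground truth: %d planted differential proteins\n",
                length(metadata(object)$groundTruth$differentialIds)))
  invisible(NULL)
})

#' ModeratedFit: per-protein moderated group-model statistics
#'
#' Result container of \code{\link{moderatedDE}}: per-protein group means,
#' pairwise log10-ratio contrasts with moderated-t p-values, the moderated
#' overall F over the group effect with Benjamini-Hochberg adjusted p-values,
#' the abundance-pattern class, and the empirical-Bayes hyperparameters.
#'
#' @slot table A \code{DataFrame}, one row per protein.
#' @slot priorDf Estimated prior degrees of freedom d0.
#' @slot priorVar Estimated prior variance s0^2.
#' @slot residDf Residual degrees of freedom of the per-protein fit.
#' @slot groupSizes Integer samples per group.
#' @slot alpha Significance level used for the pattern classification.
#' @exportClass ModeratedFit
setClass("ModeratedFit",
         slots = c(table = "DataFrame", priorDf = "numeric",
                   priorVar = "numeric", residDf = "numeric",
                   groupSizes = "integer", alpha = "numeric"))

setValidity("ModeratedFit", function(object) {
  msg <- character(0)
  if (length(object@priorDf) != 1L || object@priorDf < 0)
    msg <- c(msg, "priorDf must be a single value >= 0")
  if (length(object@priorVar) != 1L || object@priorVar < 0)
    msg <- c(msg, "priorVar must be a single value >= 0")
  if (length(object@residDf) != 1L || object@residDf <= 0)
    msg <- c(msg, "residDf must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModeratedFit", function(object) {
  tab <- object@table
  cat(sprintf("ModeratedFit: %d proteins, groups n = %s\n",
              nrow(tab), paste(object@groupSizes, collapse = "/")))
  cat(sprintf("  empirical Bayes: d0 = %.4g, s0^2 = %.4g (residual df %g)\n",
              object@priorDf, object@priorVar, object@residDf))
  cat(sprintf("  differential at BH %g%%: %d proteins\n", 100 * object@alpha,
              sum(tab$padjF < object@alpha, na.rm = TRUE)))
  invisible(NULL)
})

#' RocCurve: ROC curve and area under the curve
#'
#' @slot curve \code{data.frame} with columns \code{threshold},
#'   \code{sensitivity}, \code{specificity}, swept over unique scores.
#' @slot auc Trapezoid area under the curve, in [0, 1].
#' @slot classifier Free-text description of the scored classifier.
#' @exportClass RocCurve
setClass("RocCurve",
         slots = c(curve = "data.frame", auc = "numeric",
                   classifier = "character"))

setValidity("RocCurve", function(object) {
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
    return("auc must be a single value in [0, 1]")
  TRUE
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve (%s): AUC = %.4f, %d curve points\n",
              object@classifier, object@auc, nrow(object@curve)))
  invisible(NULL)
})
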