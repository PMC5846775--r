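# Accessor generics and methods. Slot access stays internal to the package.

#' Raw intensity matrix
#' @param x A \linkS4class{ProteomeSet}.
#' @return Numeric matrix, proteins x samples.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "ProteomeSet", function(x) assay(x, "intensity"))

#' Variance-stabilized (glog) values
#'
#' Returns the generalized-log transformed matrix fitted by
#' \code{\link{vsnNormalize}}. With \code{base = 10} the values are rescaled
#' by 1/ln(10) so that, in the high-intensity regime where the glog transform
#' approaches a logarithm, differences read as log10 ratios.
#'
#' @param x A normalized \linkS4class{ProteomeSet}.
#' @param base Logarithm base for rescaling: \code{exp(1)} (natural, the raw
#'   glog scale) or \code{10}.
#' @return Numeric matrix, proteins x samples.
#' @export
setGeneric("glogValues", function(x, base = exp(1)) standardGeneric("glogValues"))

#' @rdname glogValues
#' @export
setMethod("glogValues", "ProteomeSet", function(x, base = exp(1)) {
  if (!"glog" %in% assayNames(x))
    stop("no 'glog' assay: run vsnNormalize() first")
  assay(x, "glog") / log(base)
})

#' Sample group labels
#' @param x A \linkS4class{ProteomeSet}.
#' @return Factor of group labels, one per sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "ProteomeSet", function(x) colData(x)$group)

#' Protease annotation flag
#' @param x A \linkS4class{ProteomeSet}.
#' @return Named logical vector, one per protein.
#' @export
setGeneric("isProtease", function(x) standardGeneric("isProtease"))

#' @rdname isProtease
#' @export
setMethod("isProtease", "ProteomeSet", function(x) {
  structure(rowData(x)$protease, names = rownames(x))
})

#' Planted ground truth of a synthetic data set
#' @param x A \linkS4class{ProteomeSet} from \code{\link{simulateProteome}}.
#' @return A list with elements \code{differentialIds}, \code{shifts},
#'   \code{patterns}, \code{proteaseIds}, or \code{NULL} for real data.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "ProteomeSet", function(x) metadata(x)$groundTruth)

#' Fitted calibration of the variance-stabilizing transform
#' @param x A normalized \linkS4class{ProteomeSet}.
#' @return List with per-sample \code{offset} (a_s), \code{scale} (b_s),
#'   \code{iterations}, \code{converged} and \code{trimmedFraction}.
#' @export
setGeneric("vsnCalibration", function(x) standardGeneric("vsnCalibration"))

#' @rdname vsnCalibration
#' @export
setMethod("vsnCalibration", "ProteomeSet", function(x) metadata(x)$vsn)

#' Per-protein result table of a moderated fit
#' @param x A \linkS4class{ModeratedFit}.
#' @return A \code{DataFrame}, one row per protein.
#' @export
setGeneric("diffTable", function(x) standardGeneric("diffTable"))

#' @rdname diffTable
#' @export
setMethod("diffTable", "ModeratedFit", function(x) x@table)

#' Empirical-Bayes prior degrees of freedom
#' @param x A \linkS4class{ModeratedFit}.
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))

#' @rdname priorDf
#' @export
setMethod("priorDf", "ModeratedFit", function(x) x@priorDf)

#' Empirical-Bayes prior variance
#' @param x A \linkS4class{ModeratedFit}.
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))

#' @rdname priorVar
#' @export
setMethod("priorVar", "ModeratedFit", function(x) x@priorVar)

#' Area under the ROC curve
#' @param x A \linkS4class{RocCurve}.
#' @return The trapezoid AUC as a single number.
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname aucValue
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)

#' ROC curve points
#' @param x A \linkS4class{RocCurve}.
#' @return \code{data.frame} of thresholds, sensitivities and specificities.
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname rocPoints
#' @export
setMethod("rocPoints", "RocCurve", function(x) x@curve)
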