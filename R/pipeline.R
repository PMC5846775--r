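# End-to-end orchestration: synthetic or file input -> normalization ->
# differential abundance -> panel search (-> neurophysiology), with every
# stage output written to disk and content-hashed into a manifest.

#' Pipeline configuration
#'
#' Exactly one proteome input must be given: either a synthetic
#' configuration or a matrix/group file pair. Neurophysiology stages run
#' when a neuro configuration or recording file is supplied.
#'
#' @param synthetic A \code{\link{synthProteomeConfig}}, or \code{NULL}.
#' @param matrixFile,groupFile Proteome TSV input paths, or \code{NULL}.
#' @param neuroSynthetic A \code{\link{synthNeuroConfig}}, or \code{NULL}.
#' @param ganglionFile Ganglion recording CSV path, or \code{NULL}.
#' @param alpha FDR level for the differential selection (default 0.05).
#' @param kMin,kMax Panel size range (default 2-5).
#' @param nRep Split replicates per panel (default 100).
#' @param trainFrac Training fraction (default 2/3).
#' @param classes The two groups compared in the panel search.
#' @param targetR Planted correlation for the synthetic paired-inhibition
#'   stage (only used with \code{neuroSynthetic}).
#' @param seed Master seed; each stage draws a named substream from it.
#' @param outDir Output directory (created if needed).
#' @return Validated list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(synthetic = NULL, matrixFile = NULL,
                           groupFile = NULL, neuroSynthetic = NULL,
                           ganglionFile = NULL, alpha = 0.05,
                           kMin = 2, kMax = 5, nRep = 100,
                           trainFrac = 2 / 3, classes = c("HC", "IBS"),
                           targetR = -0.69, seed = 1, outDir = tempfile("run")) {
  hasSynth <- !is.null(synthetic)
  hasFiles <- !is.null(matrixFile)
  if (hasSynth == hasFiles)
    stop("exactly one of 'synthetic' or 'matrixFile' must be supplied")
  if (hasSynth && !inherits(synthetic, "synthProteomeConfig"))
    stop("'synthetic' must come from synthProteomeConfig()")
  if (hasFiles && is.null(groupFile))
    stop("'groupFile' is required with 'matrixFile'")
  if (!is.null(neuroSynthetic) && !inherits(neuroSynthetic, "synthNeuroConfig"))
    stop("'neuroSynthetic' must come from synthNeuroConfig()")
  assertScalarNumber(alpha, "alpha", lower = 0, upper = 1)
  assertScalarNumber(kMin, "kMin", lower = 1)
  assertScalarNumber(kMax, "kMax", lower = 1)
  if (kMax < kMin) stop("'kMax' must be >= 'kMin'")
  assertScalarNumber(nRep, "nRep", lower = 1)
  assertScalarNumber(trainFrac, "trainFrac", lower = 1e-6, upper = 1)
  if (length(classes) != 2L) stop("'classes' must name two groups")
  assertScalarNumber(seed, "seed")
  structure(list(synthetic = synthetic, matrixFile = matrixFile,
                 groupFile = groupFile, neuroSynthetic = neuroSynthetic,
                 ganglionFile = ganglionFile, alpha = alpha,
                 kMin = as.integer(kMin), kMax = as.integer(kMax),
                 nRep = as.integer(nRep), trainFrac = trainFrac,
                 classes = classes, targetR = targetR,
                 seed = as.integer(seed), outDir = outDir),
            class = "pipelineConfig")
}

.stage <- function(name, outDir, fun) {
  tryCatch(fun(), error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.stageData <- function(config, outDir) {
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- substreamSeed(config$seed, "proteome")
    obj <- simulateProteome(sc)
    writeProteomeTSV(obj, file.path(outDir, "matrix.tsv"),
                     file.path(outDir, "groups.tsv"))
    writeGroundTruthJSON(groundTruth(obj), file.path(outDir, "truth.json"))
    obj
  } else {
    readProteomeTSV(config$matrixFile, config$groupFile)
  }
}

.stageNormalize <- function(ps, outDir) {
  obj <- vsnNormalize(ps)
  cal <- vsnCalibration(obj)
  utils::write.table(
    data.frame(protein = rownames(obj),
               glogValues(obj, base = 10), check.names = FALSE),
    file.path(outDir, "normalized.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(offset = unname(cal$offset),
                            scale = unname(cal$scale),
                            sample = names(cal$offset),
                            iterations = cal$iterations,
                            converged = cal$converged,
                            trimmedFraction = cal$trimmedFraction),
                       file.path(outDir, "vsn.json"),
                       digits = 10, auto_unbox = TRUE)
  obj
}

.stageDiffexpr <- function(ps, config, outDir) {
  fit <- moderatedDE(ps, alpha = config$alpha)
  tab <- as.data.frame(diffTable(fit))
  utils::write.table(cbind(protein = rownames(tab), tab),
                     file.path(outDir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- selectDifferential(fit, config$alpha)
  if (length(sel) >= 2) {
    z <- zscoreByProtein(ps, sel)
    cl <- hierarchicalCluster(z)
    pca <- pcaSamples(z)
    jsonlite::write_json(
      list(rowOrder = rownames(z)[cl$rowOrder],
           colOrder = colnames(z)[cl$colOrder]),
      file.path(outDir, "cluster.json"), digits = 10, auto_unbox = TRUE)
    utils::write.table(
      data.frame(sample = rownames(pca$scores),
                 group = as.character(sampleGroups(ps)),
                 PC1 = pca$scores[, 1],
                 PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else 0,
                 varExplained1 = pca$varExplained[1]),
      file.path(outDir, "pca.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  list(fit = fit, selected = sel)
}

.stagePanel <- function(ps, fit, config, outDir) {
  tab <- diffTable(fit)
  prot <- rownames(tab)[!is.na(tab$protease) & tab$protease]
  up <- prot[tab[prot, "pIbsHc"] < config$alpha &
               tab[prot, "ratioIbsHc"] > 0]
  candidates <- if (length(up) >= config$kMin) up else prot
  out <- list(panelCandidates = candidates)
  if (length(candidates) < max(2L, config$kMin)) return(out)
  lb <- panelSearch(ps, candidates = candidates, kMin = config$kMin,
                    kMax = config$kMax, nRep = config$nRep,
                    trainFrac = config$trainFrac,
                    seed = substreamSeed(config$seed, "panel"),
                    classes = config$classes)
  utils::write.table(lb, file.path(outDir, "leaderboard.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$topPanel <- lb$panel[1]
  out$topMeanAccuracy <- lb$meanAccuracy[1]
  # ROC of the top panel (full-data discriminant score) and its singles
  keep <- sampleGroups(ps) %in% config$classes
  labels <- droplevels(factor(sampleGroups(ps)[keep],
                              levels = config$classes))
  feats <- t(glogValues(ps, base = 10)[, keep, drop = FALSE])
  ids <- strsplit(lb$panel[1], "+", fixed = TRUE)[[1]]
  model <- ldaFit(feats[, ids, drop = FALSE], labels)
  rocs <- list(list(classifier = lb$panel[1],
                    auc = aucValue(rocAuc(
                      panelScore(model, feats[, ids, drop = FALSE]),
                      labels, positive = config$classes[2]))))
  for (id in ids)
    rocs[[length(rocs) + 1L]] <- list(
      classifier = id,
      auc = aucValue(rocAuc(feats[, id], labels,
                            positive = config$classes[2])))
  jsonlite::write_json(rocs, file.path(outDir, "roc.json"),
                       digits = 10, auto_unbox = TRUE)
  out$auc <- rocs
  out
}

.stageNeuro <- function(config, outDir) {
  rec <- if (!is.null(config$neuroSynthetic)) {
    nc <- config$neuroSynthetic
    nc$seed <- substreamSeed(config$seed, "neuro")
    r <- simulateGanglia(nc)
    writeGanglionCSV(r, file.path(outDir, "ganglia.csv"))
    r
  } else {
    readGanglionCSV(config$ganglionFile)
  }
  perPatient <- neuroindexTable(rec, aggregate = "median")
  utils::write.table(perPatient, file.path(outDir, "neuroindex.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gc <- groupCompare(perPatient$neuroindex, perPatient$group)
  tests <- list(kruskalWallis = list(H = gc$statistic, df = gc$df,
                                     p = gc$p.value),
                dunn = gc$dunn)
  out <- list()
  if (!is.null(config$neuroSynthetic)) {
    inh <- simulatePairedInhibition(
      n = unname(config$neuroSynthetic$nPatients[["IBS"]]),
      targetR = config$targetR,
      seed = substreamSeed(config$seed, "inhibition"))
    utils::write.csv(inh, file.path(outDir, "inhibition.csv"),
                     row.names = FALSE)
    pc <- pairedCompare(inh$preIndex, inh$postIndex)
    corr <- abundanceInhibitionCorrelation(inh$abundance,
                                           inh$percentDecrease)
    tests$pairedWilcoxon <- list(V = pc$statistic, p = pc$p.value, n = pc$n)
    tests$abundanceInhibition <- corr
    out$inhibitionCorrelation <- corr$r
  }
  jsonlite::write_json(tests, file.path(outDir, "tests.json"),
                       digits = 10, auto_unbox = TRUE)
  out$neuroindexByGroup <- lapply(
    split(perPatient$neuroindex, perPatient$group), stats::median)
  out
}

#' Run the full analysis pipeline
#'
#' Executes data generation (or ingestion), variance-stabilizing
#' normalization, moderated differential abundance with clustering / PCA
#' coordinates, the exhaustive panel search with ROC summaries, and - when
#' configured - the neurophysiology statistics. All outputs are plain-text
#' files under \code{outDir}; the returned manifest lists each file with
#' its MD5 content hash, so identical configurations and seeds yield
#' identical manifests. A stage failure aborts the run with the stage name
#' and leaves a \code{FAILED} marker next to the partial outputs.
#'
#' Panel candidates are the protease-flagged proteins significantly more
#' abundant in the second vs the first compared class (unadjusted pairwise
#' p below \code{alpha}); when fewer than \code{kMin} such proteins exist,
#' all protease-flagged proteins are used.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return The manifest (list with \code{files}, \code{summary},
#'   \code{seed}), also written to \code{manifest.json}; invisibly.
#' @examples
#' cfg <- pipelineConfig(
#'   synthetic = synthProteomeConfig(nProteins = 150, nDifferential = 20,
#'                                   nProteases = 8),
#'   nRep = 10, seed = 7, outDir = tempfile())
#' manifest <- runPipeline(cfg)
#' manifest$summary$nDifferential
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig"))
    stop("'config' must come from pipelineConfig()")
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "FAILED"))
  summary <- list()

  ps <- .stage("data", outDir, function() .stageData(config, outDir))
  summary$nProteins <- nrow(ps)
  summary$nSamples <- ncol(ps)

  ps <- .stage("normalize", outDir, function() .stageNormalize(ps, outDir))

  de <- .stage("diffexpr", outDir,
               function() .stageDiffexpr(ps, config, outDir))
  summary$nDifferential <- length(de$selected)
  summary$priorDf <- priorDf(de$fit)
  summary$priorVar <- priorVar(de$fit)

  pan <- .stage("panel", outDir,
                function() .stagePanel(ps, de$fit, config, outDir))
  summary <- c(summary, pan)

  if (!is.null(config$neuroSynthetic) || !is.null(config$ganglionFile)) {
    neu <- .stage("neuro", outDir, function() .stageNeuro(config, outDir))
    summary <- c(summary, neu)
  }

  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  hashes <- tools::md5sum(file.path(outDir, files))
  names(hashes) <- files
  manifest <- list(files = as.list(hashes), summary = summary,
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = 10, auto_unbox = TRUE)
  invisible(manifest)
}

#' Render a human-readable run report
#'
#' Formats the manifest of a pipeline run as markdown, with one section
#' per completed stage; sections whose outputs are absent are omitted, and
#' no value is altered from the stage outputs. Regeneration from the same
#' manifest is byte-identical.
#'
#' @param manifest Manifest list from \code{\link{runPipeline}}, or the
#'   path of a \code{manifest.json}.
#' @param file Optional output path; when \code{NULL} the text is returned.
#' @return Character vector of report lines, invisibly when written.
#' @export
renderReport <- function(manifest, file = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  s <- manifest$summary
  fmt <- function(x, d = 4) formatC(as.numeric(x), digits = d, format = "g")
  lines <- c("# Pipeline run report", "",
             sprintf("Seed: %d", as.integer(manifest$seed)), "")
  if (!is.null(s$nProteins))
    lines <- c(lines, "## Proteome", "",
               sprintf("- %d proteins x %d samples", s$nProteins, s$nSamples))
  if (!is.null(s$nDifferential))
    lines <- c(lines,
               sprintf("- differential proteins (BH-adjusted F): %d",
                       s$nDifferential),
               sprintf("- empirical-Bayes prior: d0 = %s, s0^2 = %s",
                       fmt(s$priorDf), fmt(s$priorVar)), "")
  if (!is.null(s$topPanel)) {
    lines <- c(lines, "## Panel search", "",
               sprintf("- top panel: %s (mean accuracy %s)",
                       s$topPanel, fmt(s$topMeanAccuracy)))
    if (!is.null(s$auc)) {
      aucDf <- if (is.data.frame(s$auc)) s$auc else
        do.call(rbind, lapply(s$auc, as.data.frame))
      lines <- c(lines, "- AUC:",
                 sprintf("    - %s: %s", aucDf$classifier, fmt(aucDf$auc)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(s$neuroindexByGroup)) {
    ni <- s$neuroindexByGroup
    lines <- c(lines, "## Neurophysiology", "",
               sprintf("- median patient neuroindex: %s",
                       paste(sprintf("%s = %s", names(ni),
                                     vapply(ni, fmt, character(1))),
                             collapse = ", ")))
    if (!is.null(s$inhibitionCorrelation))
      lines <- c(lines,
                 sprintf("- abundance vs inhibition Pearson r: %s",
                         fmt(s$inhibitionCorrelation)))
    lines <- c(lines, "")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
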