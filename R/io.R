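# Plain-text readers and writers: TSV intensity matrix with a two-column
# sample->group map, CSV ganglion recordings, JSON ground truth.

#' Write a proteome matrix as TSV
#'
#' The matrix file has one row per protein with \code{protein} and
#' \code{protease} columns followed by one intensity column per sample; the
#' group map file has columns \code{sample} and \code{group}.
#'
#' @param x A \linkS4class{ProteomeSet}.
#' @param file Path of the matrix TSV.
#' @param groupFile Path of the sample-to-group map TSV.
#' @return Invisibly, the matrix file path.
#' @export
writeProteomeTSV <- function(x, file, groupFile) {
  stopifnot(is(x, "ProteomeSet"))
  m <- intensities(x)
  df <- data.frame(protein = rownames(m),
                   protease = isProtease(x),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(m),
                                group = as.character(sampleGroups(x))),
                     groupFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a proteome matrix from TSV
#'
#' Counterpart of \code{\link{writeProteomeTSV}}; also accepts any matrix
#' TSV whose first column holds protein ids, with an optional
#' \code{protease} flag column.
#'
#' @param file Matrix TSV path.
#' @param groupFile Sample-to-group map TSV path.
#' @return A \linkS4class{ProteomeSet}.
#' @export
readProteomeTSV <- function(file, groupFile) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  idCol <- colnames(df)[1]
  protease <- if ("protease" %in% colnames(df))
    as.logical(df$protease) else rep(FALSE, nrow(df))
  sampleCols <- setdiff(colnames(df), c(idCol, "protease"))
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(m) <- df[[idCol]]
  gm <- utils::read.delim(groupFile, stringsAsFactors = FALSE)
  if (!all(colnames(m) %in% gm$sample))
    stop("group map does not cover all samples")
  ProteomeSet(m, group = gm$group[match(colnames(m), gm$sample)],
              protease = protease)
}

#' Write / read ganglion recording tables
#'
#' One row per ganglion; per-responder magnitudes are a semicolon-joined
#' list in a single CSV column.
#'
#' @param recordings \code{data.frame} as from \code{\link{simulateGanglia}}.
#' @param file CSV path.
#' @return \code{writeGanglionCSV} invisibly returns the path;
#'   \code{readGanglionCSV} returns the \code{data.frame}.
#' @export
writeGanglionCSV <- function(recordings, file) {
  utils::write.csv(recordings, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @rdname writeGanglionCSV
#' @export
readGanglionCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(magnitudes = "character"))
  need <- c("patient", "group", "neuronsTotal", "responders", "magnitudes")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("ganglion CSV lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read planted ground truth as JSON
#'
#' @param truth Ground-truth list from \code{\link{groundTruth}}.
#' @param file JSON path.
#' @return \code{writeGroundTruthJSON} invisibly returns the path;
#'   \code{readGroundTruthJSON} the reconstructed list.
#' @export
writeGroundTruthJSON <- function(truth, file) {
  out <- truth
  if (!is.null(out$shifts))
    out$shifts <- list(ids = rownames(truth$shifts),
                       groups = colnames(truth$shifts),
                       values = unname(as.data.frame(truth$shifts)))
  jsonlite::write_json(out, file, digits = 10, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeGroundTruthJSON
#' @export
readGroundTruthJSON <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(raw$shifts)) {
    m <- as.matrix(as.data.frame(raw$shifts$values))
    dimnames(m) <- list(raw$shifts$ids, raw$shifts$groups)
    raw$shifts <- m
  }
  raw
}
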