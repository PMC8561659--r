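#' @include AllClasses.R feature-table.R distances.R
NULL

#' Read/write cytometry event tables
#'
#' CSV with header FL1_A,FL1_H,FL1_W,FL4_A,FSC_A,BSC_A (extra columns such
#' as a ground-truth population label pass through).
#'
#' @param path file path.
#' @param sampleId identifier for the read table (default: file name).
#' @return a \linkS4class{CytometryEventTable}.
#' @export
readEventTable <- function(path, sampleId = NULL) {
  ev <- utils::read.csv(path, check.names = FALSE)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  new("CytometryEventTable", events = ev, sampleId = sampleId)
}

#' @rdname readEventTable
#' @param x a \linkS4class{CytometryEventTable}.
#' @export
writeEventTable <- function(x, path) {
  utils::write.csv(x@events, path, row.names = FALSE)
  invisible(path)
}

#' Read/write feature tables as TSV
#'
#' Taxa-by-samples TSV with a leading "#OTU ID" column and a trailing
#' taxonomy column of semicolon-delimited ranks.
#'
#' @param path file path.
#' @return a \linkS4class{FeatureTable}.
#' @export
readFeatureTableTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "")
  idCol <- colnames(df)[1]
  taxCol <- "taxonomy"
  samples <- setdiff(colnames(df), c(idCol, taxCol))
  m <- as.matrix(df[, samples, drop = FALSE])
  rownames(m) <- df[[idCol]]
  featureTable(m, taxonomy = setNames(
    if (taxCol %in% colnames(df)) df[[taxCol]] else NULL, df[[idCol]]))
}

#' @rdname readFeatureTableTSV
#' @param x a \linkS4class{FeatureTable}.
#' @export
writeFeatureTableTSV <- function(x, path) {
  df <- data.frame(`#OTU ID` = rownames(x), counts(x),
                   taxonomy = unname(taxonomy(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM-format (JSON) feature table
#'
#' Thin adapter over the biomformat package for BIOM 1.0 JSON tables.
#'
#' @param path file path to a BIOM JSON file.
#' @return a \linkS4class{FeatureTable}.
#' @export
readBiomTable <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  rd <- biomformat::observation_metadata(b)
  tax <- if (!is.null(rd)) {
    apply(as.data.frame(rd), 1, paste, collapse = "; ")
  } else NULL
  featureTable(m, taxonomy = tax)
}

#' Read/write sample metadata TSV
#'
#' Columns: sample_id, participant, timepoint, treatment, processing,
#' volume_ml, minutes, after_meal.
#'
#' @param path file path.
#' @return data.frame indexed by sample_id.
#' @export
readMetadataTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' @rdname readMetadataTSV
#' @param metadata data.frame with a sample_id column.
#' @export
writeMetadataTSV <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a labelled square distance matrix TSV
#'
#' @param path file path.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
readDistanceMatrixTSV <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  distanceMatrix(as.matrix(df))
}

#' @rdname readDistanceMatrixTSV
#' @param dm a \linkS4class{DistanceMatrix}.
#' @export
writeDistanceMatrixTSV <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), as.matrix(dm@.Data),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
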