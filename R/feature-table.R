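#' @include AllClasses.R utils.R
NULL

#' Construct a feature table
#'
#' @param counts taxa x samples matrix of non-negative integer counts with
#'   row (taxon) and column (sample) names.
#' @param taxonomy character vector of semicolon-delimited rank strings, one
#'   per taxon (named or in row order); missing entries become "Unassigned".
#' @param sampleData optional data.frame of per-sample metadata, rows
#'   matching the sample names.
#' @return a \linkS4class{FeatureTable}.
#' @export
featureTable <- function(counts, taxonomy = NULL, sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("taxon%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  if (is.null(taxonomy)) taxonomy <- rep("Unassigned", nrow(counts))
  if (!is.null(names(taxonomy))) taxonomy <- taxonomy[rownames(counts)]
  taxonomy[is.na(taxonomy) | taxonomy == ""] <- "Unassigned"
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    S4Vectors::DataFrame(sampleData[colnames(counts), , drop = FALSE],
                         row.names = colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy = unname(taxonomy),
                                   row.names = rownames(counts)),
    colData = cd)
  new("FeatureTable", se)
}

sampleDepths <- function(x) colSums(counts(x))

#' Drop shallow samples
#'
#' Removes samples whose total read count is below \code{minReads}
#' (inclusive boundary: a sample at exactly \code{minReads} is retained) and
#' reports the removed ids.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param minReads minimum retained depth.
#' @return the filtered table.
#' @export
filterMinDepth <- function(x, minReads = 1000) {
  keep <- sampleDepths(x) >= minReads
  if (!any(keep)) stop("all samples fall below the depth threshold")
  if (any(!keep))
    msg("dropping ", sum(!keep), " sample(s) below ", minReads, " reads: ",
        paste(colnames(x)[!keep], collapse = ", "))
  x[, keep]
}

#' Drop taxa by taxonomy pattern
#'
#' Removes taxa whose taxonomy string contains any of the patterns
#' (case-insensitive substring match); by default chloroplast and
#' mitochondrial sequences, which in host-associated 16S data derive from
#' food and host organelles rather than bacteria.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param patterns character substrings.
#' @return the filtered table.
#' @export
filterTaxonomy <- function(x, patterns = c("chloroplast", "mitochondria")) {
  tax <- taxonomy(x)
  drop <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, tax, ignore.case = TRUE, fixed = FALSE)))
  x[!drop, ]
}

#' Chloroplast contamination summary
#'
#' Prevalence (fraction of samples with at least one chloroplast read) and
#' mean relative abundance among positive samples, stratified by the
#' after-meal flag and processing arm.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param metadata data.frame with \code{sample_id}, \code{after_meal} and
#'   \code{processing}; defaults to the table's column data.
#' @return data.frame with one row per stratum.
#' @export
chloroplastSummary <- function(x, metadata = NULL) {
  if (is.null(metadata))
    metadata <- as.data.frame(SummarizedExperiment::colData(x))
  if (!all(c("after_meal", "processing") %in% colnames(metadata)))
    stop("metadata must provide after_meal and processing")
  chl <- grepl("chloroplast", taxonomy(x), ignore.case = TRUE)
  chlReads <- colSums(counts(x)[chl, , drop = FALSE])
  relAb <- ifelse(sampleDepths(x) > 0, chlReads / sampleDepths(x), 0)
  meta <- metadata[colnames(x), ]
  strata <- split(seq_len(ncol(x)),
                  list(after_meal = meta$after_meal,
                       processing = meta$processing), drop = TRUE)
  out <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    posIdx <- idx[chlReads[idx] > 0]
    data.frame(stratum = s,
               after_meal = meta$after_meal[idx[1]],
               processing = meta$processing[idx[1]],
               n_samples = length(idx),
               prevalence = length(posIdx) / length(idx),
               mean_rel_abundance_positives =
                 if (length(posIdx)) mean(relAb[posIdx]) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__")

rankLabel <- function(taxStrings, rank) {
  prefix <- RANK_PREFIXES[[rank]]
  parts <- strsplit(taxStrings, ";\\s*")
  vapply(parts, function(pp) {
    hit <- grep(paste0("^", prefix), pp, value = TRUE)
    lab <- if (length(hit)) sub(paste0("^", prefix), "", hit[1]) else ""
    if (!nzchar(lab)) "Unassigned" else lab
  }, character(1))
}

#' Collapse counts to a taxonomic rank
#'
#' Sums counts over taxa sharing the label at the requested rank; taxa
#' unassigned at that rank pool into "Unassigned".  Per-sample totals are
#' conserved exactly and collapsing twice at the same rank is the identity.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @return a collapsed \linkS4class{FeatureTable} whose row names are the
#'   rank labels.
#' @export
collapseRank <- function(x, rank = "genus") {
  rank <- match.arg(rank, names(RANK_PREFIXES))
  labs <- rankLabel(taxonomy(x), rank)
  m <- rowsum(counts(x), labs)
  storage.mode(m) <- "integer"
  prefix <- RANK_PREFIXES[[rank]]
  featureTable(m, taxonomy = setNames(paste0(prefix, rownames(m)),
                                      rownames(m)),
               sampleData = as.data.frame(SummarizedExperiment::colData(x)))
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample's reads to exactly \code{depth} without
#' replacement; samples already at \code{depth} are returned unchanged and
#' samples below it are dropped with a message.  Deterministic for a given
#' seed.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param depth target reads per sample.
#' @param seed RNG seed.
#' @return the rarefied table.
#' @export
rarefyTable <- function(x, depth, seed = 1L) {
  if (depth < 1) stop("rarefaction depth must be >= 1")
  depths <- sampleDepths(x)
  keep <- depths >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  if (any(!keep))
    msg("dropping ", sum(!keep), " sample(s) below rarefaction depth ",
        depth, ": ", paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep]
  m <- counts(x)
  withSeed(seed, {
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) == depth) next
      reads <- rep.int(seq_len(nrow(m)), m[, j])
      picked <- sample(reads, depth, replace = FALSE)
      m[, j] <- tabulate(picked, nbins = nrow(m))
    }
  })
  storage.mode(m) <- "integer"
  featureTable(m, taxonomy = taxonomy(x),
               sampleData = as.data.frame(SummarizedExperiment::colData(x)))
}

#' Absolute per-taxon abundances from relative composition and live load
#'
#' Joins the two measurement arms of the workflow: scales each sample's
#' relative abundances by its measured live cell count, giving cells per
#' taxon; per-sample totals equal the supplied loads.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param liveCells named numeric vector of live cell counts, names matching
#'   sample names.
#' @return numeric matrix (taxa x samples) of cell counts.
#' @export
absoluteAbundance <- function(x, liveCells) {
  if (is.null(names(liveCells))) {
    stopifnot(length(liveCells) == ncol(x))
    names(liveCells) <- colnames(x)
  }
  m <- counts(x)
  depths <- colSums(m)
  rel <- sweep(m, 2, pmax(depths, 1), "/")
  sweep(rel, 2, liveCells[colnames(x)], "*")
}
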