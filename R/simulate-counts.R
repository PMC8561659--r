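#' @include AllClasses.R utils.R simulate-cohort.R
NULL

#' Simulate a 16S read count vector for one sample
#'
#' Multinomial draw of \code{depth} reads.  PMA-treated samples draw from the
#' record's live composition; raw samples draw from the live/relic mixture
#' weighted by the true pool sizes (the relic pool is the participant
#' composition tilted toward the dead-associated taxon).  Post-meal raw
#' samples are chloroplast-contaminated with high probability; PMA treatment
#' reduces chloroplast prevalence to a quarter of the raw rate because most
#' chloroplast DNA is extracellular or from non-intact chloroplasts.
#'
#' @param cohort a \linkS4class{SalivaCohort}.
#' @param recordId truth record id (participant_timepoint).
#' @param depth number of reads (> 0).
#' @param processing "raw" or "pma".
#' @param afterMeal logical; defaults to the record's metadata flag.
#' @param chloroplastRelAbundance target chloroplast relative abundance in a
#'   contaminated sample (default from the cohort config).
#' @param prevalenceAfterMealRaw probability that a raw post-meal sample is
#'   contaminated (default 0.8; the PMA rate is this divided by 4, and
#'   background rates off-meal are 0.16 and 0.04).
#' @return named integer vector of counts over the cohort taxa.
#' @export
simulateCounts <- function(cohort, recordId, depth,
                           processing = c("raw", "pma"), afterMeal = NULL,
                           chloroplastRelAbundance = NULL,
                           prevalenceAfterMealRaw = 0.8) {
  processing <- match.arg(processing)
  if (depth <= 0) stop("sequencing depth must be positive")
  truth <- cohort@truth[recordId, ]
  if (is.null(afterMeal)) afterMeal <- truth$after_meal
  if (is.null(chloroplastRelAbundance))
    chloroplastRelAbundance <- cohort@config@chloroplastRelAbundance
  live <- cohort@liveComposition[recordId, ]
  relic <- cohort@relicComposition[recordId, ]
  if (processing == "pma") {
    p <- live
  } else {
    wLive <- truth$true_live_cells / truth$true_total_cells
    p <- wLive * live + (1 - wLive) * relic
  }
  pContam <- if (processing == "raw") {
    if (afterMeal) prevalenceAfterMealRaw else 0.16
  } else {
    if (afterMeal) prevalenceAfterMealRaw / 4 else 0.04
  }
  chAbund <- if (afterMeal) chloroplastRelAbundance
             else chloroplastRelAbundance / 15   # trace background off-meal
  if (runif(1) < pContam) {
    p[CHLOROPLAST_TAXON] <- chAbund / (1 - chAbund) * sum(p)
    p <- renorm(p)
  }
  cts <- as.integer(rmultinom(1, depth, p))
  setNames(cts, names(p))
}

#' Simulate the cohort feature table
#'
#' One multinomial count vector per metadata sample (raw and PMA-treated for
#' every participant x timepoint), assembled into a
#' \linkS4class{FeatureTable} with the cohort taxonomy and metadata.
#'
#' @param cohort a \linkS4class{SalivaCohort}.
#' @param depth reads per sample; a single value or one per metadata row.
#' @param seed seed for the counts substream (default derived from the
#'   cohort seed).
#' @return a \linkS4class{FeatureTable}.
#' @export
simulateFeatureTable <- function(cohort, depth = 10000L, seed = NULL) {
  meta <- cohort@metadata
  depth <- rep_len(depth, nrow(meta))
  if (is.null(seed)) seed <- substreamSeed(cohort@config@seed, "counts")
  m <- withSeed(seed, {
    vapply(seq_len(nrow(meta)), function(i) {
      simulateCounts(cohort, meta$record_id[i], depth[i],
                     processing = meta$processing[i],
                     afterMeal = meta$after_meal[i])
    }, integer(length(cohort@taxonomy)))
  })
  colnames(m) <- meta$sample_id
  rownames(m) <- names(cohort@taxonomy)
  featureTable(m, taxonomy = cohort@taxonomy, sampleData = meta)
}

#' Simulate a qPCR quantification cycle value
#'
#' \eqn{Cq = intercept + slope \cdot log10(copies) + N(0, noiseSd)}.
#'
#' @param copies template copy number (> 0).
#' @param slope Cq per log10 copies (about -3.32 at 100\% efficiency).
#' @param intercept Cq at one copy.
#' @param noiseSd Gaussian Cq noise SD (0 for a noise-free readout).
#' @return numeric Cq value(s).
#' @export
simulateQpcr <- function(copies, slope = -3.3219, intercept = 38,
                         noiseSd = 0.2) {
  if (any(copies <= 0)) stop("copy number must be positive")
  intercept + slope * log10(copies) + rnorm(length(copies), 0, noiseSd)
}

#' Ten-fold qPCR standard ladder
#'
#' Serial ten-fold dilution levels for a standard curve, by default 1.3 to
#' 1.3e7 copies (8 levels).
#'
#' @param lowest lowest copy number (default 1.3).
#' @param nLevels number of ten-fold levels (default 8).
#' @return numeric vector of copy numbers.
#' @export
qpcrLadder <- function(lowest = 1.3, nLevels = 8L) {
  lowest * 10^(seq_len(nLevels) - 1)
}
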