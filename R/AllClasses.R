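#' @import methods
NULL

CYTO_CHANNELS <- c("FL1_A", "FL1_H", "FL1_W", "FL4_A", "FSC_A", "BSC_A")

#' Cytometry event table
#'
#' Per-event fluorescence and scatter intensities for one acquired sample,
#' including any spiked counting-bead events.  Channels follow the SYBR-green
#' bacterial counting convention: FL1 (525 nm, DNA stain) area/height/width,
#' FL4 (bead fluorophore) area, and forward/back scatter area.
#'
#' @slot events data.frame with numeric columns FL1_A, FL1_H, FL1_W, FL4_A,
#'   FSC_A, BSC_A (arbitrary units, finite, non-negative).  Synthetic tables
#'   carry an additional \code{population} label column with ground truth.
#' @slot sampleId length-one character identifier.
#' @export
setClass("CytometryEventTable",
  representation(events = "data.frame", sampleId = "character"))

setValidity("CytometryEventTable", function(object) {
  ev <- object@events
  if (nrow(ev) < 1L) return("event table must contain at least one event")
  miss <- setdiff(CYTO_CHANNELS, colnames(ev))
  if (length(miss)) return(paste("missing channels:", paste(miss, collapse = ", ")))
  for (ch in CYTO_CHANNELS) {
    v <- ev[[ch]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      return(paste0("channel ", ch, " must be finite and non-negative"))
  }
  if (length(object@sampleId) != 1L) return("sampleId must be length one")
  TRUE
})

#' Gating configuration
#'
#' Rectangular thresholds for the three-stage bacterial gate: a DNA-positive
#' FL1 threshold, a bead FL4 threshold, a relative band around the median
#' FL1 pulse height/width (or height/area) ratio for singlet selection, and
#' scatter ceilings that remove large (human-cell) events.  Instrument gains
#' differ between machines, so all thresholds are user-supplied.
#'
#' @slot fl1Min minimum FL1_A for a DNA-positive event.
#' @slot fl4BeadMin minimum FL4_A (among DNA-positive events) to call a bead.
#' @slot doubletBand relative half-width in (0,1) around the median singlet
#'   ratio; events outside are excluded as doublets/aggregates.
#' @slot fscMax,bscMax inclusive scatter ceilings for the bacterial gate.
#' @slot doubletDenominator "width" (FL1_H/FL1_W) or "area" (FL1_H/FL1_A).
#' @export
setClass("GatingConfig",
  representation(fl1Min = "numeric", fl4BeadMin = "numeric",
                 doubletBand = "numeric", fscMax = "numeric",
                 bscMax = "numeric", doubletDenominator = "character"))

setValidity("GatingConfig", function(object) {
  if (object@fl1Min < 0 || object@fl4BeadMin < 0) return("thresholds must be >= 0")
  if (object@fscMax < 0 || object@bscMax < 0) return("scatter ceilings must be >= 0")
  if (object@doubletBand <= 0 || object@doubletBand >= 1)
    return("doubletBand must lie in (0, 1)")
  if (!object@doubletDenominator %in% c("width", "area"))
    return("doubletDenominator must be 'width' or 'area'")
  TRUE
})

#' Gated event counts
#'
#' Partition of one event table by the composed gate: bacterial singlets
#' (\code{nCells}), counting beads, excluded doublets, excluded large events,
#' and sub-threshold events.  The five counts always sum to the event total.
#'
#' @export
setClass("GatedCounts",
  representation(nCells = "integer", nBeads = "integer",
                 nDoubletsExcluded = "integer", nLargeExcluded = "integer",
                 nSubthreshold = "integer", nTotal = "integer"))

setValidity("GatedCounts", function(object) {
  cts <- c(object@nCells, object@nBeads, object@nDoubletsExcluded,
           object@nLargeExcluded, object@nSubthreshold)
  if (any(cts < 0L)) return("counts must be non-negative")
  if (sum(cts) != object@nTotal)
    return("gate counts must partition the event total exactly")
  TRUE
})

#' Absolute quantification result
#'
#' Bead-calibrated concentration for one sample: cells per microlitre in the
#' measured tube and cells per millilitre of neat saliva after dilution
#' correction.
#'
#' @export
setClass("QuantResult",
  representation(cellsPerUlMeasured = "numeric", cellsPerMlSaliva = "numeric",
                 dilutionFactor = "numeric", beadsAdded = "numeric",
                 sampleVolumeUl = "numeric"))

setValidity("QuantResult", function(object) {
  if (object@cellsPerUlMeasured < 0 || object@cellsPerMlSaliva < 0)
    return("concentrations must be >= 0")
  if (object@dilutionFactor < 1) return("dilutionFactor must be >= 1")
  TRUE
})

#' qPCR standard curve
#'
#' Least-squares line of Cq on log10(copies) fitted to a serial-dilution
#' ladder, with amplification efficiency derived from the slope as
#' \eqn{(10^{-1/slope} - 1) \times 100}.
#'
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", efficiency = "numeric"))

#' Synthetic cohort configuration
#'
#' Study-design parameters for the synthetic saliva cohort generator: the
#' daily-dynamics design (participants sampled repeatedly through one day,
#' waking sample carrying the daily maximum live load, tooth-brushing
#' removal) or the acute-perturbation design (baseline / 15 min / 2 h around
#' a mouthwash, water or soda treatment).
#'
#' @slot nParticipants number of participants.
#' @slot timepoints ordered character labels of collection times.
#' @slot design "daily_dynamics" or "acute_perturbation".
#' @slot treatmentAssignments named character vector participant -> treatment
#'   in {water, antiseptic, alcohol_free, soda, none}.
#' @slot baselineLoadLog10Mean,baselineLoadLog10Sd log10 live cells per 5-min
#'   collection across participants.
#' @slot withinDayLoadLog10Sd random-walk step SD of log10 live load between
#'   consecutive timepoints.
#' @slot liveFractionBaseline baseline live/total fraction in (0,1].
#' @slot relicEnrichedTaxon taxon id up-weighted in the relic (dead) pool.
#' @slot relicLogFold log-fold tilt of the relic pool toward that taxon.
#' @slot nTaxa,nDominantGenera taxon richness and number of dominant genera.
#' @slot brushRemovalFactor multiplicative removal applied to both pools by
#'   tooth-brushing (daily design, second timepoint).
#' @slot killFactorAlcoholFree,killFactorAntiseptic survival fractions applied
#'   to the live pool by the two mouthwashes (killed cells move to the relic
#'   pool; totals are conserved).
#' @slot betweenParticipantCompSd,withinDayCompSd log-normal SDs of the
#'   between-participant and within-day composition perturbations.
#' @slot chloroplastRelAbundance target chloroplast relative abundance in
#'   contaminated raw post-meal samples.
#' @slot afterMealTimepoints indices of timepoints collected after eating.
#' @slot seed master seed; all stages derive named substreams from it.
#' @export
setClass("CohortConfig",
  representation(nParticipants = "integer", timepoints = "character",
                 design = "character", treatmentAssignments = "character",
                 baselineLoadLog10Mean = "numeric",
                 baselineLoadLog10Sd = "numeric",
                 withinDayLoadLog10Sd = "numeric",
                 liveFractionBaseline = "numeric",
                 relicEnrichedTaxon = "character", relicLogFold = "numeric",
                 nTaxa = "integer", nDominantGenera = "integer",
                 brushRemovalFactor = "numeric",
                 killFactorAlcoholFree = "numeric",
                 killFactorAntiseptic = "numeric",
                 betweenParticipantCompSd = "numeric",
                 withinDayCompSd = "numeric",
                 chloroplastRelAbundance = "numeric",
                 afterMealTimepoints = "integer",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  if (object@nParticipants < 1L) return("nParticipants must be >= 1")
  if (length(object@timepoints) < 1L) return("at least one timepoint required")
  if (anyDuplicated(object@timepoints)) return("timepoints must be unique")
  if (!object@design %in% c("daily_dynamics", "acute_perturbation"))
    return("design must be daily_dynamics or acute_perturbation")
  bad <- setdiff(unique(object@treatmentAssignments),
                 c("water", "antiseptic", "alcohol_free", "soda", "none"))
  if (length(bad))
    return(paste("unknown treatment label(s):", paste(bad, collapse = ", ")))
  if (object@liveFractionBaseline <= 0 || object@liveFractionBaseline > 1)
    return("liveFractionBaseline must lie in (0, 1]")
  sds <- c(object@baselineLoadLog10Sd, object@withinDayLoadLog10Sd,
           object@betweenParticipantCompSd, object@withinDayCompSd)
  if (any(sds < 0)) return("all SDs must be >= 0")
  if (object@brushRemovalFactor <= 0 || object@brushRemovalFactor > 1)
    return("brushRemovalFactor must lie in (0, 1]")
  if (object@killFactorAlcoholFree <= 0 || object@killFactorAlcoholFree > 1 ||
      object@killFactorAntiseptic <= 0 || object@killFactorAntiseptic > 1)
    return("kill factors must lie in (0, 1]")
  TRUE
})

#' Synthetic cohort with ground truth
#'
#' Output of \code{\link{simulateCohort}}: per-sample metadata (one raw and
#' one PMA-treated record per participant x timepoint), the latent truth table
#' (live/total cells, volumes, flow rates), per-record live and relic
#' composition matrices, the taxonomy, and a random rooted phylogeny over the
#' simulated taxa.
#'
#' @slot config the generating \linkS4class{CohortConfig}.
#' @slot metadata data.frame: sample_id, participant, timepoint, treatment,
#'   processing, volume_ml, minutes, after_meal.
#' @slot truth data.frame keyed by participant x timepoint with true_live_cells,
#'   true_total_cells, saliva_volume_ml, flow_rate_ml_per_min.
#' @slot liveComposition,relicComposition records x taxa probability matrices
#'   (rows sum to 1), rownames matching truth record ids.
#' @slot taxonomy named character vector of semicolon-delimited rank strings.
#' @slot tree rooted \code{phylo} whose tips are the taxon ids.
#' @export
setClass("SalivaCohort",
  representation(config = "CohortConfig", metadata = "data.frame",
                 truth = "data.frame", liveComposition = "matrix",
                 relicComposition = "matrix", taxonomy = "character",
                 tree = "ANY"))

setValidity("SalivaCohort", function(object) {
  tr <- object@truth
  if (any(tr$true_live_cells < 0) ||
      any(tr$true_live_cells > tr$true_total_cells + 1e-6))
    return("0 <= true_live_cells <= true_total_cells violated")
  for (nm in c("liveComposition", "relicComposition")) {
    m <- slot(object, nm)
    if (nrow(m) != nrow(tr)) return(paste(nm, "must have one row per record"))
    if (any(abs(rowSums(m) - 1) > 1e-9))
      return(paste(nm, "rows must sum to 1 within 1e-9"))
  }
  rate <- tr$saliva_volume_ml / tr$collection_minutes
  if (any(abs(rate - tr$flow_rate_ml_per_min) > 1e-9))
    return("flow_rate must equal volume / collection minutes")
  TRUE
})

#' Viability record
#'
#' Live/dead decomposition of one paired raw/PMA quantification: live = PMA
#' count, total = raw count, dead = max(total - live, 0), percent live capped
#' at 100 (measurement noise can push the PMA count above the raw count).
#'
#' @export
setClass("ViabilityRecord",
  representation(liveCells = "numeric", totalCells = "numeric",
                 deadCells = "numeric", percentLive = "numeric"))

setValidity("ViabilityRecord", function(object) {
  if (object@deadCells < 0) return("deadCells must be >= 0")
  if (!is.na(object@percentLive) &&
      (object@percentLive < 0 || object@percentLive > 100))
    return("percentLive must lie in [0, 100]")
  TRUE
})

#' Feature table of taxon counts
#'
#' Samples-by-taxa integer counts stored as a
#' \linkS4class{SummarizedExperiment} with taxa in rows (assay
#' \code{"counts"}) and a per-taxon semicolon-delimited taxonomy string in
#' \code{rowData(x)$taxonomy}.  The unit of all compositional analyses.
#'
#' @import SummarizedExperiment
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"counts" %in% assayNames(object)) return("assay 'counts' required")
  m <- assay(object, "counts")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) return("counts must be integers")
  if (!"taxonomy" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must carry a 'taxonomy' column")
  if (is.null(colnames(object)) || is.null(rownames(object)))
    return("taxon and sample names are required")
  TRUE
})

#' Pairwise sample distance matrix
#'
#' Square symmetric matrix of non-negative distances with matching row and
#' column sample names, zero diagonal and finite entries; the input to PCoA,
#' convex-hull dispersion and the permutation test.
#'
#' @export
setClass("DistanceMatrix", contains = "matrix")

setValidity("DistanceMatrix", function(object) {
  m <- object@.Data
  if (nrow(m) != ncol(m)) return("must be square")
  if (any(!is.finite(m))) return("entries must be finite")
  if (any(m < 0)) return("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-12) return("must be symmetric within 1e-12")
  if (any(abs(diag(m)) > 1e-12)) return("diagonal must be zero")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("row and column sample names must be present and identical")
  TRUE
})

#' Principal-coordinates ordination
#'
#' Classical metric scaling of a distance matrix: samples x axes coordinates,
#' the positive eigenvalues, and the proportion of (positive) eigenvalue mass
#' explained per axis, ordered by non-increasing eigenvalue.
#'
#' @export
setClass("OrdinationResult",
  representation(coordinates = "matrix", eigenvalues = "numeric",
                 proportionExplained = "numeric"))

setValidity("OrdinationResult", function(object) {
  ev <- object@eigenvalues
  if (length(ev) != ncol(object@coordinates))
    return("one eigenvalue per axis required")
  if (is.unsorted(rev(ev), strictly = FALSE))
    return("axes must be ordered by non-increasing eigenvalue")
  pe <- object@proportionExplained
  if (any(pe < -1e-12 | pe > 1 + 1e-12))
    return("proportions explained must lie in [0, 1]")
  TRUE
})

#' Permutation Kruskal-Wallis result
#'
#' Observed tie-corrected H statistic, permutation count, number of
#' permutations whose statistic reached the observed one, and the add-one
#' permutation p-value \eqn{(n_{exceed} + 1) / (n_{perm} + 1)}.
#'
#' @export
setClass("PermutationTestResult",
  representation(kObserved = "numeric", nPermutations = "integer",
                 nExceed = "integer", pValue = "numeric", seed = "integer"))

setValidity("PermutationTestResult", function(object) {
  expected <- (object@nExceed + 1) / (object@nPermutations + 1)
  if (abs(object@pValue - expected) > 1e-12)
    return("pValue must equal (nExceed + 1) / (nPermutations + 1)")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})
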