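#' @include AllClasses.R
NULL

#' Accessors
#'
#' Slot accessors for the package's S4 result classes; user code should use
#' these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setGeneric("cellsPerMlSaliva", function(x) standardGeneric("cellsPerMlSaliva"))
#' @rdname accessors
#' @export
setGeneric("cellsPerUlMeasured", function(x) standardGeneric("cellsPerUlMeasured"))
#' @rdname accessors
#' @export
setGeneric("percentLive", function(x) standardGeneric("percentLive"))
#' @rdname accessors
#' @export
setGeneric("liveCells", function(x) standardGeneric("liveCells"))
#' @rdname accessors
#' @export
setGeneric("deadCells", function(x) standardGeneric("deadCells"))
#' @rdname accessors
#' @export
setGeneric("totalCells", function(x) standardGeneric("totalCells"))
#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))
#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("proportionExplained", function(x) standardGeneric("proportionExplained"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("kObserved", function(x) standardGeneric("kObserved"))
#' @rdname accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortTree", function(x) standardGeneric("cohortTree"))
#' @rdname accessors
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

setMethod("nCells", "GatedCounts", function(x) x@nCells)
setMethod("nBeads", "GatedCounts", function(x) x@nBeads)
setMethod("cellsPerMlSaliva", "QuantResult", function(x) x@cellsPerMlSaliva)
setMethod("cellsPerUlMeasured", "QuantResult", function(x) x@cellsPerUlMeasured)
setMethod("percentLive", "ViabilityRecord", function(x) x@percentLive)
setMethod("liveCells", "ViabilityRecord", function(x) x@liveCells)
setMethod("deadCells", "ViabilityRecord", function(x) x@deadCells)
setMethod("totalCells", "ViabilityRecord", function(x) x@totalCells)
setMethod("curveSlope", "StandardCurve", function(x) x@slope)
setMethod("curveIntercept", "StandardCurve", function(x) x@intercept)
setMethod("efficiency", "StandardCurve", function(x) x@efficiency)
setMethod("taxonomy", "FeatureTable",
  function(x) setNames(SummarizedExperiment::rowData(x)$taxonomy, rownames(x)))
setMethod("counts", "FeatureTable", function(x) assay(x, "counts"))
setMethod("coordinates", "OrdinationResult", function(x) x@coordinates)
setMethod("eigenvalues", "OrdinationResult", function(x) x@eigenvalues)
setMethod("proportionExplained", "OrdinationResult",
  function(x) x@proportionExplained)
setMethod("pValue", "PermutationTestResult", function(x) x@pValue)
setMethod("kObserved", "PermutationTestResult", function(x) x@kObserved)
setMethod("cohortMetadata", "SalivaCohort", function(x) x@metadata)
setMethod("cohortTruth", "SalivaCohort", function(x) x@truth)
setMethod("cohortTree", "SalivaCohort", function(x) x@tree)
setMethod("eventData", "CytometryEventTable", function(x) x@events)

setMethod("show", "CytometryEventTable", function(object) {
  cat("CytometryEventTable '", object@sampleId, "': ",
      nrow(object@events), " events\n", sep = "")
})

setMethod("show", "GatedCounts", function(object) {
  cat("GatedCounts:", object@nTotal, "events ->",
      object@nCells, "cells,", object@nBeads, "beads,",
      object@nDoubletsExcluded, "doublets,",
      object@nLargeExcluded, "large,",
      object@nSubthreshold, "sub-threshold\n")
})

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult: %.4g cells/ul measured, %.4g cells/ml saliva (dilution %.3g)\n",
              object@cellsPerUlMeasured, object@cellsPerMlSaliva,
              object@dilutionFactor))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: Cq = %.4f + %.4f * log10(copies), R2 = %.4f, efficiency = %.1f%%\n",
              object@intercept, object@slope, object@rSquared,
              object@efficiency))
})

setMethod("show", "ViabilityRecord", function(object) {
  cat(sprintf("ViabilityRecord: live %.4g / total %.4g (dead %.4g, %.1f%% live)\n",
              object@liveCells, object@totalCells, object@deadCells,
              object@percentLive))
})

setMethod("show", "SalivaCohort", function(object) {
  cat("SalivaCohort:", object@config@nParticipants, "participants x",
      length(object@config@timepoints), "timepoints (",
      object@config@design, "),", length(object@taxonomy), "taxa\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix over", nrow(object), "samples\n")
})

setMethod("show", "OrdinationResult", function(object) {
  cat("OrdinationResult:", nrow(object@coordinates), "samples x",
      ncol(object@coordinates), "axes; first axes explain",
      paste(sprintf("%.1f%%", 100 * utils::head(object@proportionExplained, 3)),
            collapse = ", "), "\n")
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("Permutation Kruskal-Wallis: H = %.4f, p = %.4g (%d permutations, seed %d)\n",
              object@kObserved, object@pValue, object@nPermutations,
              object@seed))
})
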