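#' @include AllClasses.R utils.R
NULL

#' Build a gating configuration
#'
#' Defaults match the synthetic event clouds: DNA-positive threshold on FL1
#' area, bead threshold on FL4 area, a +/-30\% band around the median singlet
#' FL1 height/width ratio, and scatter ceilings that remove human cells.
#' Thresholds are instrument-dependent and should be set per data set.
#'
#' @param fl1Min DNA-positive FL1_A threshold (inclusive keep above).
#' @param fl4BeadMin bead FL4_A threshold (inclusive).
#' @param doubletBand relative half-width in (0,1) around the median ratio.
#' @param fscMax,bscMax inclusive scatter ceilings.
#' @param doubletDenominator "width" for FL1_H/FL1_W (default) or "area" for
#'   FL1_H/FL1_A; pulse height against either axis carries the singlet trend.
#' @return a validated \linkS4class{GatingConfig}.
#' @export
gatingConfig <- function(fl1Min = 1000, fl4BeadMin = 3162,
                         doubletBand = 0.3, fscMax = 1e4, bscMax = 1e4,
                         doubletDenominator = c("width", "area")) {
  new("GatingConfig", fl1Min = fl1Min, fl4BeadMin = fl4BeadMin,
      doubletBand = doubletBand, fscMax = fscMax, bscMax = bscMax,
      doubletDenominator = match.arg(doubletDenominator))
}

#' DNA-positive gate
#'
#' First gate: events with FL1_A at or above \code{fl1Min} are DNA-positive;
#' among those, events with FL4_A at or above \code{fl4BeadMin} are counting
#' beads, the rest are candidate cells.  Below-threshold events are counted
#' as sub-threshold background.  Bead identification precedes cell counting
#' so beads never contaminate the cell gate.
#'
#' @param events a \linkS4class{CytometryEventTable}.
#' @param cfg a \linkS4class{GatingConfig}.
#' @return list with \code{candidates} and \code{beads} (data.frames) and
#'   \code{nSubthreshold}.
#' @export
dnaPositiveGate <- function(events, cfg = gatingConfig()) {
  stopifnot(is(events, "CytometryEventTable"), is(cfg, "GatingConfig"))
  ev <- events@events
  if (nrow(ev) == 0L) stop("empty event table")
  positive <- ev$FL1_A >= cfg@fl1Min
  pos <- ev[positive, , drop = FALSE]
  isBead <- pos$FL4_A >= cfg@fl4BeadMin
  list(candidates = pos[!isBead, , drop = FALSE],
       beads = pos[isBead, , drop = FALSE],
       nSubthreshold = sum(!positive))
}

#' Doublet/aggregate exclusion
#'
#' Second gate: keeps candidate events whose FL1 height-to-width (or
#' height-to-area) ratio lies within \code{doubletBand} of the median ratio;
#' aggregates fall off the singlet linear trend and are excluded.  Events
#' with a zero denominator cannot be placed on the trend and are excluded
#' with a warning.
#'
#' @param candidates data.frame of candidate cell events.
#' @param cfg a \linkS4class{GatingConfig}.
#' @return list with \code{singlets} and \code{nDoubletsExcluded}.
#' @export
doubletFilter <- function(candidates, cfg = gatingConfig()) {
  if (nrow(candidates) == 0L)
    return(list(singlets = candidates, nDoubletsExcluded = 0L))
  denom <- if (cfg@doubletDenominator == "width") candidates$FL1_W
           else candidates$FL1_A
  zero <- denom == 0
  if (any(zero))
    warning(sum(zero), " event(s) with zero FL1 ",
            cfg@doubletDenominator, " excluded from the singlet trend")
  ratio <- ifelse(zero, NA_real_, candidates$FL1_H / denom)
  med <- median(ratio, na.rm = TRUE)
  keep <- !is.na(ratio) & abs(ratio - med) <= cfg@doubletBand * med
  list(singlets = candidates[keep, , drop = FALSE],
       nDoubletsExcluded = sum(!keep))
}

#' Scatter gate
#'
#' Third gate: keeps singlet events with FSC_A and BSC_A at or below the
#' configured ceilings, excluding large events (human cells and remaining
#' background).  Comparisons are inclusive.
#'
#' @param singlets data.frame of singlet events.
#' @param cfg a \linkS4class{GatingConfig}.
#' @return list with \code{bacteria} and \code{nLargeExcluded}.
#' @export
scatterFilter <- function(singlets, cfg = gatingConfig()) {
  keep <- singlets$FSC_A <= cfg@fscMax & singlets$BSC_A <= cfg@bscMax
  list(bacteria = singlets[keep, , drop = FALSE],
       nLargeExcluded = sum(!keep))
}

#' Full gating of an event table
#'
#' Composes the DNA-positive, doublet and scatter gates; the five resulting
#' counts partition the event total exactly.
#'
#' @param events a \linkS4class{CytometryEventTable}.
#' @param cfg a \linkS4class{GatingConfig}.
#' @return a \linkS4class{GatedCounts}.
#' @export
gateEvents <- function(events, cfg = gatingConfig()) {
  g1 <- dnaPositiveGate(events, cfg)
  g2 <- doubletFilter(g1$candidates, cfg)
  g3 <- scatterFilter(g2$singlets, cfg)
  new("GatedCounts",
      nCells = nrow(g3$bacteria),
      nBeads = nrow(g1$beads),
      nDoubletsExcluded = as.integer(g2$nDoubletsExcluded),
      nLargeExcluded = as.integer(g3$nLargeExcluded),
      nSubthreshold = as.integer(g1$nSubthreshold),
      nTotal = nrow(events@events))
}

#' Bead-calibrated absolute concentration
#'
#' Counting-bead quantification: cells per microlitre in the measured tube is
#' \code{(nCells / nBeads) * (beadsAdded / sampleVolumeUl)}; cells per
#' millilitre of neat saliva multiplies by 1000 and the dilution factor.
#' A gated bead count of zero signals a failed bead spike and is an error.
#'
#' @param gc a \linkS4class{GatedCounts}.
#' @param beadsAdded beads spiked into the tube (> 0).
#' @param sampleVolumeUl stained tube volume in microlitres (> 0).
#' @param dilutionFactor fold dilution from neat saliva (>= 1).
#' @return a \linkS4class{QuantResult}.
#' @export
concentration <- function(gc, beadsAdded, sampleVolumeUl,
                          dilutionFactor = 1) {
  stopifnot(is(gc, "GatedCounts"))
  if (beadsAdded <= 0) stop("beadsAdded must be positive")
  if (sampleVolumeUl <= 0) stop("sampleVolumeUl must be positive")
  if (gc@nBeads == 0L)
    stop("no bead events gated: sample is unquantifiable (bead spike failure)")
  perUl <- (gc@nCells / gc@nBeads) * (beadsAdded / sampleVolumeUl)
  new("QuantResult", cellsPerUlMeasured = perUl,
      cellsPerMlSaliva = perUl * 1000 * dilutionFactor,
      dilutionFactor = dilutionFactor, beadsAdded = beadsAdded,
      sampleVolumeUl = sampleVolumeUl)
}

#' Dilution factor of a glycerol-preserved, PBS-diluted sample
#'
#' Saliva drooled onto a glycerol cushion and later diluted in PBS:
#' \code{((saliva + glycerol) / saliva) * pbsFold}.
#'
#' @param salivaVolumeMl collected saliva volume (> 0).
#' @param glycerolMl preservative volume (default 2 ml).
#' @param pbsFold subsequent PBS fold dilution (default 10).
#' @return dimensionless dilution factor.
#' @export
glycerolDilutionFactor <- function(salivaVolumeMl, glycerolMl = 2,
                                   pbsFold = 10) {
  if (any(salivaVolumeMl <= 0)) stop("saliva volume must be positive")
  ((salivaVolumeMl + glycerolMl) / salivaVolumeMl) * pbsFold
}
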