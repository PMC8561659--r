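#' @include AllClasses.R utils.R gating.R simulate-events.R
NULL

#' Unstimulated salivary flow rate
#'
#' Volume of passively drooled saliva per minute over a timed collection.
#'
#' @param volumeMl collected volume in ml (>= 0).
#' @param minutes collection time (> 0, default 5).
#' @return flow rate in ml per minute.
#' @export
flowRate <- function(volumeMl, minutes = 5) {
  if (any(minutes <= 0)) stop("collection minutes must be positive")
  if (any(volumeMl < 0)) stop("volume cannot be negative")
  volumeMl / minutes
}

checkPairKeys <- function(raw, pma) {
  for (key in c("participant", "timepoint")) {
    if (!identical(as.character(raw[[key]]), as.character(pma[[key]])))
      stop("raw/PMA pairing mismatch on ", key, ": '", raw[[key]],
           "' vs '", pma[[key]], "'")
  }
  if (!identical(as.character(raw$processing), "raw") ||
      !identical(as.character(pma$processing), "pma"))
    stop("pair_viability expects (raw, pma) records in that order; got ",
         "processing = ('", raw$processing, "', '", pma$processing, "')")
}

#' Live/dead decomposition of a paired raw/PMA quantification
#'
#' The PMA-treated count is the live cell number, the raw count the total;
#' dead cells are the difference floored at zero and percent live is capped
#' at 100 (measurement noise can push the PMA count above the raw count).
#' A zero total leaves percent live undefined (NA) with a message.
#'
#' @param raw,pma records (one-row data.frames or lists) sharing participant
#'   and timepoint, with \code{processing} "raw" and "pma" respectively and a
#'   cell count in \code{totalCellsCollected} (or \code{cells}).
#' @return a \linkS4class{ViabilityRecord}.
#' @export
pairViability <- function(raw, pma) {
  checkPairKeys(raw, pma)
  getCount <- function(x) {
    v <- x$totalCellsCollected %||% x$cells
    if (is.null(v)) stop("record carries no cell count")
    v
  }
  total <- getCount(raw)
  live <- getCount(pma)
  dead <- max(total - live, 0)
  if (total > 0) {
    pct <- min(100 * live / total, 100)
  } else {
    msg("total cell count is zero for ", raw$participant, " ",
        raw$timepoint, ": percent live undefined")
    pct <- NA_real_
  }
  new("ViabilityRecord", liveCells = live, totalCells = total,
      deadCells = dead, percentLive = pct)
}

#' Normalize a load series to its first timepoint
#'
#' Expresses each value as a percentage of the first (baseline) timepoint.
#'
#' @param values numeric series ordered by timepoint; first value must be
#'   positive.
#' @param id label used in the error message when the baseline is zero.
#' @return percentages with value 100 at the baseline.
#' @export
normalizeToBaseline <- function(values, id = "series") {
  if (length(values) < 1L) stop("empty series")
  if (!is.finite(values[1]) || values[1] <= 0)
    stop("baseline (first timepoint) is not positive for ", id)
  values / values[1] * 100
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(copies) over a serial-dilution ladder;
#' replicate Cq values at the same level are averaged before fitting.
#' Amplification efficiency is \eqn{(10^{-1/slope} - 1) \times 100}.
#'
#' @param copies template copy numbers (> 0), one per Cq.
#' @param cq measured quantification cycles.
#' @return a \linkS4class{StandardCurve}.
#' @export
fitStandardCurve <- function(copies, cq) {
  stopifnot(length(copies) == length(cq))
  if (any(copies <= 0)) stop("copy numbers must be positive")
  lvl <- log10(copies)
  cqMean <- tapply(cq, lvl, mean)
  x <- as.numeric(names(cqMean))
  y <- as.numeric(cqMean)
  if (length(x) < 2L || var(x) == 0)
    stop("standard curve needs >= 2 distinct copy levels")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  new("StandardCurve", slope = slope, intercept = unname(coef(fit)[1]),
      rSquared = suppressWarnings(summary(fit)$r.squared),  # exact ladders

      efficiency = (10^(-1 / slope) - 1) * 100)
}

#' Copy number from a Cq value
#'
#' Inverts the standard curve: \eqn{10^{(Cq - intercept)/slope}}.
#'
#' @param cq quantification cycle value(s).
#' @param curve a \linkS4class{StandardCurve}.
#' @return extrapolated copy number(s).
#' @export
copiesFromCq <- function(cq, curve) {
  stopifnot(is(curve, "StandardCurve"))
  10^((cq - curve@intercept) / curve@slope)
}

#' Pearson correlation with optional log10 transforms
#'
#' Standard Pearson correlation between two paired series, optionally
#' log10-transforming either side; non-positive values are dropped before a
#' log transform and the exclusion count is reported.
#'
#' @param x,y paired numeric series.
#' @param logX,logY logical; log10-transform the series first.
#' @return list with \code{r}, \code{p}, \code{n} and \code{nDropped}.
#' @export
correlateLoad <- function(x, y, logX = FALSE, logY = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (logX) keep <- keep & x > 0
  if (logY) keep <- keep & y > 0
  nDropped <- sum(!keep)
  if (nDropped > 0)
    msg(nDropped, " pair(s) dropped before correlation (non-finite or ",
        "non-positive under log transform)")
  xs <- if (logX) log10(x[keep]) else x[keep]
  ys <- if (logY) log10(y[keep]) else y[keep]
  if (length(xs) < 3L) stop("fewer than 3 usable pairs")
  if (var(xs) == 0 || var(ys) == 0)
    stop("correlation undefined: a series is constant")
  ct <- cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs),
       nDropped = nDropped)
}

#' Quantify every sample of a synthetic cohort through the cytometry chain
#'
#' For each participant x timepoint, simulates the raw and PMA-treated
#' acquisitions, gates them, converts to absolute concentration with the
#' bead calibration, and assembles per-sample records with flow rate,
#' live/total/dead cells and percent live.
#'
#' @param cohort a \linkS4class{SalivaCohort}.
#' @param acq acquisition settings (see \code{\link{acquisitionSettings}}).
#' @param cfg gating configuration.
#' @param seed seed for the events substream (default derived from the
#'   cohort seed).
#' @return data.frame keyed by record with measured cells_per_ml and
#'   collected-cell counts for both processings plus viability metrics.
#' @export
quantifyCohort <- function(cohort, acq = acquisitionSettings(),
                           cfg = gatingConfig(), seed = NULL) {
  truth <- cohort@truth
  if (is.null(seed)) seed <- substreamSeed(cohort@config@seed, "events")
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    measure <- function(proc) {
      ev <- simulateEvents(tr, acq, processing = proc,
                           seed = substreamSeed(seed, paste0(tr$record_id, proc)))
      q <- concentration(gateEvents(ev, cfg), beadsAdded = acq$beadsAdded,
                         sampleVolumeUl = acq$sampleVolumeUl,
                         dilutionFactor = acq$dilutionFactor)
      cellsPerMlSaliva(q)
    }
    rawMl <- measure("raw")
    pmaMl <- measure("pma")
    rawRec <- list(participant = tr$participant, timepoint = tr$timepoint,
                   processing = "raw",
                   totalCellsCollected = rawMl * tr$saliva_volume_ml)
    pmaRec <- list(participant = tr$participant, timepoint = tr$timepoint,
                   processing = "pma",
                   totalCellsCollected = pmaMl * tr$saliva_volume_ml)
    v <- pairViability(rawRec, pmaRec)
    data.frame(record_id = tr$record_id, participant = tr$participant,
               timepoint = tr$timepoint, treatment = tr$treatment,
               flow_rate_ml_min = flowRate(tr$saliva_volume_ml,
                                           tr$collection_minutes),
               raw_cells_per_ml = rawMl, pma_cells_per_ml = pmaMl,
               live_cells = liveCells(v), total_cells = totalCells(v),
               dead_cells = deadCells(v), percent_live = percentLive(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$record_id
  out
}
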