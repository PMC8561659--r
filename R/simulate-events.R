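#' @include AllClasses.R utils.R simulate-cohort.R
NULL

#' Acquisition settings for the event simulator
#'
#' Describes how a stained tube is acquired: the stained sample volume that
#' received the counting-bead spike, the volume actually acquired, the bead
#' spike size, the overall dilution from neat saliva to the stained tube, and
#' the rates of the nuisance populations (debris, human cells, doublets).
#' With \code{exact = TRUE} event counts are the rounded expectations instead
#' of Poisson draws (noise-free acquisition).
#'
#' @param sampleVolumeUl stained tube volume (default 1000 ul = 1 ml).
#' @param acquiredVolumeUl volume run through the cytometer (default 2 ul,
#'   about 10,000 cell events for a typical 1e8 cells/ml saliva sample at
#'   20-fold dilution).
#' @param beadsAdded counting beads spiked into the tube (default 5e5, about
#'   1,000 bead events at the default acquired volume).
#' @param dilutionFactor fold dilution from neat saliva to the tube
#'   (default 20: glycerol preservative then 10-fold PBS).
#' @param debrisPerUl,humanPerUl nuisance event concentrations (events/ul).
#' @param doubletRate fraction of cell events acquired as two-cell aggregates
#'   (each doublet event consumes two cells).
#' @param exact logical; use expected counts instead of Poisson draws.
#' @return a plain list of settings.
#' @export
acquisitionSettings <- function(sampleVolumeUl = 1000, acquiredVolumeUl = 2,
                                beadsAdded = 5e5, dilutionFactor = 20,
                                debrisPerUl = 20, humanPerUl = 2,
                                doubletRate = 0.02, exact = FALSE) {
  if (acquiredVolumeUl <= 0 || sampleVolumeUl <= 0)
    stop("acquired and sample volumes must be positive")
  if (acquiredVolumeUl > sampleVolumeUl)
    stop("cannot acquire more than the stained sample volume")
  list(sampleVolumeUl = sampleVolumeUl, acquiredVolumeUl = acquiredVolumeUl,
       beadsAdded = beadsAdded, dilutionFactor = dilutionFactor,
       debrisPerUl = debrisPerUl, humanPerUl = humanPerUl,
       doubletRate = doubletRate, exact = exact)
}

# Log-normal channel cluster in linear intensity units.
channelCluster <- function(n, mu, sigma) 10^rnorm(n, mu, sigma)

drawCount <- function(lambda, exact) {
  if (exact) as.integer(round(lambda)) else rpois(1, lambda)
}

#' Simulate cytometry events for one sample
#'
#' Generates the event clouds a SYBR-green bacterial count acquires:
#' bacteria (high FL1, low FL4, small scatter), debris (sub-threshold FL1),
#' human cells (large forward/back scatter), doublets (bacterial events with
#' inflated FL1 pulse width so the height/width ratio leaves the singlet
#' trend), and counting beads (distinct high-FL4 cluster).  Raw samples draw
#' the cell event rate from the total (live + relic) pool, PMA-treated
#' samples from the live pool only.  Cell and bead event counts are
#' proportional to concentration times acquired volume; a doublet event
#' consumes two cells.  The returned table keeps a ground-truth
#' \code{population} column that the gating functions never read.
#'
#' @param truth one row of \code{cohortTruth()} (or any list with
#'   \code{true_live_cells}, \code{true_total_cells}, \code{saliva_volume_ml}).
#' @param acq settings from \code{\link{acquisitionSettings}}.
#' @param processing "raw" (total pool) or "pma" (live pool).
#' @param sampleId identifier stored on the table.
#' @param seed optional seed for this acquisition.
#' @return a \linkS4class{CytometryEventTable}.
#' @export
simulateEvents <- function(truth, acq = acquisitionSettings(),
                           processing = c("raw", "pma"),
                           sampleId = NULL, seed = NULL) {
  processing <- match.arg(processing)
  if (acq$acquiredVolumeUl <= 0) stop("acquired volume must be positive")
  pool <- if (processing == "pma") truth$true_live_cells else truth$true_total_cells
  cellsPerMl <- pool / truth$saliva_volume_ml
  concPerUl <- cellsPerMl / 1000 / acq$dilutionFactor
  acqFraction <- acq$acquiredVolumeUl / acq$sampleVolumeUl
  if (is.null(sampleId))
    sampleId <- paste(truth$record_id %||% "sample", processing, sep = "_")

  gen <- function() {
    nCellUnits <- drawCount(concPerUl * acq$acquiredVolumeUl, acq$exact)
    nDoublet <- if (acq$doubletRate > 0)
      min(rbinom(1, nCellUnits, acq$doubletRate), nCellUnits %/% 2L) else 0L
    nSinglet <- nCellUnits - 2L * nDoublet
    nBead <- drawCount(acq$beadsAdded * acqFraction, acq$exact)
    nDebris <- drawCount(acq$debrisPerUl * acq$acquiredVolumeUl, acq$exact)
    nHuman <- drawCount(acq$humanPerUl * acq$acquiredVolumeUl, acq$exact)

    bact <- function(n, doublet = FALSE) {
      if (n == 0L) return(NULL)
      h <- channelCluster(n, 3.8, 0.2)
      ratio <- pmax(rnorm(n, 2, 0.08), 0.2)
      w <- h / ratio * if (doublet) 2.2 else 1
      data.frame(FL1_A = h * w / 1e3, FL1_H = h, FL1_W = w,
                 FL4_A = channelCluster(n, 1.0, 0.3),
                 FSC_A = channelCluster(n, 2.0, 0.3),
                 BSC_A = channelCluster(n, 2.0, 0.3),
                 population = if (doublet) "doublet" else "bacteria")
    }
    debris <- function(n) {
      if (n == 0L) return(NULL)
      h <- channelCluster(n, 1.6, 0.4)
      w <- h / pmax(rnorm(n, 2, 0.5), 0.2)
      data.frame(FL1_A = h * w / 1e3, FL1_H = h, FL1_W = w,
                 FL4_A = channelCluster(n, 0.8, 0.4),
                 FSC_A = channelCluster(n, 1.5, 0.4),
                 BSC_A = channelCluster(n, 1.5, 0.4),
                 population = "debris")
    }
    human <- function(n) {
      if (n == 0L) return(NULL)
      h <- channelCluster(n, 4.3, 0.3)
      w <- h / pmax(rnorm(n, 2, 0.3), 0.2)
      data.frame(FL1_A = h * w / 1e3, FL1_H = h, FL1_W = w,
                 FL4_A = channelCluster(n, 1.2, 0.4),
                 FSC_A = channelCluster(n, 5.2, 0.2),
                 BSC_A = channelCluster(n, 5.0, 0.2),
                 population = "human")
    }
    bead <- function(n) {
      if (n == 0L) return(NULL)
      h <- channelCluster(n, 4.4, 0.1)
      w <- h / pmax(rnorm(n, 2, 0.08), 0.2)
      data.frame(FL1_A = h * w / 1e3, FL1_H = h, FL1_W = w,
                 FL4_A = channelCluster(n, 4.5, 0.12),
                 FSC_A = channelCluster(n, 3.0, 0.15),
                 BSC_A = channelCluster(n, 3.0, 0.15),
                 population = "bead")
    }
    ev <- do.call(rbind, Filter(Negate(is.null), list(
      bact(nSinglet), bact(nDoublet, doublet = TRUE),
      debris(nDebris), human(nHuman), bead(nBead))))
    if (is.null(ev) || nrow(ev) == 0L)
      ev <- debris(1L)                    # an acquisition never records zero events
    ev[sample.int(nrow(ev)), , drop = FALSE]
  }
  ev <- if (is.null(seed)) gen() else withSeed(seed, gen())
  rownames(ev) <- NULL
  new("CytometryEventTable", events = ev, sampleId = as.character(sampleId))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
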