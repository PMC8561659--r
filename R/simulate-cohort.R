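#' @include AllClasses.R utils.R
NULL

DOMINANT_GENERA <- data.frame(
  genus = c("Streptococcus", "Veillonella", "Gemella", "Granulicatella",
            "Oribacterium", "Prevotella", "Porphyromonas", "Capnocytophaga",
            "Haemophilus", "Neisseria", "Lautropia", "Rothia", "Actinomyces",
            "Atopobium", "Fusobacterium", "Leptotrichia"),
  phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
             "Firmicutes", "Bacteroidetes", "Bacteroidetes", "Bacteroidetes",
             "Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Actinobacteria", "Actinobacteria", "Actinobacteria",
             "Fusobacteria", "Fusobacteria"),
  stringsAsFactors = FALSE)

MINOR_GENERA <- data.frame(
  genus = c("Alloprevotella", "Solobacterium", "Campylobacter",
            "Corynebacterium", "Selenomonas", "Bergeyella", "Kingella",
            "Lachnoanaerobaculum", "Megasphaera", "Tannerella"),
  phylum = c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Firmicutes", "Bacteroidetes",
             "Proteobacteria", "Firmicutes", "Firmicutes", "Bacteroidetes"),
  stringsAsFactors = FALSE)

CHLOROPLAST_TAXON <- "ASV_chloroplast"

taxonomyString <- function(phylum, genus) {
  sprintf("k__Bacteria; p__%s; c__; o__; f__; g__%s", phylum, genus)
}

# Taxonomy over nTaxa bacterial ASVs plus one chloroplast taxon.  The first
# nDominantGenera ASVs carry the dominant saliva genera (five phyla); minor
# ASVs cycle through additional oral genera, with exactly one Treponema ASV
# (phylum Spirochaetes) outside the five dominant phyla.
buildTaxonomy <- function(nTaxa, nDominantGenera) {
  nDom <- min(nDominantGenera, nrow(DOMINANT_GENERA))
  ids <- sprintf("ASV%03d", seq_len(nTaxa))
  tax <- character(nTaxa)
  tax[seq_len(nDom)] <- taxonomyString(DOMINANT_GENERA$phylum[seq_len(nDom)],
                                       DOMINANT_GENERA$genus[seq_len(nDom)])
  nMinor <- nTaxa - nDom
  if (nMinor > 0) {
    tax[nDom + 1L] <- taxonomyString("Spirochaetes", "Treponema")
    if (nMinor > 1) {
      idx <- seq_len(nMinor - 1L)
      src <- rbind(MINOR_GENERA, DOMINANT_GENERA)
      pick <- ((idx - 1L) %% nrow(src)) + 1L
      tax[nDom + 1L + idx] <- taxonomyString(src$phylum[pick], src$genus[pick])
    }
  }
  c(setNames(tax, ids),
    setNames(taxonomyString("Cyanobacteria", "Chloroplast"),
             CHLOROPLAST_TAXON))
}

# Deterministic cohort-level base composition: dominant genera take 93% of
# the mass on a gentle geometric decay (all above 1%), the Treponema ASV is
# pinned at 0.12%, and the remaining minor ASVs share the rest geometrically.
# The chloroplast taxon carries zero mass (contamination is injected at the
# read-simulation stage).
baseComposition <- function(taxonomyVec, nDominantGenera) {
  ids <- names(taxonomyVec)
  nAll <- length(ids)
  nDom <- min(nDominantGenera, nrow(DOMINANT_GENERA))
  w <- numeric(nAll)
  names(w) <- ids
  w[seq_len(nDom)] <- 0.93 * renorm(0.85^(seq_len(nDom) - 1))
  trepIdx <- grep("Treponema", taxonomyVec)
  minorIdx <- setdiff(seq_len(nAll - 1L), c(seq_len(nDom), trepIdx))
  w[trepIdx] <- 0.0012
  if (length(minorIdx))
    w[minorIdx] <- (0.07 - 0.0012 * length(trepIdx)) *
      renorm(0.9^(seq_along(minorIdx) - 1))
  w[CHLOROPLAST_TAXON] <- 0
  renorm(w)
}

resolveTaxon <- function(pattern, taxonomyVec) {
  hits <- unique(c(grep(pattern, names(taxonomyVec), ignore.case = TRUE),
                   grep(pattern, taxonomyVec, ignore.case = TRUE)))
  if (!length(hits))
    stop("relicEnrichedTaxon '", pattern, "' matches no taxon")
  hits[1L]
}

#' Configure a synthetic saliva cohort
#'
#' Builds a \linkS4class{CohortConfig} with study-design defaults: the
#' daily-dynamics design samples 10 participants at 9 timepoints through one
#' day (waking sample carries the daily maximum live load; tooth-brushing at
#' the second timepoint removes cells from both the live and relic pools),
#' and the acute-perturbation design samples 28 participants at baseline,
#' 15 minutes and 2 hours around one of four treatments (7 participants
#' each): water and soda leave the pools untouched; alcohol-free mouthwash
#' kills 95\% of live cells at the 15-minute sample without removing them
#' (killed cells join the relic pool, totals conserved) and live load returns
#' to baseline by 2 hours; antiseptic mouthwash applies its kill only at the
#' 2-hour sample (delayed action).
#'
#' @param design "daily_dynamics" or "acute_perturbation".
#' @param nParticipants number of participants (default 10 daily, 28 acute).
#' @param timepoints ordered labels (default T1..T9 daily, T1..T3 acute).
#' @param treatmentAssignments named character participant -> treatment;
#'   defaults to "none" for daily and a balanced 7x4 assignment for acute.
#' @param baselineLoadLog10Mean,baselineLoadLog10Sd distribution of log10
#'   live cells per 5-minute collection across participants (defaults 8.35
#'   and 0.6: about 2e8 cells with >3 orders of magnitude across the cohort).
#' @param withinDayLoadLog10Sd per-step SD of the within-day log10 load
#'   random walk (default 0.4, giving >=10-fold daily fluctuation).
#' @param liveFractionBaseline baseline live/total fraction (default 0.4).
#' @param relicEnrichedTaxon substring identifying the taxon up-weighted in
#'   the relic pool (default "Treponema").
#' @param relicLogFold natural-log fold tilt of the relic pool toward that
#'   taxon (default 2).
#' @param nTaxa,nDominantGenera richness (default 60 ASVs, 16 dominant
#'   genera across 5 phyla).
#' @param brushRemovalFactor,killFactorAlcoholFree,killFactorAntiseptic
#'   perturbation-kernel factors (defaults 0.3, 0.05, 0.3).
#' @param betweenParticipantCompSd,withinDayCompSd log-normal SDs of the
#'   between-participant and within-day composition perturbations (defaults
#'   0.6 and 1.0: the live pool turns over strongly within a day while the
#'   participant core composition is conserved, and the stable relic pool
#'   damps apparent variation in raw samples; within-participant dispersion
#'   stays smaller than between-participant by construction).
#' @param chloroplastRelAbundance chloroplast relative abundance injected in
#'   contaminated raw post-meal samples (default 0.006).
#' @param afterMealTimepoints indices of timepoints collected after eating
#'   (default 4 and 7 for the daily design, none for acute).
#' @param seed master seed; named substreams derive from it.
#' @return a validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(design = c("daily_dynamics", "acute_perturbation"),
                         nParticipants = NULL, timepoints = NULL,
                         treatmentAssignments = NULL,
                         baselineLoadLog10Mean = 8.35,
                         baselineLoadLog10Sd = 0.6,
                         withinDayLoadLog10Sd = 0.4,
                         liveFractionBaseline = 0.4,
                         relicEnrichedTaxon = "Treponema",
                         relicLogFold = 2,
                         nTaxa = 60L, nDominantGenera = 16L,
                         brushRemovalFactor = 0.3,
                         killFactorAlcoholFree = 0.05,
                         killFactorAntiseptic = 0.3,
                         betweenParticipantCompSd = 0.6,
                         withinDayCompSd = 1.0,
                         chloroplastRelAbundance = 0.006,
                         afterMealTimepoints = NULL,
                         seed = 1L) {
  design <- match.arg(design)
  if (is.null(nParticipants))
    nParticipants <- if (design == "daily_dynamics") 10L else 28L
  if (is.null(timepoints))
    timepoints <- paste0("T", seq_len(if (design == "daily_dynamics") 9L else 3L))
  participants <- sprintf("P%02d", seq_len(nParticipants))
  if (is.null(treatmentAssignments)) {
    treatmentAssignments <- if (design == "daily_dynamics") {
      setNames(rep("none", nParticipants), participants)
    } else {
      setNames(rep(c("water", "antiseptic", "alcohol_free", "soda"),
                   length.out = nParticipants), participants)
    }
  }
  if (is.null(names(treatmentAssignments)))
    names(treatmentAssignments) <- participants
  if (is.null(afterMealTimepoints))
    afterMealTimepoints <- if (design == "daily_dynamics")
      intersect(c(4L, 7L), seq_along(timepoints)) else integer(0)
  new("CohortConfig",
      nParticipants = as.integer(nParticipants),
      timepoints = as.character(timepoints), design = design,
      treatmentAssignments = treatmentAssignments,
      baselineLoadLog10Mean = baselineLoadLog10Mean,
      baselineLoadLog10Sd = baselineLoadLog10Sd,
      withinDayLoadLog10Sd = withinDayLoadLog10Sd,
      liveFractionBaseline = liveFractionBaseline,
      relicEnrichedTaxon = relicEnrichedTaxon, relicLogFold = relicLogFold,
      nTaxa = as.integer(nTaxa), nDominantGenera = as.integer(nDominantGenera),
      brushRemovalFactor = brushRemovalFactor,
      killFactorAlcoholFree = killFactorAlcoholFree,
      killFactorAntiseptic = killFactorAntiseptic,
      betweenParticipantCompSd = betweenParticipantCompSd,
      withinDayCompSd = withinDayCompSd,
      chloroplastRelAbundance = chloroplastRelAbundance,
      afterMealTimepoints = as.integer(afterMealTimepoints),
      seed = as.integer(seed))
}

#' Simulate a saliva cohort with ground truth
#'
#' Draws per-participant live-load trajectories (log-normal random walks with
#' perturbation kernels as multiplicative factors), live and relic pool
#' sizes, per-record compositions (a per-participant log-normal perturbation
#' of the cohort base composition, jittered slightly across timepoints; the
#' relic pool is the participant composition tilted toward the designated
#' dead-associated taxon and held stable over time), salivary flow rates for
#' timed 5-minute collections, and a random rooted phylogeny over the taxa.
#'
#' Kernels: the waking sample of the daily design carries the participant's
#' maximum live load; tooth-brushing multiplies both pools by
#' \code{brushRemovalFactor}; alcohol-free mouthwash multiplies the live pool
#' by \code{killFactorAlcoholFree} at the post-treatment timepoint, moves the
#' killed cells into the relic pool (totals conserved) and restores the live
#' load to its baseline at the 2-hour timepoint; antiseptic mouthwash applies
#' its kill only at the 2-hour timepoint; water and soda change nothing.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{SalivaCohort}; access pieces with
#'   \code{cohortMetadata()}, \code{cohortTruth()}, \code{cohortTree()}.
#' @export
simulateCohort <- function(config) {
  validObject(config)
  tax <- buildTaxonomy(config@nTaxa, config@nDominantGenera)
  base <- baseComposition(tax, config@nDominantGenera)
  relicIdx <- resolveTaxon(config@relicEnrichedTaxon, tax)
  participants <- names(config@treatmentAssignments)
  tps <- config@timepoints
  nT <- length(tps)
  nAll <- length(tax)
  daily <- config@design == "daily_dynamics"

  recs <- list(); liveComp <- list(); relicComp <- list()
  withSeed(substreamSeed(config@seed, "cohort"), {
    for (p in participants) {
      treat <- config@treatmentAssignments[[p]]
      pBase <- base
      jit <- exp(rnorm(nAll, 0, config@betweenParticipantCompSd))
      jit[nAll] <- 0                       # chloroplast stays absent
      pBase <- renorm(base * jit)
      pRelic <- pBase
      pRelic[relicIdx] <- pRelic[relicIdx] * exp(config@relicLogFold)
      pRelic <- renorm(pRelic)

      l0 <- rnorm(1, config@baselineLoadLog10Mean, config@baselineLoadLog10Sd)
      steps <- rnorm(nT, 0, config@withinDayLoadLog10Sd)
      lw <- l0 + cumsum(c(0, steps[-1]))   # pre-kernel log10 live trajectory
      if (daily && nT >= 2)                # waking sample is the daily max
        lw[1] <- max(lw) + 0.15
      Lpre <- 10^lw
      Rpre <- Lpre * (1 / config@liveFractionBaseline - 1)
      L <- Lpre; R <- Rpre
      if (daily && nT >= 2) {              # tooth-brushing removes cells
        L[2] <- Lpre[2] * config@brushRemovalFactor
        R[2] <- Rpre[2] * config@brushRemovalFactor
      }
      if (!daily && treat == "alcohol_free" && nT >= 2) {
        k <- config@killFactorAlcoholFree
        L[2] <- Lpre[2] * k
        R[2] <- Rpre[2] + Lpre[2] * (1 - k)
        if (nT >= 3) L[3] <- Lpre[1]       # full recovery to baseline at 2 h
      }
      if (!daily && treat == "antiseptic" && nT >= 3) {
        k <- config@killFactorAntiseptic
        L[3] <- Lpre[3] * k
        R[3] <- Rpre[3] + Lpre[3] * (1 - k)
      }

      flow <- pmin(pmax(exp(rnorm(nT, log(0.42), 0.55)), 0.02), 1.56)
      vol <- round(flow * 5, 1)
      vol <- pmax(vol, 0.1)
      flow <- vol / 5

      for (t in seq_len(nT)) {
        rid <- paste(p, tps[t], sep = "_")
        recs[[rid]] <- data.frame(
          record_id = rid, participant = p, timepoint = tps[t],
          treatment = treat,
          true_live_cells = L[t], true_total_cells = L[t] + R[t],
          saliva_volume_ml = vol[t], collection_minutes = 5,
          flow_rate_ml_per_min = flow[t],
          after_meal = t %in% config@afterMealTimepoints,
          stringsAsFactors = FALSE)
        tj <- exp(rnorm(nAll, 0, config@withinDayCompSd))
        tj[nAll] <- 0
        liveComp[[rid]] <- renorm(pBase * tj)
        relicComp[[rid]] <- pRelic
      }
    }
  })
  truth <- do.call(rbind, recs)
  rownames(truth) <- truth$record_id
  lc <- do.call(rbind, liveComp); rownames(lc) <- truth$record_id
  rc <- do.call(rbind, relicComp); rownames(rc) <- truth$record_id
  colnames(lc) <- colnames(rc) <- names(tax)

  meta <- do.call(rbind, lapply(c("raw", "pma"), function(proc) {
    data.frame(sample_id = paste(truth$record_id, proc, sep = "_"),
               record_id = truth$record_id,
               participant = truth$participant, timepoint = truth$timepoint,
               treatment = truth$treatment, processing = proc,
               volume_ml = truth$saliva_volume_ml,
               minutes = truth$collection_minutes,
               after_meal = truth$after_meal, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- meta$sample_id

  tree <- withSeed(substreamSeed(config@seed, "tree"),
                   ape::rtree(nAll, tip.label = names(tax)))

  new("SalivaCohort", config = config, metadata = meta, truth = truth,
      liveComposition = lc, relicComposition = rc, taxonomy = tax,
      tree = tree)
}
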