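test_that("cohort simulation produces one truth record per participant x timepoint", {
  co <- simulateCohort(cohortConfig("daily_dynamics", seed = 3))
  tr <- cohortTruth(co)
  expect_equal(nrow(tr), 90L)                       # 10 participants x 9 times
  expect_equal(nrow(cohortMetadata(co)), 180L)      # raw + PMA arm per record
  expect_true(all(tr$true_live_cells >= 0))
  expect_true(all(tr$true_live_cells <= tr$true_total_cells))
  expect_equal(unname(rowSums(co@liveComposition)), rep(1, 90), tolerance = 1e-9)
  expect_equal(unname(rowSums(co@relicComposition)), rep(1, 90), tolerance = 1e-9)
  expect_equal(tr$flow_rate_ml_per_min,
               tr$saliva_volume_ml / tr$collection_minutes)

  acute <- simulateCohort(cohortConfig("acute_perturbation", seed = 3))
  expect_equal(nrow(cohortTruth(acute)), 84L)       # 28 participants x 3 times
})

test_that("identical seeds reproduce the cohort exactly; seeds differ otherwise", {
  a <- simulateCohort(cohortConfig("daily_dynamics", seed = 11))
  b <- simulateCohort(cohortConfig("daily_dynamics", seed = 11))
  c <- simulateCohort(cohortConfig("daily_dynamics", seed = 12))
  expect_identical(cohortTruth(a), cohortTruth(b))
  expect_identical(a@liveComposition, b@liveComposition)
  expect_identical(ape::write.tree(cohortTree(a)), ape::write.tree(cohortTree(b)))
  expect_false(isTRUE(all.equal(cohortTruth(a)$true_live_cells,
                                cohortTruth(c)$true_live_cells)))
})

test_that("unknown treatment labels are a configuration error", {
  expect_error(
    cohortConfig("acute_perturbation", nParticipants = 2L,
                 treatmentAssignments = c(P01 = "water", P02 = "bleach")),
    "unknown treatment")
})

test_that("identity kernels leave the live trajectory unperturbed", {
  co <- noiseFreeAcuteCohort(treatments = c("alcohol_free", "antiseptic",
                                            "water", "soda"),
                             killFactorAlcoholFree = 1,
                             killFactorAntiseptic = 1)
  tr <- cohortTruth(co)
  for (p in unique(tr$participant)) {
    live <- tr$true_live_cells[tr$participant == p]
    expect_equal(live, rep(live[1], 3))             # flat noise-free walk
    total <- tr$true_total_cells[tr$participant == p]
    expect_equal(total, live / 0.4)                 # baseline live fraction
  }
})

test_that("alcohol-free kernel kills without removing and recovers at 2 h", {
  co <- noiseFreeAcuteCohort(treatments = rep("alcohol_free", 3), n = 3L)
  tr <- cohortTruth(co)
  f <- 0.4; k <- 0.05
  for (p in unique(tr$participant)) {
    x <- tr[tr$participant == p, ]
    L1 <- x$true_live_cells[x$timepoint == "T1"]
    T1 <- x$true_total_cells[x$timepoint == "T1"]
    # independent pool arithmetic: live' = k L, relic' = relic + (1-k) L
    expect_equal(x$true_live_cells[x$timepoint == "T2"], k * L1)
    expect_equal(x$true_total_cells[x$timepoint == "T2"],
                 k * L1 + (L1 * (1 / f - 1) + (1 - k) * L1))
    lt <- x$true_live_cells[x$timepoint == "T2"] /
      x$true_total_cells[x$timepoint == "T2"]
    expect_lte(lt, 0.10)
    expect_lt(abs(x$true_total_cells[x$timepoint == "T2"] / T1 - 1), 0.01)
    expect_equal(x$true_live_cells[x$timepoint == "T3"], L1)  # full recovery
  }
})

test_that("antiseptic kernel is delayed and water/soda are null", {
  co <- noiseFreeAcuteCohort(treatments = c("antiseptic", "water", "soda"),
                             n = 3L)
  tr <- cohortTruth(co)
  anti <- tr[tr$treatment == "antiseptic", ]
  expect_equal(anti$true_live_cells[anti$timepoint == "T2"],
               anti$true_live_cells[anti$timepoint == "T1"])
  expect_equal(anti$true_live_cells[anti$timepoint == "T3"],
               0.3 * anti$true_live_cells[anti$timepoint == "T1"])
  for (tt in c("water", "soda")) {
    x <- tr[tr$treatment == tt, ]
    expect_equal(x$true_live_cells, rep(x$true_live_cells[1], 3))
    expect_equal(x$true_total_cells, rep(x$true_total_cells[1], 3))
  }
})

test_that("the waking sample carries the daily maximum and brushing removes from both pools", {
  co <- simulateCohort(cohortConfig("daily_dynamics", nParticipants = 6L,
                                    seed = 5))
  tr <- cohortTruth(co)
  for (p in unique(tr$participant)) {
    x <- tr[tr$participant == p, ]
    expect_equal(which.max(x$true_live_cells), 1L)
  }
  # with a flat walk the brushing dip is exactly the removal factor on both pools
  flat <- simulateCohort(cohortConfig("daily_dynamics", nParticipants = 2L,
                                      withinDayLoadLog10Sd = 0,
                                      baselineLoadLog10Sd = 0, seed = 5))
  x <- cohortTruth(flat)
  x1 <- x[x$participant == "P01", ]
  expect_equal(x1$true_live_cells[2], 0.3 * x1$true_live_cells[3])
  expect_equal(x1$true_total_cells[2], 0.3 * x1$true_total_cells[3])
})

test_that("daily live load fluctuates at least tenfold within a day", {
  co <- simulateCohort(cohortConfig("daily_dynamics", seed = 21))
  tr <- cohortTruth(co)
  rng <- tapply(log10(tr$true_live_cells), tr$participant,
                function(x) diff(range(x)))
  expect_gte(median(rng), 1)
})

test_that("event simulator respects pool identity, bead proportionality and emptiness", {
  tr0 <- list(record_id = "none", true_live_cells = 0, true_total_cells = 0,
              saliva_volume_ml = 1)
  acq <- acquisitionSettings(beadsAdded = 10000, sampleVolumeUl = 1000,
                             acquiredVolumeUl = 100, humanPerUl = 0,
                             doubletRate = 0, exact = TRUE)
  ev <- eventData(simulateEvents(tr0, acq, "raw", seed = 1))
  expect_true(all(ev$population %in% c("bead", "debris")))
  expect_equal(sum(ev$population == "bead"), 1000L)  # 10,000 x 0.1 fraction

  expect_error(simulateEvents(tr0, acquisitionSettings(acquiredVolumeUl = 0)),
               "positive")

  tr <- list(record_id = "x", true_live_cells = 5e7, true_total_cells = 2e8,
             saliva_volume_ml = 1)
  acq <- acquisitionSettings(acquiredVolumeUl = 1, humanPerUl = 0,
                             doubletRate = 0, exact = TRUE)
  raw <- eventData(simulateEvents(tr, acq, "raw", seed = 2))
  pma <- eventData(simulateEvents(tr, acq, "pma", seed = 2))
  nRaw <- sum(raw$population == "bacteria")
  nPma <- sum(pma$population == "bacteria")
  expect_equal(nPma / nRaw, 0.25, tolerance = 0.02)  # live / total pools
})

test_that("count simulation draws the configured mixtures", {
  co <- smallDailyCohort()
  rid <- cohortTruth(co)$record_id[1]
  expect_error(simulateCounts(co, rid, 0), "positive")

  # degenerate mixture: when live == total the raw and PMA distributions match
  co2 <- smallDailyCohort(liveFractionBaseline = 1)
  rid2 <- cohortTruth(co2)$record_id[1]
  set.seed(99); a <- simulateCounts(co2, rid2, 5000, "raw",
                                    afterMeal = FALSE,
                                    chloroplastRelAbundance = 0)
  set.seed(99); b <- simulateCounts(co2, rid2, 5000, "pma",
                                    afterMeal = FALSE,
                                    chloroplastRelAbundance = 0)
  expect_identical(a, b)

  # chloroplast contamination hits its target within binomial error
  set.seed(7)
  cts <- simulateCounts(co, rid, 10000, "raw", afterMeal = TRUE,
                        prevalenceAfterMealRaw = 1)
  frac <- cts["ASV_chloroplast"] / sum(cts)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.006) / 10000
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])

  # relic pool is tilted toward the designated dead-associated taxon
  trep <- grep("Treponema", co@taxonomy)
  expect_gt(mean(co@relicComposition[, trep] / co@liveComposition[, trep]), 2)
})

test_that("qPCR readout follows the standard-curve model", {
  set.seed(1)
  expect_equal(simulateQpcr(1, intercept = 38, noiseSd = 0), 38)
  expect_equal(simulateQpcr(10, slope = -3.3219, intercept = 38, noiseSd = 0) -
               simulateQpcr(100, slope = -3.3219, intercept = 38, noiseSd = 0),
               3.3219)
  expect_error(simulateQpcr(0), "positive")
  lad <- qpcrLadder()
  expect_length(lad, 8L)
  expect_equal(range(lad), c(1.3, 1.3e7))
})
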