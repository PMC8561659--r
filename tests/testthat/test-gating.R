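mkEvents <- function(df, id = "s") {
  new("CytometryEventTable", events = df, sampleId = id)
}

flatEvents <- function(n, FL1_A = 2000, FL1_H = 2000, FL1_W = 1000,
                       FL4_A = 10, FSC_A = 100, BSC_A = 100) {
  data.frame(FL1_A = rep(FL1_A, n), FL1_H = FL1_H, FL1_W = FL1_W,
             FL4_A = FL4_A, FSC_A = FSC_A, BSC_A = BSC_A)
}

simSample <- function(live = 1e8, total = 2e8, volume = 2,
                      seed = 1, ...) {
  tr <- list(record_id = "t", true_live_cells = live,
             true_total_cells = total, saliva_volume_ml = volume)
  acq <- acquisitionSettings(...)
  list(tab = simulateEvents(tr, acq, "raw", seed = seed), acq = acq)
}

test_that("DNA-positive gate splits events into beads, candidates and background", {
  cfg <- gatingConfig()
  ev <- mkEvents(flatEvents(10, FL1_A = 10))        # all sub-threshold
  g <- dnaPositiveGate(ev, cfg)
  expect_equal(nrow(g$candidates), 0L)
  expect_equal(nrow(g$beads), 0L)
  expect_equal(g$nSubthreshold, 10L)

  g0 <- dnaPositiveGate(ev, gatingConfig(fl1Min = 0))  # vacuous threshold
  expect_equal(nrow(g0$candidates) + nrow(g0$beads), 10L)
  expect_equal(g0$nSubthreshold, 0L)

  emptyDf <- data.frame(FL1_A = numeric(0), FL1_H = numeric(0),
                        FL1_W = numeric(0), FL4_A = numeric(0),
                        FSC_A = numeric(0), BSC_A = numeric(0))
  expect_error(mkEvents(emptyDf), "at least one")

  s <- simSample(seed = 4, beadsAdded = 10000, sampleVolumeUl = 1000,
                 acquiredVolumeUl = 100, dilutionFactor = 2e4, exact = TRUE)
  gb <- dnaPositiveGate(s$tab, cfg)
  expect_equal(nrow(gb$beads),
               sum(eventData(s$tab)$population == "bead"))
  expect_equal(nrow(gb$beads), 1000L)
})

test_that("doublet filter keeps the singlet linear trend", {
  cfg <- gatingConfig(doubletBand = 0.3)
  same <- flatEvents(20)                            # identical H/W ratios
  expect_equal(doubletFilter(same, cfg)$nDoubletsExcluded, 0L)

  two <- data.frame(FL1_A = c(1, 1), FL1_H = c(1.0, 1.01), FL1_W = c(1, 1),
                    FL4_A = 0, FSC_A = 0, BSC_A = 0)
  expect_equal(doubletFilter(two, gatingConfig(doubletBand = 0.05))$nDoubletsExcluded,
               0L)

  zw <- flatEvents(3); zw$FL1_W[2] <- 0
  expect_warning(res <- doubletFilter(zw, cfg), "zero FL1")
  expect_equal(res$nDoubletsExcluded, 1L)

  s <- simSample(seed = 5, acquiredVolumeUl = 1, doubletRate = 0.1,
                 humanPerUl = 0, exact = FALSE)
  cand <- dnaPositiveGate(s$tab, gatingConfig())$candidates
  res <- doubletFilter(cand, cfg)
  isDoubletIn <- cand$population == "doublet"
  isDoubletKept <- res$singlets$population == "doublet"
  expect_gte(1 - sum(isDoubletKept) / sum(isDoubletIn), 0.95)
  singletLost <- 1 - sum(res$singlets$population == "bacteria") /
    sum(cand$population == "bacteria")
  expect_lte(singletLost, 0.05)
})

test_that("scatter gate removes large events with inclusive thresholds", {
  cfg <- gatingConfig(fscMax = Inf, bscMax = Inf)
  df <- flatEvents(5)
  expect_equal(nrow(scatterFilter(df, cfg)$bacteria), 5L)

  atLimit <- flatEvents(4, FSC_A = 1e4, BSC_A = 1e4)
  expect_equal(nrow(scatterFilter(atLimit, gatingConfig())$bacteria), 4L)

  s <- simSample(seed = 6, acquiredVolumeUl = 1, humanPerUl = 200,
                 doubletRate = 0, exact = TRUE)
  gc <- gateEvents(s$tab, gatingConfig())
  ev <- eventData(s$tab)
  nHuman <- sum(ev$population == "human")
  # essentially no human events survive into the cell gate
  expect_lte(nCells(gc), sum(ev$population == "bacteria") + 0.01 * nHuman)
  expect_gte(gc@nLargeExcluded + gc@nDoubletsExcluded, 0.99 * nHuman)
})

test_that("gate counts partition the event total and are order-stable", {
  s <- simSample(seed = 8, acquiredVolumeUl = 1)
  gc <- gateEvents(s$tab, gatingConfig())
  expect_equal(nCells(gc) + nBeads(gc) + gc@nDoubletsExcluded +
               gc@nLargeExcluded + gc@nSubthreshold, gc@nTotal)

  ev <- eventData(s$tab)
  perm <- mkEvents(ev[rev(seq_len(nrow(ev))), ])
  gc2 <- gateEvents(perm, gatingConfig())
  expect_equal(nCells(gc2), nCells(gc))
  expect_equal(nBeads(gc2), nBeads(gc))
  expect_equal(gc2@nDoubletsExcluded, gc@nDoubletsExcluded)

  # negative control: beads + debris only, near-zero cell contamination
  neg <- simSample(live = 0, total = 0, seed = 9, humanPerUl = 0,
                   acquiredVolumeUl = 100, beadsAdded = 10000,
                   exact = TRUE)
  gcn <- gateEvents(neg$tab, gatingConfig())
  expect_lte(nCells(gcn), 10L)
})

test_that("bead calibration converts counts to absolute concentration", {
  mkGC <- function(cells, beads) new("GatedCounts", nCells = as.integer(cells),
    nBeads = as.integer(beads), nDoubletsExcluded = 0L, nLargeExcluded = 0L,
    nSubthreshold = 0L, nTotal = as.integer(cells + beads))

  expect_equal(cellsPerUlMeasured(concentration(mkGC(0, 100), 1000, 100)), 0)
  expect_equal(cellsPerUlMeasured(concentration(mkGC(50, 50), 200, 200)), 1)
  expect_error(concentration(mkGC(10, 0), 1000, 100), "unquantifiable")
  expect_error(concentration(mkGC(10, 10), 0, 100), "positive")

  # linear in nCells, inversely linear in nBeads
  base <- cellsPerUlMeasured(concentration(mkGC(100, 100), 1000, 100))
  for (k in c(2, 5, 10)) {
    expect_equal(cellsPerUlMeasured(concentration(mkGC(100 * k, 100), 1000, 100)),
                 base * k)
    expect_equal(cellsPerUlMeasured(concentration(mkGC(100, 100 * k), 1000, 100)),
                 base / k)
  }

  # closed loop at 1e5 cells/ml with >= 5000 cell events
  tr <- list(record_id = "t", true_live_cells = 1e5, true_total_cells = 1e5,
             saliva_volume_ml = 1)
  acq <- acquisitionSettings(dilutionFactor = 1, acquiredVolumeUl = 60,
                             sampleVolumeUl = 1000, beadsAdded = 1e4,
                             doubletRate = 0, humanPerUl = 0)
  tab <- simulateEvents(tr, acq, "raw", seed = 10)
  gc <- gateEvents(tab, gatingConfig())
  expect_gte(nCells(gc), 5000L)
  q <- concentration(gc, acq$beadsAdded, acq$sampleVolumeUl, acq$dilutionFactor)
  expect_equal(cellsPerMlSaliva(q), 1e5, tolerance = 0.1)
})

test_that("estimated concentration approaches truth as event depth grows", {
  tr <- list(record_id = "t", true_live_cells = 2e8, true_total_cells = 2e8,
             saliva_volume_ml = 2)
  errAt <- function(vol, seed) {
    acq <- acquisitionSettings(acquiredVolumeUl = vol, doubletRate = 0,
                               humanPerUl = 0)
    q <- concentration(gateEvents(simulateEvents(tr, acq, "raw", seed = seed)),
                       acq$beadsAdded, acq$sampleVolumeUl, acq$dilutionFactor)
    abs(cellsPerMlSaliva(q) / 1e8 - 1)
  }
  errs <- c(errAt(0.02, 21), errAt(0.5, 22), errAt(10, 23))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("glycerol dilution factor follows collection arithmetic", {
  expect_equal(glycerolDilutionFactor(2, 2, 10), 20)
  expect_equal(glycerolDilutionFactor(5, 0, 1), 1)
  expect_error(glycerolDilutionFactor(0), "positive")
  # 1.33 ml saliva on 2 ml of 40% glycerol: final glycerol fraction
  finalGlycerol <- 0.4 * 2 / (1.33 + 2)
  expect_gte(finalGlycerol, 0.08)
  expect_lte(finalGlycerol, 0.38)
})
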