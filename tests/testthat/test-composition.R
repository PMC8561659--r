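toyTable <- function() {
  m <- rbind(ASVa = c(500, 400, 2000), ASVb = c(300, 500, 2000),
             ASVc = c(199, 50, 500), ASVd = c(0, 50, 500))
  colnames(m) <- c("s1", "s2", "s3")
  featureTable(m, taxonomy = c(
    ASVa = "k__Bacteria; p__Firmicutes; g__Streptococcus",
    ASVb = "k__Bacteria; p__Firmicutes; g__Veillonella",
    ASVc = "k__Bacteria; p__Bacteroidetes; g__Prevotella",
    ASVd = "k__Bacteria; p__Cyanobacteria; c__Chloroplast; g__"))
}

test_that("depth filtering drops shallow samples with an inclusive boundary", {
  ft <- toyTable()                                  # sums 999, 1000, 5000
  expect_equal(colnames(filterMinDepth(ft, 0)), c("s1", "s2", "s3"))
  kept <- suppressMessages(filterMinDepth(ft, 1000))
  expect_equal(colnames(kept), c("s2", "s3"))
  expect_error(suppressMessages(filterMinDepth(ft, 1e6)), "all samples")
})

test_that("six forced-shallow samples leave 78 of 84 acute samples", {
  co <- simulateCohort(cohortConfig("acute_perturbation", nTaxa = 25L,
                                    seed = 13))
  meta <- cohortMetadata(co)
  rawIds <- meta$sample_id[meta$processing == "raw"]
  depths <- setNames(rep(2000L, nrow(meta)), meta$sample_id)
  depths[rawIds[1:6]] <- 500L
  ft <- simulateFeatureTable(co, depth = depths[meta$sample_id])
  raw <- ft[, rawIds]
  expect_equal(ncol(raw), 84L)
  expect_equal(ncol(suppressMessages(filterMinDepth(raw, 1000))), 78L)
})

test_that("taxonomy filtering removes organelle reads case-insensitively", {
  ft <- toyTable()
  expect_equal(nrow(filterTaxonomy(ft, "archaea")), 4L)  # no match: identity
  f2 <- filterTaxonomy(ft)
  expect_equal(nrow(f2), 3L)
  expect_equal(colSums(counts(f2)), colSums(counts(ft)) -
               counts(ft)["ASVd", ])

  co <- smallDailyCohort(afterMealTimepoints = 1:5)
  ft3 <- simulateFeatureTable(co, depth = 3000)
  filt <- filterTaxonomy(ft3)
  expect_equal(unname(chloroplastSummary(filt)$prevalence),
               rep(0, nrow(chloroplastSummary(filt))))
})

test_that("chloroplast summary stratifies prevalence and abundance", {
  ft <- toyTable()
  md <- data.frame(sample_id = colnames(ft),
                   after_meal = c(TRUE, TRUE, FALSE),
                   processing = c("raw", "raw", "raw"))
  rownames(md) <- md$sample_id
  cs <- chloroplastSummary(ft, md)
  afterMeal <- cs[cs$after_meal & cs$processing == "raw", ]
  expect_equal(afterMeal$prevalence, 0.5)           # s2 positive, s1 not
  expect_equal(afterMeal$mean_rel_abundance_positives, 50 / 1000)

  noChl <- filterTaxonomy(ft)
  expect_true(all(chloroplastSummary(noChl, md)$prevalence == 0))

  # generator: PMA arm prevalence is about a quarter of the raw arm
  co <- simulateCohort(cohortConfig("daily_dynamics", nParticipants = 20L,
                                    timepoints = paste0("T", 1:5),
                                    afterMealTimepoints = 1:5, nTaxa = 25L,
                                    seed = 17))
  cs2 <- chloroplastSummary(simulateFeatureTable(co, depth = 10000))
  praw <- cs2$prevalence[cs2$after_meal & cs2$processing == "raw"]
  ppma <- cs2$prevalence[cs2$after_meal & cs2$processing == "pma"]
  expect_gt(praw / ppma, 2.5)
  expect_lt(praw / ppma, 6.5)
})

test_that("rank collapse conserves totals and is idempotent", {
  ft <- toyTable()
  ph <- collapseRank(ft, "phylum")
  expect_equal(colSums(counts(ph)), colSums(counts(ft)))
  expect_setequal(rownames(ph), c("Firmicutes", "Bacteroidetes",
                                  "Cyanobacteria"))
  again <- collapseRank(ph, "phylum")
  expect_equal(counts(again)[rownames(ph), ], counts(ph))

  one <- featureTable(rbind(a = 1:3, b = 4:6),
                      taxonomy = c(a = "k__B; p__X; g__g1",
                                   b = "k__B; p__X; g__g2"))
  ph1 <- collapseRank(one, "phylum")
  expect_equal(nrow(ph1), 1L)
  expect_equal(unname(counts(ph1)[1, ]), unname(colSums(counts(one))))

  # generator construction: the five dominant phyla hold >99% of all reads
  co <- simulateCohort(cohortConfig("daily_dynamics", seed = 19))
  ftg <- filterTaxonomy(simulateFeatureTable(co, depth = 5000))
  phg <- collapseRank(ftg, "phylum")
  tot <- rowSums(counts(phg))
  top5 <- sum(sort(tot, decreasing = TRUE)[1:5]) / sum(tot)
  expect_gt(top5, 0.99)
})

test_that("clr transform centres logs and honours scale invariance", {
  single <- matrix(c(1, 1, 1, 1), 1, dimnames = list("s", letters[1:4]))
  expect_equal(unname(clrTransform(single, 0)[1, ]), rep(0, 4))

  m <- matrix(c(2, 5, 13), 1, dimnames = list("s", letters[1:3]))
  expect_equal(clrTransform(m, 0), clrTransform(m * 10, 0))

  v <- clrTransform(matrix(c(1, 10, 100), 1,
                           dimnames = list("s", letters[1:3])), 0)
  expect_equal(unname(v[1, ]), c(-log(10), 0, log(10)), tolerance = 1e-9)

  zero <- matrix(c(0, 0), 1)
  expect_error(clrTransform(zero), "zero-sum")
  withZero <- matrix(c(0, 5), 1)
  expect_error(clrTransform(withZero, 0), "pseudocount")
})

test_that("Aitchison distance matches hand-computed clr geometry", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1), s3 = c(1000, 2000, 3000))
  colnames(m) <- letters[1:3]
  d <- aitchisonDistance(m, pseudocount = 0)
  expect_equal(d["s1", "s1"], 0)
  expect_equal(d["s1", "s3"], 0, tolerance = 1e-12)  # scale invariance
  clr1 <- log(c(1, 2, 3)) - mean(log(c(1, 2, 3)))
  clr2 <- log(c(3, 2, 1)) - mean(log(c(3, 2, 1)))
  expect_equal(d["s1", "s2"], sqrt(sum((clr1 - clr2)^2)))
})

test_that("rarefaction hits the exact depth, is seeded, and preserves expectations", {
  ft <- toyTable()
  r1 <- suppressMessages(rarefyTable(ft, 999, seed = 4))
  expect_equal(unname(colSums(counts(r1))), rep(999, 3))
  expect_equal(counts(r1)[, "s1"], counts(ft)[, "s1"])  # already at depth

  rmin <- suppressMessages(rarefyTable(ft, 1, seed = 4))
  expect_equal(unname(colSums(counts(rmin))), rep(1, 3))

  r2 <- suppressMessages(rarefyTable(ft, 999, seed = 4))
  expect_identical(counts(r1), counts(r2))

  # expected relative abundances preserved (CLT bound over 400 draws)
  m <- matrix(c(60, 30, 10), 3, 1, dimnames = list(letters[1:3], "s"))
  fts <- featureTable(m)
  draws <- vapply(1:400, function(s)
    counts(rarefyTable(fts, 20, seed = s))[, 1], numeric(3))
  prop <- rowMeans(draws) / 20
  se <- sqrt(c(0.6, 0.3, 0.1) * c(0.4, 0.7, 0.9) / (20 * 400))
  expect_true(all(abs(prop - c(0.6, 0.3, 0.1)) < 4 * se))
})

test_that("absolute abundance joins composition with live load", {
  ft <- toyTable()
  ab <- absoluteAbundance(ft, c(s1 = 0, s2 = 1000, s3 = 2000))
  expect_equal(unname(ab[, "s1"]), rep(0, 4))
  expect_equal(unname(colSums(ab)), c(0, 1000, 2000))

  uni <- featureTable(matrix(c(5, 5, 5, 5), 4, 1,
                             dimnames = list(letters[1:4], "s")))
  expect_equal(unname(absoluteAbundance(uni, c(s = 1e6))[, 1]),
               rep(2.5e5, 4))

  # generator truth recovery within multinomial noise
  co <- smallDailyCohort(seed = 23)
  ft2 <- simulateFeatureTable(co, depth = 20000)
  meta <- cohortMetadata(co)
  pmaIds <- meta$sample_id[meta$processing == "pma"]
  tr <- cohortTruth(co)
  live <- setNames(tr[meta[pmaIds, "record_id"], "true_live_cells"], pmaIds)
  ab2 <- absoluteAbundance(ft2[, pmaIds], live)
  rid <- meta[pmaIds[1], "record_id"]
  expected <- co@liveComposition[rid, rownames(ab2)] * live[pmaIds[1]]
  big <- expected > live[pmaIds[1]] * 0.01
  expect_equal(unname(ab2[big, pmaIds[1]]), unname(expected[big]),
               tolerance = 0.15)
})
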