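test_that("scenario configs validate their parameters", {
  expect_error(scenarioConfig(u = 3), class = "dc_config_error")
  expect_error(scenarioConfig(fracSexLinked = 1.2),
               class = "dc_config_error")
  cfg <- scenarioPreset("marsupial")
  expect_equal(cfg$u, 2)
  expect_true(cfg$inactivation)
  expect_equal(attr(cfg, "focalSpecies"), "spA")
  expect_equal(attr(scenarioPreset("bird"), "focalSpecies"), "spD")
})

test_that("the dose contract yields the expected closed-form statistics", {
  # no upregulation + inactivation: halved output in both sexes
  e <- expectedStatistics(scenarioConfig(u = 1, inactivation = TRUE))
  expect_equal(unname(e$xpxx), c(0.5, 0.5))
  # two-fold upregulation in both sexes + inactivation: full restoration
  m <- expectedStatistics(scenarioConfig(u = 2, uScope = "both_sexes",
                                         inactivation = TRUE))
  expect_equal(unname(m$xpxx), c(1, 1))
  # u = 2 in both sexes, no inactivation: homogametic overshoot to 2
  o <- expectedStatistics(scenarioConfig(u = 2, uScope = "both_sexes",
                                         inactivation = FALSE))
  expect_equal(unname(o$xpxx[["hom"]]), 2)
  # partial heterogametic-only upregulation
  p <- expectedStatistics(scenarioConfig(u = 1.5,
                                         uScope = "heterogametic_only",
                                         inactivation = FALSE))
  expect_equal(unname(p$xpxx), c(0.75, 1))
  expect_equal(unname(p$mf[["XY"]]), 0.75)
  expect_equal(unname(p$mf[["ZW"]]), 1 / 0.75)
})

test_that("noise-free generation reproduces the contract exactly", {
  grid <- expand.grid(u = c(1, 1.5, 2), inact = c(TRUE, FALSE),
                      scope = c("heterogametic_only", "both_sexes"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    cfg <- scenarioConfig(u = grid$u[i], inactivation = grid$inact[i],
                          uScope = grid$scope[i], nOldFamilies = 80,
                          nRecentPerSpecies = 0, tissues = "br",
                          seed = 50 + i)
    ds <- generateDataset(cfg)
    exp <- expectedStatistics(cfg)
    anc <- inferAncestralLevels(ds$tables, ds$orthology,
                                defaultExclusionTable(cfg), "spA", "br")
    for (sx in c("M", "F")) {
      r <- xpxxRatios(ds$tables$spA, anc, ds$orthology, ds$annotation,
                      "br", sex = sx,
                      config = analysisConfig(resampleN = 10))
      want <- if (sx == "M") exp$xpxx[["het"]] else exp$xpxx[["hom"]]
      expect_equal(medianRatio(r), unname(want), tolerance = 1e-12)
      expect_equal(unname(range(geneRatios(r, log2 = FALSE))),
                   rep(unname(want), 2), tolerance = 1e-12)
    }
    mf <- mfRatios(ds$tables$spA, ds$annotation, "X", "br",
                   analysisConfig(resampleN = 10))
    expect_equal(medianRatio(mf), unname(exp$mf[["XY"]]),
                 tolerance = 1e-12)
  }
})

test_that("the ZW partial scenario mirrors the avian dose pattern", {
  cfg <- scenarioConfig(u = 1.48, uScope = "heterogametic_only",
                        inactivation = FALSE, nOldFamilies = 100,
                        nRecentPerSpecies = 0, tissues = "br", seed = 8)
  ds <- generateDataset(cfg)
  foc <- "spD"  # the ZW species of the default panel
  anc <- inferAncestralLevels(ds$tables, ds$orthology,
                              defaultExclusionTable(cfg), foc, "br")
  cfg10 <- analysisConfig(resampleN = 10)
  rF <- xpxxRatios(ds$tables[[foc]], anc, ds$orthology, ds$annotation,
                   "br", sex = "F", config = cfg10)
  rM <- xpxxRatios(ds$tables[[foc]], anc, ds$orthology, ds$annotation,
                   "br", sex = "M", config = cfg10)
  expect_equal(medianRatio(rF), 0.74, tolerance = 1e-12)
  expect_equal(medianRatio(rM), 1, tolerance = 1e-12)
  mf <- mfRatios(ds$tables[[foc]], ds$annotation, "Z", "br", cfg10)
  expect_equal(medianRatio(mf), 1 / 0.74, tolerance = 1e-12)
})

test_that("generation is deterministic and files are byte-identical", {
  cfg <- scenarioPreset("eutherian", nOldFamilies = 60,
                        nRecentPerSpecies = 10, noiseSd = 0.4, seed = 77)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(rpkm(d1$tables$spA), rpkm(d2$tables$spA))
  expect_identical(d1$ppi, d2$ppi)
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  writeDataset(d1, dirA); writeDataset(d2, dirB)
  fa <- list.files(dirA); fb <- list.files(dirB)
  expect_identical(fa, fb)
  for (f in fa)
    expect_identical(unname(tools::md5sum(file.path(dirA, f))),
                     unname(tools::md5sum(file.path(dirB, f))))

  d3 <- generateDataset(scenarioPreset("eutherian", nOldFamilies = 60,
                                       nRecentPerSpecies = 10,
                                       noiseSd = 0.4, seed = 78))
  expect_false(identical(rpkm(d3$tables$spA), rpkm(d1$tables$spA)))
})

test_that("the Poisson count layer matches the RPKM definition", {
  m <- matrix(c(0, 20, 50, 100), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lens <- c(2000, 1000)
  gc <- generateCounts(m, lens, 2e7, seed = 5)
  expect_equal(gc$counts[1, 1], 0)         # zero RPKM never yields reads
  expect_equal(dim(gc$counts), dim(m))
  # expected count for g2/s1: 50 * 1kb * 20M/1e6 = 1000; recomputed RPKM
  # concentrates around the input
  big <- matrix(20, 500, 1, dimnames = list(paste0("g", 1:500), "s1"))
  gb <- generateCounts(big, rep(1000, 500), 2e7, seed = 6)
  # expected count 400 per gene: recomputed RPKM within 10% for >= 95%
  expect_gte(mean(abs(gb$rpkm - 20) / 20 < 0.1), 0.95)
  # doubling library size doubles expected counts, RPKM stays centred
  gb2 <- generateCounts(big, rep(1000, 500), 4e7, seed = 6)
  expect_equal(mean(gb2$counts) / mean(gb$counts), 2, tolerance = 0.05)
  expect_equal(median(gb2$rpkm), 20, tolerance = 0.05)
})

test_that("planted autosomal downregulation is detectable through the PPI", {
  hits <- 0; n <- 10
  for (i in seq_len(n)) {
    # a sparse graph over a large autosome pool keeps the two interactor
    # arms mostly disjoint (an interactor of both X types carries the
    # coupled rate, which otherwise dilutes the contrast)
    cfg <- scenarioConfig(nOldFamilies = 3000, nRecentPerSpecies = 0,
                          fracSexLinked = 0.25, interactorsPerGene = 3,
                          couplingFraction = 0.13,
                          backgroundFraction = 0.06, seed = 900 + i,
                          tissues = "br")
    ds <- generateDataset(cfg)
    truth <- ds$groundTruth
    xAll <- truth$doseBySpecies$spA$sexLinkedOld
    at <- annotationTable(ds$annotation)
    auto <- at$gene_id[at$species == "spA" & at$chrom_class == "autosome"]
    sets <- buildInteractionSets(truth$droppedX, xAll, auto, ds$ppi)
    expect_gte(length(sets$type1Interactors), 60)
    expect_gte(length(sets$type2Interactors), 60)
    tab <- downregulationContingency(sets, truth$downregulatedAutosomes)
    hits <- hits + (fisherExact2x2(tab)$p < 0.05)
  }
  expect_gte(hits, 7)

  # null coupling: no signal expected (spot check, not all tiny p)
  ps <- vapply(1:5, function(i) {
    cfg <- scenarioConfig(nOldFamilies = 300, nRecentPerSpecies = 0,
                          fracSexLinked = 0.25, couplingFraction = 0.06,
                          backgroundFraction = 0.06, seed = 950 + i,
                          tissues = "br")
    ds <- generateDataset(cfg)
    truth <- ds$groundTruth
    at <- annotationTable(ds$annotation)
    auto <- at$gene_id[at$species == "spA" & at$chrom_class == "autosome"]
    sets <- buildInteractionSets(truth$droppedX,
                                 truth$doseBySpecies$spA$sexLinkedOld,
                                 auto, ds$ppi)
    fisherExact2x2(
      downregulationContingency(sets, truth$downregulatedAutosomes))$p
  }, numeric(1))
  expect_gt(max(ps), 0.05)

  # no edges, no interactors
  cfg0 <- scenarioConfig(nOldFamilies = 50, nRecentPerSpecies = 0,
                         interactorsPerGene = 0, tissues = "br", seed = 1)
  ds0 <- generateDataset(cfg0)
  expect_equal(nrow(ds0$ppi), 0L)
})
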