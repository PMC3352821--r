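cfgFast <- analysisConfig(resampleN = 50, seed = 11)

test_that("M:F ratios are autosomally normalized", {
  # identical male and female columns: median M:F is exactly 1
  eq <- toyMFTable(xMF = cbind(c(4, 8), c(4, 8)),
                   autoMF = cbind(1:20, 1:20))
  r <- mfRatios(eq$table, eq$annotation, "X", "br", cfgFast)
  expect_equal(medianRatio(r), 1)

  # X genes (M,F) = (4,8) and (8,8), autosomal M:F median 1:
  # per-gene log2 ratios -1 and 0, median log2 -0.5
  toy <- toyMFTable(xMF = rbind(c(4, 8), c(8, 8)),
                    autoMF = cbind(1:21, 1:21))
  r2 <- mfRatios(toy$table, toy$annotation, "X", "br", cfgFast)
  expect_equal(sort(unname(geneRatios(r2))), c(-1, 0))
  expect_equal(medianRatio(r2, log2 = TRUE), -0.5)

  # a global two-fold male shift (X and autosomes) cancels out
  shifted <- toy
  m <- rpkm(toy$table); m[, "sM"] <- m[, "sM"] * 2
  tbl <- ExpressionTable(m, sampleInfo(toy$table))
  r3 <- mfRatios(tbl, toy$annotation, "X", "br", cfgFast)
  expect_equal(geneRatios(r3), geneRatios(r2))

  # genes silent in one sex are excluded before ratios are formed
  toy4 <- toyMFTable(xMF = rbind(c(0, 5), c(8, 8)),
                     autoMF = cbind(1:21, 1:21))
  r4 <- mfRatios(toy4$table, toy4$annotation, "X", "br", cfgFast)
  expect_equal(length(geneRatios(r4)), 1L)

  expect_error(
    mfRatios(eq$table, eq$annotation, "Z", "br", cfgFast),
    class = "dc_empty_set")
})

test_that("X:AA ratio is the ratio of medians and robust to outliers", {
  mk <- function(xvals, avals) {
    m <- cbind(s1 = c(xvals, avals))
    rownames(m) <- c(paste0("x", seq_along(xvals)),
                     paste0("a", seq_along(avals)))
    et <- ExpressionTable(m, data.frame(species = "hsa", tissue = "br",
                                        sex = "M", replicate = 1L))
    anno <- GeneAnnotation(data.frame(
      gene_id = rownames(m), species = "hsa",
      chromosome = c(rep("X", length(xvals)),
                     rep("chr1", length(avals))),
      chrom_class = c(rep("X", length(xvals)),
                      rep("autosome", length(avals))),
      region_class = NA_character_, age_class = NA_character_))
    list(et = et, anno = anno)
  }
  a <- mk(1:9, 1:9)
  expect_equal(medianRatio(
    xaaRatio(a$et, a$anno, "br", config = cfgFast, chromClass = "X")), 1)

  b <- mk((1:9) / 2, 1:9)
  expect_equal(medianRatio(
    xaaRatio(b$et, b$anno, "br", config = cfgFast, chromClass = "X")), 0.5)

  # median X {1,2,3,4,100} = 3 against autosomal median 4: ratio 0.75,
  # untouched by the outlier 100
  c3 <- mk(c(1, 2, 3, 4, 100), c(2, 3, 4, 5, 6))
  expect_equal(medianRatio(
    xaaRatio(c3$et, c3$anno, "br", config = cfgFast, chromClass = "X")),
    0.75)
})

test_that("ancestral levels are outgroup medians excluding homologous systems", {
  toy <- toyOrthology(nFam = 3, sexLinkedFam = 3, sexSpecies = "spB")
  mk <- function(sp, vals) {
    ids <- paste0("g", 1:3, "_", sp)
    m <- cbind(s1 = vals, s2 = vals)
    rownames(m) <- ids
    ExpressionTable(m, data.frame(species = sp, tissue = "br",
                                  sex = c("M", "F"), replicate = 1L))
  }
  tables <- list(spA = mk("spA", c(5, 8, 2)),
                 spB = mk("spB", c(10, 8, 3)),
                 spC = mk("spC", c(10, 32, 4)))
  excl <- list(spA = c("spB", "spC"))
  anc <- inferAncestralLevels(tables, toy$orthology, excl, "spA", "br")
  lev <- ancestralLevels(anc)
  expect_equal(unname(lev[["fam1"]]), 10)        # {10, 10}
  expect_equal(unname(lev[["fam2"]]), 20)        # {8, 32} -> linear median
  expect_true(is.na(lev[["fam3"]]))              # sex-linked in outgroup spB
  expect_error(inferAncestralLevels(tables, toy$orthology,
                                    list(spA = character()), "spA", "br"),
               class = "dc_config_error")
})

test_that("current-to-ancestral ratios apply double autosomal normalization", {
  # 4 autosomal families (background) + 1 X family in the focal species
  toy <- toyOrthology(nFam = 5, sexLinkedFam = 5, sexSpecies = "spA")
  mkFocal <- function(vals) {
    ids <- paste0("g", 1:5, "_spA")
    m <- cbind(s1 = vals)
    rownames(m) <- ids
    ExpressionTable(m, data.frame(species = "spA", tissue = "br",
                                  sex = "M", replicate = 1L))
  }
  mkOut <- function(sp, vals) {
    ids <- paste0("g", 1:5, "_", sp)
    m <- cbind(s1 = vals)
    rownames(m) <- ids
    ExpressionTable(m, data.frame(species = sp, tissue = "br",
                                  sex = "F", replicate = 1L))
  }
  # current: X gene at 5, autosomal background median 10;
  # ancestral: X ortholog 10, background 10 -> ratio (5/10)/(10/10) = 0.5
  tables <- list(spA = mkFocal(c(8, 10, 10, 12, 5)),
                 spB = mkOut("spB", c(8, 10, 10, 12, 10)),
                 spC = mkOut("spC", c(8, 10, 10, 12, 10)))
  anc <- inferAncestralLevels(tables, toy$orthology,
                              list(spA = c("spB", "spC")), "spA", "br")
  r <- xpxxRatios(tables$spA, anc, toy$orthology, toy$annotation, "br",
                  config = cfgFast)
  expect_equal(unname(geneRatios(r, log2 = FALSE)), 0.5)

  # current equal to ancestral everywhere: ratio exactly 1
  tables2 <- tables; tables2$spA <- mkFocal(c(8, 10, 10, 12, 10))
  r2 <- xpxxRatios(tables2$spA, anc, toy$orthology, toy$annotation, "br",
                   config = cfgFast)
  expect_equal(medianRatio(r2), 1)
})

test_that("X:pXX equals current X:AA over ancestral X:AA on shared gene sets", {
  cfg <- scenarioPreset("marsupial", nOldFamilies = 150,
                        nRecentPerSpecies = 0, tissues = "br", seed = 5)
  ds <- generateDataset(cfg)
  foc <- attr(cfg, "focalSpecies")
  anc <- inferAncestralLevels(ds$tables, ds$orthology,
                              defaultExclusionTable(cfg), foc, "br")
  r <- xpxxRatios(ds$tables[[foc]], anc, ds$orthology, ds$annotation,
                  "br", sex = "M", config = cfgFast)
  # reconstruct the two X:AA sides over the identical family sets
  fam <- familyTable(ds$orthology)
  ids <- fam[[foc]]
  lev <- ancestralLevels(anc)[as.character(fam$family_id)]
  cur <- rpkm(ds$tables[[foc]])[, paste0(foc, "_br_M_1")]
  xSel <- ids %in% names(geneRatios(r))
  bgSel <- autosomalInAll(ds$orthology) & !is.na(lev)
  curXAA <- median(cur[ids[xSel]]) / median(cur[ids[bgSel]])
  ancXAA <- median(lev[xSel]) / median(lev[bgSel])
  # identity holds on noise-free data where per-gene ratios are constant
  expect_equal(medianRatio(r), curXAA / ancXAA, tolerance = 1e-12)
})

test_that("autosomal control ratio sits at 1 for conserved expression", {
  cfg <- scenarioPreset("eutherian", nOldFamilies = 200,
                        nRecentPerSpecies = 0, tissues = "br", seed = 3)
  ds <- generateDataset(cfg)
  anc <- inferAncestralLevels(ds$tables, ds$orthology,
                              defaultExclusionTable(cfg), "spA", "br")
  ctrl <- autosomalControlRatio(ds$tables$spA, anc, ds$orthology,
                                ds$annotation, "br", sex = "M",
                                config = cfgFast, nResample = 50)
  expect_equal(ctrl$median, 1)
  expect_equal(unname(diff(ctrl$range)), 0)

  # 10% multiplicative noise keeps the control within [0.9, 1.1]
  hits <- 0
  for (i in 1:10) {
    cfgN <- scenarioPreset("eutherian", nOldFamilies = 300,
                           nRecentPerSpecies = 0, tissues = "br",
                           noiseSd = log2(1.1), seed = 100 + i)
    dsN <- generateDataset(cfgN)
    ancN <- inferAncestralLevels(dsN$tables, dsN$orthology,
                                 defaultExclusionTable(cfgN), "spA", "br")
    ctrlN <- autosomalControlRatio(dsN$tables$spA, ancN, dsN$orthology,
                                   dsN$annotation, "br", sex = "M",
                                   config = cfgFast, nResample = 50)
    hits <- hits + (ctrlN$median >= 0.9 && ctrlN$median <= 1.1)
  }
  expect_gte(hits, 9)
})

test_that("subsampling intervals are seeded, central and degenerate-safe", {
  expect_equal(unclass(resampleInterval(rep(3.5, 20), seed = 1))[1:2],
               c(3.5, 3.5))
  expect_equal(resampleInterval(5), structure(c(5, 5),
               statistics = rep(5, 100)))
  v <- rnorm(200)
  expect_identical(resampleInterval(v, seed = 9),
                   resampleInterval(v, seed = 9))
  iv <- resampleInterval(1:1000, coverage = 0.95, seed = 2)
  expect_lt(iv[1], 500.5); expect_gt(iv[2], 500.5)
  ivNarrow <- resampleInterval(1:1000, fraction = 0.95, coverage = 0.95,
                               seed = 2)
  expect_lt(diff(unclass(ivNarrow)[1:2]), diff(unclass(iv)[1:2]))
})

test_that("reference-value Wilcoxon tests follow signed-rank conventions", {
  # symmetric ratios around the reference: no detectable location shift
  tv <- testVsReference(c(-1, 1, -2, 2), reference = 1)
  expect_gte(tv[["p"]], 0.9)
  # all ratios exactly at the reference: empty test, p = 1 by convention
  tv2 <- testVsReference(rep(-1, 50), reference = 0.5)
  expect_equal(tv2[["p"]], 1)
  # clear shift is detected and Bonferroni correction multiplies
  tv3 <- testVsReference(rnorm(60, mean = -1, sd = 0.2), reference = 1,
                         familySize = 10)
  expect_lt(tv3[["p"]], 1e-6)
  expect_equal(tv3[["p_adj"]], min(1, tv3[["p"]] * 10))
})

test_that("Wilcoxon and KS type-I error is calibrated at the 5% level", {
  set.seed(2024)
  rejW <- rejK <- 0; nrep <- 1000
  for (i in seq_len(nrep)) {
    x <- rnorm(40, mean = 0, sd = 0.5)      # null: median at reference 1
    if (testVsReference(x, reference = 1)[["p"]] < 0.05) rejW <- rejW + 1
    if (i <= 500) {
      a <- rnorm(60); b <- rnorm(60)
      if (compareDistributions(a, b)[["p"]] < 0.05) rejK <- rejK + 1
    }
  }
  expect_gte(rejW / nrep, 0.03); expect_lte(rejW / nrep, 0.07)
  expect_gte(rejK / 500, 0.02); expect_lte(rejK / 500, 0.08)
})

test_that("KS distribution comparison flags shifted distributions", {
  eq <- compareDistributions(1:50, 1:50)
  expect_equal(eq[["D"]], 0); expect_equal(eq[["p"]], 1)
  dis <- compareDistributions(1:50, 51:100)
  expect_equal(dis[["D"]], 1)
  set.seed(7)
  hits <- sum(vapply(1:20, function(i)
    compareDistributions(rnorm(200), rnorm(200, 0.5))[["p"]] < 0.05,
    logical(1)))
  expect_gte(hits, 18)
})

test_that("chromosome heterogeneity test behaves under null and shift", {
  mk <- function(vals, chrom) {
    ids <- paste0("g", seq_along(vals))
    m <- cbind(s1 = vals)
    rownames(m) <- ids
    et <- ExpressionTable(m, data.frame(species = "hsa", tissue = "br",
                                        sex = "M", replicate = 1L))
    anno <- GeneAnnotation(data.frame(
      gene_id = ids, species = "hsa", chromosome = chrom,
      chrom_class = "autosome", region_class = NA_character_,
      age_class = NA_character_))
    list(et = et, anno = anno)
  }
  # identical value multisets on two chromosomes: no heterogeneity
  two <- mk(c(1:10, 1:10), rep(c("chr1", "chr2"), each = 10))
  expect_equal(chromosomeHeterogeneity(two$et, two$anno, "br"), 1)

  # a two-fold shifted chromosome is detected
  set.seed(31)
  hits <- sum(vapply(1:10, function(i) {
    v <- c(2^rnorm(200, 3, 1), 2^rnorm(200, 4, 1))
    d <- mk(v, rep(c("chr1", "chr2"), each = 200))
    chromosomeHeterogeneity(d$et, d$anno, "br") < 0.01
  }, logical(1)))
  expect_gte(hits, 9)

  one <- mk(1:10, rep("chr1", 10))
  expect_error(chromosomeHeterogeneity(one$et, one$anno, "br"),
               class = "dc_config_error")
})

test_that("refined heterogametic subset selects compensated genes", {
  mkRes <- function(vals) {
    new("RatioResult", ratios = log2(vals), median = median(log2(vals)),
        interval = range(log2(vals)), coverage = 0.95,
        tests = data.frame(), metadata = list())
  }
  het <- setNames(rep(1, 5), paste0("g", 1:5))
  hom <- setNames(rep(2, 5), paste0("g", 1:5))
  out <- refinedHeterogameticSubset(mkRes(het), mkRes(hom))
  expect_equal(out$n, 5L); expect_equal(out$median, 2)

  out2 <- refinedHeterogameticSubset(mkRes(het * 0.5), mkRes(hom))
  expect_equal(out2$n, 0L); expect_true(is.na(out2$median))

  # partial upregulation restricted to a subset: the compensated genes'
  # homogametic ratios sit between 1 and 2
  het3 <- setNames(c(rep(1, 10), rep(0.5, 10)), paste0("g", 1:20))
  hom3 <- setNames(c(rep(1.4, 10), rep(1, 10)), paste0("g", 1:20))
  out3 <- refinedHeterogameticSubset(mkRes(het3), mkRes(hom3))
  expect_equal(out3$n, 10L)
  expect_gt(out3$median, 1); expect_lt(out3$median, 2)
})

test_that("ratio statistics are invariant to gene order and global scaling", {
  toy <- toyMFTable(xMF = rbind(c(4, 8), c(8, 8), c(2, 2)),
                    autoMF = cbind(1:21, sample(1:21)))
  r <- mfRatios(toy$table, toy$annotation, "X", "br", cfgFast)
  perm <- sample(nrow(rpkm(toy$table)))
  tbl2 <- ExpressionTable(rpkm(toy$table)[perm, ], sampleInfo(toy$table))
  r2 <- mfRatios(tbl2, toy$annotation, "X", "br", cfgFast)
  expect_equal(medianRatio(r2), medianRatio(r))
  expect_equal(geneRatios(r2)[names(geneRatios(r))], geneRatios(r))
})
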