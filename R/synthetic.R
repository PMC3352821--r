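## Synthetic multi-species expression datasets with a known dosage ground
## truth. The dose contract is multiplicative: a sex-linked gene's
## expression is its ancestral (diploid, two-allele) baseline times
## (active alleles / 2) times the per-allele upregulation factor u in the
## sexes covered by the scope. Hence, relative to the ancestral level:
##   heterogametic sex (one allele):      u / 2
##   homogametic sex, no inactivation:    uHom            (two alleles)
##   homogametic sex, inactivation:       uHom / 2        (one active allele)
## with uHom = u when scope = "both_sexes", else 1.

#' Scenario configuration for the synthetic-data generator
#'
#' Defines the study conditions under which a dataset is generated:
#' the species panel with sex systems and sex-chromosome homology groups,
#' gene counts, the dosage parameters (per-allele upregulation u, its
#' scope, inactivation in the homogametic sex), planted testis specificity,
#' noise levels, and the autosomal-downregulation coupling for the PPI
#' layer.
#'
#' @param species data.frame with columns \code{species}, \code{system}
#'   (\code{"XY"}, \code{"ZW"} or \code{"none"}) and \code{homology}
#'   (homology-group label; species in the same group share sex-linked
#'   families and cannot serve as each other's outgroups). The default is a
#'   four-species amniote panel: two therians (shared X), platypus and
#'   chicken (partially homologous X5/Z).
#' @param nOldFamilies number of 1:1 families spanning the panel.
#' @param nRecentPerSpecies species-private recent genes.
#' @param fracSexLinked fraction of old families sex-linked per homology
#'   group (and of recent genes per species with a sex system).
#' @param u per-allele upregulation factor, in [1, 2].
#' @param uScope \code{"heterogametic_only"} or \code{"both_sexes"}.
#' @param inactivation silence one allele in the homogametic sex.
#' @param msciTestisFactor extra expression reduction of sex-linked genes
#'   in heterogametic-sex testis (1 = off), mimicking meiotic sex
#'   chromosome inactivation.
#' @param testisFracSexRecent fraction of recent sex-linked genes planted
#'   testis-specific.
#' @param testisFracBackground background testis-specific fraction
#'   (recent autosomal genes).
#' @param noiseSd biological noise sd (log2 units), multiplicative on RPKM.
#' @param speciesSd cross-species baseline divergence sd (log2 units).
#' @param baselineMean,baselineSd log2 RPKM law for tissue baselines.
#' @param tissues tissue codes simulated.
#' @param replicates samples per (species, tissue, sex).
#' @param withCounts also sample a Poisson read-count layer.
#' @param librarySize reads per sample for the count layer.
#' @param droppedFraction fraction of old sex-linked genes flagged as
#'   having dropped in expression (inputs to the interaction analysis).
#' @param couplingFraction downregulation probability for autosomal
#'   interactors of dropped sex-linked genes.
#' @param backgroundFraction background autosomal downregulation
#'   probability.
#' @param interactorsPerGene mean PPI partners per sex-linked gene.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a list with class \code{"ScenarioConfig"}.
#' @export
scenarioConfig <- function(species = data.frame(
                             species = c("spA", "spB", "spC", "spD"),
                             system = c("XY", "XY", "XY", "ZW"),
                             homology = c("x", "x", "z", "z")),
                           nOldFamilies = 500, nRecentPerSpecies = 100,
                           fracSexLinked = 0.15,
                           u = 1,
                           uScope = c("heterogametic_only", "both_sexes"),
                           inactivation = FALSE, msciTestisFactor = 1,
                           testisFracSexRecent = 0.4,
                           testisFracBackground = 0.1,
                           noiseSd = 0, speciesSd = 0,
                           baselineMean = 3, baselineSd = 2,
                           tissues = c("br", "cb", "ht", "kd", "lv", "ts"),
                           replicates = 1, withCounts = FALSE,
                           librarySize = 3e7,
                           droppedFraction = 0.3,
                           couplingFraction = 0.13,
                           backgroundFraction = 0.06,
                           interactorsPerGene = 4, seed = 1L) {
  uScope <- match.arg(uScope)
  if (u < 1 || u > 2)
    dcStop("dc_config_error", "u must lie in [1, 2]")
  fr <- c(fracSexLinked, testisFracSexRecent, testisFracBackground,
          droppedFraction, couplingFraction, backgroundFraction)
  if (any(fr < 0 | fr > 1))
    dcStop("dc_config_error", "fractions must lie in [0, 1]")
  if (anyDuplicated(species$species))
    dcStop("dc_config_error", "duplicate species codes")
  bad <- species$system != "none" & is.na(species$homology)
  if (any(bad))
    dcStop("dc_config_error",
           "species with a sex system need a homology group")
  structure(as.list(environment()), class = "ScenarioConfig")
}

#' Preset scenarios
#'
#' Ready-made configurations mirroring the four amniote
#' dosage-compensation states: \code{"eutherian"} (no upregulation, XCI:
#' expected current-to-ancestral dose 0.5 in both sexes),
#' \code{"marsupial"} (two-fold upregulation in both sexes plus XCI: dose
#' 1 in both sexes), \code{"monotreme"} and \code{"bird"} (partial,
#' heterogametic-only upregulation u = 1.48, no inactivation: dose 0.74 in
#' the heterogametic and 1 in the homogametic sex).
#'
#' @param scenario preset name.
#' @param ... overrides passed to [scenarioConfig()].
#' @return a \code{ScenarioConfig}.
#' @export
scenarioPreset <- function(scenario = c("eutherian", "marsupial",
                                        "monotreme", "bird"), ...) {
  scenario <- match.arg(scenario)
  args <- switch(scenario,
    eutherian = list(u = 1, uScope = "heterogametic_only",
                     inactivation = TRUE),
    marsupial = list(u = 2, uScope = "both_sexes", inactivation = TRUE),
    monotreme = list(u = 1.48, uScope = "heterogametic_only",
                     inactivation = FALSE),
    bird = list(u = 1.48, uScope = "heterogametic_only",
                inactivation = FALSE))
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(scenarioConfig, args)
  ## focal species within the default panel: therian scenarios sit in the
  ## "x" homology group, monotreme on the XY member of "z" (X5-like), bird
  ## on the ZW member of "z"
  attr(cfg, "focalSpecies") <- switch(scenario,
    eutherian = , marsupial = cfg$species$species[cfg$species$homology == "x"][1],
    monotreme = cfg$species$species[cfg$species$homology == "z" &
                                      cfg$species$system == "XY"][1],
    bird = cfg$species$species[cfg$species$homology == "z" &
                                 cfg$species$system == "ZW"][1])
  cfg
}

#' Dose factors implied by a scenario
#'
#' @param config a \code{ScenarioConfig} (or the u/uScope/inactivation
#'   values directly).
#' @return named numeric \code{c(het, hom)}: expected current-to-ancestral
#'   expression dose of a sex-linked gene in each sex.
#' @export
doseFactors <- function(config) {
  u <- config$u
  uHom <- if (config$uScope == "both_sexes") u else 1
  act <- if (config$inactivation) 1 else 2
  c(het = u / 2, hom = uHom * act / 2)
}

#' Closed-form expected summary statistics for a scenario
#'
#' The test oracles implied by the dose contract: per sex system, the
#' expected current-to-ancestral ratio (X:pXX) per sex, the expected X:AA
#' ratio per sex, and the expected autosomally normalized M:F ratio
#' (males are heterogametic under XY, homogametic under ZW).
#'
#' @param config a \code{ScenarioConfig}.
#' @return list with \code{dose} (het/hom), \code{xpxx} (het/hom),
#'   \code{xaa} (het/hom) and \code{mf} (named by system, linear scale).
#' @export
expectedStatistics <- function(config) {
  d <- doseFactors(config)
  list(dose = d,
       xpxx = d,
       xaa = d,
       mf = c(XY = unname(d["het"] / d["hom"]),
              ZW = unname(d["hom"] / d["het"])))
}

#' Poisson read-count layer
#'
#' Samples read counts at the expectation implied by the RPKM definition
#' (reads = RPKM x length[kb] x librarySize[millions]) and returns both the
#' counts and the RPKM values recomputed from them.
#'
#' @param rpkm numeric matrix of RPKM values (genes x samples).
#' @param lengths gene lengths in bp, one per row.
#' @param librarySize mapped reads per sample (scalar or per column).
#' @param seed integer seed.
#' @return list with \code{counts} and \code{rpkm} matrices.
#' @export
generateCounts <- function(rpkm, lengths, librarySize, seed = 1L) {
  if (any(lengths <= 0) || any(librarySize <= 0))
    dcStop("dc_config_error", "lengths and library size must be positive")
  scale <- outer(lengths / 1000,
                 rep(librarySize, length.out = ncol(rpkm)) / 1e6)
  mu <- rpkm * scale
  counts <- .withSeed(seed, function()
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu),
           dimnames = dimnames(rpkm)))
  list(counts = counts, rpkm = counts / scale)
}

#' Generate a complete synthetic dataset
#'
#' Builds annotation, 1:1 orthology, per-species expression tables, a PPI
#' network and the ground truth for one scenario. Tissue baselines are
#' drawn per family (log-normal); orthologs share the family baseline with
#' a per-species log-normal perturbation; sex-linked genes' expression is
#' multiplied by the dose contract; species-private recent genes are added
#' with elevated testis-specific planting on the sex chromosomes;
#' multiplicative biological noise and an optional Poisson read-count
#' layer yield the final RPKM values. Deterministic given the seed.
#'
#' @param config a \code{ScenarioConfig}.
#' @return list with \code{tables} (named list of
#'   \linkS4class{ExpressionTable}), \code{annotation}, \code{orthology},
#'   \code{ppi}, \code{groundTruth} and \code{config}.
#' @export
generateDataset <- function(config) {
  .withSeed(config$seed, function() .generateDataset(config))
}

.generateDataset <- function(config) {
  sp <- config$species
  nOld <- config$nOldFamilies
  tissues <- config$tissues
  nT <- length(tissues)
  d <- doseFactors(config)
  groups <- unique(sp$homology[sp$system != "none"])
  nSexPerGroup <- round(config$fracSexLinked * nOld)
  if (length(groups) * nSexPerGroup > nOld)
    dcStop("dc_config_error",
           "too many sex-linked families for the family count")
  ## family -> homology group carrying it (NA = autosomal everywhere)
  famGroup <- rep(NA_character_, nOld)
  at <- 1L
  for (g in groups) {
    if (nSexPerGroup > 0) {
      famGroup[at:(at + nSexPerGroup - 1L)] <- g
      at <- at + nSexPerGroup
    }
  }
  ## per-family per-tissue ancestral baselines (log2 RPKM)
  base <- matrix(rnorm(nOld * nT, config$baselineMean, config$baselineSd),
                 nOld, nT, dimnames = list(NULL, tissues))
  sexChromName <- function(system, homology)
    switch(homology, x = "X", z = if (system == "ZW") "Z" else "X5",
           paste0("sex_", homology))
  sexChromClass <- function(system, homology)
    switch(homology, x = "X", z = if (system == "ZW") "Z" else "X5", "X")
  hetSex <- function(system) if (system == "ZW") "F" else "M"

  annoRows <- list(); tables <- list(); truthDose <- list()
  testisPlanted <- list()
  famTab <- data.frame(family_id = paste0("fam", seq_len(nOld)))

  for (i in seq_len(nrow(sp))) {
    s <- sp$species[i]; system <- sp$system[i]; hg <- sp$homology[i]
    oldIds <- paste0(s, "_g", seq_len(nOld))
    famTab[[s]] <- oldIds
    sexLinkedOld <- !is.na(famGroup) & system != "none" &
      famGroup == hg
    ## recent, species-private genes
    nRec <- config$nRecentPerSpecies
    recIds <- if (nRec > 0) paste0(s, "_r", seq_len(nRec)) else character()
    recSex <- if (system == "none") rep(FALSE, nRec) else
      seq_len(nRec) <= round(config$fracSexLinked * nRec)
    recTestis <- rep(FALSE, nRec)
    if (nRec > 0) {
      pr <- ifelse(recSex, config$testisFracSexRecent,
                   config$testisFracBackground)
      recTestis <- runif(nRec) < pr
    }
    sexLinked <- c(sexLinkedOld, recSex)
    ids <- c(oldIds, recIds)
    nG <- length(ids)
    ## per-gene per-tissue expected log2 level, before dose
    spOff <- if (config$speciesSd > 0)
      rnorm(nOld, 0, config$speciesSd) else numeric(nOld)
    lv <- rbind(base + spOff,
                matrix(rnorm(nRec * nT, config$baselineMean,
                             config$baselineSd), nRec, nT))
    if (any(recTestis) && "ts" %in% tissues) {
      ridx <- nOld + which(recTestis)
      other <- setdiff(tissues, "ts")
      lv[ridx, other] <- lv[ridx, "ts"] - log2(20)
    }
    ## samples
    sexes <- c("M", "F")
    si <- expand.grid(replicate = seq_len(config$replicates),
                      sex = sexes, tissue = tissues,
                      stringsAsFactors = FALSE)
    si <- data.frame(species = s, tissue = si$tissue, sex = si$sex,
                     replicate = si$replicate)
    m <- matrix(0, nG, nrow(si))
    het <- hetSex(system)
    for (j in seq_len(nrow(si))) {
      mu <- lv[, si$tissue[j]]
      dose <- rep(1, nG)
      if (system != "none") {
        dj <- if (si$sex[j] == het) d["het"] else d["hom"]
        if (si$sex[j] == het && si$tissue[j] == "ts")
          dj <- dj * config$msciTestisFactor
        dose[sexLinked] <- dj
      }
      noise <- if (config$noiseSd > 0) rnorm(nG, 0, config$noiseSd) else 0
      m[, j] <- 2^(mu + noise) * dose
    }
    rownames(m) <- ids
    colnames(m) <- paste(s, si$tissue, si$sex, si$replicate, sep = "_")
    lengths <- NULL; counts <- NULL
    if (config$withCounts) {
      lengths <- round(runif(nG, 500, 5000))
      gc <- generateCounts(m, lengths, config$librarySize,
                           seed = sample.int(.Machine$integer.max, 1))
      counts <- gc$counts
      m <- gc$rpkm
    }
    tables[[s]] <- ExpressionTable(m, si, counts = counts,
                                   lengths = lengths)
    chromName <- rep(paste0("chr", 1 + (seq_len(nG) %% 19)), 1)
    chromClass <- rep("autosome", nG)
    if (system != "none") {
      chromName[sexLinked] <- sexChromName(system, hg)
      chromClass[sexLinked] <- sexChromClass(system, hg)
    }
    annoRows[[s]] <- data.frame(
      gene_id = ids, species = s, chromosome = chromName,
      chrom_class = chromClass, region_class = NA_character_,
      age_class = c(rep("old", nOld), rep("recent", nRec)))
    truthDose[[s]] <- list(system = system,
                           sexLinkedOld = oldIds[sexLinkedOld],
                           sexLinkedRecent = recIds[recSex],
                           het = het,
                           dose = c(het = unname(d["het"]),
                                    hom = unname(d["hom"])))
    testisPlanted[[s]] <- c(recIds[recTestis])
  }
  annotation <- GeneAnnotation(do.call(rbind, annoRows))
  orthology <- OrthologFamilySet(famTab, annotation)
  truth <- list(doseBySpecies = truthDose,
                famGroup = famGroup,
                testisSpecific = testisPlanted,
                expected = expectedStatistics(config))
  ppi <- generatePPI(config, truth, annotation)
  truth$droppedX <- attr(ppi, "droppedX")
  truth$downregulatedAutosomes <- attr(ppi, "downregulatedAutosomes")
  list(tables = tables, annotation = annotation, orthology = orthology,
       ppi = ppi, groundTruth = truth, config = config)
}

#' Generate the synthetic PPI layer
#'
#' A random bipartite-flavoured graph: each sex-linked old gene of the
#' first sex-system species receives a Poisson number of distinct
#' autosomal partners. A fraction of the sex-linked genes is flagged
#' "dropped"; their autosomal interactors are downregulated with the
#' coupling fraction, all other autosomal genes with the background
#' fraction.
#'
#' @param config a \code{ScenarioConfig}.
#' @param truth ground-truth list from the generator (needs
#'   \code{doseBySpecies}).
#' @param annotation the dataset's \linkS4class{GeneAnnotation}.
#' @return PPI edge data.frame with attributes \code{"droppedX"} and
#'   \code{"downregulatedAutosomes"}.
#' @export
generatePPI <- function(config, truth, annotation) {
  sp <- config$species
  focal <- sp$species[sp$system != "none"][1]
  if (is.na(focal)) {
    out <- data.frame(gene_a = character(), gene_b = character())
    attr(out, "droppedX") <- character()
    attr(out, "downregulatedAutosomes") <- character()
    return(out)
  }
  xGenes <- truth$doseBySpecies[[focal]]$sexLinkedOld
  at <- annotationTable(annotation)
  auto <- at$gene_id[at$species == focal & at$chrom_class == "autosome" &
                       at$age_class == "old"]
  nDrop <- round(config$droppedFraction * length(xGenes))
  dropped <- if (nDrop > 0) sample(xGenes, nDrop) else character()
  edges <- list()
  for (g in xGenes) {
    k <- min(length(auto), rpois(1, config$interactorsPerGene))
    if (k > 0)
      edges[[g]] <- data.frame(gene_a = g, gene_b = sample(auto, k))
  }
  ppi <- if (length(edges)) makePPI(do.call(rbind, edges)) else
    data.frame(gene_a = character(), gene_b = character())
  droppedNb <- unique(c(ppi$gene_b[ppi$gene_a %in% dropped],
                        ppi$gene_a[ppi$gene_b %in% dropped]))
  droppedNb <- intersect(droppedNb, auto)
  pDown <- ifelse(auto %in% droppedNb, config$couplingFraction,
                  config$backgroundFraction)
  down <- auto[runif(length(auto)) < pDown]
  attr(ppi, "droppedX") <- dropped
  attr(ppi, "downregulatedAutosomes") <- down
  ppi
}

#' Default outgroup table for a scenario
#'
#' Valid outgroups for a focal species are the panel species whose sex
#' chromosomes are non-homologous: species in a different homology group,
#' or without a sex system.
#'
#' @param config a \code{ScenarioConfig}.
#' @return named list: species -> character vector of outgroup species.
#' @export
defaultExclusionTable <- function(config) {
  sp <- config$species
  out <- lapply(seq_len(nrow(sp)), function(i) {
    hi <- sp$homology[i]
    ok <- vapply(seq_len(nrow(sp)), function(j) {
      if (j == i) return(FALSE)
      if (sp$system[j] == "none") return(TRUE)
      hj <- sp$homology[j]
      is.na(hi) || is.na(hj) || hi != hj
    }, logical(1))
    sp$species[ok]
  })
  names(out) <- sp$species
  out
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits the expression table and sample metadata per species, the
#' annotation, orthology and PPI tables, and the ground truth as JSON.
#'
#' @param dataset output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (s in names(dataset$tables)) {
    tp <- file.path(dir, paste0("expression_", s, ".tsv"))
    mp <- file.path(dir, paste0("samples_", s, ".tsv"))
    writeExpression(dataset$tables[[s]], tp, mp)
    paths <- c(paths, tp, mp)
  }
  ap <- file.path(dir, "annotation.tsv")
  writeAnnotation(dataset$annotation, ap)
  op <- file.path(dir, "orthology.tsv")
  writeOrthology(dataset$orthology, op)
  pp <- file.path(dir, "ppi.tsv")
  writePPI(dataset$ppi, pp)
  gp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(dataset$groundTruth[c("famGroup", "expected")],
                       gp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, ap, op, pp, gp))
}
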