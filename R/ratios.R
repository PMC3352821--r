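## Ratio statistics: M:F, current X(Z):AA, current-to-ancestral X(Z):pXX,
## with subsampling confidence intervals and reference-value tests.

## Run code under a local seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

## Resolve a chromosome-class label (X, XCR, XAR, X1-nonPAR, X1-PAR, X1, X5,
## Z, autosome) to gene ids of one species.
.genesOfClass <- function(annotation, species, chromClass) {
  t <- annotationTable(annotation)
  t <- t[t$species == species, , drop = FALSE]
  sel <- switch(chromClass,
    "XCR" = t$chrom_class == "X" & !is.na(t$region_class) &
      t$region_class == "XCR",
    "XAR" = t$chrom_class == "X" & !is.na(t$region_class) &
      t$region_class == "XAR",
    "X1-nonPAR" = t$chrom_class == "X1" & !is.na(t$region_class) &
      t$region_class == "nonPAR",
    "X1-PAR" = t$chrom_class == "X1" & !is.na(t$region_class) &
      t$region_class == "PAR",
    "sex_linked" = t$chrom_class != "autosome" &
      !(!is.na(t$region_class) & t$region_class == "PAR"),
    t$chrom_class == chromClass)
  t$gene_id[sel]
}

## Per-gene value over the samples matching (tissue, sex): median across
## replicates; also returns the expressed indicator intersected over those
## samples under the configured mode.
.tissueValues <- function(table, tissue, sex = NULL,
                          mode = "rpkm_gt0") {
  si <- sampleInfo(table)
  idx <- which(si$tissue == tissue &
                 (is.null(sex) | (!is.na(si$sex) & si$sex %in% sex)))
  if (!length(idx))
    dcStop("dc_no_sample",
           paste("no sample for tissue", tissue,
                 if (!is.null(sex)) paste("sex", paste(sex, collapse = "/"))))
  m <- rpkm(table)[, idx, drop = FALSE]
  expr <- filterExpressed(table, mode)[, idx, drop = FALSE]
  list(value = apply(m, 1, median),
       expressed = apply(expr, 1, all))
}

#' Subsampling interval for a median (or other statistic)
#'
#' Draws \code{n} without-replacement subsamples of size
#' \code{ceiling(fraction * N)}, computes the statistic on each, and returns
#' the central \code{coverage} quantile interval of the \code{n} statistics.
#' With a single value the interval degenerates to \code{[v, v]}.
#'
#' @param values numeric vector.
#' @param n number of subsamples (default 100).
#' @param fraction subsample fraction (default 0.8).
#' @param coverage central interval coverage (default 0.95).
#' @param seed integer seed; the interval is reproducible given the seed.
#' @param statistic function applied to each subsample (default
#'   \code{median}).
#' @return numeric length-2 \code{c(low, high)}; attribute
#'   \code{"statistics"} carries the n resampled statistics.
#' @export
resampleInterval <- function(values, n = 100, fraction = 0.8,
                             coverage = 0.95, seed = 1L,
                             statistic = median) {
  if (!length(values)) dcStop("dc_empty_set", "no values to resample")
  if (coverage <= 0 || coverage >= 1)
    dcStop("dc_config_error", "coverage must be in (0, 1)")
  N <- length(values)
  if (N == 1) {
    out <- c(values, values)
    attr(out, "statistics") <- rep(values, n)
    return(out)
  }
  k <- ceiling(fraction * N)
  stats <- .withSeed(seed, function() {
    vapply(seq_len(n),
           function(i) statistic(values[sample.int(N, k)]), numeric(1))
  })
  alpha <- (1 - coverage) / 2
  out <- unname(quantile(stats, c(alpha, 1 - alpha)))
  attr(out, "statistics") <- stats
  out
}

#' One-sample Wilcoxon signed-rank test against a reference ratio
#'
#' Tests whether log2 ratios deviate from \code{log2(reference)}
#' (two-sided). Zero differences are dropped (signed-rank convention); an
#' empty test after dropping yields p = 1. The exact null is used for
#' n <= 25 without ties, otherwise the normal approximation with continuity
#' correction. The corrected p applies the configured method at the given
#' family size.
#'
#' @param log2Ratios numeric vector of per-gene log2 ratios.
#' @param reference the reference ratio on the linear scale (e.g. 0.5, 1, 2).
#' @param correction \code{"bonferroni"} or \code{"bh"}.
#' @param familySize total number of tests in the correction family.
#' @return named numeric \code{c(p, p_adj)}.
#' @export
testVsReference <- function(log2Ratios, reference,
                            correction = c("bonferroni", "bh"),
                            familySize = 1L) {
  correction <- match.arg(correction)
  mu <- log2(reference)
  d <- log2Ratios[is.finite(log2Ratios)] - mu
  d <- d[d != 0]
  if (!length(d)) {
    p <- 1
  } else {
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    p <- suppressWarnings(
      wilcox.test(d, mu = 0, alternative = "two.sided", exact = exact,
                  correct = TRUE)$p.value)
  }
  method <- if (correction == "bh") "BH" else "bonferroni"
  c(p = p, p_adj = p.adjust(p, method = method, n = max(familySize, 1L)))
}

#' Two-sample Kolmogorov-Smirnov comparison of expression distributions
#'
#' @param a,b numeric vectors (non-empty).
#' @param correction \code{"bonferroni"} or \code{"bh"}.
#' @param familySize correction family size.
#' @return named numeric \code{c(D, p, p_adj)} (asymptotic two-sided p).
#' @export
compareDistributions <- function(a, b, correction = c("bh", "bonferroni"),
                                 familySize = 1L) {
  correction <- match.arg(correction)
  if (!length(a) || !length(b))
    dcStop("dc_empty_set", "both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided",
                                 exact = FALSE))
  method <- if (correction == "bh") "BH" else "bonferroni"
  c(D = unname(kt$statistic), p = kt$p.value,
    p_adj = p.adjust(kt$p.value, method = method, n = max(familySize, 1L)))
}

.referenceTestTable <- function(log2Ratios, config, familySize) {
  do.call(rbind, lapply(config$referenceValues, function(ref) {
    tv <- testVsReference(log2Ratios, ref, correction = config$correction,
                          familySize = familySize)
    data.frame(reference = ref, p = tv[["p"]], p_adj = tv[["p_adj"]])
  }))
}

.ratioResult <- function(log2Ratios, config, metadata, familySize = 1L) {
  if (!length(log2Ratios))
    dcStop("dc_empty_set", "no genes left after filtering")
  iv <- resampleInterval(log2Ratios, n = config$resampleN,
                         fraction = config$resampleFraction,
                         coverage = config$coverage, seed = config$seed)
  new("RatioResult", ratios = log2Ratios, median = median(log2Ratios),
      interval = as.numeric(iv), coverage = config$coverage,
      tests = .referenceTestTable(log2Ratios, config, familySize),
      metadata = metadata)
}

#' Male-to-female expression ratios on a sex chromosome
#'
#' Computes per-gene log2(M/F) ratios for genes expressed in both sexes of
#' a tissue, normalizes each by subtracting the median autosomal log2(M/F)
#' of the same tissue (no global sex bias is expected for autosomes), and
#' summarizes genes of the requested chromosome class with a subsampling
#' interval and Wilcoxon tests against the reference ratios.
#'
#' @param table an \linkS4class{ExpressionTable} for one species.
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param chromClass chromosome class of interest: \code{"X"}, \code{"XCR"},
#'   \code{"XAR"}, \code{"X1-nonPAR"}, \code{"X5"}, \code{"Z"}, or
#'   \code{"sex_linked"}.
#' @param tissue tissue code.
#' @param config an [analysisConfig()].
#' @param familySize multiple-testing family size for the reference tests.
#' @return a \linkS4class{RatioResult} (ratios on the log2 scale, already
#'   autosomally normalized).
#' @export
mfRatios <- function(table, annotation, chromClass, tissue,
                     config = analysisConfig(), familySize = 1L) {
  species <- sampleInfo(table)$species[1]
  M <- .tissueValues(table, tissue, "M", config$expressedMode)
  F_ <- .tissueValues(table, tissue, "F", config$expressedMode)
  ok <- M$expressed & F_$expressed
  lr <- log2(M$value / F_$value)
  auto <- intersect(.genesOfClass(annotation, species, "autosome"),
                    names(lr)[ok])
  if (!length(auto))
    dcStop("dc_empty_set", "no expressed autosomal genes for normalization")
  lr <- lr - median(lr[auto])
  sel <- intersect(.genesOfClass(annotation, species, chromClass),
                   names(lr)[ok])
  if (!length(sel))
    dcStop("dc_empty_set",
           paste("no expressed", chromClass, "genes in", species, tissue))
  .ratioResult(lr[sel], config,
               list(species = species, tissue = tissue,
                    chromClass = chromClass, statistic = "M:F"),
               familySize)
}

#' Current X(Z)-to-autosome expression ratio
#'
#' The ratio of the median expression of expressed sex-chromosome genes to
#' the median expression of expressed autosomal genes in a tissue. Per-gene
#' values stored in the result are log2(x / median(autosomes)), so their
#' median is the log2 X:AA ratio. The interval resamples both gene sets
#' jointly. Under \code{geneMode = "conserved_1to1"} the X set is restricted
#' to genes in families spanning all species and the autosomal set to
#' families autosomal in every species.
#'
#' @inheritParams mfRatios
#' @param geneMode \code{"all_expressed"} or \code{"conserved_1to1"}.
#' @param orthology an \linkS4class{OrthologFamilySet}, required for
#'   \code{conserved_1to1}.
#' @param sex optional sex restriction for the samples used.
#' @return a \linkS4class{RatioResult}.
#' @export
xaaRatio <- function(table, annotation, tissue,
                     geneMode = c("all_expressed", "conserved_1to1"),
                     config = analysisConfig(), chromClass = "sex_linked",
                     orthology = NULL, sex = NULL, familySize = 1L) {
  geneMode <- match.arg(geneMode)
  species <- sampleInfo(table)$species[1]
  tv <- .tissueValues(table, tissue, sex, config$expressedMode)
  v <- tv$value[tv$expressed]
  xGenes <- intersect(.genesOfClass(annotation, species, chromClass),
                      names(v))
  aGenes <- intersect(.genesOfClass(annotation, species, "autosome"),
                      names(v))
  if (geneMode == "conserved_1to1") {
    if (is.null(orthology))
      dcStop("dc_config_error", "conserved_1to1 mode requires an orthology")
    fam <- familyTable(orthology)
    full <- rep(TRUE, nrow(fam))
    for (s in familySpecies(orthology)) full <- full & !is.na(fam[[s]])
    xGenes <- intersect(xGenes, fam[[species]][full])
    aGenes <- intersect(aGenes,
                        fam[[species]][full & autosomalInAll(orthology)])
  }
  if (!length(xGenes))
    dcStop("dc_empty_set", "no expressed sex-linked genes after filtering")
  if (!length(aGenes))
    dcStop("dc_empty_set", "no expressed autosomal genes after filtering")
  aMed <- median(v[aGenes])
  lr <- log2(v[xGenes] / aMed)
  ## joint resampling of both gene sets for the interval
  nX <- length(xGenes); nA <- length(aGenes)
  kX <- ceiling(config$resampleFraction * nX)
  kA <- ceiling(config$resampleFraction * nA)
  stats <- .withSeed(config$seed, function() {
    vapply(seq_len(config$resampleN), function(i) {
      log2(median(v[xGenes][sample.int(nX, kX)]) /
             median(v[aGenes][sample.int(nA, kA)]))
    }, numeric(1))
  })
  alpha <- (1 - config$coverage) / 2
  iv <- unname(quantile(stats, c(alpha, 1 - alpha)))
  new("RatioResult", ratios = lr, median = median(lr),
      interval = as.numeric(iv), coverage = config$coverage,
      tests = .referenceTestTable(lr, config, familySize),
      metadata = list(species = species, tissue = tissue,
                      chromClass = chromClass, geneMode = geneMode,
                      statistic = "X:AA"))
}

#' Infer ancestral (proto-sex-chromosome) expression levels
#'
#' For each 1:1 family, estimates the ancestral expression level of the
#' focal species' gene as the median, across valid outgroup species (those
#' with non-homologous sex chromosomes, per the exclusion table), of the
#' ortholog's expression in the matched tissue (median over that species'
#' samples, both sexes pooled — the gene is autosomal there, so sexes are
#' interchangeable). Families whose member is sex-linked in any used
#' outgroup are excluded; families expressed (> 0) in no outgroup get
#' \code{NA} (missing, not zero). Medians across outgroups are taken on the
#' linear RPKM scale.
#'
#' @param tables named list of \linkS4class{ExpressionTable} by species.
#' @param orthology an \linkS4class{OrthologFamilySet}.
#' @param exclusionTable named list: focal species -> character vector of
#'   valid outgroup species.
#' @param focalSpecies focal species code.
#' @param tissue tissue code matched in the outgroups.
#' @return an \linkS4class{AncestralEstimate}.
#' @export
inferAncestralLevels <- function(tables, orthology, exclusionTable,
                                 focalSpecies, tissue) {
  outs <- intersect(exclusionTable[[focalSpecies]], names(tables))
  if (!length(outs))
    dcStop("dc_config_error",
           paste("no valid outgroup with expression data for", focalSpecies))
  fam <- familyTable(orthology)
  fid <- as.character(fam$family_id)
  sexIn <- sexLinkedIn(orthology)
  ## per-outgroup per-family expression (linear RPKM), NA when absent/zero
  og <- matrix(NA_real_, nrow(fam), length(outs),
               dimnames = list(fid, outs))
  for (s in outs) {
    tv <- .tissueValues(tables[[s]], tissue, sex = NULL)
    idx <- match(fam[[s]], names(tv$value))
    og[, s] <- ifelse(is.na(idx), NA, tv$value[idx])
  }
  og[!is.na(og) & og == 0] <- NA  # expressed means > 0 in that outgroup
  excl <- vapply(sexIn[fid],
                 function(sp) length(intersect(sp, outs)) > 0, logical(1))
  lev <- apply(og, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) median(r) else NA_real_
  })
  lev[excl] <- NA_real_
  new("AncestralEstimate", levels = lev, outgroups = outs,
      tissue = tissue, focalSpecies = focalSpecies)
}

## Shared machinery for current-to-ancestral ratios: returns per-family
## log2 of (current/curBG) / (ancestral/ancBG) for the requested focal
## genes, plus the backgrounds.
.currentToAncestral <- function(table, ancestral, orthology, annotation,
                                tissue, sex, config, focalGenes) {
  species <- sampleInfo(table)$species[1]
  tv <- .tissueValues(table, tissue, sex, config$expressedMode)
  fam <- familyTable(orthology)
  fid <- as.character(fam$family_id)
  focalIds <- fam[[species]]
  anc <- ancestralLevels(ancestral)[fid]
  ## autosomal-in-all-species families expressed in the focal species
  bgSel <- autosomalInAll(orthology) & !is.na(focalIds) &
    focalIds %in% names(tv$value)[tv$expressed]
  curBGVals <- tv$value[focalIds[bgSel]]
  ancBGVals <- anc[bgSel]
  ancBGVals <- ancBGVals[!is.na(ancBGVals)]
  if (!length(curBGVals) || !length(ancBGVals))
    dcStop("dc_empty_set", "autosomal background is empty")
  curBG <- median(curBGVals)
  ancBG <- median(ancBGVals)
  sel <- !is.na(focalIds) & focalIds %in% focalGenes &
    focalIds %in% names(tv$value)[tv$expressed] &
    !is.na(anc) & anc > 0
  lr <- log2((tv$value[focalIds[sel]] / curBG) / (anc[sel] / ancBG))
  names(lr) <- focalIds[sel]
  list(ratios = lr, curBG = curBG, ancBG = ancBG, species = species)
}

#' Current-to-ancestral X(Z) expression ratios (X:pXX)
#'
#' For each sex-chromosome gene expressed on both the current X(Z) and the
#' proto-X(Z), forms the ratio of its current expression (normalized by the
#' median current expression of 1:1 families autosomal in all species) to
#' its ancestral expression (normalized by the median ancestral level of
#' the same family set). A ratio of 0.5 indicates uncompensated single-copy
#' expression; 1 indicates full restoration of the ancestral output.
#'
#' @inheritParams mfRatios
#' @param ancestral an \linkS4class{AncestralEstimate} for the same focal
#'   species and tissue.
#' @param orthology an \linkS4class{OrthologFamilySet}.
#' @param sex sex of the focal samples (\code{"M"}, \code{"F"} or NULL for
#'   both).
#' @return a \linkS4class{RatioResult}.
#' @export
xpxxRatios <- function(table, ancestral, orthology, annotation, tissue,
                       sex = NULL, config = analysisConfig(),
                       chromClass = "sex_linked", familySize = 1L) {
  species <- sampleInfo(table)$species[1]
  focalGenes <- .genesOfClass(annotation, species, chromClass)
  ca <- .currentToAncestral(table, ancestral, orthology, annotation,
                            tissue, sex, config, focalGenes)
  .ratioResult(ca$ratios, config,
               list(species = species, tissue = tissue,
                    chromClass = chromClass, sex = sex,
                    statistic = "X:pXX"), familySize)
}

#' Autosomal control for the current-to-ancestral comparison
#'
#' Resamples, among 1:1 families autosomal in all species, sets of as many
#' genes as there are sex-linked genes, computes each set's median
#' current-to-ancestral ratio (both sides normalized by the non-sampled
#' autosomal genes), and reports the median of the resampled medians with a
#' central 90% range. Conserved autosomal expression puts this control at 1.
#'
#' @inheritParams xpxxRatios
#' @param nGenes number of genes per resampled set (the sex-linked gene
#'   count); defaults to the number of expressed sex-linked genes.
#' @param nResample number of resampled sets (default 100).
#' @param coverage central range coverage (default 0.9).
#' @return list with \code{median}, \code{range} (length 2) and
#'   \code{medians} (all resampled medians), on the linear scale.
#' @export
autosomalControlRatio <- function(table, ancestral, orthology, annotation,
                                  tissue, sex = NULL,
                                  config = analysisConfig(),
                                  nGenes = NULL, nResample = 100,
                                  coverage = 0.9) {
  species <- sampleInfo(table)$species[1]
  tv <- .tissueValues(table, tissue, sex, config$expressedMode)
  fam <- familyTable(orthology)
  focalIds <- fam[[species]]
  anc <- ancestralLevels(ancestral)[as.character(fam$family_id)]
  ok <- autosomalInAll(orthology) & !is.na(focalIds) &
    focalIds %in% names(tv$value)[tv$expressed] & !is.na(anc) & anc > 0
  cur <- tv$value[focalIds[ok]]
  ancv <- anc[ok]
  N <- length(cur)
  if (!N) dcStop("dc_empty_set", "no usable autosomal families")
  if (is.null(nGenes)) {
    sl <- .genesOfClass(annotation, species, "sex_linked")
    nGenes <- max(1L, length(intersect(sl, names(tv$value)[tv$expressed])))
  }
  nGenes <- min(nGenes, N - 1L)
  if (nGenes < 1)
    dcStop("dc_config_error", "too few autosomal families to resample")
  meds <- .withSeed(config$seed, function() {
    vapply(seq_len(nResample), function(i) {
      idx <- sample.int(N, nGenes)
      curBG <- median(cur[-idx]); ancBG <- median(ancv[-idx])
      median((cur[idx] / curBG) / (ancv[idx] / ancBG))
    }, numeric(1))
  })
  alpha <- (1 - coverage) / 2
  list(median = median(meds),
       range = unname(quantile(meds, c(alpha, 1 - alpha))),
       medians = meds)
}

#' Kruskal-Wallis test of between-chromosome expression heterogeneity
#'
#' Tests whether expressed genes' expression levels differ across
#' chromosomes in a tissue (consensus expression per gene, all samples of
#' the tissue pooled).
#'
#' @inheritParams mfRatios
#' @return the Kruskal-Wallis p-value.
#' @export
chromosomeHeterogeneity <- function(table, annotation, tissue) {
  species <- sampleInfo(table)$species[1]
  tv <- .tissueValues(table, tissue)
  v <- tv$value[tv$expressed]
  at <- annotationTable(annotation)
  at <- at[at$species == species, , drop = FALSE]
  chrom <- setNames(at$chromosome, at$gene_id)[names(v)]
  keep <- !is.na(chrom)
  v <- v[keep]; chrom <- chrom[keep]
  if (length(unique(chrom)) < 2)
    dcStop("dc_config_error",
           "heterogeneity test needs >= 2 chromosomes with expressed genes")
  kruskal.test(v, factor(chrom))$p.value
}

#' Homogametic-sex upregulation for genes compensated in the heterogametic sex
#'
#' Selects the genes whose heterogametic-sex current-to-ancestral ratio lies
#' inside the window (default 0.71-1.41, i.e. within half a log2 unit of
#' full compensation) and returns the median homogametic-sex ratio over
#' that subset — a probe of whether upregulation is sex-specific.
#'
#' @param hetResult,homResult \linkS4class{RatioResult}s for the
#'   heterogametic and homogametic sex, sharing gene ids.
#' @param window linear-scale inclusion window for the heterogametic ratio;
#'   the stricter alternative \code{c(0.81, 1.23)} is also meaningful.
#' @return list with \code{median} (linear homogametic ratio; NA when the
#'   subset is empty), \code{n}, and \code{genes}.
#' @export
refinedHeterogameticSubset <- function(hetResult, homResult,
                                       window = c(0.71, 1.41)) {
  het <- geneRatios(hetResult, log2 = FALSE)
  hom <- geneRatios(homResult, log2 = FALSE)
  shared <- intersect(names(het), names(hom))
  sel <- shared[het[shared] >= window[1] & het[shared] <= window[2]]
  if (!length(sel))
    return(list(median = NA_real_, n = 0L, genes = character()))
  list(median = median(hom[sel]), n = length(sel), genes = sel)
}
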