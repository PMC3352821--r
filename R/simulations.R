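## Supporting simulations: read-sampling technical noise and the effect of
## expression thresholds on X:AA ratios; plus the intrachromosomal
## duplication-rate arithmetic.

#' Read-sampling noise simulation
#'
#' Emulates the stochastic allocation of sequencing reads to genes: a
#' design of \code{nGenes} hypothetical genes with expected read coverages
#' \code{coverages} (default 1..600, totalling 180,300 reads) receives
#' \code{total} reads per replicate, allocated multinomially with
#' probabilities proportional to expected coverage. Per gene and replicate
#' the percent deviation \code{(|t - s| / t) * 100} between theoretical (t)
#' and simulated (s) counts is computed; per gene, the median over
#' replicates is reported. Low-coverage genes show large deviations
#' (roughly 67.45 / sqrt(t) percent, the Poisson closed form); deviation
#' shrinks with coverage.
#'
#' @param nGenes number of genes in the design.
#' @param coverages expected read coverage per gene (all > 0; must sum to
#'   \code{total}).
#' @param total total reads allocated per replicate.
#' @param reps number of replicates.
#' @param seed integer seed; output is reproducible given the seed.
#' @return list with \code{coverage} (the design grid),
#'   \code{medianVariation} (percent, per design point) and the simulation
#'   parameters.
#' @export
simulateReadSampling <- function(nGenes = 600, coverages = seq_len(nGenes),
                                 total = sum(coverages), reps = 1000,
                                 seed = 1L) {
  if (length(coverages) != nGenes)
    dcStop("dc_config_error", "coverages must have one value per gene")
  if (any(coverages <= 0))
    dcStop("dc_config_error",
           "zero expected coverage is not allowed (division by t)")
  if (sum(coverages) != total)
    dcStop("dc_config_error", "coverages must sum to the read total")
  if (reps < 1) dcStop("dc_config_error", "need at least one replicate")
  s <- .withSeed(seed, function()
    rmultinom(reps, size = total, prob = coverages / total))
  dev <- abs(s - coverages) / coverages * 100
  medVar <- apply(dev, 1, median)
  list(coverage = coverages, medianVariation = unname(medVar),
       nGenes = nGenes, total = total, reps = reps, seed = seed)
}

#' Look up median variation at given coverages
#'
#' Returns the simulated median percent variation at the requested
#' coverages (nearest design point; the default design has unit spacing so
#' no interpolation is needed).
#'
#' @param result output of [simulateReadSampling()].
#' @param coverages coverages of interest, within the design range.
#' @return numeric vector of median percent variations.
#' @export
variationAt <- function(result, coverages) {
  rng <- range(result$coverage)
  if (any(coverages < rng[1]) || any(coverages > rng[2]))
    dcStop("dc_config_error", "coverage outside the simulated design range")
  idx <- vapply(coverages,
                function(t) which.min(abs(result$coverage - t)), 1L)
  result$medianVariation[idx]
}

#' Expression-threshold effect on X:AA ratios
#'
#' Simulates how rising expressed-gene thresholds bias X:AA ratios.
#' Autosomal expression is drawn normal on the log2 scale (given median and
#' sd); the X1 set follows the same law (nX draws), and the X2 set is X1
#' with a uniform two-fold (or \code{fold}-fold) reduction. Per threshold
#' tau (linear RPKM scale) the X:AA ratio is the median of X values above
#' tau divided by the median of autosomal values above tau, on the linear
#' scale. X1:AA stays near 1 at all thresholds, while X2:AA starts near
#' 1/fold and climbs towards 1 as the threshold censors the shifted
#' distribution — the artefact that inflates X:AA estimates under stringent
#' expression cutoffs.
#'
#' @param aaMedian,aaSd median and standard deviation of autosomal log2
#'   expression.
#' @param nA,nX number of autosomal and X-linked genes drawn per replicate.
#' @param fold expression reduction factor applied to the X2 set.
#' @param thresholds ascending expression thresholds (linear RPKM scale).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return list with per-threshold matrices of medians and central bands:
#'   \code{x1} and \code{x2}, each a data.frame with columns
#'   \code{threshold}, \code{median}, \code{low}, \code{high} (band
#'   coverage 90%); ratios where a threshold excluded all genes are NA.
#' @export
simulateThresholdEffect <- function(aaMedian, aaSd, nA, nX, fold = 2,
                                    thresholds, reps = 1000, seed = 1L) {
  if (nA < 1 || nX < 1)
    dcStop("dc_config_error", "need at least one gene per set")
  if (is.unsorted(thresholds))
    dcStop("dc_config_error", "thresholds must be ascending")
  ratioAt <- function(x, aa, tau) {
    xk <- x[x > tau]; ak <- aa[aa > tau]
    if (!length(xk) || !length(ak)) return(NA_real_)
    median(xk) / median(ak)
  }
  nT <- length(thresholds)
  r1 <- matrix(NA_real_, reps, nT)
  r2 <- matrix(NA_real_, reps, nT)
  .withSeed(seed, function() {
    for (i in seq_len(reps)) {
      aa <- 2^rnorm(nA, aaMedian, aaSd)
      x1 <- 2^rnorm(nX, aaMedian, aaSd)
      x2 <- x1 / fold
      for (j in seq_len(nT)) {
        r1[i, j] <<- ratioAt(x1, aa, thresholds[j])
        r2[i, j] <<- ratioAt(x2, aa, thresholds[j])
      }
    }
  })
  summarize <- function(r) {
    data.frame(threshold = thresholds,
               median = apply(r, 2, median, na.rm = TRUE),
               low = apply(r, 2, quantile, 0.05, na.rm = TRUE),
               high = apply(r, 2, quantile, 0.95, na.rm = TRUE))
  }
  list(x1 = summarize(r1), x2 = summarize(r2),
       params = list(aaMedian = aaMedian, aaSd = aaSd, nA = nA, nX = nX,
                     fold = fold, reps = reps, seed = seed))
}

#' Branch-wise intrachromosomal duplication rate ratio
#'
#' Classifies paralogy groups on a branch as predominantly X-linked or
#' predominantly autosomal by the majority rule (> 50% of member genes on
#' one chromosome, the duplications being intrachromosomal), and computes
#' the per-gene duplication rate ratio
#' \code{(X groups / nXGenes) / (autosomal groups / nAutoGenes)} plus the
#' ratio of median protein identities between X and autosomal groups.
#'
#' @param paralogyTable data.frame with columns \code{group_id},
#'   \code{branch}, \code{gene_id}, \code{chromosome} and \code{identity}
#'   (percent protein identity, one value per member pair row).
#' @param branch branch label to analyse.
#' @param nXGenes,nAutoGenes gene counts on the current X and autosomes,
#'   for normalization.
#' @param xChromosome chromosome name counting as X (default "X").
#' @return list with \code{rateRatio} (Inf flagged when no autosomal group
#'   exists on the branch), \code{identityRatio}, \code{nXGroups},
#'   \code{nAutoGroups}.
#' @export
duplicationRateRatio <- function(paralogyTable, branch, nXGenes, nAutoGenes,
                                 xChromosome = "X") {
  if (nXGenes <= 0 || nAutoGenes <= 0)
    dcStop("dc_config_error", "gene counts must be positive")
  pt <- paralogyTable[paralogyTable$branch == branch, , drop = FALSE]
  if (!nrow(pt))
    dcStop("dc_config_error", paste("branch", branch, "not present"))
  groups <- split(pt, pt$group_id)
  major <- vapply(groups, function(g) {
    tab <- table(g$chromosome)
    chrom <- names(tab)[which.max(tab)]
    if (max(tab) / sum(tab) > 0.5) chrom else NA_character_
  }, character(1))
  isX <- !is.na(major) & major == xChromosome
  isA <- !is.na(major) & major != xChromosome
  nX <- sum(isX); nA <- sum(isA)
  rate <- if (nA == 0) Inf else (nX / nXGenes) / (nA / nAutoGenes)
  ## one identity per group (median over its pairs), then median over groups
  idMed <- function(sel) {
    v <- vapply(groups[sel], function(g) median(g$identity), numeric(1))
    if (length(v)) median(v) else NA_real_
  }
  idX <- idMed(isX); idA <- idMed(isA)
  list(rateRatio = rate,
       identityRatio = if (is.na(idX) || is.na(idA) || idA == 0)
         NA_real_ else idX / idA,
       nXGroups = nX, nAutoGroups = nA)
}
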