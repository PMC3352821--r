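## X-autosome protein-interaction analysis: partitions X-linked genes into
## those whose expression dropped after sex chromosome origination (type 1)
## and the rest (type 2), collects their autosomal protein-interaction
## partners, and tests whether downregulation is enriched among type-1
## partners.

#' Build the two X-interactor gene sets
#'
#' Type-1 interactors are autosomal genes adjacent (in the PPI network) to
#' any downregulated X-linked gene; type-2 interactors are those adjacent
#' to any other X-linked gene. An autosomal gene adjacent to both kinds of
#' X gene appears in both sets.
#'
#' @param xDownregulated X-linked genes whose expression dropped; must be a
#'   subset of \code{xUniverse}.
#' @param xUniverse all X-linked genes in the analysis universe.
#' @param autosomalUniverse all autosomal genes in the analysis universe.
#' @param ppi PPI edge data.frame (\code{gene_a}, \code{gene_b}), as from
#'   [readPPI()] or [makePPI()].
#' @return list with \code{type1X}, \code{type2X}, \code{type1Interactors},
#'   \code{type2Interactors}.
#' @export
buildInteractionSets <- function(xDownregulated, xUniverse,
                                 autosomalUniverse, ppi) {
  bad <- setdiff(xDownregulated, xUniverse)
  if (length(bad))
    dcStop("dc_unresolved_gene",
           paste("downregulated X genes absent from universe:",
                 paste(head(bad, 5), collapse = ", ")))
  type1X <- xDownregulated
  type2X <- setdiff(xUniverse, xDownregulated)
  neighbours <- function(xset) {
    hitA <- ppi$gene_a %in% xset
    hitB <- ppi$gene_b %in% xset
    nb <- unique(c(ppi$gene_b[hitA], ppi$gene_a[hitB]))
    intersect(nb, autosomalUniverse)
  }
  list(type1X = type1X, type2X = type2X,
       type1Interactors = neighbours(type1X),
       type2Interactors = neighbours(type2X))
}

#' Contingency table of interactor downregulation
#'
#' Crosses the two interactor sets with the autosomal downregulation call:
#' row 1 counts type-1 interactors that are / are not downregulated, row 2
#' the same for type-2 interactors.
#'
#' @param sets output of [buildInteractionSets()].
#' @param autosomalDownregulated downregulated autosomal genes.
#' @return 2x2 integer matrix with informative dimnames; attribute
#'   \code{"percentages"} holds the per-row percentage of downregulated
#'   interactors.
#' @export
downregulationContingency <- function(sets, autosomalDownregulated) {
  r1 <- c(sum(sets$type1Interactors %in% autosomalDownregulated),
          sum(!(sets$type1Interactors %in% autosomalDownregulated)))
  r2 <- c(sum(sets$type2Interactors %in% autosomalDownregulated),
          sum(!(sets$type2Interactors %in% autosomalDownregulated)))
  tab <- matrix(as.integer(c(r1, r2)), 2, 2, byrow = TRUE,
                dimnames = list(c("X decreased", "X other"),
                                c("down", "not down")))
  attr(tab, "percentages") <- contingencyPercentages(tab)
  tab
}

#' Row percentages of a 2x2 contingency table
#'
#' @param tab 2x2 count matrix.
#' @return numeric vector: percentage of the first column within each row,
#'   rounded to one decimal.
#' @export
contingencyPercentages <- function(tab) {
  round(100 * tab[, 1] / rowSums(tab), 1)
}

#' Exact two-sided Fisher test on a 2x2 table
#'
#' Conditional on the margins, the first cell follows a hypergeometric
#' distribution; the two-sided p sums the probabilities of all tables whose
#' probability does not exceed that of the observed table (the conventional
#' exact definition). The sample odds ratio ad/bc is reported; a zero
#' margin yields p = 1 with an undefined (NA) odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with \code{oddsRatio} and \code{p}.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    dcStop("dc_config_error", "need a 2x2 table of non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m == 0 || n == 0 || k == 0 || b + d == 0)
    return(list(oddsRatio = NA_real_, p = 1))
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  ## relative tolerance guards against ties lost to floating point
  p <- min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf else NA_real_
  list(oddsRatio = or, p = p)
}

#' Hypergeometric enrichment of X-linked genes in a transcription module
#'
#' Given a module of \code{moduleSize} genes drawn from a universe with
#' \code{xCount} X-linked genes, the expected X count is
#' \code{moduleSize * xCount / universeSize} and the upper-tail p is
#' \code{P(K >= observed)} under the hypergeometric null.
#'
#' @param moduleSize number of genes in the module.
#' @param universeSize number of genes in the universe (e.g. the 1:1 family
#'   count).
#' @param xCountInUniverse number of X-linked genes in the universe.
#' @param observedX observed X-linked genes in the module.
#' @return list with \code{expected} and \code{p}.
#' @export
moduleXEnrichment <- function(moduleSize, universeSize, xCountInUniverse,
                              observedX) {
  if (observedX > moduleSize || xCountInUniverse > universeSize ||
      moduleSize > universeSize || any(c(moduleSize, universeSize,
                                         xCountInUniverse, observedX) < 0))
    dcStop("dc_config_error", "inconsistent enrichment counts")
  expected <- moduleSize * xCountInUniverse / universeSize
  p <- phyper(observedX - 1, xCountInUniverse,
              universeSize - xCountInUniverse, moduleSize,
              lower.tail = FALSE)
  list(expected = expected, p = p)
}
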