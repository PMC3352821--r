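#' Consensus expression per tissue
#'
#' Per-gene median expression across the samples available for a tissue
#' (both sexes, all replicates); NAs are dropped gene-wise.
#'
#' @param table an \linkS4class{ExpressionTable}.
#' @param tissue tissue code.
#' @return named numeric vector (gene -> RPKM).
#' @export
consensusExpression <- function(table, tissue) {
  si <- sampleInfo(table)
  idx <- which(si$tissue == tissue)
  if (!length(idx))
    dcStop("dc_no_sample", paste("no sample for tissue", tissue))
  apply(rpkm(table)[, idx, drop = FALSE], 1, median, na.rm = TRUE)
}

#' Tissue-specificity profile
#'
#' For each gene, the index of specificity to each tissue: the consensus
#' expression in that tissue divided by the sum of consensus expression
#' over all tissues in the run. Indices range from 0 (not expressed there
#' but expressed elsewhere) to 1 (expressed only there) and sum to 1 for
#' every gene with nonzero total expression. Genes with zero total
#' expression get all-NA indices and are flagged.
#'
#' @param table an \linkS4class{ExpressionTable}.
#' @param tissues tissue codes in the run (typically the 6 core tissues, or
#'   7 for platypus with ovary).
#' @return list with \code{index} (genes x tissues matrix),
#'   \code{consensus} (genes x tissues matrix of consensus RPKM), and
#'   \code{unexpressed} (logical: zero total expression).
#' @export
specificityIndex <- function(table, tissues) {
  cons <- vapply(tissues, function(t) consensusExpression(table, t),
                 numeric(nrow(table)))
  colnames(cons) <- tissues
  tot <- rowSums(cons)
  idx <- cons / tot
  idx[tot == 0, ] <- NA_real_
  list(index = idx, consensus = cons, unexpressed = tot == 0)
}

#' Classify tissue-specific genes
#'
#' Two rules, at most one tissue per gene under either. The two-fold rule
#' calls a gene specific to tissue t when its consensus there is positive
#' and at least twice the maximum consensus over the other tissues. The
#' index rule calls it specific when the specificity index exceeds
#' \code{theta} (strictly; the default 0.75 separates the bimodal index
#' distribution).
#'
#' @param profile output of [specificityIndex()].
#' @param rule \code{"twofold"} or \code{"index"}.
#' @param theta index threshold for the index rule.
#' @return named character vector: gene -> tissue code or NA.
#' @export
classifyTissueSpecific <- function(profile, rule = c("twofold", "index"),
                                   theta = 0.75) {
  rule <- match.arg(rule)
  cons <- profile$consensus
  out <- rep(NA_character_, nrow(cons))
  names(out) <- rownames(cons)
  if (rule == "twofold") {
    for (j in seq_len(ncol(cons))) {
      other <- apply(cons[, -j, drop = FALSE], 1, max)
      hit <- cons[, j] > 0 & cons[, j] >= 2 * other
      out[hit] <- colnames(cons)[j]
    }
  } else {
    idx <- profile$index
    for (j in seq_len(ncol(idx))) {
      hit <- !is.na(idx[, j]) & idx[, j] > theta
      out[hit] <- colnames(idx)[j]
    }
  }
  out
}

#' Fisher test of tissue-specificity enrichment (X versus autosomes)
#'
#' Two-sided Fisher exact test on the 2x2 table of (specific, nonspecific)
#' counts for the sex chromosome against autosomes. A zero margin yields
#' p = 1 with an undefined odds ratio.
#'
#' @param countsX,countsAA integer length-2 vectors
#'   \code{c(specific, nonspecific)}.
#' @return list with \code{oddsRatio} (sample OR, ad/bc; NA when a margin
#'   is zero) and \code{p}.
#' @export
enrichmentTest <- function(countsX, countsAA) {
  tab <- rbind(countsX, countsAA)
  if (any(tab < 0) || any(tab != round(tab)))
    dcStop("dc_config_error", "counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(oddsRatio = NA_real_, p = 1))
  res <- fisherExact2x2(tab)
  list(oddsRatio = res$oddsRatio, p = res$p)
}

#' Partition genes into old and recent
#'
#' A gene is "old" when it belongs to a 1:1 family with members in every
#' species of the panel (hence was present on the proto-chromosomes);
#' everything else — members of incomplete families and species-private
#' genes — is "recent".
#'
#' @param orthology an \linkS4class{OrthologFamilySet} spanning the full
#'   species panel.
#' @param annotation a \linkS4class{GeneAnnotation}; all its genes are
#'   classified.
#' @return named character vector over annotation rows (names =
#'   \code{species:gene_id}): \code{"old"} or \code{"recent"}.
#' @export
partitionAge <- function(orthology, annotation) {
  fam <- familyTable(orthology)
  sp <- familySpecies(orthology)
  full <- rep(TRUE, nrow(fam))
  for (s in sp) full <- full & !is.na(fam[[s]])
  oldKeys <- unlist(lapply(sp, function(s)
    paste(s, fam[[s]][full], sep = ":")))
  at <- annotationTable(annotation)
  keys <- paste(at$species, at$gene_id, sep = ":")
  setNames(ifelse(keys %in% oldKeys, "old", "recent"), keys)
}
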