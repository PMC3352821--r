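#' Reference gene set for median scaling
#'
#' The genes whose expression lies within the inner quartile range of every
#' sample and whose within-sample expression ranks are the most conserved
#' across samples (smallest rank variance). These anchor the median-scaling
#' normalization.
#'
#' @slot genes character, gene (or family) ids ordered by ascending rank
#'   variance.
#' @slot score numeric, the rank variance per gene, same order.
#' @slot shortfall logical, TRUE when fewer eligible genes than requested.
#' @export
setClass("ReferenceGeneSet",
         representation(genes = "character", score = "numeric",
                        shortfall = "logical"))

setMethod("show", "ReferenceGeneSet", function(object) {
  cat("ReferenceGeneSet:", length(object@genes), "genes",
      if (object@shortfall) "(shortfall: fewer eligible than requested)",
      "\n")
})

#' @rdname referenceGenes
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))

#' Reference-set accessors
#'
#' @param x a \linkS4class{ReferenceGeneSet}.
#' @return \code{referenceGenes}: the ordered gene ids;
#'   \code{rankStability}: the per-gene rank-variance scores.
#' @name referenceGenes
#' @export
setMethod("referenceGenes", "ReferenceGeneSet", function(x) x@genes)

#' @rdname referenceGenes
#' @export
setGeneric("rankStability", function(x) standardGeneric("rankStability"))

#' @rdname referenceGenes
#' @export
setMethod("rankStability", "ReferenceGeneSet", function(x)
  setNames(x@score, x@genes))

.rpkmMatrix <- function(x) {
  if (is(x, "ExpressionTable")) rpkm(x) else as.matrix(x)
}

#' Expressed-gene indicator
#'
#' Marks, per gene and sample, whether the gene counts as expressed under
#' the chosen mode: RPKM strictly positive (\code{rpkm_gt0}), or at least 1
#' or 3 mapped reads (\code{reads_ge1}, \code{reads_ge3}; these require a
#' read-count assay). Ratio analyses intersect the indicator across the
#' samples they compare, e.g. M:F ratios use genes expressed in both sexes.
#'
#' @param x an \linkS4class{ExpressionTable}.
#' @param mode expression criterion.
#' @return logical matrix, genes x samples.
#' @export
filterExpressed <- function(x, mode = c("rpkm_gt0", "reads_ge1", "reads_ge3")) {
  mode <- match.arg(mode)
  if (mode == "rpkm_gt0") return(rpkm(x) > 0)
  ct <- readCounts(x)
  if (is.null(ct))
    dcStop("dc_config_error",
           paste("mode", mode, "requires a read-count assay"))
  ct >= if (mode == "reads_ge1") 1 else 3
}

#' Select rank-conserved reference genes
#'
#' Among the genes whose expression lies within the inner quartile range
#' \code{[Q1, Q3]} of every sample's expression distribution, selects the
#' \code{n} genes whose within-sample ranks (average ranks for ties) have
#' the smallest variance across samples. Ties in the variance are broken by
#' lexicographic gene id for determinism. If fewer than \code{n} genes are
#' eligible, all of them are returned and the shortfall is flagged.
#'
#' @param x an \linkS4class{ExpressionTable} or numeric matrix (genes x
#'   samples; for cross-species use, a family-by-sample matrix as built by
#'   [familyExpressionMatrix()]).
#' @param n number of reference genes (default 1000).
#' @return a \linkS4class{ReferenceGeneSet}.
#' @export
selectReferenceGenes <- function(x, n = 1000) {
  m <- .rpkmMatrix(x)
  if (ncol(m) < 2)
    dcStop("dc_config_error", "reference selection needs >= 2 samples")
  m <- m[complete.cases(m), , drop = FALSE]
  q <- apply(m, 2, quantile, probs = c(0.25, 0.75), names = FALSE)
  eligible <- rep(TRUE, nrow(m))
  for (j in seq_len(ncol(m)))
    eligible <- eligible & m[, j] >= q[1, j] & m[, j] <= q[2, j]
  if (!any(eligible))
    dcStop("dc_empty_set", "no gene lies in the inner quartile of every sample")
  sub <- m[eligible, , drop = FALSE]
  ranks <- apply(m, 2, rank, ties.method = "average")[eligible, , drop = FALSE]
  score <- apply(ranks, 1, var)
  ord <- order(score, rownames(sub), method = "radix")
  k <- min(n, length(ord))
  sel <- ord[seq_len(k)]
  new("ReferenceGeneSet", genes = rownames(sub)[sel], score = score[sel],
      shortfall = length(ord) < n)
}

#' Median-scale samples to a common reference median
#'
#' Computes, per sample, the median log2 expression of the reference genes,
#' and shifts every sample (all genes) so those medians coincide at a common
#' target: the median of the per-sample reference medians (the minimal total
#' shift). On the linear RPKM scale the shift is a multiplicative factor
#' \code{2^shift}.
#'
#' @param x an \linkS4class{ExpressionTable} or numeric matrix.
#' @param referenceSet a \linkS4class{ReferenceGeneSet} (or character vector
#'   of gene ids).
#' @return a list with \code{scaled} (same class as \code{x}) and
#'   \code{factors} (named numeric, per-sample additive log2 shifts).
#' @export
medianScale <- function(x, referenceSet) {
  genes <- if (is(referenceSet, "ReferenceGeneSet"))
    referenceGenes(referenceSet) else as.character(referenceSet)
  m <- .rpkmMatrix(x)
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    dcStop("dc_missing_reference_gene",
           paste("reference genes absent from table:",
                 paste(head(miss, 5), collapse = ", ")))
  ref <- m[genes, , drop = FALSE]
  if (any(ref <= 0))
    dcStop("dc_config_error",
           "reference genes must have positive expression in every sample")
  med <- apply(log2(ref), 2, median)
  target <- median(med)
  shifts <- target - med
  scaled <- sweep(m, 2, 2^shifts, `*`)
  out <- if (is(x, "ExpressionTable")) {
    y <- x
    assay(y, "rpkm") <- scaled
    y
  } else scaled
  list(scaled = out, factors = shifts)
}

#' Family-by-sample expression matrix across species
#'
#' Assembles, for 1:1 families present in every species that has an
#' expression table, a matrix of family expression values with one column
#' per sample across all species (columns named \code{species.sample}).
#' This is the input for cross-species reference selection and joint
#' median scaling.
#'
#' @param tables named list of \linkS4class{ExpressionTable} by species.
#' @param orthology an \linkS4class{OrthologFamilySet}.
#' @param tissues optional tissue codes to restrict the samples.
#' @return numeric matrix, families x samples, with attribute
#'   \code{"sampleSpecies"} giving each column's species.
#' @export
familyExpressionMatrix <- function(tables, orthology, tissues = NULL) {
  fam <- familyTable(orthology)
  sp <- intersect(familySpecies(orthology), names(tables))
  keep <- rep(TRUE, nrow(fam))
  for (s in sp) keep <- keep & !is.na(fam[[s]])
  fam <- fam[keep, , drop = FALSE]
  cols <- list(); colSp <- character()
  for (s in sp) {
    m <- rpkm(tables[[s]])
    si <- sampleInfo(tables[[s]])
    idx <- if (is.null(tissues)) seq_len(ncol(m)) else
      which(si$tissue %in% tissues)
    v <- m[match(fam[[s]], rownames(m)), idx, drop = FALSE]
    colnames(v) <- paste(s, colnames(m)[idx], sep = ".")
    cols[[s]] <- v
    colSp <- c(colSp, rep(s, length(idx)))
  }
  out <- do.call(cbind, cols)
  rownames(out) <- as.character(fam$family_id)
  attr(out, "sampleSpecies") <- colSp
  out
}
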