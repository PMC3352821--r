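## On-disk format: TSV throughout, UTF-8, '.' decimal separator, missing
## cells written as "NA". Expression tables carry gene_id + one column per
## sample; sample metadata maps column names to descriptors.

.readTSV <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = "NA")
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
}

#' Read an expression table and its sample metadata
#'
#' @param tablePath TSV with a \code{gene_id} column and one numeric column
#'   per sample.
#' @param metadataPath TSV with columns \code{sample} (matching the table's
#'   column names), \code{species}, \code{tissue}, \code{sex} and optionally
#'   \code{replicate} (defaults to 1).
#' @param countsPath optional TSV of read counts in the same layout.
#' @return a validated \linkS4class{ExpressionTable}.
#' @export
readExpression <- function(tablePath, metadataPath, countsPath = NULL) {
  tab <- .readTSV(tablePath)
  if (!("gene_id" %in% colnames(tab)))
    dcStop("dc_missing_gene_column", "expression table lacks a gene_id column")
  if (anyDuplicated(tab$gene_id))
    dcStop("dc_duplicate_gene", "duplicate gene ids in expression table")
  md <- .readTSV(metadataPath)
  if (!("sample" %in% colnames(md)))
    dcStop("dc_metadata_mismatch", "metadata lacks a sample column")
  samples <- setdiff(colnames(tab), "gene_id")
  if (!setequal(md$sample, samples))
    dcStop("dc_metadata_mismatch",
           "metadata samples do not match expression columns")
  md <- md[match(samples, md$sample), , drop = FALSE]
  m <- as.matrix(tab[, samples, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (any(m < 0, na.rm = TRUE))
    dcStop("dc_negative_expression", "negative expression values in table")
  counts <- NULL
  if (!is.null(countsPath)) {
    ct <- .readTSV(countsPath)
    counts <- as.matrix(ct[match(tab$gene_id, ct$gene_id), samples,
                           drop = FALSE])
    rownames(counts) <- tab$gene_id
  }
  ExpressionTable(m, md[, setdiff(colnames(md), "sample"), drop = FALSE],
                  counts = counts)
}

#' Write an expression table and its sample metadata
#'
#' @param x an \linkS4class{ExpressionTable}.
#' @param tablePath,metadataPath output TSV paths.
#' @return invisibly, \code{x}.
#' @export
writeExpression <- function(x, tablePath, metadataPath) {
  m <- rpkm(x)
  .writeTSV(data.frame(gene_id = rownames(m), m, check.names = FALSE),
            tablePath)
  si <- sampleInfo(x)
  .writeTSV(data.frame(sample = colnames(m),
                       si[, c("species", "tissue", "sex", "replicate")]),
            metadataPath)
  invisible(x)
}

#' Read or write a gene annotation table
#'
#' TSV columns: \code{gene_id}, \code{species}, \code{chromosome},
#' \code{chrom_class}, \code{region_class}, \code{age_class}.
#'
#' @param path TSV path.
#' @return a \linkS4class{GeneAnnotation}.
#' @export
readAnnotation <- function(path) GeneAnnotation(.readTSV(path))

#' @rdname readAnnotation
#' @param x a \linkS4class{GeneAnnotation}.
#' @export
writeAnnotation <- function(x, path) {
  .writeTSV(annotationTable(x), path)
  invisible(x)
}

#' Read a 1:1 orthology table
#'
#' TSV with \code{family_id} plus one gene-id column per species; an empty
#' or NA cell means the species is absent from the family. A row listing two
#' genes for one species (comma-separated) violates 1:1 orthology and is
#' rejected.
#'
#' @param path TSV path.
#' @param annotation a \linkS4class{GeneAnnotation} used to derive the
#'   per-family flags.
#' @return an \linkS4class{OrthologFamilySet}.
#' @export
readOrthology <- function(path, annotation) {
  fam <- .readTSV(path)
  sp <- setdiff(colnames(fam), "family_id")
  for (s in sp) {
    v <- as.character(fam[[s]])
    multi <- !is.na(v) & grepl(",", v, fixed = TRUE)
    if (any(multi))
      dcStop("dc_one_to_one_violation",
             paste("family", fam$family_id[multi][1],
                   "lists two genes for species", s))
  }
  OrthologFamilySet(fam, annotation)
}

#' @rdname readOrthology
#' @param x an \linkS4class{OrthologFamilySet}.
#' @export
writeOrthology <- function(x, path) {
  .writeTSV(familyTable(x), path)
  invisible(x)
}

#' Read or write a protein-protein interaction edge list
#'
#' TSV columns \code{gene_a}, \code{gene_b} and optional \code{score}.
#' Self-edges are rejected; duplicate pairs (in either order) are collapsed.
#'
#' @param path TSV path.
#' @param minScore optional confidence threshold; edges below it are dropped.
#' @return data.frame of unique undirected edges.
#' @export
readPPI <- function(path, minScore = NULL) {
  e <- .readTSV(path)
  makePPI(e, minScore = minScore)
}

#' @rdname readPPI
#' @param edges data.frame with \code{gene_a}, \code{gene_b} and optional
#'   \code{score}.
#' @export
makePPI <- function(edges, minScore = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("gene_a", "gene_b") %in% colnames(edges)))
    dcStop("dc_metadata_mismatch", "PPI table needs gene_a and gene_b columns")
  if (!is.null(minScore) && "score" %in% colnames(edges))
    edges <- edges[!is.na(edges$score) & edges$score >= minScore, ,
                   drop = FALSE]
  if (any(edges$gene_a == edges$gene_b))
    dcStop("dc_self_edge", "self-edges are not allowed in a PPI network")
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- !duplicated(paste(a, b))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep])
  if ("score" %in% colnames(edges)) out$score <- edges$score[keep]
  out
}

#' @rdname readPPI
#' @param x a PPI edge data.frame.
#' @export
writePPI <- function(x, path) {
  .writeTSV(x, path)
  invisible(x)
}

#' Consistency report over a full dataset
#'
#' Cross-checks expression tables, annotation and orthology before analysis:
#' per species, the available tissue-by-sex sample grid, genes lacking
#' annotation, and families whose species have no expression table. The
#' report is empty exactly when the dataset is analysis-ready.
#'
#' @param tables named list of \linkS4class{ExpressionTable}, one per species.
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param orthology optional \linkS4class{OrthologFamilySet}.
#' @return a list with elements \code{sampleGrid} (data.frame of species x
#'   tissue x sex counts), \code{unannotatedGenes} (named list),
#'   \code{speciesWithoutExpression} (character), and \code{clean} (logical:
#'   no problems found).
#' @export
validateDataset <- function(tables, annotation, orthology = NULL) {
  at <- annotationTable(annotation)
  grid <- do.call(rbind, lapply(names(tables), function(s) {
    si <- sampleInfo(tables[[s]])
    cnt <- as.data.frame(table(tissue = si$tissue, sex = si$sex))
    cnt <- cnt[cnt$Freq > 0, , drop = FALSE]
    if (nrow(cnt)) cbind(species = s, cnt) else NULL
  }))
  unann <- lapply(names(tables), function(s) {
    g <- rownames(tables[[s]])
    setdiff(g, at$gene_id[at$species == s])
  })
  names(unann) <- names(tables)
  unann <- unann[vapply(unann, length, 1L) > 0]
  missingSp <- character()
  if (!is.null(orthology))
    missingSp <- setdiff(familySpecies(orthology), names(tables))
  list(sampleGrid = grid,
       unannotatedGenes = unann,
       speciesWithoutExpression = missingSp,
       clean = length(unann) == 0 && length(missingSp) == 0)
}
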