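#' Construct an ExpressionTable
#'
#' @param rpkm numeric matrix of non-negative RPKM values, genes in rows
#'   (unique rownames), samples in columns.
#' @param sampleInfo data.frame with one row per column of \code{rpkm} and
#'   columns \code{species}, \code{tissue}, \code{sex}, \code{replicate}
#'   (replicate defaults to 1 when absent).
#' @param counts optional matrix of read counts, same dimensions as
#'   \code{rpkm}.
#' @param lengths optional positive gene lengths (bp), one per gene.
#' @return an \linkS4class{ExpressionTable}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' si <- data.frame(species = "hsa", tissue = "br", sex = c("M", "F"),
#'                  replicate = 1L)
#' et <- ExpressionTable(m, si)
#' @export
ExpressionTable <- function(rpkm, sampleInfo, counts = NULL, lengths = NULL) {
  rpkm <- as.matrix(rpkm)
  if (is.null(rownames(rpkm)))
    dcStop("dc_missing_gene_column", "rpkm matrix must carry gene rownames")
  if (anyDuplicated(rownames(rpkm)))
    dcStop("dc_duplicate_gene", "duplicate gene identifiers")
  if (any(rpkm < 0, na.rm = TRUE))
    dcStop("dc_negative_expression", "negative expression values")
  sampleInfo <- as.data.frame(sampleInfo)
  if (!("replicate" %in% colnames(sampleInfo))) sampleInfo$replicate <- 1L
  sampleInfo$replicate <- as.integer(sampleInfo$replicate)
  if (nrow(sampleInfo) != ncol(rpkm))
    dcStop("dc_metadata_mismatch",
           "sampleInfo rows must match expression columns")
  if (!all(sampleInfo$tissue %in% .TISSUES))
    dcStop("dc_unknown_tissue", "tissue codes outside controlled vocabulary")
  if (!all(sampleInfo$sex %in% .SEXES | is.na(sampleInfo$sex)))
    dcStop("dc_unknown_sex", "sex codes outside {M, F, NA}")
  assays <- list(rpkm = rpkm)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(identical(dim(counts), dim(rpkm)))
    assays$counts <- counts
  }
  rd <- if (!is.null(lengths)) DataFrame(length = lengths) else NULL
  se <- SummarizedExperiment(assays = assays,
                             colData = DataFrame(sampleInfo,
                                                 row.names = colnames(rpkm)),
                             rowData = rd)
  new("ExpressionTable", se)
}

#' @rdname rpkm
#' @export
setGeneric("rpkm", function(x) standardGeneric("rpkm"))

#' Assay and descriptor accessors
#'
#' \code{rpkm} returns the RPKM matrix, \code{readCounts} the optional
#' read-count matrix (NULL if absent), \code{geneLengths} the optional gene
#' lengths, and \code{sampleInfo} the sample descriptors as a data.frame.
#'
#' @param x an \linkS4class{ExpressionTable}.
#' @return matrix, numeric vector or data.frame as described.
#' @name rpkm
#' @aliases rpkm,ExpressionTable-method
#' @export
setMethod("rpkm", "ExpressionTable", function(x) assay(x, "rpkm"))

#' @rdname rpkm
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname rpkm
#' @export
setMethod("readCounts", "ExpressionTable", function(x) {
  if ("counts" %in% assayNames(x)) assay(x, "counts") else NULL
})

#' @rdname rpkm
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname rpkm
#' @export
setMethod("geneLengths", "ExpressionTable", function(x) {
  if ("length" %in% colnames(rowData(x))) rowData(x)$length else NULL
})

#' @rdname rpkm
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname rpkm
#' @export
setMethod("sampleInfo", "ExpressionTable", function(x) {
  as.data.frame(colData(x))
})

setMethod("show", "ExpressionTable", function(object) {
  cd <- colData(object)
  cat("ExpressionTable:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  species:", paste(unique(cd$species), collapse = ", "), "\n")
  cat("  tissues:", paste(sort(unique(cd$tissue)), collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Construct a GeneAnnotation
#'
#' @param table data.frame with columns \code{gene_id}, \code{species},
#'   \code{chromosome}, \code{chrom_class}, \code{region_class},
#'   \code{age_class} (the last two may be NA).
#' @return a \linkS4class{GeneAnnotation}.
#' @export
GeneAnnotation <- function(table) {
  table <- as.data.frame(table)
  for (col in c("region_class", "age_class"))
    if (!(col %in% colnames(table))) table[[col]] <- NA_character_
  new("GeneAnnotation", table = table)
}

#' @rdname annotationTable
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' Access the annotation table
#'
#' @param x a \linkS4class{GeneAnnotation}.
#' @return the underlying data.frame.
#' @name annotationTable
#' @export
setMethod("annotationTable", "GeneAnnotation", function(x) x@table)

setMethod("show", "GeneAnnotation", function(object) {
  t <- object@table
  cat("GeneAnnotation:", nrow(t), "genes,",
      length(unique(t$species)), "species\n")
  print(table(t$species, t$chrom_class))
})

#' Is a gene sex-linked?
#'
#' A gene counts as sex-linked when it lies on a sex chromosome (X, X1, X5
#' or Z) outside a pseudoautosomal region; PAR genes are diploid in both
#' sexes and are treated as effectively autosomal for dosage purposes.
#'
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @return named logical vector over annotation rows (names =
#'   \code{species:gene_id}).
#' @export
isSexLinked <- function(annotation) {
  t <- annotationTable(annotation)
  linked <- t$chrom_class != "autosome" &
    !(!is.na(t$region_class) & t$region_class == "PAR")
  setNames(linked, paste(t$species, t$gene_id, sep = ":"))
}

#' Construct an OrthologFamilySet and derive per-family flags
#'
#' @param families data.frame with a \code{family_id} column and one gene-id
#'   column per species (NA or "" = species absent from the family).
#' @param annotation a \linkS4class{GeneAnnotation} covering every referenced
#'   gene.
#' @return an \linkS4class{OrthologFamilySet} with derived
#'   \code{autosomalInAll} and \code{sexLinkedIn} flags.
#' @export
OrthologFamilySet <- function(families, annotation) {
  families <- as.data.frame(families)
  sp <- setdiff(colnames(families), "family_id")
  for (s in sp) {
    v <- as.character(families[[s]])
    v[!is.na(v) & v == ""] <- NA_character_
    families[[s]] <- v
  }
  at <- annotationTable(annotation)
  linked <- isSexLinked(annotation)
  cls <- setNames(at$chrom_class, paste(at$species, at$gene_id, sep = ":"))
  fid <- as.character(families$family_id)
  autoAll <- setNames(logical(nrow(families)), fid)
  sexIn <- setNames(vector("list", nrow(families)), fid)
  for (i in seq_len(nrow(families))) {
    present <- sp[!is.na(unlist(families[i, sp]))]
    keys <- paste(present, unlist(families[i, present]), sep = ":")
    miss <- !(keys %in% names(cls))
    if (any(miss))
      dcStop("dc_unresolved_gene",
             paste("genes absent from annotation:",
                   paste(keys[miss], collapse = ", ")))
    autoAll[i] <- length(present) > 0 && all(cls[keys] == "autosome")
    sexIn[[i]] <- present[linked[keys]]
  }
  new("OrthologFamilySet", families = families, species = sp,
      autosomalInAll = autoAll, sexLinkedIn = sexIn)
}

#' @rdname familyTable
#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))

#' Ortholog-family accessors
#'
#' \code{familyTable} returns the family-by-species gene-id table,
#' \code{autosomalInAll} the per-family flag that every member is autosomal,
#' \code{sexLinkedIn} the per-family set of species in which the member is
#' sex-linked, and \code{familySpecies} the species panel.
#'
#' @param x an \linkS4class{OrthologFamilySet}.
#' @return data.frame, named logical, named list, or character respectively.
#' @name familyTable
#' @export
setMethod("familyTable", "OrthologFamilySet", function(x) x@families)

#' @rdname familyTable
#' @export
setGeneric("autosomalInAll", function(x) standardGeneric("autosomalInAll"))

#' @rdname familyTable
#' @export
setMethod("autosomalInAll", "OrthologFamilySet", function(x) x@autosomalInAll)

#' @rdname familyTable
#' @export
setGeneric("sexLinkedIn", function(x) standardGeneric("sexLinkedIn"))

#' @rdname familyTable
#' @export
setMethod("sexLinkedIn", "OrthologFamilySet", function(x) x@sexLinkedIn)

#' @rdname familyTable
#' @export
setGeneric("familySpecies", function(x) standardGeneric("familySpecies"))

#' @rdname familyTable
#' @export
setMethod("familySpecies", "OrthologFamilySet", function(x) x@species)

setMethod("show", "OrthologFamilySet", function(object) {
  cat("OrthologFamilySet:", nrow(object@families), "families over",
      length(object@species), "species\n")
  cat("  autosomal in all species:", sum(object@autosomalInAll), "\n")
})

#' RatioResult accessors
#'
#' \code{geneRatios} returns the per-gene log2 ratios, \code{medianRatio}
#' the median ratio (linear scale by default), \code{ratioInterval} the
#' resampling interval, and \code{referenceTests} the reference-value
#' Wilcoxon test table.
#'
#' @param x a \linkS4class{RatioResult}.
#' @param log2 logical; return values on the log2 scale instead of linear.
#' @return numeric vector/scalar or data.frame as described.
#' @name geneRatios
#' @export
setGeneric("geneRatios", function(x, log2 = TRUE) standardGeneric("geneRatios"))

#' @rdname geneRatios
#' @export
setMethod("geneRatios", "RatioResult", function(x, log2 = TRUE) {
  if (log2) x@ratios else 2^x@ratios
})

#' @rdname geneRatios
#' @export
setGeneric("medianRatio", function(x, log2 = FALSE) standardGeneric("medianRatio"))

#' @rdname geneRatios
#' @export
setMethod("medianRatio", "RatioResult", function(x, log2 = FALSE) {
  if (log2) x@median else 2^x@median
})

#' @rdname geneRatios
#' @export
setGeneric("ratioInterval", function(x, log2 = FALSE) standardGeneric("ratioInterval"))

#' @rdname geneRatios
#' @export
setMethod("ratioInterval", "RatioResult", function(x, log2 = FALSE) {
  if (log2) x@interval else 2^x@interval
})

#' @rdname geneRatios
#' @export
setGeneric("referenceTests", function(x) standardGeneric("referenceTests"))

#' @rdname geneRatios
#' @export
setMethod("referenceTests", "RatioResult", function(x) x@tests)

setMethod("show", "RatioResult", function(object) {
  md <- object@metadata
  lab <- paste(unlist(md[c("species", "tissue", "chromClass")]),
               collapse = " / ")
  cat("RatioResult", if (nzchar(lab)) paste0("(", lab, ")"), "\n")
  cat(sprintf("  %d genes; median ratio %.3f (log2 %.3f)\n",
              length(object@ratios), 2^object@median, object@median))
  if (length(object@interval) == 2)
    cat(sprintf("  %.0f%% resampling interval: [%.3f, %.3f]\n",
                100 * object@coverage, 2^object@interval[1],
                2^object@interval[2]))
  if (nrow(object@tests)) {
    cat("  reference tests:\n")
    print(object@tests, row.names = FALSE)
  }
})

#' AncestralEstimate accessors
#'
#' \code{ancestralLevels} returns the named per-family ancestral RPKM vector
#' (NA = not expressed in any outgroup); \code{usedOutgroups} the outgroup
#' species that informed the estimate.
#'
#' @param x an \linkS4class{AncestralEstimate}.
#' @return numeric vector or character vector.
#' @name ancestralLevels
#' @export
setGeneric("ancestralLevels", function(x) standardGeneric("ancestralLevels"))

#' @rdname ancestralLevels
#' @export
setMethod("ancestralLevels", "AncestralEstimate", function(x) x@levels)

#' @rdname ancestralLevels
#' @export
setGeneric("usedOutgroups", function(x) standardGeneric("usedOutgroups"))

#' @rdname ancestralLevels
#' @export
setMethod("usedOutgroups", "AncestralEstimate", function(x) x@outgroups)

setMethod("show", "AncestralEstimate", function(object) {
  cat("AncestralEstimate for", object@focalSpecies, "/", object@tissue, "\n")
  cat("  outgroups:", paste(object@outgroups, collapse = ", "), "\n")
  cat(sprintf("  %d families, %d with an expressed outgroup ortholog\n",
              length(object@levels), sum(!is.na(object@levels))))
})
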