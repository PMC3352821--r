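#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats median quantile var sd p.adjust wilcox.test ks.test
#'   kruskal.test fisher.test dhyper phyper rmultinom rpois rnorm rlnorm
#'   runif setNames complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

## Controlled vocabularies shared across the package.
.TISSUES <- c("br", "cb", "ht", "kd", "lv", "ts", "ov", "fib")
.SEXES <- c("M", "F")
.CHROM_CLASSES <- c("autosome", "X", "X1", "X5", "Z")
.REGION_CLASSES <- c("XCR", "XAR", "PAR", "nonPAR")
.AGE_CLASSES <- c("old", "recent")

## Structured error helper: every validation failure carries a distinct
## condition class ("dc_<name>") so callers can catch it by name.
dcStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dcError", "error", "condition")))
}

#' Gene-by-sample expression container
#'
#' An \code{ExpressionTable} is a \linkS4class{SummarizedExperiment} whose
#' primary assay \code{"rpkm"} holds non-negative RPKM expression values for
#' one species, with one column per sample. The column data carry the sample
#' descriptors \code{species}, \code{tissue} (one of br, cb, ht, kd, lv, ts,
#' ov, fib), \code{sex} (M, F or \code{NA}) and \code{replicate} (positive
#' integer); the 4-tuple uniquely identifies a sample. An optional assay
#' \code{"counts"} stores per-gene read counts (non-negative integers), and an
#' optional \code{rowData} column \code{length} stores gene lengths in bp.
#'
#' @seealso [ExpressionTable()] for the constructor, [rpkm()],
#'   [readCounts()], [sampleInfo()].
#' @export
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
  a <- assayNames(object)
  if (!("rpkm" %in% a)) return("assay 'rpkm' is required")
  x <- assay(object, "rpkm")
  if (is.null(rownames(object))) return("gene identifiers (rownames) required")
  if (anyDuplicated(rownames(object))) return("duplicate gene identifiers")
  if (any(x < 0, na.rm = TRUE)) return("negative expression values")
  cd <- colData(object)
  need <- c("species", "tissue", "sex", "replicate")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!all(cd$tissue %in% .TISSUES))
    return("tissue codes outside controlled vocabulary")
  if (!all(cd$sex %in% .SEXES | is.na(cd$sex)))
    return("sex codes outside {M, F, NA}")
  rep <- cd$replicate
  if (any(is.na(rep)) || any(rep < 1) || any(rep != round(rep)))
    return("replicate must be a positive integer")
  key <- paste(cd$species, cd$tissue, cd$sex, cd$replicate, sep = "_")
  if (anyDuplicated(key))
    return("(species, tissue, sex, replicate) must uniquely identify samples")
  if ("counts" %in% a) {
    ct <- assay(object, "counts")
    if (any(ct < 0, na.rm = TRUE) || any(ct != round(ct), na.rm = TRUE))
      return("read counts must be non-negative integers")
  }
  if ("length" %in% colnames(rowData(object))) {
    len <- rowData(object)$length
    if (any(!is.na(len) & len <= 0)) return("gene lengths must be positive")
  }
  TRUE
})

#' Per-gene chromosome annotation
#'
#' Holds, per gene and species, the chromosome name, its class
#' (\code{autosome}, \code{X}, \code{X1}, \code{X5} or \code{Z}), an optional
#' region class (\code{XCR}/\code{XAR} only on the therian X,
#' \code{PAR}/\code{nonPAR} only on platypus X1) and an age class
#' (\code{old} = member of a 1:1 family spanning the full species panel,
#' otherwise \code{recent}).
#'
#' @slot table data.frame with columns \code{gene_id}, \code{species},
#'   \code{chromosome}, \code{chrom_class}, \code{region_class},
#'   \code{age_class}.
#' @export
setClass("GeneAnnotation", representation(table = "data.frame"))

setValidity("GeneAnnotation", function(object) {
  t <- object@table
  need <- c("gene_id", "species", "chromosome", "chrom_class",
            "region_class", "age_class")
  if (!all(need %in% colnames(t)))
    return(paste("annotation must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(paste(t$species, t$gene_id)))
    return("duplicate gene_id within a species")
  if (!all(t$chrom_class %in% .CHROM_CLASSES))
    return("chrom_class outside controlled vocabulary")
  if (!all(is.na(t$region_class) | t$region_class %in% .REGION_CLASSES))
    return("region_class outside controlled vocabulary")
  bad <- !is.na(t$region_class) & t$region_class %in% c("XCR", "XAR") &
    t$chrom_class != "X"
  if (any(bad)) return("XCR/XAR region class only valid with chrom_class X")
  bad <- !is.na(t$region_class) & t$region_class %in% c("PAR", "nonPAR") &
    t$chrom_class != "X1"
  if (any(bad)) return("PAR/nonPAR region class only valid with chrom_class X1")
  if (!all(is.na(t$age_class) | t$age_class %in% .AGE_CLASSES))
    return("age_class must be old or recent")
  TRUE
})

#' 1:1 ortholog families across species
#'
#' One row per family, one gene-id column per species (\code{NA} where the
#' species lacks a member; at most one gene per species per family). Two
#' flags are derived from a \linkS4class{GeneAnnotation}:
#' \code{autosomalInAll} (the member is autosomal in every species that has
#' one) and \code{sexLinkedIn} (the species in which the member is
#' sex-linked).
#'
#' @slot families data.frame: \code{family_id} plus one column per species.
#' @slot species character vector of species codes (= family columns).
#' @slot autosomalInAll named logical, one per family.
#' @slot sexLinkedIn named list of character vectors, one per family.
#' @export
setClass("OrthologFamilySet",
         representation(families = "data.frame", species = "character",
                        autosomalInAll = "logical", sexLinkedIn = "list"))

setValidity("OrthologFamilySet", function(object) {
  f <- object@families
  if (!("family_id" %in% colnames(f))) return("family_id column required")
  if (anyDuplicated(f$family_id)) return("duplicate family ids")
  if (!all(object@species %in% colnames(f)))
    return("every species must have a gene-id column")
  if (!identical(names(object@autosomalInAll), as.character(f$family_id)) ||
      !identical(names(object@sexLinkedIn), as.character(f$family_id)))
    return("derived flags must be named by family_id")
  TRUE
})

#' Ratio-statistic result
#'
#' Per-gene log2 expression ratios together with their median, a resampling
#' interval at a declared coverage, and one-sample Wilcoxon signed-rank tests
#' of the median against reference ratios (0.5, 1 and 2 by default).
#'
#' @slot ratios named numeric, per-gene log2 ratios.
#' @slot median numeric, median log2 ratio.
#' @slot interval numeric length-2, resampling interval (log2 scale).
#' @slot coverage numeric, interval coverage.
#' @slot tests data.frame with columns \code{reference}, \code{p},
#'   \code{p_adj}.
#' @slot metadata list of descriptors (species, tissue, chromosome class,
#'   gene-set mode).
#' @export
setClass("RatioResult",
         representation(ratios = "numeric", median = "numeric",
                        interval = "numeric", coverage = "numeric",
                        tests = "data.frame", metadata = "list"))

setValidity("RatioResult", function(object) {
  if (length(object@ratios)) {
    r <- object@ratios[is.finite(object@ratios)]
    if (length(r) && (object@median < min(r) - 1e-9 ||
                      object@median > max(r) + 1e-9))
      return("median must lie within the range of per-gene ratios")
  }
  if (nrow(object@tests) &&
      any(object@tests$p_adj < object@tests$p - 1e-12, na.rm = TRUE))
    return("corrected p must be >= raw p")
  TRUE
})

#' Ancestral (proto-sex-chromosome) expression estimate
#'
#' Per-family ancestral expression levels for one tissue, inferred as the
#' median across outgroup species (species with non-homologous sex
#' chromosomes) of the expression of the family's autosomal ortholog there.
#' Families whose member is sex-linked in any used outgroup are excluded;
#' families expressed in no outgroup are \code{NA} (missing, not zero).
#'
#' @slot levels named numeric: family id -> ancestral RPKM (NA = missing).
#' @slot outgroups character, the outgroup species used.
#' @slot tissue character, the tissue matched in the outgroups.
#' @slot focalSpecies character.
#' @export
setClass("AncestralEstimate",
         representation(levels = "numeric", outgroups = "character",
                        tissue = "character", focalSpecies = "character"))

#' Analysis configuration
#'
#' Bundles the knobs shared by the ratio analyses: the expressed-gene filter
#' mode, the reference ratios tested, the multiple-testing correction, and
#' the resampling design for confidence intervals.
#'
#' @param expressedMode one of \code{"rpkm_gt0"}, \code{"reads_ge1"},
#'   \code{"reads_ge3"}.
#' @param referenceValues positive reference ratios (linear scale).
#' @param correction \code{"bonferroni"} or \code{"bh"}.
#' @param resampleN number of resampling draws.
#' @param resampleFraction fraction of genes per draw, in (0, 1].
#' @param coverage interval coverage, in (0, 1).
#' @param seed integer random seed for resampling.
#' @return a list with class \code{"AnalysisConfig"}.
#' @examples
#' cfg <- analysisConfig(coverage = 0.9)
#' cfg$resampleN
#' @export
analysisConfig <- function(expressedMode = c("rpkm_gt0", "reads_ge1", "reads_ge3"),
                           referenceValues = c(0.5, 1, 2),
                           correction = c("bonferroni", "bh"),
                           resampleN = 100, resampleFraction = 0.8,
                           coverage = 0.95, seed = 1L) {
  expressedMode <- match.arg(expressedMode)
  correction <- match.arg(correction)
  if (resampleFraction <= 0 || resampleFraction > 1)
    dcStop("dc_config_error", "resampleFraction must be in (0, 1]")
  if (coverage <= 0 || coverage >= 1)
    dcStop("dc_config_error", "coverage must be in (0, 1)")
  if (any(referenceValues <= 0))
    dcStop("dc_config_error", "reference values must be positive")
  structure(list(expressedMode = expressedMode,
                 referenceValues = referenceValues,
                 correction = correction, resampleN = resampleN,
                 resampleFraction = resampleFraction, coverage = coverage,
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}
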