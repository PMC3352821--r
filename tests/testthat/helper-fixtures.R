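# Toy objects shared across tests; everything is built in code.

toyExpression <- function(m, species = "hsa", tissue = NULL, sex = NULL,
                          replicate = NULL, counts = NULL) {
  n <- ncol(m)
  si <- data.frame(species = species,
                   tissue = if (is.null(tissue)) rep("br", n) else tissue,
                   sex = if (is.null(sex)) rep(c("M", "F"), length.out = n)
                         else sex,
                   replicate = if (is.null(replicate)) seq_len(n)
                               else replicate)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(n))
  ExpressionTable(m, si, counts = counts)
}

## One species, one tissue, M + F columns, with X and autosomal genes.
toyMFTable <- function(xMF, autoMF, species = "hsa", tissue = "br") {
  nx <- nrow(xMF); na <- nrow(autoMF)
  m <- rbind(xMF, autoMF)
  rownames(m) <- c(paste0("x", seq_len(nx)), paste0("a", seq_len(na)))
  colnames(m) <- c("sM", "sF")
  et <- ExpressionTable(m, data.frame(species = species, tissue = tissue,
                                      sex = c("M", "F"), replicate = 1L))
  anno <- GeneAnnotation(data.frame(
    gene_id = rownames(m), species = species,
    chromosome = c(rep("X", nx), rep("chr1", na)),
    chrom_class = c(rep("X", nx), rep("autosome", na)),
    region_class = NA_character_, age_class = NA_character_))
  list(table = et, annotation = anno)
}

## Three toy species with a 1:1 orthology; gene gN_<sp>; family famN.
toyOrthology <- function(nFam = 4, sexLinkedFam = integer(),
                         sexSpecies = "spA") {
  sp <- c("spA", "spB", "spC")
  fam <- data.frame(family_id = paste0("fam", seq_len(nFam)))
  rows <- list()
  for (s in sp) {
    ids <- paste0("g", seq_len(nFam), "_", s)
    fam[[s]] <- ids
    linked <- seq_len(nFam) %in% sexLinkedFam & s %in% sexSpecies
    rows[[s]] <- data.frame(
      gene_id = ids, species = s,
      chromosome = ifelse(linked, "X", "chr1"),
      chrom_class = ifelse(linked, "X", "autosome"),
      region_class = NA_character_, age_class = "old")
  }
  anno <- GeneAnnotation(do.call(rbind, rows))
  list(families = fam, annotation = anno,
       orthology = OrthologFamilySet(fam, anno))
}

## Independent oracle: two-sided Fisher p by direct enumeration of the
## hypergeometric support using log-binomials (no dhyper).
fisherOracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  dens <- exp(lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k))
  min(1, sum(dens[dens <= dens[a - supp[1] + 1] * (1 + 1e-7)]))
}
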