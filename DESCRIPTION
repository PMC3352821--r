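Package: dosageCompR
Title: Comparative Transcriptomic Inference of Sex-Chromosome Dosage Compensation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring sex-chromosome dosage-compensation states from
    multi-species, multi-tissue RNA-seq expression tables. Implements
    rank-conserved median-scaling normalization, male:female and X:autosome
    expression-ratio statistics with resampling confidence intervals,
    reconstruction of proto-sex-chromosome (ancestral) expression levels from
    autosomal one-to-one orthologs in outgroup species, tissue-specificity
    indices and testis-specific gene classification, X-autosome
    protein-interaction contingency analysis, read-sampling noise and
    expression-threshold simulations, and a synthetic-data generator with a
    known dosage ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
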