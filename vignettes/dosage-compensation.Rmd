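---
title: "Inferring sex-chromosome dosage compensation from comparative RNA-seq"
author: "dosageCompR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-chromosome dosage compensation from comparative RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosageCompR)
```

## The inference problem

A sex chromosome is a degenerated autosome pair. Once the Y (or W) has
lost a gene, the heterogametic sex transcribes that gene from a single
copy; without any compensation its output is half the ancestral diploid
level. Comparing the *current* expression of X(Z)-linked genes with
their *ancestral* expression tells us which compensation route a lineage
took:

| route | heterogametic dose | homogametic dose |
|---|---|---|
| none | 0.5 | 1 |
| two-fold upregulation + inactivation | 1 | 1 |
| upregulation both sexes, no inactivation | u/2 | u |
| heterogametic-only partial upregulation | u/2 | 1 |

"Dose" here is current output relative to the ancestral two-allele
output. The ancestral level of a gene is not observable directly, but
the X descends from autosomes that are *still autosomal* in species
with non-homologous sex chromosomes, so the expression of the 1:1
ortholog there — unaffected by sex-linked selective forces — estimates
it.

## Data model

`ExpressionTable` (a `SummarizedExperiment`) holds one species'
gene × sample RPKM matrix; samples are identified by the 4-tuple
(species, tissue, sex, replicate) with tissue codes
br, cb, ht, kd, lv, ts, ov, fib. An optional `counts` assay enables
read-count-based expressed-gene filters. `GeneAnnotation` labels each
gene with a chromosome, a chromosome class (autosome, X, X1, X5, Z),
an optional region class (XCR/XAR on the therian X, PAR/nonPAR on
platypus X1 — PAR genes are diploid in both sexes and treated as
effectively autosomal), and an old/recent age class.
`OrthologFamilySet` stores 1:1 families (at most one gene per species)
and derives, purely from the annotation, whether a family is autosomal
in every species and in which species it is sex-linked. All files are
plain TSV, UTF-8, `.` decimals, `NA` for missing cells — a single
bit-exact dialect that round-trips.

## Normalization

Cross-sample comparability uses median scaling anchored on
rank-conserved genes. Eligibility requires a gene's expression to lie
within `[Q1, Q3]` of *every* sample's distribution (not the pooled one),
so the anchor is mid-range wherever it is used. Rank conservation is
the variance, across samples, of the gene's within-sample rank
(average ranks on ties) — the simplest strictly ordered stability
score; the `n = 1000` smallest scores are kept, ties broken by
lexicographic gene id for determinism, and a shortfall below `n` is
flagged rather than fatal. Each sample is then shifted (on log2; a
multiplicative factor on RPKM) so that its reference-gene median meets
the common target, chosen as the median of the per-sample reference
medians — the minimal total shift. The procedure is idempotent, and a
per-sample rescaling is absorbed exactly, so all downstream ratio
statistics — which compare values within a sample or between
identically scaled samples — are invariant to per-sample scale. Zeros
never enter log space: logs are taken only of expressed (positive)
values. For cross-species scaling, `familyExpressionMatrix()` assembles
a family × sample matrix over 1:1 families so the same machinery
applies jointly across species; the default remains within-species
scaling.

## Ratio statistics

**Expressed genes.** Three filter modes: `rpkm_gt0` (RPKM > 0, the
default), `reads_ge1`, `reads_ge3` (require the count assay). Ratio
callers intersect the indicator over the samples they compare — an M:F
ratio uses genes expressed in both sexes.

**M:F.** Per-gene `log2(M/F)` (replicates collapsed by median),
minus the median autosomal `log2(M/F)` of the same tissue: autosomes
carry no expected sex bias, so this cancels global technical
differences between the sexed samples. A global per-sex scale factor
provably drops out.

**X:AA.** Median of expressed X(Z) genes over the median of expressed
autosomal genes; optionally restricted to 1:1-conserved genes (X genes
in full-panel families, autosomal genes in families autosomal
everywhere). The result object stores per-gene
`log2(x_g / med(A))`, whose median is the X:AA log-ratio.

**Ancestral levels.** For each family, the ortholog's expression in
each valid outgroup (matched tissue, both sexes pooled — the gene is
autosomal there, so sexes are interchangeable; replicates collapsed by
median), then the median across outgroups on the *linear* RPKM scale
(RPKM is the declared currency; a log-scale median of two outgroups
would silently become a geometric mean). Families sex-linked in any
used outgroup are excluded; families expressed in no outgroup are
missing, not zero. Valid outgroups come from an exclusion table keyed
by focal species — outgroups must have non-homologous sex chromosomes.
Both outgroups contribute symmetrically when two are available.

**X:pXX.** Per gene expressed on both the current X and the proto-X:
`(x_g / med(A)) / (x̂_g / med(Â))` with `med(A)`/`med(Â)` the current
and ancestral medians of families autosomal in all species. The double
normalization makes the statistic invariant to per-sample and
per-species scale and cancels the (small) upward bias of a linear-scale
median across outgroups, since the background is estimated the same
way. On noise-free data the statistic equals
(current X:AA)/(ancestral X:AA) exactly.

**Intervals.** All medians carry subsampling intervals: 100
without-replacement draws of `ceil(0.8 N)` genes, central 95% (or 90%)
quantiles of the draw medians, seeded. X:AA resamples the X and
autosomal sets jointly. These intervals describe the within-sample
stability of the median; they are not calibrated frequentist
confidence intervals (subsampling quantiles without an `m/n`
rescaling under-cover the truth — roughly half of intervals at these
settings contain the generating value in our synthetic checks), which
is why the package's recovery tests assert absolute accuracy of the
median rather than interval coverage.

**Tests.** One-sample two-sided Wilcoxon signed-rank against
`log2(0.5) / 0 / log2(2)`; zero differences dropped (signed-rank
convention; an empty test yields p = 1), exact null for n ≤ 25 without
ties, otherwise the normal approximation with continuity correction.
Correction is Bonferroni or Benjamini-Hochberg at a caller-supplied
family size, because correction scope legitimately varies — across
species and tissues per reference value for M:F, across tissues within
a species for X:pXX. Distribution shifts use the asymptotic two-sided
Kolmogorov-Smirnov test; between-chromosome heterogeneity uses
Kruskal-Wallis on per-chromosome expressed-gene distributions. The
refined heterogametic-subset analysis selects genes whose
heterogametic-sex X:pXX lies in `[0.71, 1.41]` (within half a log2
unit of 1; stricter `[0.81, 1.23]` available) and reports the median
homogametic-sex ratio over that subset — distinguishing sex-specific
from shared upregulation.

## Tissue specificity

Consensus expression is the per-tissue median across samples (sexes and
replicates pooled; NAs dropped). The specificity index is consensus in
a tissue over the summed consensus across the run's tissues (six by
default; seven with ovary for platypus-style analyses): 0 = silent
there but expressed elsewhere, 1 = expressed only there; indices of an
expressed gene sum to 1, unexpressed genes are flagged and excluded
from denominators. Two classification rules, each allowing at most one
tissue per gene: the two-fold rule (consensus at least twice the
*maximum* other tissue — the strictest reading of "higher than the
other tissues" — and positive, inclusive ≥) and the index rule
(index strictly > 0.75, the threshold that separates the bimodal index
distribution; 0.75 itself is excluded). X-versus-autosome enrichment of
testis-specific genes is a two-sided Fisher exact test; genes expressed
nowhere never enter the table. Old/recent partitioning: old iff the
gene's family spans the full species panel.

## Interaction and enrichment analyses

Autosomal interactors of downregulated ("type 1") versus other
("type 2") X-linked genes are collected by PPI adjacency; a gene
adjacent to both X types legitimately appears in both arms. The 2×2
downregulation table is tested with an exact Fisher test implemented
by hypergeometric summation — two-sided p is the total probability of
tables no more probable than the observed one (with a 1e-7 relative
tie guard, the conventional definition) — and reported with the sample
odds ratio ad/bc; zero margins give p = 1 and an undefined OR.
Transcription-module enrichment is the hypergeometric upper tail
`P(K ≥ observed)` with expectation `moduleSize × xCount / universe`;
the downregulated gene lists themselves are inputs (they come from a
prior biclustering, which this package does not re-implement), and PPI
confidence scores are accepted but unused unless a threshold is given.

## Simulations

**Read-sampling noise.** 600 hypothetical genes with expected coverages
1..600 (180,300 reads); each replicate allocates all reads multinomially
with probabilities proportional to expected coverage (read totals are
conserved exactly by construction), 1,000 replicates; per gene the
median of `(|t−s|/t)·100`. The curve tracks the Poisson closed form
`67.45/√t`, with one caveat worth knowing: the statistic is quantized
to multiples of `100/t`, so at low coverage the discrete median sits on
a lattice point rather than on the smooth curve (at t = 28 the exact
median is 4/28 ≈ 14.3% while the closed form gives 12.75%). Lookups
use the nearest design point; the unit-spaced default grid needs no
interpolation.

**Threshold bias.** Autosomal expression is drawn normal on log2
(parameterized by an observed median and sd — log-normal RPKM being the
natural choice where the generating law is unstated), an X1 set follows
the same law, and X2 is X1 halved. Rising expressed-gene thresholds
censor the shifted X2 distribution from below, dragging the measured
X2:AA from 0.5 toward 1 while X1:AA stays near 1 — the artefact that
makes stringent expression cutoffs overstate dosage compensation.

**Duplication rates.** Paralogy groups on a branch are classified
predominantly-X or predominantly-autosomal by the strict-majority rule
(> 50% of members on one chromosome); the rate ratio normalizes group
counts by chromosome gene counts; protein-identity comparison takes one
median identity per group, then the median over groups per class.

## The synthetic-data generator

`generateDataset()` emulates the study's data shape: a species panel
(default: two therian-like XY species sharing homology group "x", an
XY platypus-like and a ZW bird-like species sharing the partially
homologous group "z"), 1:1 families with per-tissue log-normal
baselines (log2 RPKM ~ N(3, 2), i.e. median 8 RPKM — a realistic bulk
RNA-seq scale), optional per-species log-normal divergence,
species-private "recent" genes with elevated testis-specific planting
on sex chromosomes (testis-specific means the testis baseline with
other tissues 20-fold lower, putting the planted index at 0.8), and a
multiplicative dose on sex-linked genes per the contract above
(u ∈ [1, 2], scope heterogametic-only or both sexes, optional
inactivation, optional extra testis reduction in the heterogametic sex
to mimic meiotic sex-chromosome inactivation). Biological noise is
multiplicative log-normal (sd in log2 units); an optional Poisson
count layer resamples reads at the RPKM-implied expectation. A PPI
layer plants autosomal downregulation at a coupled rate (default 0.13)
among interactors of "dropped" sex-linked genes against a background
rate (default 0.06), mirroring the magnitude of the published
interaction contrast. Everything is deterministic given the seed.

In noise-free mode the pipeline reproduces the contract *exactly*
(equality to numerical precision), because every sex-linked gene's
value is its ancestral baseline times the dose and the autosomal
backgrounds coincide. Presets: `eutherian` (u = 1, inactivation:
dose 0.5/0.5), `marsupial` (u = 2 both sexes + inactivation: 1/1),
`monotreme` and `bird` (u = 1.48 heterogametic-only, no inactivation:
0.74 het / 1 hom — the partial, largely sex-specific compensation
pattern).

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: mappability/GC/length
biases, correlated noise across genes or tissues, incomplete or leaky
inactivation varying by gene, escape regions, lineage-specific tissue
gains/losses, or realistic phylogenetic covariance (cross-species
correlation is induced only through shared family baselines).

## Numerical conventions and degenerate inputs

Quartiles and interval quantiles use R's default (type 7) definition.
Reference-gene ties break lexicographically. A single-value resample
yields the degenerate interval [v, v]. Empty gene sets, missing
reference genes, unknown tissue/sex codes, duplicate genes, negative
expression, 1:1 violations and inconsistent counts all raise distinct
condition classes (`dc_*`) so callers can catch them by name. Seeded
routines save and restore the caller's RNG state.

## Problem sizes in the shipped tests

The recovery checks run 50 generator seeds per scenario at 1,200 old
families (15% sex-linked per homology group, i.e. 180 sex-linked old
genes), biological noise sd 0.5, one tissue per run; the
interaction-power check uses 3,000 families with 3 interactors per
sex-linked gene so the two interactor arms stay nearly disjoint. These
sizes give the recovery and power assertions comfortable margins under
their stated thresholds while keeping the suite fast.

## Known limitations

The package consumes expression tables; read mapping, annotation,
orthology calling, module discovery and retrocopy filtering are
upstream. Subsampling intervals are descriptive (see above). The
ancestral estimator is a plain median over outgroups — no
phylogenetic weighting — and with two outgroups the linear-scale
median is their midpoint. Region-class analyses (XCR, PAR) are label
filters; no genomic coordinates are modelled.
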