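---
title: "Methods: CD8+ T cell signaling modules and the Immune Subtype Classification"
author: "iscCD8 maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CD8+ T cell signaling modules and the Immune Subtype Classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscCD8)
```

# Scope and model

`iscCD8` implements a CD8+ T cell analysis chain for colorectal cancer
(CRC), from single-cell expression and TCR tables to a bulk-tumor patient
classification with survival comparison. CRC splits into microsatellite
instable (MSI) and stable (MSS) subtypes with very different immune
landscapes; the chain quantifies that contrast through five connected
layers:

1. **IFNG gating.** Cells are called `IFNG`-positive by binarizing
   log2-CPM expression at a bimodal valley (operationally 0.2). Both QC
   ("more than" 200 genes and 1000 reads) and binarization use *strict*
   inequalities; the boundary cell is removed/negative. The binarization
   convention at the threshold itself is not dictated by the gating idea,
   so strictness is a documented package choice, applied consistently.
2. **Tumor-reactive signaling modules.** Within IFNG+ cells, a 39-gene
   universe (exhaustion markers, cytokine/TCR-signaling components,
   transcription factors, and `IFNG`) is partitioned by hierarchical
   clustering: Spearman correlation between genes, Euclidean distance
   between correlation profiles, complete linkage, tree cut at k = 5.
   Rank correlation is used throughout (ties by average ranks). The
   canonical 10-module configuration (5 per subtype) is shipped as a GMT;
   four genes whose module membership is not pinned down by the primary
   module descriptions (`SLAMF6`, `JAK3`, `NFATC1`, `IL18R1`) are placed
   by marker literature and flagged `inferred` in the GMT description
   column. Discovery mode can regenerate a partition from data.
3. **Activation axes.** Each cell is scored by Spearman correlation to a
   TCR-activation centroid and to a bystander-activation centroid over a
   shared signature. The *directionality* statistic is
   `median(r_TCR) - median(r_bystander)`; absolute values below 0.2 are
   non-directional. Quadrants are cut at a reference center taken as the
   per-axis **mean** of normal-tissue cell scores (the center convention
   is a package choice; median is one argument away). High/Low is strict
   at the center.
4. **TCR repertoire.** Local alignment under BLOSUM62 with open and
   extension penalties of 4 (a gap of length L costs `4 + 4*(L-1)`);
   identity is the query score as a fraction of the target self-score.
   MAIT calling multiplies alpha- and beta-chain identities against known
   invariant pairs and keeps the best product. Tumor-exclusive TCRs have
   best normal-tissue beta-chain identity strictly below 0.80. Clonotypes
   are exact CDR3-nucleotide matches across all productive chains of a
   cell; clonotype clusters connect sequences with alignment distance
   `d(a,b) = min(self(a), self(b)) - score(a,b)` at most 15 (connected
   components). This distance form is a package definition (the upstream
   toolkit's formula is not public) and is isolated behind
   `alignmentDistance()` so it can be swapped. Epitope annotation takes
   the most frequent (epitope, organism) among reference hits within the
   cutoff; ties are `ambiguous`, misses `Unknown`, and exclusive calls
   override the family. Diversity uses bias-corrected Chao1, normalized
   Shannon entropy (`H/ln S`, 0 for a single clone), and Heip's evenness
   (`(e^H - 1)/(S - 1)`, 1 for a single clone); the single-clone
   conventions are documented choices for degenerate repertoires.
5. **ISC and survival.** Bulk cohorts are L1-normalized per patient
   (normalization precedes distances; the alternative order changes
   nothing for rank correlations and is therefore moot). For each module,
   patient–patient distance is `1 - Spearman` over the module's genes —
   a correlation is a similarity, so the standard conversion applies —
   and the per-module matrices are averaged. Agglomerative clustering
   uses average linkage on the precomputed averaged distance (the
   conventional choice for precomputed dissimilarities); k is selected by
   mean silhouette width over 2..5 with a fixed-k override (2 for MSI, 5
   for MSS reproduces the canonical granularity; the coarser
   inflamed-vs-silent split is obtained by pooling ISC2x vs ISC3x).
   Naming: the MSI cluster with the higher stem-like-progenitor metagene
   is ISC1a; MSS clusters are ranked by overall mean metagene, split into
   ISC2 (up to 3) and ISC3 (up to 2) at the largest gap, ties broken by
   the long-term-immunosurveillance metagene then lexicographically.
   Label transfer uses repeated 5-fold cross-validated random forests;
   per-model impurity importances are normalized to sum 1 (keeping the
   0.001 retention threshold on the conventional scale) and averaged,
   and a balanced-class-weight probability forest is refit on the
   retained genes (seed 12; 5000 trees by default, 500 in the bundled
   pipeline and checks). Kaplan–Meier estimation and the two-group
   log-rank test are implemented directly (events precede censoring at
   tied times); the established survival implementations serve as
   independent oracles in the test suite only.

# What the generators emulate

The three generators produce inputs with the statistical structure the
chain assumes, so every stage is testable offline.

**Single cell** (`simulateScExpression`): Gaussian log-scale expression,
one compound-symmetric block per planted module
(`x = mu + noiseSd*(sqrt(rho) F + sqrt(1-rho) E)`), truncation at zero,
and an `IFNG` row drawn from a two-component mixture whose components are
clipped away from the 0.2 valley (low below 0.18, high above 0.30), so
the configured positive fraction is exactly the gated fraction and the
kernel-density valley falls in the empty band. `IFNG` is never part of a
correlation block — its marginal is owned by the gating model — and the
constructor rejects configurations that plant it. Defaults: 10 patients
x 200 cells, the five MSI modules planted at rho 0.8, noise SD 0.5,
IFNG+ fraction 0.45.

**TCR repertoire** (`simulateTcrRepertoire`): discretized-Pareto clone
sizes (exponent 1.2 by default; large exponents flatten toward uniform),
six epitope families with proportions (viral 0.45, bacterial/self/shared
0.05 each, exclusive 0.2, unknown 0.2). Annotated families carry CDR3s
mutated from reference entries by conservative BLOSUM62 substitutions at
a per-residue rate (default 0.05) and are planted in the normal-tissue
beta pool; exclusive clonotypes are redrawn until no normal chain reaches
75% identity (a margin below the 80% calling threshold); MAIT cells carry
exact known pairs, which are also treated as public normal-tissue
sequences. The shipped MAIT pair table is synthetic
(invariant TRAV1-2/TRAJ33-style alphas) and named accordingly.

**Bulk cohort** (`simulateBulkCohort`): baseline gene means U(2, 6), unit
noise, 60 unstructured noise genes, and per-group module shifts. A
configured shift is the module's **mean** metagene shift; it is
distributed over the module's genes with loadings spaced over
`-0.5..2.5` in a fixed, deterministic per-(module, group) order. Two
facts force this design. First, the per-signature patient distance is a
rank correlation over the module's genes, so a *uniform* module shift is
invisible to it — only gene-specific response amplitudes change a
module's internal profile. Second, if all groups shared one loading
order, different shift magnitudes would produce the same rank direction
and remain indistinguishable. Group-specific amplitude orders are
biologically plausible (patient groups engage module genes with
different relative strength) and make the planted partition recoverable.
The canonical MSI cohort (n = 60) plants a stem-like-driven ISC1a-like
group (stem shift 3 SD, immunosurveillance 2.5, exhaustion mildly
suppressed) against an exhaustion-led ISC1b-like group; the canonical
MSS cohort (n = 150) plants three inflamed groups with strong, partially
overlapping module emphases and two immune-silent groups modeled as
suppression of distinct modules below baseline, with a deliberate gap in
overall signal between the ISC2 and ISC3 sides. Survival is exponential
with group hazards (ISC1b 2x; ISC3 3x) and independent exponential
censoring calibrated to a 30% baseline rate.

What the generators do *not* emulate: count-level noise (the chain
consumes log-normalized values, so count realism buys nothing), batch
effects, doublets, read-level artifacts, V(D)J recombination realism, or
inter-gene correlation outside planted modules. Passing tests therefore
demonstrate that the implementations recover the structures they claim
to recover at the stated effect sizes — not that real cohorts carry
those structures at those effect sizes.

# Numerical choices and degenerate inputs

- KDE valley detection uses `stats::density` defaults; constant or
  unimodal input falls back to 0.2 with a warning.
- Zero-variance genes in module discovery are assigned to the module of
  the gene with the nearest mean expression, with a warning; zero-variance
  cells get `NA` activation scores.
- Patients constant over a module's genes yield `NA` distance entries
  with a warning; all-equal distance matrices collapse to k = 1.
- Clonotype ids are content hashes of the sorted `locus:junction`
  strings — stable across runs and record orderings.
- Empty normal repertoires make every tumor TCR exclusive, with a
  warning, rather than erroring.
- Forests run single-threaded with fixed seeds; results are bit-stable.
- `.seedStream` fans one user seed into per-stage child seeds so stages
  can be re-run independently yet reproducibly.

# Problem sizes

The bundled checks use 2,000 cells for module recovery, cohorts of 60
(MSI) and 150 (MSS) patients for ISC recovery and label transfer
(500-tree forests), 1,000 random CDR3s for alignment identity, and
500/200 replicates for log-rank calibration/power. These sizes were
chosen to estimate each property comfortably; all scale linearly if
larger studies are wanted.

# Known limitations

- The shipped module memberships transcribe the primary descriptions;
  four placements are literature-inferred and flagged in the GMT.
- The epitope reference is a schema-compatible synthetic stand-in, not a
  live database export; annotation quality on real data depends on the
  reference actually supplied.
- The clonotype-cluster distance is a package definition (see above).
- Cox proportional-hazards modeling and batch correction are outside
  scope; established packages should be used directly.
- k-selection by silhouette can merge genuinely adjacent patient groups
  at small effect sizes; the fixed-k override exists for exactly that
  case.
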