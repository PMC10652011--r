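# iscCD8

CD8+ T cell signaling modules and the Immune Subtype Classification (ISC)
for colorectal cancer, as a tested, end-to-end R package.

## The problem

Colorectal cancer splits into microsatellite-instable (MSI) tumors —
mutation-rich, T-cell infiltrated, checkpoint-blockade responsive — and
microsatellite-stable (MSS) tumors, where infiltrating CD8+ T cells are
often *bystanders*: activated, but recognizing tumor-irrelevant (viral,
microbial, self) antigens. Separating genuine tumor reactivity from
bystander activation requires connecting single-cell transcriptomes with
TCR repertoire specificity, and then carrying the resulting signal to bulk
tumor transcriptomes where survival and treatment data live.

`iscCD8` implements that chain for analysts working on CRC immunology:

- **Preprocessing**: QC (strictly >200 genes, >1000 reads per cell),
  log2-CPM normalization, bimodal gating of *IFNG* at the density valley
  (0.2 log2-CPM).
- **Signaling modules**: hierarchical co-expression discovery over a
  39-gene tumor-reactive universe in *IFNG*+ cells
  (Spearman correlation → Euclidean distance of correlation profiles →
  complete linkage, k = 5), binarized activation maps, signature scores,
  metagenes, Jaccard module overlap. The canonical 10-module GMT (5 per
  subtype) ships with the package.
- **Activation axes**: per-cell Spearman correlation to TCR-activation
  and bystander-activation centroids, quadrant partition against a
  normal-tissue reference center, and the directionality statistic
  `median(R_SPA) − median(R_SPB)` (|d| < 0.2 ⇒ non-directional).
- **TCR repertoire**: BLOSUM62 local-alignment identity (open/extend 4),
  MAIT calling (product of chain identities against known invariant
  pairs), tumor-exclusive calling (<80% identity to any normal beta
  chain), clonotypes (exact CDR3-nt), clonotype clusters (alignment
  distance ≤ 15), most-frequent epitope annotation with
  ambiguous/Unknown handling, and Chao1 / normalized Shannon / Heip
  diversity.
- **ISC**: per-module patient distances `1 − Spearman` on L1-normalized
  bulk expression, averaged and clustered agglomeratively (average
  linkage, silhouette-selected k ≤ 5); clusters named ISC1a/1b (MSI) and
  ISC2a–c / ISC3a–b (MSS) from module metagene profiles; an
  importance-filtered (> 0.001, repeated 5-fold CV) balanced random
  forest transfers labels to new cohorts.
- **Survival**: Kaplan–Meier product-limit curves and the two-group
  log-rank test.
- **Synthetic data**: generators for single-cell expression (planted
  correlation blocks, bimodal *IFNG*), TCR repertoires (power-law clone
  sizes, planted epitope families, exclusive and MAIT cells), and bulk
  cohorts (planted ISC groups with group-dependent exponential
  survival), so the whole chain runs and is tested without any download.

## Worked example

Stratify a synthetic MSS cohort and compare survival between the
inflamed (ISC2) and immune-silent (ISC3) sides:

```r
library(iscCD8)

signalingModules("MSI")
#> SignalingModuleSet (MSI): 5 modules, 28 unique genes
#>   stem_like_progenitor [4]: TCF7, IL2, CD28, SLAMF6
#>   inflamed_follicular_like [3]: CXCR5, BCL6, ICOS
#>   long_term_immunosurveillance [5]: EOMES, TBX21, PRDM1, KLRK1, KLRG1
#>   tumor_reactive_exhaustion [9]: IFNG, LAG3, PDCD1, CTLA4, TIGIT, ENTPD1, HAVCR2, CXCL13, NFATC2
#>   memory_differentiation [7]: TOX, IL15RA, NFATC3, NFIL3, STAT1, STAT2, JAK3

mss <- simulateBulkCohort(bulkSimConfigMss(seed = 770), signalingModules("MSS"))
pdm <- patientDistance(l1Normalize(mss$expression), signalingModules("MSS"))
cl  <- iscCluster(pdm)          # silhouette picks k
cl$k
#> [1] 5

mg  <- vapply(moduleGenes(signalingModules("MSS")),
              function(g) metagene(mss$expression, g),
              numeric(ncol(mss$expression)))
lab <- labelIsc(cl$labels, mg, subtype = "MSS")
table(called = iscLabels(lab), planted = mss$groups)
#>        planted
#> called  ISC2a ISC2b ISC2c ISC3a ISC3b
#>   ISC2a    30     0     0     0     0
#>   ISC2b     0    30     0     0     0
#>   ISC2c     0     0    30     0     0
#>   ISC3a     0     0     0    30     0
#>   ISC3b     0     0     0     0    30

sv   <- mss$survival
side <- ifelse(grepl("^ISC2", iscLabels(lab)[sv$patient_id]),
               "inflamed", "immune-silent")
a <- sv[side == "inflamed", ]; b <- sv[side == "immune-silent", ]
lr <- logrankTest(a$time, a$event, b$time, b$event)
sprintf("chi2 = %.1f, p = %.2g", lr$chi2, lr$p)
#> [1] "chi2 = 35.0, p = 3.2e-09"
```

The five planted patient groups are recovered exactly, the clusters are
named by their module metagene profiles, and the planted 3x hazard of the
immune-silent side shows up as a decisive log-rank difference (median
survival ~31 vs ~9 months in this draw). `runPipeline(runConfig())`
executes the same chain end to end — single-cell simulation, module
discovery, activation axes, TCR annotation, ISC, survival — and writes
header-commented TSVs plus a JSON manifest to an output directory
(`inst/scripts/run-pipeline.R` is a command-line wrapper).

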