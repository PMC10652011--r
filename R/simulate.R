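## One global seed fans out into per-generator child seeds so stages can be
## rerun independently yet reproducibly.
.seedStream <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## ---------------------------------------------------------------------------
## Configuration constructors (the study conditions live in these defaults)
## ---------------------------------------------------------------------------

#' Construct simulation configurations
#'
#' Constructors with validated defaults representing the emulated study
#' conditions. `scSimConfig()` defaults to 10 patients x 200 cells over the
#' 39-gene universe with the five MSI modules planted at rank correlation
#' 0.8; `IFNG` is never part of a planted block because its values follow
#' the two-component gating mixture instead.
#'
#' @param nPatients,cellsPerPatient cohort shape.
#' @param geneUniverse gene symbols (must include `IFNG`).
#' @param plantedModules named list of disjoint gene sets (no `IFNG`).
#' @param rho within-module rank correlation in `[0, 1]`.
#' @param ifngPositiveFraction fraction of cells in the high IFNG component.
#' @param noiseSd per-gene expression standard deviation.
#' @param seed integer seed.
#' @return a validated [ScSimConfig-class].
#' @export
scSimConfig <- function(nPatients = 10, cellsPerPatient = 200,
                        geneUniverse = tumorReactiveUniverse(),
                        plantedModules = NULL,
                        rho = 0.8, ifngPositiveFraction = 0.45,
                        noiseSd = 0.5, seed = 770) {
  if (is.null(plantedModules)) {
    plantedModules <- lapply(moduleGenes(signalingModules("MSI")),
                             setdiff, y = "IFNG")
  }
  if ("IFNG" %in% unlist(plantedModules))
    stop("IFNG cannot be planted in a correlation block; ",
         "its values follow the bimodal gating mixture")
  ov <- unlist(plantedModules)
  if (anyDuplicated(ov))
    stop("overlapping planted modules: ",
         paste(unique(ov[duplicated(ov)]), collapse = ", "))
  new("ScSimConfig", nPatients = as.integer(nPatients),
      cellsPerPatient = as.integer(cellsPerPatient),
      geneUniverse = geneUniverse, plantedModules = plantedModules,
      rho = rho, ifngPositiveFraction = ifngPositiveFraction,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @rdname scSimConfig
#' @param nClonotypes number of tumor clonotypes.
#' @param expansionExponent Pareto tail exponent for clone sizes.
#' @param familyProportions named proportions over the epitope families.
#' @param nMaitPairs cells carrying an exact known MAIT alpha/beta pair.
#' @param mutationRate per-residue substitution probability for planted
#'   near-match decoys.
#' @return `tcrSimConfig`: a validated [TcrSimConfig-class].
#' @export
tcrSimConfig <- function(nClonotypes = 60, expansionExponent = 1.2,
                         familyProportions = c(viral = 0.45,
                                               bacterial = 0.05,
                                               self = 0.05, shared = 0.05,
                                               exclusive = 0.2,
                                               unknown = 0.2),
                         nMaitPairs = 5, mutationRate = 0.05, seed = 770) {
  new("TcrSimConfig", nClonotypes = as.integer(nClonotypes),
      expansionExponent = expansionExponent,
      familyProportions = familyProportions,
      nMaitPairs = as.integer(nMaitPairs),
      mutationRate = mutationRate, seed = as.integer(seed))
}

#' @rdname scSimConfig
#' @param groupLabels planted group per patient (recycled in order).
#' @param metageneShift groups x modules shift matrix (noise-SD units).
#' @param baselineHazard baseline event hazard per month.
#' @param groupHazardRatio named hazard multiplier per group.
#' @param censorRate target censoring proportion.
#' @param nNoiseGenes unstructured genes appended to the universe.
#' @return `bulkSimConfig`: a validated [BulkSimConfig-class].
#' @export
bulkSimConfig <- function(nPatients, groupLabels, metageneShift,
                          baselineHazard = 0.02, groupHazardRatio,
                          censorRate = 0.3, nNoiseGenes = 60, seed = 770) {
  new("BulkSimConfig", nPatients = as.integer(nPatients),
      groupLabels = groupLabels, metageneShift = metageneShift,
      baselineHazard = baselineHazard,
      groupHazardRatio = groupHazardRatio, censorRate = censorRate,
      nNoiseGenes = as.integer(nNoiseGenes), seed = as.integer(seed))
}

#' Canonical planted MSI bulk cohort
#'
#' Two groups of 60 patients: an ISC1a-like group driven by a 3-SD
#' stem-like-progenitor shift (with immunosurveillance signal and mildly
#' suppressed exhaustion) and an ISC1b-like mixed-inflammatory group led by
#' tumor-reactive exhaustion with follicular and memory-differentiation
#' signal. The ISC1b-like group carries a 2x event hazard.
#'
#' @param nPatients cohort size (default 60).
#' @param seed integer seed.
#' @return a [BulkSimConfig-class].
#' @export
bulkSimConfigMsi <- function(nPatients = 60, seed = 770) {
  mods <- moduleNames(signalingModules("MSI"))
  shift <- matrix(0, 2, length(mods),
                  dimnames = list(c("ISC1a", "ISC1b"), mods))
  shift["ISC1a", "stem_like_progenitor"] <- 3
  shift["ISC1a", "long_term_immunosurveillance"] <- 2.5
  shift["ISC1a", "tumor_reactive_exhaustion"] <- -2
  shift["ISC1b", "tumor_reactive_exhaustion"] <- 3
  shift["ISC1b", "inflamed_follicular_like"] <- 2.5
  shift["ISC1b", "memory_differentiation"] <- 2
  bulkSimConfig(nPatients = nPatients,
                groupLabels = rep(c("ISC1a", "ISC1b"),
                                  length.out = nPatients),
                metageneShift = shift,
                groupHazardRatio = c(ISC1a = 1, ISC1b = 2),
                seed = seed)
}

#' Canonical planted MSS bulk cohort
#'
#' Five groups of 150 patients emulating the inflamed (`ISC2a/2b/2c`) to
#' immune-silent (`ISC3a/3b`) gradient: each group has a distinct module
#' emphasis so rank-correlation patient distances separate them, the
#' inflamed side carries strong positive module shifts while the
#' immune-silent side suppresses distinct modules below baseline, and the
#' overall signal drops sharply between the ISC2 and ISC3 sides (the gap
#' that drives naming). ISC3 groups carry a 3x event hazard.
#'
#' @param nPatients cohort size (default 150).
#' @param seed integer seed.
#' @return a [BulkSimConfig-class].
#' @export
bulkSimConfigMss <- function(nPatients = 150, seed = 770) {
  mods <- moduleNames(signalingModules("MSS"))
  grp <- c("ISC2a", "ISC2b", "ISC2c", "ISC3a", "ISC3b")
  shift <- matrix(0, 5, length(mods), dimnames = list(grp, mods))
  shift["ISC2a", ] <- c(5, 4, 4, 4, 4)
  shift["ISC2b", ] <- c(4, 1, 4, 1, 4)
  shift["ISC2c", ] <- c(1, 4, 3, 4, 1)
  shift["ISC3a", ] <- c(0, -4, 0, 0, -5)
  shift["ISC3b", ] <- c(-3, 0, -5, -3, 0)
  bulkSimConfig(nPatients = nPatients,
                groupLabels = rep(grp, length.out = nPatients),
                metageneShift = shift,
                groupHazardRatio = c(ISC2a = 1, ISC2b = 1, ISC2c = 1,
                                     ISC3a = 3, ISC3b = 3),
                seed = seed)
}

## ---------------------------------------------------------------------------
## Single-cell expression generator
## ---------------------------------------------------------------------------

#' Simulate single-cell log-normalized expression
#'
#' Gaussian-on-log-scale generator: each planted module is a
#' compound-symmetric correlation block (`x = mu_g + noiseSd * (sqrt(rho) F
#' + sqrt(1 - rho) E)`, one shared factor `F` per module), remaining genes
#' are independent, and all values are truncated at 0. The `IFNG` row is a
#' two-component mixture: a near-zero component (clipped below 0.18) and a
#' clearly-expressed component (clipped above 0.30), so the density valley
#' sits near the 0.2 gate and exactly the configured fraction of cells is
#' positive. Cells carry patient, tissue, subtype and subpopulation
#' metadata.
#'
#' @param config a [ScSimConfig-class].
#' @param normalFraction fraction of each patient's cells labeled as
#'   normal-adjacent tissue (default 0.25).
#' @return a `SingleCellExperiment` (assay `logcounts`).
#' @export
simulateScExpression <- function(config, normalFraction = 0.25) {
  validObject(config)
  seeds <- .seedStream(config@seed, 3L)
  genes <- config@geneUniverse
  nCells <- config@nPatients * config@cellsPerPatient
  set.seed(seeds[1L])
  mu <- stats::setNames(stats::runif(length(genes), 1, 3), genes)
  expr <- matrix(0, length(genes), nCells,
                 dimnames = list(genes,
                                 sprintf("cell%05d", seq_len(nCells))))
  set.seed(seeds[2L])
  inModule <- character(0)
  for (m in names(config@plantedModules)) {
    g <- config@plantedModules[[m]]
    inModule <- c(inModule, g)
    f <- stats::rnorm(nCells)
    e <- matrix(stats::rnorm(length(g) * nCells), length(g), nCells)
    z <- sqrt(config@rho) * rep(f, each = length(g)) +
      sqrt(1 - config@rho) * e
    expr[g, ] <- mu[g] + config@noiseSd * z
  }
  rest <- setdiff(genes, c(inModule, "IFNG"))
  if (length(rest))
    expr[rest, ] <- mu[rest] +
      config@noiseSd * matrix(stats::rnorm(length(rest) * nCells),
                              length(rest), nCells)
  ## bimodal IFNG mixture gated near 0.2
  pos <- stats::runif(nCells) < config@ifngPositiveFraction
  low <- pmin(abs(stats::rnorm(nCells, 0, 0.05)), 0.18)
  high <- pmax(stats::rnorm(nCells, 1.2, 0.35), 0.30)
  expr["IFNG", ] <- ifelse(pos, high, low)
  expr[expr < 0] <- 0
  set.seed(seeds[3L])
  patient <- rep(sprintf("P%02d", seq_len(config@nPatients)),
                 each = config@cellsPerPatient)
  tissue <- unlist(lapply(seq_len(config@nPatients), function(p) {
    nn <- round(normalFraction * config@cellsPerPatient)
    c(rep("normal", nn), rep("tumor", config@cellsPerPatient - nn))
  }))
  subtype <- ifelse(as.integer(factor(patient)) <=
                      ceiling(config@nPatients / 2), "MSI", "MSS")
  pops <- c("central_memory", "exhausted", "memory_exhausted",
            "naive", "resident_memory", "MAIT_like")
  subpop <- sample(pops, nCells, replace = TRUE)
  sce <- makeCellTable(expr, patient = patient, tissue = tissue,
                       subtype = subtype, subpopulation = subpop)
  S4Vectors::metadata(sce)$plantedModules <- config@plantedModules
  S4Vectors::metadata(sce)$seeds <- seeds
  sce
}

## ---------------------------------------------------------------------------
## TCR repertoire generator
## ---------------------------------------------------------------------------

## most conservative BLOSUM62 replacements (highest off-diagonal score) so
## planted decoys stay within the alignment-distance cutoff
.conservativeSub <- c(
  A = "S", C = "A", D = "E", E = "D", F = "Y", G = "A", H = "N", I = "V",
  K = "R", L = "M", M = "L", N = "H", P = "A", Q = "E", R = "K", S = "T",
  T = "S", V = "I", W = "Y", Y = "F"
)

.randomCdr3 <- function(n, minLen = 10, maxLen = 16) {
  len <- sample(minLen:maxLen, n, replace = TRUE)
  vapply(len, function(l) {
    paste0("C", paste(sample(.AA, l - 2L, replace = TRUE), collapse = ""),
           "F")
  }, character(1))
}

.mutateCdr3 <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  ## first and last residues (anchor C/F) are kept
  idx <- which(stats::runif(length(ch)) < rate)
  idx <- setdiff(idx, c(1L, length(ch)))
  ch[idx] <- unname(.conservativeSub[ch[idx]])
  paste(ch, collapse = "")
}

.reverseTranslate <- function(aa) {
  codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  vapply(aa, function(s)
    paste(codons[strsplit(s, "")[[1L]]], collapse = ""), character(1),
    USE.NAMES = FALSE)
}

#' Simulate a single-cell TCR repertoire with planted specificities
#'
#' Generates a tumor repertoire (AIRR-style records, one TRA and one TRB row
#' per cell), a matching epitope reference table, a normal-adjacent
#' beta-chain pool, and the planted truth. Clone sizes follow a discretized
#' Pareto law with the configured exponent. Clonotypes of the viral /
#' bacterial / self / shared families carry CDR3s mutated from reference
#' entries at the configured per-residue rate and are also planted in the
#' normal pool; `exclusive` clonotypes are re-drawn until no normal beta
#' chain reaches 80% alignment identity; `unknown` clonotypes match nothing.
#' `nMaitPairs` extra cells carry exact known MAIT alpha/beta pairs.
#'
#' @param config a [TcrSimConfig-class].
#' @param nNormalExtra extra unrelated normal-tissue beta chains
#'   (default 30).
#' @return list with `records` (AIRR data.frame), `reference` (epitope
#'   reference data.frame), `normalBeta` (character), `truth` (per-clonotype
#'   data.frame: `beta_aa`, `alpha_aa`, `family`, `epitope`, `organism`,
#'   `size`).
#' @export
simulateTcrRepertoire <- function(config, nNormalExtra = 30) {
  validObject(config)
  seeds <- .seedStream(config@seed, 2L)
  set.seed(seeds[1L])
  n <- config@nClonotypes
  fam <- names(config@familyProportions)
  nFam <- floor(config@familyProportions * n)
  while (sum(nFam) < n) {           # largest-remainder top-up
    r <- config@familyProportions * n - nFam
    i <- which.max(r)
    nFam[i] <- nFam[i] + 1L
  }
  families <- rep(fam, times = nFam)
  ## reference: 2 epitopes per annotated family, 3 CDR3 variants each
  refFam <- c("viral", "bacterial", "self", "shared")
  epNames <- list(
    viral = c("GILGFVFTL_like", "NLVPMVATV_like"),
    bacterial = c("riboflavin_deriv_1", "riboflavin_deriv_2"),
    self = c("self_antigen_1", "self_antigen_2"),
    shared = c("MAGE_like", "NYESO_like"))
  orgNames <- c(viral = "Influenza-like virus",
                bacterial = "Mycobacterium-like",
                self = "Homo sapiens",
                shared = "Homo sapiens (shared tumor)")
  ref <- do.call(rbind, lapply(refFam, function(fm) {
    do.call(rbind, lapply(epNames[[fm]], function(ep) {
      base <- .randomCdr3(1)
      ch <- strsplit(base, "")[[1L]]
      v1 <- ch; v1[3L] <- unname(.conservativeSub[v1[3L]])
      v2 <- ch; v2[5L] <- unname(.conservativeSub[v2[5L]])
      data.frame(junction_aa = c(base, paste(v1, collapse = ""),
                                 paste(v2, collapse = "")),
                 locus = "TRB", epitope = ep, organism = orgNames[[fm]],
                 family = fm, stringsAsFactors = FALSE)
    }))
  }))
  rownames(ref) <- NULL
  baseRows <- ref[!duplicated(ref$epitope), ]
  ## clone sizes: discretized Pareto, xm = 1
  sizes <- pmax(1L, floor(stats::runif(n)^(-1 / config@expansionExponent)))
  mait <- maitReferencePairs()
  ## invariant MAIT receptors are public sequences, present in normal tissue
  normalBeta <- c(.randomCdr3(nNormalExtra), mait$beta_aa)
  beta <- character(n); alpha <- .randomCdr3(n)
  epitope <- organism <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fm <- families[i]
    if (fm %in% refFam) {
      row <- baseRows[sample(which(baseRows$family == fm), 1L), ]
      beta[i] <- .mutateCdr3(row$junction_aa, config@mutationRate)
      epitope[i] <- row$epitope; organism[i] <- row$organism
      normalBeta <- c(normalBeta, beta[i])
    } else if (fm == "unknown") {
      beta[i] <- .randomCdr3(1)
      normalBeta <- c(normalBeta, beta[i])
    } else {                                   # exclusive
      repeat {
        cand <- .randomCdr3(1)
        near <- max(identityFraction(cand, c(normalBeta,
                                             ref$junction_aa)))
        if (near < 0.75) { beta[i] <- cand; break }
      }
    }
  }
  ## cells: clone-size copies of each clonotype, plus exact MAIT pairs
  cellClone <- rep(seq_len(n), times = sizes)
  nCells <- length(cellClone)
  maitIdx <- if (config@nMaitPairs > 0)
    sample(nrow(mait), config@nMaitPairs, replace = TRUE) else integer(0)
  cellId <- sprintf("tcell%05d", seq_len(nCells + config@nMaitPairs))
  alphaAa <- c(alpha[cellClone], mait$alpha_aa[maitIdx])
  betaAa <- c(beta[cellClone], mait$beta_aa[maitIdx])
  set.seed(seeds[2L])
  records <- rbind(
    data.frame(cell_id = cellId, locus = "TRA",
               junction = .reverseTranslate(alphaAa),
               junction_aa = alphaAa,
               v_call = sample(paste0("TRAV", 1:20), length(cellId),
                               replace = TRUE),
               j_call = sample(paste0("TRAJ", 1:30), length(cellId),
                               replace = TRUE),
               productive = TRUE,
               duplicate_count = stats::rpois(length(cellId), 3) + 1L,
               stringsAsFactors = FALSE),
    data.frame(cell_id = cellId, locus = "TRB",
               junction = .reverseTranslate(betaAa),
               junction_aa = betaAa,
               v_call = sample(paste0("TRBV", 1:25), length(cellId),
                               replace = TRUE),
               j_call = sample(paste0("TRBJ", 1:12), length(cellId),
                               replace = TRUE),
               productive = TRUE,
               duplicate_count = stats::rpois(length(cellId), 3) + 1L,
               stringsAsFactors = FALSE))
  records <- records[order(records$cell_id, records$locus), ]
  rownames(records) <- NULL
  truth <- data.frame(beta_aa = beta, alpha_aa = alpha, family = families,
                      epitope = epitope, organism = organism, size = sizes,
                      stringsAsFactors = FALSE)
  list(records = records, reference = ref, normalBeta = normalBeta,
       truth = truth)
}

## ---------------------------------------------------------------------------
## Bulk cohort generator
## ---------------------------------------------------------------------------

## fixed gene-amplitude permutation per (module, group): a structural
## property of the generator, not a random draw, so it is derived from the
## names alone and identical across seeds
.loadingPermutation <- function(moduleName, groupName, L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  key <- sum(utf8ToInt(paste0(moduleName, "|", groupName)) *
               seq_along(utf8ToInt(paste0(moduleName, "|", groupName))))
  set.seed(1000L + key %% 100000L)
  sample(L)
}

#' Simulate a bulk cohort with planted ISC structure and survival
#'
#' Expression for the 39-gene universe (plus unstructured noise genes) with
#' per-group module shifts: a group's configured mean shift for a module is
#' distributed over the module's genes with per-gene loadings spaced over
#' `-0.5..2.5` (mean 1, so the configured value is the module's mean
#' metagene shift; a slightly negative tail lets some genes respond against
#' the module, as dysfunctional modules do). The loading order is a fixed
#' deterministic permutation per (module, group), i.e. groups activate the
#' same module with different relative gene amplitudes, which makes group
#' structure recoverable by rank-correlation patient distances.
#' Survival times are exponential with the group's hazard; censoring is an
#' independent exponential clock calibrated so the baseline-hazard group is
#' censored at the configured rate.
#'
#' @param config a [BulkSimConfig-class].
#' @param modules [SignalingModuleSet-class] whose modules the shift-matrix
#'   columns refer to.
#' @return list with `expression` (genes x patients), `survival`
#'   (data.frame `patient_id`, `time`, `event`, `group`) and `groups`
#'   (named planted labels).
#' @export
simulateBulkCohort <- function(config, modules) {
  validObject(config)
  if (is(modules, "SignalingModuleSet")) modules <- moduleGenes(modules)
  missing <- setdiff(colnames(config@metageneShift), names(modules))
  if (length(missing))
    stop("shift columns without module definition: ",
         paste(missing, collapse = ", "))
  seeds <- .seedStream(config@seed, 2L)
  set.seed(seeds[1L])
  genes <- tumorReactiveUniverse()
  if (config@nNoiseGenes > 0)
    genes <- c(genes, sprintf("NOISE%03d", seq_len(config@nNoiseGenes)))
  n <- config@nPatients
  pid <- sprintf("B%03d", seq_len(n))
  groups <- stats::setNames(rep(config@groupLabels, length.out = n), pid)
  mu <- stats::setNames(stats::runif(length(genes), 2, 6), genes)
  expr <- mu + matrix(stats::rnorm(length(genes) * n), length(genes), n)
  dimnames(expr) <- list(genes, pid)
  glev <- rownames(config@metageneShift)
  for (m in colnames(config@metageneShift)) {
    g <- intersect(modules[[m]], genes)
    base <- seq(-0.5, 2.5, length.out = length(g))
    for (grp in glev) {
      idx <- which(groups == grp)
      if (!length(idx)) next
      load <- base[.loadingPermutation(m, grp, length(g))]
      expr[g, idx] <- expr[g, idx] +
        load * config@metageneShift[grp, m]
    }
  }
  expr[expr < 0] <- 0
  set.seed(seeds[2L])
  hz <- config@baselineHazard *
    config@groupHazardRatio[as.character(groups)]
  tEvent <- stats::rexp(n, rate = hz)
  if (config@censorRate > 0) {
    cRate <- config@baselineHazard * config@censorRate /
      (1 - config@censorRate)
    tCens <- stats::rexp(n, rate = cRate)
  } else {
    tCens <- rep(Inf, n)
  }
  surv <- data.frame(patient_id = pid,
                     time = pmin(tEvent, tCens),
                     event = tEvent <= tCens,
                     group = unname(groups),
                     stringsAsFactors = FALSE)
  list(expression = expr, survival = surv, groups = groups)
}
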