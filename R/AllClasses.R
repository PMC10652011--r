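#' @import methods
NULL

## ---------------------------------------------------------------------------
## Simulation configurations
## ---------------------------------------------------------------------------

#' Single-cell expression simulation configuration
#'
#' Parameters for [simulateScExpression()]. Expression is drawn as a
#' multivariate Gaussian on the log scale, one compound-symmetric correlation
#' block per planted module, truncated at zero; `IFNG` is a two-component
#' mixture gated at a detection valley near 0.2 so the bimodal gating step has
#' something real to find.
#'
#' @slot nPatients number of patients.
#' @slot cellsPerPatient cells simulated per patient.
#' @slot geneUniverse character vector of gene symbols; must contain `IFNG`.
#' @slot plantedModules named list of disjoint gene sets drawn from
#'   `geneUniverse`.
#' @slot rho within-module rank correlation target in `[0, 1]`.
#' @slot ifngPositiveFraction fraction of cells in the high `IFNG` mixture
#'   component.
#' @slot noiseSd non-negative independent noise standard deviation.
#' @slot seed integer seed.
#'
#' @exportClass ScSimConfig
setClass("ScSimConfig",
  representation(
    nPatients = "integer",
    cellsPerPatient = "integer",
    geneUniverse = "character",
    plantedModules = "list",
    rho = "numeric",
    ifngPositiveFraction = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("ScSimConfig", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (object@cellsPerPatient < 1L) msg <- c(msg, "cellsPerPatient must be >= 1")
  if (!"IFNG" %in% object@geneUniverse)
    msg <- c(msg, "geneUniverse must include IFNG")
  if (anyDuplicated(object@geneUniverse))
    msg <- c(msg, "geneUniverse contains duplicated symbols")
  mod <- unlist(object@plantedModules, use.names = FALSE)
  if (length(mod) && anyDuplicated(mod))
    msg <- c(msg, "plantedModules must be disjoint gene sets")
  if (length(mod) && !all(mod %in% object@geneUniverse))
    msg <- c(msg, "plantedModules must be subsets of geneUniverse")
  if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
  if (object@ifngPositiveFraction < 0 || object@ifngPositiveFraction > 1)
    msg <- c(msg, "ifngPositiveFraction must be in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TCR repertoire simulation configuration
#'
#' Parameters for [simulateTcrRepertoire()]. Clone sizes follow a discretized
#' Pareto law; clonotypes are assigned to epitope families; non-exclusive
#' clonotypes are near-copies (per-residue substitution probability
#' `mutationRate`) of reference CDR3s, while planted exclusive clonotypes are
#' guaranteed to have no normal-tissue beta-chain neighbor at or above 80%
#' alignment identity.
#'
#' @slot nClonotypes number of tumor clonotypes.
#' @slot expansionExponent positive Pareto tail exponent; large values give
#'   near-uniform clone sizes.
#' @slot familyProportions named numeric over
#'   `c("viral","bacterial","self","shared","exclusive","unknown")`, summing
#'   to 1.
#' @slot nMaitPairs number of cells carrying an exact known MAIT alpha/beta
#'   pair.
#' @slot mutationRate per-residue substitution probability for near-match
#'   decoys.
#' @slot seed integer seed.
#'
#' @exportClass TcrSimConfig
setClass("TcrSimConfig",
  representation(
    nClonotypes = "integer",
    expansionExponent = "numeric",
    familyProportions = "numeric",
    nMaitPairs = "integer",
    mutationRate = "numeric",
    seed = "integer"
  )
)

setValidity("TcrSimConfig", function(object) {
  msg <- character()
  fam <- c("viral", "bacterial", "self", "shared", "exclusive", "unknown")
  if (object@nClonotypes < 1L) msg <- c(msg, "nClonotypes must be >= 1")
  if (object@expansionExponent <= 0)
    msg <- c(msg, "expansionExponent must be > 0")
  if (!setequal(names(object@familyProportions), fam))
    msg <- c(msg, paste("familyProportions must be named over:",
                        paste(fam, collapse = ", ")))
  if (abs(sum(object@familyProportions) - 1) > 1e-9)
    msg <- c(msg, "familyProportions must sum to 1 (tolerance 1e-9)")
  if (any(object@familyProportions < 0))
    msg <- c(msg, "familyProportions must be non-negative")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be in [0, 1]")
  if (object@nMaitPairs < 0L) msg <- c(msg, "nMaitPairs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bulk cohort simulation configuration
#'
#' Parameters for [simulateBulkCohort()]. Patients receive group-dependent
#' shifts of the signaling-module metagenes (distributed over module genes
#' with fixed per-gene loadings) and exponential survival with group-dependent
#' hazards plus independent exponential censoring.
#'
#' @slot nPatients number of patients.
#' @slot groupLabels character vector of planted group names, recycled over
#'   patients in order.
#' @slot metageneShift numeric matrix, groups x modules: mean shift (in noise
#'   SD units) applied to each module's metagene for each group.
#' @slot baselineHazard positive baseline event hazard (per month).
#' @slot groupHazardRatio named positive hazard multiplier per group.
#' @slot censorRate target censoring proportion in `[0, 1)`.
#' @slot nNoiseGenes unstructured genes appended to the module universe.
#' @slot seed integer seed.
#'
#' @exportClass BulkSimConfig
setClass("BulkSimConfig",
  representation(
    nPatients = "integer",
    groupLabels = "character",
    metageneShift = "matrix",
    baselineHazard = "numeric",
    groupHazardRatio = "numeric",
    censorRate = "numeric",
    nNoiseGenes = "integer",
    seed = "integer"
  )
)

setValidity("BulkSimConfig", function(object) {
  msg <- character()
  if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
  grp <- unique(object@groupLabels)
  if (!all(grp %in% rownames(object@metageneShift)))
    msg <- c(msg, "every group label needs a row in metageneShift")
  if (!all(grp %in% names(object@groupHazardRatio)))
    msg <- c(msg, "every group label needs a groupHazardRatio entry")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (any(object@groupHazardRatio <= 0))
    msg <- c(msg, "groupHazardRatio values must be > 0")
  if (object@censorRate < 0 || object@censorRate >= 1)
    msg <- c(msg, "censorRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Analysis containers
## ---------------------------------------------------------------------------

#' Named tumor-reactive signaling module set
#'
#' A named list of gene sets over the 39-gene tumor-reactive universe, tied to
#' a CRC subtype (`MSI` or `MSS`; `both` for combined sets). The canonical
#' configuration carries 5 modules per subtype.
#'
#' @slot subtype `"MSI"`, `"MSS"` or `"both"`.
#' @slot modules named list of character gene vectors.
#' @slot provenance per-module character note (e.g. whether a membership was
#'   transcribed from the primary description or inferred from marker
#'   literature).
#'
#' @exportClass SignalingModuleSet
setClass("SignalingModuleSet",
  representation(
    subtype = "character",
    modules = "list",
    provenance = "character"
  )
)

setValidity("SignalingModuleSet", function(object) {
  msg <- character()
  if (!object@subtype %in% c("MSI", "MSS", "both"))
    msg <- c(msg, "subtype must be MSI, MSS or both")
  if (is.null(names(object@modules)) || any(names(object@modules) == ""))
    msg <- c(msg, "modules must be a named list")
  if (!all(vapply(object@modules, is.character, logical(1))))
    msg <- c(msg, "each module must be a character vector of gene symbols")
  if (any(vapply(object@modules, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "modules must not contain duplicated genes")
  if (length(msg)) msg else TRUE
})

#' Per-signature and averaged patient-patient distances
#'
#' Holds one symmetric, zero-diagonal distance matrix per signaling module
#' (`1 - Spearman` over that module's genes) plus their arithmetic mean, the
#' manifold in which ISC agglomerative clustering operates.
#'
#' @slot patients ordered patient identifiers.
#' @slot perSignature named list of symmetric distance matrices.
#' @slot averaged symmetric matrix, the arithmetic mean of `perSignature`.
#'
#' @exportClass PatientDistanceMatrix
setClass("PatientDistanceMatrix",
  representation(
    patients = "character",
    perSignature = "list",
    averaged = "matrix"
  )
)

setValidity("PatientDistanceMatrix", function(object) {
  msg <- character()
  n <- length(object@patients)
  chk <- function(m) {
    is.matrix(m) && all(dim(m) == n) &&
      max(abs(m - t(m)), na.rm = TRUE) < 1e-8 &&
      all(abs(diag(m)) < 1e-8)
  }
  if (!all(vapply(object@perSignature, chk, logical(1))))
    msg <- c(msg, "perSignature matrices must be symmetric with zero diagonal")
  if (!chk(object@averaged))
    msg <- c(msg, "averaged matrix must be symmetric with zero diagonal")
  ps <- Reduce(`+`, object@perSignature) / length(object@perSignature)
  if (max(abs(ps - object@averaged), na.rm = TRUE) > 1e-8)
    msg <- c(msg, "averaged must equal the mean of perSignature matrices")
  if (length(msg)) msg else TRUE
})

#' ISC patient labeling
#'
#' Maps patients to Immune Subtype Classification labels. MSI patients take
#' `ISC1a`/`ISC1b`; MSS patients take the inflamed `ISC2a/2b/2c` or the
#' immune-silent `ISC3a/3b` labels.
#'
#' @slot subtype `"MSI"` or `"MSS"`.
#' @slot labels named character vector, patient -> ISC label.
#' @slot clusters named integer vector, patient -> raw cluster id.
#' @slot profile matrix of per-cluster mean module metagenes used for naming.
#'
#' @exportClass IscLabeling
setClass("IscLabeling",
  representation(
    subtype = "character",
    labels = "character",
    clusters = "integer",
    profile = "matrix"
  )
)

setValidity("IscLabeling", function(object) {
  msg <- character()
  if (!object@subtype %in% c("MSI", "MSS"))
    msg <- c(msg, "subtype must be MSI or MSS")
  ok <- if (object@subtype == "MSI") c("ISC1a", "ISC1b")
        else c("ISC2a", "ISC2b", "ISC2c", "ISC3a", "ISC3b")
  if (!all(object@labels %in% ok))
    msg <- c(msg, paste0("labels for subtype ", object@subtype,
                         " must be in {", paste(ok, collapse = ", "), "}"))
  if (length(object@labels) != length(object@clusters))
    msg <- c(msg, "labels and clusters must align")
  if (length(msg)) msg else TRUE
})

#' Importance-filtered ISC random-forest classifier
#'
#' @slot selectedGenes genes retained by cross-validated importance filtering.
#' @slot forest the fitted probability forest (a `ranger` object).
#' @slot classLevels label levels in training order.
#' @slot training list of training metadata (folds, repeats, seed, threshold,
#'   number of trees).
#'
#' @exportClass IscClassifier
setClass("IscClassifier",
  representation(
    selectedGenes = "character",
    forest = "ANY",
    classLevels = "character",
    training = "list"
  )
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ScSimConfig", function(object) {
  cat("ScSimConfig:", object@nPatients, "patients x",
      object@cellsPerPatient, "cells,", length(object@geneUniverse),
      "genes,", length(object@plantedModules), "planted modules (rho =",
      object@rho, "), IFNG+ fraction", object@ifngPositiveFraction,
      ", seed", object@seed, "\n")
})

setMethod("show", "TcrSimConfig", function(object) {
  cat("TcrSimConfig:", object@nClonotypes, "clonotypes, exponent",
      object@expansionExponent, ", mutation rate", object@mutationRate,
      ",", object@nMaitPairs, "MAIT pairs, seed", object@seed, "\n")
})

setMethod("show", "BulkSimConfig", function(object) {
  cat("BulkSimConfig:", object@nPatients, "patients,",
      length(unique(object@groupLabels)), "planted groups, baseline hazard",
      object@baselineHazard, ", censor rate", object@censorRate,
      ", seed", object@seed, "\n")
})

setMethod("show", "SignalingModuleSet", function(object) {
  cat("SignalingModuleSet (", object@subtype, "): ",
      length(object@modules), " modules, ",
      length(unique(unlist(object@modules))), " unique genes\n", sep = "")
  for (nm in names(object@modules))
    cat("  ", nm, " [", length(object@modules[[nm]]), "]: ",
        paste(object@modules[[nm]], collapse = ", "), "\n", sep = "")
})

setMethod("show", "PatientDistanceMatrix", function(object) {
  cat("PatientDistanceMatrix:", length(object@patients), "patients,",
      length(object@perSignature), "signatures averaged\n")
})

setMethod("show", "IscLabeling", function(object) {
  cat("IscLabeling (", object@subtype, "): ", length(object@labels),
      " patients\n", sep = "")
  print(table(object@labels))
})

setMethod("show", "IscClassifier", function(object) {
  cat("IscClassifier:", length(object@selectedGenes), "selected genes,",
      length(object@classLevels), "classes (",
      paste(object@classLevels, collapse = ", "), "),",
      object@training$nTrees, "trees\n")
})
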