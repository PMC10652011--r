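#' Synthetic TCR/bystander activation reference centroids
#'
#' Fabricates the two reference expression centroids (average TCR-activated
#' and average bystander-activated profiles) used by [scoreActivation()],
#' playing the role of published activation signatures in synthetic runs.
#' The two profiles are drawn independently, so they are only weakly
#' rank-correlated.
#'
#' @param genes gene symbols for the signature.
#' @param seed integer seed.
#' @return data.frame with `gene`, `tcr_mean`, `bystander_mean`.
#' @export
simulateActivationCentroids <- function(genes, seed = 770) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(gene = genes,
             tcr_mean = stats::runif(length(genes), 0, 4),
             bystander_mean = stats::runif(length(genes), 0, 4),
             stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' All stage toggles and thresholds in one validated list. Defaults
#' reproduce the canonical fixed parameters: QC gates (>200 genes, >1000
#' reads), binarization 0.2, clonotype-cluster alignment cutoff 15,
#' exclusive-TCR identity 0.80, feature-importance 0.001, non-directional
#' band 0.2.
#'
#' @param stages character subset of
#'   `c("simulate", "modules", "activation", "tcr", "isc", "survival")`.
#' @param binarizationThreshold expression gate (default 0.2).
#' @param alignmentCutoff clonotype-cluster distance cutoff (default 15).
#' @param exclusiveThreshold identity threshold for exclusive TCRs
#'   (default 0.80).
#' @param importanceThreshold classifier feature filter (default 0.001).
#' @param directionalityBand non-directional half-width (default 0.2).
#' @param minGenes,minReads QC gates (defaults 200, 1000).
#' @param nTrees classifier trees for the pipeline run (default 500).
#' @param seed global seed fanned out to stage child seeds.
#' @return named list of class `"iscRunConfig"`.
#' @export
runConfig <- function(stages = c("simulate", "modules", "activation",
                                 "tcr", "isc", "survival"),
                      binarizationThreshold = 0.2, alignmentCutoff = 15,
                      exclusiveThreshold = 0.80,
                      importanceThreshold = 0.001,
                      directionalityBand = 0.2, minGenes = 200,
                      minReads = 1000, nTrees = 500, seed = 770) {
  known <- c("simulate", "modules", "activation", "tcr", "isc", "survival")
  stopifnot(all(stages %in% known))
  structure(list(stages = stages,
                 binarizationThreshold = binarizationThreshold,
                 alignmentCutoff = alignmentCutoff,
                 exclusiveThreshold = exclusiveThreshold,
                 importanceThreshold = importanceThreshold,
                 directionalityBand = directionalityBand,
                 minGenes = minGenes, minReads = minReads,
                 nTrees = nTrees, seed = as.integer(seed)),
            class = "iscRunConfig")
}

.writeTsv <- function(df, dir, name, producer, params = "") {
  path <- file.path(dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(paste0("# produced_by: ", producer,
                    if (nzchar(params)) paste0(" | ", params) else ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(df)) &&
                       !identical(rownames(df),
                                  as.character(seq_len(nrow(df)))))
  close(con)
  path
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' single-cell simulation; module discovery and activation mapping on IFNG+
#' cells; TCR/bystander activation scoring with quadrants and
#' directionality; TCR repertoire annotation, exclusivity and diversity;
#' bulk ISC stratification (MSI and MSS cohorts) with classifier label
#' transfer; and survival comparison between the planted prognostic sides.
#' Every table is written as a header-commented TSV under `outDir`, and a
#' JSON manifest records seeds, parameters and stage outputs. Rerunning
#' with the same config reproduces identical outputs.
#'
#' @param config list from [runConfig()].
#' @param outDir output directory (created if needed).
#' @return (invisibly) a named list of in-memory stage results; the
#'   manifest is written to `file.path(outDir, "manifest.json")`.
#' @export
runPipeline <- function(config = runConfig(), outDir = tempfile("iscrun")) {
  stopifnot(inherits(config, "iscRunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .seedStream(config$seed, 6L)
  res <- list()
  manifest <- list(config = unclass(config), seeds = seeds,
                   outputs = list())
  stage <- function(s) s %in% config$stages
  if (stage("simulate")) {
    sce <- simulateScExpression(scSimConfig(seed = seeds[1L]))
    res$cells <- sce
    manifest$outputs$simulate <- .writeTsv(
      as.data.frame(SummarizedExperiment::colData(sce)), outDir,
      "cell_metadata", "simulateScExpression",
      paste0("seed=", seeds[1L]))
  }
  if (stage("modules")) {
    if (is.null(res$cells)) stop("stage 'modules' needs stage 'simulate'")
    sce <- res$cells
    ifngPos <- SummarizedExperiment::colData(sce)$ifng_positive
    part <- discoverModules(sce[, ifngPos], k = 5)
    amap <- activationMap(
      sce[, ifngPos], signalingModules("MSI"),
      groups = SummarizedExperiment::colData(sce)$subpopulation[ifngPos],
      threshold = config$binarizationThreshold)
    res$modulePartition <- part
    res$activationMap <- amap
    manifest$outputs$modules <- c(
      .writeTsv(data.frame(gene = names(part), module = part), outDir,
                "module_partition", "discoverModules", "k=5"),
      .writeTsv(as.data.frame(amap), outDir, "activation_map",
                "activationMap",
                paste0("threshold=", config$binarizationThreshold)))
  }
  if (stage("activation")) {
    if (is.null(res$cells)) stop("stage 'activation' needs 'simulate'")
    sce <- res$cells
    cd <- SummarizedExperiment::colData(sce)
    cen <- simulateActivationCentroids(rownames(sce), seed = seeds[2L])
    sc <- scoreActivation(sce, cen)
    refIdx <- cd$tissue == "normal" & cd$ifng_positive
    ref <- referenceCenter(sc[refIdx, ])
    tum <- sc[cd$tissue == "tumor" & cd$ifng_positive, ]
    quad <- quadrantPartition(tum, ref)
    dirn <- directionality(tum$r_tcr, tum$r_bys,
                           nonDirectionalBand = config$directionalityBand)
    res$activation <- list(scores = sc, reference = ref,
                           quadrants = quad, directionality = dirn)
    manifest$outputs$activation <- .writeTsv(
      cbind(tum, quadrant = quad$quadrant), outDir, "activation_scores",
      "scoreActivation/quadrantPartition",
      paste0("band=", config$directionalityBand))
  }
  if (stage("tcr")) {
    rep <- simulateTcrRepertoire(tcrSimConfig(seed = seeds[3L]))
    cl <- defineClonotypes(rep$records)
    beta <- rep$records[rep$records$locus == "TRB", ]
    betaByClone <- beta$junction_aa[match(cl$cell_id, beta$cell_id)]
    uniq <- !duplicated(cl$clonotype_id)
    excl <- callExclusive(betaByClone[uniq], rep$normalBeta,
                          threshold = config$exclusiveThreshold)
    ann <- annotateEpitopes(betaByClone[uniq], rep$reference,
                            exclusive = excl,
                            cutoff = config$alignmentCutoff)
    sizes <- clonalExpansion(cl)
    div <- c(chao1 = chao1(sizes$n_cells),
             shannon = shannonNormalized(sizes$n_cells),
             heip = heipEvenness(sizes$n_cells))
    res$tcr <- list(repertoire = rep, clonotypes = cl, annotation = ann,
                    exclusive = excl, diversity = div)
    writeAirr(rep$records, file.path(outDir, "repertoire_airr.tsv"))
    manifest$outputs$tcr <- c(
      file.path(outDir, "repertoire_airr.tsv"),
      .writeTsv(cbind(ann, exclusive = excl), outDir,
                "clonotype_annotation", "annotateEpitopes",
                paste0("cutoff=", config$alignmentCutoff)))
  }
  if (stage("isc")) {
    out <- list()
    for (st in c("MSI", "MSS")) {
      cfg <- if (st == "MSI") bulkSimConfigMsi(seed = seeds[4L])
             else bulkSimConfigMss(seed = seeds[5L])
      mods <- signalingModules(st)
      bulk <- simulateBulkCohort(cfg, mods)
      l1 <- l1Normalize(bulk$expression)
      pdm <- patientDistance(l1, mods)
      cl <- iscCluster(pdm, k = if (st == "MSI") 2 else 5)
      mg <- vapply(moduleGenes(mods), function(g)
        metagene(bulk$expression, g), numeric(ncol(bulk$expression)))
      lab <- labelIsc(cl$labels, mg, subtype = st)
      out[[st]] <- list(bulk = bulk, distance = pdm, labeling = lab)
      manifest$outputs[[paste0("isc_", st)]] <- .writeTsv(
        data.frame(patient = patientIds(lab), label = iscLabels(lab),
                   group = bulk$groups[patientIds(lab)]),
        outDir, paste0("isc_labels_", st), "iscCluster/labelIsc",
        paste0("subtype=", st))
    }
    res$isc <- out
  }
  if (stage("survival")) {
    if (is.null(res$isc)) stop("stage 'survival' needs stage 'isc'")
    mss <- res$isc$MSS
    side <- stats::setNames(
      ifelse(grepl("^ISC2", iscLabels(mss$labeling)),
             "inflamed", "immune_silent"),
      patientIds(mss$labeling))
    sv <- mss$bulk$survival
    sv$side <- side[sv$patient_id]
    a <- sv[sv$side == "inflamed", ]
    b <- sv[sv$side == "immune_silent", ]
    lr <- logrankTest(a$time, a$event, b$time, b$event)
    km <- list(inflamed = kmEstimate(a$time, a$event),
               immune_silent = kmEstimate(b$time, b$event))
    res$survival <- list(logrank = lr, km = km, table = sv)
    manifest$outputs$survival <- .writeTsv(
      data.frame(side = c("inflamed", "immune_silent"),
                 n = c(nrow(a), nrow(b)),
                 chi2 = lr$chi2, p = lr$p), outDir, "survival_logrank",
      "logrankTest", "sides=ISC2 vs ISC3")
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
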