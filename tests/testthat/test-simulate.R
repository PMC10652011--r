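library(SummarizedExperiment)

test_that("all three generators are deterministic under a fixed seed", {
  s1 <- simulateScExpression(scSimConfig(nPatients = 2,
                                         cellsPerPatient = 50, seed = 5))
  s2 <- simulateScExpression(scSimConfig(nPatients = 2,
                                         cellsPerPatient = 50, seed = 5))
  expect_identical(assay(s1, "logcounts"), assay(s2, "logcounts"))

  r1 <- simulateTcrRepertoire(tcrSimConfig(nClonotypes = 20, seed = 5))
  r2 <- simulateTcrRepertoire(tcrSimConfig(nClonotypes = 20, seed = 5))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$reference, r2$reference)

  b1 <- simulateBulkCohort(bulkSimConfigMsi(nPatients = 20, seed = 5),
                           signalingModules("MSI"))
  b2 <- simulateBulkCohort(bulkSimConfigMsi(nPatients = 20, seed = 5),
                           signalingModules("MSI"))
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$survival, b2$survival)
})

test_that("rho = 0 gives near-independent genes; planted blocks are
          recoverable by module discovery", {
  mods <- list(m1 = c("TCF7", "IL2", "CD28", "SLAMF6", "CXCR5"),
               m2 = c("EOMES", "TBX21", "PRDM1", "KLRK1", "KLRG1"))
  sce0 <- simulateScExpression(scSimConfig(
    nPatients = 10, cellsPerPatient = 200, plantedModules = mods,
    rho = 0, seed = 31))
  expr <- assay(sce0, "logcounts")[unlist(mods), ]
  rc <- cor(t(expr), method = "spearman")
  expect_lt(max(abs(rc[upper.tri(rc)])), 0.1)

  sce8 <- simulateScExpression(scSimConfig(
    nPatients = 10, cellsPerPatient = 200, plantedModules = mods,
    rho = 0.8, seed = 31))
  part <- discoverModules(sce8, genes = unlist(mods), k = 2)
  truth <- rep(names(mods), lengths(mods))
  expect_equal(ariOracle(part[unlist(mods)], truth), 1.0)
})

test_that("IFNG mixture hits the configured positive fraction at the 0.2
          gate", {
  sce <- simulateScExpression(scSimConfig(
    nPatients = 5, cellsPerPatient = 400,
    ifngPositiveFraction = 0.45, seed = 8))
  frac <- mean(colData(sce)$ifng_positive)
  expect_gt(frac, 0.40)
  expect_lt(frac, 0.50)
  ## auto-detected valley sits near the planted gate
  thr <- detectBimodalThreshold(assay(sce)["IFNG", ])
  expect_gt(thr, 0.15)
  expect_lt(thr, 0.8)
})

test_that("invalid configurations are rejected with explicit messages", {
  expect_error(scSimConfig(plantedModules = list(a = c("TCF7", "IL2"),
                                                 b = c("IL2", "CD28"))),
               "overlapping")
  expect_error(scSimConfig(plantedModules = list(a = c("IFNG", "IL2"))),
               "IFNG")
  expect_error(tcrSimConfig(familyProportions = c(viral = 0.5,
                                                  bacterial = 0.2,
                                                  self = 0.1, shared = 0.1,
                                                  exclusive = 0.2,
                                                  unknown = 0.2)),
               "sum to 1")
  bad <- bulkSimConfigMsi(nPatients = 10)
  expect_error({bad@groupLabels <- c("ISC1a", "nope"); validObject(bad)},
               "metageneShift")
})

test_that("generated AIRR tables round-trip through the reader", {
  rep <- simulateTcrRepertoire(tcrSimConfig(nClonotypes = 15, seed = 3))
  tmp <- tempfile(fileext = ".tsv")
  writeAirr(rep$records, tmp)
  back <- readAirr(tmp)
  expect_equal(back, rep$records)
})

test_that("large expansion exponent flattens clone sizes toward uniform", {
  rep <- simulateTcrRepertoire(tcrSimConfig(nClonotypes = 80,
                                            expansionExponent = 50,
                                            nMaitPairs = 0, seed = 9))
  sizes <- clonalExpansion(defineClonotypes(rep$records))$n_cells
  expect_gt(shannonNormalized(sizes), 0.99)
})

test_that("clone sizes are heavy-tailed at a small exponent", {
  rep <- simulateTcrRepertoire(tcrSimConfig(nClonotypes = 200,
                                            expansionExponent = 0.8,
                                            nMaitPairs = 0, seed = 10))
  sizes <- clonalExpansion(defineClonotypes(rep$records))$n_cells
  expect_gt(max(sizes), 5)
  expect_lt(shannonNormalized(sizes), 0.99)
})

test_that("zero metagene shifts give chance-level ISC clustering", {
  cfg <- bulkSimConfigMsi(nPatients = 40, seed = 21)
  cfg@metageneShift[] <- 0
  b <- simulateBulkCohort(cfg, signalingModules("MSI"))
  pdm <- patientDistance(l1Normalize(b$expression),
                         signalingModules("MSI"))
  cl <- iscCluster(pdm, k = 2)
  expect_lt(abs(ariOracle(cl$labels, b$groups)), 0.15)
})

test_that("survival times follow the planted group hazards", {
  cfg <- bulkSimConfigMsi(nPatients = 400, seed = 17)
  cfg@censorRate <- 0
  b <- simulateBulkCohort(cfg, signalingModules("MSI"))
  sv <- b$survival
  expect_true(all(sv$event))
  mA <- mean(sv$time[sv$group == "ISC1a"])
  mB <- mean(sv$time[sv$group == "ISC1b"])
  ## hazard ratio 2 halves the mean survival time
  expect_gt(mA / mB, 1.5)
  expect_lt(mA / mB, 2.7)
})
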