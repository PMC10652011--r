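test_that("single-cell patient stratification recovers separable groups
          and co-clusters duplicates", {
  set.seed(21)
  g1 <- matrix(rnorm(10 * 5, 0), 10, 5)
  g2 <- matrix(rnorm(10 * 5, 6), 10, 5)
  mm <- rbind(g1, g2)
  rownames(mm) <- paste0("P", 1:20)
  cl <- stratifyPatientsSc(mm, nClusters = 2)
  expect_equal(ariOracle(cl, rep(1:2, each = 10)), 1)
  dup <- rbind(mm, P21 = mm["P1", ])
  cld <- stratifyPatientsSc(dup, nClusters = 2)
  expect_identical(cld[["P21"]], cld[["P1"]])
  expect_error(stratifyPatientsSc(mm, nClusters = 50), "exceeds")
})

test_that("L1 normalization divides by column sums and is idempotent", {
  m <- cbind(p1 = c(2, 2, 4), p2 = c(1, 0, 0))
  rownames(m) <- paste0("g", 1:3)
  n <- l1Normalize(m)
  expect_equal(unname(n[, "p1"]), c(0.25, 0.25, 0.5))
  expect_equal(colSums(n), c(p1 = 1, p2 = 1))
  expect_equal(l1Normalize(n), n, tolerance = 1e-12)
  set.seed(22)
  r <- matrix(abs(rnorm(12)), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("p", 1:3)))
  expect_equal(l1Normalize(r), sweep(r, 2, colSums(r), "/"),
               tolerance = 1e-12)
  expect_error(l1Normalize(cbind(z = c(0, 0))), "zero-sum")
  expect_error(l1Normalize(cbind(z = c(-1, 2))), "non-negative")
})

test_that("patient distances are 1 - Spearman with hand-checked toys", {
  expr <- cbind(p1 = c(1, 2, 3, 4), p2 = c(2, 4, 6, 8),
                p3 = c(4, 3, 2, 1), p4 = c(1, 3, 2, 4))
  rownames(expr) <- paste0("g", 1:4)
  mods <- list(m = paste0("g", 1:4))
  pdm <- patientDistance(expr, mods)
  d <- averagedDistance(pdm)
  expect_equal(d["p1", "p2"], 0)        # identical ranks
  expect_equal(d["p1", "p3"], 2)        # perfectly anti-ranked
  expect_equal(d["p1", "p4"],
               1 - cor(expr[, "p1"], expr[, "p4"], method = "spearman"))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("PatientDistanceMatrix enforces the averaged = mean invariant", {
  set.seed(23)
  expr <- matrix(abs(rnorm(39 * 12)), 39, 12,
                 dimnames = list(tumorReactiveUniverse(),
                                 paste0("p", 1:12)))
  pdm <- patientDistance(expr, signalingModules("MSI"))
  per <- signatureDistances(pdm)
  expect_length(per, 5)
  expect_equal(averagedDistance(pdm), Reduce(`+`, per) / length(per),
               tolerance = 1e-12)
  expect_warning(
    patientDistance(expr, list(tiny = c("IFNG", "TNF"),
                               ok = tumorReactiveUniverse()[1:6])),
    "fewer than")
  expect_error(
    suppressWarnings(patientDistance(expr,
                                     list(tiny = c("IFNG", "TNF")))),
    "no module")
})

test_that("ISC clustering picks planted k, is order-invariant, and warns
          on degenerate distances", {
  b <- simulateBulkCohort(bulkSimConfigMsi(nPatients = 40, seed = 24),
                         signalingModules("MSI"))
  pdm <- patientDistance(l1Normalize(b$expression),
                         signalingModules("MSI"))
  cl <- iscCluster(pdm)
  expect_equal(cl$k, 2L)
  expect_equal(ariOracle(cl$labels, b$groups), 1)
  d <- averagedDistance(pdm)
  perm <- sample(nrow(d))
  clp <- iscCluster(d[perm, perm])
  expect_equal(ariOracle(cl$labels[rownames(d)[perm]], clp$labels), 1)
  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  flat[] <- 0
  expect_warning(deg <- iscCluster(flat), "degenerate")
  expect_equal(deg$k, 1L)
})

test_that("ISC naming puts stem-like on ISC1a and low signal on the ISC3
          side, invariant to cluster relabeling", {
  mm <- rbind(matrix(c(5, 1, 1, 1, 1), 10, 5, byrow = TRUE),
              matrix(c(0, 3, 3, 3, 3), 10, 5, byrow = TRUE))
  dimnames(mm) <- list(paste0("P", 1:20),
                       moduleNames(signalingModules("MSI")))
  cl <- setNames(rep(1:2, each = 10), rownames(mm))
  lab <- labelIsc(cl, mm, "MSI")
  expect_true(all(iscLabels(lab)[1:10] == "ISC1a"))
  expect_true(all(iscLabels(lab)[11:20] == "ISC1b"))
  labSwap <- labelIsc(setNames(3 - cl, names(cl)), mm, "MSI")
  expect_identical(iscLabels(lab), iscLabels(labSwap))

  ## MSS: one silent cluster must land on the ISC3 side
  mm5 <- rbind(matrix(4, 8, 5), matrix(3, 8, 5), matrix(2.5, 8, 5),
               matrix(0, 8, 5), matrix(-1, 8, 5))
  dimnames(mm5) <- list(paste0("Q", 1:40),
                        moduleNames(signalingModules("MSS")))
  cl5 <- setNames(rep(1:5, each = 8), rownames(mm5))
  lab5 <- labelIsc(cl5, mm5, "MSS")
  expect_identical(unname(iscLabels(lab5)[c(1, 9, 17, 25, 33)]),
                   c("ISC2a", "ISC2b", "ISC2c", "ISC3a", "ISC3b"))
  expect_true(all(iscLabels(lab5)[cl5 == 4] %in% c("ISC3a", "ISC3b")))
})

test_that("feature selection retains a planted informative gene at the
          top and errors on impossible thresholds", {
  set.seed(25)
  n <- 120
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("g", 1:20)))
  y <- factor(ifelse(x[, "g7"] > 0, "hi", "lo"))
  sel <- selectFeatures(x, y, folds = 5, repeats = 1, nTrees = 200,
                        seed = 12)
  imp <- attr(sel, "importance")
  expect_identical(names(imp)[1], "g7")
  expect_true("g7" %in% sel)
  expect_error(selectFeatures(x, y, threshold = Inf, folds = 5,
                              repeats = 1, nTrees = 100),
               "threshold")
})

test_that("the classifier is deterministic, produces unit-sum
          probabilities and imputes missing genes", {
  set.seed(26)
  n <- 100
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:10)))
  y <- factor(ifelse(x[, 1] + x[, 2] > 0, "A", "B"))
  m1 <- trainIscClassifier(x, y, nTrees = 300, seed = 12)
  m2 <- trainIscClassifier(x, y, nTrees = 300, seed = 12)
  p1 <- predictIsc(m1, x)
  p2 <- predictIsc(m2, x)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1[, levels(y)])), rep(1, n),
               tolerance = 1e-9)
  expect_gt(mean(p1$label == y), 0.9)
  expect_warning(pm <- predictIsc(m1, x[, 1:8]), "imputed as 0")
  expect_equal(nrow(pm), n)
  ## constant features carry no signal
  xc <- matrix(1, 40, 4, dimnames = list(NULL, paste0("g", 1:4)))
  yc <- factor(rep(c("A", "B"), 20))
  mc <- trainIscClassifier(xc, yc, nTrees = 100, seed = 12)
  pc <- predictIsc(mc, xc)
  expect_true(all(abs(pc$A - 0.5) < 0.2))
})

test_that("bulk directionality ratio follows metagene arithmetic", {
  expr <- rbind(t1 = c(2, 4), t2 = c(2, 4), b1 = c(2, 2), b2 = c(2, 2))
  colnames(expr) <- c("p1", "p2")
  r <- directionalityRatioBulk(expr, c("t1", "t2"), c("b1", "b2"))
  expect_equal(unname(r), c(1, 2))
  r2 <- directionalityRatioBulk(rbind(expr[1:2, ] * 2, expr[3:4, ]),
                                c("t1", "t2"), c("b1", "b2"))
  expect_equal(unname(r2), 2 * unname(r))
  z <- rbind(t1 = c(1, 1), b1 = c(0, 1))
  colnames(z) <- c("p1", "p2")
  expect_true(is.na(directionalityRatioBulk(z, "t1", "b1")[["p1"]]))
})
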