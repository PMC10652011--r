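mkExpr <- function(nGenes, nCells, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(nGenes * nCells)), nGenes, nCells,
              dimnames = list(paste0("G", seq_len(nGenes)),
                              paste0("c", seq_len(nCells))))
  m
}

test_that("module discovery recovers perfectly separable blocks", {
  set.seed(2)
  f1 <- rnorm(300); f2 <- rnorm(300)
  expr <- rbind(A1 = f1, A2 = f1 * 2 + 5, A3 = f1 + 1,
                B1 = f2, B2 = f2 * 3, B3 = f2 - 2)
  colnames(expr) <- paste0("c", 1:300)
  part <- discoverModules(expr, genes = rownames(expr), k = 2)
  expect_length(unique(part[c("A1", "A2", "A3")]), 1)
  expect_length(unique(part[c("B1", "B2", "B3")]), 1)
  expect_false(part[["A1"]] == part[["B1"]])
})

test_that("module discovery is invariant to cell and gene order and cuts
          to singletons at k = n", {
  expr <- mkExpr(8, 150, seed = 4)
  p1 <- discoverModules(expr, genes = rownames(expr), k = 3)
  p2 <- discoverModules(expr[, sample(ncol(expr))],
                        genes = rownames(expr), k = 3)
  expect_identical(p1, p2)
  p3 <- discoverModules(expr[sample(nrow(expr)), ],
                        genes = rownames(expr), k = 3)
  expect_equal(ariOracle(p1[rownames(expr)], p3[rownames(expr)]), 1)
  pAll <- discoverModules(expr, genes = rownames(expr), k = 8)
  expect_length(unique(pAll), 8)
  expect_error(discoverModules(expr, genes = rownames(expr), k = 9),
               "k exceeds")
})

test_that("zero-variance genes fall back to the nearest module", {
  expr <- mkExpr(6, 100, seed = 5)
  expr["G6", ] <- 1
  expect_warning(part <- discoverModules(expr, genes = rownames(expr),
                                         k = 2),
                 "zero-variance")
  expect_length(part, 6)
  expect_true(part[["G6"]] %in% 1:2)
})

test_that("activation map matches hand-computed binarized means", {
  expr <- rbind(g1 = c(0, 0.5, 1), g2 = c(0.3, 0.1, 0))
  colnames(expr) <- paste0("c", 1:3)
  mods <- list(m = c("g1", "g2"))
  am <- activationMap(expr, mods, groups = c("a", "a", "b"),
                      threshold = 0.2)
  ## group a: cells 1,2 -> values 0,0.5,0.3,0.1 -> 2/4 above 0.2
  expect_equal(am["a", "m"], 0.5)
  expect_equal(am["b", "m"], 0.5)
  expect_true(all(activationMap(expr * 0, mods, c("a", "a", "b")) == 0))
  expect_true(all(activationMap(expr + 10, mods, c("a", "a", "b")) == 1))
})

test_that("activation map is monotone non-increasing in the threshold", {
  expr <- mkExpr(10, 80, seed = 6)
  mods <- list(m1 = paste0("G", 1:5), m2 = paste0("G", 6:10))
  g <- rep(c("x", "y"), each = 40)
  lo <- activationMap(expr, mods, g, threshold = 0.1)
  hi <- activationMap(expr, mods, g, threshold = 0.9)
  expect_true(all(hi <= lo))
})

test_that("empty groups yield NA rows, not zeros", {
  expr <- mkExpr(4, 10, seed = 7)
  g <- factor(rep("a", 10), levels = c("a", "b"))
  am <- activationMap(expr, list(m = paste0("G", 1:4)), g)
  expect_true(is.na(am["b", "m"]))
  expect_false(is.na(am["a", "m"]))
})

test_that("binarized signature scores hit the exact fractions", {
  expr <- rbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(1, 0.5),
                s4 = c(1, 0.5))
  colnames(expr) <- c("hi", "half")
  sc <- scoreSignatureBinarized(expr, paste0("s", 1:4), threshold = 0.2)
  expect_equal(unname(sc), c(1, 0.5))
  expect_equal(unname(scoreSignatureBinarized(expr * 0,
                                              paste0("s", 1:4))),
               c(0, 0))
  expect_error(scoreSignatureBinarized(expr, c("nope1", "nope2")),
               "nope1")
  expect_message(scoreSignatureBinarized(expr, c("s1", "gone")),
                 "gone")
})

test_that("metagene is the per-sample mean over the set", {
  expr <- mkExpr(5, 6, seed = 8)
  expect_equal(metagene(expr, "G2"), expr["G2", ])
  uni <- matrix(3, 4, 2, dimnames = list(paste0("G", 1:4), c("a", "b")))
  expect_equal(unname(metagene(uni, paste0("G", 1:4))), c(3, 3))
  expect_equal(metagene(expr, c("G1", "G4")),
               colMeans(expr[c("G1", "G4"), ]))
  expect_error(metagene(expr, "absent"), "absent")
})

test_that("Jaccard overlap follows the set-arithmetic definition", {
  sets <- list(x = c("a", "b", "c"), y = c("b", "c", "d"),
               z = c("e", "f"), w = c("a", "b", "c"))
  ov <- moduleOverlap(sets)
  expect_equal(ov$jaccard["x", "y"], 0.5)     # 2 / 4
  expect_equal(ov$jaccard["x", "w"], 1.0)
  expect_equal(ov$jaccard["x", "z"], 0.0)
  expect_equal(ov$jaccard, t(ov$jaccard))
  expect_true(all(diag(ov$jaccard) == 1))
  expect_equal(unname(rowSums(ov$presence)), lengths(sets, use.names = FALSE))
  expect_error(moduleOverlap(list(a = "x")), "at least 2")
})
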