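test_that("local alignment reproduces independently computed BLOSUM62
          scores", {
  ## frozen values computed with an independent implementation of
  ## Smith-Waterman local alignment (open/extend both 4)
  expect_equal(localAlign("CASSL", "CASSL"), 25)   # 9+4+4+4+4
  expect_equal(localAlign("CASSLGQAYEQYF", "CASSLGQAEQYF"), 59)
  expect_equal(localAlign("CASSLGQAYEQYF", "CASSLGAYEQYF"), 61)
  expect_equal(localAlign("CAVMDSNYQLIW", "CAVRDSNYQLIW"), 63)
  expect_equal(localAlign("CASRTGESGYTF", "CSARDPGLAGGRPEQYF"), 21)
  expect_equal(localAlign("CASSPTSGGQETQYF", "CASSPTSGGQETQYF"), 82)
  expect_error(localAlign("", "CASSL"), "empty")
  expect_error(localAlign("CAXSL", "CASSL"), "alphabet")
})

test_that("alignment score is symmetric and self-dominant over random
          CDR3s", {
  a <- randomCdr3s(30, seed = 11)
  b <- randomCdr3s(30, seed = 12)
  expect_equal(localAlign(a, b), localAlign(b, a))
  expect_true(all(localAlign(a, a) >= localAlign(a, b)))
})

test_that("identity fraction is 1 on self and clipped to [0, 1]", {
  seqs <- randomCdr3s(100, seed = 13)
  expect_true(all(identityFraction(seqs, seqs) == 1))
  f <- identityFraction(seqs, rev(seqs))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("MAIT score is 1 for exact known pairs, bounded by chain
          fractions, near 0 for unrelated sequences", {
  mp <- maitReferencePairs()
  expect_equal(maitScore(mp$alpha_aa[2], mp$beta_aa[2]), 1.0)
  a <- randomCdr3s(1, seed = 14); b <- randomCdr3s(1, seed = 15)
  s <- maitScore(a, b)
  fa <- max(vapply(mp$alpha_aa, function(x) identityFraction(a, x),
                   numeric(1)))
  fb <- max(vapply(mp$beta_aa, function(x) identityFraction(b, x),
                   numeric(1)))
  expect_lte(s, min(fa, fb) + 1e-12)
  nulls <- vapply(1:20, function(i)
    maitScore(randomCdr3s(1, seed = 100 + i),
              randomCdr3s(1, seed = 200 + i)), numeric(1))
  expect_lt(max(nulls), 0.5)
  expect_true(is.na(maitScore(character(0), "CASSLF")))
})

test_that("exclusive calling is strict at the threshold", {
  normal <- c("CASSLGQAYEQYF", "CAVMDSNYQLIW")
  ## verbatim presence -> identity 1 -> not exclusive
  res <- callExclusive("CASSLGQAYEQYF", normal)
  expect_false(res[1])
  ## a fraction exactly at the threshold is not exclusive (strict <)
  q <- "CASSLGQAEQYF"
  f <- max(identityFraction(q, normal))
  expect_false(callExclusive(q, normal, threshold = f)[1])
  expect_true(callExclusive(q, normal, threshold = f + 1e-9)[1])
  expect_warning(all(callExclusive(q, character(0))), "empty normal")
})

test_that("clonotypes are defined by exact nucleotide identity across
          productive chains", {
  rec <- data.frame(
    cell_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c4"),
    locus = c("TRA", "TRB", "TRA", "TRB", "TRA", "TRB", "TRB"),
    junction = c("TGTGCA", "TGTGCC", "TGTGCA", "TGTGCC",
                 "TGTGCA", "TGTGCG", "TGTGCC"),
    junction_aa = "CA", v_call = "V", j_call = "J",
    productive = TRUE, duplicate_count = 1L)
  cl <- defineClonotypes(rec)
  ids <- setNames(cl$clonotype_id, cl$cell_id)
  expect_identical(ids[["c1"]], ids[["c2"]])   # identical chains
  expect_false(ids[["c1"]] == ids[["c3"]])     # one nt difference
  expect_true(cl$single_chain[cl$cell_id == "c4"])
  ## order invariance and id stability
  cl2 <- defineClonotypes(rec[sample(nrow(rec)), ])
  expect_identical(sort(cl$clonotype_id), sort(cl2$clonotype_id))
})

test_that("clonotype clustering connects within the cutoff and is
          transitive over chains", {
  s <- "CASSLGQAYEQYF"
  one <- "CASSLGQAEQYF"    # within small distance of s
  far <- "CWWWWHKNNPMMF"
  d1 <- alignmentDistance(s, one)
  expect_equal(alignmentDistance(s, s), 0)
  cl <- clusterClonotypes(c(s, one, far), cutoff = d1)
  expect_identical(cl[1], cl[2])
  expect_false(cl[1] == cl[3])
  clTight <- clusterClonotypes(c(s, one, far), cutoff = d1 - 1)
  expect_false(clTight[1] == clTight[2])
  ## chain: a-b close, b-c close, a-c far -> one component
  a <- "CASSLGQAYEQYF"; b <- "CASSLGQAYEQYW"
  cc <- "CTSSLGQAYEQYW"
  dAB <- alignmentDistance(a, b); dBC <- alignmentDistance(b, cc)
  dAC <- alignmentDistance(a, cc)
  cut <- max(dAB, dBC)
  expect_gt(dAC, cut)
  expect_length(unique(clusterClonotypes(c(a, b, cc), cutoff = cut)), 1)
  ## invariance to record order
  seqs <- c(randomCdr3s(10, seed = 16), s, one, a, b, cc)
  c1 <- clusterClonotypes(seqs, cutoff = 20)
  perm <- sample(length(seqs))
  c2 <- clusterClonotypes(seqs[perm], cutoff = 20)
  ## identical co-membership structure up to label permutation
  expect_identical(outer(c1[perm], c1[perm], "=="), outer(c2, c2, "=="))
})

test_that("epitope annotation follows the most-frequent strategy with
          ambiguous ties and Unknown misses", {
  ref <- data.frame(
    junction_aa = c("CASSLGQAYEQYF", "CASSLGQAYEQYW", "CASSLGQAYEQYT",
                    "CAVMDSNYQLIWF"),
    locus = "TRB",
    epitope = c("epA", "epA", "epB", "epC"),
    organism = c("virusX", "virusX", "virusY", "self"),
    family = c("viral", "viral", "viral", "self"))
  ## exact hit on epA base + its close variant -> epA most frequent
  ann <- annotateEpitopes("CASSLGQAYEQYF", ref)
  expect_identical(ann$epitope, "epA")
  expect_identical(ann$family, "viral")
  ## tie between two equally frequent epitopes -> ambiguous
  tieRef <- ref[c(1, 3), ]
  annTie <- annotateEpitopes("CASSLGQAYEQYF", tieRef)
  expect_identical(annTie$epitope, "ambiguous")
  ## no match -> Unknown
  annNo <- annotateEpitopes("CWWWWHKNNPMMF", ref)
  expect_identical(annNo$family, "Unknown")
  ## exclusive override wins
  annEx <- annotateEpitopes("CASSLGQAYEQYF", ref, exclusive = TRUE)
  expect_identical(annEx$family, "exclusive")
  ## vocabulary invariant over random queries
  fams <- annotateEpitopes(randomCdr3s(25, seed = 17), ref)$family
  expect_true(all(fams %in% c("viral", "bacterial", "self", "shared",
                              "exclusive", "unknown", "ambiguous",
                              "Unknown")))
})

test_that("clonal expansion counts conserve totals under stratification", {
  asg <- data.frame(cell_id = paste0("c", 1:6),
                    clonotype_id = c("x", "x", "x", "y", "y", "z"))
  plain <- clonalExpansion(asg)
  expect_equal(plain$n_cells[plain$clonotype_id == "x"], 3L)
  strat <- clonalExpansion(asg, stratifyBy = list(
    ifng = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)))
  agg <- tapply(strat$n_cells, strat$clonotype_id, sum)
  expect_equal(as.integer(agg[plain$clonotype_id]), plain$n_cells)
})

test_that("diversity metrics match the closed-form examples and oracles", {
  expect_equal(chao1(c(5, 3, 2)), 3.0)
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 5.5)
  expect_equal(chao1(c(5, 3, 2, 0)), chao1(c(5, 3, 2)))
  expect_equal(shannonNormalized(c(4, 4, 4)), 1.0)
  expect_equal(shannonNormalized(7), 0.0)
  expect_equal(shannonNormalized(c(1, 1, 2)),
               (-2 * (0.25 * log(0.25)) - 0.5 * log(0.5)) / log(3))
  expect_equal(heipEvenness(c(6, 6)), 1.0)
  expect_equal(heipEvenness(42), 1.0)
  h <- -0.9 * log(0.9) - 0.1 * log(0.1)
  expect_equal(heipEvenness(c(9, 1)), (exp(h) - 1) / 1)
  set.seed(18)
  for (i in 1:25) {
    x <- rpois(sample(3:30, 1), 4) + 1
    expect_equal(chao1(x), chao1Oracle(x), tolerance = 1e-12)
    expect_equal(shannonNormalized(x), shannonNormOracle(x),
                 tolerance = 1e-12)
    expect_equal(heipEvenness(x), heipOracle(x), tolerance = 1e-12)
    expect_gte(chao1(x), sum(x > 0))
    p <- sample(length(x))
    expect_equal(chao1(x[p]), chao1(x))
    expect_equal(shannonNormalized(x[p]), shannonNormalized(x))
  }
  expect_error(chao1(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "integer")
})
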