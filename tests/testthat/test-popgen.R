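test_that("site classification partitions the alignment exhaustively", {
  aln <- makeAln(rep(strrep("A", 100), 10), rep("p", 10))
  sc <- classifySites(aln)
  expect_equal(unclass(sc)[1:4],
               list(invariable = 100L, singleton = 0L,
                    parsimonyInformative = 0L, excluded = 0L))

  # hand-enumerated: one informative site (A,A,C,C), one singleton (A,A,A,G)
  base <- strrep("A", 10)
  s <- c(base, base, base, base)
  substr(s[3], 2, 2) <- "C"; substr(s[4], 2, 2) <- "C"
  substr(s[4], 5, 5) <- "G"
  sc <- classifySites(makeAln(s, rep("p", 4)))
  expect_equal(sc$invariable, 8L)
  expect_equal(sc$singleton, 1L)
  expect_equal(sc$parsimonyInformative, 1L)

  set.seed(11)
  for (rep in 1:15) {
    m <- randomAlnMatrix(sample(3:8, 1), sample(10:30, 1),
                         pMiss = sample(c(0, 0.05), 1))
    sc <- classifySites(matToAln(m))
    expect_identical(sc$invariable + sc$singleton + sc$parsimonyInformative +
                       sc$excluded, ncol(m))
  }
})

test_that("sites with >2 states follow the two-way informative/singleton split", {
  # states A,A,C,G: two states singletons -> singleton site
  s <- c("AA", "AA", "CA", "GA")
  sc <- classifySites(makeAln(s, rep("p", 4)))
  expect_equal(sc$singleton, 1L)
  expect_equal(sc$parsimonyInformative, 0L)
  # states A,A,C,C,G: two states with multiplicity >= 2 -> informative
  s <- c("AA", "AA", "CA", "CA", "GA")
  sc <- classifySites(makeAln(s, rep("p", 5)))
  expect_equal(sc$parsimonyInformative, 1L)
})

test_that("haplotype collapsing matches direct deduplication", {
  ht <- collapseHaplotypes(makeAln(rep("ACGT", 5), rep("p", 5)))
  expect_equal(nrow(ht), 1L)
  expect_equal(ht$count, 5L)

  ht <- collapseHaplotypes(makeAln(c("AAAA", "AAAT", "AAAT"), rep("p", 3)))
  expect_equal(ht$count, c(1L, 2L))
  expect_equal(sum(ht$frequency), 1)

  set.seed(7)
  for (rep in 1:10) {
    m <- randomAlnMatrix(8, 15)
    ht <- collapseHaplotypes(matToAln(m))
    keys <- apply(m[, completeCols(m), drop = FALSE], 1, paste, collapse = "")
    expect_equal(nrow(ht), length(unique(keys)))
    expect_equal(sum(ht$count), 8L)
    expect_equal(sort(ht$count), sort(as.integer(table(keys))))
  }
})

test_that("diversity indices match closed forms and the brute-force oracle", {
  ds <- diversitySummary(makeAln(rep(strrep("G", 12), 5), rep("p", 5)))
  tot <- ds[ds$population == "Total", ]
  expect_equal(tot$p, 1L)
  expect_equal(tot$S, 0L)
  expect_equal(tot$pi, 0)
  expect_equal(tot$h, 0)

  s <- c(strrep("A", 10), paste0(strrep("A", 9), "T"))
  tot <- diversitySummary(makeAln(s, c("p", "p")))
  tot <- tot[tot$population == "Total", ]
  expect_equal(tot$S, 1L)
  expect_equal(tot$pi, 0.1)
  expect_equal(tot$h, 1)

  set.seed(21)
  for (rep in 1:12) {
    m <- randomAlnMatrix(sample(4:8, 1), sample(8:20, 1),
                         pMiss = sample(c(0, 0.05), 1))
    got <- diversitySummary(matToAln(m), byPopulation = FALSE)
    got <- got[got$population == "Total", ]
    want <- oracleDiversity(m)
    expect_equal(got$p, want$p)
    expect_equal(got$S, want$S)
    expect_equal(got$pi, want$pi)
    expect_equal(got$h, want$h)
  }
})

test_that("diversity is invariant to row order and relabeling; pi to column order", {
  set.seed(5)
  m <- randomAlnMatrix(6, 15)
  a1 <- diversitySummary(matToAln(m), byPopulation = FALSE)
  perm <- sample(nrow(m))
  m2 <- m[perm, , drop = FALSE]
  rownames(m2) <- paste0("z", seq_len(nrow(m2)))   # relabeled + reordered
  a2 <- diversitySummary(matToAln(m2), byPopulation = FALSE)
  expect_equal(a1$h, a2$h)
  expect_equal(a1$pi, a2$pi)
  m3 <- m[, sample(ncol(m)), drop = FALSE]
  a3 <- diversitySummary(matToAln(m3), byPopulation = FALSE)
  expect_equal(a1$pi, a3$pi)
})

test_that("p-distances match the brute-force count under both deletion modes", {
  aln <- makeAln(c("ACGT", "ACGT"), rep("p", 2))
  expect_equal(pDistanceMatrix(aln)[1, 2], 0)
  aln <- makeAln(c("ACGT", "ACGA"), rep("p", 2))
  expect_equal(pDistanceMatrix(aln)[1, 2], 0.25)

  set.seed(33)
  for (rep in 1:6) {
    m <- randomAlnMatrix(5, 12, pMiss = 0.08)
    aln <- matToAln(m)
    for (mode in c("pairwise", "complete")) {
      got <- pDistanceMatrix(aln, deletion = mode)
      want <- oraclePdist(m, pairwise = (mode == "pairwise"))
      expect_equal(unname(got[upper.tri(got)]), want[upper.tri(want)],
                   tolerance = 1e-12)
      # semimetric properties
      expect_true(all(got == t(got), na.rm = TRUE))
      expect_true(all(diag(got) == 0))
      expect_true(all(got[is.finite(got)] <= 1))
    }
  }
})

test_that("distance partition separates intra and inter pairs", {
  s <- c(rep("AAAAAAAAAA", 3), rep("TAAAAAAAAA", 3))
  aln <- makeAln(s, rep(c("x", "y"), each = 3))
  dp <- distancePartition(pDistanceMatrix(aln), aln)
  expect_true(all(dp$intra == 0))
  expect_true(all(dp$inter == 0.1))
  expect_equal(sum(dp$intraCounts) + sum(dp$interCounts),
               choose(6, 2))
  expect_equal(dp$groupMeans["x", "y"], 0.1)

  one <- makeAln(c("ACGT", "ACGA"), rep("only", 2))
  dp1 <- distancePartition(pDistanceMatrix(one), one)
  expect_length(dp1$inter, 0)
})

test_that("base composition excludes gaps and sums to 100", {
  bc <- baseComposition(makeAln("AACC", "p"))
  expect_equal(unname(bc), c(50, 50, 0, 0))
  bc <- baseComposition(makeAln(c("AA--", "AANN"), rep("p", 2)))
  expect_equal(unname(bc[["A"]]), 100)
  expect_equal(sum(bc), 100)
  expect_error(baseComposition(makeAln("NN--", "p")), "unambiguous")
})

test_that("theta estimators and the Ne conversion behave as stated", {
  est <- thetaNe(pi = 3.9e-3, mu = 3.9e-8, estimator = "pi")
  expect_equal(est$Ne, 1e5)
  est <- thetaNe(S = 0, n = 10, L = 100, mu = 3.9e-8)
  expect_equal(est$theta, 0)
  expect_equal(est$Ne, 0)
  est <- thetaNe(S = 20, n = 10, L = 500, mu = 1e-8)
  a9 <- sum(1 / 1:9)
  expect_equal(est$theta, 20 / (a9 * 500))
  expect_equal(est$Ne * est$mu, est$theta)   # exact round trip
  expect_error(thetaNe(S = 1, n = 10, L = 10, mu = 0), "mu")
})

test_that("per-Myr substitution rate converts to the per-generation rate", {
  expect_equal(signif(substitutionRatePerGeneration(0.01306, 3), 2), 3.9e-8)
})
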