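test_that("parsimony probability behaves and matches the Monte-Carlo oracle", {
  expect_equal(parsimonyProbability(0, 100), 1)
  p <- parsimonyProbability(1:20, 500)
  expect_true(all(diff(p) < 0))                  # decreasing in j
  expect_true(all(p >= 0 & p <= 1))

  set.seed(99)
  for (case in list(c(4, 100), c(12, 1618))) {
    mc <- mcParsimonyProbability(case[1], case[2])
    expect_equal(unname(parsimonyProbability(case[1], case[2])), unname(mc),
                 tolerance = 0.03)
  }
})

test_that("the connection limit is monotone in L and >= 1", {
  expect_gte(parsimonyLimit(1618)$maxSteps, parsimonyLimit(400)$maxSteps)
  expect_gte(parsimonyLimit(400)$maxSteps, parsimonyLimit(50)$maxSteps)
  expect_equal(parsimonyLimit(10, alpha = 0.999999)$maxSteps, 1L)
  expect_error(parsimonyLimit(100, alpha = 1.2), "alpha")
})

test_that("single-step pairs connect directly; multi-step paths avoid shortcuts", {
  aln <- makeAln(c(h1 = "AAAA", h2 = "AAAT"), rep("p", 2))
  net <- buildNetwork(aln, limit = 5)
  expect_equal(nrow(net@edges), 1L)
  expect_equal(sum(net@nodes$type == "inferred"), 0L)

  # A-B one step, B-C one step, A-C two steps: chain without the shortcut
  aln <- makeAln(c(a = "AAAA", b = "AAAT", c = "AATT"), rep("p", 3))
  net <- buildNetwork(aln, limit = 5)
  expect_equal(nrow(net@connections), 2L)
  expect_true(all(net@connections$steps == 1L))
  expect_equal(networkComponents(net)$nComponents, 1L)
})

test_that("connections beyond the limit split the network into components", {
  far <- strrep("T", 50)
  near <- paste0("A", strrep("T", 49))
  base <- strrep("A", 50)
  base2 <- paste0("C", substr(base, 2, 50))
  aln <- makeAln(c(a1 = base, a2 = base2, b1 = far, b2 = near), rep("p", 4))
  net <- buildNetwork(aln, limit = 12)
  comp <- networkComponents(net)
  expect_equal(comp$nComponents, 2L)
  expect_gte(min(comp$stepsBetween["C1", "C2"]), 13)
})

test_that("a d-step connection inserts d-1 inferred intermediates", {
  a <- strrep("A", 20)
  b <- paste0(strrep("G", 4), substr(a, 5, 20))   # 4 steps away
  net <- buildNetwork(makeAln(c(h1 = a, h2 = b), rep("p", 2)), limit = 10)
  expect_equal(sum(net@nodes$type == "inferred"), 3L)
  expect_equal(nrow(net@edges), 4L)
  expect_equal(igraph::count_components(net@graph), 1L)
  # path length between the sampled haplotypes equals the Hamming distance
  d <- igraph::distances(net@graph, "H1", "H2")
  expect_equal(unname(d[1, 1]), 4)
})

test_that("limit 1 on mutually distant haplotypes yields singleton components", {
  aln <- makeAln(c(x = "AAAA", y = "TTAA", z = "GGGG"), rep("p", 3))
  net <- buildNetwork(aln, limit = 1)
  expect_equal(networkComponents(net)$nComponents, 3L)
})

test_that("components are invariant to input order and frequencies are carried", {
  set.seed(4)
  m <- randomAlnMatrix(8, 20)
  aln1 <- matToAln(m, rep(c("x", "y"), each = 4))
  perm <- sample(nrow(m))
  aln2 <- matToAln(m[perm, , drop = FALSE], rep(c("x", "y"), each = 4)[perm])
  n1 <- buildNetwork(aln1, limit = 30)
  n2 <- buildNetwork(aln2, limit = 30)
  memb1 <- lapply(networkComponents(n1)$members, function(ids)
    sort(unlist(n1@haplotypes$members[match(ids, n1@haplotypes$haplotype)])))
  memb2 <- lapply(networkComponents(n2)$members, function(ids)
    sort(unlist(n2@haplotypes$members[match(ids, n2@haplotypes$haplotype)])))
  expect_true(setequal(unname(vapply(memb1, paste, character(1), collapse = ",")),
                       unname(vapply(memb2, paste, character(1), collapse = ","))))
  expect_equal(sum(n1@nodes$frequency), nrow(m))
})
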