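preset <- studyPreset()
scns <- scenarioLibrary()

test_that("the scenario library encodes the three hypotheses", {
  expect_named(scns, c("S1_fragmentation", "S2_one_way", "S3_two_way"))
  ev1 <- scns$S1_fragmentation@events
  expect_equal(sum(ev1$type == "merge"), 3L)
  expect_true(all(ev1$timeName[ev1$type == "merge"] == "Tt"))

  ev2 <- scns$S2_one_way@events
  mg2 <- ev2[ev2$type == "merge", ]
  expect_equal(mg2$timeName, c("t1", "t2", "t3"))
  expect_equal(mg2$from, c("WA-Az", "CA", "LarNP-CA"))
  expect_equal(mg2$to, c("CA", "LarNP-CA", "KD-EA"))

  # two-way topology: WA-Az attaches to the KD-EA branch, not to CA
  ev3 <- scns$S3_two_way@events
  mg3 <- ev3[ev3$type == "merge", ]
  expect_equal(mg3$to[mg3$from == "WA-Az"], "KD-EA")
  for (scn in scns) expect_true(validObject(scn))
})

test_that("prior draws respect bounds, moments and reproducibility", {
  set.seed(1)
  x <- drawParams(preset$prior, 1e5)
  expect_gte(min(x), 10)
  expect_lte(max(x), 7e5)
  expect_equal(mean(x), 3.5e5, tolerance = 0.01)
  set.seed(77); a <- drawParams(preset$prior, 10)
  set.seed(77); b <- drawParams(preset$prior, 10)
  expect_identical(a, b)
  set.seed(3)
  ks <- ks.test(drawParams(preset$prior, 2000)[, 1], "punif", 10, 7e5)
  expect_gt(ks$p.value, 0.01)
})

test_that("genealogies are ultrametric with the right tip count", {
  set.seed(5)
  params <- setNames(c(1e4, 2e4, 3e4, 1e4, 5e4),
                     c(scns$S1_fragmentation@popLabels, "ancestral"))
  for (scn in scns) {
    gen <- simulateGenealogy(scn, params, preset$config, preset$prior)
    expect_length(gen$tipIds, 39L)
    tr <- genealogyToPhylo(gen)
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
    expect_true(all(gen$time[40:77] > 0))
  }
})

test_that("with one sample per population all coalescences predate the splits", {
  cfg <- sampleConfig(setNames(rep(1L, 4), scns$S1_fragmentation@popLabels),
                      L = 100, mu = 0)
  params <- setNames(rep(1e3, 5), c(scns$S1_fragmentation@popLabels, "ancestral"))
  set.seed(8)
  for (rep in 1:20) {
    gen <- simulateGenealogy(scns$S1_fragmentation, params, cfg, preset$prior)
    expect_true(all(gen$time[5:7] >= preset$prior@times[["Tt"]]))
  }
})

test_that("pairwise coalescence times average to Ne (haploid convention)", {
  set.seed(12)
  noEvents <- matrix(numeric(0), 0, 4)
  tm <- replicate(2000, max(phylogeoABC:::.sim_genealogy_cpp(2L, 1000, noEvents)$time))
  expect_equal(mean(tm), 1000, tolerance = 0.05)
})

test_that("sequence evolution matches Watterson and pairwise expectations", {
  set.seed(14)
  Ne <- 1e5; L <- 1618L; mu <- 3.9e-8; n <- 10L
  noEvents <- matrix(numeric(0), 0, 4)
  S <- numeric(1500); pw <- numeric(1500)
  for (r in seq_len(1500)) {
    m <- phylogeoABC:::.sim_alignment_cpp(n, Ne, noEvents, L, mu)
    st <- phylogeoABC:::.seq_stats_cpp(m, rep(0L, n), 1L)
    S[r] <- st[2]; pw[r] <- st[3]
  }
  a9 <- sum(1 / 1:9)
  expect_equal(mean(S), 2 * Ne * mu * L * a9, tolerance = 0.05)
  expect_equal(mean(pw) / L, 2 * Ne * mu, tolerance = 0.05)
})

test_that("mu = 0 yields an invariant alignment", {
  ds <- generateCase("S2_one_way", seed = 3, overrides = list(mu = 0))
  sc <- classifySites(ds$alignment)
  expect_equal(sc$invariable, 1618L)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  d1 <- simulateDataset(scns$S3_two_way, preset$config, preset$prior, seed = 31)
  d2 <- simulateDataset(scns$S3_two_way, preset$config, preset$prior, seed = 31)
  expect_identical(as.character(sequences(d1$alignment)),
                   as.character(sequences(d2$alignment)))
  expect_identical(d1$truth$params, d2$truth$params)
})

test_that("simultaneous fragmentation gives exchangeable between-population divergence", {
  set.seed(41)
  params <- setNames(rep(2e4, 5), c(scns$S1_fragmentation@popLabels, "ancestral"))
  dxyNames <- grep("^dxy_", statNames(scns$S1_fragmentation@popLabels), value = TRUE)
  acc <- matrix(0, 60, length(dxyNames), dimnames = list(NULL, dxyNames))
  for (r in 1:60) {
    ds <- simulateDataset(scns$S1_fragmentation, preset$config, preset$prior,
                          params = params)
    acc[r, ] <- computeSumstats(ds$alignment)[dxyNames]
  }
  mns <- colMeans(acc)
  expect_lt(max(mns) / min(mns), 1.15)   # all pairs split at the same Tt
})
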