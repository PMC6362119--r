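test_that("the study preset encodes the sampling design", {
  preset <- studyPreset()
  ss <- preset$config@sampleSizes
  expect_equal(sum(ss), 39L)
  expect_equal(unname(ss[c("KD-EA", "CA", "LarNP-CA", "WA-Az")]),
               c(10L, 4L, 12L, 13L))
  expect_equal(preset$config@L, 1618)
  expect_equal(studyPreset(L = 2370)$config@L, 2370)
  expect_equal(preset$config@mu, 3.9e-8)
  expect_equal(preset$config@generationTime, 3)
  tt <- preset$prior@times
  expect_true(all(diff(tt) > 0))                 # t1 < t2 < t3 < Tt
  expect_equal(unname(preset$prior@neLower), rep(10, 5))
  expect_equal(unname(preset$prior@neUpper), rep(7e5, 5))
  # the stated per-Myr rate and generation time reproduce mu
  expect_equal(signif(substitutionRatePerGeneration(0.01306,
                                                    preset$config@generationTime), 2),
               preset$config@mu)
})

test_that("generated cases are reproducible and honor overrides", {
  d1 <- generateCase("S3_two_way", seed = 101)
  d2 <- generateCase("S3_two_way", seed = 101)
  expect_identical(as.character(sequences(d1$alignment)),
                   as.character(sequences(d2$alignment)))

  dir <- withr::local_tempdir()
  d3 <- generateCase("S3_two_way", seed = 101, dir = dir)
  d4 <- generateCase("S3_two_way", seed = 101, dir = withr::local_tempdir())
  expect_identical(readLines(d3$files[["fasta"]]), readLines(d4$files[["fasta"]]))

  d0 <- generateCase("S1_fragmentation", seed = 5, overrides = list(mu = 0))
  tot <- diversitySummary(d0$alignment, byPopulation = FALSE)
  expect_equal(tot$S[tot$population == "Total"], 0L)

  expect_error(generateCase("S9", seed = 1), "unknown scenario")
})

test_that("default cases land in the study's diversity regime", {
  # within-population nucleotide diversity of order 1e-3 to 1e-2
  set.seed(1)
  pis <- vapply(1:8, function(i) {
    ds <- generateCase("S3_two_way", seed = 7000 + i)
    d <- diversitySummary(ds$alignment, byPopulation = FALSE)
    d$pi[d$population == "Total"]
  }, numeric(1))
  expect_gt(median(pis), 1e-4)
  expect_lt(median(pis), 0.1)
})

test_that("suites are balanced with disjoint seeds and feed classification", {
  suite <- generateSuite(3, seed = 500)
  expect_equal(nrow(suite$manifest), 9L)
  expect_equal(as.integer(table(suite$manifest$scenario)), rep(3L, 3))
  expect_false(any(duplicated(suite$manifest$seed)))
  seqsets <- vapply(suite$cases, function(cs)
    paste(as.character(sequences(cs$alignment)), collapse = ""), character(1))
  expect_false(any(duplicated(seqsets)))

  # plumbing round trip: suite cases classify against a reference table
  sep <- separatedSetting()
  rt <- suppressWarnings(buildReferenceTable(sep$scenarios, sep$prior,
                                             sep$config, 200, seed = 17))
  post <- modelChoiceDirect(rt, computeSumstats(suite$cases[[1]]$alignment),
                            k = 50)
  expect_equal(sum(post$posterior), 1)
})

test_that("truth records regenerate the dataset", {
  ds <- generateCase("S2_one_way", seed = 303)
  tr <- ds$truth
  scn <- scenarioLibrary()[[tr$scenarioId]]
  preset <- studyPreset()
  ds2 <- simulateDataset(scn, preset$config, preset$prior, seed = tr$seed)
  expect_identical(as.character(sequences(ds$alignment)),
                   as.character(sequences(ds2$alignment)))
  expect_identical(tr$params, ds2$truth$params)
})
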