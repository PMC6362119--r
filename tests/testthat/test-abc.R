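preset <- studyPreset()
scns <- scenarioLibrary()

test_that("summary statistics match the brute-force oracle", {
  # all identical -> one haplotype everywhere, every other statistic 0
  st <- computeSumstats(makeAln(rep("ACGTACGT", 6), rep(c("x", "y"), each = 3)))
  nhap <- grepl("^nhap_", names(st))
  expect_true(all(st[nhap] == 1))
  expect_true(all(st[!nhap] == 0))     # includes the degenerate FST = 0
  expect_length(st, 4 * 2 + 2)

  # two populations fixed for different alleles at every variable site
  st <- computeSumstats(makeAln(c(rep("AAAAAA", 3), rep("TTAAAA", 3)),
                                rep(c("x", "y"), each = 3)))
  expect_equal(unname(st[["fst_x_y"]]), 1)
  expect_equal(unname(st[["dxy_x_y"]]), 2)
  expect_equal(unname(st[["segsites_x"]]) + unname(st[["segsites_y"]]), 0)

  set.seed(55)
  for (rep in 1:10) {
    m <- randomAlnMatrix(10, 20)
    pops <- sample(rep(c("a", "b", "c"), times = c(4, 3, 3)))
    aln <- matToAln(m, factor(pops, levels = c("a", "b", "c")))
    got <- computeSumstats(aln)
    want <- oracleSumstats(m, factor(pops, levels = c("a", "b", "c")))
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("reference tables are balanced, reproducible and separable", {
  rt <- suppressWarnings(buildReferenceTable(scns, preset$prior, preset$config,
                                             100, seed = 5))
  expect_length(rt, 300L)
  expect_equal(as.integer(table(rt@scenario)), rep(100L, 3))
  rt2 <- suppressWarnings(buildReferenceTable(scns, preset$prior, preset$config,
                                              100, seed = 5))
  expect_identical(rt@stats, rt2@stats)
  expect_identical(rt@params, rt2@params)

  # deep vs shallow split times shift the between-population distances
  shallow <- preset$prior
  shallow@times <- c(t1 = 100, t2 = 200, t3 = 300, Tt = 400)
  rtS <- suppressWarnings(buildReferenceTable(scns["S3_two_way"], shallow,
                                              preset$config, 150, seed = 6))
  rtD <- suppressWarnings(buildReferenceTable(scns["S3_two_way"], preset$prior,
                                              preset$config, 150, seed = 6))
  expect_gt(mean(rtD@stats[, "dxy_KD-EA_WA-Az"]),
            mean(rtS@stats[, "dxy_KD-EA_WA-Az"]))
})

test_that("direct rejection recovers trivial and uninformative limits", {
  rt <- suppressWarnings(buildReferenceTable(scns, preset$prior, preset$config,
                                             200, seed = 9))
  obs <- rt@stats[42, ]
  post <- modelChoiceDirect(rt, obs, k = 1)
  expect_equal(unname(post$posterior[as.character(rt@scenario[42])]), 1)
  expect_equal(sum(post$posterior), 1)

  # identical statistics for all rows -> posterior equals prior proportions
  rtFlat <- rt
  rtFlat@stats[] <- 1
  rtFlat@center <- apply(rtFlat@stats, 2, median)
  rtFlat@scale <- apply(rtFlat@stats, 2, mad)
  rtFlat@dropped <- colnames(rtFlat@stats)[rtFlat@scale == 0]
  post <- suppressWarnings(modelChoiceDirect(rtFlat, rtFlat@stats[1, ], k = 300))
  expect_equal(unname(post$posterior), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(modelChoiceDirect(rt, obs, k = 0), "positive")
  expect_error(modelChoiceDirect(rt, obs, k = 1e6), "exceeds")
})

test_that("direct posterior is invariant to uniform rescaling of the statistics", {
  rt <- suppressWarnings(buildReferenceTable(scns, preset$prior, preset$config,
                                             150, seed = 10))
  obs <- rt@stats[7, ] * 1.0
  p1 <- modelChoiceDirect(rt, obs, k = 50)$posterior
  rtScaled <- rt
  rtScaled@stats <- rt@stats * 13.7
  rtScaled@center <- rt@center * 13.7
  rtScaled@scale <- rt@scale * 13.7
  p2 <- modelChoiceDirect(rtScaled, obs * 13.7, k = 50)$posterior
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("logistic model choice agrees with rejection on separable data", {
  sep <- separatedSetting()
  rt <- suppressWarnings(buildReferenceTable(sep$scenarios, sep$prior,
                                             sep$config, 800, seed = 11))
  set.seed(12)
  ds <- simulateDataset(sep$scenarios$S3_two_way, sep$config, sep$prior)
  obs <- computeSumstats(ds$alignment)
  d <- modelChoiceDirect(rt, obs, k = 100)
  l <- modelChoiceLogistic(rt, obs, frac = 0.1)
  expect_equal(d$best, "S3_two_way")
  expect_equal(l$best, "S3_two_way")
  expect_equal(sum(l$posterior), 1, tolerance = 1e-8)
  expect_gt(l$posterior[["S3_two_way"]], 0.8)
})

test_that("parameter posteriors stay inside the prior and adjust toward the data", {
  rt <- studyReferenceTable()
  set.seed(20)
  truth <- setNames(rep(1e5, 5), colnames(rt@params))
  ds <- simulateDataset(scns$S3_two_way, preset$config, preset$prior,
                        params = truth)
  est <- suppressWarnings(
    estimateParameters(rt, computeSumstats(ds$alignment),
                       scenarioId = "S3_two_way", frac = 0.01))
  for (pn in names(est$parameters)) {
    dr <- est$parameters[[pn]]$draws
    expect_true(all(dr >= 10 & dr <= 7e5))
    expect_gte(length(dr), 50)
  }
  expect_error(
    estimateParameters(rt, computeSumstats(ds$alignment),
                       scenarioId = "S3_two_way", frac = 1e-5),
    "50")
})

test_that("PODs validation is reproducible and calibrated for identical scenarios", {
  sep <- separatedSetting()
  rt <- suppressWarnings(buildReferenceTable(sep$scenarios, sep$prior,
                                             sep$config, 500, seed = 13))
  r1 <- podsValidation(sep$scenarios, sep$prior, sep$config, rt,
                       focal = "S3_two_way", nPods = 40, k = 50, seed = 14)
  r2 <- podsValidation(sep$scenarios, sep$prior, sep$config, rt,
                       focal = "S3_two_way", nPods = 40, k = 50, seed = 14)
  expect_identical(r1$confusion, r2$confusion)
  expect_true(all(rowSums(r1$confusion) == 40))
  expect_true(r1$typeI >= 0 && r1$typeI <= 1)

  # three copies of the same scenario are indistinguishable: type I ~ 2/3
  same <- list(A = scns$S1_fragmentation,
               B = scns$S1_fragmentation,
               C = scns$S1_fragmentation)
  same$B@scenarioId <- "B"; same$C@scenarioId <- "C"
  same$A@scenarioId <- "A"
  rtSame <- suppressWarnings(buildReferenceTable(same, preset$prior,
                                                 preset$config, 400, seed = 15))
  rep1 <- podsValidation(same, preset$prior, preset$config, rtSame, focal = "A",
                         nPods = 300, k = 100, seed = 16)
  expect_equal(rep1$typeI, 2 / 3, tolerance = 0.12)
})
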