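test_that("a predicate matching nothing leaves null and observed unchanged", {
  cat <- maskingCatalogue(30, seed = 13)
  obs <- simulateMutations(cat, fig1Scenario(50), seed = 14)
  out <- excludeEntries(cat, obs, "ddg > 1e6", label = "noop")
  expect_equal(catalogueEntries(out$catalogue)$prob,
               catalogueEntries(cat)$prob)
  expect_identical(out$observed@entryIndex, obs@entryIndex)
  expect_identical(exclusionLabels(out$catalogue), "noop")
})

test_that("probabilities renormalise to one after every exclusion", {
  cat <- maskingCatalogue(50, seed = 15)
  obs <- simulateMutations(cat, fig1Scenario(200), seed = 16)
  st1 <- excludeEntries(cat, obs, "ddg > 2")
  e1 <- catalogueEntries(st1$catalogue)
  expect_equal(sum(e1$prob[e1$included]), 1, tolerance = 1e-12)
  st2 <- excludeEntries(st1$catalogue, st1$observed, "strong")
  e2 <- catalogueEntries(st2$catalogue)
  expect_equal(sum(e2$prob[e2$included]), 1, tolerance = 1e-12)
  expect_identical(exclusionLabels(st2$catalogue), c("ddg > 2", "strong"))
})

test_that("sequential exclusion of disjoint predicates equals their union", {
  cat <- maskingCatalogue(50, seed = 17)
  obs <- simulateMutations(cat, fig1Scenario(200), seed = 18)
  seqq <- excludeEntries(cat, obs, "strong")
  seqq <- excludeEntries(seqq$catalogue, seqq$observed, "weak")
  un <- excludeEntries(cat, obs, "strong | weak")
  expect_equal(catalogueEntries(seqq$catalogue)$prob,
               catalogueEntries(un$catalogue)$prob, tolerance = 1e-12)
  expect_identical(seqq$observed@entryIndex, un$observed@entryIndex)
  expect_equal(seqq$observed@count, un$observed@count)
})

test_that("emptying exclusions raise degenerate-layer errors", {
  cat <- maskingCatalogue(20, seed = 19)
  e <- catalogueEntries(cat)
  obs <- observedFromIndex(cat, which(e$included & e$strong)[1:3])
  expect_error(excludeEntries(cat, obs, "strong"), "empties the observed")
  expect_error(excludeEntries(cat, obs, "ddg > -1e6"), "empties the null")
})

test_that("predicates are restricted to a safe comparison grammar", {
  cat <- maskingCatalogue(20, seed = 20)
  obs <- simulateMutations(cat, fig1Scenario(30), seed = 21)
  expect_error(excludeEntries(cat, obs, "system('ls')"), "disallowed")
  expect_error(excludeEntries(cat, obs, "nonexistent > 1"), "unknown feature")
  expect_error(excludeEntries(cat, obs, "ddg"), "logical")
})

test_that("a single layer reduces to the plain test", {
  cat <- maskingCatalogue(60, seed = 22)
  obs <- simulateMutations(cat, fig1Scenario(150), seed = 23)
  la <- layeredAnalysis(cat, obs, list(list(feature = "strong",
                                            test = "binomial")))
  plain <- binomialFeatureTest(obs, cat, "strong")
  expect_equal(pValue(la$results[["strong"]]), pValue(plain))
  expect_equal(la$results[["strong"]]@observed, plain@observed)
})

test_that("masking hides weak selection until the strong layer is excluded", {
  # planted factors 3 (strong) and 2 (weak) on disjoint partitions:
  # under the scenario the observed weak proportion before exclusion is
  # 2a/(1+2a_s+a_w)-ish, close to its null mass; after excluding the strong
  # category it rises well above the renormalised null proportion
  cat <- maskingCatalogue(100, seed = 24)
  nRuns <- 120
  pPre <- pPost <- numeric(nRuns)
  for (i in seq_len(nRuns)) {
    obs <- simulateMutations(cat, fig1Scenario(300), seed = 1000 + i)
    pPre[i] <- pValue(binomialFeatureTest(obs, cat, "weak"))
    st <- excludeEntries(cat, obs, "strong")
    pPost[i] <- pValue(binomialFeatureTest(st$observed, st$catalogue,
                                           "weak"))
  }
  powerPre <- mean(pPre < 0.05)
  powerPost <- mean(pPost < 0.05)
  expect_gt(powerPost, powerPre)  # exclusion strictly increases power
  expect_gt(powerPost, 0.9)
  expect_lt(median(pPost), 0.05)
})

test_that("a three-layer analysis recovers all planted categories", {
  tx <- simulateTranscript(120, seed = 25)
  cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
  core <- 1:30
  cat <- attachFeatures(cat,
    ddg = simulateDdg(cat, seed = 26, coreResidues = core,
                      coreTailWeight = 0.9),
    residueSets = list(interface = residueSet("i", 40:65),
                       calcium = residueSet("c", c(70:74, 90:95))))
  scenario <- selectionScenario(list(
    list(feature = "destabilising", factor = 3),
    list(feature = "interface & !destabilising", factor = 3),
    list(feature = "calcium & !destabilising & !interface", factor = 3)),
    nMutations = 600)
  obs <- simulateMutations(cat, scenario, seed = 27)
  la <- layeredAnalysis(cat, obs, list(
    list(name = "destabilising", feature = "destabilising",
         test = "binomial", exclude_if = "ddg > 2"),
    list(name = "interface", feature = "interface", test = "binomial",
         exclude_if = "interface"),
    list(name = "calcium", feature = "calcium", test = "binomial")))
  expect_equal(la$status, "complete")
  expect_length(la$results, 3L)
  for (r in la$results) {
    expect_lt(pValue(r), 0.05)
    expect_gt(r@observed, r@expected)  # enrichment, not depletion
  }
  # residual report: most mutations fall in the three planted categories
  expect_gt(la$residual$fractionExplained, 0.5)
})

test_that("degenerate layers halt with partial results and a clear status", {
  cat <- maskingCatalogue(30, seed = 28)
  e <- catalogueEntries(cat)
  obs <- observedFromIndex(cat, which(e$included & e$strong)[1:4])
  la <- layeredAnalysis(cat, obs, list(
    list(feature = "strong", test = "binomial"),
    list(feature = "weak", test = "binomial")))
  expect_match(la$status, "halted")
  expect_length(la$results, 1L)
})

test_that("layer specs load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "layers:",
    "  - name: destabilising",
    "    feature: destabilising",
    "    test: binomial",
    "    exclude_if: ddg > 2.0",
    "  - feature: interface",
    "    test: binomial"), f)
  layers <- readLayerSpec(f)
  expect_length(layers, 2L)
  expect_identical(layers[[1]]$exclude_if, "ddg > 2.0")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("layers:", "  - test: binomial"), bad)
  expect_error(readLayerSpec(bad), "no 'feature'")
})
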