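test_that("two-tailed binomial p matches hand enumeration and binom.test", {
  # frozen from enumerating the Binomial(4, 0.25) pmf: outcomes with
  # probability <= P(k=3) are k=3 (0.046875) and k=4 (0.00390625)
  cat4 <- toyCatalogue(scores = c(1, 1, 1, 2), probs = rep(0.25, 4))
  e <- catalogueEntries(cat4)
  cat4@entries$hot <- c(TRUE, FALSE, FALSE, FALSE)
  # p0 = 0.25; observe k = 3 of n = 4 on the feature
  obs <- observedFromIndex(cat4, c(1L, 2L), count = c(3, 1))
  res <- binomialFeatureTest(obs, cat4, "hot")
  expect_equal(pValue(res), 0.05078125)
  expect_equal(res@expected, 0.25)
  expect_equal(res@observed, 0.75)

  # independent oracle across a grid
  for (n in c(2, 5, 9)) {
    for (p0 in c(0.1, 0.37, 0.5, 0.82)) {
      for (k in 0:n) {
        expect_equal(SomaticSelect:::binomTwoTailedP(k, n, p0),
                     binom.test(k, n, p0)$p.value, tolerance = 1e-12)
      }
    }
  }
})

test_that("central binomial outcomes give p = 1 within pmf granularity", {
  cat2 <- toyCatalogue(scores = 1:2, probs = c(0.5, 0.5))
  cat2@entries$hot <- c(TRUE, FALSE)
  obs <- observedFromIndex(cat2, c(1L, 2L), count = c(50, 50))
  expect_equal(pValue(binomialFeatureTest(obs, cat2, "hot")), 1)
})

test_that("degenerate binomial inputs are errors", {
  cat2 <- toyCatalogue(scores = 1:2)
  cat2@entries$hot <- c(TRUE, TRUE)
  obs <- observedFromIndex(cat2, 1L)
  expect_error(binomialFeatureTest(obs, cat2, "hot"), "degenerate")
  cat2@entries$hot <- c(FALSE, FALSE)
  expect_error(binomialFeatureTest(obs, cat2, "hot"), "degenerate")
  expect_error(binomialFeatureTest(obs, cat2, "nope"), "not found")
})

test_that("expected-count intervals equal pmf-accumulation quantiles", {
  expect_equal(expectedCountCI(50, 0), c(0, 0))
  ci <- expectedCountCI(100, 0.5)
  expect_true(ci[1] < 50 && ci[2] > 50)
  expect_equal(50 - ci[1], ci[2] - 50)  # symmetric
  expect_equal(expectedCountCI(20, 0.3),
               c(pmfQuantile(20, 0.3, 0.025), pmfQuantile(20, 0.3, 0.975)))
})

test_that("Monte Carlo p is close to 1 at the null median", {
  cat <- toyCatalogue(scores = 1:9)
  # observed at the probability-weighted null median
  obs <- observedFromIndex(cat, 5L, count = 1)
  res <- monteCarloTest(obs, cat, "ddg", nDraws = 20000, seed = 2)
  expect_gt(pValue(res), 0.9)
  expect_equal(res@expected, 5)
})

test_that("Monte Carlo p agrees with exhaustive enumeration on tiny nulls", {
  scores <- c(0.2, 1.5, 3.0)
  probs <- c(0.5, 0.3, 0.2)
  cat <- toyCatalogue(scores, probs)
  nDraws <- 20000
  for (pick in list(c(3L, 3L), c(1L, 2L), c(2L, 3L))) {
    obs <- observedFromIndex(cat, unique(pick),
                             count = as.numeric(table(pick)))
    res <- monteCarloTest(obs, cat, "ddg", nDraws = nDraws, seed = 7)
    pEx <- enumMonteCarloP(scores, probs,
                           list(scores = scores[pick]))
    t <- pEx / 2
    se <- 2 * sqrt(t * (1 - t) / nDraws)
    expect_lt(abs(pValue(res) - pEx), 3 * se + 2 / nDraws)
  }
})

test_that("constant score columns yield a degenerate p of 1", {
  cat <- toyCatalogue(scores = rep(2.5, 4))
  obs <- observedFromIndex(cat, 2L)
  expect_warning(res <- monteCarloTest(obs, cat, "ddg", nDraws = 100,
                                       seed = 1), "constant")
  expect_equal(pValue(res), 1)
})

test_that("Monte Carlo p-values floor at 2/(nDraws+1), never 0", {
  cat <- toyCatalogue(scores = 1:100)
  obs <- observedFromIndex(cat, rep(100L, 1), count = 30)
  res <- monteCarloTest(obs, cat, "ddg", nDraws = 999, seed = 3)
  expect_gte(pValue(res), 2 / 1000)
  expect_equal(res@details$pFloor, 2 / 1000)
})

test_that("mid-CDF transform matches hand values and centres at 0.5", {
  cat <- toyCatalogue(scores = c(1, 2, 3))
  expect_equal(cdfTransform(2, cat), 1 / 3 + 1 / 6)  # = 0.5
  # minimum value has F = p_min / 2
  catW <- toyCatalogue(scores = c(1, 2, 3), probs = c(0.2, 0.5, 0.3))
  expect_equal(cdfTransform(1, catW), 0.1)
  # E_null[F] = 0.5 for arbitrary discrete nulls
  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:40, 1)
    sc <- round(rnorm(k), sample(0:2, 1))  # ties likely
    pr <- runif(k)
    catR <- toyCatalogue(sc, pr)
    eR <- catalogueEntries(catR)
    f <- cdfTransform(eR$ddg, catR)
    expect_equal(sum(f * eR$prob), 0.5, tolerance = 1e-12)
  }
})

test_that("CDF shift is 0 for the null against itself, exactly", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(5:50, 1)
    catR <- toyCatalogue(rnorm(k), runif(k))
    sh <- cdfShift(NULL, catR, weights = nullProbabilities(catR))
    expect_equal(shiftValue(sh), 0, tolerance = 1e-12)
  }
})

test_that("CDF shift attains 0.5 - p_max/2 when all mass is at the maximum", {
  probs <- c(0.7, 0.2, 0.1)
  cat <- toyCatalogue(scores = c(0.1, 1.2, 5.0), probs = probs)
  obs <- observedFromIndex(cat, 3L, count = 12)
  expect_equal(shiftValue(cdfShift(obs, cat)), 0.5 - 0.1 / 2)
  # and approaches 0.5 as the top entry's null mass shrinks
  catEps <- toyCatalogue(scores = c(0.1, 1.2, 5.0),
                         probs = c(0.7, 0.2999, 1e-4))
  obsEps <- observedFromIndex(catEps, 3L)
  expect_equal(shiftValue(cdfShift(obsEps, catEps)), 0.5 - 1e-4 / 2)
  # mirrored at the minimum
  obsMin <- observedFromIndex(cat, 1L)
  expect_equal(shiftValue(cdfShift(obsMin, cat)), -0.5 + 0.7 / 2)
})

test_that("random observed sets keep the shift inside [-0.5, 0.5]", {
  set.seed(99)
  for (i in 1:50) {
    k <- sample(3:30, 1)
    cat <- toyCatalogue(rnorm(k), runif(k))
    idx <- sample(k, sample(seq_len(min(k, 5)), 1))
    obs <- observedFromIndex(cat, as.integer(idx))
    s <- shiftValue(cdfShift(obs, cat))
    expect_gte(s, -0.5)
    expect_lte(s, 0.5)
  }
})

test_that("gene shifts aggregate as the unweighted structure mean", {
  mk <- function(s) new("CdfShiftResult", geneId = "G", shift = s,
                        perStructure = s, n = 10)
  expect_equal(shiftValue(aggregateGeneShift(list(mk(0.31)))), 0.31)
  expect_equal(shiftValue(aggregateGeneShift(list(mk(0.2), mk(0.4)))), 0.3)
  perm <- list(mk(0.1), mk(0.25), mk(-0.2))
  expect_equal(shiftValue(aggregateGeneShift(perm)),
               shiftValue(aggregateGeneShift(rev(perm))))
  expect_error(aggregateGeneShift(list()), "no per-structure")
})

test_that("shift/dN-dS correlation matches the textbook Pearson formula", {
  sh <- data.frame(gene = paste0("G", 1:5),
                   shift = c(0.05, 0.12, 0.20, 0.31, 0.42))
  dn <- data.frame(gene = paste0("G", 1:5),
                   dnds = exp(c(-1, -0.4, 0.2, 0.9, 1.7)))
  out <- correlateShiftDnds(sh, dn)
  x <- sh$shift; y <- log(dn$dnds)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, rHand, tolerance = 1e-12)
  expect_equal(out$n, 5)
  # perfectly collinear table
  dn2 <- data.frame(gene = sh$gene, dnds = exp(2 * sh$shift + 1))
  expect_equal(correlateShiftDnds(sh, dn2)$r, 1, tolerance = 1e-9)
  # non-positive dN/dS excluded with a warning
  dn3 <- rbind(dn, data.frame(gene = "G6", dnds = 0))
  sh3 <- rbind(sh, data.frame(gene = "G6", shift = 0.5))
  expect_warning(out3 <- correlateShiftDnds(sh3, dn3), "non-positive")
  expect_equal(out3$n, 5)
  expect_error(correlateShiftDnds(sh[1:2, ], dn[1:2, ]), "at least 3")
})

test_that("duplicated unit-count records equal doubled counts", {
  cat <- maskingCatalogue(40, seed = 31)
  e <- catalogueEntries(cat)
  idx <- which(e$included)[c(3, 10, 25)]
  doubled <- observedFromIndex(cat, as.integer(idx), count = rep(2, 3))
  duplicated_ <- observedFromIndex(cat, as.integer(rep(idx, 2)),
                                   count = rep(1, 6))
  r1 <- binomialFeatureTest(doubled, cat, "strong")
  r2 <- binomialFeatureTest(duplicated_, cat, "strong")
  expect_equal(pValue(r1), pValue(r2))
  expect_equal(r1@n, r2@n)
  s1 <- cdfShift(doubled, cat)
  s2 <- cdfShift(duplicated_, cat)
  expect_equal(shiftValue(s1), shiftValue(s2))
})

test_that("unscored entries drop from both null and observed in tests", {
  cat <- toyCatalogue(scores = c(1, 2, NA, 4), probs = rep(0.25, 4))
  obs <- observedFromIndex(cat, c(2L, 3L), count = c(2, 5))
  expect_message(res <- monteCarloTest(obs, cat, "ddg", nDraws = 500,
                                       seed = 5), "unscored")
  expect_equal(res@n, 2)  # the 5 mutations on the unscored entry are dropped
})

test_that("Monte Carlo p-values are approximately uniform under the null", {
  # neutral observed sets drawn from the null itself; Kolmogorov distance
  # to the uniform stays small despite the discreteness at finite draws
  set.seed(1)
  k <- 200
  cat0 <- toyCatalogue(rnorm(k), runif(k))
  scn <- selectionScenario(list(), 20)
  nrep <- 5000
  ps <- numeric(nrep)
  for (i in seq_len(nrep)) {
    obs <- simulateMutations(cat0, scn, seed = 20000 + i)
    ps[i] <- pValue(monteCarloTest(obs, cat0, "ddg", statistic = "mean_cdf",
                                   nDraws = 1999, seed = 50000 + i))
  }
  expect_lt(ksUniform(ps), 0.02)
})
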