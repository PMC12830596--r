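test_that("Cohen's kappa matches hand-evaluated tables", {
  expect_equal(as.numeric(cohenKappa(c(1, 1, 0, 0), c(1, 1, 0, 0))), 1)
  # 40 both-deficient, 40 both-normal, 10 + 10 discordant: po 0.8, pe 0.5
  a <- rep(c("def", "def", "norm", "norm"), c(40, 10, 10, 40))
  b <- rep(c("def", "norm", "def", "norm"), c(40, 10, 10, 40))
  expect_equal(as.numeric(cohenKappa(a, b)), 0.6)
  # total disagreement evaluated by the same formula
  a2 <- rep("def", 20); b2 <- rep("norm", 20)
  pe <- 0 # marginals put all mass on different categories
  expect_equal(as.numeric(cohenKappa(a2, b2)), (0 - pe) / (1 - pe))
  expect_error(cohenKappa(1:3, 1:4), "length")
})

test_that("Cohen's kappa is symmetric and flags the degenerate case", {
  set.seed(1)
  for (i in 1:5) {
    a <- sample(c(-1, 0, 1), 50, replace = TRUE)
    b <- sample(c(-1, 0, 1), 50, replace = TRUE)
    expect_equal(as.numeric(cohenKappa(a, b)), as.numeric(cohenKappa(b, a)))
  }
  k <- cohenKappa(rep(1, 10), rep(1, 10))
  expect_equal(as.numeric(k), 1)
  expect_true(attr(k, "degenerate"))
})

test_that("Fleiss' kappa matches an independent computation", {
  # unanimity across two categories
  expect_equal(as.numeric(fleissKappa(matrix(rep(c(-1, 0, -1, 0), 3), 4, 3))), 1)
  # independent uniform labels: agreement is chance-level
  set.seed(2)
  M <- matrix(sample(c(-1L, 0L), 10000 * 3, replace = TRUE), 10000, 3)
  expect_lt(abs(as.numeric(fleissKappa(M))), 0.05)
  # worked 4-item, 3-rater example against a brute-force oracle
  M4 <- rbind(c(-1, -1, 0), c(0, 0, 0), c(-1, 0, 1), c(1, 1, 1))
  oracle <- local({
    lev <- sort(unique(as.vector(M4)))
    counts <- t(apply(M4, 1, function(r) table(factor(r, levels = lev))))
    n <- ncol(M4)
    Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
    pj <- colSums(counts) / (nrow(M4) * n)
    (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
  })
  expect_equal(as.numeric(fleissKappa(M4)), oracle)
  expect_error(fleissKappa(matrix(1, 3, 1)), "at least 2 raters")
})

test_that("Fleiss' kappa is invariant under rater permutation", {
  set.seed(3)
  M <- matrix(sample(c(-1L, 0L, 1L), 60 * 4, replace = TRUE), 60, 4)
  expect_equal(as.numeric(fleissKappa(M)),
               as.numeric(fleissKappa(M[, c(3, 1, 4, 2)])))
})

test_that("confusion metrics follow their definitions and conventions", {
  perfect <- confusionMetrics(c(-1, -1, 0, 0), c(-1, -1, 0, 0))
  expect_equal(perfect[, c("fpr", "fnr", "ppv", "f1")],
               data.frame(fpr = 0, fnr = 0, ppv = 1, f1 = 1))
  # all predicted deficient, none truly deficient: fpr 1, ppv 0, f1 absent
  allWrong <- confusionMetrics(rep(-1, 10), rep(0, 10))
  expect_equal(allWrong$fpr, 1)
  expect_equal(allWrong$ppv, 0)
  expect_true(is.na(allWrong$f1))
  expect_true(is.na(allWrong$sensitivity))
  # ppv 0.6, sensitivity 0.3 -> f1 = 2 * 0.18 / 0.9 = 0.4
  pred <- rep(c(-1, -1, 0, 0), c(6, 4, 14, 10))
  truth <- rep(c(-1, 0, -1, 0), c(6, 4, 14, 10))
  cm <- confusionMetrics(pred, truth)
  expect_equal(cm$ppv, 0.6)
  expect_equal(cm$sensitivity, 0.3)
  expect_equal(cm$f1, 0.4)
  expect_error(confusionMetrics(numeric(0), numeric(0)), "empty")
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  for (tp in c(1, 5, 20)) {
    for (fp in c(0, 3, 10)) {
      for (fn in c(0, 3, 10)) {
        cm <- confusionMetrics(rep(c(-1, -1, 0), c(tp, fp, fn)),
                               rep(c(-1, 0, -1), c(tp, fp, fn)))
        if (!is.na(cm$f1)) {
          expect_gte(cm$f1, min(cm$ppv, cm$sensitivity) - 1e-12)
          expect_lte(cm$f1, max(cm$ppv, cm$sensitivity) + 1e-12)
          if (fp == fn) expect_equal(cm$f1, cm$ppv)
        }
      }
    }
  }
})

test_that("weighted bootstrap summary reproduces closed-form weighted means", {
  one <- weightedBootstrapSummary(0.7, 100, nBootstrap = 200, seed = 1)
  expect_equal(one$weightedMean, 0.7)
  expect_equal(one$ciLow, 0.7)
  expect_equal(one$ciHigh, 0.7)
  two <- weightedBootstrapSummary(c(1, 0), c(100, 1), nBootstrap = 2000, seed = 2)
  expect_equal(two$weightedMean, 100 / 101)
  skewed <- weightedBootstrapSummary(c(0, 1, NA), c(1, 1, 1),
                                     nBootstrap = 500, seed = 3)
  expect_equal(skewed$weightedMean, 0.5)
  expect_equal(skewed$nExcluded, 1L)
  expect_lte(skewed$ciLow, skewed$weightedMean)
  expect_gte(skewed$ciHigh, skewed$weightedMean)
  expect_error(weightedBootstrapSummary(c(NA, NA), c(1, 1)), "undefined")
})

test_that("bootstrap confidence intervals cover a known mean at ~95%", {
  set.seed(4)
  hits <- replicate(250, {
    stats <- rnorm(40, mean = 0.5, sd = 0.3)
    w <- sample(50:150, 40, replace = TRUE)
    sm <- weightedBootstrapSummary(stats, w, nBootstrap = 400)
    sm$ciLow <= 0.5 && 0.5 <= sm$ciHigh
  })
  expect_lt(abs(mean(hits) - 0.95), 0.03 + 3 * sqrt(0.95 * 0.05 / 250))
})

test_that("zero-jitter consensus benchmarks perfectly against ground truth", {
  co <- generateCohort(smallDesign(nPatients = 1L, fibresPerSection = 150L,
                                   nControlFibres = 60L), seed = 6)
  ft <- fibreTable(patientFibres(co))
  ann <- generateAnnotations(co, nInvestigators = 3, boundaryJitterSd = 0,
                             seed = 7)
  labs <- lapply(c("INV1", "INV2", "INV3"), function(iv) {
    classifyByPolygons(ft, ann, investigator = iv)
  })
  calls <- suppressWarnings(
    consensusCertainty(labs, nResamples = 1000, seed = 8))
  bench <- benchmarkAgainstTruth(calls, patientFibres(co),
                                 nBootstrap = 500, seed = 9)
  ps <- bench$perSection
  expect_true(all(ps$fp == 0))
  expect_true(all(ps$fn == 0))
  kap <- bench$summary[bench$summary$statistic == "kappa", ]
  expect_true(all(kap$weightedMean == 1))
})
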