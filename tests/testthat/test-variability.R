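test_that("section proportion bootstrap matches binomial resampling", {
  allDef <- bootstrapSectionProportions(rep("deficient", 50), nDraws = 200,
                                        seed = 1)
  expect_true(all(allDef$draws == 1))
  noneDef <- bootstrapSectionProportions(rep("normal", 50), nDraws = 200,
                                         seed = 2)
  expect_true(all(noneDef$draws == 0))
  mix <- bootstrapSectionProportions(rep(c("deficient", "normal"), c(30, 70)),
                                     nDraws = 20000, seed = 3)
  expect_equal(mix$proportion, 0.3)
  se <- sqrt(0.3 * 0.7 / 100)
  expect_lt(abs(mean(mix$draws) - 0.30), 0.005)
  expect_lt(abs(sd(mix$draws) - se) / se, 0.1)
  expect_error(bootstrapSectionProportions(character(0)), "no classified")
})

test_that("pair enumeration matches hand-counted designs", {
  # 1 patient: 2 QD biopsies (3 sections each) + 1 TA biopsy (3 sections)
  sec <- expand.grid(section = paste0("S", 1:3),
                     biopsy = c("QD_B1", "QD_B2", "TA_B1"),
                     stringsAsFactors = FALSE)
  sec$patient <- "P1"
  sec$muscle <- sub("_B\\d", "", sec$biopsy)
  sec$section <- paste(sec$biopsy, sec$section, sep = "_")
  expect_equal(nrow(enumeratePairs(sec, "intra_biopsy")), 9)      # 3 x C(3,2)
  expect_equal(nrow(enumeratePairs(sec, "intra_muscle")), 9)      # 3 x 3 in QD
  expect_equal(nrow(enumeratePairs(sec, "intra_QD")), 9)
  expect_equal(nrow(enumeratePairs(sec, "intra_TA")), 0)
  expect_equal(nrow(enumeratePairs(sec, "inter_muscle")), 18)     # 6 x 3
  # L-splits
  sec$lSplitGroup <- ifelse(sec$muscle == "QD", "LS1", NA)
  expect_equal(nrow(enumeratePairs(sec, "intra_l_split")), 9)
  sec$lSplitGroup <- NA
  expect_error(enumeratePairs(sec, "intra_l_split"), "L-split")
  # biopsy-level pairing
  expect_equal(nrow(enumeratePairs(sec, "intra_muscle", unit = "biopsy")), 1)
  expect_equal(nrow(enumeratePairs(sec, "inter_muscle", unit = "biopsy")), 2)
  expect_error(enumeratePairs(sec, "intra_biopsy", unit = "biopsy"),
               "undefined at biopsy level")
})

test_that("all enumerated pairs stay within patient and between distinct units", {
  co <- generateCohort(smallDesign(fibresPerSection = 10L, nControlFibres = 50L),
                       seed = 4)
  sec <- sectionInfo(co)
  patOf <- setNames(sec$patient, sec$section)
  bioOf <- setNames(sec$biopsy, sec$section)
  for (st in c("intra_biopsy", "intra_muscle", "inter_muscle", "intra_l_split")) {
    pr <- enumeratePairs(sec, st)
    expect_true(all(pr$unitA != pr$unitB))
    expect_true(all(patOf[pr$unitA] == patOf[pr$unitB]))
    if (st != "intra_biopsy") expect_true(all(bioOf[pr$unitA] != bioOf[pr$unitB]))
  }
})

test_that("absolute-difference sampling matches degenerate and closed forms", {
  pairs <- data.frame(unitA = "a", unitB = "b")
  expect_true(all(sampleAbsDifferences(list(a = 10, b = 13), pairs,
                                       nIterations = 500, seed = 1) == 3))
  expect_true(all(sampleAbsDifferences(list(a = 7, b = 7), pairs,
                                       nIterations = 500, seed = 2) == 0))
  # |U - V| for independent U, V ~ Uniform(0,1): median = 1 - 1/sqrt(2)
  set.seed(3)
  dists <- list(a = runif(50000), b = runif(50000))
  d <- sampleAbsDifferences(dists, pairs, nIterations = 2e5, seed = 4)
  expect_lt(abs(median(d) - (1 - 1 / sqrt(2))), 0.01)
  expect_error(sampleAbsDifferences(list(a = 1), pairs[0, ], 10), "empty pair")
  expect_error(sampleAbsDifferences(list(a = 1), pairs, 10), "no distribution")
})

test_that("difference sampling is deterministic given a seed", {
  dists <- list(a = 1:5, b = 6:10, c = 2:4)
  pairs <- data.frame(unitA = c("a", "a"), unitB = c("b", "c"))
  expect_identical(sampleAbsDifferences(dists, pairs, 1000, seed = 9),
                   sampleAbsDifferences(dists, pairs, 1000, seed = 9))
})

test_that("distribution summaries follow the linear-interpolation convention", {
  const <- summarizeDistribution(rep(5, 10))
  expect_equal(unlist(const[c("median", "iqr_low", "iqr_high", "p2_5",
                              "p97_5", "min", "max")]),
               c(median = 5, iqr_low = 5, iqr_high = 5, p2_5 = 5,
                 p97_5 = 5, min = 5, max = 5))
  s <- summarizeDistribution(1:1000)
  expect_equal(s$median, 500.5)
  expect_equal(s$p2_5, 25.975)
  expect_equal(s$p97_5, 975.025)
  two <- summarizeDistribution(c(0, 10))
  expect_equal(two$median, 5)
  expect_equal(c(two$min, two$max), c(0, 10))
  expect_error(summarizeDistribution(numeric(0)), "empty")
})

test_that("summary quantiles are always correctly ordered", {
  set.seed(5)
  for (i in 1:20) {
    s <- summarizeDistribution(rexp(sample(2:200, 1)))
    expect_true(s$min <= s$p2_5 && s$p2_5 <= s$median &&
                  s$median <= s$p97_5 && s$p97_5 <= s$max)
    expect_true(s$iqr_low <= s$median && s$median <= s$iqr_high)
  }
})

test_that("threshold report applies the strict exceedance rule", {
  sm <- cbind(data.frame(metric = "oxphos_NDUFB8", strategy = "intra_muscle"),
              summarizeDistribution(c(rep(5, 97), rep(20, 3))))
  rep <- thresholdReport(sm, strategies = "intra_muscle")
  expect_true(exceedsExpectedVariability(rep$threshold + 0.1, rep$threshold))
  expect_false(exceedsExpectedVariability(rep$threshold, rep$threshold))
  expect_false(exceedsExpectedVariability(0, rep$threshold))
  expect_error(thresholdReport(sm, strategies = "inter_muscle"), "no summary")
})

test_that("true-label point masses recover the analytic pair-difference median", {
  sec <- data.frame(patient = "P1", muscle = "QD", biopsy = "B1",
                    section = c("S1", "S2", "S3"))
  props <- list(S1 = 0.1, S2 = 0.2, S3 = 0.4)
  pairs <- enumeratePairs(sec, "intra_biopsy")
  d <- sampleAbsDifferences(props, pairs, nIterations = 30000, seed = 6)
  # pair differences are {0.1, 0.3, 0.2}; the sampled median is their median
  expect_equal(median(d), 0.2)
  expect_true(all(round(d, 10) %in% c(0.1, 0.2, 0.3)))
})
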