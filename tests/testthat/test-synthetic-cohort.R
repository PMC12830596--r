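test_that("design validity rejects inconsistent parameterisations", {
  expect_error(CohortDesign(nPatients = 0), "count")
  expect_error(CohortDesign(deficientShift = 0), "unidentifiable")
  expect_error(CohortDesign(overabundanceRate = 1.5), "\\[0, 1\\]")
  expect_error(
    CohortDesign(biopsiesPerMuscle = 2,
                 lSplitPairs = data.frame(patient = 1, muscle = "QD",
                                          biopsyA = 1, biopsyB = 5,
                                          distanceMm = 10)),
    "do not exist")
  expect_error(
    CohortDesign(lSplitPairs = data.frame(patient = 1, muscle = "QD",
                                          biopsyA = 1, biopsyB = 2,
                                          distanceMm = -3)),
    "distances")
  bad <- CohortDesign()
  expect_s4_class(bad, "CohortDesign")
})

test_that("cohort generation is byte-identical for a fixed design and seed", {
  d <- smallDesign(fibresPerSection = 40L, nControlFibres = 50L)
  a <- generateCohort(d, seed = 7)
  b <- generateCohort(d, seed = 7)
  expect_identical(fibreTable(patientFibres(a)), fibreTable(patientFibres(b)))
  expect_identical(fibreTable(controlFibres(a)), fibreTable(controlFibres(b)))
  expect_identical(sectionInfo(a), sectionInfo(b))
  c <- generateCohort(d, seed = 8)
  expect_false(identical(fibreTable(patientFibres(a)),
                         fibreTable(patientFibres(c))))
})

test_that("deterministic assignment yields exact per-section deficient counts", {
  d <- smallDesign(fibresPerSection = 100L)
  co <- generateCohort(d, seed = 3)
  ft <- fibreTable(patientFibres(co))
  sec <- sectionInfo(co)
  for (p in oxphosProteins(patientFibres(co))) {
    counts <- tapply(ft[[paste0("label_", p)]] == -1L, ft$section, sum)
    expected <- round(sec[[paste0("true_prop_", p)]] * sec$nFibres)
    expect_identical(as.integer(counts[sec$section]), as.integer(expected))
    # and the recorded proportion is the realized one
    expect_equal(as.numeric(counts[sec$section]) / sec$nFibres,
                 sec[[paste0("true_prop_", p)]])
  }
})

test_that("with all nuisance effects off, patient fibres sit on the control line", {
  d <- smallDesign(
    nPatients = 1L, fibresPerSection = 400L,
    sectionBatchSd = 0,
    patientDisparity = list("NDUFB8" = list(gain = 1, offset = 0),
                            "MT-CO1" = list(gain = 1, offset = 0)),
    deficiencyModel = list(meanProportion = c("NDUFB8" = 0, "MT-CO1" = 0),
                           patientSd = 0, muscleOffset = c(QD = 0, TA = 0),
                           driftSdPerMm = 0),
    overabundanceRate = 0, deficientShift = 8)
  co <- generateCohort(d, seed = 11)
  ft <- fibreTable(patientFibres(co))
  cp <- cohortDesign(co)@controlParams[["NDUFB8"]]
  resid <- ft$NDUFB8 - (cp$intercept + cp$slope * ft$vdac1)
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * cp$residualSd / sqrt(n))
})

test_that("ground-truth flags form a contiguous block of the right size", {
  d <- smallDesign(fibresPerSection = 100L, groundTruthFraction = 0.05)
  co <- generateCohort(d, seed = 5)
  ft <- fibreTable(patientFibres(co))
  for (s in unique(ft$section)) {
    flag <- ft$in_ground_truth_region[ft$section == s]
    idx <- which(flag)
    expect_length(idx, 5L)
    expect_identical(idx, seq(min(idx), max(idx)))
  }
})

test_that("zero-jitter annotations reproduce true labels; agreement decays with jitter", {
  d <- smallDesign(nPatients = 1L, fibresPerSection = 80L,
                   nControlFibres = 50L)
  co <- generateCohort(d, seed = 2)
  ft <- fibreTable(patientFibres(co))
  ann0 <- generateAnnotations(co, nInvestigators = 3, boundaryJitterSd = 0,
                              seed = 1)
  labs <- lapply(c("INV1", "INV2", "INV3"), function(iv) {
    classifyByPolygons(ft, ann0, investigator = iv)
  })
  for (lt in labs) {
    for (p in c("NDUFB8", "MT-CO1")) {
      m <- merge(lt[lt$protein == p, ], ft[, c("fibre_id", paste0("label_", p))],
                 by = "fibre_id")
      expect_identical(m$label, m[[paste0("label_", p)]])
    }
  }
  # unanimity at zero jitter
  L <- sapply(labs, function(lt) lt$label[order(lt$fibre_id, lt$protein)])
  expect_equal(as.numeric(fleissKappa(L)), 1)

  # average inter-investigator agreement decreases from no jitter to heavy jitter
  kappaAt <- function(jitter, seeds = 1:3) {
    mean(sapply(seeds, function(s) {
      ann <- generateAnnotations(co, nInvestigators = 3,
                                 boundaryJitterSd = jitter, seed = s)
      lt <- lapply(c("INV1", "INV2", "INV3"), function(iv) {
        classifyByPolygons(ft, ann, investigator = iv)
      })
      M <- sapply(lt, function(x) x$label[order(x$fibre_id, x$protein)])
      as.numeric(fleissKappa(M))
    }))
  }
  expect_gt(kappaAt(0), kappaAt(60))
  expect_gt(kappaAt(60), kappaAt(250))
})

test_that("qPCR generator inverts exactly without noise and matches the Cq line", {
  co <- generateCohort(smallDesign(nPatients = 1L, fibresPerSection = 10L,
                                   nControlFibres = 50L), seed = 1)
  plate <- generateQpcr(co, cqNoiseSd = 0, seed = 4)
  # noiseless: back-calculated copies from each dilution Cq equal the truth
  for (tg in c("MT-ND1", "B2M")) {
    cu <- plate@trueCurve[plate@trueCurve$target == tg, ]
    d <- plate@dilutions[plate@dilutions$target == tg, ]
    back <- 10^((d$cq - cu$intercept) / cu$slope)
    expect_equal(back, d$copies, tolerance = 1e-12)
  }
  # direct evaluation of the line: slope -3.3219, intercept 38, 1000 copies
  expect_equal(38 + (-3.3219) * log10(1000), 28.0343, tolerance = 1e-10)
  nd1 <- plate@dilutions[plate@dilutions$target == "MT-ND1" &
                           plate@dilutions$copies == 1000, "cq"]
  expect_equal(unique(nd1), 28.0343, tolerance = 1e-10)
})

test_that("true per-biopsy copy numbers follow the configured cohort scale", {
  mcn <- generateQpcr(biopsies = sprintf("B%03d", 1:400), seed = 9)@trueMcn
  expect_true(all(mcn > 0))
  expect_lt(abs(mean(mcn) - 1476), 3 * 517 / sqrt(length(mcn)) + 20)
  expect_lt(abs(sd(mcn) - 517), 90)
})

test_that("pyrosequencing generator honours its noise parameters", {
  co <- generateCohort(smallDesign(fibresPerSection = 10L, nControlFibres = 50L),
                       seed = 1)
  # no noise at all: replicates equal the per-muscle means exactly
  py0 <- generatePyroseq(co, betweenBiopsySd = 0, replicateSd = 0, seed = 2)
  expect_identical(unique(py0$records$het[py0$records$patient == "P2" &
                                            py0$records$muscle == "QD"]), 83)
  expect_identical(unique(py0$records$het[py0$records$patient == "P2" &
                                            py0$records$muscle == "TA"]), 85)
  agg <- tapply(py0$records$het, py0$records$biopsy, mean)
  expect_equal(unname(pooledSd(split(agg, sub("_B\\d+$", "", names(agg))))), 0)
  # standards round-trip: replicate means within 3 SE of nominal levels
  py <- generatePyroseq(co, replicateSd = 1, seed = 3)
  for (lev in c(0, 16, 52, 92)) {
    reps <- py$standards$het[py$standards$level == lev]
    expect_lt(abs(mean(reps) - lev), 3 * 1 / sqrt(length(reps)) + 1e-9 + lev * 0)
  }
  expect_true(all(py$records$het >= 0 & py$records$het <= 100))
  expect_error(generatePyroseq(co, muscleMeans = list(QD = 120, TA = 50)),
               "\\[0, 100\\]")
})
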