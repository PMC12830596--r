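noiselessDilutions <- function(slopeNd = -3.3219, intNd = 38,
                               slopeB2m = -3.35, intB2m = 37.5,
                               copies = 10^(7:2), reps = 3) {
  do.call(rbind, lapply(list(c("MT-ND1", slopeNd, intNd),
                             c("B2M", slopeB2m, intB2m)), function(tg) {
    do.call(rbind, lapply(copies, function(cp) {
      data.frame(target = tg[1], copies = cp, replicate = seq_len(reps),
                 cq = as.numeric(tg[3]) + as.numeric(tg[2]) * log10(cp))
    }))
  }))
}

sampleCqFor <- function(nd1Copies, b2mCopies, slopeNd = -3.3219, intNd = 38,
                        slopeB2m = -3.35, intB2m = 37.5, biopsy = "B1") {
  rbind(data.frame(biopsy = biopsy, target = "MT-ND1", replicate = 1:3,
                   cq = intNd + slopeNd * log10(nd1Copies)),
        data.frame(biopsy = biopsy, target = "B2M", replicate = 1:3,
                   cq = intB2m + slopeB2m * log10(b2mCopies)))
}

test_that("noiseless standard curves are recovered exactly by every model", {
  fits <- bootstrapStandardCurves(noiselessDilutions(), nModels = 50, seed = 1)
  expect_equal(unique(round(fits[["MT-ND1"]]$slope, 10)), -3.3219)
  expect_equal(unique(round(fits[["MT-ND1"]]$intercept, 10)), 38)
  expect_equal(unique(round(fits[["B2M"]]$slope, 10)), -3.35)
  # single replicate per dilution: resampling is degenerate, all fits equal
  single <- noiselessDilutions(reps = 1)
  single$cq <- single$cq + rep(c(0.1, -0.1), each = 6) # any fixed perturbation
  f1 <- bootstrapStandardCurves(single, nModels = 20, seed = 2)
  expect_equal(length(unique(f1[["MT-ND1"]]$slope)), 1L)
  expect_error(bootstrapStandardCurves(
    noiselessDilutions(copies = c(1000, 100)), nModels = 5), ">= 3 dilutions")
})

test_that("bootstrapped slopes are centred on the truth under Cq noise", {
  set.seed(3)
  dil <- noiselessDilutions(reps = 6)
  dil$cq <- dil$cq + rnorm(nrow(dil), 0, 0.2)
  fits <- bootstrapStandardCurves(dil, nModels = 4000, seed = 4)
  sl <- fits[["MT-ND1"]]$slope
  # bootstrap models centre on the observed sample's fit, whose own sampling
  # error around the true slope is sigma / sqrt(nReps * sum((lx - mean(lx))^2))
  lx <- log10(unique(dil$copies))
  slopeSe <- 0.2 / sqrt(6 * sum((lx - mean(lx))^2))
  expect_lt(abs(mean(sl) + 3.3219), 3 * slopeSe)
})

test_that("copy-number identity MT-ND1/(B2M/2) holds exactly without noise", {
  curves <- bootstrapStandardCurves(noiselessDilutions(), nModels = 30, seed = 5)
  mcn <- estimateMtdnacn(sampleCqFor(1000, 2), curves, nIterations = 200,
                         seed = 6)
  expect_equal(unique(round(mcn[["B1"]]$values, 8)), 1000)
  expect_equal(mcn[["B1"]]$median, 1000, tolerance = 1e-8)
  half <- estimateMtdnacn(sampleCqFor(500, 1), curves, nIterations = 100,
                          seed = 7)
  expect_equal(half[["B1"]]$median, 1000, tolerance = 1e-8)
})

test_that("rescaling all copies leaves copies-per-nucleus unchanged", {
  curves <- bootstrapStandardCurves(noiselessDilutions(), nModels = 20, seed = 8)
  a <- estimateMtdnacn(sampleCqFor(1e6, 2e3), curves, nIterations = 100, seed = 9)
  b <- estimateMtdnacn(sampleCqFor(1e7, 2e4), curves, nIterations = 100, seed = 9)
  expect_equal(a[["B1"]]$median, b[["B1"]]$median, tolerance = 1e-8)
})

test_that("the distribution collapses to the truth as Cq noise vanishes", {
  widths <- sapply(c(0.2, 0.02, 0), function(noise) {
    set.seed(10)
    dil <- noiselessDilutions(reps = 6)
    dil$cq <- dil$cq + rnorm(nrow(dil), 0, noise)
    smp <- sampleCqFor(1476 * 1e4, 2e4)
    smp$cq <- smp$cq + rnorm(nrow(smp), 0, noise)
    curves <- bootstrapStandardCurves(dil, nModels = 2000, seed = 11)
    mcn <- estimateMtdnacn(smp, curves, nIterations = 4000, seed = 12)
    diff(quantile(mcn[["B1"]]$values, c(0.025, 0.975)))
  })
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 1e-6)
})

test_that("the reported median resists a 1% outlier contamination", {
  set.seed(13)
  dil <- noiselessDilutions(reps = 6)
  dil$cq <- dil$cq + rnorm(nrow(dil), 0, 0.2)
  smp <- sampleCqFor(1476 * 1e4, 2e4)
  smp$cq <- smp$cq + rnorm(nrow(smp), 0, 0.2)
  curves <- bootstrapStandardCurves(dil, nModels = 5000, seed = 14)
  mcn <- estimateMtdnacn(smp, curves, nIterations = 20000, seed = 15)
  contaminated <- mcn[["B1"]]$values
  idx <- seq_len(length(contaminated) %/% 100)
  contaminated[idx] <- 1e7
  expect_lt(abs(median(contaminated) - mcn[["B1"]]$median) / mcn[["B1"]]$median,
            0.01)
})

test_that("estimateMtdnacn rejects invalid curve sets", {
  curves <- list("MT-ND1" = data.frame(slope = 2, intercept = 38),
                 "B2M" = data.frame(slope = -3.3, intercept = 37))
  expect_error(estimateMtdnacn(sampleCqFor(1000, 2), curves, 10),
               "negative-slope")
})

test_that("heteroplasmy means and pooled SD follow their formulas", {
  expect_equal(heteroplasmyMean(c(83, 83, 83)), 83)
  expect_equal(heteroplasmyMean(c(80, 85, 90)), 85)
  expect_error(heteroplasmyMean(c(80, 85)), "expected 3")
  expect_warning(h <- heteroplasmyMean(c(80, 90), strict = FALSE), "2 replicates")
  expect_equal(h, 85)
  expect_error(heteroplasmyMean(c(80, 85, 120)), "\\[0, 100\\]")
  # pooled SD: variances 4 and 9 with n = 3 each -> sqrt((2*4 + 2*9) / 4)
  g1 <- c(0, 2, 4); g2 <- c(0, 3, 6)      # vars 4 and 9
  expect_equal(pooledSd(list(g1, g2)), sqrt(6.5))
  expect_equal(pooledSd(list(rep(5, 4), rep(7, 3))), 0)
  expect_equal(pooledSd(list(c(1, 2, 3))), 1)
  expect_error(pooledSd(list(1, 2)), ">= 2 values")
})

test_that("amplification efficiency diagnostic", {
  expect_equal(amplificationEfficiency(-3.3219), 1, tolerance = 1e-4)
})
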