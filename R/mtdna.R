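#' Bootstrap qPCR standard curves
#'
#' First stage of the staged bootstrap for mtDNA copy number: per iteration,
#' one Cq value is drawn with replacement from each dilution's replicates and
#' an ordinary least-squares line of Cq on log10(copies) is fitted, giving a
#' population of plausible standard curves per target that carries the
#' replicate-level Cq variability into copy-number estimates.
#'
#' @param dilutions Dilution-series table (`target`, `copies`, `cq`;
#'   replicate rows), a [QPCRPlate], or its `dilutions` slot.
#' @param nModels Bootstrap iterations (analysis default 1e5; reduce for
#'   exploration).
#' @param seed Integer seed.
#' @return Named list per target of `data.frame(slope, intercept)` with one
#'   row per bootstrap model.
#' @export
bootstrapStandardCurves <- function(dilutions, nModels = 1e5, seed = NULL) {
  if (is(dilutions, "QPCRPlate")) dilutions <- dilutions@dilutions
  .assertColumns(dilutions, c("target", "copies", "cq"), "dilution series")
  .withSeed(seed, {
    out <- list()
    for (tg in unique(dilutions$target)) {
      d <- dilutions[dilutions$target == tg, ]
      levels <- sort(unique(d$copies), decreasing = TRUE)
      if (length(levels) < 3L) {
        stop(sprintf("target '%s' needs >= 3 dilutions for a standard curve", tg))
      }
      lx <- log10(levels)
      xc <- lx - mean(lx)
      ssx <- sum(xc^2)
      # one resampled Cq per dilution per model: levels x nModels matrix
      Y <- vapply(levels, function(cp) {
        reps <- d$cq[d$copies == cp]
        if (length(reps) < 1L) stop("dilution without replicates")
        reps[sample.int(length(reps), nModels, replace = TRUE)]
      }, numeric(nModels))
      Y <- t(matrix(Y, nrow = nModels))
      slope <- colSums(xc * Y) / ssx
      intercept <- colMeans(Y) - slope * mean(lx)
      out[[tg]] <- data.frame(slope = slope, intercept = intercept)
    }
    out
  })
}

#' Amplification efficiency of a standard curve
#'
#' Diagnostic only: `10^(-1/slope) - 1`, the per-cycle amplification gain
#' implied by a Cq-vs-log10(copies) slope (1 = perfect doubling).
#'
#' @param slope Standard-curve slope(s).
#' @return Efficiency value(s).
#' @export
amplificationEfficiency <- function(slope) 10^(-1 / slope) - 1

#' Staged-bootstrap mtDNA copy number per nucleus
#'
#' Second stage of the staged bootstrap: per iteration, one bootstrap
#' standard curve and one replicate Cq value are drawn independently per
#' target (MT-ND1 and B2M); copies per reaction are back-calculated by
#' inverting the curve, `copies = 10^((Cq - intercept) / slope)`; and the
#' iteration's copy number per nucleus is `MT-ND1 / (B2M / 2)` (two B2M
#' copies per diploid nucleus). The per-biopsy distribution captures both
#' curve uncertainty and Cq replicate variability; its median is the reported
#' point estimate.
#'
#' @param sampleCq Per-biopsy Cq table (`biopsy`, `target`, `cq`) or a
#'   [QPCRPlate].
#' @param curves Output of [bootstrapStandardCurves()]; must contain entries
#'   for `MT-ND1` and `B2M`. Curves with non-negative slope are invalid
#'   amplification and are redrawn (an error is raised if no valid curve
#'   exists).
#' @param nIterations Pairing iterations per biopsy (analysis default 1e5).
#' @param seed Integer seed.
#' @param mitoTarget,nuclearTarget Target names (defaults `"MT-ND1"`,
#'   `"B2M"`).
#' @return List per biopsy with `values` (copies per nucleus), `median` and
#'   `nIterations`. A one-row-per-biopsy summary is available via
#'   [mcnSummary()].
#' @export
estimateMtdnacn <- function(sampleCq, curves, nIterations = 1e5, seed = NULL,
                            mitoTarget = "MT-ND1", nuclearTarget = "B2M") {
  if (is(sampleCq, "QPCRPlate")) sampleCq <- sampleCq@samples
  .assertColumns(sampleCq, c("biopsy", "target", "cq"), "sample Cq table")
  for (tg in c(mitoTarget, nuclearTarget)) {
    if (is.null(curves[[tg]])) stop(sprintf("no bootstrap curves for target '%s'", tg))
    if (!any(curves[[tg]]$slope < 0)) {
      stop(sprintf("no valid (negative-slope) curve for target '%s'", tg))
    }
  }
  drawCopies <- function(cq, curveSet, n) {
    nc <- nrow(curveSet)
    ci <- sample.int(nc, n, replace = TRUE)
    bad <- curveSet$slope[ci] >= 0
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > 100L) stop("kept drawing non-negative-slope curves")
      ci[bad] <- sample.int(nc, sum(bad), replace = TRUE)
      bad <- curveSet$slope[ci] >= 0
    }
    qi <- cq[sample.int(length(cq), n, replace = TRUE)]
    10^((qi - curveSet$intercept[ci]) / curveSet$slope[ci])
  }
  .withSeed(seed, {
    out <- list()
    for (b in unique(sampleCq$biopsy)) {
      nd <- sampleCq$cq[sampleCq$biopsy == b & sampleCq$target == mitoTarget]
      bm <- sampleCq$cq[sampleCq$biopsy == b & sampleCq$target == nuclearTarget]
      if (!length(nd) || !length(bm)) {
        stop(sprintf("biopsy '%s' lacks Cq replicates for both targets", b))
      }
      nd1 <- drawCopies(nd, curves[[mitoTarget]], nIterations)
      b2m <- drawCopies(bm, curves[[nuclearTarget]], nIterations)
      values <- nd1 / (b2m / 2)
      out[[b]] <- list(biopsy = b, values = values,
                       median = median(values),
                       nIterations = as.integer(nIterations))
    }
    out
  })
}

#' Summarise per-biopsy mtDNA copy-number distributions
#'
#' @param mcn Output of [estimateMtdnacn()].
#' @return data.frame with `biopsy`, `median`, `p2_5`, `p97_5`.
#' @export
mcnSummary <- function(mcn) {
  do.call(rbind, lapply(mcn, function(m) {
    q <- quantile(m$values, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(biopsy = m$biopsy, median = m$median, p2_5 = q[1L], p97_5 = q[2L])
  }))
}

#' Per-biopsy heteroplasmy as the triplicate mean
#'
#' @param replicates Numeric vector of pyrosequencing heteroplasmy replicates
#'   (\%), normally a triplicate.
#' @param nRequired Required replicate count (default 3); with
#'   `strict = FALSE`, >= 2 replicates are accepted with a warning.
#' @param strict Enforce the exact replicate count (default TRUE).
#' @return The arithmetic mean, in \[0, 100\].
#' @export
heteroplasmyMean <- function(replicates, nRequired = 3L, strict = TRUE) {
  if (any(!is.finite(replicates)) || any(replicates < 0 | replicates > 100)) {
    stop("heteroplasmy replicates must lie in [0, 100]")
  }
  if (length(replicates) != nRequired) {
    if (strict || length(replicates) < 2L) {
      stop(sprintf("expected %d replicates, got %d", nRequired, length(replicates)))
    }
    warning(sprintf("using %d replicates instead of %d", length(replicates), nRequired))
  }
  mean(replicates)
}

#' Pooled standard deviation across groups
#'
#' Square root of the degrees-of-freedom-weighted average of group variances:
#' the pooled SD of per-biopsy heteroplasmy means across patients. Groups
#' with fewer than two values contribute no degrees of freedom and are
#' skipped.
#'
#' @param groups List of numeric vectors, one per group (e.g. per patient).
#' @return The pooled SD.
#' @examples
#' pooledSd(list(c(1, 3), c(4, 8))) # sqrt((2 + 8) / 2)
#' @export
pooledSd <- function(groups) {
  if (!is.list(groups)) groups <- list(groups)
  ns <- lengths(groups)
  use <- ns >= 2L
  if (!any(use)) stop("need at least one group with >= 2 values")
  vs <- vapply(groups[use], var, 0)
  dfs <- ns[use] - 1L
  sqrt(sum(dfs * vs) / sum(dfs))
}
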