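#' Fit the control OXPHOS~VDAC1 regression and its prediction band
#'
#' Ordinary least squares of an OXPHOS channel on VDAC1 over control fibres,
#' returned as a [PredictionBand] carrying the sufficient statistics of the
#' classical t-based prediction interval. The band at coverage `level`
#' defines the normal OXPHOS range for fibres of a given mitochondrial mass;
#' patient fibres below it are OXPHOS-deficient, above it overabundant.
#'
#' @param object Control fibres: a data.frame with `vdac1` and a column per
#'   OXPHOS protein, or a [FibreExperiment].
#' @param protein Which OXPHOS channel to fit.
#' @param level Prediction-interval coverage (default 0.95).
#' @param ... Unused.
#' @return A [PredictionBand].
#' @examples
#' ctrl <- data.frame(vdac1 = 1:10, NDUFB8 = 2 * (1:10) + 1)
#' fitControlRegression(ctrl, "NDUFB8")
#' @rdname fitControlRegression
#' @export
setMethod("fitControlRegression", "data.frame",
          function(object, protein, level = 0.95, ...) {
  .assertColumns(object, c("vdac1", protein), "control table")
  x <- object$vdac1
  y <- object[[protein]]
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 control fibres with finite positive intensities")
  if (sd(x) == 0) stop("degenerate predictor: all control VDAC1 values are equal")
  fit <- lm(y ~ x)
  s <- sqrt(sum(fit$residuals^2) / (n - 2L))
  new("PredictionBand",
      protein = protein,
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      residualSd = s,
      nControl = n,
      xMean = mean(x),
      xSS = sum((x - mean(x))^2),
      level = level)
})

#' @rdname fitControlRegression
#' @export
setMethod("fitControlRegression", "FibreExperiment",
          function(object, protein, level = 0.95, ...) {
  fitControlRegression(fibreTable(object), protein, level = level, ...)
})

#' Evaluate a prediction band
#'
#' @param band A [PredictionBand].
#' @param x VDAC1 values at which to evaluate the band.
#' @return `data.frame(fit, lwr, upr)` with the regression fit and the
#'   prediction-interval bounds at each `x`.
#' @export
predictionInterval <- function(band, x) {
  stopifnot(is(band, "PredictionBand"))
  fit <- band@intercept + band@slope * x
  tc <- qt(1 - (1 - band@level) / 2, band@nControl - 2L)
  hw <- tc * band@residualSd *
    sqrt(1 + 1 / band@nControl + (x - band@xMean)^2 / band@xSS)
  data.frame(fit = fit, lwr = fit - hw, upr = fit + hw)
}

#' Classify fibres against a single prediction band
#'
#' @param band A [PredictionBand].
#' @param vdac1,oxphos Fibre intensities.
#' @return Integer labels: -1 below the band (lower than control), 0 within,
#'   +1 above. Boundary values count as within.
#' @export
classifyWithBand <- function(band, vdac1, oxphos) {
  pi <- predictionInterval(band, vdac1)
  as.integer((oxphos > pi$upr) - (oxphos < pi$lwr))
}

setMethod("show", "PredictionBand", function(object) {
  cat(sprintf("PredictionBand (%s): fit = %.4g + %.4g * VDAC1, residual SD %.4g\n",
              object@protein, object@intercept, object@slope, object@residualSd))
  cat(sprintf("  n = %d controls, level = %.2f\n", object@nControl, object@level))
})

## Closed-form OLS band labels for one bootstrap model; algebraically the
## same interval as predictionInterval() on an lm fit.
.olsBandLabels <- function(px, py, x, y, level) {
  n <- length(x)
  xb <- mean(x)
  xc <- x - xb
  ssx <- sum(xc^2)
  b <- sum(xc * y) / ssx
  a <- mean(y) - b * xb
  res <- y - a - b * x
  s <- sqrt(sum(res^2) / (n - 2))
  tc <- qt(1 - (1 - level) / 2, n - 2)
  fit <- a + b * px
  hw <- tc * s * sqrt(1 + 1 / n + (px - xb)^2 / ssx)
  (py > fit + hw) - (py < fit - hw)
}

#' Frequentist bootstrapped prediction-interval classification
#'
#' Classifies each patient fibre's OXPHOS status per protein by the
#' frequentist method: control fibres are resampled with replacement
#' `nModels` times; each resample yields an OLS fit and a `level` prediction
#' band; each patient fibre is labelled -1/0/+1 against each band; the mean
#' label across models is the fibre's classification certainty in
#' \[-1, +1\], and the final call is `deficient` when the mean is at or below
#' `-certaintyThreshold`, `overabundant` at or above `+certaintyThreshold`,
#' otherwise `normal`.
#'
#' Classification is batch-specific: when both tables carry a `batch` column,
#' each patient batch is classified against its own control batch (in
#' generated cohorts, batch = patient, since all of a patient's sections are
#' stained together).
#'
#' @param object Patient fibres ([FibreExperiment] or fibre table).
#' @param controls Control fibres (same formats).
#' @param proteins OXPHOS channels to classify (default: all present).
#' @param nModels Number of bootstrap regression models (default 10000).
#' @param certaintyThreshold Consensus fraction required for a deficient or
#'   overabundant call (default 0.95; comparisons are non-strict).
#' @param level Prediction-interval coverage (default 0.95).
#' @param resample If `FALSE`, every model uses the original controls (no
#'   bootstrap); with `nModels = 1` this reduces to a single deterministic
#'   band classification.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param minSectionFibres Sections with fewer classified fibres than this
#'   are flagged (column `section_below_min_fibres`) and a warning is
#'   emitted; around 100 fibres are needed for a confident per-section
#'   deficiency proportion (default 100).
#' @param retryCap Bootstrap resamples with a degenerate predictor (all
#'   VDAC1 equal) are redrawn at most this many times (default 100).
#' @param ... Unused.
#' @return data.frame with one row per fibre and protein: `fibre_id`,
#'   `section`, `protein`, `method = "frequentist"`, `mean_label`,
#'   `n_models`, `final_call`, `section_below_min_fibres`.
#' @rdname classifyFrequentist
#' @export
setMethod("classifyFrequentist", "data.frame",
          function(object, controls, proteins = NULL, nModels = 10000L,
                   certaintyThreshold = 0.95, level = 0.95, resample = TRUE,
                   seed = NULL, minSectionFibres = 100L, retryCap = 100L, ...) {
  if (is(controls, "FibreExperiment")) controls <- fibreTable(controls)
  .assertColumns(object, c("fibre_id", "section", "vdac1"), "patient table")
  .assertColumns(controls, "vdac1", "control table")
  if (!nrow(object)) stop("patient fibre table is empty")
  if (is.null(proteins)) {
    proteins <- setdiff(intersect(names(object), names(controls)),
                        c("fibre_id", "patient", "muscle", "biopsy", "section",
                          "batch", "vdac1", "in_ground_truth_region",
                          grep("^label_", names(object), value = TRUE)))
  }
  if (!length(proteins)) stop("no shared OXPHOS channels to classify")
  useBatch <- "batch" %in% names(object) && "batch" %in% names(controls)
  patBatches <- if (useBatch) unique(object$batch) else "all"
  .withSeed(seed, {
    res <- list()
    for (bt in patBatches) {
      pat <- if (useBatch) object[object$batch == bt, , drop = FALSE] else object
      ctl <- if (useBatch) controls[controls$batch == bt, , drop = FALSE] else controls
      if (!nrow(ctl)) stop(sprintf("no control fibres for batch '%s'", bt))
      for (p in proteins) {
        meanLab <- .bootstrapMeanLabels(
          pat$vdac1, pat[[p]], ctl$vdac1, ctl[[p]],
          nModels = nModels, level = level, resample = resample,
          retryCap = retryCap)
        res[[length(res) + 1L]] <- data.frame(
          fibre_id = pat$fibre_id, section = pat$section, protein = p,
          method = "frequentist", mean_label = meanLab,
          n_models = as.integer(nModels),
          final_call = .finalCall(meanLab, certaintyThreshold),
          check.names = FALSE)
      }
    }
    out <- do.call(rbind, res)
    .flagSmallSections(out, minSectionFibres)
  })
})

#' @rdname classifyFrequentist
#' @export
setMethod("classifyFrequentist", "FibreExperiment",
          function(object, controls, proteins = NULL, ...) {
  classifyFrequentist(fibreTable(object), controls, proteins = proteins, ...)
})

#' @rdname classifyFrequentist
#' @export
setMethod("classifyFrequentist", "MitoCohort",
          function(object, controls, proteins = NULL, ...) {
  classifyFrequentist(fibreTable(patientFibres(object)),
                      fibreTable(controlFibres(object)),
                      proteins = proteins, ...)
})

.bootstrapMeanLabels <- function(px, py, x, y, nModels, level, resample,
                                 retryCap = 100L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 control fibres")
  if (sd(x) == 0) stop("degenerate predictor: all control VDAC1 values are equal")
  sumLab <- numeric(length(px))
  for (m in seq_len(nModels)) {
    if (resample) {
      for (tr in seq_len(retryCap)) {
        i <- sample.int(n, n, replace = TRUE)
        if (var(x[i]) > 0) break
        if (tr == retryCap) stop("control bootstrap kept drawing degenerate resamples")
      }
      xx <- x[i]; yy <- y[i]
    } else {
      xx <- x; yy <- y
    }
    sumLab <- sumLab + .olsBandLabels(px, py, xx, yy, level)
  }
  sumLab / nModels
}

.flagSmallSections <- function(calls, minSectionFibres) {
  perSec <- table(calls$section[calls$protein == calls$protein[1L]])
  small <- names(perSec)[perSec < minSectionFibres]
  calls$section_below_min_fibres <- calls$section %in% small
  if (length(small)) {
    warning(sprintf(
      "%d section(s) have fewer than %d fibres; per-section deficiency proportions may be unstable",
      length(small), minSectionFibres), call. = FALSE)
  }
  calls
}
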