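#' Generate a synthetic muscle cohort with known ground truth
#'
#' Simulates per-fibre quantitative immunofluorescence intensity tables for a
#' cohort described by a [CohortDesign]: control fibres following the
#' OXPHOS~VDAC1 control line, patient fibres following the same line under a
#' systematic patient--control disparity and per-section staining batch
#' effects, mosaic OXPHOS deficiency whose proportion drifts with anatomical
#' distance along each muscle, rare overabundant fibres, and an
#' index-contiguous ground-truth-labelled block per section (emulating direct
#' visual inspection of a representative region). Every fibre carries a true
#' label per protein, so downstream classifiers can be benchmarked exactly.
#'
#' Deficient fibres are assigned deterministically (`round(p * n)` per
#' section, positions randomised) unless `bernoulliAssignment` is set in the
#' design, so each section's realized true proportion equals its target up to
#' rounding. Deficient fibres are displaced downward, and overabundant fibres
#' upward, by `deficientShift` control residual SDs before the disparity and
#' batch transforms are applied.
#'
#' @param design A [CohortDesign].
#' @param seed Integer seed; defaults to the design's own seed. The output is
#'   byte-identical across runs with the same design and seed.
#' @return A [MitoCohort].
#' @examples
#' cohort <- generateCohort(CohortDesign(nPatients = 1, biopsiesPerMuscle = 2,
#'                                       fibresPerSection = 50,
#'                                       nControlFibres = 100))
#' cohort
#' @export
generateCohort <- function(design, seed = NULL) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  seed <- seed %||% design@seed
  .withSeed(seed, {
    biopsies <- .layoutBiopsies(design)
    logits <- .deficiencyLogits(design, biopsies)
    patient <- .simulatePatientFibres(design, biopsies, logits)
    controls <- .simulateControlFibres(design)
    if (design@logScale) {
      cols <- c("vdac1", design@proteins)
      patient$table[cols] <- lapply(patient$table[cols], log10)
      controls[cols] <- lapply(controls[cols], log10)
    }
    new("MitoCohort",
        fibres = FibreExperiment(patient$table, proteins = design@proteins),
        controls = FibreExperiment(controls, proteins = design@proteins),
        sections = patient$sections,
        design = design)
  })
}

## Biopsy table with anatomical positions along each muscle. Biopsies are
## spaced biopsySpacingMm apart; members of an L-split pair sit at the
## recorded inter-face distance instead.
.layoutBiopsies <- function(design) {
  grid <- expand.grid(biopsyIdx = seq_len(design@biopsiesPerMuscle),
                      muscle = design@muscles,
                      patientIdx = seq_len(design@nPatients),
                      stringsAsFactors = FALSE)
  grid$patient <- sprintf("P%d", grid$patientIdx)
  grid$biopsy <- sprintf("%s_%s_B%d", grid$patient, grid$muscle, grid$biopsyIdx)
  grid$positionMm <- (grid$biopsyIdx - 1L) * design@biopsySpacingMm
  grid$lSplitGroup <- NA_character_
  ls <- design@lSplitPairs
  if (nrow(ls)) {
    for (i in seq_len(nrow(ls))) {
      sel <- grid$patientIdx == ls$patient[i] & grid$muscle == ls$muscle[i]
      a <- which(sel & grid$biopsyIdx == ls$biopsyA[i])
      b <- which(sel & grid$biopsyIdx == ls$biopsyB[i])
      grid$positionMm[b] <- grid$positionMm[a] + ls$distanceMm[i]
      grid$lSplitGroup[c(a, b)] <- sprintf("LS%d", i)
    }
  }
  grid
}

## Per-biopsy deficiency proportions: logistic(patient base + muscle offset +
## Gaussian random walk over biopsy positions, variance driftSdPerMm^2 per mm).
.deficiencyLogits <- function(design, biopsies) {
  dm <- design@deficiencyModel
  out <- list()
  for (p in design@proteins) {
    base <- qlogis(min(max(dm$meanProportion[[p]], 1e-6), 1 - 1e-6)) +
      rnorm(design@nPatients, 0, dm$patientSd %||% 0)
    col <- rep(NA_real_, nrow(biopsies))
    for (pi in seq_len(design@nPatients)) {
      for (m in design@muscles) {
        idx <- which(biopsies$patientIdx == pi & biopsies$muscle == m)
        idx <- idx[order(biopsies$positionMm[idx])]
        gaps <- diff(biopsies$positionMm[idx])
        steps <- rnorm(length(gaps), 0, (dm$driftSdPerMm %||% 0) * sqrt(pmax(gaps, 0)))
        off <- (dm$muscleOffset %||% setNames(0, m))[[m]] %||% 0
        col[idx] <- base[pi] + off + cumsum(c(0, steps))
      }
    }
    out[[p]] <- plogis(col)
  }
  out # list per protein, aligned with rows of `biopsies`
}

.simulatePatientFibres <- function(design, biopsies, deficiency) {
  n <- design@fibresPerSection
  tables <- vector("list", nrow(biopsies) * design@sectionsPerBiopsy)
  secRows <- tables
  k <- 0L
  for (bi in seq_len(nrow(biopsies))) {
    for (si in seq_len(design@sectionsPerBiopsy)) {
      k <- k + 1L
      section <- sprintf("%s_S%d", biopsies$biopsy[bi], si)
      vdac1 <- stats::rlnorm(n, log(1000), 0.25)
      tab <- data.frame(
        fibre_id = sprintf("%s_F%04d", section, seq_len(n)),
        patient = biopsies$patient[bi],
        muscle = biopsies$muscle[bi],
        biopsy = biopsies$biopsy[bi],
        section = section,
        batch = biopsies$patient[bi],
        vdac1 = vdac1,
        check.names = FALSE
      )
      trueProps <- numeric(length(design@proteins))
      names(trueProps) <- design@proteins
      for (p in design@proteins) {
        cp <- design@controlParams[[p]]
        dp <- design@patientDisparity[[p]]
        pTarget <- deficiency[[p]][bi]
        if (design@bernoulliAssignment) {
          flags <- runif(n) < pTarget
          kDef <- sum(flags)
        } else {
          kDef <- round(pTarget * n)
        }
        kOver <- min(round(design@overabundanceRate * n), n - kDef)
        perm <- sample.int(n)
        defIdx <- perm[seq_len(kDef)]
        overIdx <- perm[kDef + seq_len(kOver)]
        y <- cp$intercept + cp$slope * vdac1 + rnorm(n, 0, cp$residualSd)
        y[defIdx] <- y[defIdx] - design@deficientShift * cp$residualSd
        y[overIdx] <- y[overIdx] + design@deficientShift * cp$residualSd
        y <- (dp$gain %||% 1) * y + (dp$offset %||% 0)
        if (design@sectionBatchSd > 0) {
          gainS <- exp(rnorm(1, 0, design@sectionBatchSd))
          offS <- rnorm(1, 0, design@sectionBatchSd) * cp$residualSd
          y <- gainS * y + offS
        }
        tab[[p]] <- pmax(y, 1e-6)
        lab <- integer(n)
        lab[defIdx] <- -1L
        lab[overIdx] <- 1L
        tab[[.labelCol(p)]] <- lab
        trueProps[[p]] <- kDef / n
      }
      gtLen <- round(design@groundTruthFraction * n)
      if (design@groundTruthFraction > 0) gtLen <- max(1L, gtLen)
      flag <- rep(FALSE, n)
      if (gtLen > 0) {
        start <- sample.int(n - gtLen + 1L, 1L)
        flag[start:(start + gtLen - 1L)] <- TRUE
      }
      tab$in_ground_truth_region <- flag
      tables[[k]] <- tab
      row <- data.frame(patient = biopsies$patient[bi],
                        muscle = biopsies$muscle[bi],
                        biopsy = biopsies$biopsy[bi],
                        section = section,
                        positionMm = biopsies$positionMm[bi],
                        lSplitGroup = biopsies$lSplitGroup[bi],
                        nFibres = n,
                        check.names = FALSE)
      for (p in design@proteins) row[[paste0("true_prop_", p)]] <- trueProps[[p]]
      secRows[[k]] <- row
    }
  }
  list(table = do.call(rbind, tables), sections = do.call(rbind, secRows))
}

## One control staining batch per patient, drawn from the pure control line.
.simulateControlFibres <- function(design) {
  out <- vector("list", design@nPatients)
  for (pi in seq_len(design@nPatients)) {
    batch <- sprintf("P%d", pi)
    n <- design@nControlFibres
    vdac1 <- stats::rlnorm(n, log(1000), 0.25)
    tab <- data.frame(
      fibre_id = sprintf("CTRL_%s_F%05d", batch, seq_len(n)),
      patient = batch,
      muscle = "CTRL",
      biopsy = sprintf("CTRL_%s", batch),
      section = sprintf("CTRL_%s_S1", batch),
      batch = batch,
      vdac1 = vdac1,
      check.names = FALSE
    )
    for (p in design@proteins) {
      cp <- design@controlParams[[p]]
      tab[[p]] <- pmax(cp$intercept + cp$slope * vdac1 +
                         rnorm(n, 0, cp$residualSd), 1e-6)
    }
    out[[pi]] <- tab
  }
  do.call(rbind, out)
}
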