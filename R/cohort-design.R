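#' Describe a synthetic muscle cohort
#'
#' Builds a [CohortDesign] object: the full parameterisation of a synthetic
#' cohort of m.3243A>G myopathy muscle, mirroring the sampled anatomy of a
#' post-mortem study (two muscles, multiple biopsies per muscle, serial
#' section triplets, L-split biopsy pairs with known inter-face distance)
#' and the signal model the downstream classifiers assume.
#'
#' The signal model, per OXPHOS protein: control fibres follow a linear
#' OXPHOS~VDAC1 relationship with Gaussian residuals (`controlParams`);
#' patient fibres follow the same line transformed by a systematic
#' patient-control disparity (`patientDisparity`, multiplicative `gain` and
#' additive `offset`) and by per-section staining batch effects
#' (`sectionBatchSd`); OXPHOS-deficient fibres are displaced downward by
#' `deficientShift` residual SDs, overabundant fibres upward symmetrically.
#'
#' Mosaic deficiency follows a hierarchical logistic model: per patient and
#' protein a mean deficiency proportion (logit-normal around
#' `deficiencyModel$meanProportion` with SD `patientSd`), a per-muscle logit
#' offset (`muscleOffset`), and a Gaussian random walk over biopsy positions
#' along the muscle with per-mm SD `driftSdPerMm`, so deficiency drifts with
#' anatomical distance. L-split biopsy pairs are two positions on the same
#' walk separated by the recorded distance.
#'
#' @param nPatients Number of patients (default 4).
#' @param muscles Muscle labels (default `c("QD", "TA")`, quadriceps femoris
#'   and tibialis anterior).
#' @param biopsiesPerMuscle Biopsies per muscle per patient (default 4).
#' @param lSplitPairs `data.frame(patient, muscle, biopsyA, biopsyB,
#'   distanceMm)` flagging biopsy pairs that are two segments of one original
#'   biopsy with known inter-face distance. The default places four pairs
#'   (mean distance 14.4 mm) when the design is large enough; pass a
#'   zero-row data.frame for none.
#' @param sectionsPerBiopsy Serial sections per biopsy (default 3).
#' @param fibresPerSection Fibre cross-sections per section (default 300).
#' @param proteins OXPHOS channels (default `c("NDUFB8", "MT-CO1")`).
#' @param controlParams Per-protein list with `slope`, `intercept`,
#'   `residualSd` of the control OXPHOS~VDAC1 line (arbitrary fluorescence
#'   units).
#' @param nControlFibres Control fibres per staining batch (default 2000).
#' @param patientDisparity Per-protein `gain` and `offset` applied to all
#'   patient fibres relative to the control line. Both knobs are exposed
#'   because the direction of real-world disparity (additive vs
#'   multiplicative) is not identifiable from published data.
#' @param sectionBatchSd SD of per-section batch perturbations: gains are
#'   `exp(N(0, sd))`, offsets `N(0, sd) * residualSd`.
#' @param deficiencyModel List with `meanProportion` (named per protein),
#'   `patientSd` (logit SD across patients), `muscleOffset` (named logit
#'   offsets per muscle) and `driftSdPerMm` (random-walk SD per mm).
#' @param overabundanceRate Fraction of fibres with overabundant OXPHOS
#'   signal (default 3e-4, i.e. up to 0.03\% of fibre segments).
#' @param deficientShift Downward displacement of deficient fibres, in units
#'   of the control residual SD (default 8). Must be positive whenever any
#'   deficiency proportion is positive.
#' @param groundTruthFraction Fraction of fibres per section carrying
#'   ground-truth labels, as an index-contiguous block emulating visual
#'   inspection of a representative region (default 0.05).
#' @param biopsySpacingMm Default spacing between consecutive biopsies along
#'   a muscle when no L-split distance is recorded (default 25 mm).
#' @param logScale If `TRUE`, emitted intensity tables are log10-transformed
#'   (off by default; the analysis operates on the raw linear scale).
#' @param bernoulliAssignment If `TRUE`, deficiency is assigned per fibre by
#'   independent Bernoulli draws; the default is deterministic assignment of
#'   `round(p * n)` fibres so parameter-recovery tests have exact truth.
#' @param seed Integer seed stored with the design; [generateCohort()] uses
#'   it unless overridden.
#' @return A validated [CohortDesign] object.
#' @examples
#' d <- CohortDesign(nPatients = 2, biopsiesPerMuscle = 2, fibresPerSection = 100)
#' d
#' @export
CohortDesign <- function(nPatients = 4L,
                         muscles = c("QD", "TA"),
                         biopsiesPerMuscle = 4L,
                         lSplitPairs = NULL,
                         sectionsPerBiopsy = 3L,
                         fibresPerSection = 300L,
                         proteins = c("NDUFB8", "MT-CO1"),
                         controlParams = NULL,
                         nControlFibres = 2000L,
                         patientDisparity = NULL,
                         sectionBatchSd = 0.1,
                         deficiencyModel = NULL,
                         overabundanceRate = 3e-4,
                         deficientShift = 8,
                         groundTruthFraction = 0.05,
                         biopsySpacingMm = 25,
                         logScale = FALSE,
                         bernoulliAssignment = FALSE,
                         seed = 1L) {
  if (is.null(controlParams)) {
    controlParams <- list(
      "NDUFB8" = list(slope = 1.1, intercept = 50, residualSd = 60),
      "MT-CO1" = list(slope = 0.9, intercept = 80, residualSd = 55)
    )[proteins]
    names(controlParams) <- proteins
    controlParams <- lapply(controlParams, function(cp) {
      cp %||% list(slope = 1, intercept = 50, residualSd = 50)
    })
  }
  if (is.null(patientDisparity)) {
    gains <- c("NDUFB8" = 0.92, "MT-CO1" = 0.96)[proteins]
    gains[is.na(gains)] <- 0.95
    patientDisparity <- lapply(setNames(proteins, proteins), function(p) {
      list(gain = unname(gains[[p]]), offset = 0)
    })
  }
  if (is.null(deficiencyModel)) {
    mp <- c("NDUFB8" = 0.297, "MT-CO1" = 0.094)[proteins]
    mp[is.na(mp)] <- 0.15
    names(mp) <- proteins
    mo <- setNames(rep(0, length(muscles)), muscles)
    if ("TA" %in% muscles) mo[["TA"]] <- 0.3
    deficiencyModel <- list(meanProportion = mp, patientSd = 0.35,
                            muscleOffset = mo, driftSdPerMm = 0.05)
  }
  if (is.null(lSplitPairs)) {
    lSplitPairs <- .defaultLSplitPairs(nPatients, muscles, biopsiesPerMuscle)
  }
  new("CohortDesign",
      nPatients = as.integer(nPatients),
      muscles = muscles,
      biopsiesPerMuscle = as.integer(biopsiesPerMuscle),
      lSplitPairs = lSplitPairs,
      sectionsPerBiopsy = as.integer(sectionsPerBiopsy),
      fibresPerSection = as.integer(fibresPerSection),
      proteins = proteins,
      controlParams = controlParams,
      nControlFibres = as.integer(nControlFibres),
      patientDisparity = patientDisparity,
      sectionBatchSd = sectionBatchSd,
      deficiencyModel = deficiencyModel,
      overabundanceRate = overabundanceRate,
      deficientShift = deficientShift,
      groundTruthFraction = groundTruthFraction,
      biopsySpacingMm = biopsySpacingMm,
      logScale = logScale,
      bernoulliAssignment = bernoulliAssignment,
      seed = as.integer(seed))
}

## Four L-split pairs with distances averaging 14.4 mm (SD ~3.7), assigned to
## the first two biopsies of alternating muscles, as far as the design allows.
.defaultLSplitPairs <- function(nPatients, muscles, biopsiesPerMuscle) {
  empty <- data.frame(patient = integer(), muscle = character(),
                      biopsyA = integer(), biopsyB = integer(),
                      distanceMm = numeric())
  if (biopsiesPerMuscle < 2L) return(empty)
  distances <- c(10.4, 13.1, 15.0, 19.1)
  pat <- c(1L, 2L, 3L, 4L)
  mus <- rep(muscles, length.out = 4L)
  keep <- pat <= nPatients
  if (!any(keep)) return(empty)
  data.frame(patient = pat[keep], muscle = mus[keep],
             biopsyA = 1L, biopsyB = 2L,
             distanceMm = distances[keep])
}

#' @describeIn MitoCohort-accessors The design stored in a cohort, or the
#'   design itself when called on a `CohortDesign`.
#' @export
setMethod("cohortDesign", "CohortDesign", function(object) object)

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:",
      object@nPatients, "patient(s) x",
      length(object@muscles), "muscle(s) x",
      object@biopsiesPerMuscle, "biopsies x",
      object@sectionsPerBiopsy, "sections x",
      object@fibresPerSection, "fibres/section\n")
  cat("  proteins:", paste(object@proteins, collapse = ", "), "\n")
  cat("  deficiency means:",
      paste(sprintf("%s=%.3f", names(object@deficiencyModel$meanProportion),
                    object@deficiencyModel$meanProportion), collapse = ", "), "\n")
  cat("  L-split pairs:", nrow(object@lSplitPairs),
      "| seed:", object@seed, "\n")
})
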