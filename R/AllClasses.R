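## S4 class definitions. Constructors live next to their module code.

#' CohortDesign: parameters of a synthetic muscle cohort
#'
#' Describes the hierarchical structure (patients, muscles, biopsies, serial
#' sections, fibres) and the signal/deficiency model of a synthetic cohort.
#' Create instances with [CohortDesign()]; see that page for the meaning and
#' defaults of every slot.
#'
#' @aliases CohortDesign-class
#' @exportClass CohortDesign
setClass("CohortDesign", slots = c(
  nPatients = "integer",
  muscles = "character",
  biopsiesPerMuscle = "integer",
  lSplitPairs = "data.frame",
  sectionsPerBiopsy = "integer",
  fibresPerSection = "integer",
  proteins = "character",
  controlParams = "list",
  nControlFibres = "integer",
  patientDisparity = "list",
  sectionBatchSd = "numeric",
  deficiencyModel = "list",
  overabundanceRate = "numeric",
  deficientShift = "numeric",
  groundTruthFraction = "numeric",
  biopsySpacingMm = "numeric",
  logScale = "logical",
  bernoulliAssignment = "logical",
  seed = "integer"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  counts <- c(nPatients = object@nPatients,
              biopsiesPerMuscle = object@biopsiesPerMuscle,
              sectionsPerBiopsy = object@sectionsPerBiopsy,
              fibresPerSection = object@fibresPerSection,
              nControlFibres = object@nControlFibres)
  if (any(counts < 1L)) {
    msg <- c(msg, sprintf("count(s) below 1: %s",
                          paste(names(counts)[counts < 1L], collapse = ", ")))
  }
  if (!length(object@muscles) || anyDuplicated(object@muscles)) {
    msg <- c(msg, "muscles must be a non-empty set of distinct labels")
  }
  if (!length(object@proteins) || anyDuplicated(object@proteins)) {
    msg <- c(msg, "proteins must be a non-empty set of distinct labels")
  }
  for (p in object@proteins) {
    cp <- object@controlParams[[p]]
    if (is.null(cp) || !all(c("slope", "intercept", "residualSd") %in% names(cp))) {
      msg <- c(msg, sprintf("controlParams for '%s' need slope/intercept/residualSd", p))
    } else if (cp[["residualSd"]] < 0) {
      msg <- c(msg, sprintf("controlParams residualSd for '%s' must be >= 0", p))
    }
  }
  dm <- object@deficiencyModel
  props <- dm$meanProportion
  if (is.null(props) || !all(object@proteins %in% names(props))) {
    msg <- c(msg, "deficiencyModel$meanProportion must name every protein")
  } else {
    if (any(props < 0 | props > 1)) {
      msg <- c(msg, "deficiency proportions must lie in [0, 1]")
    }
    if (any(props + object@overabundanceRate > 1)) {
      msg <- c(msg, "deficiency proportion + overabundance rate exceeds 1")
    }
    if (object@deficientShift == 0 && any(props > 0)) {
      msg <- c(msg, paste("deficientShift must be > 0 when any deficiency",
                          "proportion is positive (truth would be unidentifiable)"))
    }
  }
  if (object@overabundanceRate < 0 || object@overabundanceRate > 1) {
    msg <- c(msg, "overabundanceRate must lie in [0, 1]")
  }
  if (object@groundTruthFraction < 0 || object@groundTruthFraction > 1) {
    msg <- c(msg, "groundTruthFraction must lie in [0, 1]")
  }
  ls <- object@lSplitPairs
  if (nrow(ls)) {
    need <- c("patient", "muscle", "biopsyA", "biopsyB", "distanceMm")
    if (!all(need %in% names(ls))) {
      msg <- c(msg, sprintf("lSplitPairs needs columns: %s", paste(need, collapse = ", ")))
    } else {
      if (any(ls$distanceMm <= 0)) msg <- c(msg, "L-split distances must be > 0")
      if (any(ls$patient < 1 | ls$patient > object@nPatients) ||
          any(!ls$muscle %in% object@muscles) ||
          any(ls$biopsyA < 1 | ls$biopsyA > object@biopsiesPerMuscle) ||
          any(ls$biopsyB < 1 | ls$biopsyB > object@biopsiesPerMuscle) ||
          any(ls$biopsyA == ls$biopsyB)) {
        msg <- c(msg, "lSplitPairs references biopsies that do not exist or are not distinct")
      }
    }
  }
  if (object@sectionBatchSd < 0) msg <- c(msg, "sectionBatchSd must be >= 0")
  if (object@biopsySpacingMm <= 0) msg <- c(msg, "biopsySpacingMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' FibreExperiment: per-fibre intensity data with tissue hierarchy
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `"intensity"` assay
#' holds one column per fibre cross-section and one row per measured channel
#' (`VDAC1` plus one or more OXPHOS proteins). `colData` carries the tissue
#' hierarchy (`patient`, `muscle`, `biopsy`, `section`, `batch`), optional
#' per-protein true labels (`label_<protein>`, values -1/0/+1) and the
#' `in_ground_truth_region` flag. Build from a flat table with
#' [FibreExperiment()]; flatten with [fibreTable()].
#'
#' @aliases FibreExperiment-class
#' @exportClass FibreExperiment
setClass("FibreExperiment", contains = "SummarizedExperiment")

setValidity("FibreExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'intensity' is required")
  }
  m <- SummarizedExperiment::assay(object, "intensity")
  if (!"VDAC1" %in% rownames(m)) msg <- c(msg, "channel 'VDAC1' is required")
  if (nrow(m) < 2) msg <- c(msg, "need VDAC1 plus at least one OXPHOS channel")
  if (ncol(m) && (!all(is.finite(m)) || any(m <= 0))) {
    msg <- c(msg, "intensities must be finite and > 0")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient", "muscle", "biopsy", "section")
  if (!all(need %in% names(cd))) {
    msg <- c(msg, sprintf("colData needs columns: %s", paste(need, collapse = ", ")))
  }
  for (nm in grep("^label_", names(cd), value = TRUE)) {
    v <- cd[[nm]]
    if (!all(v[!is.na(v)] %in% c(-1L, 0L, 1L))) {
      msg <- c(msg, sprintf("%s must take values -1, 0, +1 (or NA)", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' MitoCohort: a generated synthetic cohort
#'
#' Bundle of patient fibres, control fibres, per-section metadata (anatomical
#' positions, L-split links, realized true deficiency proportions) and the
#' [CohortDesign] that produced them. Returned by [generateCohort()].
#'
#' @aliases MitoCohort-class
#' @exportClass MitoCohort
setClass("MitoCohort", slots = c(
  fibres = "FibreExperiment",
  controls = "FibreExperiment",
  sections = "data.frame",
  design = "CohortDesign"
))

setValidity("MitoCohort", function(object) {
  msg <- character()
  need <- c("patient", "muscle", "biopsy", "section", "positionMm", "nFibres")
  if (!all(need %in% names(object@sections))) {
    msg <- c(msg, sprintf("sections table needs columns: %s", paste(need, collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object@fibres)
  if (nrow(object@sections) &&
      !all(unique(cd$section) %in% object@sections$section)) {
    msg <- c(msg, "every fibre section must appear in the sections table")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionBand: a control OXPHOS~VDAC1 prediction interval
#'
#' Ordinary least-squares fit of an OXPHOS channel on VDAC1 over control
#' fibres, with the sufficient statistics needed to evaluate a t-based
#' prediction interval at any VDAC1 value: at `x` the band is
#' `fit(x) +/- t(1-(1-level)/2, n-2) * residualSd *
#' sqrt(1 + 1/n + (x - xMean)^2 / xSS)`.
#' Created by [fitControlRegression()]; evaluate with [predictionInterval()]
#' and classify points with [classifyWithBand()].
#'
#' @aliases PredictionBand-class
#' @exportClass PredictionBand
setClass("PredictionBand", slots = c(
  protein = "character",
  slope = "numeric",
  intercept = "numeric",
  residualSd = "numeric",
  nControl = "integer",
  xMean = "numeric",
  xSS = "numeric",
  level = "numeric"
))

setValidity("PredictionBand", function(object) {
  msg <- character()
  if (object@residualSd < 0) msg <- c(msg, "residualSd must be >= 0")
  if (object@nControl < 3L) msg <- c(msg, "nControl must be >= 3")
  if (object@level <= 0 || object@level >= 1) msg <- c(msg, "level must be in (0, 1)")
  if (object@xSS <= 0) msg <- c(msg, "xSS must be > 0 (degenerate predictor)")
  if (!all(is.finite(c(object@slope, object@intercept)))) {
    msg <- c(msg, "coefficients must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' QPCRPlate: qPCR dilution series and per-biopsy Cq replicates
#'
#' Holds, per target (`MT-ND1`, `B2M`): the standard-curve dilution series
#' (known copies per reaction with replicate Cq values) and per-biopsy
#' replicate Cq measurements, plus (for synthetic plates) the generating
#' curve and true per-biopsy mtDNA copy numbers. Created by [generateQpcr()]
#' or read from CSV with [readQpcrPlate()].
#'
#' @aliases QPCRPlate-class
#' @exportClass QPCRPlate
setClass("QPCRPlate", slots = c(
  dilutions = "data.frame",   # target, copies, replicate, cq
  samples = "data.frame",     # biopsy, target, replicate, cq
  trueCurve = "data.frame",   # target, slope, intercept (may be empty)
  trueMcn = "numeric",        # named per biopsy (may be empty)
  cqNoiseSd = "numeric"
))

setValidity("QPCRPlate", function(object) {
  msg <- character()
  d <- object@dilutions
  if (!all(c("target", "copies", "replicate", "cq") %in% names(d))) {
    return("dilutions needs columns target, copies, replicate, cq")
  }
  if (!all(c("biopsy", "target", "replicate", "cq") %in% names(object@samples))) {
    return("samples needs columns biopsy, target, replicate, cq")
  }
  if (nrow(d)) {
    if (any(d$copies <= 0)) msg <- c(msg, "dilution copies must be > 0")
    if (!all(is.finite(d$cq)) || any(d$cq <= 0)) {
      msg <- c(msg, "dilution Cq values must be finite and > 0")
    }
    for (tg in unique(d$target)) {
      cp <- sort(unique(d$copies[d$target == tg]), decreasing = TRUE)
      if (length(cp) < 2) msg <- c(msg, sprintf("target '%s' needs >= 2 dilutions", tg))
    }
  }
  s <- object@samples
  if (nrow(s) && (!all(is.finite(s$cq)) || any(s$cq <= 0))) {
    msg <- c(msg, "sample Cq values must be finite and > 0")
  }
  if (length(msg)) msg else TRUE
})
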