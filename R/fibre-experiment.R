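#' Build a FibreExperiment from a flat fibre table
#'
#' A fibre table has one row per fibre cross-section with identifier columns
#' (`fibre_id`, `patient`, `muscle`, `biopsy`, `section`, optionally `batch`),
#' a `vdac1` intensity column, one intensity column per OXPHOS protein, and
#' optionally per-protein true labels (`label_<protein>` in -1/0/+1) plus an
#' `in_ground_truth_region` flag. [FibreExperiment()] packs it into a
#' [SummarizedExperiment::SummarizedExperiment]-derived container with the
#' intensity matrix as the `"intensity"` assay (channels x fibres) and all
#' identifiers/labels in `colData`; [fibreTable()] flattens it back.
#'
#' @param table A data.frame as described above.
#' @param proteins OXPHOS channel names; by default every column that is
#'   neither an identifier, `vdac1`, a label column nor a flag.
#' @return `FibreExperiment()` returns a [FibreExperiment] object.
#' @examples
#' tab <- data.frame(fibre_id = c("f1", "f2"), patient = "P1", muscle = "QD",
#'                   biopsy = "B1", section = "S1", vdac1 = c(900, 1100),
#'                   NDUFB8 = c(1000, 1200))
#' fe <- FibreExperiment(tab)
#' oxphosProteins(fe)
#' head(fibreTable(fe))
#' @export
FibreExperiment <- function(table, proteins = NULL) {
  .assertColumns(table, c("fibre_id", "patient", "muscle", "biopsy",
                          "section", "vdac1"), "fibre table")
  idCols <- c("fibre_id", "patient", "muscle", "biopsy", "section", "batch",
              "in_ground_truth_region")
  if (is.null(proteins)) {
    proteins <- setdiff(names(table),
                        c(idCols, "vdac1", grep("^label_", names(table), value = TRUE)))
  }
  if (!length(proteins)) stop("no OXPHOS intensity columns found")
  m <- t(as.matrix(table[, c("vdac1", proteins), drop = FALSE]))
  rownames(m) <- c("VDAC1", proteins)
  colnames(m) <- table$fibre_id
  keep <- intersect(c(idCols, grep("^label_", names(table), value = TRUE)),
                    names(table))
  cd <- S4Vectors::DataFrame(table[, keep, drop = FALSE], check.names = FALSE)
  names(cd) <- keep  # guard non-syntactic protein names, e.g. label_MT-CO1
  rownames(cd) <- table$fibre_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m), colData = cd)
  new("FibreExperiment", se)
}

#' @rdname FibreExperiment
#' @param object A [FibreExperiment].
#' @param ... Unused.
#' @return `fibreTable()` returns the flat data.frame representation.
#' @export
setMethod("fibreTable", "FibreExperiment", function(object, ...) {
  m <- SummarizedExperiment::assay(object, "intensity")
  cdS4 <- SummarizedExperiment::colData(object)
  cd <- as.data.frame(cdS4)
  names(cd) <- names(cdS4)  # keep non-syntactic label columns intact
  out <- cbind(cd, vdac1 = m["VDAC1", ])
  for (p in setdiff(rownames(m), "VDAC1")) out[[p]] <- m[p, ]
  rownames(out) <- NULL
  out
})

#' @describeIn FibreExperiment The OXPHOS channels measured (all assay rows
#'   except `VDAC1`).
#' @export
setMethod("oxphosProteins", "FibreExperiment", function(object) {
  setdiff(rownames(SummarizedExperiment::assay(object, "intensity")), "VDAC1")
})

setMethod("show", "FibreExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("FibreExperiment:", ncol(object), "fibre cross-sections,",
      "channels:", paste(rownames(object), collapse = ", "), "\n")
  if (ncol(object)) {
    cat("  patients:", length(unique(cd$patient)),
        "| sections:", length(unique(cd$section)),
        "| with ground truth:",
        if ("in_ground_truth_region" %in% names(cd))
          sum(cd$in_ground_truth_region) else 0L, "\n")
  }
})

#' Accessors for MitoCohort components
#'
#' @param object A [MitoCohort] (or, for `cohortDesign`, a [CohortDesign]).
#' @return `patientFibres()` and `controlFibres()` return
#'   [FibreExperiment]s; `sectionInfo()` the per-section metadata table
#'   (anatomical position, L-split group, realized true deficiency
#'   proportions); `cohortDesign()` the [CohortDesign].
#' @name MitoCohort-accessors
NULL

#' @describeIn MitoCohort-accessors Patient fibres.
#' @export
setMethod("patientFibres", "MitoCohort", function(object) object@fibres)

#' @describeIn MitoCohort-accessors Control fibres (one staining batch per
#'   patient).
#' @export
setMethod("controlFibres", "MitoCohort", function(object) object@controls)

#' @describeIn MitoCohort-accessors Per-section metadata.
#' @export
setMethod("sectionInfo", "MitoCohort", function(object) object@sections)

#' @describeIn MitoCohort-accessors Generating design.
#' @export
setMethod("cohortDesign", "MitoCohort", function(object) object@design)

setMethod("show", "MitoCohort", function(object) {
  cat("MitoCohort\n")
  cat("  patient fibres: ", ncol(object@fibres),
      " in ", nrow(object@sections), " sections\n", sep = "")
  cat("  control fibres: ", ncol(object@controls), "\n", sep = "")
  nls <- if ("lSplitGroup" %in% names(object@sections)) {
    length(unique(stats::na.omit(object@sections$lSplitGroup)))
  } else 0L
  cat("  L-split groups: ", nls, "\n", sep = "")
})
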