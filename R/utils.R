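## Internal helpers shared across modules.

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. seed = NULL leaves the RNG alone.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.labelCol <- function(protein) paste0("label_", protein)

## Trichotomous call from a mean classification in [-1, +1].
.finalCall <- function(meanLabel, threshold = 0.95) {
  out <- rep("normal", length(meanLabel))
  out[meanLabel <= -threshold] <- "deficient"
  out[meanLabel >= threshold] <- "overabundant"
  out
}

.assertColumns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Unique fibres represented by serial cross-sections
#'
#' Serial sectioning images the same muscle fibre once per section, so a
#' triplet of serial sections yields three cross-sections per fibre. This
#' helper converts a total cross-section count into the number of unique
#' fibres it represents.
#'
#' @param nCrossSections Total number of analysable fibre cross-sections.
#' @param sectionsPerTriplet Number of serial sections per biopsy (default 3).
#' @return Integer count of unique fibres.
#' @examples
#' uniqueFibreCount(120306, 3)
#' @export
uniqueFibreCount <- function(nCrossSections, sectionsPerTriplet = 3L) {
  stopifnot(length(nCrossSections) == 1L, nCrossSections >= 1,
            length(sectionsPerTriplet) == 1L, sectionsPerTriplet >= 1)
  if (nCrossSections %% sectionsPerTriplet != 0) {
    stop("nCrossSections is not a multiple of sectionsPerTriplet")
  }
  as.integer(nCrossSections %/% sectionsPerTriplet)
}
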