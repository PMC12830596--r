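#' Bootstrap the per-section proportion of a fibre phenotype
#'
#' Captures the uncertainty in a section's proportion of OXPHOS-deficient
#' (or overabundant) fibres: each draw resamples the section's fibres with
#' replacement and records the phenotype proportion. For a binary phenotype
#' this resampling distribution is exactly Binomial(n, p-hat)/n, which is how
#' the draws are generated.
#'
#' @param calls The section's fibre calls: a character vector of final calls,
#'   a logical vector (TRUE = phenotype) or -1/0/+1 labels.
#' @param phenotype `"deficient"` or `"overabundant"` (for character calls;
#'   -1 resp. +1 for numeric labels).
#' @param nDraws Number of bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @return List with `draws` (proportions in \[0, 1\]), `proportion` (the
#'   observed proportion), `nFibres`, `nDraws`, `phenotype`.
#' @export
bootstrapSectionProportions <- function(calls, phenotype = c("deficient", "overabundant"),
                                        nDraws = 10000L, seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (!length(calls)) stop("section has no classified fibres")
  flag <- if (is.logical(calls)) calls
          else if (is.numeric(calls)) calls == (if (phenotype == "deficient") -1 else 1)
          else calls == phenotype
  n <- length(flag)
  p <- mean(flag)
  draws <- .withSeed(seed, rbinom(nDraws, n, p) / n)
  list(draws = draws, proportion = p, nFibres = n,
       nDraws = as.integer(nDraws), phenotype = phenotype)
}

#' Per-section proportion distributions for a whole call table
#'
#' Convenience wrapper applying [bootstrapSectionProportions()] to every
#' section and protein of a classification output.
#'
#' @param calls Output of [classifyFrequentist()] or [consensusCertainty()].
#' @param phenotype,nDraws,seed See [bootstrapSectionProportions()].
#' @return Nested list: `result[[protein]][[section]]` is the numeric vector
#'   of bootstrap proportion draws.
#' @export
sectionProportionDistributions <- function(calls, phenotype = "deficient",
                                           nDraws = 10000L, seed = NULL) {
  .assertColumns(calls, c("section", "protein", "final_call"), "call table")
  .withSeed(seed, {
    out <- list()
    for (p in sort(unique(calls$protein))) {
      sub <- calls[calls$protein == p, ]
      secs <- sort(unique(sub$section))
      out[[p]] <- lapply(setNames(secs, secs), function(s) {
        bootstrapSectionProportions(sub$final_call[sub$section == s],
                                    phenotype, nDraws = nDraws)$draws
      })
    }
    out
  })
}

#' Enumerate anatomical unit pairs for a pairing strategy
#'
#' The six within-patient pairing strategies, ordered by increasing
#' anatomical distance: `intra_biopsy` (sections of one serial triplet),
#' `intra_l_split` (sections across the two segments of an L-split biopsy),
#' `intra_muscle` (sections or biopsies across different biopsies of the same
#' muscle, pooled over muscles), `intra_QD` / `intra_TA` (same, restricted to
#' one muscle), and `inter_muscle` (across the two muscles). All pairs are
#' within-patient, unordered, between distinct units, pooled over patients.
#'
#' @param sections Section metadata ([sectionInfo()] output or any data.frame
#'   with `patient`, `muscle`, `biopsy`, `section` and optionally
#'   `lSplitGroup`), or a [MitoCohort].
#' @param strategy One of `"intra_biopsy"`, `"intra_l_split"`,
#'   `"intra_muscle"`, `"intra_<muscle label>"`, `"inter_muscle"`.
#' @param unit `"section"` (OXPHOS proportions) or `"biopsy"` (homogenate
#'   metrics: mtDNA copy number, heteroplasmy).
#' @return data.frame with columns `unitA`, `unitB`.
#' @examples
#' cohort <- generateCohort(CohortDesign(nPatients = 1, fibresPerSection = 20,
#'                                       nControlFibres = 50))
#' nrow(enumeratePairs(sectionInfo(cohort), "intra_biopsy"))
#' @export
enumeratePairs <- function(sections, strategy, unit = c("section", "biopsy")) {
  if (is(sections, "MitoCohort")) sections <- sectionInfo(sections)
  unit <- match.arg(unit)
  .assertColumns(sections, c("patient", "muscle", "biopsy", "section"),
                 "section metadata")
  muscles <- unique(sections$muscle)
  restrictedMuscle <- NULL
  if (grepl("^intra_", strategy) &&
      sub("^intra_", "", strategy) %in% muscles) {
    restrictedMuscle <- sub("^intra_", "", strategy)
    strategy <- "intra_muscle"
  }
  strategy <- match.arg(strategy, c("intra_biopsy", "intra_l_split",
                                    "intra_muscle", "inter_muscle"))
  if (unit == "biopsy" && strategy == "intra_biopsy") {
    stop("intra_biopsy pairing is undefined at biopsy level")
  }
  df <- unique(sections[, intersect(c("patient", "muscle", "biopsy", "section",
                                      "lSplitGroup"), names(sections))])
  if (!is.null(restrictedMuscle)) df <- df[df$muscle == restrictedMuscle, ]
  id <- if (unit == "section") df$section else df$biopsy
  pairs <- list()
  add <- function(a, b) {
    if (length(a) && length(b)) {
      pairs[[length(pairs) + 1L]] <<- expand.grid(unitA = a, unitB = b,
                                                  stringsAsFactors = FALSE)
    }
  }
  addWithin <- function(ids) {
    ids <- unique(ids)
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      pairs[[length(pairs) + 1L]] <<- data.frame(unitA = cmb[1L, ],
                                                 unitB = cmb[2L, ],
                                                 stringsAsFactors = FALSE)
    }
  }
  for (pat in unique(df$patient)) {
    dp <- df[df$patient == pat, ]
    if (strategy == "intra_biopsy") {
      for (b in unique(dp$biopsy)) addWithin(id[df$patient == pat & df$biopsy == b])
    } else if (strategy == "intra_l_split") {
      if (!"lSplitGroup" %in% names(dp)) next
      for (g in unique(stats::na.omit(dp$lSplitGroup))) {
        bs <- unique(dp$biopsy[!is.na(dp$lSplitGroup) & dp$lSplitGroup == g])
        if (length(bs) != 2L) next
        sel <- df$patient == pat
        add(unique(id[sel & df$biopsy == bs[1L]]),
            unique(id[sel & df$biopsy == bs[2L]]))
      }
    } else if (strategy == "intra_muscle") {
      for (m in unique(dp$muscle)) {
        bs <- unique(dp$biopsy[dp$muscle == m])
        if (length(bs) < 2L) next
        cmb <- utils::combn(bs, 2L)
        for (i in seq_len(ncol(cmb))) {
          sel <- df$patient == pat
          add(unique(id[sel & df$biopsy == cmb[1L, i]]),
              unique(id[sel & df$biopsy == cmb[2L, i]]))
        }
      }
    } else { # inter_muscle
      ms <- unique(dp$muscle)
      if (length(ms) < 2L) next
      cmb <- utils::combn(ms, 2L)
      for (i in seq_len(ncol(cmb))) {
        sel <- df$patient == pat
        add(unique(id[sel & df$muscle == cmb[1L, i]]),
            unique(id[sel & df$muscle == cmb[2L, i]]))
      }
    }
  }
  if (!length(pairs)) {
    if (strategy == "intra_l_split") stop("no L-split biopsy pairs are recorded")
    return(data.frame(unitA = character(), unitB = character()))
  }
  out <- unique(do.call(rbind, pairs))
  rownames(out) <- NULL
  out
}

#' Sample a distribution of absolute paired differences
#'
#' Each iteration picks one eligible unit pair uniformly at random, draws one
#' value from each unit's distribution (uniformly, with replacement), and
#' records the absolute difference. This turns per-unit uncertainty
#' distributions (bootstrapped section proportions, mtDNA copy-number
#' distributions, heteroplasmy replicates) into a probabilistic distribution
#' of between-unit differences for a pairing strategy.
#'
#' @param distributions Named list mapping unit id to its numeric value
#'   vector (each with >= 1 value).
#' @param pairs Pair table from [enumeratePairs()].
#' @param nIterations Number of sampled differences (the analysis default is
#'   1e6 for OXPHOS proportions and 1e5 for homogenate metrics).
#' @param seed Integer seed.
#' @return Numeric vector of `nIterations` absolute differences.
#' @export
sampleAbsDifferences <- function(distributions, pairs, nIterations = 1e6,
                                 seed = NULL) {
  if (!nrow(pairs)) stop("empty pair list")
  units <- names(distributions)
  miss <- setdiff(unique(c(pairs$unitA, pairs$unitB)), units)
  if (length(miss)) {
    stop(sprintf("no distribution for unit(s): %s", paste(miss, collapse = ", ")))
  }
  lens <- lengths(distributions)
  if (any(lens < 1L)) stop("every unit needs a distribution with >= 1 value")
  flat <- unlist(distributions, use.names = FALSE)
  offset <- cumsum(c(0L, lens[-length(lens)]))
  ia <- match(pairs$unitA, units)
  ib <- match(pairs$unitB, units)
  .withSeed(seed, {
    pi <- sample.int(nrow(pairs), nIterations, replace = TRUE)
    ua <- ia[pi]; ub <- ib[pi]
    va <- flat[offset[ua] + ceiling(runif(nIterations) * lens[ua])]
    vb <- flat[offset[ub] + ceiling(runif(nIterations) * lens[ub])]
    abs(va - vb)
  })
}

#' Summarise a difference distribution
#'
#' Median, interquartile range, 2.5th-97.5th percentiles and full range, the
#' interpretable summaries of expected within-individual variability.
#' Quantiles use linear interpolation between order statistics
#' (`type = 7`), so summaries are reproducible bit-for-bit given a seed.
#'
#' @param values Numeric vector (>= 1 value), e.g. from
#'   [sampleAbsDifferences()].
#' @return One-row data.frame: `median`, `iqr_low`, `iqr_high`, `p2_5`,
#'   `p97_5`, `min`, `max`, `n`.
#' @export
summarizeDistribution <- function(values) {
  if (!length(values)) stop("empty distribution")
  q <- quantile(values, c(0.25, 0.5, 0.75, 0.025, 0.975), names = FALSE, type = 7)
  data.frame(median = q[2L], iqr_low = q[1L], iqr_high = q[3L],
             p2_5 = q[4L], p97_5 = q[5L],
             min = min(values), max = max(values), n = length(values))
}

#' Variability thresholds for longitudinal interpretation
#'
#' For each metric and pairing strategy, the 97.5th percentile of the
#' absolute-difference distribution is the expected-variability threshold:
#' only longitudinal differences strictly exceeding it should be interpreted
#' as time-dependent change rather than anatomical variability or assay
#' noise.
#'
#' @param summaries data.frame of [summarizeDistribution()] rows with at
#'   least a `p97_5` column plus identifying columns (e.g. `metric`,
#'   `strategy`, `method`).
#' @param strategies If given, require and keep only these strategies
#'   (errors when one is missing).
#' @return The identifying columns plus `threshold` (the 97.5th percentile).
#' @seealso [exceedsExpectedVariability()]
#' @export
thresholdReport <- function(summaries, strategies = NULL) {
  .assertColumns(summaries, "p97_5", "summary table")
  if (!is.null(strategies)) {
    .assertColumns(summaries, "strategy", "summary table")
    miss <- setdiff(strategies, summaries$strategy)
    if (length(miss)) {
      stop(sprintf("no summary for strategy(ies): %s", paste(miss, collapse = ", ")))
    }
    summaries <- summaries[summaries$strategy %in% strategies, , drop = FALSE]
  }
  keep <- setdiff(names(summaries),
                  c("median", "iqr_low", "iqr_high", "p2_5", "p97_5",
                    "min", "max", "n"))
  out <- summaries[, keep, drop = FALSE]
  out$threshold <- summaries$p97_5
  rownames(out) <- NULL
  out
}

#' Flag a longitudinal difference against a variability threshold
#'
#' @param difference Observed absolute difference(s) between timepoints.
#' @param threshold Expected-variability threshold(s) from
#'   [thresholdReport()].
#' @return Logical: `TRUE` when the difference strictly exceeds the
#'   threshold (a difference exactly at the threshold is not flagged).
#' @examples
#' exceedsExpectedVariability(15, 13.8)   # TRUE
#' exceedsExpectedVariability(13.8, 13.8) # FALSE
#' @export
exceedsExpectedVariability <- function(difference, threshold) {
  difference > threshold
}
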