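#' Classify fibres by investigator-drawn 2D-mitoplot polygons
#'
#' The visual 2D-mitoplot method: an investigator lassoes clusters of fibres
#' with relatively low (or high) OXPHOS signal in OXPHOS--VDAC1 space. A
#' fibre inside any `"low"` polygon for its section and protein is labelled
#' -1, inside any `"high"` polygon +1, otherwise 0. Membership uses the
#' even-odd rule and is boundary-inclusive; a fibre falling inside both a low
#' and a high polygon is a contradictory annotation and raises an error.
#'
#' @param object Fibres to classify ([FibreExperiment] or fibre table with
#'   `fibre_id`, `section`, `vdac1` and per-protein intensity columns).
#' @param annotations Annotation records as produced by
#'   [generateAnnotations()] or [readAnnotations()]: each a list with
#'   `investigator`, `protein`, `scope` (section), `category` and a
#'   `vertices` matrix in (VDAC1, OXPHOS) coordinates.
#' @param investigator Which investigator's annotations to apply. Required
#'   when `annotations` contains several investigators.
#' @param ... Unused.
#' @return data.frame with `fibre_id`, `section`, `protein`, `investigator`,
#'   `label` (-1/0/+1) for every fibre and every protein present in the
#'   annotation set.
#' @rdname classifyByPolygons
#' @export
setMethod("classifyByPolygons", "data.frame",
          function(object, annotations, investigator = NULL, ...) {
  .assertColumns(object, c("fibre_id", "section", "vdac1"), "fibre table")
  invs <- unique(vapply(annotations, `[[`, "", "investigator"))
  if (is.null(investigator)) {
    if (length(invs) > 1L) {
      stop("annotations contain several investigators; pick one via `investigator`")
    }
    investigator <- invs
  }
  ann <- Filter(function(a) a$investigator == investigator, annotations)
  if (!length(ann)) stop(sprintf("no annotations for investigator '%s'", investigator))
  for (a in ann) .checkPolygon(a$vertices)
  proteins <- unique(vapply(ann, `[[`, "", "protein"))
  out <- list()
  for (p in proteins) {
    lab <- integer(nrow(object))
    inLow <- logical(nrow(object))
    inHigh <- logical(nrow(object))
    for (a in Filter(function(a) a$protein == p, ann)) {
      rows <- which(object$section == a$scope)
      if (!length(rows)) next
      inside <- pracma::inpolygon(object$vdac1[rows], object[[p]][rows],
                                  a$vertices[, 1L], a$vertices[, 2L],
                                  boundary = TRUE)
      if (a$category == "low") inLow[rows] <- inLow[rows] | inside
      else inHigh[rows] <- inHigh[rows] | inside
    }
    clash <- inLow & inHigh
    if (any(clash)) {
      stop(sprintf("contradictory annotation: %d fibre(s) fall inside both a low and a high polygon",
                   sum(clash)))
    }
    lab[inLow] <- -1L
    lab[inHigh] <- 1L
    out[[p]] <- data.frame(fibre_id = object$fibre_id, section = object$section,
                           protein = p, investigator = investigator,
                           label = lab, check.names = FALSE)
  }
  do.call(rbind, unname(out))
})

#' @rdname classifyByPolygons
#' @export
setMethod("classifyByPolygons", "FibreExperiment",
          function(object, annotations, investigator = NULL, ...) {
  classifyByPolygons(fibreTable(object), annotations,
                     investigator = investigator, ...)
})

## A polygon must have >= 3 finite vertices and be simple (no two
## non-adjacent edges may intersect).
.checkPolygon <- function(v) {
  if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L || !all(is.finite(v))) {
    stop("malformed polygon: need a numeric matrix of >= 3 finite (x, y) vertices")
  }
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next # adjacent through the closing edge
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
        stop("malformed polygon: edges self-intersect")
      }
    }
  }
  invisible(TRUE)
}

#' Bootstrapped inter-investigator consensus certainty
#'
#' Aggregates per-investigator 2D-mitoplot labels into per-fibre certainty
#' scores: each of `nResamples` bootstrap iterations draws investigators with
#' replacement (as many as there are investigators) and averages their labels
#' per fibre; the mean over iterations is the fibre's mean classification in
#' \[-1, +1\], converted to a final call with the same non-strict
#' `certaintyThreshold` rule as the frequentist method.
#'
#' @param labels Either a numeric matrix (fibres x investigators) of -1/0/+1
#'   labels, or a list of per-investigator label tables as returned by
#'   [classifyByPolygons()] (aligned by `fibre_id` and `protein`; the fibre
#'   sets must match exactly).
#' @param nResamples Bootstrap iterations (default 10000).
#' @param certaintyThreshold Consensus fraction for a deficient/overabundant
#'   call (default 0.95).
#' @param seed Integer seed.
#' @param mode `"investigator"` (default) resamples investigators, the
#'   literal reading of bootstrapped inter-investigator classification;
#'   `"label"` resamples each fibre's labels independently, provided for
#'   sensitivity analysis.
#' @param minSectionFibres Flag threshold for small sections (see
#'   [classifyFrequentist()]); only applied when section information is
#'   available from label tables.
#' @return data.frame with `fibre_id`, `section` (when known), `protein`,
#'   `method = "mitoplot"`, `mean_label`, `n_resamples`, `final_call`.
#' @export
consensusCertainty <- function(labels, nResamples = 10000L,
                               certaintyThreshold = 0.95, seed = NULL,
                               mode = c("investigator", "label"),
                               minSectionFibres = 100L) {
  mode <- match.arg(mode)
  if (is.matrix(labels)) {
    meanLab <- .consensusMeanLabels(labels, nResamples, seed, mode)
    return(data.frame(fibre_id = rownames(labels) %||% seq_len(nrow(labels)),
                      protein = NA_character_, method = "mitoplot",
                      mean_label = meanLab, n_resamples = as.integer(nResamples),
                      final_call = .finalCall(meanLab, certaintyThreshold),
                      check.names = FALSE))
  }
  stopifnot(is.list(labels), length(labels) >= 1L)
  ref <- labels[[1L]][order(labels[[1L]]$protein, labels[[1L]]$fibre_id), ]
  mats <- lapply(labels, function(tb) {
    tb <- tb[order(tb$protein, tb$fibre_id), ]
    if (!identical(tb$fibre_id, ref$fibre_id) || !identical(tb$protein, ref$protein)) {
      stop("investigator label tables cover different fibre sets")
    }
    tb$label
  })
  L <- do.call(cbind, mats)
  out <- list()
  for (p in unique(ref$protein)) {
    rows <- ref$protein == p
    meanLab <- .consensusMeanLabels(L[rows, , drop = FALSE], nResamples, seed, mode)
    out[[p]] <- data.frame(fibre_id = ref$fibre_id[rows],
                           section = ref$section[rows], protein = p,
                           method = "mitoplot", mean_label = meanLab,
                           n_resamples = as.integer(nResamples),
                           final_call = .finalCall(meanLab, certaintyThreshold),
                           check.names = FALSE)
  }
  .flagSmallSections(do.call(rbind, unname(out)), minSectionFibres)
}

.consensusMeanLabels <- function(L, nResamples, seed, mode) {
  k <- ncol(L)
  nfib <- nrow(L)
  .withSeed(seed, {
    if (mode == "investigator") {
      idx <- sample.int(k, k * nResamples, replace = TRUE)
      w <- tabulate(idx, nbins = k) / (k * nResamples)
      as.numeric(L %*% w)
    } else {
      acc <- numeric(nfib)
      for (r in seq_len(nResamples)) {
        idx <- sample.int(k, nfib * k, replace = TRUE)
        sel <- L[cbind(rep(seq_len(nfib), k), idx)]
        acc <- acc + rowMeans(matrix(sel, nfib, k))
      }
      acc / nResamples
    }
  })
}
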