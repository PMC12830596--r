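#' Cohen's kappa for two label vectors
#'
#' Chance-corrected agreement between two raters (or a classifier and the
#' ground truth): `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o` and chance agreement `p_e` from the marginal label frequencies.
#' When both raters use a single identical category, `p_e = 1` and kappa is
#' undefined; by convention 1 is returned, marked with attribute
#' `degenerate = TRUE` so callers can exclude it from averages.
#'
#' @param a,b Label vectors of equal length over a shared category set.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohenKappa(c(1, 1, 0, 0), c(1, 1, 0, 0)) # 1
#' @export
cohenKappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (!length(a)) stop("label vectors are empty")
  lev <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pa <- table(factor(a, levels = lev)) / length(a)
  pb <- table(factor(b, levels = lev)) / length(b)
  pe <- sum(pa * pb)
  if (pe >= 1) {
    k <- if (po == 1) 1 else -Inf # po < 1 impossible when pe = 1
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement among `n >= 2` raters labelling the same items,
#' in the standard fixed-rater-count formulation over the category set
#' present in the data. Perfect unanimity across two or more categories
#' yields 1; a single category used throughout is degenerate and returns 1
#' with attribute `degenerate = TRUE`.
#'
#' @param labels Matrix of labels, items in rows and raters in columns.
#' @return Kappa.
#' @examples
#' fleissKappa(cbind(c(-1, 0, -1), c(-1, 0, -1), c(-1, 0, -1))) # 1
#' @export
fleissKappa <- function(labels) {
  labels <- as.matrix(labels)
  nRaters <- ncol(labels)
  if (nRaters < 2L) stop("Fleiss' kappa needs at least 2 raters")
  if (!nrow(labels)) stop("no items to rate")
  lev <- sort(unique(as.vector(labels)))
  counts <- vapply(lev, function(l) rowSums(labels == l),
                   numeric(nrow(labels)))
  counts <- matrix(counts, nrow = nrow(labels))
  Pi <- (rowSums(counts^2) - nRaters) / (nRaters * (nRaters - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (nrow(labels) * nRaters)
  Pe <- sum(pj^2)
  if (Pe >= 1) {
    k <- 1
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Confusion metrics for deficiency calls against ground truth
#'
#' Binary framing: `deficient` versus not-deficient. Ratios with a zero
#' denominator are reported as `NA` (absent), not as 0; the F1 score is the
#' harmonic mean of precision (PPV) and sensitivity,
#' `2 * PPV * Sens / (PPV + Sens)`.
#'
#' @param predicted Final calls (`"deficient"`/`"normal"`/`"overabundant"`),
#'   or -1/0/+1 labels, or logicals (TRUE = deficient).
#' @param truth Ground-truth labels in the same encodings.
#' @return One-row data.frame: `tp`, `fp`, `tn`, `fn`, `ppv`, `sensitivity`,
#'   `fpr`, `fnr`, `f1`.
#' @examples
#' confusionMetrics(c(-1, -1, 0, 0), c(-1, 0, 0, 0))
#' @export
confusionMetrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("prediction/truth length mismatch")
  if (!length(predicted)) stop("empty benchmark set")
  p <- .asDeficient(predicted)
  t <- .asDeficient(truth)
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             ppv = ppv, sensitivity = sens,
             fpr = ratio(fp, fp + tn), fnr = ratio(fn, fn + tp), f1 = f1)
}

.asDeficient <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x == -1)
  x == "deficient"
}

#' Fibre-count-weighted bootstrap mean and confidence interval
#'
#' Summarises per-section statistics (e.g. kappas or false-positive rates)
#' across sections: the point estimate is the fibre-count-weighted mean; each
#' bootstrap iteration resamples sections with replacement and recomputes the
#' weighted mean, and the 2.5th/97.5th percentiles of the bootstrap
#' distribution give the 95\% confidence interval. Sections whose statistic
#' is undefined (`NA`) are excluded and counted.
#'
#' @param statistics Per-section statistic values.
#' @param weights Per-section weights, normally fibre counts (> 0).
#' @param nBootstrap Bootstrap iterations; 10000 by default for desk-scale
#'   runtime, raise to 1e6 for publication-grade intervals.
#' @param seed Integer seed.
#' @return List with `weightedMean`, `ciLow`, `ciHigh`, `nBootstrap`,
#'   `nSections` (used), `nExcluded` (undefined statistics).
#' @export
weightedBootstrapSummary <- function(statistics, weights, nBootstrap = 10000L,
                                     seed = NULL) {
  if (length(statistics) != length(weights)) stop("statistics/weights length mismatch")
  ok <- !is.na(statistics)
  nExcluded <- sum(!ok)
  v <- as.numeric(statistics[ok])
  w <- as.numeric(weights[ok])
  if (!length(v)) stop("all statistics are undefined")
  if (any(w <= 0)) stop("weights must be > 0")
  k <- length(v)
  est <- weighted.mean(v, w)
  boot <- numeric(nBootstrap)
  .withSeed(seed, {
    chunk <- 100000L
    done <- 0L
    while (done < nBootstrap) {
      m <- min(chunk, nBootstrap - done)
      idx <- matrix(sample.int(k, m * k, replace = TRUE), nrow = m)
      num <- rowSums(matrix(v[idx] * w[idx], nrow = m))
      den <- rowSums(matrix(w[idx], nrow = m))
      boot[done + seq_len(m)] <- num / den
      done <- done + m
    }
  })
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  list(weightedMean = est, ciLow = ci[1L], ciHigh = ci[2L],
       nBootstrap = as.integer(nBootstrap), nSections = k,
       nExcluded = nExcluded)
}

#' Benchmark classification calls against ground truth
#'
#' Restricts fibres to the ground-truth-labelled regions, computes per
#' section (per protein) Cohen's kappa between the method's deficiency calls
#' and the true labels plus confusion metrics, and aggregates each statistic
#' across sections with [weightedBootstrapSummary()] (weights = benchmarked
#' fibre count per section). Degenerate per-section kappas (single shared
#' category) are excluded from aggregation, as are undefined ratios.
#'
#' @param calls Classification output from [classifyFrequentist()] or
#'   [consensusCertainty()] (columns `fibre_id`, `section`, `protein`,
#'   `final_call`).
#' @param truth Fibre table with per-protein `label_<protein>` columns and
#'   `in_ground_truth_region` (a [FibreExperiment] or data.frame).
#' @param nBootstrap,seed Passed to [weightedBootstrapSummary()].
#' @return List with `perSection` (data.frame: protein, section, n, kappa,
#'   confusion metrics) and `summary` (data.frame of weighted means and CIs
#'   per protein and statistic).
#' @export
benchmarkAgainstTruth <- function(calls, truth, nBootstrap = 10000L, seed = NULL) {
  if (is(truth, "FibreExperiment")) truth <- fibreTable(truth)
  .assertColumns(truth, c("fibre_id", "in_ground_truth_region"), "truth table")
  truth <- truth[truth$in_ground_truth_region, , drop = FALSE]
  if (!nrow(truth)) stop("no fibres flagged in_ground_truth_region")
  perSec <- list()
  for (p in unique(calls$protein)) {
    cp <- calls[calls$protein == p, ]
    m <- merge(cp, truth[, c("fibre_id", .labelCol(p))], by = "fibre_id")
    m$trueDef <- m[[.labelCol(p)]] == -1L
    m$predDef <- m$final_call == "deficient"
    for (sec in unique(m$section)) {
      ms <- m[m$section == sec, ]
      kap <- cohenKappa(ms$predDef, ms$trueDef)
      conf <- confusionMetrics(ms$predDef, ms$trueDef)
      perSec[[length(perSec) + 1L]] <- cbind(
        data.frame(protein = p, section = sec, n = nrow(ms),
                   kappa = if (isTRUE(attr(kap, "degenerate"))) NA_real_
                           else as.numeric(kap)),
        conf)
    }
  }
  perSec <- do.call(rbind, perSec)
  stats <- c("kappa", "ppv", "sensitivity", "fpr", "fnr", "f1")
  rows <- list()
  for (p in unique(perSec$protein)) {
    sub <- perSec[perSec$protein == p, ]
    for (st in stats) {
      if (all(is.na(sub[[st]]))) next
      sm <- weightedBootstrapSummary(sub[[st]], sub$n,
                                     nBootstrap = nBootstrap, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = p, statistic = st, weightedMean = sm$weightedMean,
        ciLow = sm$ciLow, ciHigh = sm$ciHigh,
        nSections = sm$nSections, nExcluded = sm$nExcluded)
    }
  }
  list(perSection = perSec, summary = do.call(rbind, rows))
}

#' Per-section inter-investigator agreement
#'
#' Fleiss' kappa per section (and protein) over the investigators' 2D-mitoplot
#' labels, aggregated with the fibre-count-weighted bootstrap.
#'
#' @param labelTables List of per-investigator label tables from
#'   [classifyByPolygons()].
#' @param nBootstrap,seed Passed to [weightedBootstrapSummary()].
#' @return List with `perSection` (protein, section, n, kappa) and `summary`
#'   (weighted mean and CI per protein).
#' @export
interInvestigatorAgreement <- function(labelTables, nBootstrap = 10000L,
                                       seed = NULL) {
  stopifnot(length(labelTables) >= 2L)
  ref <- labelTables[[1L]][order(labelTables[[1L]]$protein,
                                 labelTables[[1L]]$fibre_id), ]
  L <- vapply(labelTables, function(tb) {
    tb <- tb[order(tb$protein, tb$fibre_id), ]
    if (!identical(tb$fibre_id, ref$fibre_id)) {
      stop("investigator label tables cover different fibre sets")
    }
    as.numeric(tb$label)
  }, numeric(nrow(ref)))
  perSec <- list()
  for (p in unique(ref$protein)) {
    for (sec in unique(ref$section[ref$protein == p])) {
      rows <- ref$protein == p & ref$section == sec
      kap <- fleissKappa(L[rows, , drop = FALSE])
      perSec[[length(perSec) + 1L]] <- data.frame(
        protein = p, section = sec, n = sum(rows),
        kappa = if (isTRUE(attr(kap, "degenerate"))) NA_real_
                else as.numeric(kap))
    }
  }
  perSec <- do.call(rbind, perSec)
  rows <- list()
  for (p in unique(perSec$protein)) {
    sub <- perSec[perSec$protein == p, ]
    if (all(is.na(sub$kappa))) next
    sm <- weightedBootstrapSummary(sub$kappa, sub$n,
                                   nBootstrap = nBootstrap, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      protein = p, weightedMean = sm$weightedMean, ciLow = sm$ciLow,
      ciHigh = sm$ciHigh, nSections = sm$nSections, nExcluded = sm$nExcluded)
  }
  list(perSection = perSec, summary = do.call(rbind, rows))
}
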