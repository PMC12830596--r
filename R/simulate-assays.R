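#' Simulate a qPCR plate for mtDNA copy number estimation
#'
#' Builds dilution-series and per-biopsy Cq replicates for the two targets
#' used to compute mtDNA copies per nucleus, MT-ND1 (mitochondrial) and B2M
#' (nuclear). Each Cq value is `intercept + slope * log10(copies) +
#' Normal(0, cqNoiseSd)`. Per biopsy, B2M is present at `b2mCopies` per
#' reaction and MT-ND1 at `trueMcn * b2mCopies / 2`, so the true copy number
#' per nucleus satisfies the MT-ND1/(B2M/2) identity exactly.
#'
#' @param cohort A [MitoCohort] (provides the biopsy set), or `NULL` if
#'   `biopsies` is given directly.
#' @param trueMcn Named vector of true mtDNA copies per nucleus per biopsy;
#'   by default drawn from Normal(`mcnMean`, `mcnSd`) truncated to positive
#'   values, matching the copy-number scale reported for m.3243A>G muscle.
#' @param biopsies Character vector of biopsy ids (ignored when `cohort` is
#'   given).
#' @param mcnMean,mcnSd Mean and SD of the true copy-number distribution
#'   (defaults 1476 and 517 copies per nucleus).
#' @param b2mCopies B2M copies per reaction (default 2e4).
#' @param curves `data.frame(target, slope, intercept)` of the generating
#'   standard curves; slopes must be negative (default slope -3.3219, the
#'   perfect-efficiency value, for MT-ND1).
#' @param cqNoiseSd Replicate Cq noise SD (default 0.2 cycles).
#' @param dilutionCopies Copies per reaction along the standard dilution
#'   series (default 1e7 down to 1e2, ten-fold steps).
#' @param nReplicates Replicates per dilution and per biopsy measurement
#'   (default 6).
#' @param seed Integer seed.
#' @return A [QPCRPlate].
#' @export
generateQpcr <- function(cohort = NULL, trueMcn = NULL, biopsies = NULL,
                         mcnMean = 1476, mcnSd = 517, b2mCopies = 2e4,
                         curves = data.frame(
                           target = c("MT-ND1", "B2M"),
                           slope = c(-3.3219, -3.35),
                           intercept = c(38, 37.5)),
                         cqNoiseSd = 0.2,
                         dilutionCopies = 10^(7:2),
                         nReplicates = 6L, seed = NULL) {
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "MitoCohort"))
    biopsies <- unique(sectionInfo(cohort)$biopsy)
  }
  if (!all(is.finite(curves$slope)) || !all(is.finite(curves$intercept)) ||
      any(curves$slope == 0)) {
    stop("curve parameters must be finite with non-zero slope")
  }
  .withSeed(seed, {
    if (is.null(trueMcn)) {
      if (is.null(biopsies)) stop("need a cohort, biopsies or trueMcn")
      trueMcn <- rnorm(length(biopsies), mcnMean, mcnSd)
      for (i in seq_len(100)) {
        bad <- trueMcn <= 0
        if (!any(bad)) break
        trueMcn[bad] <- rnorm(sum(bad), mcnMean, mcnSd)
      }
      names(trueMcn) <- biopsies
    }
    if (any(trueMcn <= 0)) stop("true mtDNA copy numbers must be > 0")
    biopsies <- names(trueMcn)
    cq <- function(target, copies, n) {
      cu <- curves[curves$target == target, ]
      cu$intercept + cu$slope * log10(copies) + rnorm(n, 0, cqNoiseSd)
    }
    dil <- do.call(rbind, lapply(curves$target, function(tg) {
      do.call(rbind, lapply(dilutionCopies, function(cp) {
        data.frame(target = tg, copies = cp, replicate = seq_len(nReplicates),
                   cq = cq(tg, cp, nReplicates))
      }))
    }))
    copiesFor <- function(tg, b) {
      if (tg == "B2M") b2mCopies else trueMcn[[b]] * b2mCopies / 2
    }
    samp <- do.call(rbind, lapply(biopsies, function(b) {
      do.call(rbind, lapply(curves$target, function(tg) {
        data.frame(biopsy = b, target = tg, replicate = seq_len(nReplicates),
                   cq = cq(tg, copiesFor(tg, b), nReplicates))
      }))
    }))
    new("QPCRPlate", dilutions = dil, samples = samp, trueCurve = curves,
        trueMcn = trueMcn, cqNoiseSd = cqNoiseSd)
  })
}

#' Simulate pyrosequencing heteroplasmy triplicates
#'
#' Per biopsy, a true m.3243A>G heteroplasmy is drawn around the patient's
#' per-muscle mean with between-biopsy SD, and measured as a triplicate with
#' replicate noise; all values are clipped to \[0, 100\]. The four assay
#' standards (0, 16, 52 and 92\% heteroplasmy) are measured alongside.
#'
#' @param cohort A [MitoCohort]; its patient/muscle/biopsy hierarchy defines
#'   the records.
#' @param muscleMeans Named list, one numeric vector per muscle giving the
#'   per-patient mean heteroplasmy (\%), recycled over patients. Defaults to
#'   historical homogenate values for four m.3243A>G patients.
#' @param betweenBiopsySd Between-biopsy SD of true heteroplasmy (default
#'   2.9\%).
#' @param replicateSd Replicate (technical) SD (default 1\%).
#' @param standards Nominal standard levels (default `c(0, 16, 52, 92)`).
#' @param nReplicates Replicates per measurement (default 3).
#' @param seed Integer seed.
#' @return List with `records` (biopsy, patient, muscle, replicate, het,
#'   true_het) and `standards` (level, replicate, het) data.frames.
#' @export
generatePyroseq <- function(cohort, muscleMeans = NULL, betweenBiopsySd = 2.9,
                            replicateSd = 1, standards = c(0, 16, 52, 92),
                            nReplicates = 3L, seed = NULL) {
  stopifnot(is(cohort, "MitoCohort"))
  if (is.null(muscleMeans)) {
    muscleMeans <- list(QD = c(52, 83, 72, 77), TA = c(52, 85, 64, 86))
  }
  if (any(unlist(muscleMeans) < 0 | unlist(muscleMeans) > 100)) {
    stop("heteroplasmy means must lie in [0, 100]")
  }
  sec <- sectionInfo(cohort)
  bio <- unique(sec[, c("patient", "muscle", "biopsy")])
  clip <- function(x) pmin(pmax(x, 0), 100)
  .withSeed(seed, {
    recs <- do.call(rbind, lapply(seq_len(nrow(bio)), function(i) {
      pIdx <- as.integer(sub("^P", "", bio$patient[i]))
      means <- muscleMeans[[bio$muscle[i]]] %||% 70
      mu <- means[((pIdx - 1L) %% length(means)) + 1L]
      truth <- clip(rnorm(1, mu, betweenBiopsySd))
      data.frame(biopsy = bio$biopsy[i], patient = bio$patient[i],
                 muscle = bio$muscle[i], replicate = seq_len(nReplicates),
                 het = clip(rnorm(nReplicates, truth, replicateSd)),
                 true_het = truth)
    }))
    std <- do.call(rbind, lapply(standards, function(s) {
      data.frame(level = s, replicate = seq_len(nReplicates),
                 het = clip(rnorm(nReplicates, s, replicateSd)))
    }))
    list(records = recs, standards = std)
  })
}
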