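#' Simulate investigator lasso annotations
#'
#' Emulates investigators classifying fibres on 2D-mitoplots (OXPHOS signal
#' versus VDAC1) by lassoing clusters of relatively low or high OXPHOS
#' signal. For every section and protein, each simulated investigator draws a
#' `"low"` polygon around the true deficient cluster (and a `"high"` polygon
#' around overabundant fibres when present), built as the convex hull of the
#' cluster's points dilated by a negligible margin; each vertex is then
#' perturbed radially (toward or away from the cluster centroid) with
#' Gaussian jitter of SD `boundaryJitterSd` (intensity units), modelling an
#' imperfect hand-drawn boundary while keeping the lasso a simple polygon.
#' With zero jitter, the polygons classify exactly the true labels.
#'
#' @param cohort A [MitoCohort] with true labels.
#' @param nInvestigators Number of simulated investigators (default 3).
#' @param boundaryJitterSd SD of vertex jitter in intensity units (default 0).
#' @param seed Integer seed.
#' @return A list of annotation records, each a list with fields
#'   `investigator`, `protein`, `scope` (section id), `category`
#'   (`"low"`/`"high"`) and `vertices` (matrix with columns `vdac1`,
#'   `oxphos`). Serialise with [writeAnnotations()].
#' @export
generateAnnotations <- function(cohort, nInvestigators = 3L,
                                boundaryJitterSd = 0, seed = NULL) {
  stopifnot(is(cohort, "MitoCohort"), nInvestigators >= 1L,
            boundaryJitterSd >= 0)
  ft <- fibreTable(patientFibres(cohort))
  proteins <- oxphosProteins(patientFibres(cohort))
  sections <- sectionInfo(cohort)$section
  .withSeed(seed, {
    out <- list()
    for (sec in sections) {
      rows <- ft[ft$section == sec, , drop = FALSE]
      if (!nrow(rows)) stop(sprintf("section '%s' has no fibres", sec))
      for (p in proteins) {
        lab <- rows[[.labelCol(p)]]
        for (cat in c("low", "high")) {
          want <- if (cat == "low") -1L else 1L
          pts <- cbind(rows$vdac1[lab == want], rows[[p]][lab == want])
          if (!nrow(pts)) next
          base <- .clusterHull(pts)
          for (inv in seq_len(nInvestigators)) {
            v <- base
            if (boundaryJitterSd > 0) {
              v <- .radialJitter(base, boundaryJitterSd)
            }
            colnames(v) <- c("vdac1", "oxphos")
            out[[length(out) + 1L]] <- list(
              investigator = sprintf("INV%d", inv),
              protein = p, scope = sec, category = cat, vertices = v)
          }
        }
      }
    }
    out
  })
}

## Convex hull of a point cluster, dilated by a tiny diamond at each point so
## that degenerate clusters (1-2 points, collinear points) still yield a
## simple polygon with >= 3 vertices containing every cluster point.
.clusterHull <- function(pts) {
  eps <- 1e-3 * max(1, abs(pts))
  cloud <- rbind(cbind(pts[, 1] + eps, pts[, 2]),
                 cbind(pts[, 1] - eps, pts[, 2]),
                 cbind(pts[, 1], pts[, 2] + eps),
                 cbind(pts[, 1], pts[, 2] - eps))
  cloud[grDevices::chull(cloud), , drop = FALSE]
}

## Perturb each hull vertex along its direction from the centroid. Angular
## order is preserved and radii stay positive, so the jittered lasso remains
## a simple (star-shaped) polygon no matter the jitter size.
.radialJitter <- function(v, sd) {
  centre <- colMeans(v)
  d <- sweep(v, 2L, centre)
  r <- sqrt(rowSums(d^2))
  r[r == 0] <- 1e-9
  rNew <- pmax(r + rnorm(nrow(v), 0, sd), 0.05 * r)
  centre[col(d)] + d / r * rNew
}
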