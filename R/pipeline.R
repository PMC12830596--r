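#' Default end-to-end pipeline configuration
#'
#' A demo-scale configuration for [runPipeline()]: the default synthetic
#' cohort, three simulated investigators with moderately jittered lasso
#' boundaries, both classification methods, and reduced iteration counts
#' that keep a full run in the minutes range. All randomness derives from
#' `seed`; per-stage seeds are fixed offsets from it.
#'
#' @param seed Base seed for every stage.
#' @return Named list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(),             # arguments to CohortDesign()
    methods = c("frequentist", "mitoplot"),
    nInvestigators = 3L,
    boundaryJitterSd = 25,
    nModels = 1000L,             # frequentist bootstrap regressions
    nConsensusResamples = 10000L,
    proportionDraws = 2000L,     # per-section bootstrap proportion draws
    differenceIterations = 1e5,  # sampled absolute differences per strategy
    benchmarkBootstrap = 10000L,
    curveModels = 20000L,        # qPCR standard-curve bootstrap
    mcnIterations = 20000L,      # curve--Cq pairing iterations per biopsy
    strategies = c("intra_biopsy", "intra_l_split", "intra_muscle",
                   "intra_QD", "intra_TA", "inter_muscle")
  )
}

#' Run the full simulate-classify-benchmark-variability pipeline
#'
#' Executes, in order: cohort simulation; fibre classification by the
#' requested method(s); benchmarking against ground truth and
#' inter-investigator agreement; per-section proportion bootstraps and
#' absolute-difference variability distributions per pairing strategy; qPCR
#' staged-bootstrap mtDNA copy number; pyrosequencing heteroplasmy; and the
#' expected-variability threshold report. Re-running with an identical
#' configuration reproduces identical outputs; each stage logs its seed and
#' problem size.
#'
#' @param config Configuration list (see [defaultPipelineConfig()]; missing
#'   entries fall back to the defaults). `config$design` may be a
#'   [CohortDesign] or a list of arguments to [CohortDesign()].
#' @param outputDir If given, tables (CSV), summaries (JSON) and the run log
#'   are written there.
#' @param verbose Print log lines as the run progresses.
#' @return List with `cohort`, `annotations`, `calls` (per method),
#'   `benchmark` (per method), `fleiss`, `variability` (one summary row per
#'   metric/method/strategy), `mcn`, `heteroplasmy`, `pooledHetSd`,
#'   `thresholds`, `log`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outputDir = NULL,
                        verbose = FALSE) {
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  if (is.null(cfg$seed)) stop("config must fix a seed (no wall-clock seeding)")
  seeds <- list(cohort = cfg$seed, annotations = cfg$seed + 1L,
                qpcr = cfg$seed + 2L, pyroseq = cfg$seed + 3L,
                classify = cfg$seed + 4L, consensus = cfg$seed + 5L,
                proportions = cfg$seed + 6L, differences = cfg$seed + 7L,
                benchmark = cfg$seed + 8L, mtdnacn = cfg$seed + 9L)
  logLines <- character()
  logMsg <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## --- simulate -----------------------------------------------------------
  cohort <- stage("simulate", {
    design <- if (is(cfg$design, "CohortDesign")) cfg$design
              else do.call(CohortDesign, cfg$design)
    generateCohort(design, seed = seeds$cohort)
  })
  design <- cohortDesign(cohort)
  logMsg("simulate: %d fibres in %d sections (seed %d)",
         ncol(patientFibres(cohort)), nrow(sectionInfo(cohort)), seeds$cohort)
  annotations <- stage("simulate", generateAnnotations(
    cohort, nInvestigators = cfg$nInvestigators,
    boundaryJitterSd = cfg$boundaryJitterSd, seed = seeds$annotations))
  plate <- stage("simulate", generateQpcr(cohort, seed = seeds$qpcr))
  pyro <- stage("simulate", generatePyroseq(cohort, seed = seeds$pyroseq))

  ## --- classify -----------------------------------------------------------
  calls <- list()
  labelTables <- NULL
  if ("frequentist" %in% cfg$methods) {
    calls$frequentist <- stage("classify", suppressWarnings(
      classifyFrequentist(cohort, nModels = cfg$nModels, seed = seeds$classify)))
    logMsg("classify/frequentist: %d models x %d fibre-protein rows",
           cfg$nModels, nrow(calls$frequentist))
  }
  if ("mitoplot" %in% cfg$methods) {
    ft <- fibreTable(patientFibres(cohort))
    invs <- unique(vapply(annotations, `[[`, "", "investigator"))
    labelTables <- stage("classify", lapply(invs, function(iv) {
      classifyByPolygons(ft, annotations, investigator = iv)
    }))
    calls$mitoplot <- stage("classify", suppressWarnings(
      consensusCertainty(labelTables, nResamples = cfg$nConsensusResamples,
                         seed = seeds$consensus)))
    logMsg("classify/mitoplot: %d investigators, %d consensus resamples",
           length(invs), cfg$nConsensusResamples)
  }

  ## --- benchmark ----------------------------------------------------------
  benchmark <- lapply(calls, function(cl) {
    stage("benchmark", benchmarkAgainstTruth(
      cl, patientFibres(cohort), nBootstrap = cfg$benchmarkBootstrap,
      seed = seeds$benchmark))
  })
  fleiss <- if (!is.null(labelTables) && length(labelTables) >= 2L) {
    stage("benchmark", interInvestigatorAgreement(
      labelTables, nBootstrap = cfg$benchmarkBootstrap, seed = seeds$benchmark))
  }
  logMsg("benchmark: %d bootstrap iterations per statistic", cfg$benchmarkBootstrap)

  ## --- variability (OXPHOS proportions, per method/protein/strategy) ------
  sec <- sectionInfo(cohort)
  strategies <- cfg$strategies
  if (!any(!is.na(sec$lSplitGroup))) {
    strategies <- setdiff(strategies, "intra_l_split")
  }
  strategies <- intersect(strategies,
                          c("intra_biopsy", "intra_l_split", "intra_muscle",
                            paste0("intra_", design@muscles), "inter_muscle"))
  varRows <- list()
  for (meth in names(calls)) {
    props <- stage("variability", sectionProportionDistributions(
      calls[[meth]], nDraws = cfg$proportionDraws, seed = seeds$proportions))
    for (p in names(props)) {
      for (st in strategies) {
        pairs <- enumeratePairs(sec, st, unit = "section")
        if (!nrow(pairs)) next
        diffs <- stage("variability", sampleAbsDifferences(
          props[[p]], pairs, nIterations = cfg$differenceIterations,
          seed = seeds$differences))
        sm <- summarizeDistribution(diffs * 100) # percent
        varRows[[length(varRows) + 1L]] <- cbind(
          data.frame(metric = paste0("oxphos_", p), method = meth,
                     strategy = st, nPairs = nrow(pairs)), sm)
      }
    }
  }

  ## --- mtDNA copy number ---------------------------------------------------
  curves <- stage("mtdnacn", bootstrapStandardCurves(
    plate, nModels = cfg$curveModels, seed = seeds$mtdnacn))
  mcn <- stage("mtdnacn", estimateMtdnacn(
    plate, curves, nIterations = cfg$mcnIterations, seed = seeds$mtdnacn))
  logMsg("mtdnacn: %d curve models, %d pairing iterations x %d biopsies",
         cfg$curveModels, cfg$mcnIterations, length(mcn))
  mcnValues <- lapply(mcn, `[[`, "values")
  bioLevelStrategies <- setdiff(strategies, "intra_biopsy")
  for (st in bioLevelStrategies) {
    pairs <- enumeratePairs(sec, st, unit = "biopsy")
    if (!nrow(pairs)) next
    diffs <- stage("variability", sampleAbsDifferences(
      mcnValues, pairs, nIterations = cfg$differenceIterations,
      seed = seeds$differences))
    varRows[[length(varRows) + 1L]] <- cbind(
      data.frame(metric = "mtdnacn", method = "qpcr", strategy = st,
                 nPairs = nrow(pairs)), summarizeDistribution(diffs))
  }

  ## --- heteroplasmy --------------------------------------------------------
  hetMeans <- stage("heteroplasmy", {
    recs <- pyro$records
    do.call(rbind, lapply(split(recs, recs$biopsy), function(d) {
      data.frame(biopsy = d$biopsy[1L], patient = d$patient[1L],
                 muscle = d$muscle[1L], mean_het = heteroplasmyMean(d$het))
    }))
  })
  pooledHetSd <- pooledSd(split(hetMeans$mean_het, hetMeans$patient))
  logMsg("heteroplasmy: %d biopsies, pooled SD %.2f%%", nrow(hetMeans), pooledHetSd)
  hetValues <- split(pyro$records$het, pyro$records$biopsy)
  for (st in bioLevelStrategies) {
    pairs <- enumeratePairs(sec, st, unit = "biopsy")
    if (!nrow(pairs)) next
    diffs <- stage("variability", sampleAbsDifferences(
      hetValues, pairs, nIterations = cfg$differenceIterations,
      seed = seeds$differences))
    varRows[[length(varRows) + 1L]] <- cbind(
      data.frame(metric = "heteroplasmy", method = "pyroseq", strategy = st,
                 nPairs = nrow(pairs)), summarizeDistribution(diffs))
  }
  variability <- do.call(rbind, varRows)
  rownames(variability) <- NULL
  logMsg("variability: %d iterations per strategy, %d summaries",
         cfg$differenceIterations, nrow(variability))

  ## --- thresholds -----------------------------------------------------------
  thresholds <- thresholdReport(
    variability[variability$strategy == "intra_muscle", , drop = FALSE])
  logMsg("thresholds: %d intra-muscle expected-variability thresholds",
         nrow(thresholds))

  result <- list(cohort = cohort, annotations = annotations, calls = calls,
                 benchmark = benchmark, fleiss = fleiss,
                 variability = variability, mcn = mcnSummary(mcn),
                 heteroplasmy = hetMeans, pooledHetSd = pooledHetSd,
                 thresholds = thresholds, log = logLines)
  if (!is.null(outputDir)) .writePipelineOutputs(result, cohort, plate, pyro, outputDir)
  result
}

.writePipelineOutputs <- function(result, cohort, plate, pyro, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outputDir, ...)
  writeFibreTable(patientFibres(cohort), fp("fibres.csv"))
  writeFibreTable(controlFibres(cohort), fp("controls.csv"))
  writeCohortMetadata(cohort, fp("cohort.json"))
  writeAnnotations(result$annotations, fp("annotations.json"))
  writeQpcrPlate(plate, fp("qpcr.csv"))
  writePyroseq(pyro, fp("pyroseq.csv"))
  for (m in names(result$calls)) {
    .writeCsvWithSchema(result$calls[[m]], fp(sprintf("calls_%s.csv", m)),
                        .SCHEMAS[["generic"]])
  }
  .writeCsvWithSchema(result$variability, fp("variability.csv"),
                      .SCHEMAS[["generic"]])
  .writeCsvWithSchema(result$thresholds, fp("thresholds.csv"),
                      .SCHEMAS[["generic"]])
  summary <- list(
    benchmark = lapply(result$benchmark, `[[`, "summary"),
    fleiss = if (!is.null(result$fleiss)) result$fleiss$summary,
    mcn = result$mcn,
    pooledHeteroplasmySdPct = result$pooledHetSd,
    thresholds = result$thresholds)
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  writeLines(result$log, fp("run.log"))
  invisible(outputDir)
}
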