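# mitovar

Quantifying **intra-individual variability of mitochondrial markers** in
skeletal muscle with m.3243A>G-related myopathy.

Repeat muscle biopsies are the workhorse of mitochondrial disease progression
studies and clinical trials, but a difference between two biopsies can
reflect anatomical mosaicism or assay noise rather than true change over
time. `mitovar` implements, as a tested and reusable pipeline, the analysis
needed to put numbers on that problem: single-fibre OXPHOS (oxidative
phosphorylation) classification from quantitative immunofluorescence,
benchmarking of classification methods against ground truth, resampling-based
distributions of between-biopsy differences organised by anatomical distance,
and expected-variability thresholds for OXPHOS deficiency, mtDNA copy number
and m.3243A>G heteroplasmy. It is aimed at biostatisticians and muscle
pathology groups designing or analysing longitudinal single-fibre studies.

Because the post-mortem tissue data this methodology was developed on are not
publicly deposited, the package ships a seeded synthetic-cohort generator
that reproduces the assumed statistical structure — patients x muscles
(quadriceps, tibialis anterior) x biopsies x serial section triplets, with
patient–control signal disparity, per-section staining batch effects, mosaic
deficiency drifting with anatomical distance, L-split biopsy pairs at known
separation, qPCR and pyrosequencing noise — with full ground truth, so every
component is testable end to end.

## The methods

**Frequentist single-fibre classification.** Per staining batch and OXPHOS
protein (NDUFB8 for complex I, MT-CO1 for complex IV), control fibres define
an OLS regression of OXPHOS signal on VDAC1 (mitochondrial mass). Control
fibres are bootstrapped to give *B* = 10,000 regression models; each model
classifies a patient fibre against its 95% t-based prediction interval,

```
fit(x) ± t(0.975, n−2) · s · sqrt(1 + 1/n + (x − x̄)² / Sxx),
```

as −1 (below), 0 (within) or +1 (above). The fibre's certainty score is the
mean label across models; a fibre is called *deficient* when the mean is
≤ −0.95 (≥ 95% of models concur) and *overabundant* when ≥ +0.95.

**Visual 2D-mitoplot classification.** Investigators lasso clusters of
relatively low (or high) OXPHOS signal on the OXPHOS–VDAC1 scatter plot;
fibres inside a lasso get −1 (or +1), boundary-inclusive. Investigators are
bootstrapped (10,000 resamples) and per-fibre mean labels are thresholded
with the same ±0.95 rule.

**Benchmarking.** Calls are scored against ground-truth-labelled regions per
section: Cohen's kappa, FPR/FNR/PPV/sensitivity and
F1 = 2·PPV·Sens/(PPV+Sens), aggregated across sections by fibre-count-
weighted bootstrap means with percentile 95% CIs; inter-investigator
agreement uses per-section Fleiss' kappa.

**Variability engine.** Per-section bootstrap distributions of the deficient
proportion are paired under six anatomical strategies (within triplet,
across L-splits, between biopsies within muscle / within QD / within TA,
between muscles); sampled absolute differences (10⁶ draws) are summarised as
median, IQR, 2.5th–97.5th percentiles and range. The 97.5th percentile for
within-muscle pairing is the *expected-variability threshold*: only a
longitudinal change strictly above it should be read as time-dependent. The
same machinery handles mtDNA copy number per nucleus — estimated by a staged
bootstrap of qPCR standard curves and Cq replicates, reported as the median
of per-biopsy MT-ND1/(B2M/2) distributions — and pyrosequencing heteroplasmy
triplicates.

## Worked example

```r
library(mitovar)

design <- CohortDesign(nPatients = 2, biopsiesPerMuscle = 2,
                       fibresPerSection = 200, nControlFibres = 1000)
cohort <- generateCohort(design, seed = 42)
cohort
#> MitoCohort
#>   patient fibres: 4800 in 24 sections
#>   control fibres: 2000
#>   L-split groups: 2

## frequentist bootstrapped prediction-interval classification
calls <- classifyFrequentist(cohort, nModels = 1000, seed = 1)
head(calls[calls$protein == "NDUFB8", c("fibre_id", "mean_label", "final_call")], 3)
#>            fibre_id mean_label final_call
#> 1 P1_QD_B1_S1_F0001         -1  deficient
#> 2 P1_QD_B1_S1_F0002         -1  deficient
#> 3 P1_QD_B1_S1_F0003         -1  deficient

## simulated investigators, polygon consensus, benchmark vs ground truth
ann <- generateAnnotations(cohort, nInvestigators = 3, boundaryJitterSd = 25, seed = 2)
labs <- lapply(paste0("INV", 1:3), function(iv)
  classifyByPolygons(patientFibres(cohort), ann, investigator = iv))
consensus <- consensusCertainty(labs, seed = 3)
bench <- benchmarkAgainstTruth(consensus, patientFibres(cohort), seed = 4)
subset(bench$summary, protein == "NDUFB8" & statistic %in% c("kappa", "fpr", "f1"))
#>    protein statistic weightedMean     ciLow    ciHigh nSections nExcluded
#> 7   NDUFB8     kappa    0.8932040 0.8257290 0.9535278        24         0
#> 10  NDUFB8       fpr    0.0000000 0.0000000 0.0000000        24         0
#> 12  NDUFB8        f1    0.9343962 0.8934343 0.9705628        24         0

## between-biopsy variability within a muscle, and the threshold it implies
props <- sectionProportionDistributions(consensus, nDraws = 2000, seed = 5)
pairs <- enumeratePairs(cohort, "intra_muscle")
diffs <- sampleAbsDifferences(props$NDUFB8, pairs, nIterations = 1e5, seed = 6)
summarizeDistribution(diffs * 100)   # percentage points
#>   median iqr_low iqr_high p2_5 p97_5 min  max      n
#> 1    3.5       2      6.5    0    12   0 23.5 100000

thr <- summarizeDistribution(diffs * 100)$p97_5
exceedsExpectedVariability(c(5, thr + 2), thr)
#> [1] FALSE  TRUE
```

Here the consensus method recovers the simulated mosaic almost perfectly
(kappa 0.89, no false positives on the benchmarked fibres), and between-biopsy
differences in NDUFB8-deficient proportion up to 12 percentage points are
expected from anatomical variability alone: in a longitudinal study of this
cohort, only larger changes would be evidence of progression or treatment
effect.

`runPipeline(defaultPipelineConfig(seed = 1))` chains all stages (simulation,
both classifiers, benchmarking, variability for OXPHOS/mtDNAcn/heteroplasmy,
thresholds) and `inst/scripts/run_pipeline.R` wraps it for the shell.

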