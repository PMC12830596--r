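---
title: "Models and design choices in mitovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mitovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitovar` quantifies how much single-fibre OXPHOS deficiency, mtDNA copy
number and m.3243A>G heteroplasmy vary *within* one individual's skeletal
muscle, so that longitudinal differences between biopsies can be judged
against the variability expected from anatomy and assay noise alone. This
vignette documents the statistical models the package implements, the
parameters that matter, what the synthetic cohort does and does not emulate,
and the choices made where the underlying methodology left the design open.

## 1. Single-fibre classification models

### Frequentist prediction-interval method

Per staining batch and OXPHOS protein, control fibres define an ordinary
least-squares regression of OXPHOS intensity on VDAC1 intensity (both in
arbitrary fluorescence units, linear scale). The normal range at
mitochondrial mass `x` is the classical t-based prediction interval

    fit(x) ± t(1 − α/2, n − 2) · s · sqrt(1 + 1/n + (x − x̄)² / Sxx)

with coverage `level = 0.95` by default. Controls are resampled with
replacement `nModels = 10000` times (resample size = control sample size);
every resampled fit classifies each patient fibre as −1/0/+1, and the mean
label across models is the fibre's certainty score in [−1, +1]. Final calls
use non-strict thresholds: deficient iff mean ≤ −0.95, overabundant iff
mean ≥ +0.95. The methodology literature states only "95% predictive
intervals"; the classical t-based form above is adopted and fixed here. A
bootstrap resample whose VDAC1 values are all equal cannot be fit and is
redrawn (cap 100, then an error).

Assumptions: linearity of the control OXPHOS–VDAC1 relation, homoscedastic
Gaussian residuals, and — critically — that patient "normal" fibres follow
the *control* line. Systematic patient–control signal disparity violates the
last assumption and inflates false-positive deficiency calls; this is
precisely the weakness the synthetic cohort's `patientDisparity` knob
reproduces and the consensus method below overcomes.

### Visual 2D-mitoplot consensus method

Investigators lasso clusters of relatively low (or high) OXPHOS signal on
the per-section OXPHOS–VDAC1 scatter plot. A fibre inside any "low" polygon
is −1, inside any "high" polygon +1, otherwise 0. Point-in-polygon uses the
even-odd rule and is **boundary-inclusive** — deterministic and independent
of vertex orientation; a fibre inside both a low and a high polygon is a
contradictory annotation and raises an error rather than being resolved
silently. Inter-investigator uncertainty is captured by bootstrapping
*investigators* (with replacement, as many as there are investigators,
`nResamples = 10000`), the most literal reading of "bootstrapped
inter-investigator classifications"; a per-fibre label-resampling mode is
available behind `mode = "label"` for sensitivity analysis. The consensus
mean label converges to the arithmetic mean of investigator labels, so with
three investigators the reachable certainty values are effectively
{−1, −2/3, −1/3, 0, ...}; only unanimity can cross the ±0.95 threshold.

Sections with fewer than ~100 classified fibres give unstable deficiency
proportions; both classifiers flag such sections
(`section_below_min_fibres`) and warn.

## 2. Benchmarking

Ground-truth comparisons are restricted to the flagged ground-truth regions
and use a binary deficient/not-deficient framing (ground truth is labelled
for deficiency; a trichotomous kappa would mostly score the empty
overabundant class). Per-section Cohen's kappa and confusion metrics are
aggregated as fibre-count-weighted means, with 95% CIs from resampling
*sections* with replacement — the unit of replication in the design; what the
1-million-iteration bootstrap resamples was not specified upstream, and
section-level resampling is the choice documented here. The default is
10,000 bootstrap iterations (raise `nBootstrap` to 1e6 for
publication-grade CIs; the estimate itself does not change, only CI
smoothness). Undefined statistics (kappa when a section's benchmark region
is single-class with perfect agreement; ratios with zero denominators) are
reported as absent and excluded from aggregation with their count, rather
than coerced to 0.

## 3. Variability engine

Per-section uncertainty in the deficient proportion is captured by
resampling the section's classified fibres with replacement; for a binary
phenotype the resulting proportion distribution is exactly
Binomial(n, p̂)/n, which is how draws are generated. Six pairing strategies
order comparisons by anatomical distance: within serial-section triplets;
across the two faces of an L-split biopsy (known separation); between
biopsies within the same muscle (QD and TA pooled — pooling pair sets, not
averaging per-muscle summaries); within QD only; within TA only; and between
muscles. All pairs are within-patient and pooled across patients.

Differences are sampled pair-then-draw: an eligible pair uniformly at
random, then one value per side uniformly with replacement — uniform over
*pairs*, not weighted by section counts (the upstream description,
"randomly pairing values", does not decide this; uniform-over-pairs is
fixed here). Heteroplasmy pairing draws uniformly over the 3 × 3 replicate
combinations per biopsy pair, i.e. replicates are paired directly.
Summaries (median, IQR, 2.5th–97.5th percentiles, range) use quantile
type 7 (linear interpolation between order statistics) so results are
bit-reproducible given a seed. The within-muscle 97.5th percentile is
reported as the expected-variability threshold, applied with a strict rule:
a longitudinal difference exactly at the threshold is *not* flagged.

Reference iteration counts are 1e6 (OXPHOS) and 1e5 (homogenate metrics);
the pipeline default is 1e5 and tests run at 1e4–1e5. These counts only
smooth the difference distribution — medians and percentiles are stable well
below 1e5.

## 4. mtDNA copy number and heteroplasmy

The staged bootstrap propagates both qPCR uncertainty sources: (i) standard
curves are refit 1e5 times, drawing one Cq per dilution from its replicates
with replacement and fitting Cq ~ log10(copies) by OLS; (ii) per biopsy,
1e5 iterations each draw one curve and one replicate Cq per target —
independently for MT-ND1 and B2M, including independent curve indices per
target (whether the two targets should share a curve index per iteration is
unspecified upstream; independence is the choice here) — invert the curve
(`copies = 10^((Cq − intercept)/slope)`), and record MT-ND1/(B2M/2) copies
per nucleus. The median of the per-biopsy distribution is the point
estimate; curves with non-negative slope are invalid amplification and are
redrawn. Amplification efficiency `10^(−1/slope) − 1` is reported as a
diagnostic only. Heteroplasmy per biopsy is the arithmetic mean of the
pyrosequencing triplicate (exactly 3 replicates enforced by default; ≥ 2
accepted with a warning behind `strict = FALSE`), and the pooled SD across
patients is the df-weighted root-mean variance.

## 5. The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions, chosen once:

* **Hierarchy**: 4 patients × 2 muscles (QD, TA) × 4 biopsies × 3 serial
  sections — 32 biopsies / 96 sections, matching the scale of a 31-biopsy /
  93-section post-mortem design. Four L-split biopsy pairs with inter-face
  distances averaging 14.4 mm; other biopsies are spaced 25 mm (spacing
  otherwise unknown in real designs).
* **Problem sizes**: 300 fibres per section and 2000 control fibres per
  batch (real sections carry ~1300 and ~1800–4800); these sizes keep a full
  pipeline run in the tens of seconds while leaving per-section binomial
  noise realistic in relative terms. Tests and the acceptance script state
  their own sizes.
* **Signal model**: control line per protein (slope 1.1/0.9, intercept
  50/80, residual SD 60/55 for NDUFB8/MT-CO1, arbitrary units around a
  VDAC1 scale of ~1000); patient–control disparity is exposed as both a
  gain and an offset because its additive/multiplicative nature is not
  identifiable from published evidence — defaults use gains 0.92 (NDUFB8)
  and 0.96 (MT-CO1), magnitudes set so the frequentist classifier
  over-calls deficiency markedly for NDUFB8 and mildly for MT-CO1, the
  reported qualitative failure mode. Per-section batch effects are a
  log-normal gain and an offset in residual-SD units (`sectionBatchSd`,
  default 0.1).
* **Mosaic deficiency**: per-biopsy proportion =
  logistic(patient base + muscle offset + Gaussian random walk over biopsy
  positions, SD 0.05 per √mm), with protein means 0.297 (NDUFB8) and 0.094
  (MT-CO1) and TA offset +0.3 — deficiency drifts with anatomical distance,
  and L-split pairs sit on the same walk at their recorded separation.
  Deficient fibres are displaced −8 control residual SDs (overabundant +8,
  at rate 3e-4); assignment is deterministic, `round(p·n)` fibres per
  section, so recovery tests have exact truth (Bernoulli mode behind a
  flag). A design with positive deficiency but zero shift is rejected —
  truth would be unidentifiable.
* **Ground truth**: an index-contiguous block of ~5% of each section's
  fibres, emulating exhaustive visual inspection of a representative region
  without modelling tissue geometry.
* **Annotators**: per investigator and cluster, the convex hull of the true
  cluster dilated by a negligible margin, vertices jittered *radially*
  about the cluster centroid (SD in intensity units) — imperfect hand-drawn
  lassos that remain simple polygons at any jitter; zero jitter reproduces
  the true labels exactly, giving the end-to-end identity tests their
  oracle.
* **Assays**: qPCR Cq = intercept + slope·log10(copies) + N(0, 0.2), six
  replicates, ten-fold dilution series 1e7–1e2; true copy numbers
  N(1476, 517) truncated positive; B2M at 2e4 copies per reaction with
  MT-ND1 = mtDNAcn · B2M/2 so the copy-number identity holds exactly.
  Pyrosequencing: per-muscle patient means from historical homogenate
  values (e.g. 83/85% for the second patient), between-biopsy SD 2.9%,
  replicate SD 1%, standards 0/16/52/92% measured alongside, all clipped to
  [0, 100].

Not emulated: microscopy images, segmentation, staining chemistry or
background (the pipeline consumes per-fibre intensity tables); spatial
structure beyond the 1-D along-muscle walk; correlation between NDUFB8 and
MT-CO1 deficiency within a fibre (labels are drawn independently per
protein, although real complex I/IV defects co-occur); heteroplasmy–
deficiency coupling; fibre-type composition. Green tests therefore show the
*statistical machinery* is correct under the assumed generating model — they
do not validate the biological assumptions on real tissue.

## 6. Numerical conventions and degenerate inputs

* Quantiles: type 7 everywhere (summaries, bootstrap CIs).
* Certainty thresholds: non-strict (≤ −0.95 / ≥ +0.95); threshold
  exceedance for longitudinal flags: strict (>).
* Kappa degeneracies return 1 flagged `degenerate` and are excluded from
  weighted averages; undefined ratios are `NA`, never 0.
* All randomness flows through explicit seeds; generators and resamplers
  restore the caller's RNG state. Identical config + seed ⇒ byte-identical
  pipeline outputs.
* CSV outputs carry a `#mitovar:<schema>/<version>` header line; readers
  reject unknown schemas. Ingested fibre rows with non-finite or
  non-positive intensities are dropped with a logged count.

## 7. Known limitations

* The frequentist classifier's false-positive behaviour depends strongly on
  the disparity/batch parameters; its benchmark numbers on synthetic data
  characterise the failure mode qualitatively, not quantitatively.
* Consensus certainty with three investigators is coarse (step 1/3), so the
  ±0.95 rule effectively requires unanimity; more investigators refine it.
* Variability thresholds inherit the generator's drift and batch settings;
  on real data they must be recomputed from real per-section distributions
  (the pipeline accepts ingested fibre tables and annotations for exactly
  that purpose).
* Biopsy positions other than L-split separations are conventions, not
  measurements; only the L-split strategy is anchored to a known distance.
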