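---
title: "Methods: stacked Random-Forest SDMs and richness mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked Random-Forest SDMs and richness mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksdm)
```

## The modelling problem

Richness mapping for rare plants proceeds from presence-only records: for
each species we know a set of grid cells where it was observed, and nothing
reliable about where it is absent. The workflow implemented here follows the
standard stacked-SDM recipe: fit a per-species climatic suitability model
against pseudo-absences, binarise the predicted suitability at a
species-specific threshold, and count predicted presences per cell and per
reporting zone — under a baseline climate and under warming scenarios
predicted with the *same* fitted models. The scientific quantity of interest
is not any single species' map but the spatial and temporal pattern of the
stacked counts.

All data structures are tabular tibbles or small S3 objects wrapping
matrices; every stochastic step draws its seed deterministically from one
pipeline seed via `derive_seed()`, so a run is reproducible bit for bit.

## The suitability model

Each species is modelled with a Random-Forest probability classifier
(`randomForest`, 500 trees, 2 candidate predictors per split) on six
bioclim-style predictors: annual mean temperature (BIO1, °C), mean diurnal
range (BIO2, °C), isothermality (BIO3, unitless), annual precipitation
(BIO12, mm), and wettest/driest-month precipitation (BIO13/BIO14, mm).
Training sets are *matched*: pseudo-absences equal the presence count, drawn
uniformly from the masked study area. Known presence cells are excluded from
the pseudo-absence pool by default — sampling a presence as an absence
injects label noise with no compensating benefit — but
`sample_pseudo_absences(exclude_presences = FALSE)` restores fully
unconstrained background sampling for sensitivity analyses.

Remaining forest hyperparameters stay at library defaults (node size 1,
unlimited depth) and are recorded in the run manifest. One degenerate case
is intercepted before it reaches the split search: when every predictor is
constant on the training rows, no valid split exists, and the model reduces
to predicting the class prevalence (0.5 under the matched design).

## Evaluation protocol

Performance is estimated by 10 repetitions of stratified 5-fold
cross-validation; pseudo-absences are resampled independently in every
repetition, so the evaluation integrates over the background-sampling noise.
Folds are stratified by class, keeping every fold at the 1:1 balance.
Species with fewer presence cells than folds fall back to `n_folds =
n_cells` (minimum 2) and carry a `reduced_folds` flag; such species are
modelled, but their metrics should be read with caution.

Three metrics are computed on each held-out fold:

* **AUC** via the Mann–Whitney rank-sum identity (ties half credit); a
  property test asserts exact agreement with brute-force pair counting.
* **TSS** = sensitivity + specificity − 1, and **Cohen's κ**, both at the
  fold's TSS-maximising threshold. The protocol does not prescribe which
  cutoff the fold-level TSS/κ should use; the TSS-max cutoff keeps them
  consistent with the thresholding rule used for range maps. Under the
  matched design the test sets have balanced class margins, where κ and TSS
  coincide algebraically — visible throughout the demo outputs.

The TSS-maximising threshold scans midpoints between consecutive distinct
scores plus {0, 1}; since TSS is piecewise constant between observed scores
this equals a dense grid scan, and the *smallest* maximiser is returned so
ties resolve reproducibly. Per-species mean AUC is graded into half-open
decimal performance classes (Perfect exactly 1.0, Near-perfect [0.99, 1),
Excellent [0.90, 0.99), Very Good, Good, Fair, Poor, Random < 0.5) that
cover [0, 1] without gaps; cohort percentages are rounded half-up to one
decimal, so columns may not sum to exactly 100.

The species-level threshold used for range maps is the TSS-max threshold of
the *pooled* held-out predictions across all folds and repetitions. Pooling
was chosen over averaging per-fold thresholds because it yields a single
defensible aggregate with the same optimality property as its inputs;
per-fold thresholds remain available in the CV records. The baseline
threshold is applied unchanged to every scenario surface.

## Permutation importance

Variable importance is the mean decrease in held-out accuracy when one
predictor's column is shuffled (10 shuffles per variable), accumulated over
every fold of every repetition. Held-out data rather than the out-of-bag
sample keeps the importance aligned with the cross-validation design. Raw
values are clipped at zero (a shuffled column can beat the intact one by
chance for uninformative predictors), normalised to sum to 1 per species,
and ranked 1–6 with ties broken by the fixed variable order BIO1 < BIO2 <
BIO3 < BIO12 < BIO13 < BIO14, so ranks are always a permutation — a cohort's
mean ranks therefore average to exactly 3.5, a useful invariant check. The
top-three composition types each species as temperature-centred,
precipitation-centred, or mixed.

## Richness stacking and zonal aggregation

Binarisation uses `suitability >= threshold`. The ≥ convention (rather than
strict >) keeps cells whose score equals a candidate threshold stable across
replications; `binarize(strict = TRUE)` is available. Cell richness is the
sum of binary maps; zone richness uses the any-suitable-cell rule, so a
zone's species count always dominates its best single cell. Richness
classes come in two schemes — four 10-wide classes to 40, or six 5-wide
classes to 30 — as half-open bins `[lo, hi)` with a closed top bin, which
resolves the overlap in conventionally printed labels ("5–10, 10–15"): a
count of 10 is "10–15". Which scheme a run uses is a configuration choice;
counts above a scheme's maximum land in the top class with a warning.
Scenario-versus-baseline change is reported as per-zone deltas and a
class-transition tally.

## The virtual-species generator

Real occurrence archives and 1-km national climate grids are typically not
redistributable, so the package's test bed is synthetic:

* **Climate** (`generate_climate()`): each layer is a deterministic trend
  plus spatially autocorrelated noise, built by Gaussian-smoothing white
  noise with kernel width `spatial_corr_length` (default 6 cells) — the
  simplest reproducible random-field generator. BIO1 carries a monotone
  south-to-north cooling gradient (≈16 °C down to ≈4 °C) so that latitude is
  a real, recoverable signal. Precipitation is built driest-month first
  (BIO14 ≈ 15–60 mm; BIO13 = BIO14 + a nonnegative field ≈ 250–400 mm;
  BIO12 = BIO13 + a nonnegative field ≈ 1100–1500 mm), which makes the
  nesting BIO12 ≥ BIO13 ≥ BIO14 ≥ 0 true cell-wise *by construction*. BIO3
  is BIO2 divided by an internally generated annual range × 100, bounded in
  (0, 100]. Magnitudes were fixed once to resemble temperate-monsoon
  normals. The land mask is carved from a smoothed noise field so it forms
  coastline-like blobs (default 90% of cells).
* **Scenarios** (`generate_scenario()`): spatially uniform warming deltas
  and multiplicative precipitation factors (which preserve nesting), plus an
  optional latitudinal ramp. The generator deliberately does not emulate
  multi-model ensemble climatology — a controllable trend is all the
  downstream stages need.
* **Species** (`generate_virtual_species()`): true suitability is the
  product of per-variable responses (Gaussian, logistic, or flat), rescaled
  to [0, 1] — the product form is standard virtual-species practice and
  keeps gradients smooth. Presences are drawn without replacement weighted
  by suitability; a `detection_noise` fraction is drawn uniformly from the
  mask instead, emulating misdetection and positional error.
* **Zones** (`generate_zones()`): seeded region growth from k random cells
  over 4-neighbourhoods; unreached mask components attach to the nearest
  seed, so the zones always partition the mask exactly.

What the generator does *not* emulate: topography and microclimate, spatial
sampling bias in occurrence effort, dispersal limitation, biotic
interactions, and non-climatic habitat filters. Recovery tests on this
test bed therefore demonstrate that the pipeline machinery is correct and
well calibrated — not that climatic SDMs suffice for any particular real
flora.

## Calibration of the recovery experiments

Two generator settings deserve explanation because they bound what the
recovery tests can show:

* With a `detection_noise` of 0.1, one presence in ten carries no climatic
  signal, which caps the achievable AUC near 0.9 · AUC_clean + 0.05
  regardless of model quality.
* The *achievable* clean AUC is itself bounded by the sampling design:
  presences are suitability-weighted rather than thresholded, so broad
  niches produce heavily overlapping presence/absence suitability
  distributions. A Bayes-optimal scorer on a niche with sd ≈ 0.3 × the
  predictor's SD only reaches ≈ 0.78.

The recovery experiments therefore use *narrow* niches (sd = 0.05 × the
layer SD), as appropriate for range-restricted species, which put the noisy
ceiling near 0.91 and leave the test measuring engine recovery rather than
generator sampling variance. The default cohort generator draws niche
breadths in [0.04, 0.3] × SD, spreading species across the whole
performance-class range, with presence counts log-uniform between 2 and a
few hundred cells — mirroring the long-tailed sample sizes of real
endangered-plant archives.

## Numerical and interface conventions

* Cells are 1-based `(row, col)` with row 1 southernmost; each cell covers
  the half-open square `[edge, edge + cell_size)`, so a point on a cell's
  upper or right edge belongs to the next cell. Synthetic occurrences are
  emitted at cell centers and snap back to their source cells exactly.
* Erroneous occurrence records are operationalised as: non-finite
  coordinates, outside the grid, or on masked-out cells; they are dropped
  and counted per species.
* The collinearity screen (greedy, priority order BIO1 > BIO14 > BIO2 >
  BIO12 > BIO3 > BIO13, reflecting the primacy of coarse thermal and
  dry-season moisture gradients) guarantees max pairwise |r| ≤ 0.7 among
  retained variables; a constant layer's undefined correlations are treated
  as 0 with a warning.
* Rasters are exchanged as ESRI ASCII grids (plain text, exact double
  round-trip); all tables as CSV. The run manifest (JSON) records the
  configuration snapshot, versions, per-stage timings, flags, and every
  exclusion with its reason.

## Problem sizes used by the test-suite

Unit tests run on grids between 2 × 2 toys and 32 × 32 fields with 2-fold
repetition counts; the acceptance checks use a 64 × 64 grid with the full
10 × 5 protocol for recovery and null calibration, a 100 × 100 grid for the
richness oracles, a 48 × 48 twelve-species cohort for the directional
scenario response, and the bundled 20-species demo configuration (five
repetitions, two scenarios) for end-to-end determinism. These sizes were
chosen so the whole suite exercises every code path at study-like
resolution while remaining comfortable to run on a laptop.

## Known limitations

* Pseudo-absence evaluation inflates discrimination metrics when species
  prevalence is high; AUC values are comparable within a cohort modelled
  this way, not against presence-absence studies.
* The fallback for 2–4-cell species keeps them in the cohort but their
  metrics rest on very few held-out points; the `reduced_folds` flag is the
  signal to treat them descriptively.
* Importance ranks of strongly correlated predictors (here the nested
  precipitation triplet) share credit; the pattern typing on the top three
  ranks is more robust than individual ranks 4–6.
* Scenario projections reuse baseline-fitted models; no novel-climate
  extrapolation check is performed, so scenario suitability far outside the
  baseline predictor range is an extrapolation like in any correlative SDM.
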