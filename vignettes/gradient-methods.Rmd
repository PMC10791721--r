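---
title: "Connectome gradients, segregation metrics and trait associations"
author: "gradientScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome gradients, segregation metrics and trait associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradientScope)
```

## The model

Resting-state functional connectivity between cortical parcels can be
summarized by a small number of *gradients*: components of a low-dimensional
embedding of the parcel-by-parcel correlation structure. The principal
gradient typically runs from unimodal (sensory) cortex to transmodal
(default-mode) cortex, and a parcel's score is its coordinate along that
axis. Differences between people in how far apart networks sit along the
gradient quantify the *integration/segregation* of their connectomes; the
pipeline in this package relates those differences to questionnaire traits
(the 50-item AQ for broad autistic-like traits, the 42-item GSQ for sensory
sensitivity) while accounting for age, gender and head motion.

The processing chain is:

1. **Connectome.** Per subject, Pearson correlations of parcel-mean time
   series (`correlateTimeSeries`), optionally after OLS residualization on
   supplied motion traces (`regressMotion`). The group connectome is the
   element-wise Fisher-z mean, back-transformed (`groupAverage`); the
   diagonal is excluded from the transform (atanh(1) is infinite) and
   restored as 1.
2. **Gradients.** Each row of the connectome is sparsified to its top
   `1 - sparsity` fraction of entries (`sparsifyRows`, default 0.95),
   retaining each parcel's strongest connections. Cosine similarity of the
   sparsified rows (`cosineAffinity`) yields the affinity matrix, whose
   column-centred principal components are the gradients
   (`pcaGradients`, default 10 components with explained-variance
   fractions). Individual gradients are brought into the group frame by
   orthogonal Procrustes alignment — rotation/reflection only, no scaling
   or translation (`procrustesAlign`).
3. **Segregation metrics.** From aligned gradients and a parcel-to-network
   partition: pairwise network median distance (gradient 1), network peak
   distance (KDE mode locations), gradient range and SD, per-network and
   global eccentricity, within- and between-network dispersion, and binned
   score distributions (`segregationReport`, `binGradient`).
4. **Association.** Spearman rank correlation of every metric against every
   trait (`runAssociationGrid`), Bonferroni-controlled at
   `alpha / (pairs x traits)` — 42 tests for 7 networks and two traits,
   threshold displayed as 0.0012 — plus covariate-adjusted OLS models
   (`fitCovariateModel`) with AQ, GSQ, age, gender, FD and DVARS entered on
   their raw scales.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sparsity` | 0.95 | fraction of each connectome row zeroed before the kernel; 0.95 keeps the top 5% of connections per parcel |
| `kernel` | cosine | similarity of sparsified connectivity profiles |
| `nGradients` | 10 | embedding components extracted and aligned |
| `eccentricityDims` | 3 | leading gradients spanning the eccentricity/dispersion space |
| `nBins` | 50 | histogram bins for gradient-score distributions |
| `alpha` | 0.05 | family-wise level before Bonferroni correction |

Several definitional choices were genuinely open and are fixed as follows.

- **Sparsification order.** Entries are removed by *signed* value —
  negatives first — zeroing exactly `floor(sparsity * P)` per row, with
  ties broken toward the lower parcel index so results are reproducible
  across platforms. At 0.95 sparsity the survivors are overwhelmingly
  positive, so retaining signed values is immaterial in practice but keeps
  the rule total.
- **PCA sign convention.** Component signs are arbitrary; each component is
  flipped so its largest-magnitude score is positive, and the group
  reference then fixes signs for all aligned subjects.
- **Eccentricity aggregate.** A network's eccentricity is the *mean*
  Euclidean norm of its parcels over the first three gradients; a
  sum-of-squares variant is available (`aggregate = "sumsq"`) since both
  aggregations appear in the field's usage. Global eccentricity is the mean
  norm over all parcels.
- **Peak location.** The mode of a network's score distribution is the
  argmax of a Gaussian kernel density estimate with Silverman's bandwidth
  on a 512-point grid spanning `[min - 3h, max + 3h]`; ties resolve to the
  lower score. Peak metrics are unreliable for flat distributions, which
  is a documented weakness of the metric itself, not of the estimator.
- **Gradient SD** uses the sample (n-1) convention.
- **Spearman p-values** use the two-sided t approximation
  `t = rho * sqrt((n-2)/(1-rho^2))`; an exact permutation enumeration is
  used as a test oracle at tiny n.
- **Median splits** send subjects at the threshold to the low group
  (`<= median` is "low"), which reproduces unequal group sizes under ties.
- **Framewise displacement** is the mean over the twelve realignment
  parameters of the median absolute temporal derivative — deliberately the
  median-then-mean form rather than the more common summed-displacement
  variant, which is available via `method = "sum"`. DVARS is the RMS over
  in-mask voxels of the temporal derivative, averaged over volume pairs.

## The synthetic cohort generator

No subject-level imaging data ship with the package; every pipeline stage
is exercised on synthetic cohorts (`cohortSpec`, `simulateCohort`) built to
emulate the statistical structure the analysis assumes:

- **Latent geometry.** Each of the 7 networks has a centre on three latent
  axes, ordered along axis 1 from visual to default. Parcels scatter around
  their network centre with SD `sigmaParcel = 0.3`, so network score
  distributions overlap along the axis as real gradient histograms do. The
  layout is drawn once per cohort from the root seed: parcel topography is
  an atlas-level property, identical across subjects.
- **Edges.** Correlations follow a low-rank Gram model in Fisher-z space:
  `z_ij = baseline + <x_i, x_j> / lambda + blockBonus * [same network] +
  noise`, `r_ij = tanh(z_ij)`. Parcels pointing the same way in latent
  space correlate positively, opposite ends anticorrelate — the structure
  PCA embeddings of connectomes assume. An exponential distance-decay
  kernel was considered and rejected: under rank-based row sparsification
  it is nearly scale-invariant, so a planted expansion of the axis barely
  moves (and in fact slightly *shrinks*) the measured gradient distance.
  The tanh link also avoids the plateau a hard clip at |r| = 0.99 would
  introduce, keeping the measured distance strictly increasing in the
  planted expansion.
- **Planted effect.** Each subject has an expansion score that multiplies
  the axis-1 coordinates by `1 + betaExpand * expansion`
  (`betaExpand = 0.2`). The expansion score is coupled to the GSQ-like
  trait through a Gaussian copula with target Spearman 0.4 and is
  decorrelated from the AQ-like trait by construction (the AQ-GSQ latent
  correlation of 0.3 is accounted for when building the copula weights).
  Trait totals are truncated normals matching the study-scale moments
  (GSQ 50.1 +/- 18.2 in [0, 168]; AQ 19.6 +/- 5.3 in [0, 50]).
- **Items.** GSQ item responses (42 items, 7 modalities x 3 hyper + 3 hypo,
  each 0-4) are drawn to reproduce each subject's total exactly, so
  hyper + hypo subscales and the 7 modality subscales always reconstruct
  the total. AQ items are 4-level responses placed on or off a randomly
  keyed pole per item; the scoring key is emitted with the data rather than
  hard-coded.
- **Motion.** Realignment traces are Gaussian random walks with step SD
  `targetFD / qnorm(0.75)`, so the median absolute derivative matches the
  target FD (default 0.03 mm with lognormal between-subject spread,
  spanning roughly 0.01-0.07 mm); masked voxel series are white noise with
  SD `targetDVARS / sqrt(2)`.

What the generator does *not* emulate: realistic BOLD spectra, spatial
autocorrelation within parcels, distance-dependent motion artefacts, or
any empirical parcel geometry. Passing tests therefore demonstrate that
the pipeline recovers the effects it assumes from data with the assumed
low-rank structure — not that those effects exist in any real population.

## Numerical choices and degenerate inputs

- Matrices asymmetric beyond 1e-8 are rejected rather than silently
  averaged; asymmetry at or below that tolerance is symmetrized.
- Off-diagonal |r| >= 1 - 1e-12 (duplicated signals in degenerate
  simulations) is clipped to the bound with a warning before the
  z-transform; real duplicates still surface through the warning count.
- `pcaGradients` errors on affinities whose centred rank is below the
  requested component count, and on zero-variance (all-rows-identical)
  affinities.
- `cosineAffinity` errors on all-zero rows, naming the parcel; at the
  default sparsity this occurs only if a row has no nonzero survivors.
- Bin edges default to the observed score range; averaging histograms
  across subjects requires explicitly shared edges and errors otherwise.
- All randomness flows from one root seed; per-subject substreams are drawn
  up front so cohorts are reproducible and subject order is immaterial.

## Scale of the shipped checks

The package's tests and the acceptance script run the full pipeline at a
desk scale chosen to keep the whole suite in the low minutes: cohorts of
n = 200 subjects at P = 100 parcels for parameter-recovery replicates
(100 cohorts), n = 60-150 at P = 30-60 for end-to-end pipeline checks, and
n = 10000 subjects for trait-moment calibration. The default `cohortSpec()`
mirrors the study shape (n = 370, P = 400, 7 networks) and runs the same
code paths.

## Known limitations

- The pipeline starts at parcellated matrices or time series; surface
  processing, realignment and parcellation are upstream concerns.
- Only the cosine kernel and PCA embedding are implemented; diffusion-map
  embeddings and joint multi-dataset alignment are out of scope.
- The Procrustes step aligns to a single group template in one pass; no
  iterative re-referencing is performed.
- Peak-distance metrics inherit the instability of mode estimation on flat
  distributions.

## A worked example

```{r example, eval = FALSE}
spec <- cohortSpec(nSubjects = 150, nParcels = 100, seed = 7)
cohort <- simulateCohort(spec)
out <- runPipeline(runConfig(), cohort = cohort)
grid <- out$grid
subset(grid, metric == "median_distance" &
             network_a == "visual" & network_b == "default")
```

The visual-default median distance row for the GSQ-like trait shows a
positive Spearman correlation near the planted 0.4 that survives the
42-test Bonferroni threshold, while the AQ-like row stays null -- the
pattern the pipeline is designed to detect.
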