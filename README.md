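# gradientScope

Macroscale functional-connectome gradient analysis as a reusable, tested R
package. The scientific question it serves: do individual differences in
how segregated the cortex's functional networks are along the principal
connectivity gradient track questionnaire-measured traits — broad
autistic-like traits (AQ) and sensory sensitivity (GSQ) — once age, gender
and head motion are accounted for?

The package is aimed at researchers working with parcellated resting-state
data (parcel-mean time series or parcel-by-parcel Pearson correlation
matrices) who want the full chain from connectomes to motion-aware
brain-behaviour statistics, plus a synthetic cohort generator so every
stage is testable without any imaging data.

## The method

For each subject with parcellated time series `Y` (T x P):

1. **Connectome** `R = cor(Y)`; group connectome `tanh(mean(atanh(R_s)))`
   over subjects (Fisher-z averaging, diagonal excluded).
2. **Gradients.** Row-sparsify `R` keeping the top `1 - s` fraction of each
   row (default sparsity `s = 0.95`); form the cosine affinity
   `A_ij = <r_i, r_j> / (|r_i||r_j|)` of sparsified rows; extract the top
   10 principal components of the column-centred affinity. The component
   scores are the gradient coordinates of each parcel, with
   explained-variance fractions `d_k^2 / sum(d^2)`. Individual embeddings
   are Procrustes-rotated (orthogonal, no scaling) onto the group
   gradients so scores are comparable across subjects.
3. **Segregation metrics** from aligned gradients and a parcel-to-network
   partition (7 networks): network median distance along gradient 1,
   gradient range and SD, KDE-based network peak distance, eccentricity
   (mean parcel norm in gradient-1:3 space), within-network dispersion
   (sum of squared distances from the network's median centroid) and
   between-network dispersion (distance between centroids; at one
   dimension this *is* the median distance).
4. **Association.** Spearman rank correlation of each metric with each
   trait over subjects — 21 network pairs x 2 traits = 42 tests per
   pairwise metric family, Bonferroni threshold 0.05/42 = 0.0012 — and
   ordinary-least-squares models of each metric on AQ, GSQ, age, gender,
   FD and DVARS with two-sided t-tests on raw-scale coefficients.

Head-motion summaries follow the median-absolute-derivative convention:
FD is the mean over the 12 realignment parameters of the median |temporal
derivative|, DVARS the mean over volume pairs of the RMS voxel-wise
derivative.

## Worked example

```r
library(gradientScope)

spec   <- cohortSpec(nSubjects = 150, nParcels = 100, seed = 7)
cohort <- simulateCohort(spec)          # planted GSQ effect, null AQ
out    <- runPipeline(runConfig(), cohort = cohort)

subset(out$grid, metric == "median_distance" &
                 network_a == "visual" & network_b == "default")
```

```
          metric network_a network_b     trait    rho        p   n bonferroni stars
 median_distance    visual   default  aq_total -0.174 3.28e-02 150      FALSE     *
 median_distance    visual   default gsq_total  0.325 5.03e-05 150       TRUE   ***
```

The generator plants a Spearman correlation of 0.4 between the GSQ-like
trait and the expansion of the principal gradient: the visual-default
median distance recovers it (rho = 0.325 here) and survives the 42-test
Bonferroni threshold (`bonferroni = TRUE`). The AQ-like trait is
null-coupled by construction; its nominally significant cell (one star) is
exactly the kind of chance finding the correction exists to absorb. The
group gradients for this cohort put 47.6% of affinity variance on
gradient 1 (`explainedVariance(out$groupGradients)`).

A thin command-line wrapper over the same functions ships at
`inst/cli/gradientscope.R` (`run`, `generate-cohort`, `gradients`
subcommands; exit codes 0/1/2 for ok / input error / compute error).

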