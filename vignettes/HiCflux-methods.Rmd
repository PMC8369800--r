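---
title: "HiCflux: models, estimators and numerical choices"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HiCflux: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

HiCflux analyzes multi-timepoint Hi-C experiments in which chromatin
condensates are transiently disrupted (for example by 1,6-hexanediol) and
the genome is allowed to recover. This vignette documents the generative
model behind the synthetic data, the estimators implemented at each
analysis stage, and the numerical choices that matter for reproducing
results. It intentionally quotes no empirical numbers; every quantitative
claim the package makes is computed by its test suite and by
`scripts/acceptance.R`.

# The synthetic contact-map model

All statistics in the package are validated against simulated matrices
with planted ground truth. A chromosome of `nBins` bins at `binSize`
resolution carries a Poisson intensity for the cis contact between bins
$i$ and $j$:

$$
\lambda_{ij} \;\propto\; |i-j|^{-\alpha}
\; e^{\,c\, e_i e_j}
\; t^{\,[i,j \text{ in the same TAD}]}
\; \ell^{\,[i,j \text{ near a planted anchor pair}]}
$$

with

* $\alpha$ (`decayExponent`): the power-law distance decay;
* $e_i$: the planted compartment profile, piecewise constant on segments
  whose breakpoints are a subset of TAD boundaries, with alternating sign
  and amplitude `compartmentAmplitude`;
* $t$ (`tadBoost`): a multiplicative boost inside TAD blocks whose sizes
  are drawn uniformly between 8 and 16 bins;
* $\ell$ (`loopBoost`): a boost on 3×3 neighborhoods of planted anchor
  pairs, half at short range (25–100 bins apart) and half at long range
  (at least half the chromosome apart), all kept away from the matrix
  edge.

Replicate matrices are independent Poisson draws scaled to a target
`depth` (total cis counts). Because intensities are known exactly, every
estimator can be checked against the planted truth rather than against
another implementation.

## Perturbation schedules

A `perturbationSchedule` turns the static model into a timecourse.
Baseline is always the first timepoint; each treated timepoint applies:

* `attenuation`: multiplies intensities at genomic separations of at
  least `longRangeMinBp` (default 5 Mb), modelling the loss of long-range
  contacts;
* `ampMultiplier`: scales the compartment amplitude, modelling the
  transient strengthening of checkerboard segregation;
* `homogenize`: compresses $|e_i|$ toward its segment-wise mean, so that
  same-type interactions become more uniform without changing signs. This
  emulates the observed homogenization of compartmental interactions
  while leaving the A/B partition intact;
* `loopAttenuation`: attenuates only the long-range planted anchor
  neighborhoods, leaving short-range loops untouched;
* `switches`: planted compartment sign flips in four subtypes (early or
  late onset crossed with recoverable or irrecoverable at withdrawal);
* `tadEvents`: planted boundary fusions, shifts (by two bins) and
  separations. Deleted boundaries are drawn away from compartment-segment
  edges so that a TAD event never silently changes the compartment
  profile.

`identitySchedule()` keeps every knob at its neutral value and is the
null model used for false-positive rate checks.

# Estimators by stage

## Balancing and observed/expected

`downsampleToMin` equalizes sequencing depth across matrices by drawing,
without replacement, a fixed number of the pooled counts of each matrix
(a multivariate hypergeometric draw, implemented by sampling count
indices and binning them with `findInterval`). `iceBalance` is standard
iterative correction: bins below the `maskQuantile` coverage quantile are
masked, row sums are equalized to machine tolerance (`tol`, default
1e-6, `maxIter` 200), and the result is rescaled to preserve the total.
`oeTransform` divides each diagonal by its unmasked mean, so every
distance stratum has mean exactly 1 and all-zero strata become `NA`.

## Distance decay

`rcp` computes the relative contact probability curve (per-distance mean
normalized to unit sum), `rcpFoldChange` the log2 ratio between
conditions, and `changedFraction` the fraction of bin pairs beyond a
distance cutoff whose counts changed by more than a fold threshold.

## Compartments

`computePC1` takes the leading eigenvector of the Pearson correlation of
the O/E matrix (computed on complete columns when no values are missing,
pairwise-complete otherwise), orients it by correlation with a signal
track that is enriched in A-type chromatin, and scales it by its 99th
percentile. `smoothByTADs` replaces each TAD's bins with their mean —
compartment identity is a domain-level property. `perBinStrength` is the
ratio of mean same-type to mean cross-type O/E per bin (a perfect
checkerboard with O/E values 2 and 0.5 scores exactly 4). `saddle`
aggregates O/E into a 50×50 grid of PC1 quantile pairs (clipping the
0.5% tails) and scores segregation by the extreme-20% corner ratio.
`homogeneity` of a vector of group means is mean² over sample variance —
larger values mean more uniform same-type interactions —
and `sameTypeGroupMeans` feeds it decile-wise means of same-type O/E.
`classifySwitch` labels runs of bins by their A/B trajectory across all
timepoints and assigns the four onset/recovery subtypes.

## TADs

`binSignal` is a TopDom-style diamond mean; `callTADs` takes smoothed
local minima and keeps those where the diamond contrast passes a
one-sided Wilcoxon test. `directionIndex` counts upstream and downstream
contacts per bin and replicate; `testBoundaryChange` pools replicates
into a log-ratio z-statistic per candidate boundary, adjusts with
Benjamini–Hochberg, and labels boundaries lost, gained or stable.
`classifyReorganization` pairs lost and gained boundaries within a shift
tolerance of two bins (ties resolved leftward) into fusion, shifting and
separation events. `ata` (aggregate TAD analysis) rescales each TAD with
its flanks onto a common grid by separable bilinear interpolation — the
weight matrix form `W %*% sub %*% t(W)`, which is algebraically
identical to bilinear interpolation of the grid but orders of magnitude
faster than pointwise evaluation.

## TAD-pair interactions

`aggregateTADPairs` sums raw counts per TAD pair and fits the expected
value as the product of TAD marginals times a distance factor estimated
by robust log–log lowess (`f = 0.3`, three robustness iterations) on the
pairwise aggregates. Lowess is used instead of the raw per-distance mean
so that a handful of strongly enriched pairs cannot inflate their own
expectation and mask themselves. `callSignificant` computes a
hypergeometric upper-tail p-value per pair, adjusts with
Benjamini–Hochberg and requires both FDR below `fdrThresh` and
observed/expected at or above `minOE` (default 10) — the O/E floor is
what separates condensate-sized enrichment from diffuse elevation.
`apa` (aggregate peak analysis) averages O/E submatrices around anchor
pairs and reports the center score against the mean of an off-corner
reference.

## Enrichment and imaging statistics

`foldEnrichment`, `regionVsRestTest`, `pseudoClusterCorrelation` and
`boundaryPeakDensity` relate signal tracks to called regions using
GenomicRanges overlaps. `ripleyK` is the exact unedged estimator
$\hat K(r) = \frac{A}{N(N-1)} \sum_{i \ne j} 1[d_{ij} \le r]$; no edge
correction is applied, so for complete spatial randomness on the unit
square the expectation falls below $\pi r^2$ by a boundary term of order
$r^3$ — tests therefore evaluate CSR behavior only at radii that are
small relative to the window. `msd` averages squared displacements over
all overlapping origins; the 3D estimate is 1.5 times the observed 2D
value under isotropy. `fitDiffusion` fits the first lags of the 2D curve
and divides the slope by 4.

# The pipeline

`runPipeline` chains the stages over a multi-chromosome timecourse —
simulate, downsample, balance, O/E, decay, compartments, TADs,
interactions, enrichment — and writes tab-separated tables plus a
`manifest.json` with MD5 checksums of every output. All randomness
derives from the single `seed` in `pipelineConfig`, so two runs of the
same configuration produce byte-identical outputs; the test suite and
the acceptance script verify this on reduced problem sizes (two to five
chromosomes of 150–500 bins), which complete in minutes.

# Scope and limitations

The generator is deliberately minimal: Poisson counts without
overdispersion, piecewise-constant compartment profiles, rectangular TAD
boosts, and a single chromosome per matrix (trans contacts are not
modelled). It is designed to make estimator behavior checkable, not to
reproduce the full complexity of experimental Hi-C libraries. Fragment-
or restriction-site-level biases, copy-number variation and
translocations are out of scope, as is statistical phasing of single
cells. The boundary z-test assumes replicate direction indices are
approximately log-normal, which holds at the simulated depths but may
need revisiting for very sparse data.
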