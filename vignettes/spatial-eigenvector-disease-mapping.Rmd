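---
title: "Spatial eigenvector modelling of incidence rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial eigenvector modelling of incidence rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnmepi)
```

## The model

Area-level disease rates are spatially autocorrelated, and the processes
behind that structure — demographics, environment, exposure history — are
collinear with one another and often unmeasured. Principal coordinates of
neighbor matrices (PCNM) sidestep both problems by deriving regression
predictors from the site geometry alone. The construction:

1. Each area is represented by one planar point; areas with several
   settlement concentrations use the population-weighted centroid
   (`weightedCentroids()`).
2. The Euclidean distance matrix **D** is truncated at *t*, the longest
   edge of its minimum spanning tree (`mstThreshold()`): `w_ij = d_ij` for
   `d_ij <= t` (the threshold itself is inclusive) and `w_ij = 4t`
   otherwise. *t* is the smallest radius at which all sites form one
   connected graph, and it bounds the finest wavelength the eigenvectors
   can resolve.
3. `computeEigenmap()` applies a principal coordinate analysis to **W**:
   the Gower transform `A = -0.5 * W^2`, double-centering, and a symmetric
   eigendecomposition. Eigenvectors with positive eigenvalues model
   positive spatial autocorrelation and are kept, ordered broad to fine;
   negative-eigenvalue vectors model negative autocorrelation and are out
   of scope here.

The retained score columns are exactly zero-mean and mutually orthogonal
(a consequence of double-centering and the symmetric eigendecomposition),
which is the statistical point of the method: OLS coefficients on any
subset of eigenvectors are invariant to adding further ones, so there is no
multicollinearity among the spatial predictors by construction.

The response is the unadjusted pooled rate, `scale * sum(cases) /
sum(person_years)` per area with `scale = 1000` (`pooledRate()`). Pooling
over all years *before* dividing absorbs zero-case years in small areas.
Age adjustment is deliberately not implemented: the method's premise is to
test how much of the variation the spatial vectors alone explain, without
demographic information. Sex-specific responses (breast- or prostate-type
analyses) require sex-specific denominators; supplying a both-sex
denominator is an error rather than a warning, since the resulting rates
would be silently wrong by a factor near two.

`forwardSelect()` runs forward stepwise OLS under the double stopping
criterion: the candidate with the smallest entry p-value (partial F-test)
enters while p < alpha, and selection also stops once the running adjusted
r-squared reaches the adjusted r-squared of the model containing *all*
candidate eigenvectors. Because many eigenvectors can proxy the same
spatial process, alpha-only forward selection keeps entering vectors well
past the point of diminishing returns; the all-vector adjusted r-squared is
a natural ceiling for how much spatial signal there is to explain. The
returned model is the first along the path to reach the ceiling, so its
adjusted r-squared may slightly exceed it; the trace records both stops.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `multiplier` | 4 | — | fill value `multiplier * t` for beyond-threshold pairs; the canonical constant. Must exceed 1. |
| `positivity_tol` | 1e-9 | relative | eigenvalues above `positivity_tol * max(lambda)` count as positive; separates structure from floating-point zeros. |
| `alpha` | 0.05 | — | entry level for forward selection and the normality gate. |
| `scale` | 1000 | person-years | rate denominator (cases per 1,000 person-years). |
| `cutoff` | 3 | sd units | studentized-residual outlier threshold. |
| `snr` | 5 | — | signal-to-noise ratio `var(signal)/noise_sd^2` used by the synthetic scenarios when `noise_sd` is not given. |

Coordinates are assumed to be projected planar meters; the package never
reprojects. Inputs whose coordinates all fall inside the
longitude/latitude range are rejected unless the caller passes
`planar = TRUE`, because silently treating degrees as meters is the classic
failure mode of distance-based methods.

## Numerical and design choices

* **Centering convention.** "Centering" the connectivity matrix admits two
  readings; the package uses the standard PCNM/PCoA Gower double-centering
  of `-0.5 * W^2` (recorded as `centering = "gower_sq"`), the construction
  the method's ecology toolchain implements, with `centering = "raw"`
  (double-centering W itself) available for sensitivity analysis.
  Reproducibility of the canonical method was preferred over a literal but
  nonstandard reading.
* **Score scaling.** Columns are unit-norm by default; the regression stage
  is scale-invariant (standardized coefficients), and unit norm is simpler.
  `scaling = "sqrt_lambda"` rescales columns by the square root of the
  eigenvalue, in which case the scores of an *untruncated* map reproduce
  the original intersite distances (the classical PCoA property used by the
  test suite's brute-force oracle).
* **Sign convention.** Eigenvector signs are arbitrary; each column is
  flipped so its largest-magnitude entry (ties to the lowest site index) is
  positive, making outputs deterministic.
* **Entry statistic and ties.** The entry p-value is the partial F-test of
  the entering coefficient (equivalent to the coefficient t-test, and with
  orthogonal predictors to the r-squared-increment test). Ties are broken
  by larger r-squared increment, then by lower eigenvector index —
  preferring broader scales. Selection is pure forward; no removal step.
* **Ceiling fallback.** If the all-candidate model is unfittable
  (`m >= n - 1`) the ceiling is taken from the broadest `floor(n/2)`
  vectors with a warning. With a realistic ratio of positive eigenvectors
  to sites (roughly 0.5–0.65) this does not arise.
* **Normality gate.** The Kolmogorov–Smirnov test with estimated mean and
  sd is anti-conservative; the default is the Lilliefors-corrected version
  (`nortest::lillie.test`), with `method = "plain"` for replicating
  toolchains that use the uncorrected test. Rejected responses are
  log10-transformed.
* **Zero rates under log10** are a hard error by default; pooling over
  enough years is supposed to remove zeros, and silently offsetting would
  hide data problems. `zero_policy = "offset"` adds half the smallest
  nonzero rate and reports the offset.
* **Residuals.** Outlier flags use internally studentized residuals
  (`e_i / (s * sqrt(1 - h_ii))`), matching mainstream statistical-package
  output. Chauvenet's criterion is applied in a single pass; its critical
  value `qnorm(1 - 0.25/n)` exceeds 3 for n ≥ 187, so at a 320-area study
  every Chauvenet flag is also a `|z| > 3` flag.
* **Moran's I** diagnostics use binary within-threshold weights, not the
  `4t`-filled matrix: the fill constant is a device for the
  eigendecomposition, not a meaningful spatial weight. The reference value
  for "no autocorrelation" is `-1/(n-1)`.
* **No multiple-testing adjustment** is applied across separate disease
  models; each disease is a separate analysis by design.

## What the synthetic generator emulates — and what it does not

`makeGridSites()`, `makeRandomSites()`, `simulateResponse()` and
`simulateCaseCounts()` produce, respectively: lattice and uniform-random
irregular layouts at realistic map scales (the built-in "country-scale"
fixture is 320 sites in a 1,100 × 550 km rectangle, mimicking the
magnitude of a national municipality registry); responses that are known
linear combinations of eigenvectors plus Gaussian noise; and Poisson case
counts over person-year denominators around planted rates. All randomness
flows through a single integer seed, truth records replay exactly, and
`recoveryExperiment()` measures planted-vector recovery and spurious
inclusion under both stopping rules on paired simulations.

Real registry data differ in ways the generator does not emulate: sites
cluster along coasts and valleys rather than uniformly; populations (and
hence person-years) span four orders of magnitude across areas, making
rate variance strongly heteroscedastic; counts can be overdispersed
relative to Poisson; and migration decouples residence from exposure.
Passing tests therefore demonstrate that the machinery is correct for the
model class it assumes — not that any particular share of real-disease
variation will be explained. One consequence observed with the generator:
uniform-random layouts of 320 sites yield a positive-eigenvector fraction
of about 0.57–0.63, a little above the ~0.52 seen for real clustered
municipality layouts.

## Problem sizes

The shipped tests and the acceptance script run on deliberately compact
problems chosen to exercise every code path while keeping the suite quick:
brute-force principal-coordinate oracles at 5–12 sites (where literal
double-centering loops are exact), transect and lattice layouts of 36–100
sites for structure and selection properties, 100-replicate recovery and
null experiments on a 10×10 lattice, and 320-site layouts where a
quantity's value depends on that scale (the Chauvenet critical value, the
positive-eigenvector share). None of the methods is size-limited beyond
the O(n^3) eigendecomposition, which handles thousands of sites
comfortably.

## Known limitations

* Only positive-eigenvalue vectors are produced; negative spatial
  autocorrelation is out of scope.
* Exact wavelength per vector is undefined on irregular layouts; sign-change
  counts and Moran's I serve as scale proxies.
* The pipeline assumes person-years are supplied, not derived from annual
  populations; how a registry computed them (mid-year vs year-end) is the
  caller's concern.
* Duplicate coordinates across distinct sites are permitted (they stay
  connected at any threshold) but warn, since they make some score
  columns non-unique.
* Variation partitioning, Bayesian space-time models, and temporal
  eigenvector analysis are complementary techniques, not included.
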