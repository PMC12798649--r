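---
title: "Modeling task activation from connectivity fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling task activation from connectivity fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connfit)
```

## The model

`connfit` asks how well a vertex's resting-state *connectivity
fingerprint* — its vector of Fisher-z correlations to the mean timecourse
of every target brain region — explains that vertex's expected activation
in a cognitive domain. For one region $R$ and one domain $d$, the model
over the region's vertices is ridge regression with an unpenalized
intercept:

$$\hat w, \hat b \;=\; \arg\min_{w,b} \sum_{v \in R} \big(y_v - w^\top x_v - b\big)^2 + \lambda \lVert w \rVert_2^2 .$$

Centering reduces this to the normal equations
$(X_c^\top X_c + \lambda I)\, w = X_c^\top y_c$ with
$b = \bar y - \bar x^\top w$. Because the intercept is unpenalized, the
penalized objective at the solution is no larger than its value at $w = 0$,
hence the in-sample residual sum of squares never exceeds the total sum of
squares and the reported in-sample $R^2 = 1 - \mathrm{SS}_{res} /
\mathrm{SS}_{tot}$ always lies in $[0, 1]$. The in-sample $R^2$ (not an
out-of-fold estimate) is the fit statistic throughout: there is a single
group-level activation map per domain, so there is no out-of-sample map to
predict. The in-sample optimism this induces is what the permutation null
quantifies.

### Penalty selection

The penalty is selected by $k$-fold cross-validation ($k = 5$ by default)
over a deterministic log-spaced grid of at most 100 candidates. The raw
grid spans $[10^{-6}, 10^{4}]$ and is scaled by the mean diagonal of
$X_c^\top X_c$, so the same relative shrinkage is explored regardless of
predictor scale or region size. Folds are a seeded shuffle followed by
contiguous blocks; regions with fewer than $2k$ vertices drop to
$\max(2, \lfloor n/2 \rfloor)$ folds with a warning, and fewer than 4
vertices is an error. Ties in the cross-validation error go to the larger
(more regularized) candidate. A deterministic grid was chosen over a
stochastic black-box optimizer of the same evaluation budget because it
makes every selection exactly reproducible from the seed; the grid bounds
are configuration-exposed. On pure-noise responses the cross-validation
curve is nearly flat across the heavily-regularized end of the grid, so the
selected candidate sits in the top half of the grid in every pilot
replicate but rattles within the top decade; tests assert exactly that.

### Permutation null

The chance distribution for one model shuffles the activation values across
the region's vertices — each vertex keeps its fingerprint, the multiset of
activation values is preserved — and refits at the *true* model's
$\lambda$, 1,000 times by default. The empirical p-value is the strict
exceedance fraction $\#\{R^2_{perm} > R^2_{true}\}/n_{perm}$ (a smoothed
$(k+1)/(n+1)$ variant is available but off by default, matching the
printed formula), and the summary percentile is the nearest-rank 99th
order statistic. Permutation indices derive from a hash of
(master seed, region, domain), so the null of any model is reproducible in
isolation and results are identical for any number of parallel workers.

Two properties of this scheme are worth knowing. First, because permuted
fits are also in-sample ridge fits, their mean approximates the in-sample
optimism at $\lambda_{true}$, which shrinks as region size grows at fixed
target count. Second, reusing the $\lambda$ optimized on the unpermuted
response gives the true model a slight edge, so the test is mildly
anticonservative when the predictor matrix is close to rank-deficient
(pilot runs on nearly collinear designs with as many targets as vertices
showed rejection rates near 0.08 at nominal 0.05). At the conditioning
that the generator's fingerprints actually exhibit, measured type-I error
is within Monte-Carlo error of nominal (see the acceptance tests).

### Group statistics

The inferential layer mirrors standard practice for comparing goodness of
fit across conditions: per-model $R^2$ values are transformed by
$\arcsin\sqrt{R^2}$ to reduce left skew, then

* one-way ANOVA across domain categories with effect size
  $\eta^2 = \mathrm{SS}_{between}/\mathrm{SS}_{total}$ (the identity
  $\eta^2 = d_1 F / (d_1 F + d_2)$ is exposed as a helper and asserted in
  tests);
* pairwise two-sample t-tests over all category pairs (pooled-variance
  Student by default; Welch behind a flag, since printed degrees of
  freedom in comparable analyses are often not integer-consistent with the
  pooled convention), Holm-adjusted over the full family, with Cohen's
  $d$ from the pooled SD;
* paired laterality t-tests per selected domain, pairing each modeled
  left-hemisphere region's fit with its right homolog's (41 pairs at the
  full design, hence 40 degrees of freedom). Both paired effect-size
  conventions are reported ($d_z$ from the SD of differences, $d_{av}$
  from the average group SD) because neither convention is canonical. A
  zero-variance difference vector is an explicit error rather than an
  infinite statistic.

Medians by domain, category, and lobe are reported with the IQR and a
seeded bootstrap standard error of the median (1,000 resamples), since
"standard error of a median" has no closed form at these group sizes. The
ANOVA treats the (region, domain) models as independent observations, with
no correction for the spatial clustering of regions; this matches the
design being emulated and is a documented limitation.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
scaled down from a design of 91,282 grayordinates x 89 connectivity
targets (82 of them modeled), 33 domains in 7 categories, and 4
resting-state runs per subject.

* **Parcellation.** `n_regions_per_hemisphere` modeled regions per
  hemisphere (default 41), each left region paired with exactly one right
  homolog sharing a lobe (round-robin over occipital, temporal, parietal,
  frontal, cingulate, subcortical), plus `n_extra_targets` (default 7)
  midline regions that serve as connectivity targets only. Every target
  region receives vertices — the unmodeled extras are real structures with
  timecourses, they just get no models. Sizes are near-equal by default;
  `size_dispersion` switches on lognormal size heterogeneity, since real
  parcel sizes vary by orders of magnitude.
* **Timeseries.** Each target region carries a latent AR(1) signal per run
  (coefficient `noise_ar_coefficient`, default 0.4, unit stationary
  variance) — chosen as the simplest latent model with controllable
  autocorrelation. A vertex's timecourse is its loading (uniform in
  `loading_range`) on the own-region latent, plus dense Gaussian mixing
  onto *all* target latents (SD `mixing_sd`; fixed by the seed and shared
  across subjects and runs, so group-average fingerprints are stable and
  heterogeneous), plus leakage from two shared noise compartments (WM-like
  and CSF-like multichannel signals driven by a few latent factors —
  the aCompCor targets), plus white noise.
* **Activation.** Given the group fingerprints $X$, each (modeled region,
  domain) gets a weight vector $w \sim \mathcal N(0, I)$ over targets, a
  signal $s = X_R w$, and i.i.d. Gaussian vertex noise whose SD is
  calibrated so that $\mathrm{var}(s) / (\mathrm{var}(s) + \sigma^2)$
  equals the requested `planted_r2` exactly; the region's activation is
  the standardized sum. Ground truth records the (rescaled) weights, noise
  SD, and achieved R² — the recalibrated ratio is asserted to 1e-10 in
  tests. The default planted grid spans `planted_r2_range`
  (0.2–0.95) deterministically, so heterogeneity covers the configured
  range by construction.

What the generator does *not* emulate: cortical mesh geometry and geodesic
smoothing, hemodynamics, spatial autocorrelation of activation maps
(activation noise is i.i.d. across vertices), subject-level idiosyncratic
fingerprints (the group-average regime only), and realistic
region-size distributions by default. Passing tests therefore demonstrate
that the machinery is correct and calibrated under the assumed generative
structure, not that real cortical data satisfy that structure.

## Nuisance regression

aCompCor-style denoising extracts the top five temporal principal
components per noise compartment separately, concatenates them with an
intercept (the analysis being emulated does not state whether an intercept
or detrending was included; we include an intercept and document it), and
residualizes every vertex timecourse by least squares, per run (whether
the original regressed per run or per concatenated session is likewise
unstated; per run is the safer choice). Residuals are orthogonal to every
regressor to numerical precision. A compartment of rank below five
contributes its available components with a warning.

## Numerical choices

* Correlations at $\pm 1$ are clipped to $1 - 10^{-7}$ before `atanh`,
  keeping fingerprints finite; entries beyond $\pm(1 + 10^{-12})$ are
  invalid input and raise an error. Zero-variance timecourses are hard
  errors, never silent `NaN`s.
* Group averaging is the two-stage mean (runs within subject, then
  subjects), entirely in z-space, with no inverse transform.
* Own-region connectivity is retained as a predictor (all targets enter
  every model).
* The ridge solve uses the eigendecomposition of $X_c^\top X_c$ when a
  whole grid or permutation batch is evaluated (one decomposition, many
  right-hand sides), and a direct solve for single fits. $\lambda = 0$ is
  permitted only for full-column-rank designs. Floating-point dust below 0
  or above 1 in $R^2$ is clamped at $10^{-8}$ tolerance; genuine
  violations raise.
* All randomness flows from one master seed through named substreams
  (hash of the stage name and keys), so any stage can be regenerated
  independently and execution order never matters.

## Problem sizes used in the tests

The test suite exercises the full design arithmetic (82 x 33 = 2,706
models; ANOVA error df 2,699; 21 post hoc contrasts; laterality df 40)
symbolically on generated designs, and runs the stochastic calibration
suites at reduced sizes chosen by pilot power analysis: permutation-null
type-I error on 500 replicate null datasets (100-vertex regions, 89
targets, 200 permutations each); signal detection on 100 replicates of
300-vertex regions with planted R² 0.5 (the full-scale design averages
roughly a thousand vertices per region) and 1,000 permutations; planted-R²
recovery at 2,000-vertex regions against a ±0.05 tolerance frozen from the
closed-form optimism approximation
$\mathbb E[\hat R^2] \approx \rho^2 + (1 - \rho^2)\,p/n$ plus a pilot
Monte-Carlo; and coefficient recovery at 1,000-vertex regions. The
end-to-end pipeline tests use small studies (a few hundred vertices, a
handful of regions and domains) where every stage remains exactly
reproducible.

## Known limitations

* The permutation scheme reuses the cross-validated penalty of the true
  model, which is mildly anticonservative for ill-conditioned designs (see
  above); spatially constrained nulls (spin or variogram-matched) are not
  implemented.
* In-sample $R^2$ overstates generative coupling by the optimism term;
  comparisons across regions of very different sizes inherit a
  size-dependent bias that the permutation null, but not the raw $R^2$,
  accounts for.
* The group-statistics layer treats models as independent observations.
* Real-data ingestion expects already vertex-aligned inputs (dense
  matrices, TSV, or NIfTI vectors); surface registration, smoothing, and
  grayordinate bookkeeping are out of scope.
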