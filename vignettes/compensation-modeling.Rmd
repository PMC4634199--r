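---
title: "Modeling neural compensation with moderated regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural compensation with moderated regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

In premanifest Huntington's disease, measurable atrophy precedes any
behavioural deficit, which suggests that the brain actively compensates for
neuronal loss. `neurocomp` operationalises compensation as a statistical
interaction: performance is predicted not by brain activity alone but by the
product of activity and structural disease load,

$$y = \alpha + \beta_1 d + \beta_2 f + \beta_3\, d f + \boldsymbol\gamma
\mathbf c + e, \qquad e \sim N(0, \sigma_e^2),$$

where $y$ is a performance measure (n-back d-prime, a cognitive composite,
or a motor score), $d$ a structural disease load — a regional volume
(caudate, putamen, global grey, global white) expressed as a *fraction of
intracranial volume*, so smaller $d$ means higher load — $f$ a scalar fMRI
signal (a voxel's task contrast value or a cluster-mean resting-state
connectivity estimate), and $\mathbf c$ covariates: age, gender, study
site, education level, and the cumulative probability of onset (CPO).
Evidence for modulation of the performance–activity relationship by
atrophy is the rejection of $H_0 : \beta_3 = 0$; fits are ordinary least
squares on complete cases (`fit_compensation()`), and the performance–
activity slope at load $d$ is $\beta_2 + \beta_3 d$.

A significant interaction is *compensatory* when that slope is larger —
and positive — at high load (low volume) than at low load: activity buys
more performance precisely where atrophy is greater. A slope that weakens
or turns negative with increasing load is *non-compensatory*
(`classify_pattern()` evaluates the slopes at the 10th and 90th
percentiles of the observed volume fractions). Note one asymmetry that is
intrinsic to this definition, not to the code: jointly negating the sign
convention of $f$ negates both slopes, so a compensatory pattern maps onto
a non-compensatory one. Compensation in this operational sense requires a
positive performance–activity relationship, as in the Cabeza–Dennis
criteria it descends from.

Two testing policies coexist deliberately. Individual interaction tests
use the *nominal* p ≤ 0.05 criterion with no multiplicity adjustment
across features or voxels — interaction effects among correlated
predictors are small, and the design favours sensitivity over strict error
control, which mandates caution in interpretation. The single pre-planned
correction is a Bonferroni adjustment across the four disease-load
measures tested per feature (`bonferroni_disease_load()`, significant iff
$p \le \alpha/4$).

## Pipelines around the model

**Task pathway.** Subject-level contrast images enter a group one-sample
t-test; voxels surviving family-wise error control at 0.05 define the
task main-effect mask; the compensation model is then fitted independently
at every in-mask voxel with that voxel's contrast value as $f$
(`voxelwise_compensation()`), and voxels are reported at p < 0.001
uncorrected (two-sided; the reporting sidedness is a documented choice —
signed effects in both directions are of interest).

**Resting-state pathway.** Per subject, the mean series of a 4 mm-radius
sphere at the seed coordinate is extracted after discarding the first four
volumes; the seed and every voxel series are residualised against white
matter, CSF and six motion regressors plus an intercept, and the map value
is the Fisher z of the resulting partial correlation
(`seed_correlation_map()`). The z scale is chosen for variance
stabilisation; the source's "correlation maps" are ambiguous between
correlation and regression parameters, and partial correlation given the
nuisance set is the documented resolution. Group maps enter a one-tailed
(positive) one-sample t-test; FWE thresholding is Bonferroni by default,
with a sign-flip max-statistic permutation option. Random-field-theory FWE
is out of scope; Bonferroni is deterministic and conservative on these
grids, and the permutation route is the exact-under-exchangeability
alternative. Surviving voxels are clustered by 26-connectivity (minimum
size 1) and each cluster's per-subject mean Fisher z is the feature $f$.
The seed's own cluster is reported, not silently removed; downstream
scripts exclude clusters within 12 mm of the seed.

**Visualisation.** Conditioning plots use Cleveland's equal-count rule:
with $n$ observations, $k$ intervals and overlap fraction $r$, the target
count is $m = n / (k(1-r) + r)$ and interval $j$ spans sorted ranks
$\mathrm{round}((j-1)m(1-r))$ through that $+\lceil m\rceil - 1$ (0-based,
clipped), so each interval holds $m \pm 1$ points and successive intervals
share about $mr$. Per-interval least-squares lines of $y$ on $f$ are
display aids only.

## The synthetic cohort

No subject-level data from the motivating study are deposited, so the
package ships a generator whose defaults *are* the study conditions it
emulates: 106 gene-carriers and 111 controls over 4 sites; carriers with
CAG ≥ 40 resampled to satisfy the recruitment filter disease-burden
$= \mathrm{age}\times(\mathrm{CAG}-35.5) > 250$; TR 3 s and 165
resting-state volumes. Volumetric images use a 24 × 28 × 24 grid of 4 mm
voxels — a deliberate desk-scale reduction that preserves 3D geometry
while keeping a full pipeline run under a minute per stage.

Choices the source leaves open, fixed here once and documented:

* **CPO surrogate.** The study cites an external onset model it does not
  reproduce; any monotone-in-burden surrogate suffices. We use
  $\mathrm{CPO} = \mathrm{logistic}((\mathrm{burden}-350)/60)$, which
  spreads carriers over roughly (0.1, 0.9); controls are 0.
* **Atrophy.** Volume fractions are Gaussian with means declining linearly
  in CPO (e.g. caudate $0.0048 - 0.0016\,\mathrm{CPO}$, sd $5\times
  10^{-4}$) — the simplest structure that yields the load variance the
  interaction model needs. Values are clamped to (0, 1).
* **Planted interaction.** The latent feature $f$ is drawn first
  ($N(2,1)$) and performance generated *forward* from the model equation,
  with the interaction centred at reference values ($d_{\mathrm{ref}} =
  0.0044$, $f_{\mathrm{ref}} = 2$). Centring means a null cohort
  ($\beta_3 = 0$) and a planted cohort share the same performance mean and
  range, and $\beta_3$ remains exactly the coefficient of the raw $d f$
  product an analyst estimates. Solving the equation backwards for $f$
  from an already-generated $y$ with fresh noise would correlate $f$ with
  the regression error and bias ordinary least squares — the forward
  construction is what makes parameter recovery a fair oracle.
* **Counts.** 2-back performance maps to 24 targets / 48 non-targets; the
  false-alarm rate absorbs boundary cases so that any $y \in [-1,1]$ is
  represented *exactly* as hit rate minus false-alarm rate up to count
  rounding (granularity 1/24). Without this, clamping hit probabilities at
  the boundaries induces a load-dependent distortion that visibly biases
  $\beta_3$.
* **Defaults** $\alpha = 0.03$, $\beta_1 = 60$, $\beta_2 = 0.10$,
  $\beta_3 = -75$, $\sigma_e = 0.08$ put the planted interaction at about
  6 residual-sd per unit of its regressor's spread — detectable at
  $n = 100$ without being trivial — while keeping d-prime inside its
  bounds for essentially all subjects.
* **Images.** Task maps are smoothed white noise (6 mm FWHM) plus
  Gaussian-profile main-effect blobs (amplitude $2 \pm 0.5$ across
  subjects, spatial sd 2 voxels) at the planted coordinates; the first
  coordinate's voxel value is replaced by the subject's latent $f$, so the
  group main-effect mask recovers the region and the compensation equation
  holds exactly at that voxel. Resting series put a shared latent course
  in the seed sphere and a $\rho$-weighted mixture in the target sphere
  (per-subject $\rho \sim N(0.6, 0.1)$ truncated), add global WM/CSF
  confounds everywhere (coefficient 0.7), and report six random-walk
  motion regressors. The analogous cognition-by-grey-matter interaction
  ($\beta_3^{\mathrm{rest}} = -52$ on the composite scale) is planted
  borderline-detectable at $n \approx 100$, mirroring the size of
  reported connectivity effects.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: haemodynamic nonlinearity, temporal
autocorrelation (series are white; the OLS first-level model is exact here
but would be mildly anticonservative on real autocorrelated data),
physiological noise spectra, scanner-site intensity differences beyond a
mean shift, motion-correlated artefacts, and spatial correlation of the
behavioural residuals.

## Numerical choices

Gaussian smoothing uses separable normalised kernels
($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$ per axis in mm, converted to
voxels via the affine; zero padding at the grid boundary; sheared affines
are rejected). Sphere membership is by voxel-centre distance, without
partial volumes. The first-level GLM uses the canonical double-gamma HRF
(peak 6 s, undershoot 16 s, ratio 1/6 — the convention of the major
analysis packages) and plain OLS. Fisher z values are capped at |z| = 10;
voxels whose series lie numerically in the nuisance span get z = 0.
One-sample t statistics with zero sample variance are capped at $10^6$.
Collinearity in compensation fits is flagged when the condition number of
the column-normalised design exceeds $10^{10}$, naming the offending
columns. Gender and site enter as reference-coded factors, education as an
integer level; factors that collapse to one level in the analysed subset
(e.g. CPO among controls-only data) are dropped rather than made singular.

## A worked run

```{r, eval = FALSE}
library(neurocomp)
report <- run_pipeline(demo_config(seed = 3))
report$stages$task$planted_voxel$label     # "compensatory"
report$stages$connectivity$target_cluster_found
```

The calibration functions reproduce the package's own statistical
guarantees: `calibrate_type1()` (rejection rate of the nominal test over
null cohorts), `calibrate_recovery()` (bias and 95% CI coverage of the
planted coefficient), and `detection_study()` (how often the planted voxel
is the minimum-p in-mask voxel, and how often the planted resting-state
target survives FWE). The problem sizes used throughout — 1000 null
cohorts of 100 carriers, 200 recovery cohorts of 200, 20 end-to-end
detection runs with 60 resting-state subjects — are the package's chosen
simulation scale: large enough that Monte-Carlo error is small against the
properties being checked, small enough to run on a laptop.

## Limitations

The pipeline is cross-sectional; longitudinal compensation dynamics and
multivariate integration of the four (correlated) disease-load measures
are out of scope. Effective-connectivity modelling is not implemented.
Site enters as a fixed effect; with many sites a random effect would be
preferable. The d-prime measure is the bounded hit-minus-false-alarm
difference, not the z-transformed signal-detection statistic, and the
linear model ignores its boundedness — acceptable at the simulated
operating point, questionable near ceiling.
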