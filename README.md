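# neurocomp

Moderated-regression mapping of neural compensation in premanifest
neurodegeneration.

In premanifest Huntington's disease, regional brain atrophy is measurable
years before performance declines — evidence that the brain compensates for
neuronal loss. `neurocomp` implements an explicit operational model of that
compensation: behavioural performance is predicted by the *interaction*
between structural disease load and an fMRI signal,

```
y = α + β₁ d + β₂ f + β₃ d·f + γᵀc + e
```

where `y` is performance (n-back d-prime, a PCA cognitive composite, or a
motor score), `d` a regional volume (caudate, putamen, global grey or white
matter) as a fraction of intracranial volume (small volume = high load),
`f` a voxel's task-contrast value or a cluster-mean resting-state
connectivity estimate, and `c` covariates (age, gender, site, education,
cumulative probability of onset). Rejecting `H₀: β₃ = 0` means the
performance–activity slope `β₂ + β₃ d` changes with atrophy; the pattern is
*compensatory* when the slope is positive and strongest at high load.

The package provides the full analysis pipeline around that model:

* **`synthetic_cohort`** — a generator for a complete synthetic study
  (tabular cohort with disease-burden-dependent atrophy, task contrast
  images with a planted compensation voxel, resting-state series with a
  planted coupled network and WM/CSF/motion confounds), with known ground
  truth so every stage has a parameter-recovery oracle.
* **behavioural metrics** — n-back d-prime (hit rate − false-alarm rate)
  and the PCA-derived global cognitive composite.
* **imaging core** — NIfTI I/O, Gaussian smoothing (6 mm FWHM default),
  sphere extraction at mm coordinates, and a simplified first-level GLM
  with the canonical double-gamma HRF.
* **connectivity** — seed-based partial-correlation maps after nuisance
  regression, one-tailed group t-tests on Fisher-z maps, Bonferroni or
  sign-flip permutation FWE, 26-connectivity clusters and cluster-mean
  features.
* **compensation engine** — single-feature and voxelwise interaction fits,
  the pre-planned Bonferroni correction across the four disease-load
  measures, compensatory/non-compensatory classification, and Cleveland
  equal-count conditioning-plot construction.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
study (106 carriers, 111 controls, 24×28×24 grid of 4 mm voxels), writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_behavior.R
Rscript analysis/03_task_activation.R
Rscript analysis/04_connectivity.R
Rscript analysis/05_compensation.R
Rscript analysis/06_calibration.R
```

Representative output:

```
cohort: 106 carriers, 111 controls
2-back d-prime: carriers 0.417, controls 0.516
composite: first component explains 72.2% of battery variance

main-effect mask: 684 voxels in 2 cluster(s)
voxels below p < 0.001: 1
top voxel: (34, -54, 42) mm, beta3 = -80.4, t(95) = -6.79, p = 9.8e-10
planted compensation coordinate: (36, -56, 44) mm   # same voxel on the 4 mm grid

FWE-significant clusters: 2                         # seed + planted target
coplot display slopes (high -> low load): 5.85 3.10 0.98 -2.61

type-I error at nominal 0.05: 0.057 (MC se 0.007, 1000 cohorts)
planted beta3 = -75: mean estimate -75.26, bias -0.26 (MC se 0.62)
95% CI coverage: 0.955 (200 cohorts)
```

Reading these numbers: carriers underperform controls on the 2-back task;
the voxelwise interaction map flags exactly the planted compensation voxel
(negative β₃: the performance–activity slope steepens as caudate volume
shrinks, i.e. a compensatory pattern); the resting-state pathway recovers
the planted seed-coupled target cluster, whose cognition-by-grey-matter
interaction is nominally significant but — like the borderline effects such
designs produce — does not survive the four-way Bonferroni correction; and
the conditioning-plot slopes fall monotonically from the highest-load to
the lowest-load interval. The calibration stage confirms the interaction
test holds its nominal level and the planted coefficient is recovered
without bias.

Or programmatically:

```r
library(neurocomp)
report <- run_pipeline(demo_config(seed = 3))
report$stages$task$planted_voxel$label   # "compensatory"
```

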