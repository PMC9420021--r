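---
title: "Individualized normative brain volumetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized normative brain volumetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pednorm)
```

## The problem

After a moderate or severe traumatic brain injury (TBI) in childhood,
diffuse axonal injury can drive progressive volume loss that is
invisible on routine radiology. Detecting it in an individual child is
hard because the healthy adolescent brain is itself changing rapidly:
relative to head size, grey matter volume falls through adolescence
while white matter volume rises. A patient can therefore only be judged
against healthy references *of the same age*.

`pednorm` implements that comparison as a reusable pipeline:

1. **TICV correction** — each regional volume is divided by the
   subject's total intracranial volume, removing head-size (and almost
   all sex-related) variance.
2. **Population QC** — within each (region, age-year) cell of the
   reference cohort, observations beyond ±3 SD of the cell mean are
   removed. Under normality this retains over 99% of genuine data
   (Φ(3) − Φ(−3) ≈ 99.73%) while discarding gross segmentation
   failures.
3. **Age norms** — per (region, age-year) mean, SD and n; a bin is
   usable only with at least `min_bin_n = 45` subjects ("more than 44
   per year of age").
4. **Individual classification** — for a patient of age *a*,
   `Z_j = (v_j − μ_{j,⌊a⌋}) / σ_{j,⌊a⌋}` per region, one-sided
   lower-tail p-values, Benjamini–Hochberg FDR over the region family,
   and a subject label of *low volume* (any flag) or *normal volume*.
5. **Lesion-matched norms** — for patients with focal lesions, the
   patient's lesion mask is applied to every control's tissue map
   before extraction, and the norms are rebuilt from those masked
   volumes, so patient and reference share the same tissue exclusion.
6. **Developmental curves** — per region, OLS of corrected volume on
   continuous age, summarised as the annual percentage rate of change
   (APR).
7. **Cognitive stage** — exploratory factor analysis reduces a
   standardized neuropsychological battery to one representative
   measure per latent domain, followed by group comparisons with FDR
   control.

## The APR convention

The per-region age trajectory is modelled as linear on the
TICV-corrected scale. APR is defined relative to the fitted value at
age 8, the youngest reference age:

$$\mathrm{APR} = 100\,\beta \,/\, \hat V(8),$$

so the fitted percent change between ages 8 and 20 equals exactly
12 × APR. This choice makes per-year rates and 8→20 percent changes
mutually consistent: a region declining 1.9%/yr loses 22.8% over those
twelve years, and the global grey/white presets (−17% and +9% over
8→20) correspond to APRs of −17/12 and +9/12 %/yr. Alternative APR
definitions (e.g. mean year-over-year change of a nonlinear fit) exist
but are not implemented; with a linear trajectory they coincide with
this one up to the choice of denominator.

## What the synthetic generator emulates

Real reference data of this kind (large multi-site healthy adolescent
MRI cohorts) are access-controlled, so the package ships a generator
whose defaults encode the population structure the pipeline targets:

* 1200 subjects, uniform over age-years 8–22 (~80 per bin, above the
  45-per-bin floor);
* three sites with ±1% multiplicative volume offsets — site then
  accounts for roughly 1–2% of corrected-volume variance, matching
  what multi-site adolescent references report;
* sex-dependent TICV (male/female ratio 1.10) and TICV growth of
  0.5%/yr, so raw volumes carry a large head-size signal that TICV
  correction removes almost entirely (the sex share of corrected
  variance is < 1%);
* per-region linear trajectories with the calibrated APRs
  (posterior cingulate −1.9, amygdala −0.8, corticospinal tract +0.8,
  body of corpus callosum +0.5, genu +0.1 %/yr, plus the global
  aggregates);
* multiplicative log-normal noise with log-SD 0.05 (~5% CV — a
  realistic repeatability for segmentation-derived regional volumes;
  the population noise level is a free parameter, not an empirically
  fixed one);
* 1% of volume cells replaced by gross outliers at 6–8 log-SD, the
  kind of segmentation failure the ±3 SD QC stage exists to remove.

Patient cohorts add known ground truth: each deficit region is shifted
down by `deficit × σ(region, age)` on the corrected scale, where σ is
the analytic population SD implied by the generative model (site-offset
moments × log-normal moments). A 5 SD deficit therefore has expected
Z ≈ −5 by construction, which is what makes power and specificity
measurable exactly.

What the generator does **not** emulate: cortical anatomy, scanner
artefacts and contrast differences, registration error, nonlinear
growth, age-varying noise, or site-by-age interactions. Passing
recovery tests on these synthetics demonstrates that the *estimators
and decision rules* are correct under the stated model; it does not
validate any segmentation pipeline on real images.

Voxel phantoms are deliberately schematic: each region is a uniform-
density slab on a small grid (32³ by default, 1 mm isotropic), scaled
so unmasked integration reproduces the tabular volume to numerical
precision. This is enough to exercise real NIfTI geometry, lesion
masking arithmetic, and the lesion-matched norm rebuild, at desk scale.

## Numerical and design choices

* **Capping is exclusion, not winsorising**, computed in a single pass
  per (region, age-year) cell on TICV-corrected values using the
  original cell statistics. Re-capping a capped table may flag further
  points (the recomputed SD shrinks); one pass is the defined
  behaviour. Cells with zero SD warn and remove nothing.
* **Age bins** are `floor(age)`, for both norm building and patient
  matching — "each year of age".
* **One-sided lower-tail testing** by default: the clinical question
  is low volume. A two-sided option exists (`side = "two"`).
* **FDR family** defaults to all tested regions per subject; separate
  grey/white families are available (`family = "tissue"`), since both
  conventions are defensible.
* **TICV correction** defaults to the proportional method (v/TICV);
  a residual-regression option is provided behind a flag.
* **Lesion masks** are applied by exact voxel indexing on a shared
  grid after asserting identical geometry — no interpolation.
* **`coverage_max = 0.9`**: a region with ≥ 90% of its voxels under
  the lesion is untestable rather than tested against a sliver of
  tissue. Configurable.
* **Variance decomposition** uses sequential (type-I) sums of squares
  in the fixed order age, sex, cohort — stated prominently because
  order matters for correlated predictors; an oracle test checks it
  against nested-model R² differences.
* **EFA** uses maximum-likelihood extraction with varimax rotation
  (`stats::factanal`), the default loading cut-off of 0.3, a fixed
  5-factor solution, and alphabetical tie-breaking on equal maximal
  loadings so results are invariant to column order.
* **Specificity is assessed on clean test subjects**
  (`outlier_fraction = 0`): gross outliers model artefacts that the
  population QC removes; the false-positive property concerns the
  statistical procedure, not artefact handling at test time.

## Problem sizes and determinism

All validation runs at desk scale: recovery uses the default n = 1200
cohort; specificity uses 500 independent subjects; power uses 200
replicate patients with 5 SD deficits; oracle checks use families up
to 12 tests and 16³ random phantoms. Every stochastic stage is
deterministic given its seed, and the pipeline stamps each run with a
config hash and seed (`manifest.json`), so artifacts are reproducible
byte for byte.

## Worked example

```{r example, eval = FALSE}
presets <- default_presets()
cohort <- generate_normative_cohort(generator_config(seed = 1), presets)
capped <- cap_outliers(correct_volumes(cohort))
norms <- build_age_norms(capped$table)

# developmental trajectories
glance(fit_age_curve(capped$table, "pcg"))
percent_change_between(fit_age_curve(capped$table, "global_grey"), 8, 20)

# classify a synthetic patient with a 5 SD genu deficit
pat <- generate_patient_cohort(
  generator_config(n_subjects = 1, min_bin_n = 0, seed = 2),
  presets, list(deficit_spec(c(genu_cc = 5)))
)
classify_cohort(correct_volumes(pat$table), norms)
```

## Known limitations

* Linear age trajectories only; adolescent development is not exactly
  linear, and spline/quantile growth models are out of scope.
* No site harmonisation is estimated; site offsets are assumed small.
  Quantile regression and site-specific offsets are natural extensions.
* Norm SDs are treated as known when Z-scoring; with ≥ 45 controls per
  bin the extra t-type variance is small but not zero, and the
  specificity test bounds its practical effect.
* The lesion-matched rebuild assumes all phantoms share one template
  grid; registration into that space is upstream of this package, as
  is tissue segmentation itself.
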