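---
title: "Methods: reference-tissue MTV quantification and the composite MTV/CgA survival model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-tissue MTV quantification and the composite MTV/CgA survival model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtvsurv)
```

## Scope and model

`mtvsurv` implements the quantitative chain used to derive prognostic
imaging biomarkers for neuroendocrine-tumor patients treated with peptide
receptor radionuclide therapy (PRRT):

1. **SUV quantification and reference VOIs.** PET voxel values are
   body-weight standardized uptake values (SUV), with tissue density taken
   as 1 g/ml and inputs assumed decay-corrected, as scanner software
   delivers them. Reference statistics come from fixed-volume spherical
   VOIs (5 ml in the left liver lobe and spleen, 3 ml in the fifth lumbar
   vertebra), rasterized by the voxel-centre rule.
2. **Molecular tumor volume (MTV).** Pathologic somatostatin-receptor
   expression is any SUV *strictly above*
   $T = 1.5\,\mu_\text{liver} + 2\,\sigma_\text{liver}$.
   Supra-threshold voxels are grouped into 26-connected components;
   components flagged by an exclusion mask (physiological uptake such as
   kidney or pituitary, supplied by the caller in place of the physician's
   review) are dropped and counted. Total MTV is the volume sum of the
   remaining lesions.
3. **Volumetric response.** The relative MTV change between the baseline
   and the interim scan after two therapy cycles classifies patients as
   PR (reduction of more than 73%), PD (increase of more than 63%) or SD
   (everything between); PR and SD are responders.
4. **Composite biomarker.** Baseline MTV and chromogranin A are both
   right-skewed tumor-burden measures and individually violate
   proportional hazards; they are log-transformed, z-standardized on the
   cohort (sample SD), and averaged into a single predictor.
5. **Survival layer.** Univariable and multivariable Cox regression
   (Efron ties, Wald intervals), Schoenfeld-residual checks of
   proportional hazards, Kaplan–Meier estimation, log-rank tests,
   Mann–Whitney comparisons, and a fixed-horizon ROC (default 60 months,
   i.e. 5-year overall survival) with a Youden-optimal cutoff.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| threshold rule | $1.5\mu + 2\sigma$ (liver) | SUV | reference-tissue definition of pathologic uptake |
| connectivity | 26 (configurable 6) | – | matches workstation single-click region behaviour |
| threshold inequality | strict (`>`) | – | "higher than" leaves boundary voxels in background |
| exclusion overlap | 0.5 | fraction | component dropped when `>` half its voxels are flagged |
| `min_lesion_ml` | 0 | ml | no clinical minimum; phantom analyses pass 0.5 ml (below) |
| PR / PD bounds | −73 / +63 | % MTV change | strict inequalities; boundary values are SD |
| ROC horizon | 60 | months | 5-year overall survival |
| AUC interval | DeLong | – | bootstrap (2000 reps) when a group has < 5 subjects |
| Youden ties | higher specificity | – | deterministic cutoff choice |
| Cox ties | Efron | – | accurate default for tied event times |

Open choices we fixed, with reasoning:

* **Sample vs population SD** in reference VOIs: workstations do not
  document their convention; we use the sample SD (n − 1) and expose
  `sd_type = "population"` as a switch. The difference is below 0.1% for
  the ~600-voxel VOIs involved.
* **Order of log and z steps** for the composite: the skewness rationale
  for log-transforming implies standardizing the *log* values, so the
  composite is `0.5 * (z(log MTV) + z(log CgA))`. The log base is
  irrelevant (z-standardization removes affine changes), which the tests
  assert.
* **Global threshold + connected components** rather than seeded region
  growing: a click-seeded region grower restricted to one component is a
  special case of global labeling; global labeling is reproducible without
  interaction and differences only arise for lesions a reader would never
  click, which have no counterpart in an automated pipeline.
* **ROC direction**: markers are oriented so that higher values indicate
  the poorer 5-year outcome (true for MTV, CgA and the composite);
  reported cutoffs are midpoints between adjacent observed marker values,
  so thresholds read "marker > cutoff".
* **Patients censored before the horizon** carry no information about
  5-year status and are excluded from the ROC dichotomization.

## What the synthetic data emulate — and what they do not

**Phantoms.** A digital phantom is a 64³ grid of 2 mm isotropic voxels
(128 mm field of view): a quiet body background (SUV 0.5 ± 0.2), a 30 mm
liver sphere with Gaussian texture at the cohort-scale liver values
(4.41 ± 1.14 SUV), spherical lesions of known analytic volume painted at
tumor-scale uptake (SUVmean ≈ 12), and physiological hot spots flagged in
an exclusion mask. Interim phantoms rescale each lesion radius by
$f^{1/3}$ so volumes scale by $f$, with the same seed reproducing the
identical background. The phantoms deliberately omit scanner blur (PSF),
attenuation and reconstruction noise correlations, and partial-volume
effects; recovery results therefore demonstrate correctness of the
segmentation arithmetic, not clinical accuracy on reconstructed scans.

One consequence of the Gaussian liver texture is worth noting: the
threshold sits 3.9σ above the liver mean, so a ~14,000-voxel liver sphere
produces on the order of one isolated supra-threshold voxel per phantom.
These one-voxel specks (0.008 ml) are real features of the simulated
texture, not bugs; phantom analyses in the tests and the acceptance script
pass `min_lesion_ml = 0.5` to remove them, while the user-facing default
remains 0 because the clinical workflow states no minimum.

**Cohorts.** Simulated cohorts draw demographics at the frequencies of a
typical well-differentiated NET population (58% male, grading
G1/G2/G3 ≈ 34/63/3%, primary site GEP/bronchopulmonary/CUP ≈ 85/10/5%,
age ≈ N(62, 11²) truncated to 27–80). Baseline MTV and chromogranin A are
jointly log-normal; the MTV parameters (meanlog 4.01, sdlog 1.26) are the
log-normal moment match to a mean of 121.5 ml with SD 238.1 ml, and CgA
uses meanlog log(600), sdlog 1.5, a clinically realistic heavy tail whose
scale puts the upper quartile near the 1,250 µg/l range where prognostic
cutoffs are typically reported. The within-patient correlation of the two
log markers is a free parameter (`rho`, default 0.6) because no empirical
value is available; conclusions that depend on it should be reported as a
function of ρ. Death times follow a Weibull-baseline proportional-hazards
model
$S(t\mid x) = \exp\{-(t/\lambda)^k e^{\beta^\top x}\}$ with
$\lambda = 105$ months and $k = 1.3$, chosen so that baseline 5-year
survival is ≈ 62%, the scale reported for this disease setting; the
default effects are a composite log-HR of $\log 2.67 = 0.98$ and an age
effect of $\log 1.15$ per year. Default censoring is administrative at a
96-month follow-up cap. The generating linear predictor uses the *same*
composite the analysis recomputes from the sampled markers, so
parameter-recovery checks are exact in expectation.

The parameter-recovery study condition (n = 500, composite-only effect,
~30% censoring) is realized with `admin_horizon = 130` months and no
random loss to follow-up, which yields 30% censoring under the default
marker model.

## Problem sizes used by the test suite

The repeated-replicate checks run at: 200 replicates of n = 500 for Cox
recovery of the composite log-HR (median within ±0.15 of 0.98) and the
null-covariate rejection rate; 1000 null replicates each for log-rank and
Mann–Whitney type-I calibration (5% ± 2%); 500 replicates of n = 500 for
Schoenfeld calibration under proportional hazards and power against an
effect that reverses sign at the median follow-up; n = 5000 for the
Kaplan–Meier/Weibull closed-form comparison; and 2000 subjects per arm for
the binormal ROC check against $\Phi(1/\sqrt2) = 0.7602$. These sizes give
Monte-Carlo error comfortably below the asserted tolerances.

## Numerical notes and degenerate inputs

* Connected components are labeled by building the voxel adjacency graph
  over supra-threshold voxels and taking graph components; a brute-force
  flood fill serves as the oracle in the tests.
* A zero baseline MTV makes the relative change undefined and raises an
  error rather than silently classifying; the clinical rule has no such
  case.
* Constant marker vectors cannot be z-standardized (degenerate spread
  error naming the offending input); non-positive values fail the log
  transform with the patient id in the message.
* Cox fits abort with a convergence error when a coefficient diverges
  (monotone likelihood / perfect separation); a warning is emitted when
  there are fewer than 10 events per covariate.
* Kaplan–Meier evaluation uses the right-continuous step convention; ties
  in the Youden criterion resolve toward higher specificity; ties in the
  largest-lesion rule resolve by higher SUVmax, then lower lesion id.
* The report written by `run_pipeline()` contains no timestamps, so equal
  seeds produce byte-identical JSON.

## Known limitations

* No partial-volume correction or scanner-resolution modelling: MTV from
  small or low-contrast lesions will be biased on real data in ways the
  phantoms cannot show.
* The exclusion of physiological uptake is only as good as the supplied
  mask; the package does not segment organs.
* The fixed-horizon ROC discards patients censored before the horizon
  rather than using inverse-probability-of-censoring weights; with heavy
  early censoring this loses efficiency and can bias the AUC.
* Clinical headline values (hazard ratios, cutoffs, AUCs of the original
  62-patient cohort) are not reproducible from this package because the
  patient data are not public; the simulated cohorts reproduce the
  *structure and scale* of those analyses, and all quantitative claims in
  the test suite concern the synthetic generative models.
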