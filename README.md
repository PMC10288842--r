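# mtvsurv

Quantitative imaging biomarkers and survival modelling for
somatostatin-receptor (SSTR) PET in neuroendocrine tumors (NET) treated
with peptide receptor radionuclide therapy (PRRT).

Well-differentiated NETs overexpress somatostatin receptors, which makes
their total tumor burden measurable on SSTR-PET as a **molecular tumor
volume (MTV)**. `mtvsurv` is for imaging scientists and biostatisticians
who want that measurement — and the prognostic analyses built on it —
as reproducible, tested code rather than workstation clicks:

* **Reference-tissue segmentation.** Pathologic uptake is any SUV
  strictly above the liver-derived threshold

  > T = 1.5 · SUVmean(liver) + 2 · SD(liver)

  with liver statistics read from a 5 ml spherical VOI. Supra-threshold
  voxels are grouped into 26-connected components; components covered by
  an exclusion mask (kidney, pituitary, other physiological uptake) are
  dropped. Total MTV is the volume sum of the remaining lesions.
* **Volumetric response after two therapy cycles.** Relative MTV change
  classifies patients as partial response (reduction > 73%), progressive
  disease (increase > 63%) or stable disease in between; PR and SD are
  responders.
* **Composite MTV/chromogranin-A biomarker.** Both tumor-burden markers
  are log-transformed, z-standardized on the cohort and averaged:
  `score = (z(log MTV) + z(log CgA)) / 2`.
* **Survival layer.** Cox regression (Efron ties) with
  Schoenfeld-residual proportional-hazards diagnostics, Kaplan–Meier
  curves, log-rank and Mann–Whitney tests, and fixed-horizon ROC analysis
  (default: 5-year overall survival) with a Youden-optimal cutoff and
  DeLong confidence interval.
* **Synthetic data.** Seeded digital PET phantoms with known lesion
  volumes and simulated cohorts from a Weibull-baseline
  proportional-hazards model, so the whole chain is testable end to end
  without patient data.

Everything tabular flows through tibbles: results have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

A baseline phantom with one 25 mm lesion (true volume 65.45 ml), its
interim counterpart after shrinking the lesion to 20% of its volume, and
a simulated 62-patient cohort:

```r
library(mtvsurv)

cfg <- phantom_config(
  lesions = data.frame(x = 90, y = 64, z = 64, radius_mm = 25, suv = 12),
  seed = 42)
baseline <- generate_phantom(cfg)

liver <- reference_stats(baseline$volume, sphere_voi(cfg$liver_center, 5, "liver"))
thr <- segmentation_threshold(liver)   # 8.796 on this phantom's liver draw
seg <- segment_mtv(baseline$volume, thr, min_lesion_ml = 0.5)
seg
#> <mtv_segmentation> threshold 8.796 SUV, 1 lesion(s), total MTV 65.15 ml (0 excluded)
#> # A tibble: 1 x 5
#>   lesion_id n_voxels volume_ml suv_max suv_mean
#>       <int>    <int>     <dbl>   <dbl>    <dbl>
#> 1         1     8144      65.2      12       12
```

The recovered 65.15 ml is within 0.5% of the analytic 65.45 ml; the
threshold 8.796 is the liver rule evaluated on this phantom's measured
liver statistics (cohort-scale values 4.41/1.14 give exactly 8.895).

```r
interim <- generate_interim_phantom(cfg, 0.2)
seg_i <- segment_mtv(interim$volume, thr, min_lesion_ml = 0.5)
pct <- percent_change(total_mtv(seg), total_mtv(seg_i))
classify_response(pct)   # pct = -79.9 -> PR (a reduction of more than 73%)

cohort <- generate_cohort(cohort_config(n = 62, seed = 42))$records |>
  prepare_cohort()
fit <- fit_cox(cohort, c("mtv_cga_composite", "age"))
tidy(fit)
#> # A tibble: 2 x 8
#>   term              estimate std.error statistic  p.value hazard_ratio conf.low conf.high
#> 1 mtv_cga_composite    0.879    0.207       4.25  2.11e-5         2.41     1.61      3.61
#> 2 age                  0.145    0.0248      5.84  5.14e-9         1.16     1.10      1.21
```

The composite hazard ratio of 2.41 (95% CI 1.61–3.61) estimates the
generating effect of HR 2.67 per composite unit from 62 patients; age adds
HR 1.16 per year. Kaplan–Meier and ROC summaries follow the same pattern:

```r
km <- km_estimate(cohort)
survival_at(km, 60)                      # 0.50: this cohort's 5-year OS
glance(roc_fixed_horizon(cohort, "mtv_ml"))
#> auc 0.727 (95% CI 0.599-0.856), cutoff > 65.8 ml,
#> sensitivity 0.677, specificity 0.774 (31 cases / 31 controls)
autoplot(km); autoplot(roc_fixed_horizon(cohort, "mtv_ml"))
```

`run_pipeline(list(seed = 7))` chains all stages (imaging → response →
composite → survival) and, given `out_dir`, writes the per-lesion CSV,
the prepared cohort and a deterministic JSON report.

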