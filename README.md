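# relloi — cross-sectional ADC profiling of ring-enhancing brain lesions

Ring-enhancing lesions (RELs) such as glioblastoma (GBM) and brain abscess
look alike on conventional MRI but differ sharply in how water diffuses
through their compartments: abscess pus restricts diffusion (low apparent
diffusion coefficient, ADC), necrotic tumour core does not (high ADC).
`relloi` implements a region-of-interest-free way to exploit this: sample
the ADC map along a **line of interest (LOI)** running from normal-looking
tissue, across the perilesional edema and the enhancing ring, into the
lesion core; segment the resulting 1-D profile at six landmarks A–F; and
summarise it by the dynamics of the ADC values rather than absolute
regional means.

For a profile `f(x)` the features are two-point gradients
`∇f ≈ (f(x) − f(x₀)) / (x − x₀)` over the transitions — A–B (gradient 1,
edema rise), C–D (gradient 2, edema-to-ring fall) and D–E (gradient 3,
ring-to-core rise) — plus the mean, sample SD and median of the two
plateaus B–C (perilesional edema) and E–F (core), giving the feature vector

```
fv = (∇ADC_E_rise, ADC̄_E, σ_ADC_E, med_ADC_E, ∇ADC_E_fall,
      ∇ADC_T_rise, ADC̄_T, σ_ADC_T, med_ADC_T)
```

Group differences are assessed with Wilcoxon rank-sum / Kruskal–Wallis
tests after a Shapiro–Wilk normality screen; lesions are classified with
k-nearest neighbours and a Gaussian-kernel soft-margin SVM (accuracy,
TPR, FNR = 1 − TPR from the confusion matrix), with subject-level
train/test splitting and subject-grouped five-fold cross-validation.

The package targets image analysts and methods researchers working on
diffusion MRI of brain lesions. Because the clinical dataset the design
derives from is not public, `relloi` ships a synthetic REL phantom
(1-D profiles, radially symmetric 2-D maps, whole labeled cohorts with
known ground truth) that the entire test suite runs against.

## Worked example

```r
library(relloi)

co <- generate_cohort(cohort_spec(seed = 42))   # 26 GBM + 14 abscess x 5 LOIs
co
#> synthetic REL cohort: 200 samples (130 GBM, 70 ABSCESS lines), 40 subjects

compare_cohort(co)[, c("feature", "test", "p_value", "significant")]
#>       feature              test  p_value significant
#> 1    median_E Wilcoxon rank-sum 2.18e-31        TRUE
#> 2    median_T Wilcoxon rank-sum 2.18e-31        TRUE
#> 3       std_E Wilcoxon rank-sum 3.88e-01       FALSE
#> 4       std_T Wilcoxon rank-sum 8.78e-01       FALSE
#> 5 grad_E_rise    Kruskal-Wallis 7.03e-01       FALSE
#> 6 grad_E_fall    Kruskal-Wallis 9.82e-01       FALSE
#> 7 grad_T_rise    Kruskal-Wallis 5.35e-01       FALSE

sp <- split_cohort(co, train_fraction = 0.75, seed = 42)
sp
#> subject-level split: 30 train subjects (150 lines) / 10 test subjects (50 lines)

fit <- rel_train(sp$train, "knn")               # or "svm"
pred <- predict(fit, sp$test)
metrics(confusion(sp$test$label, pred, positive_class = "ABSCESS"))
#> accuracy      tpr      fnr
#>        1        1        0
```

Reading: the plateau medians of edema and core separate the classes
(p < 0.05) while the gradients and plateau SDs do not — the synthetic
cohort is built to reproduce exactly this qualitative pattern — and the
held-out subjects are classified perfectly because the default phantom's
class separation is generous relative to its noise. On a real map you
would start from `read_adc_map()` + `read_loi_json()`, run `sample_loi()`,
place landmarks manually or with `detect_landmarks()`, and continue with
`extract_features()`; `run_pipeline(run_config(...), out_dir)` drives the
whole chain and writes a reproducibility manifest.

## Layout

- `R/` — phantom generator, image/annotation I/O, LOI sampling, landmark
  detection, feature extraction, group statistics, classifiers, pipeline.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
- `vignettes/adc-loi-profiling.Rmd` — the methods vignette: model,
  assumptions, parameter choices, phantom design, limitations.
- `exec/relloi` — command-line front end.
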