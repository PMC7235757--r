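# tiradsx

Rule-based risk stratification of thyroid nodules, with elastography and
volumetric (4D) Color Doppler as added suspicion features.

Thyroid nodules are common; the clinical problem is picking out the few
that are malignant without sending every patient to fine-needle
aspiration. Several Thyroid Imaging Reporting and Data Systems (TI-RADS)
turn B-mode ultrasound findings into an ordinal malignancy-risk category.
`tiradsx` implements five of them as explicit, testable rule engines over
a per-nodule feature table:

* **EU-TIRADS** — any of four suspicious features (taller-than-wide
  shape, irregular margins, microcalcifications, marked hypoechogenicity)
  puts a nodule in category 5;
* **ACR TI-RADS** — a cumulative point score over composition,
  echogenicity, shape, margins and echogenic foci, banded into TR1–TR5;
* **Horvath TI-RADS** — pattern matching, highest-risk pattern wins;
* **French TI-RADS** — counts high-suspicion features including
  elastographic stiffness (strain ratio SR > 4); 1–2 features → 4B,
  ≥3 features or metastatic lymph nodes → 5;
* **French TI-RADS + 4D** — the French count extended by a sixth
  feature: interrupted thyroid capsule or increased intranodular
  vascularization on volumetric Doppler. The extra feature can only
  upgrade a category, never downgrade it.

Around the classifiers the package provides the full evaluation pipeline
used to compare such systems against a histopathological gold standard:
per-category contingency tables with calculated malignancy risk,
confusion matrices at each system's operating threshold (≥4 for EU/ACR,
≥4B for the others), sensitivity/specificity/PPV/NPV/accuracy
(`se = tp/(tp+fn)`, `sp = tn/(tn+fp)`, `acc = (tp+tn)/N`, with undefined
ratios reported as `NA`), calibration against published expected-risk
bands, a binomial logistic GLM fitted by Fisher scoring (deviance, AIC
`= deviance + 2k`, Wald z tests) for predictor analysis, and a calibrated
synthetic cohort generator so the whole pipeline is exercisable without
patient data.

The package ships the per-category pathology counts of a published
133-nodule surgical series (26.31% malignant) as a plain-text fixture,
so the published diagnostic metrics can be recomputed directly.

## Worked example

Re-derive the diagnostic metrics of all five systems from the shipped
per-category counts:

```r
library(tiradsx)
tabs <- read_counts(system.file("extdata", "category_counts.csv", package = "tiradsx"))
cmp  <- comparison_from_tables(tabs)
writeLines(render_category_table(tabs$french))
writeLines(render_metrics_table(cmp$metrics))
```

```
System: french
category  total  benign  malignant        risk (%)
2             6       6          0            0.00
3            19      19          0            0.00
4A           59      56          3            5.08
4B           27      13         14           51.85
5            22       4         18           81.82

system           Se       Sp      PPV      NPV      Acc
eu            97.14    23.47    31.19    95.83    42.86
acr           94.29    28.57    32.04    93.33    45.86
horvath       80.00    62.24    43.08    89.71    66.92
french        91.43    82.65    65.31    96.43    84.96
french4d      94.29    75.51    57.89    97.37    80.45
```

Reading the French row: at the ≥4B operating threshold the French system
catches 32 of 35 cancers (Se 91.43%) while keeping 81 of 98 benign
nodules test-negative (Sp 82.65%); 113 of 133 nodules are called
correctly (Acc 84.96%). The category-5 calculated risk (18/22 = 81.82%)
is the observed malignancy fraction inside that category. The 4D-extended
variant trades specificity (75.51%) for sensitivity (94.29%) because the
extra Doppler feature can only upgrade categories.

Fit the predictor model on a synthetic cohort generated at the study
conditions (n = 133, prevalence 35/133, published feature prevalences and
strain-ratio group means 2.54/5.56):

```r
co   <- generate_cohort(n = 133, seed = 42)
base <- c("taller_than_wide", "marked_hypoechoic", "microcalcification", "strain_ratio")
fit  <- fit_logistic(design_matrix(co, base))
fit4 <- fit_logistic(design_matrix(co, c(base, "doppler4d")))
print(fit4)
compare_models(fit, fit4, labels = c("french_features", "plus_4d"))
```

```
Binomial logistic GLM (Fisher scoring)
                   estimate std_error  wald_z   p_value
(Intercept)         -7.1055    1.2812 -5.5461 2.921e-08
taller_than_wide     2.3152    0.7804  2.9665 3.012e-03
marked_hypoechoic    0.8929    1.0932  0.8168 4.141e-01
microcalcification   3.4871    1.0486  3.3255 8.826e-04
strain_ratio         1.1159    0.2526  4.4169 1.001e-05
doppler4d            2.0668    0.8010  2.5801 9.876e-03

Deviance: 60.9056   AIC: 72.9056   Fisher scoring iterations: 6

                deviance     aic fisher_iterations
french_features  68.4210 78.4210                 6
plus_4d          60.9056 72.9056                 6

Preferred by AIC: plus_4d (lower AIC is better)
```

The strain ratio is the strongest single predictor; the 4D Doppler flag
is an informative addition on generator-default cohorts (where it is
genuinely class-dependent: 14.28% positive in benign vs 65% in malignant
nodules).

A thin command-line wrapper over the same functions is installed at
`inst/cli/tirads.R` (subcommands `classify`, `evaluate`, `simulate`,
`glm`, `corr`).

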