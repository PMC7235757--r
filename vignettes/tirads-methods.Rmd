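---
title: "Methods: TI-RADS rule engines, diagnostic evaluation and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TI-RADS rule engines, diagnostic evaluation and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiradsx)
```

## The problem

Ultrasound-based Thyroid Imaging Reporting and Data Systems (TI-RADS)
assign each thyroid nodule an ordinal malignancy-risk category from a
fixed set of B-mode features. Newer variants add two advanced-ultrasound
features: elastographic stiffness, summarised semi-quantitatively by the
strain ratio (SR, the parenchyma-to-nodule strain quotient), and
volumetric (3D/4D) Color Doppler findings — an interrupted thyroid
capsule or increased intranodular vascularization. `tiradsx` implements
five such systems as rule engines, the machinery to evaluate them
against a histopathological gold standard, a logistic-regression module
for predictor analysis, and a synthetic cohort generator calibrated to a
published 133-nodule surgical series so that the entire pipeline can be
exercised and tested without patient data.

## Nodule data model

A cohort is a plain `data.frame`, one row per nodule: composition,
echogenicity, shape (taller-than-wide), margins, echogenic foci (a set,
encoded as four 0/1 columns, because several foci types can co-occur and
the ACR score sums over them), 2D capsule and vascularity descriptors,
Hashimoto-background and colloid-pattern flags, the strain ratio
(non-negative real, optional), the Asteria 4-level color-map grade
(optional), the two 4D Doppler flags, lymph-node status, and the
pathology label. Pathology is binary; borderline follicular tumours are
labelled malignant, matching surgical-series convention for lesions with
unclear progression.

Validation enforces the vocabulary and three substantive invariants:
anechoic echogenicity only in cystic or mixed nodules; strain ratio
finite and non-negative; Asteria grade in 1–4. Completely cystic nodules
are valid records but carry an `out_of_study` flag, since the systems
compared here were evaluated on solid and mixed nodules.

Two positivity predicates are fixed by the design: stiffness is
`strain_ratio > 4` (strict; the cutoff established for this class of
strain-elastography equipment), and 4D Doppler positivity is the
disjunction of the capsule and intranodular flags. A missing strain
ratio is never imputed: predicates return `NA` and the French feature
count treats stiffness as absent with an explicit warning, so the gap is
always visible to the caller.

## The five rule engines

The EU, ACR and Horvath engines are direct transcriptions of the
published rules. Points for the cumulative ACR score live in an editable
configuration (`acr_points()`), since published band boundaries
(0–1 → TR1, 2 → TR2, 3 → TR3, 4–6 → TR4, ≥7 → TR5) are what the
classifier consumes. Two places required a design decision:

* **ACR total of 1.** The published bands leave a 1-point total
  unmapped; it arises only from near-contradictory inputs. We map totals
  below 2 to TR1, the conservative convention.
* **Horvath fallback.** The Horvath pattern list is not exhaustive.
  Patterns are evaluated from category 5 downward (highest risk wins,
  the usual risk-stratification convention), and an unmatched solid
  nodule falls back to 4A — the lowest solid-nodule suspicion tier. The
  fallback count is attached to the result so its frequency is never
  silent. Horvath's "thick capsule", "penetrating vessels" and
  "hypervascularized" were operator judgments in the original; their
  mapping onto the `capsule_2d`/`vasc_2d` enums is a modelling choice of
  this package.

The French engine counts high-suspicion features — taller-than-wide,
irregular margins (including extrathyroidal extension; *blurred* margins
deliberately do not count, as they are tracked as a separate descriptive
feature), marked hypoechogenicity, microcalcifications, and stiffness —
and maps lymph-node metastasis or ≥3 features to category 5, 1–2
features to 4B, mild hypoechogenicity to 4A, benign morphologies
(cyst/spongiform/isolated macrocalcification, read literally as
macrocalcification being the only focus with zero suspicion features) to
2, and the rest to 3. The 4D-augmented variant adds Doppler positivity
as a sixth countable feature. Because a feature can only be added, the
augmented category is never below the classic one — an upgrade-only
property that is property-tested over randomized records. The Asteria
grade is carried in the data model but not used for classification by
default; the strain ratio is the stiffness parameter of record.

EU-TIRADS folds "irregular shape" and taller-than-wide into one shape
feature, as the two are not separable in a feature table of this shape.

## Operating thresholds and diagnostic metrics

Each system's binary test-positive call is category ≥4 (EU, ACR) or ≥4B
(Horvath, French, French+4D). These are the operating points under which
the shipped per-category counts reproduce the published sensitivity,
NPV and accuracy values exactly; the original report does not state them
explicitly. All five metrics are computed at full precision as fractions
and rendered as percentages with two decimals (round half to even);
undefined ratios (zero denominators) are `NA`, never zero. Two published
ACR cells (specificity 31.81%, PPV 35.48%) are not reconstructible from
the published per-category counts under any single threshold; the
comparison report carries a note instead of force-matching them.

Calibration compares each category's calculated risk (malignant/total)
with the system's published expected band. Point expectations are
encoded as zero-width bands, open-ended ones as `[0, 0.05]` ("<5%"),
`[0.80, 1]` (">80%") and `[0.95, 1]` ("~100%"); the report flags each
category `below`, `inside`, `above` or `no data`.

## Synthetic cohort model

The generator emulates the study conditions of the surgical series:
n = 133, malignancy prevalence 35/133, class-conditional Bernoulli
prevalences for blurred margins (28.57%/37%), microcalcification
(9.1%/31.4%), marked hypoechogenicity (3.06%/25.7%), taller-than-wide
(15.3%/42.8%) and 4D positivity (14.28%/65%), and per-class lognormal
strain ratios. Lognormal was chosen for its positive support and right
skew, typical of strain-ratio data, and because the two published
constraints per class — the arithmetic mean (2.54 benign, 5.56
malignant) and the exceedance P(SR > 4) (12.24%, 80%) — pin down exactly
two parameters. Writing `z = qnorm(1 - p)`, they reduce to
`sdlog^2/2 - z*sdlog + log(4/mean) = 0`; the smaller admissible root
(the less skewed distribution) is taken, giving (meanlog, sdlog) =
(0.809, 0.496) benign and (1.662, 0.328) malignant.

Marginals the series does not report are free defaults, chosen once as
plausible for a surgical solid-nodule population and not tuned:
irregular margins 5%/35% (strongly malignancy-associated, distinct from
blurred margins; the two are mutually exclusive, irregular drawn first
with the blurred draw probability inflated so the blurred *marginal*
stays on target), suspicious lymph nodes 2.5%/30% (expected ≈13
node-positive cases per 133 nodules, matching the series' surgical
indications), mild hypoechogenicity 45%/40%, Hashimoto background
8%/3%, colloid pattern 15%/0, spongiform 5%/0, 2D hypervascularity
10%/30%, thin/thick capsule 20%/10% and 10%/10%, macrocalcification
15%/10%, comet-tail 10%/2%, rim calcification 3%/5%. These affect only
the Horvath and ACR category mixes, not the quantities checked against
the published series. The combined 4D flag is split
vascularity-only/capsule-only/both at 50/35/15, a free default, because
per-component rates are not recoverable from a combined published rate.

The binary stiffness feature is always *derived* from the drawn strain
ratio, never drawn separately, so stiffness and SR can never disagree
downstream. Asteria grades are the cohort's SR quartile bins — a
monotone stand-in for the qualitative color-map grade. Composition is
solid unless the spongiform or colloid flag fires (colloid nodules are
generated mixed isoechoic, which is what makes the Horvath category-2
pattern reachable).

Dependence defaults to class-conditional independence. An optional
Gaussian copula couples any subset of the core features (the binary
suspicion features and SR): latent multivariate normals are transformed
to uniforms, binaries fire on the *upper* tail of their latent uniform
and SR uses the increasing lognormal quantile transform, so a positive
latent correlation induces positive association while every marginal is
preserved exactly. Non-PSD matrices are projected by eigenvalue
clipping (and rescaling to unit diagonal); asymmetric or unnamed
matrices are rejected. Independence remains the default because the
published correlation table mixes binary, ordinal and continuous
variables with an unstated estimator, so any target matrix would be a
guess.

What passing tests on synthetic cohorts do *not* show: real nodule
features are correlated (stiff nodules tend to be hypoechoic with
irregular margins), real strain-ratio distributions need not be
lognormal, and operator-judged features (Horvath's vascularity and
capsule descriptors) have inter-observer noise the generator does not
model. Synthetic recovery results validate the pipeline's plumbing and
the calibration of the generator, not clinical performance.

## Logistic regression

The predictor analysis uses a binomial logistic GLM fitted by Fisher
scoring (for the canonical logit link this is identical to
Newton–Raphson and to IRLS), authored in the package. Implementation
choices:

* initialisation at the observation level, `mu0 = (y + 1/2)/2`, with the
  working response built from a consistent `(eta, mu)` state — this
  makes the per-iterate deviance sequence monotone in practice and the
  iteration counts comparable to standard GLM software;
* convergence when the relative deviance change drops below `1e-8`
  (default), with `max_iter = 25`;
* deviance is −2 × log-likelihood (the saturated model has
  log-likelihood 0 for binary data) and `aic = deviance + 2k` by
  construction;
* standard errors come from the inverse Fisher information evaluated at
  the final coefficients; per-coefficient tests are Wald z statistics
  with two-sided normal p-values. (Descriptions of such analyses
  sometimes say "t-test"; the z/Wald reference is the binomial-GLM
  convention and is what is implemented.)
* (quasi-)separation is detected by coefficient-norm divergence or
  fitted probabilities pinned to 0/1 and is reported as
  `converged = FALSE` with a warning rather than silent estimates;
* TI-RADS categories enter the design matrix as their common ordinal
  rank (2→2, 3→3, 4A→4, 4B→5, 5→6), an order-preserving coding that is
  configurable by building the matrix differently.

The test suite verifies the fitter against closed forms (intercept-only
fit; single-binary-predictor slope = table log odds ratio), against a
direct BFGS maximisation of the log-likelihood on randomized small
datasets (agreement to 1e-6), and against `stats::glm` as an independent
cross-check. Model comparison reports deviance and AIC verdicts
separately, preferring the lower-AIC model; the correlation matrix is
plain Pearson on the coded columns, which for binary pairs is the phi
coefficient and for binary-continuous pairs the point-biserial
correlation (the estimator behind the published correlation table is
unstated; Pearson on coded values is the implemented default).

## Problem sizes and numerical choices

The stochastic checks use cohorts of 8,000–10,000 nodules with fixed
seeds and 3 (acceptance) or 3.5 (unit-level) Monte-Carlo standard-error
bands around the calibrated marginals; the oracle-equivalence check runs
100 randomized datasets of 25–50 observations with 1–3 predictors.
Published-table reproduction is exact arithmetic on shipped integer
counts and is checked to ±0.01 percentage points (the original tables
truncate rather than round, e.g. 32/35 printed as 91.42%), with
integer-printed risk cells checked at their printed precision. Degenerate
inputs are defined rather than accidental: empty cohorts produce empty
tables and all-zero confusion matrices, empty categories report `NA`
risk, and zero-denominator metrics are `NA`.

## Known limitations

* The rule engines operate on a coded feature table; anything upstream
  of feature extraction (image acquisition, elastography map processing,
  measurement of SR) is out of scope — SR arrives as a number.
* No confidence intervals or paired significance tests between systems
  are produced, and no size-based FNA recommendations: the package
  carries nodule size but no classifier uses it.
* The handling of technically inadequate elastography is a policy
  decision the package surfaces (explicit `NA`/warning) but does not
  make; no imputation is offered.
* K-TIRADS, ATA and AACE systems are not implemented.
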