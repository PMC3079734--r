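---
title: "Methods: CSF biomarker panel discovery and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF biomarker panel discovery and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpanels)
```

# The problem

Multiplex immunoassay panels measure on the order of 100–200 candidate
analytes in cerebrospinal fluid from cohorts that mix cognitively normal
subjects (Clinical Dementia Rating, CDR 0) with very mildly and mildly
demented subjects (CDR 0.5 and 1). Two questions drive the analysis: which
small combinations of analytes improve on the established CSF markers
(amyloid-β42, tau, p-tau181 and their ratios) for *diagnosis* — separating
CDR > 0 from CDR 0 — and which markers measured at baseline predict
*conversion* of cognitively normal subjects to CDR > 0. `csfpanels`
implements both arms as a reproducible pipeline with a synthetic cohort
generator that makes every stage testable.

# QC and preprocessing

Immunoassay data arrive with three pathologies the pipeline must handle
before any modelling: values censored below the assay's lower detection
limit (LDL), sporadically missing cells, and rare extreme readings.

The QC pass runs in a fixed, logged order — the order is part of the
contract, because permuting the LDL and outlier steps changes the outlier
moments:

1. **Measurability filter.** An analyte is excluded when *more than* 10% of
   its values are missing or below the LDL (the two are pooled for this
   rule; an analyte at exactly 10% is retained). The threshold is
   configurable (`run_config(missing_threshold=)`).
2. **LDL/2 imputation.** Below-LDL cells in retained analytes become LDL/2,
   the conventional point estimate for left-censored immunoassay readings.
   Truly missing cells stay missing and are deleted casewise per analysis;
   the package deliberately does no multivariate imputation of missing data.
3. **Outlier imputation.** Cells more than 5 SD from the analyte mean are
   replaced by the mean of the analyte in the 5 nearest subjects (Euclidean
   distance over all other retained analytes, each standardized, averaged
   over co-observed dimensions). Detection uses one-pass trimmed moments: a
   provisional sweep flags extremes, the mean/SD are recomputed without
   them, and a single final sweep fixes the outlier set. One pass keeps the
   procedure deterministic; an iterated version can chase its own tail on
   heavy-tailed analytes. Detection runs on the raw concentration scale,
   before transformation — the 5-SD rule is a data-cleaning rule about
   assay readings, not about the analysis distribution — and the report
   records this assumption.
4. **Transform selection.** Per analyte, the Box–Cox exponent λ is estimated
   by profile likelihood (grid −2…2, step 0.01) with a 95% profile CI.
   log10 is chosen when the CI excludes 1 *and* |λ̂| < 0.5, i.e. when the
   data look decisively closer to log-normal than normal; otherwise the
   identity is kept. Non-positive values force the identity (with a
   rationale code), and fewer than 20 positive observations are considered
   too little evidence to leave the raw scale. These two thresholds
   operationalize "log when appropriate"; they are intentionally
   conservative so that borderline analytes stay interpretable in raw
   units.

The pass conserves the data shape (cells change value, never count) and is
idempotent: running it twice changes nothing the second time.

# Univariate screen

Each analyte is tested with the linear model `value ~ group + age + gender`
(group = CDR 0 vs CDR > 0; the very mild and mild groups are pooled because
both carry the same clinical diagnosis and the mild group is small). The
group effect uses the partial F-test; adjusted means are least-squares means
evaluated at the whole-sample covariate means, with gender at its sample
proportion — the standard LS-means convention. For logged analytes the
adjusted mean is back-transformed as 10^LSmean so tables read in
concentration units. Interaction models (`group × age`, `group × gender`)
are reported separately and never alter the main screen.

Multiple testing uses Bonferroni only — with 125 measurable analytes plus 3
traditional markers the familywise 5% cutoff is 0.05/128 ≈ 0.0004. The test
count is exposed in `run_config(bonferroni_n=)` because whether derived
ratios count as extra tests is a study-level decision.

Spearman correlations (midranks, t-approximation p-values, pairwise
deletion, minimum 10 pairs) describe each analyte's association with age and
the established markers; gender contrasts use the Mann–Whitney test with the
tie-corrected normal approximation.

# Binormal ROC panels

The diagnostic arm assumes markers (on their analysis scale) are
approximately Gaussian within each group. For a panel with group means
μ₀, μ₁ and covariances Σ₀, Σ₁, the linear combination maximizing the AUC is

$$ a \propto (\Sigma_0 + \Sigma_1)^{-1} (\mu_1 - \mu_0), \qquad
   \mathrm{AUC} = \Phi\!\left(\sqrt{(\mu_1-\mu_0)^\top (\Sigma_0+\Sigma_1)^{-1} (\mu_1-\mu_0)}\right), $$

which reduces to Φ(|δ|/√(σ₀²+σ₁²)) for one marker. Sensitivity at fixed
specificity p sets the threshold on the control score distribution,
c = aᵀμ₀ + z_p √(aᵀΣ₀a), and evaluates Φ((aᵀμ₁ − c)/√(aᵀΣ₁a)). The test
suite verifies the optimality claim directly: on random 2–4 marker
instances the closed form dominates 10,000 random unit directions to 1e-9.

Panel search is deliberately targeted rather than exhaustive: the best
2-marker panels (an established ratio plus one analyte) are expanded with
the top single analytes into 3-marker panels, skipping candidates already in
the base and deduplicating by marker set.

Evaluation uses a stratified bootstrap (resampling with replacement within
the CDR groups, preserving the design's group sizes), default B = 100. Per
resample the panel and its nested 2-marker reduction are refitted and the
analytic AUC, the sensitivity at the target specificity, and a one-sided
p-value for ΔAUC > 0 are recorded; the p-value comes from the paired DeLong
(placement-value) comparison of the two panels' combination scores on that
resample, a normal approximation to the paired ΔAUC. Reported summaries are
means, SDs, and 95% normal-theory CIs (mean ± 1.96 SD/√B) across iterations.
Bootstrap dispersion was chosen for the CIs in preference to asymptotic
formulas because it is consistent with averaging all performance measures
over the same resamples; with a degenerate resample (a collapsed group) the
iteration is redrawn and counted.

Derived ratio markers (e.g. tau/Aβ42) are computed on the raw concentration
scale *before* transformation — after LDL/2 imputation so the denominator is
positive — and then log10-transformed, which is how such ratios are
conventionally analysed.

# The resampling classifier harness

The machine-learning arm is a protocol, not a particular learner: the data
are split into stratified 80% training / 20% test sets, default 200 times;
classifiers are fitted on each training split (all hyperparameter tuning
happens inside the split, by inner resampling — 5 inner splits by default)
and scored on the held-out subjects. Sensitivity and specificity are taken
at the argmax-posterior operating point (score ≥ 0.5; positive class =
CDR > 0), the AUC from held-out scores, and all metrics are averaged over
splits. The Youden index J = sens + spec − 1 is recomputed on every emitted
row as an invariant. Age, gender and APOE ε4 carrier status are appended to
every predictor set.

Three reference classifiers are implemented natively — nearest shrunken
centroids (threshold grid 0.325–9.097 over 30 values), k-NN (k = 5…15) and
naïve Bayes (Gaussian or kernel-density conditionals) — because they are
simple enough to verify against closed forms in tests. Anything else
(random forests, boosting, SVM, PLS, …) attaches through the
`make_classifier()` adapter contract; importance extraction is native only
for NSC (the absolute shrunken standardized differences of surviving
features), since built-in importance is learner-specific. Top-k importance
overlap across models, and against the ROC panel's marker set, is reported
by `importance_overlap()`.

# Prognosis

Conversion analysis uses the baseline CDR 0 subjects with follow-up.
Markers are Z-scored over that analysis subset (not the full cohort — the
CDR > 0 subjects are not part of the risk set, and a config switch would be
the only defensible alternative), so hazard ratios read per SD; age stays in
raw years so its HR reads per year. Markers whose *decrease* raises risk
(amyloid-β42) enter as reciprocals computed before log/Z-scoring, keeping
all reported HRs above 1.

Cox models are fitted by partial-likelihood maximization with Efron tie
handling — annual-visit conversion times are heavily tied, and Efron's
approximation is the accurate default there. The staged selector mirrors
standard epidemiological practice: univariate screen at p < 0.15; any pair
of surviving markers with Spearman |ρ| ≥ 0.4 (p < 0.05) is never
co-included, the conflict graph being split into alternative candidate
models evaluated separately (the 0.4 threshold is exposed in config — it is
a judgment call, set well below the level at which joint inclusion becomes
uninterpretable); backward elimination at p < 0.05 with age and gender
re-tested at every step; final models ranked by AIC = −2 logPL + 2k. The
overall HR is the product of the component HRs (= exp of the coefficient
sum), an arithmetic identity the tests verify against the fitted
coefficients.

# The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated. Analytes are driven by a two-factor latent Gaussian model: a
"tau-like" neurodegeneration factor that a majority (default 60%) of
analytes load on, and an "amyloid-like" factor that few (default 10%) load
on — reproducing with two parameters the empirical pattern that many CSF
analytes track tau while few track Aβ42. Defaults emulate the cohort scale
the analyses assume: 242/63/28 subjects at CDR 0/0.5/1, ages ≥ 60 drawn
from group-specific normals (means 71.6/74.6/76.8), group-specific female
and APOE ε4 fractions, 125 analytes of which 12 carry true latent shifts
(1.0 down to 0.4 SD — the magnitude range a Bonferroni-surviving hit needs
at this sample size), half log-normal marginals, 2% LDL censoring, 1%
missingness, and an outlier rate of ~0.2% chosen so a full cohort carries
roughly 80 extreme values. Outliers are injected at mean ± U(5.5, 8) SD so
the 5-SD rule must catch them; conversion times are exponential
proportional-hazards draws observed at annual visits with censoring at the
last visit.

What the generator does *not* emulate: analyte-specific real-world
distributions (units and scales are schematic), assay plate/batch effects,
longitudinal within-subject correlation, or informative missingness.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artefact of real
immunoassay data.

`true_panel_model()` returns the closed-form binormal truth (means,
factor-implied covariance including age/gender variance contributions,
optimal combination, AUC) for any panel, enabling parameter-recovery tests;
it assumes the covariate distributions are group-balanced, so truth-based
tests switch covariate effects off.

# Numerical choices and degenerate inputs

* Binormal fits require per-group n above the panel size; a singular summed
  covariance gets a small logged ridge (or an error in strict mode).
* The combination coefficients are normalized to unit length with the sign
  pointing from controls to cases; with δ = 0 the AUC is exactly 0.5.
* Empirical AUC uses midranks (ties count 1/2) in double precision (the
  pair count overflows integers near n = 10⁵).
* `empirical_auc` returns the raw orientation plus a folded variant rather
  than silently orienting — a panel that scores *below* chance is a sign
  error the analyst should see.
* Box–Cox on a constant vector is an error; on non-positive data the
  identity is returned with a rationale code.
* k-NN breaks distance ties by training order; NSC and naïve Bayes
  normalize posteriors in log space.
* Cox fits stop after 50 Newton iterations with non-finite coefficients;
  complete separation surfaces as the usual monotone-likelihood warning.

# Problem sizes used in the shipped checks

The test suite exercises the pipeline at the sizes the statistics need, not
larger: calibration of the screen uses 20 null cohorts of 333 × 125;
optimality checks use 200 random instances against 10,000 directions;
ROC/empirical agreement uses n = 10,000; Cox recovery uses n = 2,000; the
staged-selection recovery scenario uses 500 baseline-normal subjects with
~10 annual visits and baseline hazard 0.03/yr (≈ 180 events — a sound
events-per-variable regime for a selection demonstration, chosen once as
the demonstration condition); the end-to-end determinism check runs a
reduced cohort (165 subjects, 30 analytes, B = 15, 10 splits), since
determinism is a property of the seeding discipline, not of scale.

# Known limitations

* The binormal machinery is exact only under within-group normality; the
  transform-selection stage is what makes that assumption tenable, and
  markers that refuse normalization are still analysed, just with an
  approximate model.
* Bootstrap CIs are normal-theory summaries of the iteration distribution;
  no BCa or studentized variants.
* No FDR option in the screen (Bonferroni only, by design); no partial AUC;
  panels beyond 3 markers are out of scope for the targeted search.
* The selector's correlated-pair rule arbitrates pairs, not higher-order
  collinearity.
* Native learners cover NSC, k-NN and naïve Bayes only; everything else is
  the adapter's responsibility, including its own importance measure.
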