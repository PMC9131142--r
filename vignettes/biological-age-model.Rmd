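---
title: "Estimating biological age from physiological biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biological age from physiological biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bioage)
```

## The problem and the model

Chronological age (CA) is a poor summary of individual physiology: two
60-year-olds can differ widely in blood pressure, glycemic control, lung
function and aerobic capacity. Biological age (BA) condenses a panel of such
biomarkers into a single year-scaled quantity that locates an individual on
the aging trajectory of a healthy reference population. `bioage` implements
the first-principal-component (1PC) family of BA estimators: the leading
eigenvector of the standardized biomarker correlation matrix is treated as a
general aging axis, projected scores are rescaled to years, and a final
linear correction removes the regression-toward-the-mean artifact inherent
in score-based estimators.

The estimator is built in four steps, all of which are exact linear algebra
rather than iterative fitting:

1. **Score.** For biomarkers $x_1,\dots,x_N$ with training means $\mu_n$,
   SDs $\sigma_n$ and unit-norm loadings $a_n$,
   $\mathrm{BAS} = w_0 + \sum_n w_n x_n$ with $w_n = a_n/\sigma_n$ and
   $w_0 = -\sum_n w_n \mu_n$. By construction the training score has mean 0
   and SD $\sqrt\lambda$, where $\lambda$ is the leading eigenvalue.
2. **T-scale.** $\mathrm{BA} = (\mathrm{BAS}/\sqrt\lambda)\,\sigma_{CA} +
   \overline{CA}$, so BA matches the mean and SD of CA on the training
   sample.
3. **Correction.** With $b$ the OLS slope of BA on CA,
   $\mathrm{BAc} = \mathrm{BA} + (CA - \overline{CA})(1-b)$.
4. **Expansion.** Substituting 1–3 gives corrected coefficients on the raw
   biomarker scale: $w_n\,\sigma_{CA}/\sqrt\lambda$ per biomarker, $1-b$ on
   CA, and intercept $w_0\,\sigma_{CA}/\sqrt\lambda + b\,\overline{CA}$.

Three identities follow algebraically and are enforced to $10^{-9}$ in the
test suite for every fitted model: $\overline{\mathrm{BAc}} =
\overline{CA}$, the in-sample slope of BAc on CA is exactly 1, and
$\mathrm{corr}(\mathrm{BAc}, CA) = 1/\sqrt{2-b^2}$. The last identity is
worth noting: the in-sample correlation of a corrected 1PC estimator is a
deterministic function of the score-age correlation $b$, not independent
evidence of validity. For the shipped reference models ($b = 0.80$ women,
$b = 0.68$ men) it evaluates to 0.86 and 0.81.

### The T-scale normalization

The single most consequential numerical choice in the package is whether the
score is standardized to unit variance before T-scaling. A literal reading
of the scale step is $\mathrm{BA} = \mathrm{BAS}\,\sigma_{CA} +
\overline{CA}$, but the published corrected equations are only consistent
with prior division by $\sqrt\lambda$: for the male model,
$0.431 \times 13.8/\sqrt{2.25} = 3.97 \approx 3.96$ (the printed FEV1
coefficient), whereas $0.431 \times 13.8 = 5.95$ is not. `tscale()`
therefore standardizes by default and offers `standardize = FALSE` for
comparison. Without standardization BA would have SD
$\sqrt\lambda\,\sigma_{CA}$ — about 20 years here — and none of the
identities above would hold.

Orientation is the second necessary convention: eigenvectors are
sign-ambiguous, so loadings are anchored by forcing one biomarker's loading
non-negative (default: total cholesterol, which rises with age in the
reference cohort; CA itself when it is included diagnostically).
Standardization uses the sample SD (n−1); complete cases over the model
columns define the training rows, and the CA scale constants are computed on
those same rows so the identities are exact.

## Screening conventions

The screening module reproduces a systematic stepwise selection:

* Gate: $|r| > 0.15$ strict, $p \le .05$ inclusive (two-sided, from the t
  transform of r with n−2 df — the conventional choice; the method source
  does not state one). No multiple-testing correction is applied, by design.
* Outliers: a 99% reference interval of mean ± 2.96 SD, flagging strictly
  outside values. The 2.96 multiplier is unusual (2.576 is the conventional
  99% z value) but is retained as published. Flags are advisory only.
* Redundancy: edges at $|r| \ge 0.7$ inclusive; clusters are connected
  components (the published analysis reasons pairwise and never encounters a
  chained cluster; components are the deterministic generalization). The
  representative is the highest-priority member if any appears in the
  clinical-priority list, else the most age-correlated member. Decisions
  that published analyses made on clinical grounds below the 0.7 threshold
  (keeping HbA1c over fasting glucose at $r = 0.29$) are expressed as manual
  overrides, not encoded as rules.
* MAP replacement: when systolic and diastolic pressure both pass the gate
  and cluster together, the pipeline synthesizes mean arterial pressure,
  re-screens it, and retires the two pressures (default on).
* Missing data: correlations use complete pairs; pruning uses pairwise
  complete observations. Disease-history eligibility is modelled as a
  boolean `eligible` column honored by a filter, never inferred from
  biomarker values.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` emulates the design of the reference study: equal
numbers of each sex per age bin over 18–65 y (default ten 4.7-year bins,
five per sex per bin, 100 adults total), ages uniform within bins. This
design has mean age 41.5 and SD 13.6 y, bracketing the published scale
constants (41.3/13.6 women, 41.1/13.8 men). Each biomarker follows the
linear model `mean + sex_shift + slope (age − 41.2) + ε`, with the
published pooled means, SDs and per-year slopes of all 32 candidates, and
the residual SD chosen so the marginal SD over the age design equals the
published SD. Residual variance is floored at 10% of the marginal variance:
the floor binds only for handgrip strength, whose published slope (−0.8/y,
with a CI of −0.2 to 0.1 that excludes its own point estimate — stored as
printed and surfaced by `registry_quality_flags()`) explains more variance
than the published SD allows; the generator warns accordingly, and the
resulting near-deterministic handgrip-age correlation in synthetic data is
an artifact of that published inconsistency.

Choices the data could not pin down, made once and documented here:

* Within-bin age distribution: uniform (the study balances counts per bin
  but does not state the within-bin law).
* Sex offsets: the reference table is pooled across sexes, so sex-specific
  marginals are unrecoverable. The defaults (males +8 cm waist, +0.8 L
  FEV1, +6 mL/min/kg VO2max, −0.25 mmol/L HDL, −3500 adiponectin, +4/+2
  mmHg SBP/DBP) are plausible physiological differences, applied
  symmetrically (±offset/2) so pooled means still match the registry. They
  are package defaults, not published values.
* Residual correlation: identity except SBP–DBP at 0.81 (the one published
  intercorrelation value). Real biomarkers share further residual
  correlation; omitting it means synthetic leading eigenvalues (typically
  2.0–2.5 for the 9-biomarker panel at n = 50 per sex) sit at or below the
  published 2.79/2.25, since here biomarkers co-vary only through their age
  trends.
* Impossible values: non-positive draws are resampled, not clipped, to
  preserve distributional shape (at most 100 redraws per record). For
  biomarkers whose mean is within ~1.5 SD of zero (leptin, CRP) this
  truncation upward-biases the marginal mean — an intended consequence of
  positivity, checked explicitly in the tests.

Consequently, passing tests on synthetic data demonstrate the estimator's
constructional guarantees and parameter recovery (generator slopes are
recovered with ≥ 90% CI coverage over 50 seeds at n = 200 per sex), not the
empirical performance figures of the original human cohort (r = 0.86/0.81,
SEE 8.2/10.2 y), which cannot be reproduced without the undeposited data.

## Published reference models and the audit

`published_model()` returns both published parameterizations verbatim: the
score equations and the expanded corrected equations, with loadings,
eigenvalues (2.79 female / 2.25 male over 9 variables, i.e. 31.0% / 25.0%
explained) and scale constants attached. Reconstructing each corrected
coefficient from its score coefficient reproduces all nine printed male
biomarker coefficients within 0.01 (the rounding noise of 2–3 significant
figures). `audit_published_model()` flags every print-level inconsistency
and deliberately leaves the fixtures uncorrected: the male corrected
intercept (−70.37 printed vs ≈ −75.4 derived, almost certainly a typo); the
female FEV1 score coefficient (−0.018 printed, yet only ≈ −0.249 is
consistent with the printed corrected coefficient −2.03 — apparently a
duplication of the neighbouring waist coefficient); and 0.01–0.03 drift in
the female intercept, MAP, HDL, TC and suPAR terms attributable to score
coefficients being rounded before expansion.
Similarly, the published male VO2max contribution (22.6%) differs by 0.05
from the value recomputed from the printed (rounded) loadings (22.5%);
contributions are reported as computed.

## Problem sizes and numerical tolerances

The test suite exercises cohorts of 100–400 individuals and checks the
exact identities at $10^{-9}$, oracle equivalences (power-iteration
eigenpairs, two-pass Pearson r, brute-force SEE) at $10^{-8}$–$10^{-12}$,
and stochastic properties (coverage, sign recovery, held-out slope/bias)
over 5–50 seeds; these sizes give stable Monte-Carlo behaviour at
negligible runtime. Degenerate inputs are defined errors, not silent
results: zero CA variance, constant biomarkers in a PCA, missing model
biomarkers at prediction, and truncated or version-mismatched model
documents all fail with specific messages, while zero-variance differences
in the paired t test return an explicit degenerate flag.

## Limitations

The model is linear throughout — linear biomarker-age trends and a linear
projection — and is estimated from cross-sectional data, so it quantifies
age differences at one point in time, not individual aging rates. Only the
first principal component is used; sex-stratified fits on ~50 individuals
per stratum carry substantial sampling error in loadings. The synthetic
generator shares these assumptions and therefore cannot reveal violations
of them.
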