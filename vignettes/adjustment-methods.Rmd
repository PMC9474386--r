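---
title: "Head-size and age adjustment of regional brain volumes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-size and age adjustment of regional brain volumes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tivadj)
```

## The two adjustment models

`tivadj` compares two ways of removing head size (total intracranial
volume, TIV) and age from a regional brain volume ROIV before judging
whether an individual subject deviates from a normative database.

**Residual method.** ROIV is regressed on TIV and age in the database
with quadratic and interaction terms,

$$\mathrm{ROIV} = a\,\mathrm{TIV}^2 + b\,\mathrm{age}^2
  + c\,\mathrm{TIV}\cdot\mathrm{age} + d\,\mathrm{TIV} + e\,\mathrm{age} + f,$$

by ordinary least squares, and a subject is characterized by the residual
$\mathrm{resROIV} = \mathrm{ROIV} - \widehat{\mathrm{ROIV}}$. The
quadratic age term captures the accelerating decline of brain volume over
the adult range, and the TIV×age interaction the steeper volume-vs-TIV
slope in younger subjects. The TIV² term is retained even where its
coefficient is not significant: the full model is the specification, and
significance flags are reported but never used to drop terms
(per-coefficient two-sided t-tests at α = 0.05 — a reporting convention,
not a model-selection device).

**Proportion method.** The fraction ROIF = ROIV/TIV is formed first, then
age-adjusted via $\mathrm{ROIF} = r\,\mathrm{age}^2 + s\,\mathrm{age} + t$
with residual $\mathrm{resROIF}$. Its implicit assumption is strict
proportionality, ROIV = slope·TIV. Empirically the relation has a positive
intercept, ROIV = slope·TIV + intercept, so
ROIF = slope + intercept/TIV still decreases with TIV: the proportion
method *flips* the TIV association instead of removing it. The residual
method removes it exactly — least-squares residuals are orthogonal to
every regressor, so their sample correlation with TIV and age is zero to
machine precision on the fitting set. These two facts are the package's
central contrast, and both are asserted in the test suite.

## Outlier handling: two passes, Tukey fences

Each model is fitted twice. Pass 1 uses all subjects; residuals outside
the Tukey fences — below Q1 − 1.5·IQR or above Q3 + 1.5·IQR — mark their
subjects as outliers; pass 2 (the final fit) uses the remainder. There is
deliberately **no** iteration to convergence: the procedure is exactly
two passes, and outlier sets are determined separately per ROI and per
method. Choices a user can change: the fence multiplier (`fence_k`,
default 1.5) and the minimum fitting size (`min_n`, default 30 complete
subjects — normative fits should of course use far more; the floor only
guards against degenerate calls).

Quartiles (and the 95th percentile of |z-diff|) use linear interpolation
of order statistics (`stats::quantile` type 7). No convention is uniquely
standard here; type 7 is R's default and the choice is isolated inside
`flag_outliers()` so it can be swapped. A numerical guard widens the
fences by `1e-8·SD(response)` so that the rounding jitter of an exactly
fitting (noise-free) model is never mistaken for dispersion; it is
invisible at any realistic noise level. Values exactly on a fence are
inside it.

## z-scores and the reference SD

Residuals become z-scores by division by the **normative database's**
residual SD: `z-resROIV = resROIV / SD(resROIV)`, likewise for the
fraction, and the method discrepancy is `z-diff = z-resROIF − z-resROIV`.
Two decisions matter:

- The reference SD is the **pass-2 SD over non-outlier subjects**. The
  alternative (all subjects including outliers) would inflate the
  denominator with exactly the points the fit excluded; the non-outlier
  SD is also what makes the database's own z-scores have unit SD, which
  the tests assert to 1e-8.
- Target subjects (patients) are **never refitted and never
  outlier-filtered**: they are scored against the frozen database models.
  Subjects outside the database's age range are scored but flagged as
  extrapolations; subjects with missing inputs get a per-row error note
  rather than aborting the run.

## The synthetic cohort generator

Clinical normative databases are not shareable, so the package generates
cohorts whose joint distribution of TIV, age and regional volumes is
**moment-matched** to published normative summaries. The generative model
per ROI is

$$\mathrm{ROIV} = \beta_0 + \beta_1\,\mathrm{TIV} + \beta_2\,\mathrm{age}
  + \beta_3\,\mathrm{age}^2 + \beta_4\,\mathrm{TIV}\cdot\mathrm{age}
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_\varepsilon^2),$$

with TIV and age independent truncated normals. Given targets (mean, SD,
corr with TIV, corr with age) and fixed small $\beta_3, \beta_4$, the
remaining coefficients have closed forms: with TIV ⟂ age,
$\mathrm{Cov}(\mathrm{ROIV},\mathrm{TIV}) = \beta_1\mathrm{Var(TIV)} +
\beta_4\,\mathrm{E[age]}\,\mathrm{Var(TIV)}$ identifies $\beta_1$, the
age covariance (including the age² and interaction contributions, via
exact truncated-normal moments up to order four) identifies $\beta_2$,
$\sigma_\varepsilon^2$ is the target variance minus the systematic
variance, and $\beta_0$ centres the mean. If the requested correlations
would explain more than the total variance the calibration aborts with a
named infeasibility error. `calibrate_generator()` is validated against a
brute-force oracle: a 200 000-record simulation must reproduce every
target moment (mean within 0.5% relative, SD within 2%, correlations
within 0.01 absolute; the brain-parenchyma row additionally within
0.5 ml / 1 ml / 0.01).

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| age | TN(49.6, 16.7) y on [20, 90] | the reference cohort's printed mean, SD and range |
| female fraction | 0.576 | reference cohort; sex is carried but enters no model (it exists for subgroup reruns) |
| TIV mean | 1112.66/0.813 ≈ 1368.6 ml | identified by the ratio of the mean parenchymal volume to the mean parenchymal fraction |
| TIV SD | 140 ml | not identifiable from first moments; chosen once so the implied fraction-scale SDs (≈5.4%, 0.11%, 0.06%) and fraction-vs-TIV correlations (≈−0.3 to −0.5) sit in the plausible reference range |
| β₃ | −1.5·10⁻⁶ × target mean (ml/y²) | the reference analysis reports the quadratic age term's sign and significance but no magnitude; a small negative keeps the term present while σ_ε absorbs the unexplained variance |
| β₄ | −1·10⁻⁷ × target mean (1/y) | same status as β₃: negative (steeper TIV slope at younger age), magnitude a configurable stand-in |
| thalamic atrophy | 0.10 | closed-form calibration atrophy ≈ 1.5·σ_ε/E[THALV at patient age] so the synthetic patient cohort's mean residual-method z is ≈ −1.5, the regime where the AUC contrast between methods is informative |
| patient ages | mixture: 33/127 at TN(42.2, 10.1), 94/127 at TN(37.3, 8.9), on [20, 90] | the two patient subsamples' printed means and SDs |

Records violating 0 < ROIV < TIV are **redrawn wholly** (rejection
sampling), not clipped — clipping would distort the calibrated moments;
with the default calibration violations are vanishingly rare, so the
conditional law is essentially the unconditional one. Ages in
user-supplied tables outside [20, 90] produce a warning and an
extrapolation flag, not rejection: the models' validity range is the
database's range, but refusing to score a subject would hide rather than
flag the issue.

**What the generator does not emulate.** Gaussian noise around a smooth
surface: real residuals are heavier-tailed (real outlier counts will
exceed the ~0.7% that Tukey fences flag under normality), multi-scanner
heterogeneity is absent, the true age distribution is only matched in
mean/SD/range (the truncated normal is a stand-in, not the empirical
histogram), and segmentation error structure is not modelled. Passing
tests therefore demonstrate the *methodological* contrasts — orthogonality,
sign flip, variability ordering, z-diff∼TIV coupling, AUC ordering — not
agreement with any particular scanner population's numbers.

## Evaluation battery

- **CoV** = 100·SD/mean, with adjusted values referenced to the *raw*
  measure's mean (residuals have mean zero, so their own mean is not a
  usable denominator).
- **Nuisance correlations**: Pearson r with TIV and age, significance
  starred at p < 10⁻⁴.
- **z-diff summary**: mean, 95th percentile and maximum of |z-diff|,
  fraction above one z-point, and correlations of signed z-diff with TIV
  and age.
- **Normality QC**: sample skewness and excess kurtosis with advisory
  pass bands (|skew| < 0.5, |excess kurtosis| < 1, configurable). A named
  hypothesis test is deliberately avoided — at n ≈ 5000 any formal test
  rejects trivially; the QC never gates the pipeline.
- **ROC/AUC**: Mann–Whitney rank formulation with mid-rank ties, equal by
  construction to the fraction of correctly ordered patient–control pairs
  and to the trapezoidal integral of the curve (both asserted to 1e-10).
  Orientation is fixed and documented: lower z = atrophy = positive
  class, with an internal sign flip so reported AUC is always on the
  higher-score-is-more-diseased scale. Controls are the non-outlier
  database subjects of the respective method, consistent with the z
  calibration; since patients are young and z-scores are age-adjusted,
  using all controls rather than an age-matched subset changes AUC only
  through the residual age-independence the models already enforce.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; the pipeline derives named
per-stage substreams from one top-level seed (`stage_seed()`), so adding
a stage never perturbs another stage's draws, and identical
configurations produce byte-identical artifacts (models carry a creation
timestamp; all other artifacts round-trip losslessly, with doubles
serialized at full precision). The test suite runs the study-scale
configuration — a 5059-subject database and a 127-patient cohort — for
single-seed checks, ten seeds for the cross-seed ordering properties, and
200 000 records for the calibration oracle; these sizes keep the full
suite in the tens of seconds while leaving Monte-Carlo error far below
the asserted tolerances.

## Known limitations

- No allometric (log–log) or higher-order polynomial models, no sex term,
  and no stepwise TIV-then-age residual variant: the comparison is
  between the two models above, as specified.
- Percentile/quantile normative scores are out of scope; only plain
  z-scores are produced.
- AUC is a point estimate; no DeLong or bootstrap confidence intervals.
- The generator's β₃/β₄ magnitudes are stand-ins. Their recovery by the
  fitted models is asserted only within standard errors, not as
  detectability (at realistic noise they are individually
  non-significant, which mirrors how weakly such terms are determined in
  real databases).
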