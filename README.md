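# tivadj

Head-size and age adjustment of regional brain volumes for single-subject
normative analysis.

## The problem

MRI-based regional brain volumes (brain parenchyma, thalamus, hippocampus)
scale with head size, and head size — proxied by the total intracranial
volume (TIV) — is a nuisance covariate in any between-subject comparison.
When a single patient's volume is compared against a normative database to
decide whether a region is atrophic, the adjustment method matters. Two
approaches dominate clinical volumetry:

- **Residual method.** Regress the regional volume (ROIV, ml) on TIV and
  age in a normative database,

  `ROIV = a·TIV² + b·age² + c·TIV·age + d·TIV + e·age + f`,

  and characterize a subject by the residual
  `resROIV = ROIV − model(TIV, age)`.

- **Proportion method.** Scale the volume to head size,
  `ROIF = ROIV / TIV`, then age-adjust the fraction via
  `ROIF = r·age² + s·age + t` and take `resROIF = ROIF − model(age)`.

Both residuals are converted to z-scores by dividing by the SD of the
normative database's residuals (computed over non-outlier subjects):
`z-resROIV = resROIV / SD(resROIV)`, likewise `z-resROIF`, and the
per-subject discrepancy between the methods is
`z-diff = z-resROIF − z-resROIV`.

The crux: regional volumes relate to TIV approximately linearly **with a
positive intercept**, `ROIV ≈ slope·TIV + intercept`, so the fraction
`ROIF = slope + intercept/TIV` still depends on TIV. The proportion method
therefore flips, rather than removes, the TIV association; the residual
method removes it exactly (an algebraic property of least squares). The
package quantifies the downstream consequences for single-subject
z-scores and for atrophy detection.

`tivadj` is aimed at researchers in quantitative neuroradiology and
biostatisticians evaluating normative volumetry pipelines. Because
clinical normative databases are rarely shareable, the package ships a
**moment-matched synthetic cohort generator**: given per-ROI target
moments (mean, SD, correlations with TIV and age), it solves in closed
form for generator coefficients whose simulated cohorts reproduce those
moments, and can add regional atrophy to emulate a patient group.

## Worked example

```r
library(tivadj)

params <- calibrate_generator()                       # built-in normative targets
db     <- generate_normal_database(params, n = 5059, seed = 20)
pat    <- generate_patient_cohort(params, n = 127, seed = 21)  # thalamic atrophy
report <- build_report(db, pat)
print(report)
```

```
residual method (volume, ml scale)
  ROI   values         n       mean        SD    CoV%   r_TIV   r_age
  BP    raw         5033       1114     116.9   10.49   0.79*  -0.43*
  BP    adjusted    5033 -2.455e-14     52.97    4.75  -0.00   -0.00
  ...
proportion method (fraction of TIV scale)
  BP    raw         5026     0.8146   0.05426    6.66  -0.25*  -0.63*
  BP    adjusted    5026  4.565e-17   0.04198    5.15  -0.36*  -0.00
  ...
abs(z-diff) of proportion vs residual method z-scores:
  ROI        n     mean      p95      max       >1   r_TIV   r_age
  BP      5059     0.31     0.84     2.44     2.6%   -0.92   -0.01
  THAL    5059     0.46     1.19     3.00     9.0%   -0.93   -0.01
  HIPP    5059     0.44     1.13     2.58     8.0%   -0.95   -0.01

Patient-vs-control discrimination (AUC, lower z = atrophy):
  THAL  residual 0.808  proportion 0.776  (127 patients)
```

Reading this: raw volumes correlate strongly with TIV (r = 0.79 for brain
parenchyma) and negatively with age. After residual-method adjustment the
correlations are 0.00 by construction and the coefficient of variation
(CoV = 100·SD/mean, adjusted rows referenced to the raw mean) drops from
10.49% to 4.75% — below the proportion method's 5.15%, whose adjusted
values still carry a *negative* TIV correlation (−0.36): the sign flip.
The z-score difference between the methods tracks TIV almost perfectly
(r ≈ −0.93) — the proportion method overestimates z in small heads and
underestimates it in large heads — and exceeds one z-point in several
percent of normal subjects. For a patient cohort with ~10% thalamic
atrophy, the residual-method z separates patients from controls better
(AUC 0.81 vs 0.78 here).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/tivadj.R simulate --n 5059 --seed 20 --out db.csv
Rscript inst/cli/tivadj.R fit --db db.csv --roi THAL --method residual --out thal_res.json
Rscript inst/cli/tivadj.R run-all --seed 20 --out results/
```

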