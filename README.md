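# isoqsar

QSAR model building and validation for Hsp90 inhibitors of the
3,4-isoxazolediamide class.

Heat-shock protein 90 (Hsp90) is an ATP-dependent chaperone that is
overexpressed in tumour cells; inhibiting its N-terminal ATPase is an
established anticancer strategy, and resorcinylic isoxazole amides
(the NVP-AUY922/luminespib family) are among the most advanced chemotypes.
`isoqsar` implements the statistical workflow used to model the inhibitory
activity (pIC50) of a 50-compound 3,4-isoxazolediamide series from large
molecular-descriptor matrices (DRAGON/quantum-chemical style, hundreds to
~1000 columns), for cheminformaticians who want that workflow as tested,
reusable, seed-reproducible R functions rather than a one-off analysis.

## What it computes

For an *n* compounds × *p* descriptors matrix **X** and activities
*y* = pIC50 = −log₁₀(IC50 in mM):

* **Preprocessing** — remove constant/near-constant descriptors, then
  greedily prune pairs with |r| > 0.9, keeping the member most correlated
  with *y* (`drop_invariant()`, `prune_collinear()`).
* **CDFS** (combined data-splitting feature selection) — repeat the
  calibration/validation split (default 9 of 50 held out, 5 repeats),
  select descriptors on each calibration set, elect the best per-split
  model, pool all selected descriptors, and refit on one calibration set
  to obtain a *general model* (`make_splits()`, `run_cdfs()`).
* **Selectors** — partial-F stepwise MLR (entry p < 0.05, removal
  p > 0.10, ≤ 7 terms; `stepwise_mlr()`) or a genetic algorithm over
  descriptor-inclusion bit vectors with cross-validated NIPALS-PLS Q² as
  fitness (`ga_pls()`, `fit_pls()`).
* **Validation** — leave-one-out / leave-three-out Q² with
  PRESS = Σ(yᵢ − ŷ₍ᵢ₎)², Q² = 1 − PRESS/Σ(yᵢ − ȳ)²,
  RMSE_CV = √(PRESS/n); external R²p (squared observed–predicted
  correlation); Y-randomization null models (`q2_cv()`,
  `r2_prediction()`, `y_randomization()`).
* **Applicability domain** — leverages h = xᵀ(XᵀX)⁻¹x, warning leverage
  h\* = 3(k+1)/n, standardized residuals and Williams-plot outlier flags
  (`leverages()`, `warning_leverage()`, `williams_table()`).
* **Published reference models** — the two published six-descriptor
  equations (general MLR, intercept 16.977; GA-PLS, intercept 9.018) as
  fixed predictors (`published_models()`, `predict_published()`), plus
  the published experimental/predicted activity tables as data fixtures
  (`hsp90_activity_table()`, `hsp90_ic50_table()`).
* **Synthetic data** — a seeded generator planting a sparse signal,
  collinear blocks and constant columns, including a 50 × 300
  study-shaped instance with known truth for end-to-end testing
  (`generate_qsar_data()`, `study_instance()`).

## Worked example

```r
library(isoqsar)

sim <- study_instance(seed = 1)   # 50 x 300 synthetic matrix, known truth
fit <- run_cdfs(sim$dataset, seed = 1)
summary(fit)
```

```
CDFS fit: 5 splits, selector stepwise, seed 1
  pooled descriptors: 23; best split: 3
general model (N = 41):
STEPWISE_MLR model (N = 41)
  pIC50 = 4.866 +1.526 D097 -0.864 D078 +1.136 D163 -0.798 D065 +1.134 D279 -0.644 D261 +0.664 D191
  R2c = 0.842, S.E. = 1.339
  Q2(LOO) = 0.760, RMSE_CV = 1.479, R2p = 0.241

per-split models:
 split n_descriptors                              descriptors  r2_c    se  r2_p    q2 rmse_cv
     1             7 D097, D078, D163, D065, D279, D261, D191 0.842 1.339 0.241 0.760   1.479
     2             7 D078, D063, D044, D261, D274, D020, D003 0.792 1.464 0.188 0.675   1.642
     3             7 D078, D163, D097, D164, D103, D186, D220 0.890 1.238 0.013 0.822   1.410
     4             7 D078, D163, D017, D202, D170, D164, D076 0.869 1.174 0.001 0.790   1.336
     5             7 D078, D063, D044, D220, D278, D086, D088 0.830 1.424 0.373 0.727   1.619

Y-randomization: 10 permutations
  original:  R2 = 0.842, Q2(LOO) = 0.760
  scrambled: max R2 = 0.287, max Q2 = -0.105
applicability domain: h* = 0.480; 4 response / 1 structural outlier(s)
```

The general model explains 84% of the calibration variance and holds a
leave-one-out Q² of 0.76, close to the planted signal level of 0.775;
every response-scrambled refit stays far below it (max R² 0.287), and the
Williams table flags the few compounds outside the ±2.5 SD / h\* = 0.48
domain. Checking which planted descriptors the model found (a selected
collinear child counts as a proxy for its parent):

```r
recovered_descriptors(sim$truth, names(coef(fit$general_model)))
#> [1] "D078" "D023" "D287"
```

Three of the six planted descriptors are recovered here — with ~270
surviving descriptors and 41 calibration compounds, chance correlations
compete with the weaker planted ones (see the methods vignette).
Predictions from a published reference equation:

```r
predict_published("mlr", c(X5A = 0.04, HATS4u = 0.5, Mor26p = -0.3,
                           TIE = 250, `dipole z` = 1.2, Mor26e = 0.1))
#> [1] 8.91576
```

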