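---
title: "Methods: CDFS QSAR modelling, validation and applicability domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDFS QSAR modelling, validation and applicability domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoqsar)
```

## The modelling problem

`isoqsar` models the Hsp90 inhibitory activity of 3,4-isoxazolediamides
as a linear function of molecular descriptors. The data situation is the
typical small-n/large-p QSAR setting: ~50 compounds described by
hundreds of correlated DRAGON-style descriptors (connectivity indices,
3D-MoRSE, WHIM, GETAWAY, RDF, autocorrelations, quantum-chemical
dipoles). The statistical task is therefore dominated by variable
selection and by honest validation of the selected model.

The activity is pIC50 on a millimolar base:
$\mathrm{pIC50} = -\log_{10}(\mathrm{IC50\ in\ mM})$. This base is
unusual (molar is conventional) but it is the only convention that
reconciles the packaged micromolar IC50 table with the packaged pIC50
table (0.153 uM maps to 3.82, 0.020 uM to 4.70); `ic50_to_pic50()`
exposes the unit as an explicit parameter, so molar-scale users are not
locked in.

## The CDFS procedure

Because a single calibration/validation split strongly influences which
descriptors a selector picks, the workflow repeats the split several
times (combined data-splitting feature selection):

1. Preprocess: drop constant/near-constant columns, then greedily prune
   collinear pairs (|r| > 0.9), keeping the member more correlated with
   the activity.
2. Draw `n_repeats = 5` random splits, each holding out
   `n_validation = 9` of the 50 compounds (a 41-compound calibration
   set).
3. On each calibration set, run the descriptor selector — partial-F
   stepwise MLR by default, or GA-PLS — and validate the resulting model
   (R²c, S.E., leave-one-out Q², RMSE_CV, external R²p).
4. Elect the best split model: highest Q²(LOO), ties broken by R²c. The
   published account asks for an "equilibrium" between R²c and Q²; a
   lexicographic rule is the closest formalization, and both statistics
   are retained in the report so users can re-rank.
5. Pool every descriptor selected by any split model, and refit the
   selector restricted to that pool on one designated split's
   calibration set (split 1 by default, recorded in the manifest; an
   `"all"` option refits on all compounds at the cost of the N = 41
   convention). This is the *general model*.
6. Validate the general model fully: Q²(LOO), external R²p (with the
   stricter external Q²F1 reported alongside), a 10-iteration
   Y-randomization, and the leverage applicability domain.

Every stage derives its RNG stream from the master seed via fixed
substreams, so reports are byte-identical across runs and adding repeats
never changes earlier splits.

## Model engines and numerical choices

**OLS / stepwise.** OLS is solved by QR; rank deficiency is an error
naming the dependent column. Stepwise uses classic forward-entry /
backward-removal on partial-F p-values with the conventional
probability-of-F thresholds `p_enter = 0.05`, `p_remove = 0.10` (the
published work names the SPSS stepwise procedure without thresholds, so
the SPSS defaults are assumed and documented), and `max_terms = 7`, the
size of the largest elected split model. `p_enter < p_remove` is
enforced to preclude entry/removal oscillation; p-value ties break by
column order, making the output invariant to column permutation.

**PLS.** `fit_pls()` is PLS1 NIPALS: descriptors autoscaled (constant
columns rejected), activity centered, components extracted with
deflation of both blocks; the final model is re-expressed in raw
descriptor units. With a univariate response the NIPALS recursion
converges on the second pass; the iteration cap (`max_iter = 200`) and
tolerance (`1e-9` on the score vector) guard the general case. When the
component count is unspecified it maximizes leave-one-out Q², capped at
`min(6, rank)`. The cross-validated PRESS used for component selection
and as GA fitness runs in a small compiled kernel (RcppArmadillo) that
re-scales within each training fold; its exact agreement with per-fold
NIPALS refits in R is part of the test suite.

**GA-PLS.** Chromosomes are inclusion bit vectors; fitness is the
cross-validated PLS Q² of the selected columns (leave-one-out by
default; leave-three-out available, with the triplet covering drawn once
per run). Selection is tournament (size 2), recombination uniform
crossover (rate 0.9), mutation 1/p per gene, elitism 2 — none of these
settings are published, so conventional GA-PLS values scaled to
~100-descriptor inputs are used. Parsimony is a hard cap
(`max_subset_size = 10`, matching the six-descriptor outcome scale)
rather than a penalty, because a cap is easier to verify; oversized or
empty chromosomes get fitness −Inf and can never be elected. Fitness is
cached by gene vector, and elitism makes the best-ever fitness
non-decreasing (a tested invariant).

**Validation statistics.** Q² uses the full-calibration mean in its
denominator (not per-fold means) — the standard QSAR convention and the
one consistent with reporting a single RMSE_CV. Leave-three-out draws
random disjoint triplets covering all compounds (a remainder forms one
smaller group), repeated 10 rounds and averaged. R²p is the squared
observed–predicted correlation; its shift/scale blindness is documented,
and the external Q²F1 (about the calibration mean) is reported next to
it rather than silently substituted, because published R²p values
exceeding R²c indicate the correlation convention was used.
Y-randomization refits, by default, the fixed final descriptor subset;
passing a selecting fitter gives the stricter full re-selection variant.

**Applicability domain.** Leverage is the intercept-augmented hat value;
the warning leverage is h\* = 3(k+1)/n. The published number 0.42 equals
3·7/50 — i.e. n counted as all 50 compounds — although the accompanying
text defines n as the calibration size (3·7/41 ≈ 0.512). The default
follows the printed number (`h_star_n = "all"`); the calibration
convention is selectable, never silently resolved. Standardized
residuals divide by the population SD (divisor n) of calibration
residuals by default, with the (n−k−1) form available, since no formula
was published. Response-outlier limits default to ±2.5 SD for MLR-type
models and ±3.0 SD for PLS/GA-PLS, as in the published Williams plots. A
perfect-fit model (all residuals numerically zero) yields standardized
residuals of zero rather than an error; a zero residual scale with
non-zero residuals cannot occur.

**Published equations.** Both six-descriptor reference equations are
stored exactly as printed, including the TIE coefficient 0.001 (±0.00),
whose truncation propagates to predictions with large TIE values. The
equation-block Q²(LOO) of 0.637 and the narrative value 0.710 for the
same general model disagree in the source; both are carried as
documentation (`published_models()`), and neither is treated as a
regression target — the original descriptor matrix was never deposited,
so those statistics are not reproducible.

## The synthetic generator

`generate_qsar_data()` emulates the *statistical* structure the workflow
assumes: independent standard-normal base descriptors, a sparse linear
signal over a few informative columns, collinear children at a target
|r|, constant columns, and Gaussian activity noise.
`study_instance()` fixes the study-shaped defaults: n = 50, p = 300 (a
desk-scale stand-in for the original 50 × 1126 matrix), 6 informative
descriptors with absolute coefficients drawn from (0.75, 1.5) — chosen
so the weakest descriptor still carries a detectable partial signal
(partial t ≈ 3 at n = 41) while the coefficients remain unequal —
20 collinear pairs at r = 0.95 (children split evenly between
informative and uninformative parents, so the pruning rule is exercised
both ways), 10 constant columns, and the noise vector rescaled so the
realized OLS R² on the true descriptors is exactly 0.775, the middle of
the plausible 0.70–0.85 calibration band for six-descriptor models on
this series.

What the generator does *not* emulate: DRAGON descriptors' heavy-tailed,
bounded, family-specific marginals; block correlation structure beyond
planted pairs; and the experimental activity scale (the synthetic
activity spread is wider than the series' 2.8–5.0 pIC50 range — harmless
for testing, since every reported statistic is invariant to the scale
and location of y). Passing tests on synthetic data therefore
demonstrate correctness of the algorithms and calibration of the
validation statistics, not predictive performance on real descriptor
matrices.

A note on planted-descriptor recovery: a selected collinear child counts
as recovering its informative parent (`recovered_descriptors()`),
because at r = 0.95 the two are near-interchangeable proxies and the
collinearity filter legitimately keeps whichever is more
activity-correlated in sample. Even so, recovery at the study conditions
is intrinsically hard: with six descriptors sharing R² ≈ 0.775, each
one's marginal correlation with the activity (~0.35–0.45) is comparable
to the largest chance correlation among ~270 null descriptors at n = 41
(~0.55), so greedy stepwise admits spurious columns early and the 7-term
cap can exhaust before the weaker planted descriptors enter. The
package's test suite measures exactly this: the general model's Q²(LOO)
reliably tracks the planted signal level, while full recovery of 5 of 6
planted names is *not* reliably achieved at these settings — a genuine
property of sparse selection at this n/p ratio, reported rather than
hidden.

## Problem sizes used in the tests

The test suite exercises the full pipeline at the study shape
(50 × 300, 20 seeds for the recovery/Q² and Y-randomization properties),
the GA on a 60 × 40 benchmark with four planted descriptors (50
generations), and all numerical oracles (hat-matrix diagonal, brute-force
LOO refits, full-component PLS = OLS) on 18–30-compound problems —
sizes chosen so the whole suite completes in well under a minute while
still leaving the multi-seed properties statistically meaningful.

## Known limitations

* Stepwise and GA selections inherit the instability of variable
  selection at n ≈ 40–50; the CDFS repetition mitigates but does not
  remove it.
* R²p's correlation convention rewards any monotone-linear relation,
  biased or not; consult the reported `q2_ext` for a bias-sensitive
  view.
* The published models' descriptors (X5A, HATS4u, ...) must be computed
  elsewhere; the package deliberately contains no descriptor-generation
  or structure-handling code.
* Leave-three-out Q² depends on the random covering; it is averaged over
  10 rounds and seeded, but it is not a deterministic statistic like
  Q²(LOO).
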