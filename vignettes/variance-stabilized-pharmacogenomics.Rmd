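---
title: "Variance-stabilized drug response and drug-choice scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-stabilized drug response and drug-choice scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxscale)
```

## The problem

Pharmacogenomic studies of drug efficacy compare a biomarker before treatment
(baseline, $X$) and during stable treatment (on-drug, $Y$), and test genetic
variants against a change score. The two conventional change scores are the
absolute change $Y - X$ (raw scale) and the relative change $\log(Y/X)$ (log
scale). Both are differences of transformed levels, and both inherit a
well-known pathology: when the transformed baseline and on-drug distributions
have unequal variances, the change score correlates strongly with the levels
themselves. Any variant that shifts the *baseline* level then acquires a
spurious association with the *change* — inverted in sign on the raw scale
(where baseline variance typically exceeds on-drug variance for treated lipid
levels) and aligned in sign on the log scale (where the ordering reverses).

`pgxscale` implements the remedy: choose the Box–Cox power transformation

$$bc(x,\lambda) = \begin{cases}(x^\lambda - 1)/\lambda & \lambda \neq 0\\ \ln x & \lambda = 0\end{cases}$$

whose parameter $\lambda$ equalizes the two variances, by minimizing

$$\left| \log \frac{\mathrm{Var}[bc(Y,\lambda)]}{\mathrm{Var}[bc(X,\lambda)]} \right|$$

over a grid, and analyze the stabilized change
$bc(Y,\hat\lambda) - bc(X,\hat\lambda)$. The raw and log scales are the
$\lambda = 1$ and $\lambda = 0$ special cases, so the stabilized analysis
interpolates between the two conventional ones.

The package also implements a second, complementary analysis: a polygenic
score (PGS) for the *drug-choice* trait — among patients with a disease,
was this particular drug class prescribed? — trained by a multi-stage
residual-Lasso procedure and validated by AUC-ROC and decile stratification.

## The lambda search

`find_lambda()` evaluates the objective on the grid $\lambda \in [-2, 2]$ in
steps of $0.05$ with unbiased ($n-1$) sample variances.

* Grid rather than continuous optimization: the sample objective can be
  non-smooth, the grid is cheap (81 points), and a resolution of $0.05$ is
  finer than the scientific meaning of $\lambda$. Minimizers at $\pm 2$ set
  `boundary_hit`, signalling that the grid should be widened.
* Ties (within $10^{-12}$) break toward $\lambda = 1$, then toward
  $\lambda = 0$ — prefer the least-transformed scale when the data cannot
  discriminate. The degenerate case $Y = X$ ties everywhere and returns 1.
* Two exact special cases anchor the search and are asserted in the tests:
  a purely multiplicative drug effect ($Y = cX$) makes the objective exactly
  zero at $\lambda = 0$ and nowhere else on the grid; a purely additive
  effect ($Y = X - d$) does the same at $\lambda = 1$.
* The simple (unshifted, non-rescaled) Box–Cox form suffices because the
  variance *ratio* is invariant to the common geometric-mean rescaling some
  formulations apply.

`variance_objective()` refuses samples whose transformed variance is zero,
and `compute_response_metrics()` propagates domain errors (non-positive
levels) per subject rather than dropping them silently.

## The synthetic biobank generator

Nothing in the package requires controlled-access biobank data: the
generator (`sim_config()`, `simulate_cohort()`) produces genotypes,
demographics, disease status, drug choice and longitudinal records with
known ground truth. Its generative model is chosen so that the stabilized
analysis is *exactly* null while the raw and log analyses show the artifact:

* Latent baseline on the stabilized scale:
  $X' = \mu + \textstyle\sum_j \beta_j g_j + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$.
* Drug effect additive on the same scale: $Y' = X' - d + \eta$,
  $\eta \sim N(0, \tau^2)$.
* Observed levels by the inverse transform at the configured $\lambda_0$:
  $X = bc^{-1}(X', \lambda_0)$, $Y = bc^{-1}(Y', \lambda_0)$. Draws
  violating the inverse-transform domain are resampled a bounded number of
  times, then an error is raised — biomarkers stay positive without
  silently truncating the distribution.

Because the per-variant effect on $Y' - X'$ is identically zero, any
change-score association on another scale is the scaling artifact by
construction, and `find_lambda()` applied to $(X, Y)$ should recover
$\lambda_0$.

Default parameter values are fixed once, to resemble an LDL-C-on-statin arm
of a European-ancestry biobank: $\lambda_0 = 0.35$, $\mu = 1.8$ and
$\sigma = 0.30$ on the stabilized scale (raw baseline $\approx 4.0$ mmol/L),
$d = 0.9$ (raw on-drug $\approx 2.2$ mmol/L), ages uniform on 40–70 years,
BMI normal(29, 5) truncated at 15 kg/m², and a choice-model intercept of
$-0.2$ (about 45% of diseased subjects prescribed). The response noise
defaults to $\tau = 0.03$: the variance-equalization premise means
$\tau^2/\sigma^2$ must be small (here 1%), otherwise the objective's
minimizer is displaced from $\lambda_0$ by construction rather than by
sampling noise. $\tau$ and the measurement-noise coefficient of variation
(3%) are free knobs with no counterpart reported for the real data.

Drug choice follows a liability model: disease by thresholded liability at a
configured prevalence (default 50%), and, among the diseased, choice is
Bernoulli with log-odds
$\alpha_0 + b_s\,\mathrm{sex} + b_a(\mathrm{age}-\bar{\mathrm{age}}) +
b_b(\mathrm{BMI}-\overline{\mathrm{BMI}}) + \sum_j w_j g_j$ (genetic term
centered so $\alpha_0$ controls prevalence). The true genetic liability is
stored for recovery tests. Choice-causal variants occupy the tail of the
panel so they stay disjoint from baseline-causal variants.

What the generator does **not** emulate: linkage disequilibrium, imputation
error, sex chromosomes, relatedness, and population stratification. Passing
tests therefore demonstrate correctness of the *procedures* under a clean
additive model, not robustness to confounding that real cohorts carry —
which is why the association stage still accepts principal-component
covariates even though the synthetic cohorts do not need them.

## Longitudinal phenotyping rules

`derive_response_phenotypes()` converts prescription fills and dated
measurements into one $(X, Y)$ pair per subject:

* **Episodes**: maximal runs of fills of one drug class with consecutive
  gaps $\le$ 14 days (closed bound: a gap of exactly 14 days does not
  split). Episode end is the last fill date — no coverage duration is
  imputed, and on-drug eligibility is additionally capped at the episode
  end so post-discontinuation measurements never enter.
* **Baseline**: measurements $0 < \Delta \le 730$ days before initiation,
  with no same-disease prescription of *any* class in the 180 days up to and
  including the measurement date (the drug-free rule is anchored to the
  measurement, whose validity it protects). A measurement on the initiation
  day is neither baseline nor on-drug.
* **On-drug**: measurements 28–730 days after initiation (28 days for full
  therapeutic effect), inside the analyzed episode, and outside any
  overlapping episode of a different same-disease class (e.g. ezetimibe or
  fibrate during a statin episode).
* **Averaging**: multiple eligible measurements are combined with linear
  weights $w_i = D + 1 - \Delta_i$ ($D$ = window width), favouring
  measurements closer to initiation; the $+1$ keeps a boundary measurement
  at $\Delta = D$ strictly positive. Only "linear weighting toward
  initiation" is externally specified; this normalization is one admissible
  reading and is frozen in the worked example
  $(631 \cdot 4.0 + 381 \cdot 3.0)/1012 \approx 3.6235$.
* **One phenotype per subject**: the first episode with at least one
  eligible measurement on each side is analyzed. Measurements are
  deduplicated on (subject, biomarker, date) and the output is invariant to
  input row order.

Disease status (`derive_disease_status()`) combines diagnosis codes (E78
prefix for dyslipidemia, I10–I15 for hypertension) with biomarker
thresholds: LDL-C $\ge$ 190 mg/dL or HDL-C $<$ 40 mg/dL (cholesterol in
mmol/L converted at 38.67), SBP $\ge$ 160 or DBP $\ge$ 100 mmHg. Choice
labels (`derive_choice_labels()`) are restricted to diseased subjects —
cases use the drug, controls do not; healthy users are excluded, which is
what separates drug *choice* from drug *use*.

## Association testing and meta-analysis

`run_scan()` fits per-variant ordinary least squares with an intercept and
optional covariates via Frisch–Waugh residualization, vectorized across the
dosage matrix; `test_variant()` is the single-variant equivalent and agrees
with `lm()` to machine precision (and with a brute-force two-stage residual
regression in the tests). For response metrics only genetic principal
components should be supplied as covariates — adjusting a composite change
score for the demographic predictors of its components is improper.
Whole-genome mixed-model machinery is deliberately out of scope: synthetic
cohorts are unrelated and unstratified by construction, and the scaling
artifact argument does not depend on the estimator.

`meta_fixed()` combines studies by inverse-variance fixed effects
($\beta = \sum \beta_k/se_k^2 / \sum 1/se_k^2$,
$se = (\sum 1/se_k^2)^{-1/2}$), restricted to variants present in all
studies, harmonizing swapped allele pairs by negating the effect.
`sign_concordance()` summarizes the artifact: among baseline-associated
variants, the fraction whose change-score effect shares the baseline
effect's sign — near 0 for absolute change, near 1 for relative change,
near one half once stabilized.

## Drug-choice PGS

`train_choice_pgs()` implements the multi-stage construction:

1. **Splits** (`make_splits()`): a fixed 20% blind-test set; the remaining
   80% re-partitioned 20 times into 60%/20% (of the whole cohort)
   train/tune sets. Test subjects never touch any fitting stage, which the
   tests assert from the split bookkeeping.
2. **Basic score** (`fit_basic_score()`): logistic regression of choice on
   sex, age and BMI with principal-component covariates; the three
   demographic coefficients are the basic-score weights.
3. **Residual Lasso** (`fit_lasso_residual()`): squared-error Lasso
   (glmnet) of the response residuals (label minus fitted probability) on
   the index-SNP dosages, over 25 log-spaced penalties on $[0.001, 1]$. The
   external specification says only "residuals"; response residuals with a
   linear Lasso are used because the later calibration stage absorbs any
   scale this choice induces.
4. **Penalty tuning** (`tune_penalty()`): per penalty, logistic regression
   of the tuning labels on the tentative PGS alone; the penalty with the
   largest Wald Z wins, ties to the sparser model.
5. **Scaling factor** (`fit_scaling_factor()`): joint unpenalized logistic
   fit of tuning labels on basic score and tentative PGS. The basic-score
   coefficient should be near one (a diagnostic that the training
   regression replicates); the tentative-PGS coefficient rescales the SNP
   weights to unit log-odds. Rescaling the tentative PGS by any constant
   changes the factor inversely and leaves the final score invariant.
6. **Averaging** (`finalize_weights()`): per-repeat final weights are
   allele-harmonized and averaged element-wise into one model for external
   use.

`score_subjects()` evaluates models: PGS = weighted dosage sum (missing
dosages imputed with twice the training allele frequency; subjects missing
more than 10% of the panel flagged), combined = basic + PGS. Intercepts are
kept in the model object but not added to scores — AUC and deciles are
intercept-invariant.

## Validation metrics

`compute_auc()` computes the midrank Mann–Whitney AUC with the DeLong
variance estimator (cross-checked against pROC in the tests);
`compare_auc()` is the paired one-sided DeLong test of
$AUC_a < AUC_b$, the comparison used for basic-vs-combined scores.
`decile_analysis()` assigns rank-based deciles from the evaluation cohort's
own score distribution (sizes differ by at most one; ties broken by stable
order) and reports the prescribed fraction per decile. The "top-decile
sensitivity" reported alongside is the prescribed proportion *within* the
top decile, as conventionally quoted for such decile plots — under strict
nomenclature a positive predictive value, which the documentation notes.

## Problem sizes and numerical choices

The shipped tests exercise: exact-special-case $\lambda$ fixtures at
$n = 1{,}000$; $\lambda_0$ recovery at $n = 10{,}000$ over 20 seeds for
$\lambda_0 \in \{0, 0.35, 1\}$ (pass criterion: within one grid step in at
least 18); the artifact reproduction at $n = 10{,}000$ with 20 planted
baseline variants (absolute-change concordance $\le 0.1$, relative
$\ge 0.9$, stabilized planted significance within the binomial 95% band of
the 5% level); a 1,000-variant null scan at $n = 2{,}000$
(Kolmogorov–Smirnov uniformity at $\alpha = 0.01$, zero genome-wide hits);
and PGS training at a cohort of 20,000 (10,000 diseased), where the final
PGS correlates with the true genetic liability at $r > 0.3$ and the
combined score beats the basic score on the blind test set in at least
18 of 20 repeats. These sizes were chosen as the smallest at which the
binomial/KS bands are informative.

Other numerical decisions: unbiased sample variances throughout the
objective (the ratio makes the denominator convention immaterial);
two-sided t reference for OLS scans; dates handled internally as integer
day offsets with closed windows on both ends; glmnet convergence threshold
tightened to $10^{-10}$ so the vanishing-penalty limit matches unpenalized
least squares to $10^{-4}$.

## Known limitations

* No linkage disequilibrium in the generator: Lasso behaviour under real LD
  is exercised only through exact duplicate columns.
* The drug-choice model has no unmeasured severity/comorbidity confounding,
  so synthetic AUCs are not calibrated to the modest real-world values.
* Episode construction has no fill-duration model; a subject who stockpiles
  medication splits into artificial episodes.
* The stabilization objective equalizes marginal variances only; it does
  not Gaussianize residuals, which is a different (and not implemented) use
  of the Box–Cox family.

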