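# pgxscale

Variance-stabilized drug-response phenotypes and drug-choice polygenic
scores for pharmacogenomic analyses of longitudinal biobank data.

## The problem

Pharmacogenomic GWAS of drug efficacy compare a biomarker before treatment
(baseline, *X*) and on treatment (*Y*), testing variants against a change
score — conventionally the absolute change *Y − X* or the relative change
log(*Y*/*X*). When the variances of the (transformed) baseline and on-drug
distributions differ, the change score correlates strongly with the levels,
and every variant that affects the *baseline* level acquires a spurious
association with the *change*: systematically sign-inverted on the raw
scale, sign-aligned on the log scale. `pgxscale` implements the remedy — a
variance-stabilizing Box–Cox transformation

> bc(x, λ) = (x^λ − 1)/λ  (λ ≠ 0),  ln x  (λ = 0)

with λ chosen on a grid over [−2, 2] (step 0.05) to minimize
|log(Var[*Y′*]/Var[*X′*])| of the transformed levels, and the stabilized
change bc(*Y*, λ̂) − bc(*X*, λ̂) as the response phenotype. Raw and log
analyses are the λ = 1 and λ = 0 special cases.

Around that core the package provides, for analysts working with
prescription/measurement records and genotype dosages:

* **Phenotyping** — prescription episodes (≤14-day refill gaps), drug-free
  baseline windows (≥180 days drug-free, ≤730 days before initiation),
  on-drug windows (28–730 days post-initiation, concurrent same-disease
  medication excluded), linearly weighted averaging of eligible
  measurements, disease status from diagnosis codes and biomarker
  thresholds, and drug-*choice* case/control labels (cases prescribed the
  drug, controls diseased but not prescribed — healthy users excluded).
* **Association** — per-variant OLS with covariate adjustment
  (Frisch–Waugh, vectorized), MAF/missingness QC, fixed-effect
  inverse-variance meta-analysis across cohorts, and the baseline-vs-change
  sign-concordance summary that exposes the scaling artifact.
* **Drug-choice PGS** — basic demographic score (sex, age, BMI), residual
  Lasso over an index-SNP panel, penalty tuning by Z score, scaling-factor
  calibration to the log-odds scale, cross-repeat weight averaging, and
  blind-test evaluation by AUC-ROC (DeLong), paired AUC comparison and
  decile analysis.
* **Synthetic biobank generator** — genotypes, demographics, liability-model
  disease and drug choice, and longitudinal records with planted
  ground truth (true λ₀, causal variants, eligibility bookkeeping), so every
  stage is testable without controlled-access data.
* **I/O** — VCF dosages (DS field), delimited dosage/record tables,
  GWAS-style sumstats, PGS-Catalog-style scoring files, YAML run configs.

## Worked example

The pipeline wrapper chains all stages on synthetic data: two simulated
studies, record-based phenotyping, λ search, four association scans each,
meta-analysis, PGS training and blind-test evaluation.

```r
library(pgxscale)
cfg <- sim_config(n_subjects = 1500, n_variants = 100, n_causal_baseline = 20,
                  n_causal_choice = 30, seed = 5)
run <- run_pipeline(cfg, n_studies = 2, plan = split_plan(n_repeats = 5, seed = 5))
print(run)
#> Synthetic pharmacogenomic pipeline run
#>   stabilizing lambda per study: 0.35, 0.35 (true 0.35)
#>   sign concordance (planted baseline variants): absolute 0.00, relative 0.95, stabilized 0.65
#>   test AUC: basic 0.603, PGS 0.516, combined 0.605 (P basic<combined = 0.37)
#>   top-decile prescribed proportion: 67%
```

Reading the output: the λ grid search recovers the generative λ₀ = 0.35 in
both studies from the record-derived phenotypes. All 20 planted
baseline-affecting variants show the artifact — their absolute-change
effects are sign-inverted relative to their baseline effects (concordance
0.00) and their relative-change effects aligned (0.95) — while on the
stabilized metric the signs are close to coin flips (0.65), i.e. the
planted variants are no longer systematically associated with response. The
drug-choice PGS adds little on top of demographics at this small training
size; the blind-test AUCs and the one-sided paired DeLong P quantify that
honestly.

The λ search alone:

```r
x <- run$phenotypes
find_lambda(x$baseline, x$ondrug)
#> Variance-stabilizing Box-Cox parameter
#>   lambda = 0.35  (objective 0.005041 over 81 grid points)
```

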