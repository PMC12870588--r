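test_that("splits have the planned sizes, stay disjoint and fix the test set", {
  plan <- split_plan(n_repeats = 3, seed = 9)
  sp <- make_splits(1:100, plan)
  expect_length(sp$test, 20)
  for (r in sp$repeats) {
    expect_length(r$train, 60)
    expect_length(r$tune, 20)
    expect_setequal(c(sp$test, r$train, r$tune), 1:100)
    expect_length(intersect(sp$test, c(r$train, r$tune)), 0)
    expect_length(intersect(r$train, r$tune), 0)
  }
  # same seed -> identical plan; train/tune differ across repeats
  sp2 <- make_splits(1:100, plan)
  expect_identical(sp, sp2)
  expect_false(setequal(sp$repeats[[1]]$train, sp$repeats[[2]]$train))
  expect_error(split_plan(test_fraction = 0.5, train_fraction = 0.6,
                          tune_fraction = 0.2), "sum to 1")
  expect_error(make_splits(1:20), "at least 50")
})

test_that("basic score recovers planted demographic effects and is null-calibrated", {
  set.seed(20)
  n <- 4000
  demo <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 40, 70),
                     bmi = rnorm(n, 29, 5))
  # strong planted age effect
  y <- rbinom(n, 1, plogis(0.1 * (demo$age - 55)))
  fit <- fit_basic_score(y, demo)
  expect_gt(fit$weights[["age"]], 0)
  expect_equal(fit$weights[["age"]], 0.1, tolerance = 0.03)

  # null: coefficients near zero and out-of-sample AUC near 1/2
  y0 <- rbinom(n, 1, 0.4)
  fit0 <- fit_basic_score(y0, demo)
  expect_lt(max(abs(fit0$weights * c(1, 10, 5))), 0.5)
  sc0 <- demo$sex * fit0$weights[["sex"]] + demo$age * fit0$weights[["age"]] +
    demo$bmi * fit0$weights[["bmi"]]
  expect_equal(compute_auc(sc0, y0)$auc, 0.5, tolerance = 0.05)

  expect_error(fit_basic_score(rep(1, n), demo), "cases and controls")
})

test_that("lasso weights shrink with the penalty and match OLS in the limit", {
  set.seed(21)
  n <- 300
  g <- matrix(rbinom(n * 6, 2, 0.4), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  r <- 0.2 * g[, 1] - 0.15 * g[, 4] + rnorm(n, 0, 0.5)
  r <- r - mean(r)
  las <- fit_lasso_residual(r, g, penalty_grid = c(1e-8, 0.01, 0.05, 0.2, 1))
  l1 <- colSums(abs(las$weights))
  expect_true(all(diff(l1) <= 1e-8))          # L1 norm non-increasing in penalty
  expect_equal(unname(las$weights[, ncol(las$weights)]), rep(0, 6)) # heavy shrinkage
  ols <- coef(lm(r ~ g))[-1]                   # unpenalized oracle
  expect_equal(unname(las$weights[, 1]), unname(ols), tolerance = 1e-4)
})

test_that("lasso keeps at most one of an exactly duplicated SNP column", {
  set.seed(22)
  n <- 200
  g <- matrix(rbinom(n * 3, 2, 0.4), n, 3, dimnames = list(NULL, c("a", "b", "dup")))
  g[, "dup"] <- g[, "a"]
  r <- 0.4 * g[, "a"] + rnorm(n, 0, 0.3); r <- r - mean(r)
  las <- fit_lasso_residual(r, g, penalty_grid = c(0.01, 0.05, 0.1))
  both <- colSums(abs(las$weights[c("a", "dup"), ]) > 1e-10)
  expect_true(all(both <= 1))
})

test_that("penalty tuning maximizes Z and breaks ties toward sparsity", {
  set.seed(23)
  n <- 500
  signal <- rnorm(n)
  y <- rbinom(n, 1, plogis(signal))
  scores <- cbind(signal + rnorm(n, 0, 0.2),   # good
                  rnorm(n),                    # noise
                  rep(0, n))                   # all-zero -> skipped
  expect_warning(sel_all0 <- tune_penalty(y, scores[, 3, drop = FALSE], 0.5),
                 "constant")
  sel <- suppressWarnings(tune_penalty(y, scores, c(0.01, 0.1, 1)))
  expect_identical(sel$index, 1L)
  # exact tie on duplicated scores -> larger penalty wins
  sel_tie <- tune_penalty(y, scores[, c(1, 1)], c(0.01, 0.1))
  expect_identical(sel_tie$penalty, 0.1)
})

test_that("scaling factor calibrates the tentative PGS to the log-odds scale", {
  set.seed(24)
  n <- 20000
  basic <- rnorm(n, 0, 0.8)
  pgs_true <- rnorm(n, 0, 0.6)
  y <- rbinom(n, 1, plogis(basic + pgs_true))
  cal <- fit_scaling_factor(y, basic, pgs_true)
  # both predictors already on the log-odds scale -> coefficients near 1
  expect_equal(cal$scaling_factor, 1, tolerance = 0.1)
  expect_equal(cal$basic_coef, 1, tolerance = 0.1)
  # multiplying the tentative PGS by 10 shrinks the factor ~10-fold,
  # leaving the implied final score invariant
  cal10 <- fit_scaling_factor(y, basic, 10 * pgs_true)
  expect_equal(cal10$scaling_factor * 10, cal$scaling_factor, tolerance = 1e-6)
  expect_error(fit_scaling_factor(y, rep(1, n), pgs_true), "non-constant")
})

test_that("weight averaging harmonizes allele orientation across repeats", {
  sw <- function(w, ea = "A", oa = "G") {
    data.frame(variant_id = c("v1", "v2"), chrom = 1, pos = 1:2,
               effect_allele = ea, other_allele = oa, effect_weight = w)
  }
  mk <- function(snp_weights, bw = c(sex = 0.1, age = 0.02, bmi = 0.03)) {
    pgxscale:::new_score_model(bw, 0, snp_weights, 0.05, 1, 1,
                               c(v1 = 0.3, v2 = 0.4))
  }
  m1 <- mk(sw(c(0.5, 0)))
  m2 <- mk(sw(c(-0.5, -2), ea = "G", oa = "A"))  # same effects, flipped coding
  avg <- finalize_weights(list(m1, m2))
  expect_equal(avg$snp_weights$effect_weight, c(0.5, 1))
  expect_identical(avg$snp_weights$effect_allele, c("A", "A"))
  # identical repeats -> identity
  expect_equal(finalize_weights(list(m1, m1))$snp_weights$effect_weight,
               m1$snp_weights$effect_weight)
  m3 <- mk(sw(c(1, 1), ea = "T", oa = "C"))
  expect_error(finalize_weights(list(m1, m3)), "allele mismatch")
})

test_that("scoring is a dosage-weighted sum plus the basic demographic score", {
  g <- matrix(c(2, 1, 0, 0, 1, 2), 3, 2, dimnames = list(c("p1", "p2", "p3"),
                                                         c("v1", "v2")))
  geno <- list(dosages = g,
               variants = data.frame(variant_id = c("v1", "v2"), chrom = 1,
                                     pos = 1:2, effect_allele = "A",
                                     other_allele = "G", maf = 0.3))
  demo <- data.frame(subject_id = c("p1", "p2", "p3"), sex = c(1, 0, 1),
                     age = c(50, 60, 70), bmi = c(25, 30, 35))
  model <- pgxscale:::new_score_model(
    c(sex = 0, age = 0, bmi = 0), 0,
    data.frame(variant_id = c("v1", "v2"), chrom = 1, pos = 1:2,
               effect_allele = "A", other_allele = "G",
               effect_weight = c(0.5, 0)),
    0.05, 1, 1, c(v1 = 0.3, v2 = 0.4))
  sc <- score_subjects(geno, model, demo)
  expect_equal(sc$pgs, c(1, 0.5, 0))        # single SNP, weight 0.5
  expect_equal(sc$combined, sc$pgs)          # zero basic weights
  # all-zero weights -> PGS identically 0, combined equals basic
  model0 <- model; model0$snp_weights$effect_weight <- c(0, 0)
  model0$basic_weights <- c(sex = 0.2, age = 0.01, bmi = 0.02)
  sc0 <- score_subjects(geno, model0, demo)
  expect_equal(sc0$pgs, rep(0, 3))
  expect_equal(sc0$combined, sc0$basic)
})

test_that("missing dosages are imputed from training frequency and flagged", {
  g <- matrix(c(NA, 1, 0, NA, NA, 2), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("v1", "v2")))
  geno <- list(dosages = g,
               variants = data.frame(variant_id = c("v1", "v2"), chrom = 1,
                                     pos = 1:2, effect_allele = "A",
                                     other_allele = "G", maf = 0.3))
  demo <- data.frame(sex = c(0, 0, 0), age = c(50, 50, 50), bmi = c(25, 25, 25))
  model <- pgxscale:::new_score_model(
    c(sex = 0, age = 0, bmi = 0), 0,
    data.frame(variant_id = c("v1", "v2"), chrom = 1, pos = 1:2,
               effect_allele = "A", other_allele = "G",
               effect_weight = c(1, 1)),
    0.05, 1, 1, c(v1 = 0.25, v2 = 0.4))
  sc <- score_subjects(geno, model, demo)
  expect_equal(sc$pgs[1], 2 * 0.25 + 2 * 0.4)  # both imputed
  expect_equal(sc$pgs[2], 1 + 2 * 0.4)
  expect_equal(sc$flagged, c(TRUE, TRUE, FALSE)) # >10% of the panel missing
})

test_that("end-to-end training honours blind-test discipline and null behavior", {
  set.seed(26)
  cfg <- sim_config(n_subjects = 3000, n_variants = 60, n_causal_baseline = 0,
                    n_causal_choice = 20, seed = 61)
  sim <- simulate_cohort(cfg, with_records = FALSE)
  lab <- sim$choice$labels
  dis <- which(lab$diseased)
  geno <- list(dosages = sim$genotypes$dosages[dis, ],
               variants = sim$genotypes$variants)
  plan <- split_plan(n_repeats = 4, seed = 7)
  tr <- train_choice_pgs(geno, lab$choice[dis], sim$cohort[dis, ], plan = plan)
  # the fixed test subjects never enter any training stage
  for (r in tr$splits$repeats) {
    expect_length(intersect(tr$splits$test, c(r$train, r$tune)), 0)
  }
  expect_identical(nrow(tr$test_auc), 4L)
  expect_true(all(is.finite(tr$test_auc$combined)))

  # dosage recoding invariance: AUC is rank-invariant under 2x rescaling
  sc1 <- score_subjects(geno, tr$final_model, sim$cohort[dis, ])
  geno2 <- geno; geno2$dosages <- geno$dosages * 1   # same panel, rescaled weights
  model2 <- tr$final_model
  model2$snp_weights$effect_weight <- model2$snp_weights$effect_weight * 2
  sc2 <- score_subjects(geno2, model2, sim$cohort[dis, ])
  expect_equal(compute_auc(sc2$pgs, lab$choice[dis])$auc,
               compute_auc(sc1$pgs, lab$choice[dis])$auc)
})
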