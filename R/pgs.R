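#' Split plan for PGS development
#'
#' The cohort is split into a fixed blind-test fraction and, within the
#' remainder, repeated train/tune sub-samplings used to fit SNP weights and
#' tune the Lasso penalty. Default fractions are 60% train / 20% tune / 20%
#' test with 20 repeats.
#'
#' @param test_fraction,train_fraction,tune_fraction Fractions of the whole
#'   cohort; must sum to 1.
#' @param n_repeats Number of train/tune re-samplings (test set stays fixed).
#' @param seed RNG seed for the split draws.
#' @return List of class `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.20, train_fraction = 0.60,
                       tune_fraction = 0.20, n_repeats = 20, seed = 1) {
  if (abs(test_fraction + train_fraction + tune_fraction - 1) > 1e-8 ||
      any(c(test_fraction, train_fraction, tune_fraction) <= 0)) {
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  }
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  structure(list(test_fraction = test_fraction,
                 train_fraction = train_fraction,
                 tune_fraction = tune_fraction,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Draw train/tune/test splits
#'
#' @param ids Vector of subject identifiers (n >= 50).
#' @param plan A [split_plan()].
#' @return List with `test` (fixed id vector) and `repeats` (list of
#'   `list(train, tune)` per repeat); each repeat's three sets partition
#'   `ids`.
#' @export
make_splits <- function(ids, plan = split_plan()) {
  n <- length(ids)
  if (n < 50L) stop("need at least 50 subjects to split", call. = FALSE)
  set.seed(plan$seed)
  n_test <- round(n * plan$test_fraction)
  n_train <- round(n * plan$train_fraction)
  test <- sample(ids, n_test)
  pool <- setdiff(ids, test)
  repeats <- lapply(seq_len(plan$n_repeats), function(r) {
    train <- sample(pool, n_train)
    list(train = train, tune = setdiff(pool, train))
  })
  list(test = test, repeats = repeats)
}

assert_two_classes <- function(y) {
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("both cases and controls must be present", call. = FALSE)
  }
}

# logistic fit that treats (quasi-)complete separation as an error
safe_logistic <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (sep || !fit$converged) {
    stop("logistic fit failed (separation or non-convergence)", call. = FALSE)
  }
  fit
}

#' Fit the basic demographic score
#'
#' Logistic regression of drug choice on sex, age and BMI, adjusting for
#' genetic principal components. The fitted sex/age/BMI coefficients define
#' the basic score (PCs are covariates only, not part of the score). The
#' response residuals (label minus fitted probability) feed the Lasso stage.
#'
#' @param choice 0/1 drug-choice labels.
#' @param demographics Data frame with columns `sex`, `age`, `bmi`.
#' @param pcs Optional matrix/data.frame of principal components.
#' @return List: `weights` (named sex/age/bmi coefficients), `intercept`,
#'   `residuals` (response scale), `fitted`.
#' @export
fit_basic_score <- function(choice, demographics, pcs = NULL) {
  assert_two_classes(choice)
  dat <- data.frame(choice = choice,
                    sex = demographics$sex, age = demographics$age,
                    bmi = demographics$bmi)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    dat <- cbind(dat, as.data.frame(pcs))
  }
  fit <- safe_logistic(choice ~ ., dat)
  co <- stats::coef(fit)
  list(weights = co[c("sex", "age", "bmi")],
       intercept = co[["(Intercept)"]],
       residuals = dat$choice - stats::fitted(fit),
       fitted = stats::fitted(fit))
}

basic_score_values <- function(weights, demographics) {
  as.vector(weights[["sex"]] * demographics$sex +
              weights[["age"]] * demographics$age +
              weights[["bmi"]] * demographics$bmi)
}

#' Default Lasso penalty grid
#'
#' 25 logarithmically spaced penalties on [0.001, 1].
#' @return Numeric vector (increasing).
#' @export
default_penalty_grid <- function() 10^seq(log10(0.001), 0, length.out = 25)

#' Lasso regression of basic-score residuals on index SNPs
#'
#' Squared-error Lasso (via glmnet) of the residual drug-choice signal on
#' allele dosages of the candidate SNP panel, over a grid of penalties. Lasso
#' variable selection zeroes out SNPs in linkage disequilibrium with
#' stronger-associated SNPs.
#'
#' @param residuals Centered residuals from [fit_basic_score()].
#' @param dosages Subject x variant dosage matrix restricted to the panel.
#' @param penalty_grid Penalties (glmnet lambda scale), default
#'   [default_penalty_grid()].
#' @return List: `weights` (variant x penalty matrix), `penalties`
#'   (increasing, matching the columns).
#' @export
fit_lasso_residual <- function(residuals, dosages,
                               penalty_grid = default_penalty_grid()) {
  stopifnot(length(residuals) == nrow(dosages), ncol(dosages) >= 1L)
  pen <- sort(unique(penalty_grid))
  fit <- glmnet::glmnet(x = dosages, y = residuals, family = "gaussian",
                        alpha = 1, lambda = rev(pen), thresh = 1e-10,
                        standardize = TRUE)
  # glmnet columns follow the decreasing lambda sequence
  w <- as.matrix(fit$beta)[, match(pen, rev(pen)), drop = FALSE]
  colnames(w) <- formatC(pen, format = "g")
  list(weights = w, penalties = pen)
}

#' Tune the Lasso penalty by Z score
#'
#' For each penalty, fits a logistic regression of the tuning-set drug-choice
#' labels on the tentative PGS alone and records the Wald Z of its
#' coefficient. Returns the penalty with the largest Z; ties go to the larger
#' penalty (sparser model). Penalties whose tentative PGS is constant (all
#' weights zero) are skipped with a warning.
#'
#' @param choice Tuning-set 0/1 labels.
#' @param scores Tuning-subject x penalty matrix of tentative PGS values.
#' @param penalties Penalty values matching the columns of `scores`.
#' @return List: `penalty`, `index`, `z` (per-penalty Z, NA where skipped).
#' @export
tune_penalty <- function(choice, scores, penalties) {
  assert_two_classes(choice)
  stopifnot(ncol(scores) == length(penalties))
  z <- rep(NA_real_, length(penalties))
  for (j in seq_along(penalties)) {
    s <- scores[, j]
    if (stats::sd(s) == 0) next
    fit <- safe_logistic(choice ~ s, data.frame(choice = choice, s = s))
    sm <- summary(fit)$coefficients
    z[j] <- sm["s", "z value"]
  }
  if (all(is.na(z))) {
    warning("all tentative scores constant; returning largest penalty")
    return(list(penalty = penalties[length(penalties)],
                index = length(penalties), z = z))
  }
  best <- max(z, na.rm = TRUE)
  idx <- max(which(!is.na(z) & z >= best - 1e-12)) # ties -> larger penalty
  list(penalty = penalties[idx], index = idx, z = z)
}

#' Calibrate the scaling factor of the tentative PGS
#'
#' Unpenalized logistic regression of tuning-set labels on the basic score
#' and the tentative PGS jointly. The basic-score coefficient should be close
#' to one (the training-set regression is essentially replicated); the
#' tentative-PGS coefficient is the scaling factor that puts the SNP weights
#' on the log-odds scale.
#'
#' @param choice Tuning-set 0/1 labels.
#' @param basic Basic-score values for the tuning subjects.
#' @param tentative Tentative PGS values for the tuning subjects.
#' @return List: `scaling_factor`, `basic_coef`.
#' @export
fit_scaling_factor <- function(choice, basic, tentative) {
  assert_two_classes(choice)
  if (stats::sd(basic) == 0 || stats::sd(tentative) == 0) {
    stop("scores must be non-constant for calibration", call. = FALSE)
  }
  fit <- safe_logistic(choice ~ basic + tentative,
                       data.frame(choice = choice, basic = basic,
                                  tentative = tentative))
  co <- stats::coef(fit)
  list(scaling_factor = co[["tentative"]], basic_coef = co[["basic"]])
}

new_score_model <- function(basic_weights, intercept, snp_weights, penalty,
                            scaling_factor, basic_coef, train_af) {
  structure(list(basic_weights = basic_weights, intercept = intercept,
                 snp_weights = snp_weights, penalty = penalty,
                 scaling_factor = scaling_factor, basic_coef = basic_coef,
                 train_af = train_af),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("Drug-choice score model: %d/%d nonzero SNP weights, penalty %.4g, scaling factor %.3f (basic coef %.3f)\n",
              sum(x$snp_weights$effect_weight != 0), nrow(x$snp_weights),
              x$penalty, x$scaling_factor, x$basic_coef))
  invisible(x)
}

#' Average score models across cross-validation repeats
#'
#' Harmonizes allele orientation to the first model (flipping the weight sign
#' where the effect/other alleles are swapped) and takes the element-wise
#' mean of the final SNP weights, basic weights, intercept and scaling
#' factor.
#'
#' @param models List of `score_model` objects over the same variant panel.
#' @return A single averaged `score_model`.
#' @export
finalize_weights <- function(models) {
  stopifnot(length(models) >= 1L)
  ref <- models[[1L]]$snp_weights
  wmat <- vapply(models, function(m) {
    sw <- m$snp_weights[match(ref$variant_id, m$snp_weights$variant_id), , drop = FALSE]
    if (anyNA(sw$variant_id)) stop("models cover different variant panels", call. = FALSE)
    same <- sw$effect_allele == ref$effect_allele & sw$other_allele == ref$other_allele
    flip <- sw$effect_allele == ref$other_allele & sw$other_allele == ref$effect_allele
    if (!all(same | flip)) stop("allele mismatch across repeats", call. = FALSE)
    ifelse(flip, -sw$effect_weight, sw$effect_weight)
  }, numeric(nrow(ref)))
  bw <- rowMeans(vapply(models, function(m) m$basic_weights, numeric(3)))
  sw <- ref
  sw$effect_weight <- rowMeans(as.matrix(wmat))
  new_score_model(
    basic_weights = bw,
    intercept = mean(vapply(models, `[[`, numeric(1), "intercept")),
    snp_weights = sw,
    penalty = stats::median(vapply(models, `[[`, numeric(1), "penalty")),
    scaling_factor = mean(vapply(models, `[[`, numeric(1), "scaling_factor")),
    basic_coef = mean(vapply(models, `[[`, numeric(1), "basic_coef")),
    train_af = models[[1L]]$train_af
  )
}

#' Score subjects with a drug-choice score model
#'
#' PGS = weighted sum of allele dosages (0/1/2); basic score = weighted sum
#' of sex, age, BMI; combined = basic + PGS. Missing dosages are imputed with
#' twice the training allele frequency; subjects missing more than 10% of the
#' panel are flagged.
#'
#' @param genotypes A `genotype_matrix` covering the model's panel.
#' @param model A `score_model`.
#' @param demographics Data frame with `sex`, `age`, `bmi` (and optionally
#'   `subject_id`), aligned with the dosage rows.
#' @return Data frame: `subject_id`, `basic`, `pgs`, `combined`, `flagged`.
#' @export
score_subjects <- function(genotypes, model, demographics) {
  sw <- model$snp_weights
  g <- genotypes$dosages
  missing_var <- setdiff(sw$variant_id, colnames(g))
  if (length(missing_var)) {
    stop(sprintf("%d panel variant(s) absent from genotypes (e.g. %s)",
                 length(missing_var), missing_var[1L]), call. = FALSE)
  }
  g <- g[, sw$variant_id, drop = FALSE]
  # harmonize: genotype matrix allele orientation must match the weights
  vi <- genotypes$variants[match(sw$variant_id, genotypes$variants$variant_id), ]
  flip <- vi$effect_allele == sw$other_allele & vi$other_allele == sw$effect_allele
  same <- vi$effect_allele == sw$effect_allele & vi$other_allele == sw$other_allele
  if (!all(flip | same)) stop("allele mismatch between panel and genotypes", call. = FALSE)
  if (any(flip)) g[, flip] <- 2 - g[, flip, drop = FALSE]
  flagged <- rowMeans(is.na(g)) > 0.1
  if (anyNA(g)) {
    af <- model$train_af[sw$variant_id]
    af[is.na(af)] <- colMeans(g[, is.na(af), drop = FALSE], na.rm = TRUE) / 2
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- 2 * af[idx[, 2]]
  }
  pgs <- as.vector(g %*% sw$effect_weight)
  basic <- basic_score_values(model$basic_weights, demographics)
  data.frame(
    subject_id = if ("subject_id" %in% names(demographics)) demographics$subject_id else rownames(g),
    basic = basic, pgs = pgs, combined = basic + pgs, flagged = flagged
  )
}

#' Train a drug-choice polygenic score
#'
#' End-to-end multi-stage PGS construction: a fixed blind-test split plus
#' repeated train/tune sub-sampling; per repeat, (1) the basic demographic
#' score is fit on the training set, (2) its response residuals are Lasso-
#' regressed on the index-SNP dosages over a penalty grid, (3) the penalty is
#' tuned on the tuning set by the Z score of the tentative PGS, (4) a joint
#' logistic refit of the tuning labels on basic score and tentative PGS
#' yields the scaling factor that puts SNP weights on the log-odds scale.
#' Per-repeat final models are averaged into one model for external use, and
#' every repeat's model is evaluated on the blind test set.
#'
#' @param genotypes A `genotype_matrix` for the labelled subjects.
#' @param choice 0/1 labels aligned with the dosage rows (diseased subjects
#'   only).
#' @param demographics Data frame with `sex`, `age`, `bmi` (and optional
#'   `subject_id`), aligned with the dosage rows.
#' @param pcs Optional principal-component matrix used as covariates in the
#'   basic-score fit.
#' @param panel Variant ids of the candidate index-SNP panel (default: all
#'   variants in `genotypes`).
#' @param plan A [split_plan()].
#' @param penalty_grid Lasso penalties, default [default_penalty_grid()].
#' @return List of class `pgs_training`: `final_model`, `models` (per
#'   repeat), `splits`, `test_auc` (data.frame with per-repeat basic, pgs and
#'   combined AUC on the fixed test set), `plan`.
#' @export
train_choice_pgs <- function(genotypes, choice, demographics, pcs = NULL,
                             panel = NULL, plan = split_plan(),
                             penalty_grid = default_penalty_grid()) {
  g <- genotypes$dosages
  n <- nrow(g)
  stopifnot(length(choice) == n, nrow(demographics) == n)
  assert_two_classes(choice)
  if (is.null(panel)) panel <- colnames(g)
  gp <- g[, panel, drop = FALSE]
  ids <- seq_len(n)
  splits <- make_splits(ids, plan)
  vi <- genotypes$variants[match(panel, genotypes$variants$variant_id), ]
  train_af <- stats::setNames(colMeans(gp, na.rm = TRUE) / 2, panel)

  models <- vector("list", plan$n_repeats)
  aucs <- data.frame(repeat_id = seq_len(plan$n_repeats),
                     basic = NA_real_, pgs = NA_real_, combined = NA_real_)
  test <- splits$test
  for (r in seq_len(plan$n_repeats)) {
    tr <- splits$repeats[[r]]$train
    tu <- splits$repeats[[r]]$tune
    bs <- fit_basic_score(choice[tr], demographics[tr, , drop = FALSE],
                          if (!is.null(pcs)) pcs[tr, , drop = FALSE])
    las <- fit_lasso_residual(bs$residuals, gp[tr, , drop = FALSE], penalty_grid)
    tune_scores <- gp[tu, , drop = FALSE] %*% las$weights
    sel <- tune_penalty(choice[tu], tune_scores, las$penalties)
    basic_tu <- basic_score_values(bs$weights, demographics[tu, , drop = FALSE])
    cal <- fit_scaling_factor(choice[tu], basic_tu, tune_scores[, sel$index])
    sw <- data.frame(variant_id = panel, chrom = vi$chrom, pos = vi$pos,
                     effect_allele = vi$effect_allele,
                     other_allele = vi$other_allele,
                     effect_weight = las$weights[, sel$index] * cal$scaling_factor,
                     row.names = NULL)
    models[[r]] <- new_score_model(bs$weights, bs$intercept, sw, sel$penalty,
                                   cal$scaling_factor, cal$basic_coef, train_af)
    sc <- score_subjects(
      list(dosages = gp[test, , drop = FALSE], variants = vi),
      models[[r]], demographics[test, , drop = FALSE])
    aucs$basic[r] <- compute_auc(sc$basic, choice[test])$auc
    aucs$pgs[r] <- compute_auc(sc$pgs, choice[test])$auc
    aucs$combined[r] <- compute_auc(sc$combined, choice[test])$auc
  }
  structure(list(final_model = finalize_weights(models), models = models,
                 splits = splits, test_auc = aucs, plan = plan),
            class = "pgs_training")
}

#' @export
print.pgs_training <- function(x, ...) {
  cat(sprintf("Drug-choice PGS training: %d repeats; mean test AUC basic %.3f, PGS %.3f, combined %.3f\n",
              nrow(x$test_auc), mean(x$test_auc$basic), mean(x$test_auc$pgs),
              mean(x$test_auc$combined)))
  invisible(x)
}
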