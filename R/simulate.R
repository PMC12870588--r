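#' Simulation configuration for a synthetic biobank cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' generative model mirrors the mechanism that produces scaling artifacts in
#' drug-response GWAS: SNP and noise effects are additive on a latent
#' Box-Cox-stabilized scale with parameter `true_lambda`, the drug effect is
#' a constant downward shift `drug_shift` on that same scale, and raw
#' biomarker values are obtained by the inverse transformation. Under this
#' model the variance-ratio objective is exactly stabilized at `true_lambda`,
#' while raw (absolute-change) and log (relative-change) analyses show
#' opposite-signed spurious associations for baseline-affecting variants.
#'
#' Defaults emulate an LDL-C-on-statin arm: stabilized baseline mean 1.8 and
#' sd 0.30 with `true_lambda = 0.35` give raw baseline levels around
#' 4.0 mmol/L, and `drug_shift = 0.9` gives on-drug levels around 2.2 mmol/L;
#' the choice-model intercept of -0.2 gives roughly 45% of diseased subjects
#' prescribed the drug.
#'
#' @param n_subjects,n_variants Cohort and panel sizes.
#' @param maf_range Length-2 vector of allele-frequency bounds in (0, 0.5].
#' @param true_lambda Latent stabilizing parameter lambda0.
#' @param baseline_mean,baseline_sd Mean/sd of the latent stabilized baseline.
#' @param drug_shift Drug effect d > 0, subtracted on the stabilized scale.
#' @param ondrug_noise_sd Response noise sd tau (>= 0) on the stabilized scale.
#' @param n_causal_baseline Number of variants with baseline effects.
#' @param beta_baseline Per-allele effect(s) on the stabilized baseline;
#'   scalar (recycled) or vector of length `n_causal_baseline`.
#' @param n_causal_choice Number of variants with drug-choice liability
#'   weights.
#' @param choice_weight_sd Sd of the normal draw for nonzero choice weights.
#' @param demographic_effects Named vector with elements `sex`, `age`, `bmi`:
#'   log-odds effects of sex (0/1), age (per year, centered) and BMI (per
#'   kg/m2, centered) on drug choice.
#' @param choice_intercept Log-odds intercept alpha0 of choice among the
#'   diseased (demographic and genetic terms are centered, so
#'   `plogis(choice_intercept)` is the approximate prescribing prevalence).
#' @param disease_prevalence Fraction of the cohort labelled diseased.
#' @param n_pcs Number of genetic principal components to simulate.
#' @param records List of longitudinal-record knobs: `drug_class`,
#'   `other_class` (a second same-disease class used to violate the drug-free
#'   rule), `rx_interval_days`, `gap_prob` and `gap_days` (probability and
#'   size of an injected refill gap that splits the episode),
#'   `n_baseline_meas`, `n_ondrug_meas`, `meas_noise_cv` (lognormal
#'   coefficient of variation of measurement noise),
#'   `p_ineligible_baseline`, `p_ineligible_ondrug` (per-subject
#'   probabilities of being planted as filter-failing), `p_extra_invalid`
#'   (probability of adding deliberately ineligible extra measurements).
#' @param max_retries Bounded resampling attempts when the inverse transform
#'   domain is violated.
#' @param seed Integer master seed; every generator stage derives its RNG
#'   state from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000,
                       n_variants = 200,
                       maf_range = c(0.05, 0.5),
                       true_lambda = 0.35,
                       baseline_mean = 1.8,
                       baseline_sd = 0.30,
                       drug_shift = 0.9,
                       ondrug_noise_sd = 0.03,
                       n_causal_baseline = 20,
                       beta_baseline = 0.08,
                       n_causal_choice = 50,
                       choice_weight_sd = 0.12,
                       demographic_effects = c(sex = 0.3, age = 0.04, bmi = 0.05),
                       choice_intercept = -0.2,
                       disease_prevalence = 0.5,
                       n_pcs = 4,
                       records = list(),
                       max_retries = 50,
                       seed = 1) {
  rec <- utils::modifyList(list(
    drug_class = "C10AA", other_class = "C10AX09",
    rx_interval_days = 14, gap_prob = 0.2, gap_days = 60,
    n_baseline_meas = 2, n_ondrug_meas = 2, meas_noise_cv = 0.03,
    p_ineligible_baseline = 0.10, p_ineligible_ondrug = 0.10,
    p_extra_invalid = 0.5, biomarker = "LDLC"
  ), records)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range), true_lambda = true_lambda,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    drug_shift = drug_shift, ondrug_noise_sd = ondrug_noise_sd,
    n_causal_baseline = as.integer(n_causal_baseline),
    beta_baseline = beta_baseline,
    n_causal_choice = as.integer(n_causal_choice),
    choice_weight_sd = choice_weight_sd,
    demographic_effects = demographic_effects,
    choice_intercept = choice_intercept,
    disease_prevalence = disease_prevalence,
    n_pcs = as.integer(n_pcs), records = rec,
    max_retries = as.integer(max_retries), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 1L || cfg$n_variants < 1L) {
    stop("n_subjects and n_variants must be >= 1", call. = FALSE)
  }
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] <= 0 || mr[2] > 0.5 ||
      mr[1] > mr[2]) {
    stop("maf_range must lie within (0, 0.5] with min <= max", call. = FALSE)
  }
  if (cfg$n_causal_baseline > cfg$n_variants || cfg$n_causal_choice > cfg$n_variants) {
    stop("n_causal_* cannot exceed n_variants", call. = FALSE)
  }
  if (cfg$drug_shift < 0 || cfg$ondrug_noise_sd < 0 || cfg$baseline_sd <= 0) {
    stop("drug_shift, ondrug_noise_sd must be >= 0 and baseline_sd > 0", call. = FALSE)
  }
  if (cfg$disease_prevalence <= 0 || cfg$disease_prevalence > 1) {
    stop("disease_prevalence must be in (0, 1]", call. = FALSE)
  }
  if (!all(c("sex", "age", "bmi") %in% names(cfg$demographic_effects))) {
    stop("demographic_effects must name sex, age and bmi", call. = FALSE)
  }
  invisible(cfg)
}

subject_ids <- function(n) sprintf("S%05d", seq_len(n))

#' Simulate a genotype dosage matrix
#'
#' Per-variant allele frequencies are drawn uniformly from `maf_range` and
#' genotypes as binomial(2, f) allele doses. Variants are laid out on a
#' single synthetic chromosome at 10 kb spacing (no linkage disequilibrium is
#' simulated).
#'
#' @param config A [sim_config()].
#' @return A list of class `genotype_matrix` with elements `dosages`
#'   (subject x variant matrix, values in 0..2), `variants` (data.frame with
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `maf` =
#'   observed folded allele frequency) and `freq` (simulated effect-allele
#'   frequencies).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects; m <- config$n_variants
  f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  g <- vapply(f, function(fj) stats::rbinom(n, 2L, fj), integer(n))
  g <- matrix(as.numeric(g), nrow = n, ncol = m)
  ids <- sprintf("var%04d", seq_len(m))
  dimnames(g) <- list(subject_ids(n), ids)
  af <- colMeans(g) / 2
  structure(list(
    dosages = g,
    variants = data.frame(
      variant_id = ids, chrom = 1L, pos = 10000L * seq_len(m),
      effect_allele = "A", other_allele = "G",
      maf = pmin(af, 1 - af)
    ),
    freq = f
  ), class = "genotype_matrix")
}

#' Simulate subject demographics and genetic principal components
#'
#' Ages are uniform on 40-70 years, BMI normal(29, 5) truncated at 15, sex
#' balanced 0/1, and PCs standard normal (the cohort is unstratified by
#' construction).
#'
#' @param config A [sim_config()].
#' @return Data frame with `subject_id`, `sex`, `age`, `bmi`, `PC1..PCk`,
#'   `ancestry_label`.
#' @export
simulate_demographics <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  bmi <- stats::rnorm(n, 29, 5)
  while (any(bmi < 15)) bmi[bmi < 15] <- stats::rnorm(sum(bmi < 15), 29, 5)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
  cbind(
    data.frame(
      subject_id = subject_ids(n),
      sex = stats::rbinom(n, 1L, 0.5),
      age = stats::runif(n, 40, 70),
      bmi = bmi
    ),
    as.data.frame(pcs),
    data.frame(ancestry_label = "SYN")
  )
}

#' Simulate baseline and on-drug biomarker levels
#'
#' Latent stabilized levels are `X' = baseline_mean + G beta + eps` with
#' `eps ~ N(0, baseline_sd)`, and `Y' = X' - drug_shift + eta` with
#' `eta ~ N(0, ondrug_noise_sd)`; raw levels are the inverse Box-Cox
#' transform of `X'` and `Y'` at `true_lambda`. SNP effects therefore act on
#' the stabilized baseline and carry over to the on-drug level, so the true
#' per-variant effect on the stabilized change `Y' - X'` is zero — any
#' change-score association on another scale is the scaling artifact by
#' construction. Subjects whose latent draws violate the inverse-transform
#' domain are resampled up to `max_retries` passes, then an error is
#' signalled.
#'
#' @param config A [sim_config()].
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @return List with `baseline`, `ondrug` (positive raw-scale vectors),
#'   `latent_baseline`, `latent_ondrug`, and `true` (list: `lambda0`,
#'   `beta` full-length per-variant effect vector, `causal_idx`).
#' @export
simulate_biomarker_and_drug <- function(config, genotypes) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- config$n_subjects
  m <- config$n_variants
  beta <- numeric(m)
  if (config$n_causal_baseline > 0L) {
    beta[seq_len(config$n_causal_baseline)] <-
      rep_len(config$beta_baseline, config$n_causal_baseline)
  }
  gterm <- as.vector(genotypes$dosages %*% beta)
  gterm <- gterm - mean(gterm)   # keep baseline_mean the actual mean
  lam <- config$true_lambda

  draw <- function(idx, sd) stats::rnorm(length(idx), 0, sd)
  xp <- config$baseline_mean + gterm + draw(seq_len(n), config$baseline_sd)
  yp <- xp - config$drug_shift + draw(seq_len(n), config$ondrug_noise_sd)
  ok <- function(v) if (lam == 0) rep(TRUE, length(v)) else (1 + lam * v) > 0
  for (i in seq_len(config$max_retries)) {
    bad <- which(!(ok(xp) & ok(yp)))
    if (!length(bad)) break
    xp[bad] <- config$baseline_mean + gterm[bad] + draw(bad, config$baseline_sd)
    yp[bad] <- xp[bad] - config$drug_shift + draw(bad, config$ondrug_noise_sd)
  }
  if (!all(ok(xp) & ok(yp))) {
    stop("inverse Box-Cox domain violated after max_retries resampling passes; ",
         "reduce noise or shift relative to baseline_mean", call. = FALSE)
  }
  list(
    baseline = boxcox_inverse(xp, lam),
    ondrug = boxcox_inverse(yp, lam),
    latent_baseline = xp,
    latent_ondrug = yp,
    true = list(lambda0 = lam, beta = beta,
                causal_idx = which(beta != 0))
  )
}

#' Simulate disease status and drug choice
#'
#' Disease is assigned by thresholding a standard-normal-plus-demographics
#' liability at the configured prevalence. Among diseased subjects, drug
#' choice is Bernoulli with log-odds
#' `alpha0 + b_sex sex + b_age (age - mean) + b_bmi (bmi - mean) + sum_j w_j g_j`
#' where `w_j` are nonzero for `n_causal_choice` variants (drawn
#' `N(0, choice_weight_sd)`) and the genetic term is centered so `alpha0`
#' controls prevalence. Non-diseased subjects receive no choice label.
#'
#' @param config A [sim_config()].
#' @param genotypes A `genotype_matrix`.
#' @param cohort Demographics from [simulate_demographics()].
#' @return List with `labels` (data.frame: `subject_id`, `diseased`, `choice`
#'   with NA for non-diseased) and `true` (list: `choice_weights` full-length
#'   vector, `causal_idx`, `genetic_liability`, `liability` = full linear
#'   predictor, NA for non-diseased).
#' @export
simulate_choice <- function(config, genotypes, cohort) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  n <- config$n_subjects
  m <- config$n_variants
  de <- config$demographic_effects

  # disease liability: mild demographic load plus unit normal noise
  dl <- 0.2 * cohort$sex + 0.02 * (cohort$age - mean(cohort$age)) +
    0.03 * (cohort$bmi - mean(cohort$bmi)) + stats::rnorm(n)
  diseased <- dl >= stats::quantile(dl, 1 - config$disease_prevalence)

  w <- numeric(m)
  if (config$n_causal_choice > 0L) {
    # choice-causal variants occupy the tail of the panel so they are
    # disjoint from baseline-causal variants whenever the counts allow
    idx <- seq.int(m - config$n_causal_choice + 1L, m)
    w[idx] <- stats::rnorm(config$n_causal_choice, 0, config$choice_weight_sd)
  }
  glia <- as.vector(genotypes$dosages %*% w)
  glia_c <- glia - mean(glia)
  lp <- config$choice_intercept + de[["sex"]] * cohort$sex +
    de[["age"]] * (cohort$age - mean(cohort$age)) +
    de[["bmi"]] * (cohort$bmi - mean(cohort$bmi)) + glia_c
  choice <- rep(NA_integer_, n)
  choice[diseased] <- stats::rbinom(sum(diseased), 1L, stats::plogis(lp[diseased]))
  list(
    labels = data.frame(subject_id = cohort$subject_id,
                        diseased = diseased, choice = choice),
    true = list(choice_weights = w, causal_idx = which(w != 0),
                genetic_liability = glia,
                liability = ifelse(diseased, lp, NA_real_))
  )
}

#' Simulate longitudinal prescription and measurement records
#'
#' Emits dated prescription fills and biomarker measurements for treated
#' subjects, deliberately including records that downstream filters must
#' reject: refill gaps larger than the episode gap allowance (splitting
#' episodes), measurements earlier than the baseline window or inside the
#' pre-therapeutic first 28 days, and baseline measurements invalidated by a
#' same-disease fill of a different drug class during the drug-free window.
#' A per-subject eligibility plan is returned so phenotyping output can be
#' checked against exact bookkeeping.
#'
#' @param config A [sim_config()].
#' @param baseline,ondrug Raw-scale biomarker vectors (one value per cohort
#'   subject), e.g. from [simulate_biomarker_and_drug()].
#' @param treated Logical or index vector selecting treated subjects;
#'   defaults to all subjects.
#' @return List with `prescriptions` (subject_id, atc_code, date),
#'   `measurements` (subject_id, biomarker, date, value) and `planted`
#'   (subject_id, treated, initiation_date, eligible).
#' @export
simulate_records <- function(config, baseline, ondrug, treated = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  n <- config$n_subjects
  ids <- subject_ids(n)
  rc <- config$records
  if (is.null(treated)) treated <- rep(TRUE, n)
  treated <- if (is.logical(treated)) which(treated) else as.integer(treated)
  origin <- as.Date("2000-01-01")

  rx <- list(); ms <- list()
  plan <- data.frame(subject_id = ids, treated = FALSE,
                     initiation_date = as.Date(NA), eligible = FALSE)
  noisy <- function(v, k) v * exp(stats::rnorm(k, 0, rc$meas_noise_cv))

  for (i in treated) {
    t0 <- sample(400:600, 1L)
    u <- stats::runif(1)
    cat_i <- if (u < rc$p_ineligible_baseline) "bad_baseline"
             else if (u < rc$p_ineligible_baseline + rc$p_ineligible_ondrug) "bad_ondrug"
             else "eligible"

    fill_days <- t0 + seq(0L, 730L, by = rc$rx_interval_days)
    if (stats::runif(1) < rc$gap_prob) {
      # shift later fills to open a gap wider than the 14-day allowance
      cut <- min(which(fill_days > t0 + 250L))
      fill_days[cut:length(fill_days)] <- fill_days[cut:length(fill_days)] + rc$gap_days
      fill_days <- fill_days[fill_days <= t0 + 730L]
    }
    rx[[length(rx) + 1L]] <- data.frame(
      subject_id = ids[i], atc_code = rc$drug_class, date = origin + fill_days)

    bdays <- switch(cat_i,
      bad_baseline = t0 - sample(760:900, rc$n_baseline_meas),
      t0 - sample(30:400, rc$n_baseline_meas))
    odays <- switch(cat_i,
      bad_ondrug = t0 + sample(5:25, rc$n_ondrug_meas),
      t0 + sample(28:200, rc$n_ondrug_meas))
    if (cat_i == "bad_baseline" && i %% 2L == 0L) {
      # drug-free-rule variant: baseline measurement in-window but preceded
      # by a same-disease fill of another class within 180 days
      bdays <- t0 - sample(60:150, rc$n_baseline_meas)
      rx[[length(rx) + 1L]] <- data.frame(
        subject_id = ids[i], atc_code = rc$other_class,
        date = origin + (min(bdays) - 90L))
    }
    mday <- c(bdays, odays)
    mval <- c(noisy(rep(baseline[i], length(bdays)), length(bdays)),
              noisy(rep(ondrug[i], length(odays)), length(odays)))
    if (cat_i == "eligible" && stats::runif(1) < rc$p_extra_invalid) {
      mday <- c(mday, t0 + sample(5:20, 1L), t0 - sample(800:900, 1L))
      mval <- c(mval, noisy(ondrug[i], 1L), noisy(baseline[i], 1L))
    }
    ms[[length(ms) + 1L]] <- data.frame(
      subject_id = ids[i], biomarker = rc$biomarker,
      date = origin + mday, value = mval)
    plan$treated[i] <- TRUE
    plan$initiation_date[i] <- origin + t0
    plan$eligible[i] <- cat_i == "eligible"
  }
  list(
    prescriptions = do.call(rbind, rx),
    measurements = do.call(rbind, ms),
    planted = plan
  )
}

#' Generate a complete synthetic biobank cohort
#'
#' Runs every generator stage in a fixed order with RNG states derived from
#' the master seed, so the entire cohort is bit-reproducible for a fixed
#' configuration.
#'
#' @param config A [sim_config()].
#' @param with_records Also simulate longitudinal records for subjects
#'   prescribed the drug (default TRUE).
#' @return List of class `syn_cohort` with elements `config`, `genotypes`,
#'   `cohort`, `biomarker`, `choice`, and (optionally) `records`.
#' @export
simulate_cohort <- function(config = sim_config(), with_records = TRUE) {
  geno <- simulate_genotypes(config)
  demo <- simulate_demographics(config)
  bio <- simulate_biomarker_and_drug(config, geno)
  cho <- simulate_choice(config, geno, demo)
  out <- list(config = config, genotypes = geno, cohort = demo,
              biomarker = bio, choice = cho)
  if (with_records) {
    treated <- !is.na(cho$labels$choice) & cho$labels$choice == 1L
    out$records <- simulate_records(config, bio$baseline, bio$ondrug, treated)
  }
  structure(out, class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d variants (lambda0 = %.2f, seed %d)\n",
              x$config$n_subjects, x$config$n_variants,
              x$config$true_lambda, x$config$seed))
  if (!is.null(x$records)) {
    cat(sprintf("  records: %d fills, %d measurements, %d treated (%d planted eligible)\n",
                nrow(x$records$prescriptions), nrow(x$records$measurements),
                sum(x$records$planted$treated), sum(x$records$planted$eligible)))
  }
  invisible(x)
}
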