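subset_genotypes <- function(genotypes, ids) {
  out <- genotypes
  out$dosages <- genotypes$dosages[ids, , drop = FALSE]
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage on generated data: simulate one or more synthetic
#' study cohorts, derive response phenotypes from their longitudinal
#' records, find the variance-stabilizing lambda, scan baseline levels and
#' the three change metrics per study, meta-analyze the studies, summarize
#' the baseline-vs-change sign concordance of the planted baseline variants,
#' train the drug-choice PGS on the first study's diseased subjects, and
#' evaluate it by AUC and deciles on the blind test set.
#'
#' @param config A [sim_config()] describing each study cohort (study k gets
#'   seed `config$seed + (k-1) * 1000`).
#' @param n_studies Number of synthetic studies for the meta-analysis step.
#' @param window A [window_config()].
#' @param plan A [split_plan()] for PGS training.
#' @param out_dir Optional directory: writes phenotypes, sumstats, the
#'   scoring file and a machine-readable JSON report.
#' @return List of class `pgx_run`: `lambda` (per study), `meta` (per
#'   metric), `concordance` (per metric, planted baseline variants),
#'   `pgs` (training object), `evaluation` (test AUCs, paired comparison,
#'   decile table), `phenotypes`, `config`.
#' @export
run_pipeline <- function(config = sim_config(), n_studies = 2,
                         window = window_config(), plan = split_plan(),
                         out_dir = NULL) {
  metrics_names <- c("absolute", "relative", "stabilized")
  studies <- vector("list", n_studies)
  for (k in seq_len(n_studies)) {
    cfg <- config
    cfg$seed <- config$seed + (k - 1L) * 1000L
    sim <- simulate_cohort(cfg)
    phen <- derive_response_phenotypes(
      sim$records$prescriptions, sim$records$measurements,
      drug_class = cfg$records$drug_class,
      same_disease_classes = c(cfg$records$drug_class, cfg$records$other_class),
      window = window)
    lam <- find_lambda(phen$baseline, phen$ondrug)
    met <- compute_response_metrics(phen, lam$lambda)
    idx <- match(phen$subject_id, sim$cohort$subject_id)
    geno <- qc_filter(subset_genotypes(sim$genotypes, idx))
    pcs <- as.matrix(sim$cohort[idx, grep("^PC", names(sim$cohort)), drop = FALSE])
    scans <- list(baseline = run_scan(met$baseline, geno, pcs, metric = "baseline"))
    for (m in metrics_names) scans[[m]] <- run_scan(met[[m]], geno, pcs, metric = m)
    studies[[k]] <- list(sim = sim, phenotypes = phen, lambda = lam,
                         metrics = met, scans = scans)
  }

  meta <- lapply(c("baseline", metrics_names), function(m) {
    meta_fixed(lapply(studies, function(st) st$scans[[m]]))
  })
  names(meta) <- c("baseline", metrics_names)

  planted <- studies[[1L]]$sim$genotypes$variants$variant_id[
    studies[[1L]]$sim$biomarker$true$causal_idx]
  conc <- vapply(metrics_names, function(m) {
    b <- studies[[1L]]$scans$baseline
    ch <- studies[[1L]]$scans[[m]]
    keep <- b$variant_id %in% planted
    sign_concordance(b[keep, ], ch[ch$variant_id %in% planted, ])$concordance
  }, numeric(1))

  # drug-choice PGS on the first study's diseased subjects
  sim1 <- studies[[1L]]$sim
  lab <- sim1$choice$labels
  dis <- which(lab$diseased)
  pgs <- train_choice_pgs(
    subset_genotypes(sim1$genotypes, dis), lab$choice[dis],
    sim1$cohort[dis, , drop = FALSE],
    pcs = as.matrix(sim1$cohort[dis, grep("^PC", names(sim1$cohort)), drop = FALSE]),
    plan = plan)

  test <- pgs$splits$test
  sc <- score_subjects(subset_genotypes(sim1$genotypes, dis[test]),
                       pgs$final_model, sim1$cohort[dis[test], , drop = FALSE])
  y_test <- lab$choice[dis][test]
  evaluation <- list(
    auc = list(basic = compute_auc(sc$basic, y_test),
               pgs = compute_auc(sc$pgs, y_test),
               combined = compute_auc(sc$combined, y_test)),
    basic_vs_combined = compare_auc(sc$basic, sc$combined, y_test),
    deciles = decile_analysis(sc$combined, y_test)
  )

  out <- structure(list(
    lambda = vapply(studies, function(st) st$lambda$lambda, numeric(1)),
    meta = meta, concordance = conc, pgs = pgs, evaluation = evaluation,
    phenotypes = studies[[1L]]$phenotypes, config = config,
    studies = studies
  ), class = "pgx_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$phenotypes, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    for (m in names(meta)) {
      write_sumstats(meta[[m]], file.path(out_dir, sprintf("meta_%s.tsv", m)))
    }
    write_score_model(pgs$final_model, file.path(out_dir, "choice_pgs.txt"))
    report <- list(
      lambda_per_study = out$lambda,
      sign_concordance = as.list(conc),
      test_auc = list(basic = evaluation$auc$basic$auc,
                      pgs = evaluation$auc$pgs$auc,
                      combined = evaluation$auc$combined$auc),
      p_basic_lt_combined = evaluation$basic_vs_combined$p,
      top_decile_sensitivity = evaluation$deciles$top_decile_sensitivity,
      n_phenotyped = nrow(out$phenotypes),
      seed = config$seed
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pgx_run <- function(x, ...) {
  cat("Synthetic pharmacogenomic pipeline run\n")
  cat(sprintf("  stabilizing lambda per study: %s (true %.2f)\n",
              paste(sprintf("%.2f", x$lambda), collapse = ", "),
              x$config$true_lambda))
  cat(sprintf("  sign concordance (planted baseline variants): absolute %.2f, relative %.2f, stabilized %.2f\n",
              x$concordance[["absolute"]], x$concordance[["relative"]],
              x$concordance[["stabilized"]]))
  cat(sprintf("  test AUC: basic %.3f, PGS %.3f, combined %.3f (P basic<combined = %.2g)\n",
              x$evaluation$auc$basic$auc, x$evaluation$auc$pgs$auc,
              x$evaluation$auc$combined$auc, x$evaluation$basic_vs_combined$p))
  cat(sprintf("  top-decile prescribed proportion: %.0f%%\n",
              100 * x$evaluation$deciles$top_decile_sensitivity))
  invisible(x)
}
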