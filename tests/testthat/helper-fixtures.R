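# shared fixtures built in code

# tiny deterministic cohort for fast unit tests
small_sim <- function(seed = 3, n = 600, m = 40) {
  sim_config(n_subjects = n, n_variants = m,
             n_causal_baseline = min(8L, m %/% 5L),
             n_causal_choice = min(12L, m %/% 3L), seed = seed)
}

# prescriptions/measurements tables from day offsets (integer days)
rx_table <- function(subject, days, atc = "C10AA") {
  k <- length(days)
  data.frame(subject_id = rep_len(subject, k), atc_code = rep_len(atc, k),
             date = as.integer(days))
}
meas_table <- function(subject, days, values, biomarker = "LDLC") {
  k <- length(days)
  data.frame(subject_id = rep_len(subject, k),
             biomarker = rep_len(biomarker, k),
             date = as.integer(days), value = values)
}

# brute-force AUC over all case-control pairs (independent oracle)
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# trapezoidal area under the empirical ROC curve (second independent route)
auc_trapezoid <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
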