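# fast DeLong structural components via midranks (cases = labels 1)
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) {
    stop("both cases and controls are required", call. = FALSE)
  }
  r_all <- rank(c(x, y))            # midranks handle ties
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC-ROC with DeLong standard error
#'
#' The AUC is the normalized Mann-Whitney U statistic (probability that a
#' random case scores above a random control, ties counted one half), with
#' the DeLong variance estimator and a one-sided test against AUC = 0.5.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels (1 = case).
#' @return List of class `auc_result`: `auc`, `se`, `p_vs_half` (one-sided,
#'   alternative AUC > 0.5), `n_cases`, `n_controls`.
#' @examples
#' compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc # 0.75
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  cp <- delong_components(scores, labels)
  v <- stats::var(cp$v10) / cp$m + stats::var(cp$v01) / cp$n
  se <- sqrt(v)
  z <- if (se > 0) (cp$auc - 0.5) / se else 0
  structure(list(auc = cp$auc, se = se,
                 p_vs_half = stats::pnorm(-z),
                 n_cases = cp$m, n_controls = cp$n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC-ROC = %.4f (DeLong SE %.4f; one-sided P vs 0.5 = %.3g; %d cases / %d controls)\n",
              x$auc, x$se, x$p_vs_half, x$n_cases, x$n_controls))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Tests whether score `b` discriminates better than score `a` on the same
#' subjects (one-sided alternative AUC_a < AUC_b), using the paired DeLong
#' covariance of the two empirical AUCs.
#'
#' @param scores_a,scores_b Two score vectors for the same subjects.
#' @param labels 0/1 labels (1 = case).
#' @return List: `auc_a`, `auc_b`, `se_diff`, `p` (one-sided, alternative
#'   AUC_a < AUC_b).
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- cb$auc - ca$auc
  if (v <= 0) {
    # identical scores: no evidence either way
    return(list(auc_a = ca$auc, auc_b = cb$auc, se_diff = 0, p = 0.5))
  }
  z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, se_diff = sqrt(v),
       p = stats::pnorm(-z))
}

#' Drug-choice frequency by score decile
#'
#' Assigns subjects to deciles of the score distribution (rank-based, ties
#' broken by stable input order; decile sizes differ by at most one) and
#' tabulates the fraction prescribed the drug in each decile. The reported
#' `top_decile_sensitivity` is the prescribed proportion within the top
#' decile — the quantity conventionally quoted for the highest-scoring tenth
#' of patients (a positive predictive value in strict nomenclature).
#'
#' @param scores Numeric scores (n >= 10).
#' @param labels 0/1 labels (1 = prescribed).
#' @return List of class `decile_table`: `table` (data.frame with `decile`,
#'   `score_min`, `score_max`, `n`, `n_prescribed`, `frequency`) and
#'   `top_decile_sensitivity`.
#' @export
decile_analysis <- function(scores, labels) {
  n <- length(scores)
  stopifnot(n >= 10L, length(labels) == n)
  ord <- order(scores)                      # stable for ties
  dec <- integer(n)
  dec[ord] <- ceiling(10 * seq_len(n) / n)  # sizes differ by <= 1
  tab <- data.frame(
    decile = 1:10,
    score_min = tapply(scores, dec, min),
    score_max = tapply(scores, dec, max),
    n = as.integer(table(dec)),
    n_prescribed = as.integer(tapply(labels, dec, sum)),
    row.names = NULL
  )
  tab$frequency <- tab$n_prescribed / tab$n
  structure(list(table = tab,
                 top_decile_sensitivity = tab$frequency[10]),
            class = "decile_table")
}

#' @export
print.decile_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Top-decile prescribed proportion: %.1f%%\n",
              100 * x$top_decile_sensitivity))
  invisible(x)
}
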