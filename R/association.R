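#' Variant quality-control filter
#'
#' Removes variants with minor allele frequency below `maf_min` (computed
#' from observed dosages, folded to <= 0.5; monomorphic variants have MAF 0
#' and are removed) or missing call rate above `missing_max`.
#'
#' @param genotypes A `genotype_matrix` (see [simulate_genotypes()]) or any
#'   list with `dosages` and `variants`.
#' @param maf_min Minimum MAF, default 0.01.
#' @param missing_max Maximum fraction of missing dosages per variant.
#' @return The filtered `genotype_matrix`, with attribute `qc_report`
#'   (counts removed per filter).
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, missing_max = 0.1) {
  g <- genotypes$dosages
  miss <- colMeans(is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- maf < maf_min | is.nan(maf)
  fail_miss <- miss > missing_max
  keep <- !(fail_maf | fail_miss)
  if (!any(keep)) warning("no variants pass QC")
  out <- genotypes
  out$dosages <- g[, keep, drop = FALSE]
  out$variants <- genotypes$variants[keep, , drop = FALSE]
  out$variants$maf <- maf[keep]
  if (!is.null(out$freq)) out$freq <- genotypes$freq[keep]
  attr(out, "qc_report") <- c(n_input = ncol(g), fail_maf = sum(fail_maf),
                              fail_missing = sum(fail_miss), n_retained = sum(keep))
  out
}

# residual-maker for intercept + covariates; returns the QR object
covariate_qr <- function(n, covariates = NULL) {
  x <- cbind(intercept = rep(1, n), covariates)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    stop("covariate matrix is rank-deficient after adding an intercept", call. = FALSE)
  }
  qrx
}

#' Test one variant against a quantitative phenotype
#'
#' Ordinary least squares of the phenotype on the allele dosage, adjusting
#' for an intercept and optional covariates by Frisch-Waugh residualization:
#' both `y` and `g` are projected off the covariate space, the slope of the
#' residual regression is the adjusted effect, and the two-sided P-value uses
#' the t reference with `n - n_covariates - 2` degrees of freedom.
#'
#' @param y Numeric phenotype vector.
#' @param g Dosage vector (same length; missing dosages mean-imputed).
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (without intercept).
#' @return One-row data.frame: `beta`, `se`, `p`, `n`.
#' @export
test_variant <- function(y, g, covariates = NULL) {
  stopifnot(length(y) == length(g))
  if (any(!is.finite(y))) stop("phenotype must be finite", call. = FALSE)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  qrx <- covariate_qr(length(y), covariates)
  yr <- qr.resid(qrx, y)
  gr <- qr.resid(qrx, g)
  sgg <- sum(gr^2)
  if (sgg < .Machine$double.eps * length(g)) {
    stop("degenerate variant: dosage collinear with covariates", call. = FALSE)
  }
  df <- length(y) - qrx$rank - 1L
  if (df < 1L) stop("not enough observations for the covariate set", call. = FALSE)
  beta <- sum(gr * yr) / sgg
  rss <- sum(yr^2) - beta^2 * sgg
  if (rss <= 0) {
    stop("degenerate fit: zero residual variance (perfect fit)", call. = FALSE)
  }
  se <- sqrt(rss / df / sgg)
  tval <- beta / se
  data.frame(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), df),
             n = length(y))
}

#' Association scan of a response metric over all variants
#'
#' Runs [test_variant()] for every variant, vectorized by residualizing the
#' phenotype and the whole dosage matrix on the covariates once. For
#' drug-response metrics the covariates should be genetic principal
#' components only, to avoid improper adjustment of the composite
#' change-score phenotype.
#'
#' @param y Numeric phenotype (one value per subject, aligned with the rows
#'   of `genotypes$dosages`).
#' @param genotypes A `genotype_matrix` (ideally after [qc_filter()]).
#' @param covariates Optional covariate matrix/data.frame.
#' @param metric Label stored with the results (e.g. "baseline",
#'   "absolute", "relative", "stabilized").
#' @param sig_threshold Genome-wide significance level, default 5e-8.
#' @return Data frame with one row per variant: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `p`,
#'   `significant`, `n`, `metric`, ordered by position.
#' @export
run_scan <- function(y, genotypes, covariates = NULL,
                     metric = "response", sig_threshold = 5e-8) {
  g <- genotypes$dosages
  if (length(y) != nrow(g)) {
    stop("phenotype and genotype subject sets are misaligned", call. = FALSE)
  }
  if (ncol(g) == 0L) {
    warning("no variants to scan")
    return(cbind(genotypes$variants,
                 data.frame(beta = numeric(0), se = numeric(0), p = numeric(0),
                            significant = logical(0), n = integer(0),
                            metric = character(0))))
  }
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  qrx <- covariate_qr(length(y), covariates)
  yr <- qr.resid(qrx, y)
  gr <- qr.resid(qrx, g)
  sgg <- colSums(gr^2)
  degen <- sgg < .Machine$double.eps * nrow(g)
  if (any(degen)) {
    warning(sprintf("%d variant(s) collinear with covariates: results set NA", sum(degen)))
    sgg[degen] <- NA_real_
  }
  df <- length(y) - qrx$rank - 1L
  beta <- colSums(gr * yr) / sgg
  rss <- sum(yr^2) - beta^2 * sgg
  se <- sqrt(rss / df / sgg)
  p <- 2 * stats::pt(-abs(beta / se), df)
  res <- cbind(genotypes$variants,
               data.frame(beta = beta, se = se, p = p,
                          significant = p < sig_threshold,
                          n = length(y), metric = metric,
                          row.names = NULL))
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-study association results with inverse-variance weights:
#' `beta = sum(beta_k / se_k^2) / sum(1 / se_k^2)`,
#' `se = sqrt(1 / sum(1 / se_k^2))`. Only variants present in every study are
#' combined; effect alleles are harmonized to the first study (a study
#' reporting the swapped allele pair has its beta negated; an unresolvable
#' allele pair is an error).
#'
#' @param results_by_study List of scan result data frames (from
#'   [run_scan()]), each with `variant_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`.
#' @return Data frame: `variant_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, `n_studies`.
#' @export
meta_fixed <- function(results_by_study) {
  stopifnot(length(results_by_study) >= 1L)
  shared <- Reduce(intersect, lapply(results_by_study, `[[`, "variant_id"))
  if (!length(shared)) stop("no variants shared across studies", call. = FALSE)
  ref <- results_by_study[[1L]]
  ref <- ref[match(shared, ref$variant_id), , drop = FALSE]
  wsum <- bsum <- rep(0, length(shared))
  for (st in results_by_study) {
    st <- st[match(shared, st$variant_id), , drop = FALSE]
    if (any(st$se <= 0)) stop("standard errors must be positive", call. = FALSE)
    flip <- st$effect_allele == ref$other_allele & st$other_allele == ref$effect_allele
    same <- st$effect_allele == ref$effect_allele & st$other_allele == ref$other_allele
    if (!all(flip | same)) {
      stop("allele mismatch that cannot be resolved by flipping", call. = FALSE)
    }
    b <- ifelse(flip, -st$beta, st$beta)
    w <- 1 / st$se^2
    wsum <- wsum + w
    bsum <- bsum + w * b
  }
  beta <- bsum / wsum
  se <- sqrt(1 / wsum)
  data.frame(variant_id = shared,
             effect_allele = ref$effect_allele, other_allele = ref$other_allele,
             beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(beta / se)),
             n_studies = length(results_by_study), row.names = NULL)
}

#' Sign concordance between baseline and change-score effects
#'
#' For variants associated with the baseline biomarker level, computes the
#' fraction whose change-score effect has the same sign as their baseline
#' effect. Under the raw-scale (absolute change) artifact this fraction
#' approaches 0 (systematic inversion); under the log-scale (relative
#' change) artifact it approaches 1; at the variance-stabilizing scale the
#' signs are undetermined (about one half).
#'
#' @param baseline_results,change_results Scan result data frames sharing
#'   `variant_id` and `effect_allele`.
#' @param baseline_p_max Restrict to variants with baseline `p` below this
#'   threshold (default 1: use all supplied variants, e.g. an externally
#'   defined set of known baseline loci).
#' @return List: `concordance` (fraction), `n_variants`, `variant_id`.
#' @export
sign_concordance <- function(baseline_results, change_results,
                             baseline_p_max = 1) {
  shared <- intersect(baseline_results$variant_id, change_results$variant_id)
  if (!length(shared)) stop("no shared variants", call. = FALSE)
  b <- baseline_results[match(shared, baseline_results$variant_id), , drop = FALSE]
  ch <- change_results[match(shared, change_results$variant_id), , drop = FALSE]
  if (!all(b$effect_allele == ch$effect_allele)) {
    stop("effect alleles must be harmonized before comparing signs", call. = FALSE)
  }
  sel <- b$p <= baseline_p_max
  if (!any(sel)) stop("no variants pass the baseline significance filter", call. = FALSE)
  conc <- mean(sign(ch$beta[sel]) == sign(b$beta[sel]))
  list(concordance = conc, n_variants = sum(sel), variant_id = shared[sel])
}
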