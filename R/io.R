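stop_with_rows <- function(bad, what, file) {
  stop(sprintf("%s in %s at data row(s) %s", what, file,
               paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
}

#' Read a delimited dosage table
#'
#' Expects one row per variant with columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele` followed by one dosage column per subject
#' (values in 0..2, NA allowed).
#'
#' @param path File path (comma- or tab-separated, header row).
#' @return A `genotype_matrix` (see [simulate_genotypes()]).
#' @export
read_dosage_table <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(meta_cols %in% names(dt))) {
    stop(sprintf("dosage table %s must contain columns: %s", path,
                 paste(meta_cols, collapse = ", ")), call. = FALSE)
  }
  subj <- setdiff(names(dt), meta_cols)
  g <- t(as.matrix(dt[, subj, drop = FALSE]))
  colnames(g) <- dt$variant_id
  rownames(g) <- subj
  bad <- which(apply(g, 2, function(col) any(col < 0 | col > 2, na.rm = TRUE)))
  if (length(bad)) stop_with_rows(bad, "dosages outside [0, 2]", path)
  af <- colMeans(g, na.rm = TRUE) / 2
  structure(list(
    dosages = g,
    variants = data.frame(variant_id = dt$variant_id, chrom = dt$chrom,
                          pos = dt$pos, effect_allele = dt$effect_allele,
                          other_allele = dt$other_allele,
                          maf = pmin(af, 1 - af))
  ), class = "genotype_matrix")
}

#' Write a delimited dosage table
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path (written tab-separated).
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(genotypes, path) {
  v <- genotypes$variants[c("variant_id", "chrom", "pos",
                            "effect_allele", "other_allele")]
  out <- cbind(v, as.data.frame(t(genotypes$dosages)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write genotype dosages as a minimal VCF
#'
#' One record per variant with the effect allele as ALT and a per-sample
#' `DS` (dosage) FORMAT field, the conventional encoding for imputed
#' genotypes. Plain text (uncompressed).
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(genotypes, path) {
  v <- genotypes$variants
  g <- genotypes$dosages
  samples <- rownames(g)
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(g)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- formatC(g[, j], format = "g", digits = 10)
    ds[is.na(g[, j])] <- "."
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS field
#'
#' Parses the per-sample `DS` FORMAT field via the vcfR package. The ALT
#' allele is taken as the effect allele.
#'
#' @param path VCF path.
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  g <- t(ds)
  colnames(g) <- fix$ID
  af <- colMeans(g, na.rm = TRUE) / 2
  structure(list(
    dosages = g,
    variants = data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                          pos = as.integer(fix$POS),
                          effect_allele = fix$ALT, other_allele = fix$REF,
                          maf = pmin(af, 1 - af))
  ), class = "genotype_matrix")
}

#' Read and validate longitudinal record tables
#'
#' Comma-separated files with a header row and ISO-8601 dates. Prescriptions
#' need `subject_id, atc_code, date`; measurements need
#' `subject_id, biomarker, date, value` with strictly positive values;
#' diagnoses need `subject_id, code, date`. Malformed dates and non-positive
#' values are reported with their row numbers rather than dropped.
#'
#' @param path CSV path.
#' @return Data frame with `date` parsed to `Date`.
#' @export
read_prescriptions <- function(path) {
  read_records(path, c("subject_id", "atc_code", "date"))
}

#' @rdname read_prescriptions
#' @export
read_measurements <- function(path) {
  m <- read_records(path, c("subject_id", "biomarker", "date", "value"))
  bad <- which(!is.finite(m$value) | m$value <= 0)
  if (length(bad)) stop_with_rows(bad, "non-positive measurement values", path)
  m
}

#' @rdname read_prescriptions
#' @export
read_diagnoses <- function(path) {
  read_records(path, c("subject_id", "code", "date"))
}

read_records <- function(path, required) {
  dt <- data.table::fread(path, data.table = FALSE)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("%s lacks required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dt$date <- as.character(dt$date)
  d <- as.Date(dt$date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(dt$date) & nzchar(dt$date))
  if (length(bad)) stop_with_rows(bad, "unparseable ISO dates", path)
  dt$date <- d
  dt
}

#' Write/read GWAS-style summary statistics
#'
#' Conventional sumstats layout: `variant_id, chrom, pos, effect_allele,
#' other_allele, beta, se, p, n, metric`, tab-separated.
#'
#' @param results Scan results from [run_scan()] or [meta_fixed()].
#' @param path Output path.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_sumstats <- function(results, path) {
  keep <- intersect(c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "beta", "se", "p", "n", "metric"),
                    names(results))
  data.table::fwrite(results[keep], path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

#' Write/read a PGS scoring file
#'
#' PGS-Catalog-style columns: `variant_id, chrom, pos, effect_allele,
#' other_allele, effect_weight` (tab-separated). [write_score_model()] also
#' stores the basic weights, intercept, penalty and scaling factor in a JSON
#' metadata file alongside, and [read_score_model()] reassembles the
#' `score_model`.
#'
#' @param snp_weights Data frame of SNP weights (a `score_model`'s
#'   `snp_weights`).
#' @param path Scoring-file path.
#' @return `path` invisibly (writers); data frame or `score_model` (readers).
#' @export
write_scoring_file <- function(snp_weights, path) {
  data.table::fwrite(snp_weights[c("variant_id", "chrom", "pos",
                                   "effect_allele", "other_allele",
                                   "effect_weight")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_scoring_file
#' @export
read_scoring_file <- function(path) {
  sf <- data.table::fread(path, data.table = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "effect_weight")
  if (!all(need %in% names(sf))) {
    stop(sprintf("scoring file %s lacks required column(s): %s", path,
                 paste(setdiff(need, names(sf)), collapse = ", ")), call. = FALSE)
  }
  sf
}

#' @rdname write_scoring_file
#' @param model A `score_model`.
#' @export
write_score_model <- function(model, path) {
  write_scoring_file(model$snp_weights, path)
  meta <- list(basic_weights = as.list(model$basic_weights),
               intercept = model$intercept, penalty = model$penalty,
               scaling_factor = model$scaling_factor,
               basic_coef = model$basic_coef,
               train_af = as.list(model$train_af))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scoring_file
#' @export
read_score_model <- function(path) {
  sw <- read_scoring_file(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  new_score_model(
    basic_weights = unlist(meta$basic_weights),
    intercept = meta$intercept, snp_weights = sw, penalty = meta$penalty,
    scaling_factor = meta$scaling_factor, basic_coef = meta$basic_coef,
    train_af = unlist(meta$train_af)
  )
}

#' Read a run configuration file
#'
#' YAML file whose `simulation` section maps to [sim_config()] arguments and
#' whose optional `windows` section maps to [window_config()] arguments.
#'
#' @param path YAML path.
#' @return List with elements `simulation` (a `sim_config`) and `windows`
#'   (a `window_config`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$maf_range)) sim_args$maf_range <- unlist(sim_args$maf_range)
  if (!is.null(sim_args$demographic_effects)) {
    sim_args$demographic_effects <- unlist(sim_args$demographic_effects)
  }
  win_args <- y$windows %||% list()
  list(simulation = do.call(sim_config, sim_args),
       windows = do.call(window_config, win_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
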