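#' Phenotyping window configuration
#'
#' Day-granularity rules for deriving response phenotypes from longitudinal
#' records: prescriptions at most `gap_days` apart belong to one episode;
#' baseline measurements must precede initiation by at most
#' `baseline_max_days` and follow a period of `drugfree_days` without any
#' same-disease prescription; on-drug measurements must fall
#' `ondrug_min_days`-`ondrug_max_days` after initiation (the lower bound
#' marks the time to full therapeutic effect). All intervals are closed on
#' both ends.
#'
#' @param gap_days Maximum within-episode refill gap (days).
#' @param drugfree_days Required drug-free run before a baseline measurement.
#' @param baseline_max_days Maximum days a baseline measurement may precede
#'   initiation.
#' @param ondrug_min_days,ondrug_max_days On-drug eligibility window after
#'   initiation.
#' @return List of class `window_config`.
#' @export
window_config <- function(gap_days = 14L, drugfree_days = 180L,
                          baseline_max_days = 730L,
                          ondrug_min_days = 28L, ondrug_max_days = 730L) {
  w <- list(gap_days = as.integer(gap_days),
            drugfree_days = as.integer(drugfree_days),
            baseline_max_days = as.integer(baseline_max_days),
            ondrug_min_days = as.integer(ondrug_min_days),
            ondrug_max_days = as.integer(ondrug_max_days))
  if (w$ondrug_min_days <= 0L || w$ondrug_min_days >= w$ondrug_max_days ||
      w$drugfree_days <= 0L || w$baseline_max_days <= 0L || w$gap_days < 0L) {
    stop("invalid window configuration", call. = FALSE)
  }
  structure(w, class = "window_config")
}

as_day <- function(d) {
  if (inherits(d, "Date")) return(as.integer(d))
  if (is.character(d)) return(as.integer(as.Date(d)))
  as.integer(d)
}

#' Build prescription episodes
#'
#' Partitions each subject's fills of each drug class into maximal runs in
#' which consecutive fills are at most `gap_days` apart. Episode start/end
#' are the first/last fill dates; no coverage duration is imputed beyond the
#' last fill.
#'
#' @param prescriptions Data frame with columns `subject_id`, `atc_code` (or
#'   `drug_class`) and `date` (Date, ISO string, or integer day).
#' @param gap_days Maximum allowed gap, default 14 (gaps of exactly
#'   `gap_days` stay within the episode).
#' @return Data frame: `subject_id`, `drug_class`, `episode` (1-based index
#'   within subject x class), `start_date`, `end_date`, `n_prescriptions`.
#'   Dates are returned in the class of the input.
#' @export
build_episodes <- function(prescriptions, gap_days = 14L) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0L) {
    return(data.frame(subject_id = character(), drug_class = character(),
                      episode = integer(), start_date = numeric(),
                      end_date = numeric(), n_prescriptions = integer()))
  }
  cls <- if ("drug_class" %in% names(prescriptions)) prescriptions$drug_class
         else prescriptions$atc_code
  if (is.null(cls) || any(!nzchar(cls))) {
    stop("prescriptions need a non-empty atc_code/drug_class column", call. = FALSE)
  }
  dt <- data.table::data.table(
    subject_id = prescriptions$subject_id,
    drug_class = cls,
    day = as_day(prescriptions$date)
  )
  was_date <- inherits(prescriptions$date, "Date") || is.character(prescriptions$date)
  data.table::setorder(dt, subject_id, drug_class, day)
  dt[, episode := cumsum(c(1L, diff(day) > gap_days)),
     by = .(subject_id, drug_class)]
  ep <- dt[, .(start_date = min(day), end_date = max(day),
               n_prescriptions = .N),
           by = .(subject_id, drug_class, episode)]
  ep <- as.data.frame(ep)
  if (was_date) {
    ep$start_date <- as.Date(ep$start_date, origin = "1970-01-01")
    ep$end_date <- as.Date(ep$end_date, origin = "1970-01-01")
  }
  ep
}

#' Select eligible baseline measurements for one subject
#'
#' Keeps measurements strictly before initiation by at most
#' `baseline_max_days` days, with no same-disease prescription (of any drug
#' class) in the `drugfree_days` days up to and including the measurement
#' date. A measurement on the initiation day itself is not baseline.
#'
#' @param measurements Data frame with `date` and `value` for one subject.
#' @param same_disease_rx_dates Vector of fill dates of all same-disease drug
#'   classes for the subject (any date representation).
#' @param initiation_date Start of the analyzed episode.
#' @param window A [window_config()].
#' @return The eligible rows of `measurements` plus a `delta` column (days
#'   before initiation).
#' @export
select_baseline <- function(measurements, same_disease_rx_dates,
                            initiation_date, window = window_config()) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    return(cbind(measurements, delta = integer(0)))
  }
  d <- as_day(measurements$date)
  t0 <- as_day(initiation_date)
  delta <- t0 - d
  keep <- delta > 0L & delta <= window$baseline_max_days
  if (any(keep) && length(same_disease_rx_dates)) {
    rx <- as_day(same_disease_rx_dates)
    drugfree <- vapply(d, function(di) {
      !any(rx >= di - window$drugfree_days & rx <= di)
    }, logical(1))
    keep <- keep & drugfree
  }
  out <- measurements[keep, , drop = FALSE]
  out$delta <- delta[keep]
  out
}

#' Select eligible on-drug measurements for one subject
#'
#' Keeps measurements `ondrug_min_days`-`ondrug_max_days` after initiation,
#' not after the analyzed episode's last fill, and not during any overlapping
#' episode of a different same-disease drug class (e.g. ezetimibe or fibrate
#' episodes are excluded from a statin response window).
#'
#' @param measurements Data frame with `date` and `value` for one subject.
#' @param episode One-row data frame (or list) with `start_date`, `end_date`
#'   of the analyzed episode.
#' @param other_episodes Data frame of same-disease episodes of *other* drug
#'   classes (`start_date`, `end_date`); may be empty or NULL.
#' @param window A [window_config()].
#' @return The eligible rows plus a `delta` column (days after initiation).
#' @export
select_ondrug <- function(measurements, episode, other_episodes = NULL,
                          window = window_config()) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    return(cbind(measurements, delta = integer(0)))
  }
  d <- as_day(measurements$date)
  t0 <- as_day(episode$start_date)
  t1 <- as_day(episode$end_date)
  delta <- d - t0
  keep <- delta >= window$ondrug_min_days & delta <= window$ondrug_max_days & d <= t1
  if (any(keep) && !is.null(other_episodes) && nrow(other_episodes) > 0L) {
    os <- as_day(other_episodes$start_date)
    oe <- as_day(other_episodes$end_date)
    inside <- vapply(d, function(di) any(di >= os & di <= oe), logical(1))
    keep <- keep & !inside
  }
  out <- measurements[keep, , drop = FALSE]
  out$delta <- delta[keep]
  out
}

#' Linearly weighted average of measurements
#'
#' Averages measurement values with linear weights that favour measurements
#' closer to drug initiation: `w_i = D + 1 - delta_i`, where `D` is the width
#' of the eligibility window. The `+ 1` keeps a measurement at the window
#' boundary (`delta = D`) strictly positive in weight. A single measurement
#' is returned unchanged; equidistant measurements get a plain mean.
#'
#' @param values Numeric measurement values (at least one).
#' @param delta Day distances from initiation, all within `window_width`.
#' @param window_width Window width `D` in days.
#' @return Weighted average (scalar).
#' @examples
#' weighted_average(c(4, 3), c(100, 350), 730) # (631*4 + 381*3) / 1012
#' @export
weighted_average <- function(values, delta, window_width) {
  if (length(values) == 0L) {
    stop("no eligible measurements: phenotype undefined", call. = FALSE)
  }
  stopifnot(length(values) == length(delta), all(delta <= window_width))
  w <- window_width + 1 - delta
  sum(w * values) / sum(w)
}

#' Derive baseline/on-drug response phenotypes
#'
#' Composes episode construction, baseline and on-drug measurement selection,
#' and weighted averaging into one response phenotype per subject. For each
#' subject the first episode of `drug_class` with at least one eligible
#' baseline and one eligible on-drug measurement is analyzed; subjects with
#' no qualifying episode are simply absent from the output. Duplicate
#' measurement rows are deduplicated on (subject, biomarker, date) before
#' selection, and the result is invariant to input row order.
#'
#' @param prescriptions Data frame: `subject_id`, `atc_code`, `date`.
#' @param measurements Data frame: `subject_id`, `biomarker`, `date`,
#'   `value` (positive).
#' @param drug_class Analyzed drug class code (e.g. "C10AA").
#' @param same_disease_classes Drug classes treating the same disease
#'   (including `drug_class`); used for the drug-free baseline rule and the
#'   concurrent-medication exclusion. Defaults to every class present in
#'   `prescriptions`.
#' @param biomarker Restrict to one biomarker name (default: the only one
#'   present; an error if several).
#' @param window A [window_config()].
#' @return Data frame: `subject_id`, `drug_class`, `baseline`, `ondrug`,
#'   `n_baseline_meas`, `n_ondrug_meas`, `initiation_date`.
#' @export
derive_response_phenotypes <- function(prescriptions, measurements, drug_class,
                                       same_disease_classes = NULL,
                                       biomarker = NULL,
                                       window = window_config()) {
  empty <- data.frame(subject_id = character(), drug_class = character(),
                      baseline = numeric(), ondrug = numeric(),
                      n_baseline_meas = integer(), n_ondrug_meas = integer(),
                      initiation_date = as.Date(character()))
  if (is.null(measurements) || nrow(measurements) == 0L ||
      is.null(prescriptions) || nrow(prescriptions) == 0L) {
    warning("empty prescriptions or measurements: no phenotypes derived")
    return(empty)
  }
  if (any(!is.finite(measurements$value) | measurements$value <= 0)) {
    stop("measurement values must be positive (power transforms require it)",
         call. = FALSE)
  }
  if (is.null(same_disease_classes)) {
    same_disease_classes <- unique(prescriptions$atc_code)
  }
  if (!drug_class %in% same_disease_classes) {
    same_disease_classes <- c(drug_class, same_disease_classes)
  }
  if (is.null(biomarker)) {
    bm <- unique(measurements$biomarker)
    if (length(bm) > 1L) stop("several biomarkers present; specify one", call. = FALSE)
    biomarker <- bm
  }

  bm_sel <- biomarker
  ms <- data.table::data.table(
    subject_id = measurements$subject_id,
    biomarker = measurements$biomarker,
    day = as_day(measurements$date),
    value = measurements$value
  )
  ms <- ms[ms$biomarker == bm_sel, ]
  data.table::setorder(ms, subject_id, day, value)
  ms <- ms[!duplicated(ms[, .(subject_id, biomarker, day)])]

  rx <- prescriptions[prescriptions$atc_code %in% same_disease_classes, , drop = FALSE]
  eps <- build_episodes(rx, gap_days = window$gap_days)
  if (nrow(eps) == 0L) return(empty)
  eps$start_day <- as_day(eps$start_date)
  eps$end_day <- as_day(eps$end_date)
  rx_day <- as_day(rx$date)

  out <- vector("list", 0L)
  for (sid in unique(eps$subject_id[eps$drug_class == drug_class])) {
    m_s <- as.data.frame(ms[ms$subject_id == sid, .(day, value)])
    if (nrow(m_s) == 0L) next
    names(m_s)[1] <- "date"
    ep_s <- eps[eps$subject_id == sid & eps$drug_class == drug_class, , drop = FALSE]
    ep_s <- ep_s[order(ep_s$start_day), , drop = FALSE]
    other_eps <- eps[eps$subject_id == sid & eps$drug_class != drug_class,
                     c("start_day", "end_day"), drop = FALSE]
    names(other_eps) <- c("start_date", "end_date")
    rx_s <- rx_day[rx$subject_id == sid]
    for (k in seq_len(nrow(ep_s))) {
      ep <- list(start_date = ep_s$start_day[k], end_date = ep_s$end_day[k])
      base <- select_baseline(m_s, rx_s, ep$start_date, window)
      if (nrow(base) == 0L) next
      ond <- select_ondrug(m_s, ep, other_eps, window)
      if (nrow(ond) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, drug_class = drug_class,
        baseline = weighted_average(base$value, base$delta, window$baseline_max_days),
        ondrug = weighted_average(ond$value, ond$delta, window$ondrug_max_days),
        n_baseline_meas = nrow(base), n_ondrug_meas = nrow(ond),
        initiation_date = as.Date(ep$start_date, origin = "1970-01-01")
      )
      break # first qualifying episode per subject
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$subject_id), , drop = FALSE]
}

#' Derive disease status from measurements and diagnoses
#'
#' A subject is diseased if they carry a qualifying diagnosis code or breach
#' a biomarker threshold at assessment: for dyslipidemia, LDL-C >= 190 mg/dL
#' or HDL-C < 40 mg/dL (cholesterol in mmol/L is converted with factor
#' 38.67); for hypertension, SBP >= 160 mmHg or DBP >= 100 mmHg. Diagnosis
#' codes are matched by prefix (E78 for dyslipidemia; I10-I15 for
#' hypertension).
#'
#' @param measurements Data frame: `subject_id`, `biomarker` (LDLC, HDLC,
#'   SBP, DBP), `value`.
#' @param diagnoses Optional data frame: `subject_id`, `code`.
#' @param disease `"dyslipidemia"` or `"hypertension"`.
#' @param lipid_units Units of cholesterol measurements, `"mmol/L"` or
#'   `"mg/dL"`.
#' @param subjects Optional vector defining the output universe; defaults to
#'   all subjects seen in `measurements`/`diagnoses`.
#' @return Data frame: `subject_id`, `diseased` (logical).
#' @export
derive_disease_status <- function(measurements, diagnoses = NULL,
                                  disease = c("dyslipidemia", "hypertension"),
                                  lipid_units = c("mmol/L", "mg/dL"),
                                  subjects = NULL) {
  disease <- match.arg(disease)
  lipid_units <- match.arg(lipid_units)
  conv <- if (lipid_units == "mmol/L") 38.67 else 1
  if (is.null(subjects)) {
    subjects <- unique(c(measurements$subject_id, diagnoses$subject_id))
  }
  flag <- stats::setNames(rep(FALSE, length(subjects)), subjects)

  if (!is.null(measurements) && nrow(measurements)) {
    m <- measurements
    breach <- if (disease == "dyslipidemia") {
      (m$biomarker == "LDLC" & m$value * conv >= 190) |
        (m$biomarker == "HDLC" & m$value * conv < 40)
    } else {
      (m$biomarker == "SBP" & m$value >= 160) |
        (m$biomarker == "DBP" & m$value >= 100)
    }
    hit <- unique(m$subject_id[breach])
    flag[names(flag) %in% hit] <- TRUE
  }
  if (!is.null(diagnoses) && nrow(diagnoses)) {
    pref <- if (disease == "dyslipidemia") "^E78" else "^I1[0-5]"
    hit <- unique(diagnoses$subject_id[grepl(pref, diagnoses$code)])
    flag[names(flag) %in% hit] <- TRUE
  }
  data.frame(subject_id = names(flag), diseased = unname(flag))
}

#' Derive drug-choice case/control labels
#'
#' Among diseased subjects, cases are those using the drug class and controls
#' are those not using it. Healthy drug users are excluded: this is the
#' drug-*choice* trait (which drug, given the disease), not the drug-*use*
#' trait whose controls include healthy non-users.
#'
#' @param disease_status Data frame from [derive_disease_status()].
#' @param users Vector of subject ids using the drug (from interview flags or
#'   prescription episodes extending beyond three months).
#' @return Data frame: `subject_id`, `choice` (1 case / 0 control), diseased
#'   subjects only.
#' @export
derive_choice_labels <- function(disease_status, users) {
  d <- disease_status[disease_status$diseased, , drop = FALSE]
  data.frame(subject_id = d$subject_id,
             choice = as.integer(d$subject_id %in% users))
}
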