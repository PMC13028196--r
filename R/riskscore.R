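#' Default (synthetic) hypoglycemia risk-score coefficients
#'
#' The dispensing-based hypoglycemia risk score is a logistic-regression
#' score; its original coefficients belong to a separately published
#' algorithm and are supplied by the user as a coefficients file. The
#' shipped default is synthetic: directions are clinically plausible
#' (insulin exposure dominates, sulfonylureas and age contribute) and the
#' magnitudes are calibrated so that roughly a quarter of the default
#' simulated cohort exceeds the 0.6 cutoff, mirroring published estimates
#' that about 25% of primary-care T2D patients are at high risk.
#'
#' @param path optional path to a two-column (`term`, `estimate`)
#'   delimited file; defaults to the synthetic coefficients shipped with
#'   the package.
#' @return named numeric vector, first element `(Intercept)`.
#' @export
risk_coefficients_default <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "risk_coefficients_synthetic.csv",
                        package = "hypotraj", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$estimate, tab$term)
}

RISK_TERMS <- c("age", "sex_female", "total_drug_count", "gld_count",
                "su_count", "insulin_count", "premixed_insulin_use",
                "antidepressant_use", "insulin_duration_years")

#' Dispensing-based risk predictors at the index date
#'
#' Extracts, for each cohort member, the predictor vector of the
#' hypoglycemia risk score: age and sex at index; distinct ATC-5 subgroups
#' dispensed in the index +/-45-day window in total (`total_drug_count`),
#' among glucose-lowering drugs (`gld_count`), sulfonylureas (`su_count`)
#' and insulins (`insulin_count`); any premixed insulin (A10AD) and any
#' antidepressant (N06A) in the window; and the time in years from the
#' first pre-index insulin dispensing (within the five pre-index years,
#' boundary inclusive) to the index date, zero when there is none.
#'
#' @param members cohort table (`patient_id`, `index_date`, `age_at_index`,
#'   `sex`).
#' @param dispensings dispensing records.
#' @param window_days index window half-width (default 45).
#' @return data.frame of risk profiles, one row per member.
#' @export
build_profiles <- function(members, dispensings, window_days = 45) {
  d <- dispensings
  d$dispense_date <- as_date(d$dispense_date)
  idx <- as_date(members$index_date)[match(d$patient_id, members$patient_id)]
  delta <- as.numeric(d$dispense_date - idx)
  inw <- !is.na(delta) & abs(delta) <= window_days
  pid5 <- paste(d$patient_id, substr(d$atc_code, 1, 5))
  # first in-window occurrence of each (patient, subgroup); out-of-window
  # rows get unique keys so they can never mask an in-window one
  u <- inw & !duplicated(ifelse(inw, pid5, paste0("out:", seq_along(pid5))))
  f <- factor(d$patient_id[u], levels = members$patient_id)
  nb <- nlevels(f)
  atc <- d$atc_code[u]
  total <- tabulate(f, nbins = nb)
  gld <- tabulate(f[startsWith(atc, "A10")], nbins = nb)
  su <- tabulate(f[startsWith(atc, "A10BB")], nbins = nb)
  ins <- tabulate(f[startsWith(atc, "A10A")], nbins = nb)
  premix <- tabulate(f[startsWith(atc, "A10AD")], nbins = nb) > 0
  antidep <- tabulate(f[startsWith(atc, "N06A")], nbins = nb) > 0

  # insulin duration: first pre-index A10A dispensing within 5 years
  pre5 <- ann_shift(members$index_date, -5)
  lo <- pre5[match(d$patient_id, members$patient_id)]
  sel <- !is.na(idx) & startsWith(d$atc_code, "A10A") &
    d$dispense_date >= lo & d$dispense_date < idx
  first_ins <- rep(NA_real_, nrow(members))
  if (any(sel)) {
    agg <- stats::aggregate(dispense_date ~ patient_id, data = d[sel, ], FUN = min)
    first_ins[match(agg$patient_id, members$patient_id)] <-
      as.numeric(agg$dispense_date)
  }
  dur <- ifelse(is.na(first_ins), 0,
                (as.numeric(as_date(members$index_date)) - first_ins) / 365.25)
  data.frame(patient_id = members$patient_id,
             age = members$age_at_index,
             sex_female = as.integer(members$sex == "female"),
             total_drug_count = total, gld_count = gld,
             su_count = su, insulin_count = ins,
             premixed_insulin_use = as.integer(premix),
             antidepressant_use = as.integer(antidep),
             insulin_duration_years = pmin(dur, 5),
             stringsAsFactors = FALSE)
}

#' Hypoglycemia risk score and category
#'
#' Inverse-logit score on the risk profile; patients at or above the
#' cutoff (default 0.6) are classified high-risk.
#'
#' @param profiles data.frame from [build_profiles()].
#' @param coefficients named vector with `(Intercept)` and one weight per
#'   predictor (see [risk_coefficients_default()]); a missing term is a
#'   configuration error.
#' @param cutoff dichotomization threshold (default 0.6; `high` iff
#'   `score >= cutoff`).
#' @return `profiles` with added columns `score` (in `[0, 1]`) and
#'   `category` (`"low"`/`"high"`).
#' @export
#' @examples
#' p <- data.frame(patient_id = "p1", age = 70, sex_female = 1,
#'                 total_drug_count = 5, gld_count = 2, su_count = 0,
#'                 insulin_count = 1, premixed_insulin_use = 0,
#'                 antidepressant_use = 0, insulin_duration_years = 2)
#' risk_score(p)[, c("score", "category")]
risk_score <- function(profiles, coefficients = risk_coefficients_default(),
                       cutoff = 0.6) {
  need <- c("(Intercept)", RISK_TERMS)
  missing <- setdiff(need, names(coefficients))
  if (length(missing))
    stop_cfg("risk_coefficients",
             paste("missing coefficient(s):", paste(missing, collapse = ", ")))
  X <- as.matrix(profiles[, RISK_TERMS])
  eta <- coefficients[["(Intercept)"]] + as.numeric(X %*% coefficients[RISK_TERMS])
  profiles$score <- stats::plogis(eta)
  profiles$category <- ifelse(profiles$score >= cutoff, "high", "low")
  profiles
}
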