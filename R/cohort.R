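#' Cohort selection settings
#'
#' Defaults reproduce a prevalent-user design: index is the first
#' glucose-lowering (A10) dispensing between 1 July 2016 and 30 June 2017
#' (both boundaries inclusive), adults aged 35 and over, at least two A10
#' dispensings in the closed interval `[index, index + 365]` (the index
#' dispensing counts as one of the two), continuous registration covering
#' five calendar years before and after index, and exclusion of patients
#' whose pre-index A10 dispensings were exclusively insulin (a type-1-like
#' pattern). Patients with no pre-index A10 dispensings at all are
#' retained as incident-like users.
#'
#' @param index_window_start,index_window_end index window boundaries.
#' @param min_age_at_index minimum age in completed years (default 35).
#' @param min_a10_dispensings minimum number of A10 dispensings within
#'   `lookahead_days` of index, index dispensing included (default 2).
#' @param lookahead_days exposure-evidence window after index (default 365).
#' @param required_pre_years,required_post_years continuous-registration
#'   requirement in calendar years (defaults 5 and 5).
#' @param dummy_id_pattern optional regular expression; patients whose id
#'   matches are dropped before any other rule (screening hook for test
#'   records in production databases; default `NULL`, off).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(index_window_start = as.Date("2016-07-01"),
                          index_window_end = as.Date("2017-06-30"),
                          min_age_at_index = 35L,
                          min_a10_dispensings = 2L,
                          lookahead_days = 365L,
                          required_pre_years = 5L,
                          required_post_years = 5L,
                          dummy_id_pattern = NULL) {
  index_window_start <- as_date(index_window_start)
  index_window_end <- as_date(index_window_end)
  if (!index_window_start < index_window_end)
    stop_cfg("index_window_start", "must precede index_window_end")
  for (f in c("min_age_at_index", "min_a10_dispensings", "lookahead_days",
              "required_pre_years", "required_post_years")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v <= 0) stop_cfg(f, "must be positive")
  }
  structure(list(index_window_start = index_window_start,
                 index_window_end = index_window_end,
                 min_age_at_index = as.integer(min_age_at_index),
                 min_a10_dispensings = as.integer(min_a10_dispensings),
                 lookahead_days = as.integer(lookahead_days),
                 required_pre_years = as.integer(required_pre_years),
                 required_post_years = as.integer(required_post_years),
                 dummy_id_pattern = dummy_id_pattern),
            class = "cohort_config")
}

#' Index date of a patient
#'
#' The earliest dispensing with ATC prefix "A10" inside the index window
#' (boundaries inclusive), or `NA` if the patient has none.
#'
#' @param patient one patient row (needs `patient_id`).
#' @param dispensings dispensing records of that patient.
#' @param config a [cohort_config()].
#' @return a `Date`, or `NA` when no qualifying dispensing exists.
#' @export
find_index_date <- function(patient, dispensings, config = cohort_config()) {
  d <- dispensings[dispensings$patient_id == patient$patient_id[1], ]
  dates <- as_date(d$dispense_date)
  ok <- startsWith(d$atc_code, "A10") &
    dates >= config$index_window_start & dates <= config$index_window_end
  if (!any(ok)) return(as.Date(NA))
  min(dates[ok])
}

#' Select the analysis cohort
#'
#' Applies the selection rules in a fixed declared order and reports a
#' selection-flow tally (count removed at each step); the tally plus the
#' retained count always equals the input patient count. Steps, in order:
#' `dummy_id`, `no_index_dispensing`, `age_below_minimum`, `spot_user`,
#' `insufficient_registration`, `insulin_only_preindex`.
#'
#' @param patients patient table (`patient_id`, `birth_year`, `sex`,
#'   `registration_start`, `registration_end`).
#' @param dispensings dispensing records.
#' @param config a [cohort_config()].
#' @return list with `members` (cohort table: `patient_id`, `index_date`,
#'   `age_at_index`, `sex`, `age_band`) and `flow` (named integer vector of
#'   exclusion counts, ending in `retained`).
#' @export
select_cohort <- function(patients, dispensings, config = cohort_config()) {
  steps <- c("dummy_id", "no_index_dispensing", "age_below_minimum",
             "spot_user", "insufficient_registration", "insulin_only_preindex")
  flow <- stats::setNames(integer(length(steps)), steps)
  empty <- data.frame(patient_id = character(0), index_date = as.Date(character(0)),
                      age_at_index = integer(0), sex = character(0),
                      age_band = factor(character(0),
                                        levels = levels(age_band_of(40))))
  if (nrow(patients) == 0 || nrow(dispensings) == 0) {
    warning("empty input tables; returning empty cohort")
    return(list(members = empty, flow = c(flow, retained = 0L)))
  }
  p <- patients
  p$registration_start <- as_date(p$registration_start)
  p$registration_end <- as_date(p$registration_end)
  d <- dispensings
  d$dispense_date <- as_date(d$dispense_date)

  if (!is.null(config$dummy_id_pattern)) {
    drop <- grepl(config$dummy_id_pattern, p$patient_id)
    flow["dummy_id"] <- sum(drop)
    p <- p[!drop, ]
  }

  a10 <- d[startsWith(d$atc_code, "A10"), ]

  # step: index date exists
  in_win <- a10$dispense_date >= config$index_window_start &
    a10$dispense_date <= config$index_window_end
  if (any(in_win)) {
    idx_tab <- stats::aggregate(dispense_date ~ patient_id,
                                data = a10[in_win, ], FUN = min)
    p$index_date <- idx_tab$dispense_date[match(p$patient_id, idx_tab$patient_id)]
  } else p$index_date <- as.Date(NA)
  drop <- is.na(p$index_date)
  flow["no_index_dispensing"] <- sum(drop)
  p <- p[!drop, ]

  # step: age
  p$age_at_index <- age_at(p$index_date, p$birth_year)
  drop <- p$age_at_index < config$min_age_at_index
  flow["age_below_minimum"] <- sum(drop)
  p <- p[!drop, ]

  # step: exposure evidence (spot users)
  i <- match(a10$patient_id, p$patient_id)
  idx_d <- p$index_date[i]
  in_look <- !is.na(idx_d) & a10$dispense_date >= idx_d &
    a10$dispense_date <= idx_d + config$lookahead_days
  n_look <- tabulate(factor(a10$patient_id[in_look], levels = p$patient_id),
                     nbins = nrow(p))
  drop <- n_look < config$min_a10_dispensings
  flow["spot_user"] <- sum(drop)
  p <- p[!drop, ]

  # step: continuous registration coverage
  pre <- ann_shift(p$index_date, -config$required_pre_years)
  post <- ann_shift(p$index_date, config$required_post_years)
  drop <- !(p$registration_start <= pre & p$registration_end >= post)
  flow["insufficient_registration"] <- sum(drop)
  p <- p[!drop, ]
  pre <- pre[!drop]

  # step: insulin-only pre-index (likely type 1); patients with zero
  # pre-index A10 dispensings are retained
  i <- match(a10$patient_id, p$patient_id)
  idx_d <- p$index_date[i]
  pre_d <- pre[i]
  in_pre <- !is.na(idx_d) & a10$dispense_date >= pre_d & a10$dispense_date < idx_d
  f <- factor(a10$patient_id[in_pre], levels = p$patient_id)
  n_pre <- tabulate(f, nbins = nrow(p))
  n_pre_ins <- tabulate(f[startsWith(a10$atc_code[in_pre], "A10A")],
                        nbins = nrow(p))
  drop <- n_pre > 0 & n_pre == n_pre_ins
  flow["insulin_only_preindex"] <- sum(drop)
  p <- p[!drop, ]

  members <- data.frame(patient_id = p$patient_id, index_date = p$index_date,
                        age_at_index = p$age_at_index, sex = p$sex,
                        age_band = age_band_of(p$age_at_index),
                        stringsAsFactors = FALSE)
  rownames(members) <- NULL
  list(members = members, flow = c(flow, retained = nrow(members)))
}
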