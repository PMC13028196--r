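#' Configuration of the synthetic dispensing-data generator
#'
#' Builds a validated configuration for [simulate_population()]. The
#' generator emulates the longitudinal structure of a community-pharmacy
#' dispensing database: prevalent glucose-lowering drug users with a latent
#' annual change process on the states no change / intensification /
#' de-intensification, per-drug refill renewal processes, and the edge
#' cases a cohort-selection stage must handle (spot users, insulin-only
#' pre-index patients, patients with short registration).
#'
#' The latent process is a continuous-time Markov chain on (NC, IN, DI)
#' observed annually; `annual_change_rates` are its transition intensities
#' (yearly hazards). The defaults are calibrated so that the implied
#' one-year transition matrix has NC row (0.876, 0.077, 0.047) and
#' persistence around 0.4 in the IN and DI states, the pattern reported for
#' large Dutch primary-care cohorts. A drawn change is applied to the
#' drug regimen at one uniformly drawn date per year, in the interior of
#' the interval (at least `window + 1` days clear of both anniversaries) so
#' the change is attributable to a single interval; a drawn change that is
#' infeasible for the current regimen (e.g. intensification when both
#' insulin and sulfonylurea are already present) degrades to no change, and
#' the recorded latent truth is what actually happened.
#'
#' @param n_patients number of patients.
#' @param seed master seed; per-patient latent substreams are derived from
#'   it so [latent_truth()] can be recomputed independently.
#' @param start_date,end_date database coverage (defaults 2011-01-01 and
#'   2022-12-31).
#' @param index_window_start,index_window_end window in which each
#'   patient's therapy anchor (index) date is drawn.
#' @param annual_change_rates named non-negative vector of CTMC intensities
#'   `nc_in, nc_di, in_nc, in_di, di_nc, di_in`.
#' @param refill_interval_days `c(mean, sd)` of the per-drug refill
#'   renewal interval (truncated below at `refill_floor_days`).
#' @param refill_floor_days minimum refill interval (default 14).
#' @param filler_interval_days `c(mean, sd)` for non-diabetes filler drugs.
#' @param frac_spot_users fraction of patients with exactly one A10
#'   dispensing in the 365 days from index.
#' @param frac_insulin_only_preindex fraction whose pre-index
#'   glucose-lowering history is insulin only (type-1-like).
#' @param frac_short_registration fraction registered for less than the
#'   required ten years.
#' @param age_distribution `c(mean, sd)` of age at 2016-07-01.
#' @param frac_female fraction female.
#' @param initial_regimen_probs named probability vector over the baseline
#'   regimen taxonomy (default: frequencies of a large Dutch T2D cohort).
#' @param other_churn_rate yearly probability that a no-change year still
#'   modifies a non-hypoglycemia-associated ("other") drug.
#' @param female_di_multiplier hazard multiplier on transitions into DI for
#'   female patients (default 1.12).
#' @param insulin_user_di_multiplier hazard multiplier on transitions into
#'   DI while the regimen contains insulin (default 2.5; insulin users are
#'   the high-hypoglycemia-risk group and de-intensify more).
#' @param mean_filler_drugs Poisson mean of non-diabetes filler drugs per
#'   patient.
#' @param frac_antidepressant probability of a chronic antidepressant
#'   (N06A) filler.
#' @param risk_coefficients coefficient vector for the hypoglycemia risk
#'   score (see [risk_coefficients_default()]).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       start_date = as.Date("2011-01-01"),
                       end_date = as.Date("2022-12-31"),
                       index_window_start = as.Date("2016-07-01"),
                       index_window_end = as.Date("2017-06-30"),
                       annual_change_rates = c(nc_in = 0.123873, nc_di = 0.069380,
                                               in_nc = 0.787510, in_di = 0.195366,
                                               di_nc = 0.743561, di_in = 0.235209),
                       refill_interval_days = c(mean = 60, sd = 15),
                       refill_floor_days = 14,
                       filler_interval_days = c(mean = 90, sd = 20),
                       frac_spot_users = 0.05,
                       frac_insulin_only_preindex = 0.02,
                       frac_short_registration = 0.492,
                       age_distribution = c(mean = 66.19, sd = 11.11),
                       frac_female = 0.482,
                       initial_regimen_probs = default_regimen_probs(),
                       other_churn_rate = 0.10,
                       female_di_multiplier = 1.12,
                       insulin_user_di_multiplier = 2.5,
                       mean_filler_drugs = 2,
                       frac_antidepressant = 0.15,
                       risk_coefficients = risk_coefficients_default()) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop_cfg("n_patients", "must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_cfg("seed", "must be an integer")
  start_date <- as_date(start_date); end_date <- as_date(end_date)
  if (!start_date < end_date) stop_cfg("start_date", "must precede end_date")
  need <- c("nc_in", "nc_di", "in_nc", "in_di", "di_nc", "di_in")
  if (!all(need %in% names(annual_change_rates)))
    stop_cfg("annual_change_rates",
             paste("must name all of", paste(need, collapse = ", ")))
  if (any(annual_change_rates < 0))
    stop_cfg("annual_change_rates", "hazards must be non-negative")
  if (refill_interval_days[["mean"]] <= 0)
    stop_cfg("refill_interval_days", "mean must be positive")
  if (refill_interval_days[["sd"]] < 0)
    stop_cfg("refill_interval_days", "sd must be non-negative")
  check_prop(frac_spot_users, "frac_spot_users")
  check_prop(frac_insulin_only_preindex, "frac_insulin_only_preindex")
  check_prop(frac_short_registration, "frac_short_registration")
  check_prop(frac_female, "frac_female")
  check_prop(other_churn_rate, "other_churn_rate")
  check_prop(frac_antidepressant, "frac_antidepressant")
  if (frac_spot_users + frac_insulin_only_preindex + frac_short_registration > 1)
    stop_cfg("frac_spot_users", "edge-case fractions must sum to at most 1")
  if (any(initial_regimen_probs < 0) || sum(initial_regimen_probs) <= 0)
    stop_cfg("initial_regimen_probs", "must be non-negative with positive sum")
  if (age_distribution[["sd"]] <= 0) stop_cfg("age_distribution", "sd must be positive")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    start_date = start_date, end_date = end_date,
    index_window_start = as_date(index_window_start),
    index_window_end = as_date(index_window_end),
    annual_change_rates = annual_change_rates[need],
    refill_interval_days = refill_interval_days,
    refill_floor_days = refill_floor_days,
    filler_interval_days = filler_interval_days,
    frac_spot_users = frac_spot_users,
    frac_insulin_only_preindex = frac_insulin_only_preindex,
    frac_short_registration = frac_short_registration,
    age_distribution = age_distribution, frac_female = frac_female,
    initial_regimen_probs = initial_regimen_probs / sum(initial_regimen_probs),
    other_churn_rate = other_churn_rate,
    female_di_multiplier = female_di_multiplier,
    insulin_user_di_multiplier = insulin_user_di_multiplier,
    mean_filler_drugs = mean_filler_drugs,
    frac_antidepressant = frac_antidepressant,
    risk_coefficients = risk_coefficients), class = "sim_config")
}

#' Default baseline-regimen distribution
#'
#' Frequencies of the baseline treatment-regimen taxonomy in a large Dutch
#' community-pharmacy T2D cohort. ("SU combination", two distinct
#' sulfonylurea subgroups, is unreachable at ATC-5 granularity and omitted;
#' it accounted for 0.1% of that cohort.)
#'
#' @return named probability vector.
#' @export
default_regimen_probs <- function() {
  counts <- c("Metformin monotherapy" = 10315,
              "Non-insulin, non-SU combination" = 437,
              "DPP4 inhibitors monotherapy" = 47,
              "GLP-1 analogs monotherapy" = 25,
              "Alpha glucosidase inhibitors monotherapy" = 17,
              "Thiazolidinediones monotherapy" = 10,
              "SGLT2 inhibitors monotherapy" = 4,
              "SU + non-insulin combination" = 6623,
              "Insulin + other combination" = 3886,
              "Insulin + SU combination" = 1652,
              "SU monotherapy" = 1075,
              "Insulin combination" = 545,
              "Insulin monotherapy" = 408)
  counts / sum(counts)
}

INSULIN_SUBGROUPS <- c("A10AB", "A10AC", "A10AD", "A10AE")
OTHER_POOL <- c("A10BA", "A10BH", "A10BK", "A10BJ", "A10BG", "A10BF")
FILLER_POOL <- c("C07AB02", "C10AA01", "A02BC02", "B01AC06",
                 "C03CA01", "N02BE01", "R03AC02", "C09AA02")
PRODUCT_MAP <- c(A10BA = "A10BA02", A10AB = "A10AB05", A10AC = "A10AC01",
                 A10AD = "A10AD05", A10AE = "A10AE04", A10BH = "A10BH01",
                 A10BJ = "A10BJ02", A10BK = "A10BK01", A10BF = "A10BF01",
                 A10BG = "A10BG03")
SU_PRODUCTS <- c("A10BB01", "A10BB09", "A10BB12")

patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629)
}

# regimen-category name -> set of active ATC-5 subgroups (insulin subgroup
# choices consume the latent RNG stream)
initial_set_for <- function(category) {
  ins <- function(n = 1) sample(INSULIN_SUBGROUPS, n, prob = c(.35, .15, .2, .3)[seq_along(INSULIN_SUBGROUPS)])
  switch(category,
    "Metformin monotherapy" = "A10BA",
    "Non-insulin, non-SU combination" = c("A10BA", "A10BH"),
    "DPP4 inhibitors monotherapy" = "A10BH",
    "GLP-1 analogs monotherapy" = "A10BJ",
    "Alpha glucosidase inhibitors monotherapy" = "A10BF",
    "Thiazolidinediones monotherapy" = "A10BG",
    "SGLT2 inhibitors monotherapy" = "A10BK",
    "SU + non-insulin combination" = c("A10BA", "A10BB"),
    "Insulin + other combination" = c(ins(), "A10BA"),
    "Insulin + SU combination" = c(ins(), "A10BB"),
    "SU monotherapy" = "A10BB",
    "Insulin combination" = sample(INSULIN_SUBGROUPS, 2),
    "Insulin monotherapy" = ins(),
    stop("unknown regimen category: ", category))
}

# one-year transition matrix cache over (regimen has insulin) x (female)
make_P_cache <- function(cfg) {
  r <- cfg$annual_change_rates
  cache <- new.env(parent = emptyenv())
  function(has_ins, female) {
    key <- paste0(as.integer(has_ins), as.integer(female))
    if (!is.null(cache[[key]])) return(cache[[key]])
    m_di <- (if (female) cfg$female_di_multiplier else 1) *
            (if (has_ins) cfg$insulin_user_di_multiplier else 1)
    q <- matrix(0, 3, 3, dimnames = list(c("NC", "IN", "DI"), c("NC", "IN", "DI")))
    q["NC", "IN"] <- r[["nc_in"]]; q["NC", "DI"] <- r[["nc_di"]] * m_di
    q["IN", "NC"] <- r[["in_nc"]]; q["IN", "DI"] <- r[["in_di"]] * m_di
    q["DI", "NC"] <- r[["di_nc"]]; q["DI", "IN"] <- r[["di_in"]]
    diag(q) <- -rowSums(q)
    P <- as.matrix(Matrix::expm(q))
    cache[[key]] <- P
    P
  }
}

# Stage 1 (latent substream): demographics, edge-case type, anchor date,
# regimen path and drug episodes for one patient. Re-run verbatim by
# latent_truth(), so everything random here must stay in this function.
sim_patient_latent <- function(i, cfg, P_of) {
  set.seed(patient_seed(cfg$seed, i))
  sex <- if (stats::runif(1) < cfg$frac_female) "female" else "male"
  age <- round(min(95, max(25, stats::rnorm(1, cfg$age_distribution[["mean"]],
                                            cfg$age_distribution[["sd"]]))))
  birth_year <- 2016L - as.integer(age)
  u <- stats::runif(1)
  type <- if (u < cfg$frac_spot_users) "spot"
          else if (u < cfg$frac_spot_users + cfg$frac_insulin_only_preindex) "insulin_only"
          else if (u < cfg$frac_spot_users + cfg$frac_insulin_only_preindex +
                       cfg$frac_short_registration) "short_reg"
          else "regular"
  win_len <- as.numeric(cfg$index_window_end - cfg$index_window_start)
  anchor <- cfg$index_window_start + floor(stats::runif(1) * (win_len + 1))
  reg_start <- cfg$start_date; reg_end <- cfg$end_date
  if (type == "short_reg")
    reg_start <- anchor - round(stats::runif(1, 365, 4.9 * 365))

  # chronic filler (non-diabetes) drugs, active for the whole registration
  fillers <- character(0)
  if (stats::runif(1) < cfg$frac_antidepressant) fillers <- "N06AB06"
  n_fill <- stats::rpois(1, cfg$mean_filler_drugs)
  if (n_fill > 0)
    fillers <- c(fillers, sample(FILLER_POOL, min(n_fill, length(FILLER_POOL))))

  out <- list(patient_id = sprintf("P%06d", i), sex = sex,
              birth_year = birth_year, type = type, anchor = anchor,
              reg_start = reg_start, reg_end = reg_end, fillers = fillers,
              states = character(0))
  if (type == "spot") return(out)
  if (type == "insulin_only") {
    ig <- sample(INSULIN_SUBGROUPS, 1)
    out$episodes <- data.frame(atc5 = ig, start = reg_start, end = reg_end)
    return(out)
  }

  cat0 <- sample(names(cfg$initial_regimen_probs), 1,
                 prob = cfg$initial_regimen_probs)
  set <- initial_set_for(cat0)
  ep_atc5 <- set
  ep_start <- rep(reg_start, length(set))
  ep_end <- rep(as.Date(NA), length(set))
  if (!any(atc_class(set) %in% c("SU", "OTHER_GLD"))) {
    # insulin-only regimens at index get a discontinued oral in their
    # history (they switched to insulin in the past), so the type-1-like
    # "insulin only pre-index" exclusion does not misfire on them
    hist_end <- anchor - round(stats::runif(1, 400, 1500))
    if (hist_end > reg_start) {
      ep_atc5 <- c(ep_atc5, "A10BA")
      ep_start <- c(ep_start, reg_start)
      ep_end <- c(ep_end, hist_end)
    }
  }
  drop_drug <- function(sub) {
    open <- which(ep_atc5 %in% sub & is.na(ep_end))
    ep_end[open] <<- change_date
    set <<- setdiff(set, sub)
  }
  add_drug <- function(sub) {
    ep_atc5 <<- c(ep_atc5, sub)
    ep_start <<- c(ep_start, rep(change_date, length(sub)))
    ep_end <<- c(ep_end, rep(as.Date(NA), length(sub)))
    set <<- union(set, sub)
  }

  ann <- anniversary_dates(anchor, 5)
  states <- character(5)
  s_prev <- "NC"
  for (k in 1:5) {
    cls <- atc_class(set)
    has_ins <- any(cls == "INSULIN"); has_su <- any(cls == "SU")
    others <- set[cls == "OTHER_GLD"]
    P <- P_of(has_ins, sex == "female")
    s <- sample(c("NC", "IN", "DI"), 1, prob = P[s_prev, ])
    if (s == "IN" && has_ins && has_su) s <- "NC"
    if (s == "DI" && !has_ins && !has_su) s <- "NC"
    gap <- as.numeric(ann[k + 1] - ann[k])
    change_date <- ann[k] + round(stats::runif(1, 46, gap - 46))
    if (s == "IN") {
      a <- if (!has_su && !has_ins) {
        opts <- c("add_su", "add_ins"); w <- c(.55, .25)
        if (length(others)) { opts <- c(opts, "sw_to_su", "sw_to_ins"); w <- c(w, .12, .08) }
        sample(opts, 1, prob = w)
      } else if (has_su) sample(c("add_ins", "sw_su_ins"), 1, prob = c(.75, .25))
      else "add_su"
      switch(a,
        add_su = add_drug("A10BB"),
        add_ins = add_drug(sample(INSULIN_SUBGROUPS, 1)),
        sw_to_su = { drop_drug(sample(others, 1)); add_drug("A10BB") },
        sw_to_ins = { drop_drug(sample(others, 1))
                      add_drug(sample(INSULIN_SUBGROUPS, 1)) },
        sw_su_ins = { drop_drug("A10BB")
                      add_drug(sample(INSULIN_SUBGROUPS, 1)) })
    } else if (s == "DI") {
      ins_subs <- set[cls == "INSULIN"]
      a <- if (has_ins && has_su) sample(c("drop_su", "drop_ins", "drop_both"),
                                         1, prob = c(.6, .35, .05))
      else if (has_ins) sample(c("drop_ins", "sw_ins_su", "sw_ins_other"),
                               1, prob = c(.7, .15, .15))
      else sample(c("drop_su", "sw_su_other"), 1, prob = c(.7, .3))
      avail <- setdiff(OTHER_POOL, set)
      if (a %in% c("sw_ins_other", "sw_su_other") && !length(avail))
        a <- if (a == "sw_ins_other") "drop_ins" else "drop_su"
      switch(a,
        drop_su = drop_drug("A10BB"),
        drop_ins = drop_drug(ins_subs),
        drop_both = drop_drug(c(ins_subs, "A10BB")),
        sw_ins_su = { drop_drug(ins_subs); add_drug("A10BB") },
        sw_ins_other = { drop_drug(ins_subs); add_drug(sample(avail, 1)) },
        sw_su_other = { drop_drug("A10BB"); add_drug(sample(avail, 1)) })
    } else if (stats::runif(1) < cfg$other_churn_rate) {
      # other-drug churn in a no-change year (rule A(ii))
      if (length(others) && length(set) >= 2) drop_drug(sample(others, 1))
      else {
        avail <- setdiff(OTHER_POOL, set)
        if (length(avail)) add_drug(sample(avail, 1))
      }
    }
    states[k] <- s
    s_prev <- s
  }
  ep_end[is.na(ep_end)] <- reg_end
  out$episodes <- data.frame(atc5 = ep_atc5, start = ep_start, end = ep_end)
  out$states <- states
  out
}

#' Generate a synthetic patient and dispensing table
#'
#' Runs the latent stage for every patient (see [sim_config()]), then emits
#' per-drug dispensings as a renewal process with truncated-normal refill
#' intervals. Drugs active at the anchor date are emitted backwards from
#' just before the index window and forwards from the anchor, so the first
#' in-window glucose-lowering dispensing falls exactly on the anchor and a
#' drug active at an assessment date has a dispensing inside the +/-45-day
#' window with high probability. Identical configuration and seed give
#' byte-identical tables.
#'
#' @param config a [sim_config()].
#' @return list of class `hypotraj_sim` with elements `patients`
#'   (`patient_id`, `birth_year`, `sex`, `registration_start`,
#'   `registration_end`), `dispensings` (`patient_id`, `atc_code`,
#'   `dispense_date`, `n_days_supplied`), `truth` (per-patient latent
#'   states: `patient_id`, `interval`, `state`, plus the edge-case `type`
#'   and anchor date per patient) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  P_of <- make_P_cache(config)
  n <- config$n_patients
  lat <- vector("list", n)
  for (i in seq_len(n)) lat[[i]] <- sim_patient_latent(i, config, P_of)

  patients <- data.frame(
    patient_id = vapply(lat, `[[`, character(1), "patient_id"),
    birth_year = vapply(lat, `[[`, integer(1), "birth_year"),
    sex = vapply(lat, `[[`, character(1), "sex"),
    registration_start = as.Date(vapply(lat, function(p) as.numeric(p$reg_start),
                                        numeric(1)), origin = "1970-01-01"),
    registration_end = as.Date(vapply(lat, function(p) as.numeric(p$reg_end),
                                      numeric(1)), origin = "1970-01-01"),
    stringsAsFactors = FALSE)

  has_states <- vapply(lat, function(p) length(p$states) == 5, logical(1))
  truth <- list(
    states = data.frame(
      patient_id = rep(patients$patient_id[has_states], each = 5),
      interval = rep(1:5, sum(has_states)),
      state = unlist(lapply(lat[has_states], `[[`, "states")),
      stringsAsFactors = FALSE),
    patients = data.frame(
      patient_id = patients$patient_id,
      type = vapply(lat, `[[`, character(1), "type"),
      anchor = as.Date(vapply(lat, function(p) as.numeric(p$anchor),
                              numeric(1)), origin = "1970-01-01"),
      stringsAsFactors = FALSE))

  dispensings <- emit_dispensings(lat, config)
  structure(list(patients = patients, dispensings = dispensings,
                 truth = truth, config = config),
            class = "hypotraj_sim")
}

# Stage 2: vectorized renewal-process emission over all drug episodes.
# An "episode row" is one emission run: forward runs walk from `lo` up to
# `hi`; backward runs re-create the pre-index refill history by walking
# down from just before the index window to the registration start, so no
# glucose-lowering dispensing lands inside [window start, anchor) and the
# first in-window dispensing is exactly the anchor.
emit_dispensings <- function(lat, cfg) {
  set.seed(patient_seed(cfg$seed, 0L))
  win_start <- as.numeric(cfg$index_window_start)
  su_i <- 0L
  rows <- vector("list", length(lat))
  for (pi in seq_along(lat)) {
    p <- lat[[pi]]
    pid <- character(0); code <- character(0)
    lo <- numeric(0); hi <- numeric(0); dir <- integer(0); gld <- logical(0)
    reg_s <- as.numeric(p$reg_start); reg_e <- as.numeric(p$reg_end)
    anc <- as.numeric(p$anchor)
    if (p$type == "spot") {
      pid <- p$patient_id; code <- "A10BA02"
      lo <- anc; hi <- anc; dir <- 1L; gld <- TRUE
    } else if (!is.null(p$episodes) && nrow(p$episodes)) {
      ep <- p$episodes
      prods <- character(nrow(ep))
      for (j in seq_len(nrow(ep))) {
        if (ep$atc5[j] == "A10BB") {
          su_i <- su_i + 1L
          prods[j] <- SU_PRODUCTS[(su_i %% length(SU_PRODUCTS)) + 1L]
        } else prods[j] <- PRODUCT_MAP[[ep$atc5[j]]]
      }
      s <- pmax(as.numeric(ep$start), reg_s)
      e <- pmin(as.numeric(ep$end), reg_e)
      # episodes spanning the index window are emitted backward (from just
      # before the window down to the episode start) plus forward from the
      # anchor; episodes fully before the window, or starting at/after the
      # anchor (treatment changes), are plain forward runs
      pre <- s < anc & e >= anc
      nb <- sum(pre)
      pid <- c(rep(p$patient_id, nb), rep(p$patient_id, nrow(ep)))
      code <- c(prods[pre], prods)
      lo <- c(s[pre], ifelse(pre, anc, s))
      hi <- c(rep(win_start - 1, nb), e)
      dir <- c(rep(-1L, nb), rep(1L, nrow(ep)))
      gld <- rep(TRUE, nb + nrow(ep))
    }
    if (length(p$fillers)) {
      k <- length(p$fillers)
      pid <- c(pid, rep(p$patient_id, k)); code <- c(code, p$fillers)
      lo <- c(lo, rep(reg_s, k)); hi <- c(hi, rep(reg_e, k))
      dir <- c(dir, rep(1L, k)); gld <- c(gld, rep(FALSE, k))
    }
    rows[[pi]] <- list(pid = pid, code = code, lo = lo, hi = hi,
                       dir = dir, gld = gld)
  }
  pid <- unlist(lapply(rows, `[[`, "pid"), use.names = FALSE)
  code <- unlist(lapply(rows, `[[`, "code"), use.names = FALSE)
  lo <- unlist(lapply(rows, `[[`, "lo"), use.names = FALSE)
  hi <- unlist(lapply(rows, `[[`, "hi"), use.names = FALSE)
  dir <- unlist(lapply(rows, `[[`, "dir"), use.names = FALSE)
  is_gld <- unlist(lapply(rows, `[[`, "gld"), use.names = FALSE)

  m <- ifelse(is_gld, cfg$refill_interval_days[["mean"]],
              cfg$filler_interval_days[["mean"]])
  sdev <- ifelse(is_gld, cfg$refill_interval_days[["sd"]],
                 cfg$filler_interval_days[["sd"]])
  cur <- ifelse(dir > 0, lo, hi + 1)
  bk <- dir < 0
  if (any(bk)) cur[bk] <- cur[bk] - ceiling(stats::runif(sum(bk), 1, m[bk]))
  acc_i <- list(); acc_d <- list(); r <- 0L
  alive <- cur >= lo & cur <= hi
  idx <- seq_along(cur)
  while (any(alive)) {
    r <- r + 1L
    acc_i[[r]] <- idx[alive]
    acc_d[[r]] <- cur[alive]
    step <- pmax(cfg$refill_floor_days,
                 round(stats::rnorm(sum(alive), m[alive], sdev[alive])))
    cur[alive] <- cur[alive] + dir[alive] * step
    keep <- cur[alive] >= lo[alive] & cur[alive] <= hi[alive]
    stay <- idx[alive][keep]
    alive <- rep(FALSE, length(cur)); alive[stay] <- TRUE
  }
  ei <- unlist(acc_i); dd <- unlist(acc_d)
  out <- data.frame(patient_id = pid[ei], atc_code = code[ei],
                    dispense_date = as.Date(dd, origin = "1970-01-01"),
                    n_days_supplied = ifelse(is_gld[ei], 60L, 90L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$dispense_date, out$atc_code), ]
  rownames(out) <- NULL
  out
}

#' Latent annual state sequence of the generator
#'
#' Recomputes, from the configuration alone, the true generative state of
#' every patient-year (the oracle for classifier-recovery tests). The
#' configuration and seed must be the ones used for the matching
#' [simulate_population()] call.
#'
#' @param config a [sim_config()].
#' @param seed must equal `config$seed`; a mismatched seed is an error
#'   because the returned truth would not describe the generated tables.
#' @return data.frame with `patient_id`, `interval` (1-5), `state`.
#' @export
latent_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(as.integer(seed), as.integer(config$seed)))
    stop("seed does not match the configuration used to generate the data")
  P_of <- make_P_cache(config)
  out <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    p <- sim_patient_latent(i, config, P_of)
    if (length(p$states) == 5)
      out[[i]] <- data.frame(patient_id = p$patient_id, interval = 1:5,
                             state = p$states, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' @export
print.hypotraj_sim <- function(x, ...) {
  cat(sprintf("Synthetic dispensing data: %d patients, %d dispensings (seed %d)\n",
              nrow(x$patients), nrow(x$dispensings), x$config$seed))
  cat("edge cases: ", paste(sprintf("%s=%d",
      names(table(x$truth$patients$type)),
      as.integer(table(x$truth$patients$type))), collapse = ", "), "\n")
  invisible(x)
}

#' Write simulated tables as delimited text
#'
#' @param sim a `hypotraj_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (patients, dispensings, latent
#'   states, config as YAML).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "dispensings.csv",
                            "latent_states.csv", "sim_config.yaml"))
  utils::write.csv(sim$patients, paths[1], row.names = FALSE)
  utils::write.csv(sim$dispensings, paths[2], row.names = FALSE)
  utils::write.csv(sim$truth$states, paths[3], row.names = FALSE)
  cfg <- sim$config
  cfg$start_date <- format(cfg$start_date); cfg$end_date <- format(cfg$end_date)
  cfg$index_window_start <- format(cfg$index_window_start)
  cfg$index_window_end <- format(cfg$index_window_end)
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v), paths[4])
  invisible(paths)
}
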