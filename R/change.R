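#' Classify the change between two consecutive medication snapshots
#'
#' Each patient-interval is classified by the net change in the
#' hypoglycemia-associated classes (sulfonylureas, insulins) between the two
#' anniversary snapshots:
#'
#' * **NC** (no change): no net addition or discontinuation of a
#'   hypoglycemia-associated class, including intervals in which only
#'   "other" (non-SU, non-insulin) glucose-lowering drugs changed;
#' * **IN** (intensification): addition of, or switch to, a
#'   hypoglycemia-associated class;
#' * **DI** (de-intensification): discontinuation of, or switch away from,
#'   a hypoglycemia-associated class.
#'
#' Mixed changes follow an insulin-dominance rule: a sulfonylurea dropped
#' while insulin is added is an intensifying switch ("Switching from SU to
#' insulin"); insulin dropped while a sulfonylurea is added is a
#' de-intensifying switch ("Switching from insulin to SU"); simultaneous
#' addition (or discontinuation) of both classes is counted once at the
#' insulin level. Subtype labels carry a "Mono"/"Comb" prefix from the
#' therapy type at the start of the interval.
#'
#' @param prev,next_ snapshots for the same patient (see
#'   [regimen_snapshot()]); `next_`'s assessment date is the later one.
#' @return list with elements `state` (`"NC"`, `"IN"` or `"DI"`) and
#'   `subtype` (a change-subtype label, or `"none"` for NC).
#' @export
#' @examples
#' d <- data.frame(patient_id = "p1",
#'                 atc_code = c("A10BA02", "A10BA02", "A10BB01"),
#'                 dispense_date = as.Date(c("2016-09-01", "2017-08-30",
#'                                           "2017-09-05")))
#' s0 <- regimen_snapshot(d, "p1", as.Date("2016-09-01"))
#' s1 <- regimen_snapshot(d, "p1", as.Date("2017-09-01"))
#' classify_change(s0, s1)  # Mono—Addition of SU
classify_change <- function(prev, next_) {
  r <- classify_change_table(prev, next_)
  list(state = r$state[1], subtype = r$subtype[1])
}

# Vectorized decision procedure over aligned snapshot tables.
classify_change_table <- function(prev, next_) {
  ins_add <- !prev$has_insulin & next_$has_insulin
  ins_drop <- prev$has_insulin & !next_$has_insulin
  su_add <- !prev$has_su & next_$has_su
  su_drop <- prev$has_su & !next_$has_su

  # non-hypo ("other") subgroup movements drive the switch subtypes
  other_new <- set_has_new(next_$other_groups, prev$other_groups)
  other_gone <- set_has_new(prev$other_groups, next_$other_groups)

  prefix <- ifelse(prev$therapy_type == "combination", "Comb", "Mono")
  em <- "—"

  state <- rep("NC", length(ins_add))
  state[su_add] <- "IN"
  state[su_drop] <- "DI"
  state[ins_add] <- "IN"   # insulin dominance overrides an SU drop
  state[ins_drop] <- "DI"  # and an SU add

  subtype <- rep("none", length(ins_add))

  i <- state == "IN" & ins_add
  subtype[i & su_drop] <- "Switching from SU to insulin"
  subtype[i & !su_drop & other_gone] <- "Switching from non-SU to insulin"
  subtype[i & !su_drop & !other_gone] <- "Addition of insulin"
  i <- state == "IN" & !ins_add  # SU added, insulin unchanged
  subtype[i & other_gone] <- "Switching from non-SU to SU"
  subtype[i & !other_gone] <- "Addition of SU"

  i <- state == "DI" & ins_drop
  subtype[i & su_add] <- "Switching from insulin to SU"
  subtype[i & !su_add & other_new] <- "Switching from insulin to non-SU"
  subtype[i & !su_add & !other_new] <- "Discontinuation of insulin"
  i <- state == "DI" & !ins_drop  # SU dropped, insulin unchanged
  subtype[i & other_new] <- "Switching from SU to non-SU"
  subtype[i & !other_new] <- "Discontinuation of SU"

  chg <- state != "NC"
  subtype[chg] <- paste0(prefix[chg], em, subtype[chg])
  list(state = state, subtype = subtype)
}

#' Annual treatment-change states for one cohort member
#'
#' Builds the six anniversary snapshots (index plus Years 1-5) and
#' classifies the five consecutive intervals. States reflect the net annual
#' change: only differences between the endpoint snapshots of an interval
#' are seen, so within-year churn that reverts by the next anniversary is
#' invisible by design.
#'
#' @param member one row of a cohort table (needs `patient_id` and
#'   `index_date`).
#' @param dispensings dispensing records.
#' @param window_days eligibility window half-width (default 45).
#' @param combo_table combination-product lookup.
#' @return data.frame with five rows: `patient_id`, `interval` (1-5),
#'   `state`, `subtype`, `begin_label`, `end_label`.
#' @export
annual_states <- function(member, dispensings, window_days = 45,
                          combo_table = atc_combo_table()) {
  annual_states_all(member[1, , drop = FALSE], dispensings,
                    window_days = window_days, combo_table = combo_table)
}

#' Annual states for a whole cohort
#'
#' Batch version of [annual_states()]; one pass over the dispensing table
#' per anniversary wave.
#'
#' @param cohort cohort table (`patient_id`, `index_date`, ...).
#' @param dispensings dispensing records.
#' @param window_days,combo_table see [annual_states()].
#' @return events data.frame with `5 * nrow(cohort)` rows.
#' @export
annual_states_all <- function(cohort, dispensings, window_days = 45,
                              combo_table = atc_combo_table()) {
  snaps <- anniversary_snapshots(cohort, dispensings, window_days, combo_table)
  n <- nrow(cohort)
  events <- vector("list", 5)
  for (k in 1:5) {
    prev <- snaps[[k]]; nxt <- snaps[[k + 1]]
    cc <- classify_change_table(prev, nxt)
    events[[k]] <- data.frame(
      patient_id = cohort$patient_id, interval = k,
      state = cc$state, subtype = cc$subtype,
      begin_label = prev$label, end_label = nxt$label,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, events)
  out <- out[order(match(out$patient_id, cohort$patient_id), out$interval), ]
  rownames(out) <- NULL
  out
}

# list of 6 snapshot tables (index, year 1..5), rows aligned with `cohort`
anniversary_snapshots <- function(cohort, dispensings, window_days = 45,
                                  combo_table = atc_combo_table()) {
  idx <- as_date(cohort$index_date)
  lapply(0:5, function(k) {
    dates <- ann_shift(idx, k)
    snapshot_table(dispensings,
                   data.frame(patient_id = cohort$patient_id,
                              assessment_date = dates),
                   window_days = window_days, combo_table = combo_table)
  })
}

#' Annual transition matrices of treatment-change states
#'
#' Tabulates, for each of the five follow-up intervals, the counts of
#' patients by (previous state, current state); the first interval is the
#' 1x3 marginal of first-year states. Subtotal percentages are rounded to
#' one decimal, half away from zero, matching printed cohort tables.
#'
#' @param events events table from [annual_states_all()] (five rows per
#'   patient).
#' @return object of class `transition_tables`: a list with one element per
#'   interval, each holding `counts`, `subtotals` and `subtotal_pct`.
#' @export
transition_tables <- function(events) {
  states <- c("NC", "IN", "DI")
  s <- events_to_panel(events)
  n <- nrow(s)
  out <- vector("list", 5)
  first <- table(factor(s[, 1], levels = states))
  out[[1]] <- list(interval = 1,
                   counts = matrix(as.integer(first), nrow = 1,
                                   dimnames = list("ALL", states)),
                   subtotals = as.integer(first),
                   subtotal_pct = pct1(as.integer(first), n))
  for (k in 2:5) {
    m <- table(factor(s[, k - 1], levels = states),
               factor(s[, k], levels = states))
    sub <- as.integer(colSums(m))
    out[[k]] <- list(interval = k,
                     counts = matrix(as.integer(m), 3, 3,
                                     dimnames = list(states, states)),
                     subtotals = sub, subtotal_pct = pct1(sub, n))
  }
  structure(list(periods = out, n = n, states = states),
            class = "transition_tables")
}

#' @export
print.transition_tables <- function(x, ...) {
  cat(sprintf("Annual transition matrices (n = %d)\n", x$n))
  for (p in x$periods) {
    cat(sprintf("-- period %d --\n", p$interval))
    print(p$counts)
    cat("subtotals: ",
        paste(sprintf("%s %d (%.1f%%)", x$states, p$subtotals, p$subtotal_pct),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Pooled change subtypes ranked by frequency
#'
#' Pools all person-intervals across the five follow-up years and ranks the
#' intensification and de-intensification subtypes by frequency;
#' percentages are computed within each category.
#'
#' @param events events table (or any data.frame with `state` and `subtype`
#'   columns).
#' @return data.frame with `category`, `subtype`, `count`, `pct`, ordered
#'   by category then descending count.
#' @export
pooled_subtypes <- function(events) {
  ev <- events[events$state %in% c("IN", "DI"), c("state", "subtype")]
  out <- do.call(rbind, lapply(c("IN", "DI"), function(cat) {
    sub <- ev$subtype[ev$state == cat]
    if (!length(sub)) return(NULL)
    t <- sort(table(sub), decreasing = TRUE)
    data.frame(category = cat, subtype = names(t),
               count = as.integer(t),
               pct = pct1(as.integer(t), length(sub)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Crude state rates stratified by age band and sex
#'
#' @param events events table (five rows per patient).
#' @param members cohort table with `patient_id`, `age_band`, `sex`.
#' @return data.frame with one row per (interval, age_band, sex) stratum:
#'   counts and percentages of NC/IN/DI (percentages sum to 100 up to
#'   rounding within each stratum-interval).
#' @export
stratified_rates <- function(events, members) {
  i <- match(events$patient_id, members$patient_id)
  ev <- cbind(events, age_band = members$age_band[i], sex = members$sex[i])
  agg <- stats::aggregate(list(n = ev$interval),
                          by = list(interval = ev$interval,
                                    age_band = ev$age_band, sex = ev$sex,
                                    state = ev$state),
                          FUN = length)
  wide <- stats::reshape(agg, idvar = c("interval", "age_band", "sex"),
                         timevar = "state", direction = "wide")
  for (s in c("NC", "IN", "DI")) {
    col <- paste0("n.", s)
    if (!col %in% names(wide)) wide[[col]] <- 0L
    wide[[col]][is.na(wide[[col]])] <- 0L
  }
  tot <- wide$n.NC + wide$n.IN + wide$n.DI
  out <- data.frame(wide[, c("interval", "age_band", "sex")],
                    n_NC = wide$n.NC, n_IN = wide$n.IN, n_DI = wide$n.DI,
                    total = tot,
                    pct_NC = pct1(wide$n.NC, tot),
                    pct_IN = pct1(wide$n.IN, tot),
                    pct_DI = pct1(wide$n.DI, tot))
  out <- out[order(out$interval, out$age_band, out$sex), ]
  rownames(out) <- NULL
  out
}

#' Net five-year outcome for one member
#'
#' Compares the index snapshot directly with the Year-5 snapshot, ignoring
#' interim churn: an intensification in Year 1 that is reversed by Year 3
#' nets out to no change.
#'
#' @inheritParams annual_states
#' @return `"NC"`, `"IN"` or `"DI"`.
#' @export
net_five_year_outcome <- function(member, dispensings, window_days = 45,
                                  combo_table = atc_combo_table()) {
  net_outcomes_all(member[1, , drop = FALSE], dispensings,
                   window_days = window_days, combo_table = combo_table)$net_state[1]
}

#' Net five-year outcomes for a whole cohort
#'
#' @inheritParams annual_states_all
#' @return data.frame with `patient_id`, `net_state`, `net_subtype`.
#' @export
net_outcomes_all <- function(cohort, dispensings, window_days = 45,
                             combo_table = atc_combo_table()) {
  idx <- as_date(cohort$index_date)
  y5 <- ann_shift(idx, 5)
  s0 <- snapshot_table(dispensings,
                       data.frame(patient_id = cohort$patient_id,
                                  assessment_date = idx),
                       window_days, combo_table)
  s5 <- snapshot_table(dispensings,
                       data.frame(patient_id = cohort$patient_id,
                                  assessment_date = y5),
                       window_days, combo_table)
  cc <- classify_change_table(s0, s5)
  data.frame(patient_id = cohort$patient_id, net_state = cc$state,
             net_subtype = cc$subtype, stringsAsFactors = FALSE)
}

#' Shares of net five-year outcomes
#'
#' @param net data.frame from [net_outcomes_all()] (or a vector of states).
#' @return data.frame with `state`, `count`, `pct` over NC/IN/DI.
#' @export
outcome_shares <- function(net) {
  s <- if (is.data.frame(net)) net$net_state else net
  t <- table(factor(s, levels = c("NC", "IN", "DI")))
  data.frame(state = names(t), count = as.integer(t),
             pct = pct1(as.integer(t), length(s)))
}
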