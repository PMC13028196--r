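#' Medication snapshot around an assessment date
#'
#' A drug subgroup is considered active when at least one dispensing with
#' that ATC-5 prefix falls in the closed interval
#' `[assessment_date - window_days, assessment_date + window_days]`
#' (the anniversary-method eligibility window; both boundaries inclusive).
#' Only glucose-lowering drugs (ATC `A10`) enter the snapshot; fixed
#' combination products (`A10BD`) are decomposed into their constituent
#' chemical subgroups first, so sulfonylurea exposure inside a combination
#' tablet is not missed.
#'
#' @param dispensings data.frame with columns `patient_id`, `atc_code`,
#'   `dispense_date`.
#' @param patient_id single patient identifier.
#' @param assessment_date single `Date`.
#' @param window_days half-width of the eligibility window in days
#'   (default 45).
#' @param combo_table combination-product lookup, see [atc_combo_table()].
#' @return one-row data.frame of class `regimen_snapshot` with the active
#'   subgroup set, class flags (`has_insulin`, `has_su`, `has_other`),
#'   subgroup counts, `therapy_type`, the regimen taxonomy `label` and the
#'   `hypo_associated` flag.
#' @export
#' @examples
#' d <- data.frame(patient_id = "p1", atc_code = c("A10BA02", "A10BB01"),
#'                 dispense_date = as.Date(c("2016-08-20", "2016-09-10")))
#' regimen_snapshot(d, "p1", as.Date("2016-09-01"))
regimen_snapshot <- function(dispensings, patient_id, assessment_date,
                             window_days = 45, combo_table = atc_combo_table()) {
  stopifnot(window_days > 0)
  if (!patient_id %in% dispensings$patient_id)
    warning(sprintf("patient '%s' has no dispensing records; empty snapshot",
                    patient_id))
  snap <- snapshot_table(dispensings,
                         data.frame(patient_id = patient_id,
                                    assessment_date = as_date(assessment_date)),
                         window_days = window_days, combo_table = combo_table)
  class(snap) <- c("regimen_snapshot", class(snap))
  snap
}

# Batch snapshot builder. `assessments` is a data.frame(patient_id,
# assessment_date); a patient may appear several times (one row per
# anniversary). Returns one row per assessment row, in the same order.
snapshot_table <- function(dispensings, assessments, window_days = 45,
                           combo_table = atc_combo_table()) {
  stopifnot(window_days > 0)
  assessments$assessment_date <- as_date(assessments$assessment_date)
  n <- nrow(assessments)
  out <- data.frame(
    patient_id = assessments$patient_id,
    assessment_date = assessments$assessment_date,
    active_atc5 = character(n), other_groups = character(n),
    n_gld_groups = integer(n), n_insulin_groups = integer(n),
    n_su_groups = integer(n),
    has_insulin = logical(n), has_su = logical(n), has_other = logical(n),
    stringsAsFactors = FALSE
  )

  a10 <- dispensings[startsWith(dispensings$atc_code, "A10"),
                     c("patient_id", "atc_code", "dispense_date")]
  a10$dispense_date <- as_date(a10$dispense_date)
  a10 <- expand_records(a10, combo_table)

  # assessments may list a patient more than once; process in waves with
  # at most one row per patient so the dispensing table is scanned once
  # per wave rather than exploded by a many-to-many join
  occ <- stats::ave(seq_len(n), assessments$patient_id, FUN = seq_along)
  for (w in unique(occ)) {
    rows <- which(occ == w)
    sub <- assessments[rows, ]
    t_at <- sub$assessment_date[match(a10$patient_id, sub$patient_id)]
    keep <- !is.na(t_at) & abs(as.numeric(a10$dispense_date - t_at)) <= window_days
    pid <- a10$patient_id[keep]
    atc5 <- a10$atc5[keep]
    u <- !duplicated(paste(pid, atc5))
    pid <- pid[u]; atc5 <- atc5[u]
    cls <- atc_class(atc5)
    f <- factor(pid, levels = sub$patient_id)
    nb <- nlevels(f)
    out$n_gld_groups[rows] <- tabulate(f, nbins = nb)
    out$n_insulin_groups[rows] <- tabulate(f[cls == "INSULIN"], nbins = nb)
    out$n_su_groups[rows] <- tabulate(f[cls == "SU"], nbins = nb)
    out$has_other[rows] <- tabulate(f[cls == "OTHER_GLD"], nbins = nb) > 0
    coll <- function(sel) {
      g <- split(atc5[sel], f[sel])
      vapply(g, function(x) paste(sort(x), collapse = ";"), character(1))
    }
    out$active_atc5[rows] <- coll(rep(TRUE, length(atc5)))
    out$other_groups[rows] <- coll(cls == "OTHER_GLD")
  }
  out$has_insulin <- out$n_insulin_groups > 0
  out$has_su <- out$n_su_groups > 0
  out$therapy_type <- ifelse(out$n_gld_groups == 0, "none",
                      ifelse(out$n_gld_groups == 1, "monotherapy", "combination"))
  lab <- classify_regimen_table(out)
  out$label <- lab$label
  out$hypo_associated <- lab$hypo_associated
  out
}

#' Classify a medication snapshot into the regimen taxonomy
#'
#' Maps a snapshot to one of the baseline regimen categories
#' (e.g. "Metformin monotherapy", "SU + non-insulin combination",
#' "Insulin + SU combination"). Insulin-containing labels take precedence,
#' then sulfonylurea labels, then the non-hypoglycemia-associated labels.
#' A snapshot with no active glucose-lowering drug is labelled `"none"`.
#'
#' @param s a `regimen_snapshot` (or any one-row snapshot data.frame).
#' @return list with elements `label` and `hypo_associated` (`TRUE` iff the
#'   regimen contains insulin or a sulfonylurea).
#' @export
classify_regimen <- function(s) {
  r <- classify_regimen_table(s)
  list(label = r$label[1], hypo_associated = r$hypo_associated[1])
}

# vectorized taxonomy; `snap` is a snapshot table
classify_regimen_table <- function(snap) {
  n <- nrow(snap)
  label <- character(n)
  mono_map <- c(A10BA = "Metformin monotherapy",
                A10BH = "DPP4 inhibitors monotherapy",
                A10BJ = "GLP-1 analogs monotherapy",
                A10BF = "Alpha glucosidase inhibitors monotherapy",
                A10BG = "Thiazolidinediones monotherapy",
                A10BK = "SGLT2 inhibitors monotherapy")
  for (i in seq_len(n)) {
    if (snap$n_gld_groups[i] == 0) { label[i] <- "none"; next }
    if (snap$has_insulin[i]) {
      label[i] <-
        if (snap$has_su[i]) "Insulin + SU combination"
        else if (snap$has_other[i]) "Insulin + other combination"
        else if (snap$n_insulin_groups[i] >= 2) "Insulin combination"
        else "Insulin monotherapy"
    } else if (snap$has_su[i]) {
      label[i] <-
        if (snap$has_other[i]) "SU + non-insulin combination"
        else if (snap$n_su_groups[i] >= 2) "SU combination"
        else "SU monotherapy"
    } else if (snap$n_gld_groups[i] >= 2) {
      label[i] <- "Non-insulin, non-SU combination"
    } else {
      g <- split_set(snap$other_groups[i])[1]
      label[i] <- if (!is.na(g) && g %in% names(mono_map)) mono_map[[g]]
                  else "Other non-insulin monotherapy"
    }
  }
  list(label = label,
       hypo_associated = snap$has_insulin | snap$has_su)
}

#' @export
print.regimen_snapshot <- function(x, ...) {
  cat(sprintf("Regimen snapshot for %s at %s (+/- window)\n",
              x$patient_id[1], format(x$assessment_date[1])))
  cat(sprintf("  active subgroups : %s\n",
              if (nzchar(x$active_atc5[1])) x$active_atc5[1] else "(none)"))
  cat(sprintf("  therapy type     : %s\n", x$therapy_type[1]))
  cat(sprintf("  label            : %s%s\n", x$label[1],
              if (x$hypo_associated[1]) "  [hypoglycemia-associated]" else ""))
  invisible(x)
}
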