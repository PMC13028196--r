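#' Reference tabulations from a published five-year Dutch cohort
#'
#' The package ships, as plain-text tables, the aggregate results of a
#' published five-year drug-utilization study of 25,057 type 2 diabetes
#' patients in Dutch community pharmacies: the annual transition counts of
#' the three change states, the pooled change-subtype counts, and the
#' headline summary counts (net five-year outcomes, risk categories,
#' baseline regimen counts). They serve as fixtures for reproducing the
#' published percentages through this package's tabulation code.
#'
#' @param name one of `"transition_counts"`, `"subtype_counts"`,
#'   `"summary_counts"`.
#' @return the corresponding data.frame.
#' @export
reference_counts <- function(name = c("transition_counts", "subtype_counts",
                                      "summary_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("ref_", name, ".csv"),
                      package = "hypotraj", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Reconstruct a patient-level state panel from aggregate transition counts
#'
#' Given per-period transition counts (first period: marginal counts over
#' the three states; later periods: 3x3 counts of previous-state by
#' current-state), builds one of the patient-level state panels consistent
#' with every period's counts. Such a panel exists whenever the column
#' sums of each period equal the row sums of the next (conservation), and
#' the reconstruction assigns next-states deterministically within each
#' previous-state group, so the result is reproducible and exactly
#' reproduces all printed counts and subtotal percentages when fed through
#' [transition_tables()].
#'
#' @param counts data.frame as returned by
#'   `reference_counts("transition_counts")`: columns `period`,
#'   `from_state` (`"ALL"` for the first-period marginal), `NC`, `IN`,
#'   `DI`.
#' @return character matrix (patients x 5) of states.
#' @export
panel_from_transition_counts <- function(counts = reference_counts("transition_counts")) {
  states <- c("NC", "IN", "DI")
  first <- counts[counts$period == 1 & counts$from_state == "ALL", states]
  n <- sum(as.integer(first))
  panel <- matrix(NA_character_, n, 5)
  panel[, 1] <- rep(states, times = as.integer(first))
  for (k in 2:5) {
    m <- counts[counts$period == k, ]
    m <- m[match(states, m$from_state), states]
    for (s in seq_along(states)) {
      rows <- which(panel[, k - 1] == states[s])
      cnt <- as.integer(m[s, ])
      if (length(rows) != sum(cnt))
        stop(sprintf("period %d counts are inconsistent with period %d (%d vs %d)",
                     k, k - 1, sum(cnt), length(rows)))
      panel[rows, k] <- rep(states, times = cnt)
    }
  }
  rownames(panel) <- sprintf("R%05d", seq_len(n))
  panel
}

#' Events table from a state panel
#'
#' @param panel character matrix (patients x 5) of states; row names are
#'   patient ids (generated when absent).
#' @return events data.frame usable by [transition_tables()].
#' @export
panel_to_events <- function(panel) {
  panel <- as.matrix(panel)
  ids <- rownames(panel)
  if (is.null(ids)) ids <- sprintf("R%05d", seq_len(nrow(panel)))
  data.frame(patient_id = rep(ids, each = ncol(panel)),
             interval = rep(seq_len(ncol(panel)), nrow(panel)),
             state = as.character(t(panel)),
             subtype = "none", stringsAsFactors = FALSE)
}
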