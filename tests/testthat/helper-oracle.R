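# Independent rule oracle for the change classifier, written directly from
# the A/B/C outcome definitions as a literal case analysis over drug-class
# presence, deliberately not sharing code with the package implementation.
# Inputs are character vectors of ATC product codes.

oracle_change <- function(prev, nxt) {
  ins_p <- any(grepl("^A10A", prev)); ins_n <- any(grepl("^A10A", nxt))
  su_p <- any(grepl("^A10BB", prev)); su_n <- any(grepl("^A10BB", nxt))
  oth <- function(s) unique(substr(s[grepl("^A10", s) & !grepl("^A10A", s) &
                                       !grepl("^A10BB", s)], 1, 5))
  oth_p <- oth(prev); oth_n <- oth(nxt)
  n_groups_prev <- length(unique(substr(prev[grepl("^A10", prev)], 1, 5)))
  pre <- if (n_groups_prev >= 2) "Comb" else "Mono"
  lab <- function(s) paste0(pre, "—", s)

  # B: intensification — addition of, or switch to, SU/insulin
  if (ins_n && !ins_p) {
    sub <- if (su_p && !su_n) lab("Switching from SU to insulin")
    else if (length(setdiff(oth_p, oth_n))) lab("Switching from non-SU to insulin")
    else lab("Addition of insulin")
    return(list(state = "IN", subtype = sub))
  }
  # C: de-intensification — discontinuation of, or switch away from, insulin
  if (ins_p && !ins_n) {
    sub <- if (su_n && !su_p) lab("Switching from insulin to SU")
    else if (length(setdiff(oth_n, oth_p))) lab("Switching from insulin to non-SU")
    else lab("Discontinuation of insulin")
    return(list(state = "DI", subtype = sub))
  }
  if (su_n && !su_p) {
    sub <- if (length(setdiff(oth_p, oth_n))) lab("Switching from non-SU to SU")
    else lab("Addition of SU")
    return(list(state = "IN", subtype = sub))
  }
  if (su_p && !su_n) {
    sub <- if (length(setdiff(oth_n, oth_p))) lab("Switching from SU to non-SU")
    else lab("Discontinuation of SU")
    return(list(state = "DI", subtype = sub))
  }
  # A: no change (includes other-class-only modifications)
  list(state = "NC", subtype = "none")
}
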