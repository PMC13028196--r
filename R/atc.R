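#' @title ATC drug-class rules for glucose-lowering therapy
#' @description
#' Glucose-lowering drugs (ATC group A10) are partitioned into three classes
#' by hypoglycemia risk under Dutch primary-care guidelines:
#' insulins (`A10A*`), sulfonylureas (`A10BB*`) and all remaining
#' glucose-lowering drugs (`OTHER_GLD`). Everything outside A10 is `NON_GLD`.
#' Sulfonylureas and insulins together form the hypoglycemia-associated
#' classes. Classification is a pure function of the ATC string.
#' @name atc-classes
NULL

#' Classify ATC codes into hypoglycemia-relevant drug classes
#'
#' @param codes character vector of ATC codes (any depth >= 5 characters;
#'   fixed oral combination products `A10BD*` should be expanded with
#'   [atc_expand_combos()] first, otherwise they fall into `OTHER_GLD`).
#' @return character vector with values `"INSULIN"`, `"SU"`, `"OTHER_GLD"`,
#'   `"NON_GLD"`.
#' @export
#' @examples
#' atc_class(c("A10BA02", "A10BB01", "A10AB05", "N06AB06"))
atc_class <- function(codes) {
  out <- rep("NON_GLD", length(codes))
  a10 <- startsWith(codes, "A10")
  out[a10] <- "OTHER_GLD"
  out[startsWith(codes, "A10A")] <- "INSULIN"
  out[startsWith(codes, "A10BB")] <- "SU"
  out
}

#' Constituent classes of fixed-combination antidiabetic products
#'
#' Fixed oral combinations (ATC `A10BD`) contain two or three constituent
#' drug classes; treating them as a single "other" drug would miss
#' sulfonylurea exposure. The shipped lookup maps each `A10BD` code to its
#' constituent ATC chemical subgroups and can be replaced by the user.
#'
#' @return data.frame with columns `code` (7-character ATC) and
#'   `constituents` (";"-separated ATC-5 subgroups).
#' @export
atc_combo_table <- function() {
  path <- system.file("extdata", "atc_combo_constituents.csv",
                      package = "hypotraj", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expand combination products into constituent ATC-5 subgroups
#'
#' Non-combination codes are truncated to their 5-character chemical
#' subgroup; `A10BD` codes found in `combo_table` are replaced by their
#' constituent subgroups (one or more per input code). Unknown `A10BD`
#' codes are kept as subgroup `A10BD`.
#'
#' @param codes character vector of ATC codes.
#' @param combo_table lookup as returned by [atc_combo_table()].
#' @return list parallel to `codes`; each element a character vector of
#'   ATC-5 subgroups.
#' @export
atc_expand_combos <- function(codes, combo_table = atc_combo_table()) {
  atc5 <- substr(codes, 1, 5)
  idx <- match(codes, combo_table$code)
  lapply(seq_along(codes), function(i) {
    if (!is.na(idx[i])) split_set(combo_table$constituents[idx[i]]) else atc5[i]
  })
}

# Vectorized helper used by the snapshot builder: returns a data.frame
# (row per original record possibly duplicated) with the subgroup column.
expand_records <- function(df, combo_table = atc_combo_table()) {
  atc5 <- substr(df$atc_code, 1, 5)
  is_combo <- atc5 == "A10BD" & df$atc_code %in% combo_table$code
  if (!any(is_combo)) {
    df$atc5 <- atc5
    return(df)
  }
  plain <- df[!is_combo, , drop = FALSE]
  plain$atc5 <- atc5[!is_combo]
  combo <- df[is_combo, , drop = FALSE]
  cons <- combo_table$constituents[match(combo$atc_code, combo_table$code)]
  cons_list <- strsplit(cons, ";", fixed = TRUE)
  n_each <- lengths(cons_list)
  combo <- combo[rep(seq_len(nrow(combo)), n_each), , drop = FALSE]
  combo$atc5 <- unlist(cons_list)
  out <- rbind(plain, combo)
  rownames(out) <- NULL
  out
}

# checks basic ATC syntax: letter, 2 digits, then optionally 2 letters + 2 digits
is_valid_atc <- function(codes) {
  grepl("^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$", codes)
}
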