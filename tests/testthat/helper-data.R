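# small builders used across test files

disp_tab <- function(pid, codes, dates) {
  data.frame(patient_id = pid, atc_code = codes,
             dispense_date = as.Date(dates), n_days_supplied = 60L,
             stringsAsFactors = FALSE)
}

# snapshot of a drug set, all dispensed on the assessment date
snap_of <- function(codes, date = "2016-09-01") {
  if (length(codes) == 0)
    return(suppressWarnings(
      regimen_snapshot(disp_tab("px", "A10BA02", "1990-01-01"),
                       "p0", as.Date(date))))
  regimen_snapshot(disp_tab("p0", codes, rep(date, length(codes))),
                   "p0", as.Date(date))
}

# classify the change between two drug sets a year apart
change_of <- function(prev_codes, next_codes) {
  classify_change(snap_of(prev_codes, "2016-09-01"),
                  snap_of(next_codes, "2017-09-01"))
}

# one patient table row
patient_row <- function(pid, birth_year = 1950, sex = "male",
                        reg_start = "2011-01-01", reg_end = "2022-12-31") {
  data.frame(patient_id = pid, birth_year = birth_year, sex = sex,
             registration_start = as.Date(reg_start),
             registration_end = as.Date(reg_end), stringsAsFactors = FALSE)
}

# shared expensive simulations, built once per test run
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# generator matrix with exact zero row sums from its six off-diagonals
mk_q <- function(nc_in, nc_di, in_nc, in_di, di_nc, di_in) {
  q <- rbind(c(0, nc_in, nc_di), c(in_nc, 0, in_di), c(di_nc, di_in, 0))
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(c("NC", "IN", "DI"), c("NC", "IN", "DI"))
  q
}

# the generator's default latent intensities
q_ref <- function()
  mk_q(0.123873, 0.069380, 0.787510, 0.195366, 0.743561, 0.235209)

# the default-configuration study-scale simulation shared by the cohort,
# change, riskscore and inference suites
default_sim_big <- function() cached("dbig", function() {
  cfg <- sim_config(25000, seed = 101)
  list(cfg = cfg, sim = simulate_population(cfg))
})
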