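test_that("index date is the earliest in-window A10 dispensing, boundaries inclusive", {
  cfg <- cohort_config()
  p <- patient_row("p1")
  d <- disp_tab("p1", c("A10BA02", "A10BA02", "N06AB06"),
                c("2016-09-01", "2017-01-10", "2016-08-01"))
  expect_equal(find_index_date(p, d, cfg), as.Date("2016-09-01"))
  # only pre-window A10 -> absent
  d2 <- disp_tab("p1", "A10BA02", "2016-06-30")
  expect_true(is.na(find_index_date(p, d2, cfg)))
  # exactly on the window boundary
  d3 <- disp_tab("p1", "A10BA02", "2016-07-01")
  expect_equal(find_index_date(p, d3, cfg), as.Date("2016-07-01"))
})

test_that("each exclusion rule fires and the flow tally conserves patients", {
  mk_ok <- function(pid, by = 1950) {
    list(patient_row(pid, birth_year = by),
         disp_tab(pid, c("A10BA02", "A10BA02", "A10BA02"),
                  c("2014-05-01", "2016-09-01", "2016-11-01")))
  }
  ok <- mk_ok("keep")
  too_young <- mk_ok("young", by = 1983)       # age 33 at index
  spot <- list(patient_row("spot"),
               disp_tab("spot", "A10BA02", "2016-09-01"))
  short <- list(patient_row("short", reg_start = "2013-01-01"),
                mk_ok("short")[[2]])
  ins_only <- list(patient_row("insonly"),
                   disp_tab("insonly", c("A10AB05", "A10AB05", "A10AB05"),
                            c("2014-05-01", "2016-09-01", "2016-11-01")))
  no_idx <- list(patient_row("noidx"),
                 disp_tab("noidx", "A10BA02", "2015-01-01"))
  patients <- do.call(rbind, lapply(list(ok, too_young, spot, short, ins_only,
                                         no_idx), `[[`, 1))
  disp <- do.call(rbind, lapply(list(ok, too_young, spot, short, ins_only,
                                     no_idx), `[[`, 2))
  sel <- select_cohort(patients, disp)
  expect_equal(sel$members$patient_id, "keep")
  expect_equal(sum(sel$flow), nrow(patients))  # tally + retained conserve
  expect_equal(unname(sel$flow[c("no_index_dispensing", "age_below_minimum",
                                 "spot_user", "insufficient_registration",
                                 "insulin_only_preindex")]),
               rep(1L, 5))
  expect_equal(as.character(sel$members$age_band), "65-74")  # age 66 at index
})

test_that("patients with no pre-index A10 history are retained (incident-like)", {
  p <- patient_row("p1")
  d <- disp_tab("p1", c("A10BA02", "A10BA02"), c("2016-09-01", "2016-11-01"))
  sel <- select_cohort(p, d)
  expect_equal(nrow(sel$members), 1)
})

test_that("pre-index oral use rescues an insulin user from the type-1 exclusion", {
  p <- patient_row("p1")
  d <- disp_tab("p1", c("A10BA02", "A10AB05", "A10AB05", "A10AB05"),
                c("2013-02-01", "2014-05-01", "2016-09-01", "2016-11-01"))
  expect_equal(nrow(select_cohort(p, d)$members), 1)
})

test_that("selection is idempotent and retained members pass every rule independently", {
  s <- default_sim_big()
  sel <- select_cohort(s$sim$patients, s$sim$dispensings)
  m <- sel$members
  expect_equal(sum(sel$flow), nrow(s$sim$patients))
  # rerun on the already-selected population removes nobody
  kept_pat <- s$sim$patients[s$sim$patients$patient_id %in% m$patient_id, ]
  sel2 <- select_cohort(kept_pat, s$sim$dispensings)
  expect_equal(sort(sel2$members$patient_id), sort(m$patient_id))
  # independent re-check of each rule
  cfg <- cohort_config()
  expect_true(all(m$index_date >= cfg$index_window_start &
                    m$index_date <= cfg$index_window_end))
  expect_true(all(m$age_at_index >= 35))
  d <- s$sim$dispensings
  d$dispense_date <- as.Date(d$dispense_date)
  a10 <- d[startsWith(d$atc_code, "A10"), ]
  for (i in sample(nrow(m), 25)) {
    di <- a10[a10$patient_id == m$patient_id[i], ]
    n_look <- sum(di$dispense_date >= m$index_date[i] &
                    di$dispense_date <= m$index_date[i] + 365)
    expect_gte(n_look, 2)
    pre <- di[di$dispense_date < m$index_date[i] &
                di$dispense_date >= seq(m$index_date[i], by = "-5 years",
                                        length.out = 2)[2], ]
    expect_false(nrow(pre) > 0 && all(startsWith(pre$atc_code, "A10A")))
  }
})

test_that("empty inputs yield an empty cohort with a warning", {
  expect_warning(sel <- select_cohort(patient_row("p")[0, ],
                                      disp_tab("p", "A10BA02", "2016-09-01")[0, ]),
                 "empty")
  expect_equal(nrow(sel$members), 0)
  expect_equal(unname(sel$flow[["retained"]]), 0L)
})

test_that("dummy-id screening hook removes matching ids first", {
  p <- rbind(patient_row("TEST001"), patient_row("p1"))
  d <- rbind(disp_tab("TEST001", c("A10BA02", "A10BA02"),
                      c("2016-09-01", "2016-11-01")),
             disp_tab("p1", c("A10BA02", "A10BA02"),
                      c("2016-09-01", "2016-11-01")))
  sel <- select_cohort(p, d, cohort_config(dummy_id_pattern = "^TEST"))
  expect_equal(sel$members$patient_id, "p1")
  expect_equal(unname(sel$flow[["dummy_id"]]), 1L)
})
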