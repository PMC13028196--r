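test_that("change classification reproduces the canonical subtype examples", {
  em <- "—"
  cases <- list(
    list(c("A10BA02"), c("A10BA02", "A10BB01"),
         "IN", paste0("Mono", em, "Addition of SU")),
    list(c("A10BA02", "A10BB01", "A10AB05"), c("A10BA02", "A10BB01"),
         "DI", paste0("Comb", em, "Discontinuation of insulin")),
    list(c("A10BA02"), c("A10BA02", "A10BH01"), "NC", "none"),
    list(c("A10BB01"), c("A10BA02"),
         "DI", paste0("Mono", em, "Switching from SU to non-SU")),
    list(c("A10AB05"), c("A10BB01"),
         "DI", paste0("Mono", em, "Switching from insulin to SU")),
    list(c("A10BA02", "A10BB01"), c("A10BA02", "A10BB01", "A10AB05"),
         "IN", paste0("Comb", em, "Addition of insulin")),
    list(c("A10BB01"), c("A10AB05"),
         "IN", paste0("Mono", em, "Switching from SU to insulin")),
    list(c("A10BA02"), c("A10AB05"),
         "IN", paste0("Mono", em, "Switching from non-SU to insulin")),
    list(c("A10BA02", "A10BB01"), c("A10BA02"),
         "DI", paste0("Comb", em, "Discontinuation of SU")))
  for (cs in cases) {
    r <- change_of(cs[[1]], cs[[2]])
    expect_equal(r$state, cs[[3]])
    expect_equal(r$subtype, cs[[4]])
  }
})

test_that("pure add/drop pairs are antisymmetric under reversal", {
  sets <- list(c("A10BA02"), c("A10BA02", "A10BH01"), c("A10AB05"),
               c("A10BB01"), c("A10BA02", "A10BB01"))
  adds <- list(su = "A10BB01", insulin = "A10AB05")
  for (s in sets) for (a in adds) {
    if (a %in% s) next
    fwd <- change_of(s, c(s, a))
    rev <- change_of(c(s, a), s)
    expect_equal(fwd$state, "IN")
    expect_equal(rev$state, "DI")
    expect_match(fwd$subtype, "Addition")
    expect_match(rev$subtype, "Discontinuation")
    # the same drug class is named in both directions
    expect_equal(sub(".*of ", "", fwd$subtype), sub(".*of ", "", rev$subtype))
  }
})

test_that("annual states classify each interval and net out over five years", {
  # metformin throughout; SU added in year 2 only, removed again in year 3
  d <- rbind(
    disp_tab("p1", "A10BA02",
             format(seq(as.Date("2016-08-20"), as.Date("2021-10-01"), by = 60))),
    disp_tab("p1", "A10BB01", c("2018-08-25", "2018-10-05")))
  member <- data.frame(patient_id = "p1", index_date = as.Date("2016-09-01"))
  ev <- annual_states(member, d)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$state, c("NC", "IN", "DI", "NC", "NC"))
  expect_equal(net_five_year_outcome(member, d), "NC")
})

test_that("complete drug stop counts as de-intensification only after hypo exposure", {
  # SU monotherapy stopped entirely
  d <- disp_tab("p1", "A10BB01", c("2016-08-25", "2016-10-01"))
  member <- data.frame(patient_id = "p1", index_date = as.Date("2016-09-01"))
  ev <- annual_states(member, d)
  expect_equal(ev$state[1], "DI")
  expect_equal(ev$subtype[1], "Mono—Discontinuation of SU")
  # metformin monotherapy stopped entirely: not a hypo-associated change
  d2 <- disp_tab("p2", "A10BA02", c("2016-08-25", "2016-10-01"))
  m2 <- data.frame(patient_id = "p2", index_date = as.Date("2016-09-01"))
  expect_equal(annual_states(m2, d2)$state, rep("NC", 5))
})

test_that("transition tables conserve counts across periods", {
  states <- c("NC", "IN", "DI")
  set.seed(5)
  panel <- matrix(sample(states, 200 * 5, replace = TRUE,
                         prob = c(.8, .12, .08)), 200, 5)
  rownames(panel) <- sprintf("p%03d", 1:200)
  tt <- transition_tables(panel_to_events(panel))
  expect_equal(sum(tt$periods[[1]]$counts), 200)
  for (k in 2:5) {
    # rows of period k sum to the subtotals of period k-1
    expect_equal(as.integer(rowSums(tt$periods[[k]]$counts)),
                 tt$periods[[k - 1]]$subtotals)
    # columns sum to period-k subtotals
    expect_equal(as.integer(colSums(tt$periods[[k]]$counts)),
                 tt$periods[[k]]$subtotals)
    expect_equal(sum(tt$periods[[k]]$counts), 200)
  }
})

test_that("hand-counted three-patient transition table", {
  panel <- rbind(p1 = c("NC", "NC", "NC", "NC", "NC"),
                 p2 = c("IN", "NC", "NC", "NC", "NC"),
                 p3 = c("DI", "IN", "NC", "NC", "NC"))
  tt <- transition_tables(panel_to_events(panel))
  expect_equal(as.integer(tt$periods[[1]]$counts), c(1, 1, 1))
  m2 <- tt$periods[[2]]$counts
  expect_equal(m2["NC", "NC"], 1L)
  expect_equal(m2["IN", "NC"], 1L)
  expect_equal(m2["DI", "IN"], 1L)
  expect_equal(sum(m2), 3L)
})

test_that("patients without exactly five intervals are rejected by name", {
  panel <- rbind(p1 = rep("NC", 5), p2 = rep("NC", 5))
  ev <- panel_to_events(panel)
  expect_error(transition_tables(ev[-3, ]), "p1")
})

test_that("pooled subtype percentages sum to 100 within category", {
  ev <- data.frame(patient_id = "x", interval = 1,
                   state = c(rep("IN", 7), rep("DI", 5)),
                   subtype = c(rep("Mono—Addition of SU", 4),
                               rep("Comb—Addition of insulin", 3),
                               rep("Comb—Discontinuation of SU", 5)))
  ps <- pooled_subtypes(ev)
  expect_equal(sum(ps$pct[ps$category == "IN"]), 100, tolerance = 0.11)
  expect_equal(ps$pct[ps$category == "DI"], 100)
  # single-event category sits at 100%
  ps1 <- pooled_subtypes(ev[ev$state == "DI", ][1, ])
  expect_equal(ps1$pct, 100)
})

test_that("stratified rates sum to 100 within stratum and conserve counts", {
  s <- default_sim_big()
  sel <- select_cohort(s$sim$patients, s$sim$dispensings)
  ev <- cached("dbig_events", function()
    annual_states_all(sel$members, s$sim$dispensings))
  sr <- stratified_rates(ev, sel$members)
  expect_true(all(abs(sr$pct_NC + sr$pct_IN + sr$pct_DI - 100) <= 0.2))
  tt <- transition_tables(ev)
  for (k in 1:5) {
    sub <- sr[sr$interval == k, ]
    expect_equal(sum(sub$n_NC + sub$n_IN + sub$n_DI), tt$n)
    expect_equal(sum(sub$n_IN), tt$periods[[k]]$subtotals[2])
  }
})

test_that("females de-intensify more when the generator says so", {
  cfg <- sim_config(4000, seed = 77, female_di_multiplier = 3,
                    frac_short_registration = 0, frac_spot_users = 0,
                    frac_insulin_only_preindex = 0, mean_filler_drugs = 0)
  sim <- simulate_population(cfg)
  sel <- select_cohort(sim$patients, sim$dispensings)
  ev <- annual_states_all(sel$members, sim$dispensings)
  sex <- sel$members$sex[match(ev$patient_id, sel$members$patient_id)]
  di_f <- mean(ev$state[sex == "female"] == "DI")
  di_m <- mean(ev$state[sex == "male"] == "DI")
  expect_gt(di_f, di_m)
})
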