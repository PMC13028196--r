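test_that("configuration validation names the offending field", {
  expect_error(sim_config(0), "n_patients")
  expect_error(sim_config(10, frac_spot_users = 1.2), "frac_spot_users")
  expect_error(sim_config(10, refill_interval_days = c(mean = -1, sd = 5)),
               "refill_interval_days")
  expect_error(sim_config(10, annual_change_rates = c(nc_in = -0.1, nc_di = 0,
                                                      in_nc = 0, in_di = 0,
                                                      di_nc = 0, di_in = 0)),
               "annual_change_rates")
})

test_that("identical seed and configuration give byte-identical tables", {
  cfg <- sim_config(150, seed = 7)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$dispensings, s2$dispensings)
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the tables
  s3 <- simulate_population(sim_config(150, seed = 8))
  expect_false(identical(s1$dispensings, s3$dispensings))
})

test_that("dispensing dates stay inside each patient's registration", {
  s <- simulate_population(sim_config(400, seed = 3))
  d <- merge(s$dispensings, s$patients, by = "patient_id")
  expect_true(all(d$dispense_date >= d$registration_start))
  expect_true(all(d$dispense_date <= d$registration_end))
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", d$atc_code)))
})

test_that("zero hazards and no edge cases give pure no-change trajectories", {
  cfg <- sim_config(120, seed = 11,
                    annual_change_rates = c(nc_in = 0, nc_di = 0, in_nc = 0,
                                            in_di = 0, di_nc = 0, di_in = 0),
                    refill_interval_days = c(mean = 30, sd = 7),
                    frac_spot_users = 0, frac_insulin_only_preindex = 0,
                    frac_short_registration = 0, other_churn_rate = 0)
  sim <- simulate_population(cfg)
  lt <- latent_truth(cfg)
  expect_true(all(lt$state == "NC"))
  sel <- select_cohort(sim$patients, sim$dispensings)
  ev <- annual_states_all(sel$members, sim$dispensings)
  expect_true(all(ev$state == "NC"))
  net <- net_outcomes_all(sel$members, sim$dispensings)
  expect_true(all(net$net_state == "NC"))
})

test_that("latent truth has exactly five states per pathed patient and needs the right seed", {
  cfg <- sim_config(100, seed = 5)
  sim <- simulate_population(cfg)
  lt <- latent_truth(cfg)
  expect_true(all(table(lt$patient_id) == 5))
  expect_identical(lt, sim$truth$states)
  expect_error(latent_truth(cfg, seed = 99), "seed")
})

test_that("classification recovers the latent state for nearly all patient-years", {
  # short refill intervals make window misses negligible
  cfg <- sim_config(1500, seed = 21,
                    refill_interval_days = c(mean = 30, sd = 7),
                    frac_short_registration = 0)
  sim <- simulate_population(cfg)
  sel <- select_cohort(sim$patients, sim$dispensings)
  ev <- annual_states_all(sel$members, sim$dispensings)
  lt <- latent_truth(cfg)
  i <- match(paste(ev$patient_id, ev$interval), paste(lt$patient_id, lt$interval))
  expect_gte(mean(ev$state == lt$state[i]), 0.99)
})

test_that("year-1 state frequencies match the configured generative rates at scale", {
  # every patient starts on SU + metformin, so both intensification and
  # de-intensification are always feasible and the year-1 distribution is
  # exactly the NC row of the one-year transition matrix
  cfg <- sim_config(25000, seed = 31,
                    initial_regimen_probs = c("SU + non-insulin combination" = 1),
                    female_di_multiplier = 1, insulin_user_di_multiplier = 1,
                    frac_spot_users = 0, frac_insulin_only_preindex = 0,
                    frac_short_registration = 0, mean_filler_drugs = 0,
                    frac_antidepressant = 0, other_churn_rate = 0,
                    refill_interval_days = c(mean = 30, sd = 7))
  sim <- simulate_population(cfg)
  sel <- select_cohort(sim$patients, sim$dispensings)
  ev <- annual_states_all(sel$members, sim$dispensings)
  p1 <- prop.table(table(factor(ev$state[ev$interval == 1],
                                levels = c("NC", "IN", "DI"))))
  n <- sum(ev$interval == 1)
  se_in <- sqrt(0.077 * (1 - 0.077) / n)
  se_di <- sqrt(0.047 * (1 - 0.047) / n)
  expect_lt(abs(p1[["IN"]] - 0.077), 3 * se_in)
  expect_lt(abs(p1[["DI"]] - 0.047), 3 * se_di)
})

test_that("written tables round-trip through the delimited format", {
  cfg <- sim_config(60, seed = 13)
  sim <- simulate_population(cfg)
  dir <- tempfile()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  d <- read.csv(paths[2], stringsAsFactors = FALSE)
  expect_equal(nrow(d), nrow(sim$dispensings))
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", d$dispense_date)))
})
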