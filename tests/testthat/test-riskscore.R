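profile_row <- function(age = 66, sex_female = 0, total = 3, gld = 1, su = 0,
                        ins = 0, premix = 0, antidep = 0, dur = 0) {
  data.frame(patient_id = "p1", age = age, sex_female = sex_female,
             total_drug_count = total, gld_count = gld, su_count = su,
             insulin_count = ins, premixed_insulin_use = premix,
             antidepressant_use = antidep, insulin_duration_years = dur)
}

test_that("profile extraction counts distinct subgroups in the index window", {
  member <- data.frame(patient_id = "p1", index_date = as.Date("2016-09-01"),
                       age_at_index = 70, sex = "female")
  d <- disp_tab("p1",
                c("A10BA02", "A10BA02", "A10AD05", "N06AB06", "C07AB02",
                  "A10AB05"),
                c("2016-08-20", "2016-09-10", "2016-09-01", "2016-08-01",
                  "2016-10-10", "2014-03-01"))
  pr <- build_profiles(member, d)
  expect_equal(pr$total_drug_count, 4)  # A10BA, A10AD, N06AB, C07AB
  expect_equal(pr$gld_count, 2)
  expect_equal(pr$su_count, 0)
  expect_equal(pr$insulin_count, 1)
  expect_equal(pr$premixed_insulin_use, 1L)
  expect_equal(pr$antidepressant_use, 1L)
  # first pre-index insulin 2014-03-01 -> about 2.5 years of insulin use
  expect_equal(pr$insulin_duration_years, 2.5, tolerance = 0.01)
})

test_that("insulin duration is clamped to the five pre-index years, boundary inclusive", {
  member <- data.frame(patient_id = "p1", index_date = as.Date("2016-09-01"),
                       age_at_index = 70, sex = "male")
  d <- disp_tab("p1", c("A10AB05", "A10AB05", "A10BA02"),
                c("2011-09-01", "2016-08-30", "2016-09-01"))
  pr <- build_profiles(member, d)
  expect_equal(pr$insulin_duration_years, 5, tolerance = 0.01)
  # insulin older than five years is ignored
  d2 <- disp_tab("p1", c("A10AB05", "A10BA02", "A10BA02"),
                 c("2010-09-01", "2016-08-30", "2016-09-01"))
  expect_equal(build_profiles(member, d2)$insulin_duration_years, 0)
})

test_that("score is the inverse-logit of the linear predictor", {
  co <- risk_coefficients_default()
  zero <- setNames(rep(0, length(co)), names(co))
  expect_equal(risk_score(profile_row(), zero)$score, 0.5)
  expect_equal(risk_score(profile_row(), zero)$category, "low")  # 0.5 < 0.6
  at_cut <- zero; at_cut[["(Intercept)"]] <- qlogis(0.6)
  r <- risk_score(profile_row(), at_cut)
  expect_equal(r$score, 0.6)
  expect_equal(r$category, "high")  # boundary is high by the >= rule
  # hand-computed linear predictor on a worked profile
  p <- profile_row(age = 72, sex_female = 1, total = 6, gld = 3, su = 1,
                   ins = 1, premix = 1, antidep = 1, dur = 3.2)
  eta <- co[["(Intercept)"]] + 72 * co[["age"]] + 1 * co[["sex_female"]] +
    6 * co[["total_drug_count"]] + 3 * co[["gld_count"]] +
    1 * co[["su_count"]] + 1 * co[["insulin_count"]] +
    1 * co[["premixed_insulin_use"]] + 1 * co[["antidepressant_use"]] +
    3.2 * co[["insulin_duration_years"]]
  expect_equal(risk_score(p, co)$score, plogis(eta), tolerance = 1e-12)
})

test_that("score is monotone in positively weighted predictors and in the cutoff", {
  co <- risk_coefficients_default()
  base <- risk_score(profile_row(), co)$score
  expect_gt(risk_score(profile_row(ins = 1), co)$score, base)
  expect_gt(risk_score(profile_row(su = 1), co)$score, base)
  expect_gt(risk_score(profile_row(age = 80), co)$score, base)
  # raising the cutoff never moves a patient from low to high
  p <- profile_row(ins = 1, dur = 4)
  for (cut in c(0.4, 0.6, 0.8)) {
    lo <- risk_score(p, co, cutoff = cut)$category
    hi <- risk_score(p, co, cutoff = cut + 0.1)$category
    expect_false(lo == "low" && hi == "high")
  }
})

test_that("a missing coefficient is a configuration error", {
  co <- risk_coefficients_default()
  expect_error(risk_score(profile_row(), co[-3]), "missing coefficient")
})

test_that("induced high-risk fraction matches the covariate-distribution expectation", {
  s <- default_sim_big()
  sel <- select_cohort(s$sim$patients, s$sim$dispensings)
  pr <- build_profiles(sel$members, s$sim$dispensings)
  rs <- risk_score(pr, s$cfg$risk_coefficients)
  induced <- mean(rs$category == "high")

  # expectation computed directly from the configured covariate
  # distributions, without the dispensing machinery: draw age, sex,
  # regimen category, fillers, and score the implied profile
  set.seed(991)
  n <- 50000
  cfg <- s$cfg
  age <- round(pmin(95, pmax(25, rnorm(n, cfg$age_distribution[["mean"]],
                                       cfg$age_distribution[["sd"]]))))
  keep <- age >= 35
  age <- age[keep]; n <- length(age)
  fem <- as.integer(runif(n) < cfg$frac_female)
  cat0 <- sample(names(cfg$initial_regimen_probs), n, replace = TRUE,
                 prob = cfg$initial_regimen_probs)
  has_ins <- grepl("^Insulin", cat0)
  has_su <- grepl("SU", cat0) & !grepl("non-SU", cat0) | cat0 == "Insulin + SU combination"
  n_gld <- ifelse(grepl("combination", cat0), 2, 1)
  n_fill <- rpois(n, cfg$mean_filler_drugs) +
    as.integer(runif(n) < cfg$frac_antidepressant)
  antidep <- as.integer(runif(n) < cfg$frac_antidepressant)
  premix <- has_ins & runif(n) < 0.2
  prof <- data.frame(patient_id = "x", age = age, sex_female = fem,
                     total_drug_count = n_gld + n_fill, gld_count = n_gld,
                     su_count = as.integer(has_su),
                     insulin_count = as.integer(has_ins),
                     premixed_insulin_use = as.integer(premix),
                     antidepressant_use = antidep,
                     insulin_duration_years = ifelse(has_ins, 5, 0))
  expected <- mean(risk_score(prof, cfg$risk_coefficients)$category == "high")
  expect_lt(abs(induced - expected), 0.02)
})
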