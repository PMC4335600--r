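test_that("linear predictor is the plain dot product over derived covariates", {
  cs <- toy_coeffs(betas = c(diabetes = 0.4, current_smoker = 0.5,
                             atrial_fibrillation = 0.6))
  none <- risk_profile(age = 50, sex = "male", sbp = 120)
  expect_identical(linear_predictor(none, cs), 0)

  one <- risk_profile(age = 50, sex = "male", sbp = 120, diabetes = TRUE)
  expect_identical(linear_predictor(one, cs), 0.4)

  cs5 <- toy_coeffs()
  p <- risk_profile(age = 63, sex = "male", sbp = 142, diabetes = TRUE,
                    smoking = "current")
  # term-by-term sum by hand: 0.05*63 + 0.01*142 + 0.4 + 0.5 + 0
  expect_equal(linear_predictor(p, cs5),
               0.05 * 63 + 0.01 * 142 + 0.4 + 0.5, tolerance = 1e-15)

  expect_error(linear_predictor(risk_profile(age = 50, sex = "female",
                                             sbp = 120), cs5),
               "sex mismatch")
  expect_error(coefficient_set("male", c(cholesterol = 0.1),
                               baseline_survival = c("5" = 0.9)),
               "cholesterol")
})

test_that("baseline-survival transform matches the closed form", {
  cs <- coefficient_set("male", c(diabetes = 0.1),
                        baseline_survival = c("10" = 0.9))
  # centered lp = ln 2 -> 1 - 0.9^2
  expect_equal(risk_from_lp(log(2), cs, 10), 1 - 0.9^2, tolerance = 1e-15)
  # exponent collapses at the covariate mean
  cs2 <- coefficient_set("male", c(diabetes = 0.7), c(diabetes = 1),
                         baseline_survival = c("5" = 0.93))
  expect_equal(risk_from_lp(0.7, cs2, 5), 1 - 0.93, tolerance = 1e-15)
  # S0 = 1 -> risk 0 for any lp
  cs3 <- coefficient_set("male", c(diabetes = 0.5),
                         baseline_survival = c("5" = 1))
  expect_equal(risk_from_lp(c(-5, 0, 5), cs3, 5), c(0, 0, 0))
  # S0(5) derived as sqrt(S0(10)) when unspecified
  cs4 <- coefficient_set("male", c(diabetes = 0.5),
                         baseline_survival = c("10" = 0.81))
  expect_equal(risk_from_lp(0, cs4, 5), 1 - 0.9, tolerance = 1e-12)
  expect_error(risk_from_lp(0, cs, 5.5), "horizon")
})

test_that("anthropometric fallback chain applies the printed rules", {
  d <- delta_config()
  at_thr <- risk_profile(age = 50, sex = "male", sbp = 120, whr = 0.96)
  expect_identical(anthropometric_delta(at_thr, d), 0)

  over <- risk_profile(age = 50, sex = "male", sbp = 120, whr = 0.98)
  expect_equal(anthropometric_delta(over, d), 0.20 + 0.10 * 2,
               tolerance = 1e-12)

  waist <- risk_profile(age = 50, sex = "female", sbp = 120,
                        waist_circumference_cm = 90)
  expect_equal(anthropometric_delta(waist, d), log(1.02), tolerance = 1e-15)

  bmi <- risk_profile(age = 50, sex = "male", sbp = 120, bmi = 27.5)
  expect_equal(anthropometric_delta(bmi, d), 0.10 * 2.5, tolerance = 1e-12)
  bmi_cn <- risk_profile(age = 50, sex = "male", sbp = 120, bmi = 27.5,
                         ethnic_group = "chinese")
  expect_equal(anthropometric_delta(bmi_cn, d), 0.10 * 3.5, tolerance = 1e-12)

  # optional base term on the BMI rule
  d2 <- delta_config(bmi_rule = list(include_base_rr = TRUE))
  expect_equal(anthropometric_delta(bmi, d2), log(1.02) + 0.10 * 2.5,
               tolerance = 1e-12)
  expect_equal(anthropometric_delta(at_thr, d2), 0)  # whr branch untouched

  none <- risk_profile(age = 50, sex = "male", sbp = 120)
  expect_identical(anthropometric_delta(none, d), 0)
})

test_that("whr takes precedence over bmi and waist", {
  d <- delta_config()
  base <- risk_profile(age = 50, sex = "male", sbp = 120, whr = 1.0,
                       bmi = 30, waist_circumference_cm = 120)
  perturbed <- base
  perturbed$bmi <- 45
  perturbed$waist_circumference_cm <- 170
  expect_identical(anthropometric_delta(base, d),
                   anthropometric_delta(perturbed, d))
  expect_gt(anthropometric_delta(base, d), 0)
})

test_that("each add-on flag shifts the linear predictor by its configured value", {
  cs <- toy_coeffs()
  d <- delta_config()
  base <- risk_profile(age = 60, sex = "male", sbp = 140)
  flags <- list(non_caucasian = d$lp_deltas[["non_caucasian"]],
                poor_diet = d$lp_deltas[["poor_diet"]],
                high_alcohol = d$lp_deltas[["high_alcohol"]],
                low_physical_activity = d$lp_deltas[["low_physical_activity"]],
                family_history_stroke_or_mi = d$lp_deltas[["family_history"]],
                stress = d$lp_deltas[["stress"]],
                cognitive_problems = log(1.80),
                memory_problems = log(1.40),
                previous_tbi = log(1.20))
  for (f in names(flags)) {
    toggled <- base
    toggled[[f]] <- TRUE
    expect_equal(riskometer_lp(toggled, cs, d) - riskometer_lp(base, cs, d),
                 flags[[f]], tolerance = 1e-12, info = f)
  }
  # memory term suppressed when cognitive problems present
  cog <- base; cog$cognitive_problems <- TRUE
  both_would <- cog; both_would$memory_problems <- TRUE
  expect_error(riskometer_risk(both_would, toy_config()),
               "cannot both be TRUE")
})

test_that("prior stroke/TIA adds exact percentage points below the cap", {
  cfg <- toy_config()
  base <- risk_profile(age = 60, sex = "female", sbp = 150, diabetes = TRUE)
  prior <- base; prior$previous_stroke_or_tia <- TRUE
  for (h in c(5, 10)) {
    r0 <- riskometer_risk(base, cfg, horizon = h)$absolute_risk_percent
    r1 <- riskometer_risk(prior, cfg, horizon = h)$absolute_risk_percent
    expect_equal(r1 - r0, cfg$deltas$prior_stroke_percent_points[[as.character(h)]],
                 tolerance = 1e-12)
  }
  # cap: a near-certain profile cannot exceed 100
  hot <- coefficient_set("male", c(age = 0.2), baseline_survival = c("5" = 0.5))
  cfg_hot <- toy_config(male = hot)
  extreme <- risk_profile(age = 95, sex = "male", sbp = 120,
                          previous_stroke_or_tia = TRUE)
  expect_lte(riskometer_risk(extreme, cfg_hot)$absolute_risk_percent, 100)
})

test_that("riskometer risk dominates the base risk, equality iff no delta", {
  cfg <- toy_config()
  profiles <- random_profiles(60, seed = 42)
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, , drop = FALSE]
    rk <- riskometer_risk(p, cfg)$absolute_risk_percent
    fr <- fsrs_risk(p, cfg)$absolute_risk_percent
    expect_gte(rk, fr - 1e-12)
  }
  clean <- risk_profile(age = 70, sex = "male", sbp = 160, diabetes = TRUE,
                        smoking = "current")
  expect_equal(riskometer_risk(clean, cfg)$absolute_risk_percent,
               fsrs_risk(clean, cfg)$absolute_risk_percent, tolerance = 1e-15)
})

test_that("risk is monotone in sbp and in each anthropometric slot", {
  cfg <- toy_config()
  risk_at <- function(field, values) {
    vapply(values, function(v) {
      args <- list(age = 60, sex = "male", sbp = 140)
      args[[field]] <- v
      riskometer_risk(do.call(risk_profile, args), cfg)$absolute_risk_percent
    }, numeric(1))
  }
  expect_true(all(diff(risk_at("sbp", seq(100, 220, by = 20))) > 0))
  expect_true(all(diff(risk_at("whr", seq(0.9, 1.2, by = 0.05))) >= 0))
  expect_true(all(diff(risk_at("bmi", seq(22, 40, by = 3))) >= 0))
  expect_true(all(diff(risk_at("waist_circumference_cm",
                               seq(95, 140, by = 10))) >= 0))
})

test_that("end-to-end risk matches an independent closed-form recomputation", {
  set.seed(11)
  for (rep in 1:5) {
    betas <- setNames(runif(5, 0.01, 0.7),
                      c("age", "sbp", "diabetes", "current_smoker", "lvh"))
    betas[["age"]] <- runif(1, 0.01, 0.08)
    betas[["sbp"]] <- runif(1, 0.005, 0.02)
    means <- setNames(c(runif(1, 50, 70), runif(1, 120, 150), 0.1, 0.2, 0.05),
                      names(betas))
    s0 <- sort(runif(2, 0.7, 0.99))
    cs <- coefficient_set("female", betas, means,
                          c("5" = s0[2], "10" = s0[1]))
    cfg <- toy_config(female = cs)
    profiles <- random_profiles(20, seed = rep)
    profiles$sex <- "female"
    for (i in seq_len(nrow(profiles))) {
      p <- profiles[i, , drop = FALSE]
      for (h in c(5, 10)) {
        expect_equal(riskometer_risk(p, cfg, h)$absolute_risk_percent,
                     riskometer_closed_form(as.list(p), cs, cfg$deltas, h),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("baseline reference risk is the all-reference profile, monotone in age", {
  cfg <- toy_config()
  ref <- risk_profile(age = 55, sex = "male", sbp = cfg$deltas$reference_sbp)
  expect_equal(baseline_reference_risk(55, "male", cfg, 5),
               riskometer_risk(ref, cfg, 5)$absolute_risk_percent,
               tolerance = 1e-15)
  risks <- vapply(seq(20, 90, by = 10), baseline_reference_risk,
                  numeric(1), sex = "female", config = cfg, horizon = 10)
  expect_true(all(diff(risks) > 0))
  expect_error(baseline_reference_risk(15, "male", cfg), "age")
})

test_that("score_cohort equals looped scalar calls and preserves order", {
  cfg <- toy_config()
  cohort <- random_profiles(100, seed = 3)
  vec <- score_cohort(cohort, model = "riskometer", config = cfg, horizon = 5)
  loop <- vapply(seq_len(nrow(cohort)), function(i) {
    riskometer_risk(cohort[i, , drop = FALSE], cfg, 5)$absolute_risk_percent
  }, numeric(1))
  expect_equal(vec, loop, tolerance = 1e-12)

  perm <- sample(nrow(cohort))
  expect_equal(score_cohort(cohort[perm, ], model = "riskometer",
                            config = cfg, horizon = 5), vec[perm],
               tolerance = 1e-12)

  expect_error(score_cohort(cohort[0, ], config = cfg), "empty")

  bad <- cohort
  bad$age[7] <- 10
  expect_error(score_cohort(bad, config = cfg), "row 7")
  expect_warning(skipped <- score_cohort(bad, config = cfg,
                                         on_error = "skip"), "row 7")
  expect_true(is.na(skipped[7]))
  expect_equal(skipped[-7], vec[-7], tolerance = 1e-12)
})
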