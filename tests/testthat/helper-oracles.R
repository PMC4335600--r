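# Toy fixtures and independent brute-force oracles. Every oracle here is
# deliberately naive (loops, explicit enumeration) so it shares no code
# path with the implementation it checks.

toy_coeffs <- function(sex = "male",
                       betas = c(age = 0.05, sbp = 0.01, diabetes = 0.4,
                                 current_smoker = 0.5,
                                 atrial_fibrillation = 0.6),
                       means = c(age = 60, sbp = 140, diabetes = 0.1,
                                 current_smoker = 0.25,
                                 atrial_fibrillation = 0.03),
                       s0 = c("5" = 0.96, "10" = 0.92)) {
  coefficient_set(sex, betas, means, s0, provenance = "toy")
}

toy_config <- function(male = toy_coeffs("male"),
                       female = toy_coeffs("female"),
                       deltas = delta_config()) {
  structure(
    list(model_name = "toy", coefficients = list(male = male, female = female),
         deltas = deltas, config_hash = "toy"),
    class = "model_config"
  )
}

# A valid random profile data frame covering the whole schema.
random_profiles <- function(n, seed = 1, with_anthro = TRUE) {
  withr::with_seed(seed, {
    df <- data.frame(
      age = runif(n, 20, 95),
      sex = sample(c("male", "female"), n, replace = TRUE),
      sbp = runif(n, 90, 220),
      smoking = sample(c("never", "ex", "current"), n, replace = TRUE),
      ethnic_group = sample(c("chinese", "south_asian", "other"), n,
                            replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (col in riskometer:::.profile_logical_fields) {
      df[[col]] <- runif(n) < 0.3
    }
    df$memory_problems <- df$memory_problems & !df$cognitive_problems
    if (with_anthro) {
      pick <- sample(c("whr", "bmi", "waist", "none"), n, replace = TRUE)
      df$whr <- ifelse(pick == "whr", runif(n, 0.7, 1.2), NA_real_)
      df$bmi <- ifelse(pick == "bmi", runif(n, 18, 45), NA_real_)
      df$waist_circumference_cm <- ifelse(pick == "waist",
                                          runif(n, 60, 140), NA_real_)
    } else {
      df$whr <- df$bmi <- df$waist_circumference_cm <- NA_real_
    }
    riskometer:::complete_profiles(df)
  })
}

# All-pairs Mann-Whitney AUROC (0.5 per tie).
auc_pairs_oracle <- function(scores, events) {
  pos <- scores[events == 1]
  neg <- scores[events == 0]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(pos) * length(neg))
}

# DeLong placement components and variance, expanded with explicit loops.
delong_oracle <- function(scores, events) {
  pos <- scores[events == 1]
  neg <- scores[events == 0]
  m <- length(pos)
  n <- length(neg)
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(auc = mean(v10),
       var = var(v10) / m + var(v01) / n,
       v10 = v10, v01 = v01)
}

# Exhaustive comparable-pair table for Harrell's C (default tie policy:
# tied event times excluded).
harrell_oracle <- function(scores, times, events) {
  n <- length(scores)
  conc <- 0
  pairs <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (events[i] == 1 && times[i] < times[j]) {
        pairs <- pairs + 1
        conc <- conc + (scores[i] > scores[j]) +
          0.5 * (scores[i] == scores[j])
      }
    }
  }
  list(c = conc / pairs, pairs = pairs)
}

# Term-by-term Hosmer-Lemeshow chi-square for a pre-grouped table.
hl_chi2_oracle <- function(n, observed, expected) {
  total <- 0
  for (k in seq_along(n)) {
    total <- total + (observed[k] - expected[k])^2 / expected[k] +
      ((n[k] - observed[k]) - (n[k] - expected[k]))^2 / (n[k] - expected[k])
  }
  total
}

# Closed-form end-to-end recomputation of the Riskometer risk for a single
# profile row, written independently of the package internals.
riskometer_closed_form <- function(p, coeffs, deltas, horizon) {
  x <- c(age = p$age, sbp = p$sbp,
         antihypertensive_treatment = as.numeric(p$antihypertensive_treatment),
         diabetes = as.numeric(p$diabetes),
         cvd_history = as.numeric(p$cvd_history),
         current_smoker = as.numeric(p$smoking == "current"),
         ex_smoker = as.numeric(p$smoking == "ex"),
         atrial_fibrillation = as.numeric(p$atrial_fibrillation),
         lvh = as.numeric(p$lvh))
  lp <- sum(coeffs$betas * x[names(coeffs$betas)])
  lp <- lp +
    deltas$lp_deltas[["non_caucasian"]] * p$non_caucasian +
    deltas$lp_deltas[["poor_diet"]] * p$poor_diet +
    deltas$lp_deltas[["high_alcohol"]] * p$high_alcohol +
    deltas$lp_deltas[["low_physical_activity"]] * p$low_physical_activity +
    deltas$lp_deltas[["family_history"]] * p$family_history_stroke_or_mi +
    deltas$lp_deltas[["stress"]] * p$stress
  if (p$cognitive_problems) lp <- lp + log(deltas$rr_multipliers[["cognitive_problems"]])
  if (p$memory_problems && !p$cognitive_problems) {
    lp <- lp + log(deltas$rr_multipliers[["memory_only"]])
  }
  if (p$previous_tbi) lp <- lp + log(deltas$rr_multipliers[["previous_tbi"]])
  if (!is.na(p$whr)) {
    thr <- if (p$sex == "male") deltas$whr_rule$threshold_male
           else deltas$whr_rule$threshold_female
    if (p$whr > thr) lp <- lp + 0.20 + 0.10 * (p$whr - thr) / 0.01
  } else if (!is.na(p$bmi)) {
    thr <- switch(p$ethnic_group, chinese = 24, south_asian = 23, 25)
    lp <- lp + 0.10 * max(0, p$bmi - thr)
  } else if (!is.na(p$waist_circumference_cm)) {
    thr <- if (p$sex == "male") 103 else 89
    lp <- lp + log(1.02) * max(0, p$waist_circumference_cm - thr)
  }
  center <- sum(coeffs$betas *
                  ifelse(names(coeffs$betas) %in% names(coeffs$covariate_means),
                         coeffs$covariate_means[names(coeffs$betas)], 0))
  s0 <- coeffs$baseline_survival[[as.character(horizon)]]
  risk <- 100 * (1 - s0^exp(lp - center))
  if (p$previous_stroke_or_tia) {
    risk <- min(100, risk + if (horizon == 5) 10 else 15)
  }
  risk
}
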