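# Scoring engine: Cox-style linear predictor, baseline-survival transform,
# and the add-on delta layer that turns the base (FSRS-style) score into the
# Riskometer score. Internal engines are vectorised over profile data
# frames; the exported scalar functions wrap them into RiskEstimate objects.

#' Linear predictor of the base model
#'
#' Computes the Cox linear predictor \eqn{\sum_i \beta_i x_i} over the base
#' model covariates, uncentered (centering is applied inside
#' [risk_from_lp()] via the coefficient set's covariate means).
#'
#' @param profile a risk profile (one-row data frame from [risk_profile()]
#'   or a data frame of several profiles).
#' @param coeffs a [coefficient_set()] whose sex matches the profile(s).
#' @return a numeric vector, one linear predictor per profile row.
#' @export
linear_predictor <- function(profile, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  profile <- as.data.frame(profile)
  if (!all(profile$sex == coeffs$sex)) {
    stop("sex mismatch: coefficient set is for ", coeffs$sex, call. = FALSE)
  }
  x <- derive_covariates(profile)
  missing <- setdiff(names(coeffs$betas), colnames(x))
  if (length(missing) > 0L) {
    stop("missing required covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop(x[, names(coeffs$betas), drop = FALSE] %*% coeffs$betas)
}

# S0(t) with the constant-baseline-hazard fallback for S0(5).
baseline_survival_at <- function(coeffs, horizon) {
  key <- as.character(horizon)
  s0 <- coeffs$baseline_survival
  if (key %in% names(s0)) return(s0[[key]])
  if (horizon == 5 && "10" %in% names(s0)) return(s0[["10"]]^0.5)
  stop("no baseline survival configured for horizon ", horizon, " years",
       call. = FALSE)
}

#' Absolute risk from a linear predictor
#'
#' Applies the baseline-survival transform
#' \eqn{1 - S_0(t)^{\exp(lp - \sum_i \beta_i \bar x_i)}} and clips the
#' result to \[0, 1\] (with a warning if clipping was needed, which can
#' happen for extreme linear predictors).
#'
#' @param lp numeric vector of (uncentered) linear predictors.
#' @param coeffs a [coefficient_set()].
#' @param horizon 5 or 10 (years). `S0(5)` is derived as `S0(10)^(1/2)` when
#'   only the 10-year baseline survival is configured.
#' @return risk as a fraction in \[0, 1\], same length as `lp`.
#' @export
risk_from_lp <- function(lp, coeffs, horizon) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  s0 <- baseline_survival_at(coeffs, horizon)
  center <- sum(coeffs$betas *
                  ifelse(names(coeffs$betas) %in% names(coeffs$covariate_means),
                         coeffs$covariate_means[names(coeffs$betas)], 0),
                na.rm = TRUE)
  risk <- 1 - s0^exp(lp - center)
  if (any(risk < 0 | risk > 1, na.rm = TRUE)) {
    warning("risk outside [0, 1] clipped (extreme linear predictor)")
    risk <- pmin(pmax(risk, 0), 1)
  }
  risk
}

#' Anthropometric add-on term (fallback chain WHR -> BMI -> waist)
#'
#' Computes the log-hazard-scale addition from body shape. The first
#' available measurement wins:
#' * waist-to-hip ratio above the sex threshold (0.96 male / 0.80 female):
#'   0.20 plus 0.10 per 0.01 unit above the threshold; at or below, 0.
#' * otherwise BMI above the ethnic threshold (24 Chinese / 23 South Asian /
#'   25 other, kg/m^2): 0.10 per unit above; optionally plus `log(1.02)` as
#'   a base term when `bmi_rule$include_base_rr` is `TRUE`.
#' * otherwise waist circumference above the sex threshold (103 cm male /
#'   89 cm female): a 1.02 hazard multiplier per cm above, i.e.
#'   `log(1.02)` per cm.
#' * all missing: 0.
#'
#' @param profile risk profile data frame (any number of rows).
#' @param deltas a [delta_config()].
#' @return numeric vector of log-hazard additions, one per row.
#' @export
anthropometric_delta <- function(profile, deltas = delta_config()) {
  stopifnot(inherits(deltas, "delta_config"))
  profile <- as.data.frame(profile)
  profile <- complete_profiles(profile)
  bad <- c(which(!is.na(profile$whr) & profile$whr <= 0),
           which(!is.na(profile$bmi) & profile$bmi <= 0),
           which(!is.na(profile$waist_circumference_cm) &
                   profile$waist_circumference_cm <= 0))
  if (length(bad) > 0L) {
    stop("anthropometric measurements must be positive (rows ",
         paste(sort(unique(bad)), collapse = ", "), ")", call. = FALSE)
  }
  wr <- deltas$whr_rule
  br <- deltas$bmi_rule
  cr <- deltas$waist_rule
  n <- nrow(profile)
  out <- numeric(n)

  whr_thr <- ifelse(profile$sex == "male", wr$threshold_male, wr$threshold_female)
  use_whr <- !is.na(profile$whr)
  over <- pmax(0, profile$whr - whr_thr)
  out[use_whr] <- ifelse(profile$whr[use_whr] > whr_thr[use_whr],
                         wr$base_delta +
                           wr$per_unit_delta * over[use_whr] / wr$unit,
                         0)

  bmi_thr <- ifelse(profile$ethnic_group == "chinese", br$threshold_chinese,
                    ifelse(profile$ethnic_group == "south_asian",
                           br$threshold_south_asian, br$threshold_other))
  use_bmi <- !use_whr & !is.na(profile$bmi)
  bmi_term <- br$per_unit_delta * pmax(0, profile$bmi - bmi_thr) / br$unit
  if (isTRUE(br$include_base_rr)) {
    bmi_term <- bmi_term + ifelse(profile$bmi > bmi_thr, log(br$base_rr), 0)
  }
  out[use_bmi] <- bmi_term[use_bmi]

  waist_thr <- ifelse(profile$sex == "male", cr$threshold_male_cm,
                      cr$threshold_female_cm)
  use_waist <- !use_whr & !use_bmi & !is.na(profile$waist_circumference_cm)
  waist_term <- log(cr$per_unit_rr) *
    pmax(0, profile$waist_circumference_cm - waist_thr) / cr$unit
  out[use_waist] <- waist_term[use_waist]
  out
}

#' Riskometer linear predictor
#'
#' Base-model linear predictor plus the add-on terms: additive log-hazard
#' deltas for the active lifestyle/ethnicity/family-history/stress flags,
#' `log()` of the relative-risk multipliers for cognition and head injury
#' (the memory term applies only when `cognitive_problems` is `FALSE`),
#' and the anthropometric fallback term. The prior stroke/TIA addition is
#' *not* part of the linear predictor; it acts on the final risk (see
#' [riskometer_risk()]).
#'
#' @inheritParams linear_predictor
#' @param deltas a [delta_config()].
#' @return numeric vector of linear predictors, one per profile row.
#' @export
riskometer_lp <- function(profile, coeffs, deltas = delta_config()) {
  profile <- complete_profiles(as.data.frame(profile))
  lp <- linear_predictor(profile, coeffs)
  for (key in names(deltas$lp_deltas)) {
    field <- .lp_delta_fields[[key]]
    if (is.null(field)) {
      stop("unknown lp delta key: ", key, call. = FALSE)
    }
    lp <- lp + deltas$lp_deltas[[key]] * as.numeric(profile[[field]])
  }
  active <- cbind(
    cognitive_problems = as.numeric(profile$cognitive_problems),
    memory_only = as.numeric(profile$memory_problems &
                               !profile$cognitive_problems),
    previous_tbi = as.numeric(profile$previous_tbi)
  )
  bad <- setdiff(names(deltas$rr_multipliers), colnames(active))
  if (length(bad) > 0L) {
    stop("unknown rr multiplier key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lp <- lp + drop(active[, names(deltas$rr_multipliers), drop = FALSE] %*%
                    log(deltas$rr_multipliers))
  lp + anthropometric_delta(profile, deltas)
}

check_one_profile <- function(profile) {
  profile <- as.data.frame(profile)
  stopifnot(nrow(profile) == 1L)
  profile <- complete_profiles(profile)
  problems <- validate_profiles(profile)
  if (nrow(problems) > 0L) {
    stop("invalid risk profile: ", paste(problems$message, collapse = "; "),
         call. = FALSE)
  }
  profile
}

check_horizon <- function(horizon) {
  if (length(horizon) != 1L || !horizon %in% c(5, 10)) {
    stop("horizon must be 5 or 10 (years)", call. = FALSE)
  }
  horizon
}

new_risk_estimate <- function(model, horizon, risk_pct, baseline_pct, lp) {
  structure(
    list(model = model, horizon = horizon,
         absolute_risk_percent = risk_pct,
         baseline_risk_percent = baseline_pct,
         linear_predictor = lp),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("<%s> %d-year absolute stroke risk: %.1f%%", x$model,
              x$horizon, x$absolute_risk_percent), "\n")
  if (!is.na(x$baseline_risk_percent)) {
    cat(sprintf("  baseline (same age/sex, no risk factors): %.1f%%\n",
                x$baseline_risk_percent))
  }
  invisible(x)
}

#' Base-model (FSRS-style) absolute stroke risk
#'
#' Scores one profile with the base Cox equation only (no add-on deltas).
#'
#' @param profile a single risk profile (one row).
#' @param config a `"model_config"` (default: the shipped synthetic
#'   stand-in, see [default_model_config()]).
#' @param horizon 5 or 10 years.
#' @return a `"risk_estimate"` with `model = "fsrs"`, absolute and baseline
#'   risks in percent, and the (uncentered) linear predictor.
#' @export
fsrs_risk <- function(profile, config = default_model_config(), horizon = 5) {
  check_horizon(horizon)
  profile <- check_one_profile(profile)
  coeffs <- coeffs_for_sex(config, profile$sex)
  lp <- linear_predictor(profile, coeffs)
  risk <- 100 * risk_from_lp(lp, coeffs, horizon)
  base <- baseline_reference_risk(profile$age, profile$sex, config, horizon,
                                  model = "fsrs")
  new_risk_estimate("fsrs", horizon, risk, base, lp)
}

#' Riskometer absolute stroke risk
#'
#' Scores one profile with the base equation plus the add-on terms: additive
#' log-hazard deltas for lifestyle/ethnicity/family history, log
#' relative-risk terms for cognition and head injury, the anthropometric
#' fallback chain, and -- after the baseline-survival transform -- the
#' absolute percentage-point addition for previous stroke/TIA (10 at 5
#' years, 15 at 10 years, capped at 100%).
#'
#' @inheritParams fsrs_risk
#' @return a `"risk_estimate"` with `model = "riskometer"`.
#' @export
riskometer_risk <- function(profile, config = default_model_config(),
                            horizon = 5) {
  check_horizon(horizon)
  profile <- check_one_profile(profile)
  coeffs <- coeffs_for_sex(config, profile$sex)
  deltas <- config$deltas
  lp <- riskometer_lp(profile, coeffs, deltas)
  risk <- 100 * risk_from_lp(lp, coeffs, horizon)
  if (profile$previous_stroke_or_tia) {
    risk <- min(100, risk +
                  deltas$prior_stroke_percent_points[[as.character(horizon)]])
  }
  base <- baseline_reference_risk(profile$age, profile$sex, config, horizon,
                                  model = "riskometer")
  new_risk_estimate("riskometer", horizon, risk, base, lp)
}

#' Risk of the no-risk-factor reference person
#'
#' Absolute risk for someone of the same age and sex with no risk factors:
#' every binary flag off, never-smoker, systolic blood pressure at the
#' configured reference value (default 120 mmHg), anthropometrics absent.
#' This is the comparison figure a user sees next to their own risk.
#'
#' @param age age in years (>= 20).
#' @param sex `"male"` or `"female"`.
#' @param config a `"model_config"`.
#' @param horizon 5 or 10 years.
#' @param model `"riskometer"` or `"fsrs"` (identical for the reference
#'   person, who has no active deltas; kept for symmetry).
#' @return risk in percent.
#' @export
baseline_reference_risk <- function(age, sex, config = default_model_config(),
                                    horizon = 5, model = "riskometer") {
  check_horizon(horizon)
  ref <- risk_profile(age = age, sex = sex,
                      sbp = config$deltas$reference_sbp)
  coeffs <- coeffs_for_sex(config, sex)
  lp <- if (model == "riskometer") {
    riskometer_lp(ref, coeffs, config$deltas)
  } else {
    linear_predictor(ref, coeffs)
  }
  100 * risk_from_lp(lp, coeffs, horizon)
}

#' Score a cohort
#'
#' Vectorised scoring of a cohort data frame; order-preserving and
#' deterministic. Rows failing profile validation either abort the call
#' (`on_error = "fail"`, default) with row indices and reasons, or are
#' skipped (`on_error = "skip"`) and returned as `NA` with a warning.
#'
#' @param cohort data frame of profiles (columns as in [risk_profile()];
#'   extra columns `follow_up_years`, `event`, `true_risk` are ignored).
#' @param model `"riskometer"`, `"fsrs"`, or `"comparator"` (base equation
#'   of a user-supplied comparator config, e.g. a QStroke-style score).
#' @param config a `"model_config"`.
#' @param horizon 5 or 10 years.
#' @param on_error `"fail"` or `"skip"`.
#' @return numeric vector of absolute risks in percent, aligned to rows.
#' @export
score_cohort <- function(cohort, model = c("riskometer", "fsrs", "comparator"),
                         config = default_model_config(), horizon = 5,
                         on_error = c("fail", "skip")) {
  model <- match.arg(model)
  on_error <- match.arg(on_error)
  check_horizon(horizon)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  cohort <- complete_profiles(cohort)
  problems <- validate_profiles(cohort)
  ok <- rep(TRUE, nrow(cohort))
  if (nrow(problems) > 0L) {
    msg <- paste(sprintf("row %d: %s", problems$row, problems$message),
                 collapse = "\n  ")
    if (on_error == "fail") {
      stop("invalid cohort rows:\n  ", msg, call. = FALSE)
    }
    ok[problems$row] <- FALSE
    warning("skipped ", length(unique(problems$row)), " invalid row(s):\n  ",
            msg, call. = FALSE)
  }
  out <- rep(NA_real_, nrow(cohort))
  for (sex in c("male", "female")) {
    idx <- which(ok & cohort$sex == sex)
    if (length(idx) == 0L) next
    sub <- cohort[idx, , drop = FALSE]
    coeffs <- coeffs_for_sex(config, sex)
    if (model == "riskometer") {
      lp <- riskometer_lp(sub, coeffs, config$deltas)
      risk <- 100 * risk_from_lp(lp, coeffs, horizon)
      pp <- config$deltas$prior_stroke_percent_points[[as.character(horizon)]]
      risk <- pmin(100, risk + pp * as.numeric(sub$previous_stroke_or_tia))
    } else {
      lp <- linear_predictor(sub, coeffs)
      risk <- 100 * risk_from_lp(lp, coeffs, horizon)
    }
    out[idx] <- risk
  }
  out
}
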