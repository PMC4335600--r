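# Seeded synthetic cohorts. Continuous risk factors are drawn from
# truncated normals at published cohort-style means/SDs, binary factors
# from independent Bernoullis (marginals only; no correlation structure by
# default), and outcomes either from a risk model (calibration-faithful)
# or at a constant rate (null).

# Physiologic plausibility bounds used to truncate the normal draws.
.trunc_bounds <- list(
  age = c(20, 100), sbp = c(70, 260), bmi = c(14, 60),
  whr = c(0.5, 1.4), waist_circumference_cm = c(50, 180)
)

# Inverse-CDF truncated normal: one uniform per draw, so the RNG stream
# advances deterministically regardless of the bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Specify a synthetic cohort
#'
#' Describes the marginal distributions a generated cohort should follow:
#' per-sex means/SDs for the continuous factors, prevalences for the
#' binary factors, a smoking distribution, and the outcome mechanism.
#'
#' @param name label recorded in the cohort metadata.
#' @param n number of subjects (>= 1).
#' @param sex_ratio proportion male, in \[0, 1\].
#' @param age,sbp lists with elements `male` and `female`, each `c(mean, sd)`
#'   (a single `c(mean, sd)` is recycled for both sexes). Units: years, mmHg.
#' @param bmi,waist,whr as `age`, or `NULL` when the cohort does not
#'   measure them (kg/m^2, cm, ratio).
#' @param prevalences named list of binary-factor prevalences in \[0, 1\];
#'   names are profile fields. `memory_problems` is applied only to
#'   subjects without cognitive problems (the two flags are exclusive).
#' @param smoking probabilities for never/ex/current, summing to 1.
#' @param target_event_rate `"model"` (events drawn from the scored risk of
#'   each subject) or a fraction (constant-rate null mode).
#' @param horizon 5 or 10 years.
#' @param censoring_rate fraction of subjects given a uniform random
#'   censoring time before the horizon, default 0.
#' @param case_only `TRUE` for register-style all-event cohorts (every
#'   subject has an event, follow-up drawn within `follow_up_years`).
#' @param follow_up_years maximum follow-up, defaults to the horizon.
#' @return a list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(name, n, sex_ratio = 0.5,
                        age = list(male = c(60, 10), female = c(60, 10)),
                        sbp = list(male = c(135, 20), female = c(135, 20)),
                        bmi = NULL, waist = NULL, whr = NULL,
                        prevalences = list(),
                        smoking = c(never = 0.5, ex = 0.25, current = 0.25),
                        target_event_rate = "model",
                        horizon = 5, censoring_rate = 0,
                        case_only = FALSE, follow_up_years = NULL) {
  per_sex <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x) && length(x) == 2L) x <- list(male = x, female = x)
    stopifnot(is.list(x), all(c("male", "female") %in% names(x)))
    for (s in c("male", "female")) {
      if (length(x[[s]]) != 2L || x[[s]][2] <= 0) {
        stop(what, " must be c(mean, sd) with sd > 0", call. = FALSE)
      }
    }
    x
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio in [0,1]", call. = FALSE)
  bad <- names(prevalences)[!unlist(prevalences) >= 0 |
                              !unlist(prevalences) <= 1]
  unknown <- setdiff(names(prevalences), .profile_logical_fields)
  if (length(unknown) > 0L || length(bad) > 0L) {
    stop("invalid prevalences: ",
         paste(unique(c(unknown, bad)), collapse = ", "), call. = FALSE)
  }
  if (abs(sum(smoking) - 1) > 1e-8 || any(smoking < 0)) {
    stop("smoking probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!identical(target_event_rate, "model")) {
    if (!is.numeric(target_event_rate) || target_event_rate < 0 ||
        target_event_rate > 1) {
      stop("target_event_rate must be 'model' or a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  check_horizon(horizon)
  structure(
    list(name = name, n = as.integer(n), sex_ratio = sex_ratio,
         age = per_sex(age, "age"), sbp = per_sex(sbp, "sbp"),
         bmi = per_sex(bmi, "bmi"), waist = per_sex(waist, "waist"),
         whr = per_sex(whr, "whr"),
         prevalences = prevalences, smoking = smoking,
         target_event_rate = target_event_rate, horizon = horizon,
         censoring_rate = censoring_rate, case_only = case_only,
         follow_up_years = if (is.null(follow_up_years)) horizon
                           else follow_up_years),
    class = "cohort_spec"
  )
}

#' Shipped cohort presets
#'
#' Three presets emulating the published validation-cohort marginals:
#' * `"russia-like"`: n = 1378, mean age ~50 (SD ~6), SBP ~131-136 mmHg,
#'   BMI ~27.5-27.8 kg/m^2, diabetes ~4.6%, overall event rate 3.2% at the
#'   5-year horizon.
#' * `"rotterdam-like"`: n = 7713, elderly (age ~69-72), SBP ~139-140,
#'   BMI ~25.6-26.7, diabetes ~6.6%, event rate 8.4%, 10-year horizon.
#' * `"arcos-like"`: n = 410, stroke-register style case-only cohort
#'   (every subject an event within 1 year of follow-up), age ~69-72,
#'   SBP ~157, WHR 0.9 (0.1), waist ~97-99 cm, diabetes 20%.
#'
#' Only the continuous means/SDs, diabetes prevalence and event rates are
#' published for these cohorts; the remaining prevalences are neutral,
#' field-plausible defaults and can be overridden via `...`, which is
#' passed on to [cohort_spec()].
#'
#' @param preset preset name.
#' @param ... overrides forwarded to [cohort_spec()] (e.g. `n`,
#'   `prevalences`, `target_event_rate`).
#' @return a `"cohort_spec"`.
#' @export
cohort_preset <- function(preset = c("russia-like", "rotterdam-like",
                                     "arcos-like"), ...) {
  name <- match.arg(preset)
  base <- switch(
    name,
    "russia-like" = list(
      name = "russia-like", n = 1378, sex_ratio = 0.5,
      age = list(male = c(50.3, 6.2), female = c(50.6, 6.4)),
      sbp = list(male = c(135.8, 19.4), female = c(130.8, 21.1)),
      bmi = list(male = c(27.8, 4.3), female = c(27.5, 5.4)),
      prevalences = list(
        diabetes = 0.046, antihypertensive_treatment = 0.15,
        cvd_history = 0.05, atrial_fibrillation = 0.02, lvh = 0.03,
        family_history_stroke_or_mi = 0.15, non_caucasian = 0.05,
        poor_diet = 0.5, high_alcohol = 0.15, low_physical_activity = 0.4,
        stress = 0.2, previous_stroke_or_tia = 0.01,
        cognitive_problems = 0.02, memory_problems = 0.05,
        previous_tbi = 0.03),
      smoking = c(never = 0.5, ex = 0.2, current = 0.3),
      target_event_rate = 0.032, horizon = 5),
    "rotterdam-like" = list(
      name = "rotterdam-like", n = 7713, sex_ratio = 0.4,
      age = list(male = c(69.0, 8.7), female = c(71.7, 10.2)),
      sbp = list(male = c(138.7, 21.8), female = c(140.0, 22.8)),
      bmi = list(male = c(25.6, 2.9), female = c(26.7, 3.7)),
      prevalences = list(
        diabetes = 0.066, antihypertensive_treatment = 0.3,
        cvd_history = 0.12, atrial_fibrillation = 0.05, lvh = 0.04,
        family_history_stroke_or_mi = 0.2, non_caucasian = 0.05,
        poor_diet = 0.5, high_alcohol = 0.15, low_physical_activity = 0.5,
        stress = 0.15, previous_stroke_or_tia = 0.03,
        cognitive_problems = 0.05, memory_problems = 0.1,
        previous_tbi = 0.03),
      smoking = c(never = 0.35, ex = 0.42, current = 0.23),
      target_event_rate = 0.084, horizon = 10),
    "arcos-like" = list(
      name = "arcos-like", n = 410, sex_ratio = 0.5,
      age = list(male = c(68.8, 13.2), female = c(72.4, 15.7)),
      sbp = list(male = c(156.8, 30.1), female = c(157.3, 29.9)),
      whr = list(male = c(0.9, 0.1), female = c(0.9, 0.1)),
      waist = list(male = c(97.2, 15.9), female = c(99.3, 14.5)),
      prevalences = list(
        diabetes = 0.20, antihypertensive_treatment = 0.45,
        cvd_history = 0.25, atrial_fibrillation = 0.12, lvh = 0.08,
        family_history_stroke_or_mi = 0.25, non_caucasian = 0.30,
        poor_diet = 0.55, high_alcohol = 0.15, low_physical_activity = 0.5,
        stress = 0.2, previous_stroke_or_tia = 0.15,
        cognitive_problems = 0.08, memory_problems = 0.12,
        previous_tbi = 0.05),
      smoking = c(never = 0.45, ex = 0.35, current = 0.2),
      target_event_rate = 1, horizon = 5,
      case_only = TRUE, follow_up_years = 1)
  )
  do.call(cohort_spec, modifyList(base, list(...)))
}

# Save/restore RNG state around seeded draws so callers' streams are
# untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Sample risk-factor profiles from a cohort spec
#'
#' Draws `n` profiles with the spec's marginals: sex Bernoulli at the sex
#' ratio, continuous factors from truncated normals (physiologic bounds:
#' age 20-100, SBP 70-260 mmHg, BMI 14-60, WHR 0.5-1.4, waist 50-180 cm),
#' binary factors Bernoulli at the configured prevalence, smoking
#' multinomial. Draw order is fixed column by column, so a given spec and
#' seed always produce the identical data frame.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return a `data.frame` of profiles.
#' @export
sample_profiles <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(seed, {
    sex <- ifelse(runif(n) < spec$sex_ratio, "male", "female")
    draw_cont <- function(par, bounds) {
      if (is.null(par)) return(rep(NA_real_, n))
      m <- ifelse(sex == "male", par$male[1], par$female[1])
      s <- ifelse(sex == "male", par$male[2], par$female[2])
      rtruncnorm(n, m, s, bounds[1], bounds[2])
    }
    df <- data.frame(
      age = draw_cont(spec$age, .trunc_bounds$age),
      sex = sex,
      sbp = draw_cont(spec$sbp, .trunc_bounds$sbp),
      stringsAsFactors = FALSE
    )
    for (col in .profile_logical_fields) {
      p <- spec$prevalences[[col]]
      df[[col]] <- if (is.null(p)) rep(FALSE, n) else runif(n) < p
    }
    # poor memory is defined as memory trouble *without* cognitive problems
    df$memory_problems <- df$memory_problems & !df$cognitive_problems
    df$smoking <- sample(names(spec$smoking), n, replace = TRUE,
                         prob = spec$smoking)
    df$whr <- draw_cont(spec$whr, .trunc_bounds$whr)
    df$bmi <- draw_cont(spec$bmi, .trunc_bounds$bmi)
    df$waist_circumference_cm <- draw_cont(spec$waist,
                                           .trunc_bounds$waist_circumference_cm)
    df$ethnic_group <- "other"
    complete_profiles(df)
  })
}

#' Simulate binary stroke outcomes
#'
#' Independent Bernoulli draws, either calibration-faithful (probability =
#' each subject's predicted risk) or at a constant null rate.
#'
#' @param risks predicted risks in percent (0-100), one per subject.
#' @param seed integer seed.
#' @param rate optional constant event rate as a fraction; when given, the
#'   risks are ignored (null mode).
#' @return integer 0/1 vector of events.
#' @export
simulate_binary_outcomes <- function(risks, seed = NULL, rate = NULL) {
  if (is.null(rate)) {
    if (any(risks < 0 | risks > 100)) {
      stop("risks must be percentages in [0, 100]", call. = FALSE)
    }
    p <- risks / 100
  } else {
    p <- rep(rate, length(risks))
  }
  with_seed(seed, as.integer(runif(length(p)) < p))
}

#' Simulate event and censoring times
#'
#' Per subject, an exponential event time with rate
#' \eqn{\lambda_i = -\log(1 - r_i)/h} where \eqn{r_i} is the predicted
#' risk (fraction) and \eqn{h} the horizon, so that by construction
#' \eqn{P(T_i \le h) = r_i}. A fraction `censoring_rate` of subjects gets a
#' uniform censoring time on (0, h\]; everyone else is administratively
#' censored at the horizon. A risk of 100% is capped at
#' \eqn{\lambda = -\log(10^{-12})/h}.
#'
#' @param risks predicted risks in percent.
#' @param horizon 5 or 10 years.
#' @param censoring_rate fraction in \[0, 1\].
#' @param seed integer seed.
#' @return a list with `times` (observed follow-up, years) and `events`
#'   (0/1).
#' @export
simulate_event_times <- function(risks, horizon, censoring_rate = 0,
                                 seed = NULL) {
  check_horizon(horizon)
  if (any(risks < 0 | risks > 100)) {
    stop("risks must be percentages in [0, 100]", call. = FALSE)
  }
  r <- pmin(risks / 100, 1 - 1e-12)
  lambda <- -log(1 - r) / horizon
  n <- length(r)
  with_seed(seed, {
    t_event <- ifelse(lambda > 0, -log(runif(n)) / lambda, Inf)
    censored <- runif(n) < censoring_rate
    t_cens <- ifelse(censored, runif(n) * horizon, horizon)
    times <- pmin(t_event, t_cens)
    list(times = times, events = as.integer(t_event <= t_cens))
  })
}

#' Build a complete synthetic cohort
#'
#' Composes [sample_profiles()] with an outcome simulator. In `"model"`
#' mode outcomes are drawn from the scored risk of each subject under
#' `model`/`config` (calibration-faithful); with a numeric
#' `target_event_rate` every subject gets that constant risk (null mode);
#' `case_only` specs make every subject an event with follow-up uniform on
#' (0, `follow_up_years`\].
#'
#' @param spec a [cohort_spec()] or preset name for [cohort_preset()].
#' @param config a `"model_config"` used for scoring in `"model"` mode.
#' @param model `"riskometer"` or `"fsrs"`.
#' @param seed integer seed controlling profiles and outcomes.
#' @return a `data.frame` of profiles plus `follow_up_years`, `event` and
#'   `true_risk` columns, with attributes `spec`, `seed` and `model`
#'   recording provenance.
#' @export
build_cohort <- function(spec, config = default_model_config(),
                         model = "riskometer", seed = 1L) {
  if (is.character(spec)) spec <- cohort_preset(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  profiles <- sample_profiles(spec, seed = seed)
  if (spec$case_only) {
    out <- with_seed(seed + 1L, {
      list(times = runif(spec$n) * spec$follow_up_years,
           events = rep(1L, spec$n))
    })
    true_risk <- rep(NA_real_, spec$n)
  } else {
    true_risk <- if (identical(spec$target_event_rate, "model")) {
      score_cohort(profiles, model = model, config = config,
                   horizon = spec$horizon)
    } else {
      rep(100 * spec$target_event_rate, spec$n)
    }
    out <- simulate_event_times(true_risk, spec$horizon,
                                censoring_rate = spec$censoring_rate,
                                seed = seed + 1L)
  }
  cohort <- profiles
  cohort$follow_up_years <- out$times
  cohort$event <- out$events
  cohort$true_risk <- true_risk
  attr(cohort, "spec") <- spec
  attr(cohort, "seed") <- seed
  attr(cohort, "model") <- model
  cohort
}
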