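# Model configuration: sex-specific Cox coefficient sets plus the add-on
# (Riskometer) delta table. Both are data, not code, so alternative
# interpretations of the published constants are selectable without
# touching the scoring engine.

#' Construct a sex-specific coefficient set
#'
#' A coefficient set holds the log-hazard betas of a Cox-style risk
#' equation, the covariate means used for centering, and the baseline
#' survival \eqn{S_0(t)} per horizon. Risk is computed as
#' \deqn{1 - S_0(t)^{\exp(lp - \sum_i \beta_i \bar x_i)}.}
#'
#' @param sex `"male"` or `"female"`.
#' @param betas named numeric vector of log-hazard coefficients. Names must
#'   resolve against the derived covariates: `age`, `sbp`,
#'   `antihypertensive_treatment`, `diabetes`, `cvd_history`,
#'   `current_smoker`, `ex_smoker`, `atrial_fibrillation`, `lvh`.
#' @param covariate_means named numeric vector of covariate means used for
#'   centering; names missing from it are treated as mean 0 (a set with all
#'   means 0 reproduces the uncentered form).
#' @param baseline_survival named numeric vector of baseline survival
#'   probabilities, names are horizons in years (e.g. `c("5" = 0.95,
#'   "10" = 0.90)`). Each value must lie in (0, 1]. When only `S0(10)` is
#'   supplied, `S0(5)` is derived as `S0(10)^(1/2)` (constant baseline
#'   hazard).
#' @param provenance free-text description of where the numbers come from.
#' @return an object of class `"coefficient_set"`.
#' @export
coefficient_set <- function(sex, betas, covariate_means = NULL,
                            baseline_survival, provenance = "") {
  if (!sex %in% c("male", "female")) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  betas <- unlist(betas)
  if (is.null(names(betas)) || any(!nzchar(names(betas)))) {
    stop("betas must be a named numeric vector", call. = FALSE)
  }
  known <- c("age", "sbp", "antihypertensive_treatment", "diabetes",
             "cvd_history", "current_smoker", "ex_smoker",
             "atrial_fibrillation", "lvh")
  bad <- setdiff(names(betas), known)
  if (length(bad) > 0L) {
    stop("beta name(s) not resolvable against profile covariates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(covariate_means)) {
    covariate_means <- setNames(numeric(length(betas)), names(betas))
  }
  covariate_means <- unlist(covariate_means)
  s0 <- unlist(baseline_survival)
  if (is.null(names(s0)) || !all(names(s0) %in% c("5", "10"))) {
    stop("baseline_survival must be named by horizon ('5' and/or '10')",
         call. = FALSE)
  }
  if (any(s0 <= 0 | s0 > 1)) {
    stop("baseline survival must lie in (0, 1]", call. = FALSE)
  }
  if (all(c("5", "10") %in% names(s0)) && s0[["10"]] > s0[["5"]]) {
    stop("baseline survival must be non-increasing: S0(10) <= S0(5)",
         call. = FALSE)
  }
  structure(
    list(sex = sex, betas = betas, covariate_means = covariate_means,
         baseline_survival = s0, provenance = provenance),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set>", x$sex, "\n")
  cat("  betas:", paste(sprintf("%s=%.4g", names(x$betas), x$betas),
                        collapse = ", "), "\n")
  cat("  S0:", paste(sprintf("%s yr: %.4g", names(x$baseline_survival),
                             x$baseline_survival), collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Keys of the additive (log-hazard scale) deltas, mapped to profile fields.
.lp_delta_fields <- c(
  non_caucasian = "non_caucasian",
  poor_diet = "poor_diet",
  high_alcohol = "high_alcohol",
  low_physical_activity = "low_physical_activity",
  family_history = "family_history_stroke_or_mi",
  stress = "stress"
)

#' Construct the add-on (Riskometer) delta configuration
#'
#' Holds the published add-on risk terms and how each is interpreted:
#' * `lp_deltas` -- additive terms on the log-hazard linear predictor
#'   (values in (0, 1): non-Caucasian 0.20, poor diet 0.20, high alcohol
#'   0.10, low physical activity 0.10, family history 0.05; stress is
#'   listed as a variable but carries no published coefficient, default 0).
#' * `rr_multipliers` -- relative-risk style multipliers (values >= 1),
#'   applied as `log(value)` additions to the linear predictor: cognitive
#'   problems 1.80, memory problems without cognitive problems 1.40,
#'   previous traumatic brain injury 1.20.
#' * `prior_stroke_percent_points` -- absolute percentage points added to
#'   the final risk for previous stroke/TIA: 10 at 5 years, 15 at 10 years
#'   (capped at 100).
#' * the anthropometric fallback chain `whr_rule` -> `bmi_rule` ->
#'   `waist_rule` (see [anthropometric_delta()]).
#'
#' @param lp_deltas,rr_multipliers,prior_stroke_percent_points,whr_rule,bmi_rule,waist_rule
#'   overrides merged over the defaults; see Details and the package
#'   vignette for interpretation.
#' @param reference_sbp systolic blood pressure (mmHg) assigned to the
#'   no-risk-factor reference person, default 120.
#' @return an object of class `"delta_config"`.
#' @export
delta_config <- function(lp_deltas = NULL, rr_multipliers = NULL,
                         prior_stroke_percent_points = NULL,
                         whr_rule = NULL, bmi_rule = NULL, waist_rule = NULL,
                         reference_sbp = 120) {
  cfg <- list(
    lp_deltas = c(non_caucasian = 0.20, poor_diet = 0.20, high_alcohol = 0.10,
                  low_physical_activity = 0.10, family_history = 0.05,
                  stress = 0.0),
    rr_multipliers = c(cognitive_problems = 1.80, memory_only = 1.40,
                       previous_tbi = 1.20),
    prior_stroke_percent_points = c("5" = 10, "10" = 15),
    whr_rule = list(threshold_male = 0.96, threshold_female = 0.80,
                    base_delta = 0.20, per_unit_delta = 0.10, unit = 0.01),
    bmi_rule = list(threshold_chinese = 24, threshold_south_asian = 23,
                    threshold_other = 25, per_unit_delta = 0.10,
                    base_rr = 1.02, include_base_rr = FALSE, unit = 1),
    waist_rule = list(threshold_male_cm = 103, threshold_female_cm = 89,
                      per_unit_rr = 1.02, unit = 1),
    reference_sbp = reference_sbp
  )
  merge_named <- function(base, override, what) {
    if (is.null(override)) return(base)
    override <- unlist(override)
    bad <- setdiff(names(override), names(base))
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    base[names(override)] <- override
    base
  }
  cfg$lp_deltas <- merge_named(cfg$lp_deltas, lp_deltas, "lp_deltas")
  cfg$rr_multipliers <- merge_named(cfg$rr_multipliers, rr_multipliers,
                                    "rr_multipliers")
  cfg$prior_stroke_percent_points <- merge_named(
    cfg$prior_stroke_percent_points, prior_stroke_percent_points,
    "prior_stroke_percent_points")
  merge_rule <- function(base, override, what) {
    if (is.null(override)) return(base)
    bad <- setdiff(names(override), names(base))
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    modifyList(base, override)
  }
  cfg$whr_rule <- merge_rule(cfg$whr_rule, whr_rule, "whr_rule")
  cfg$bmi_rule <- merge_rule(cfg$bmi_rule, bmi_rule, "bmi_rule")
  cfg$waist_rule <- merge_rule(cfg$waist_rule, waist_rule, "waist_rule")

  if (any(cfg$lp_deltas < 0)) {
    stop("lp_deltas must be non-negative", call. = FALSE)
  }
  if (any(cfg$rr_multipliers < 1)) {
    stop("rr_multipliers must be >= 1", call. = FALSE)
  }
  if (any(cfg$prior_stroke_percent_points < 0)) {
    stop("prior_stroke_percent_points must be non-negative", call. = FALSE)
  }
  thresholds <- c(cfg$whr_rule$threshold_male, cfg$whr_rule$threshold_female,
                  cfg$bmi_rule$threshold_chinese, cfg$bmi_rule$threshold_south_asian,
                  cfg$bmi_rule$threshold_other, cfg$waist_rule$threshold_male_cm,
                  cfg$waist_rule$threshold_female_cm)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (cfg$waist_rule$per_unit_rr < 1 || cfg$bmi_rule$base_rr < 1) {
    stop("relative-risk style terms must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$reference_sbp) || cfg$reference_sbp <= 0) {
    stop("reference_sbp must be positive", call. = FALSE)
  }
  structure(cfg, class = "delta_config")
}

#' @export
print.delta_config <- function(x, ...) {
  cat("<delta_config>\n")
  cat("  lp deltas:", paste(sprintf("%s=%.2f", names(x$lp_deltas), x$lp_deltas),
                            collapse = ", "), "\n")
  cat("  rr multipliers:", paste(sprintf("%s=%.2f", names(x$rr_multipliers),
                                         x$rr_multipliers), collapse = ", "), "\n")
  cat("  prior stroke/TIA: +", x$prior_stroke_percent_points[["5"]],
      " pp (5 yr), +", x$prior_stroke_percent_points[["10"]],
      " pp (10 yr)\n", sep = "")
  invisible(x)
}

#' Load a model configuration from JSON
#'
#' Reads a JSON file with the layout
#' `{model_name, sex_specific: {male: {...}, female: {...}}, deltas: {...}}`
#' where each sex block is a [coefficient_set()] (keys `betas`,
#' `covariate_means`, `baseline_survival`, `provenance`) and `deltas`
#' (optional) overrides the [delta_config()] defaults. Unknown keys are
#' rejected with the offending paths named.
#'
#' @param path path to the JSON file.
#' @return a list of class `"model_config"` with elements `model_name`,
#'   `coefficients` (list with `male` and `female`), `deltas` and
#'   `config_hash` (md5 of the file contents).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed_top <- c("model_name", "sex_specific", "deltas")
  bad <- setdiff(names(raw), allowed_top)
  if (length(bad) > 0L) {
    stop("unknown config key(s): /", paste(bad, collapse = ", /"), call. = FALSE)
  }
  if (is.null(raw$sex_specific$male) || is.null(raw$sex_specific$female)) {
    stop("config must provide /sex_specific/male and /sex_specific/female",
         call. = FALSE)
  }
  parse_sex <- function(block, sex) {
    allowed <- c("betas", "covariate_means", "baseline_survival", "provenance")
    bad <- setdiff(names(block), allowed)
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) under /sex_specific/%s: %s", sex,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    coefficient_set(
      sex = sex,
      betas = block$betas,
      covariate_means = block$covariate_means,
      baseline_survival = block$baseline_survival,
      provenance = if (is.null(block$provenance)) "" else block$provenance
    )
  }
  deltas <- if (is.null(raw$deltas)) {
    delta_config()
  } else {
    allowed <- c("lp_deltas", "rr_multipliers", "prior_stroke_percent_points",
                 "whr_rule", "bmi_rule", "waist_rule", "reference_sbp")
    bad <- setdiff(names(raw$deltas), allowed)
    if (length(bad) > 0L) {
      stop("unknown key(s) under /deltas: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(delta_config, c(
      raw$deltas[setdiff(names(raw$deltas), "reference_sbp")],
      if (!is.null(raw$deltas$reference_sbp))
        list(reference_sbp = raw$deltas$reference_sbp)
    ))
  }
  structure(
    list(
      model_name = if (is.null(raw$model_name)) "unnamed" else raw$model_name,
      coefficients = list(male = parse_sex(raw$sex_specific$male, "male"),
                          female = parse_sex(raw$sex_specific$female, "female")),
      deltas = deltas,
      config_hash = unname(tools::md5sum(path))
    ),
    class = "model_config"
  )
}

#' Default (synthetic stand-in) model configuration
#'
#' Loads the coefficient file shipped with the package,
#' `extdata/fsrs_coefficients_synthetic.json`. The betas, means and
#' baseline survivals in that file are a *synthetic stand-in* with
#' Framingham-like magnitudes: they produce plausible absolute risks and
#' exercise every code path, but are not a verified transcription of any
#' published equation. Replace them with your own coefficient file for
#' substantive use; every exactness guarantee of the add-on deltas is
#' independent of the base coefficients.
#'
#' @return a `"model_config"` list, as from [load_model_config()].
#' @export
default_model_config <- function() {
  path <- system.file("extdata", "fsrs_coefficients_synthetic.json",
                      package = "riskometer", mustWork = TRUE)
  load_model_config(path)
}

# Pick the coefficient set matching a sex from a model_config.
coeffs_for_sex <- function(config, sex) {
  stopifnot(inherits(config, "model_config"))
  config$coefficients[[sex]]
}
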