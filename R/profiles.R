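# Risk-factor profile schema: one row per person, fields mirroring the
# questions a stroke-risk app asks. Booleans are logical; optional
# anthropometrics are NA when unmeasured.

.profile_logical_fields <- c(
  "antihypertensive_treatment", "diabetes", "cvd_history",
  "atrial_fibrillation", "lvh", "family_history_stroke_or_mi",
  "non_caucasian", "poor_diet", "high_alcohol", "low_physical_activity",
  "stress", "previous_stroke_or_tia", "cognitive_problems",
  "memory_problems", "previous_tbi"
)

.profile_numeric_fields <- c("age", "sbp", "whr", "bmi", "waist_circumference_cm")

.profile_fields <- c(
  "age", "sex", "sbp", .profile_logical_fields[1:5], "smoking",
  .profile_logical_fields[6:15], "whr", "bmi", "waist_circumference_cm",
  "ethnic_group"
)

.smoking_levels <- c("never", "ex", "current")
.ethnic_levels <- c("chinese", "south_asian", "other")

#' Build a single risk-factor profile
#'
#' Constructs a one-row data frame describing one person's stroke risk
#' factors. Unspecified binary factors default to `FALSE`, smoking to
#' `"never"`, the optional anthropometrics (waist-to-hip ratio, BMI, waist
#' circumference) to missing, and the ethnic group (used only for the BMI
#' thresholds) to `"other"`.
#'
#' @param age age in years, must be at least 20.
#' @param sex `"male"` or `"female"`.
#' @param sbp systolic blood pressure in mmHg.
#' @param antihypertensive_treatment,diabetes,cvd_history,atrial_fibrillation,lvh
#'   logical flags for the base-model risk factors.
#' @param smoking one of `"never"`, `"ex"`, `"current"`.
#' @param family_history_stroke_or_mi,non_caucasian,poor_diet,high_alcohol,low_physical_activity,stress,previous_stroke_or_tia,cognitive_problems,memory_problems,previous_tbi
#'   logical flags for the add-on risk factors. `memory_problems` means poor
#'   memory *without* cognitive problems; it cannot be `TRUE` together with
#'   `cognitive_problems`.
#' @param whr waist-to-hip ratio (optional).
#' @param bmi body-mass index in kg/m^2 (optional).
#' @param waist_circumference_cm waist circumference in cm (optional).
#' @param ethnic_group `"chinese"`, `"south_asian"` or `"other"`; selects the
#'   BMI threshold in the anthropometric fallback chain.
#'
#' @return a one-row `data.frame` with class `"risk_profile"` prepended.
#' @examples
#' p <- risk_profile(age = 65, sex = "male", sbp = 150, diabetes = TRUE,
#'                   smoking = "current", poor_diet = TRUE)
#' @export
risk_profile <- function(age, sex, sbp,
                         antihypertensive_treatment = FALSE,
                         diabetes = FALSE,
                         cvd_history = FALSE,
                         smoking = "never",
                         atrial_fibrillation = FALSE,
                         lvh = FALSE,
                         family_history_stroke_or_mi = FALSE,
                         non_caucasian = FALSE,
                         poor_diet = FALSE,
                         high_alcohol = FALSE,
                         low_physical_activity = FALSE,
                         stress = FALSE,
                         previous_stroke_or_tia = FALSE,
                         cognitive_problems = FALSE,
                         memory_problems = FALSE,
                         previous_tbi = FALSE,
                         whr = NA_real_,
                         bmi = NA_real_,
                         waist_circumference_cm = NA_real_,
                         ethnic_group = "other") {
  df <- data.frame(
    age = as.numeric(age), sex = as.character(sex), sbp = as.numeric(sbp),
    antihypertensive_treatment = as.logical(antihypertensive_treatment),
    diabetes = as.logical(diabetes),
    cvd_history = as.logical(cvd_history),
    smoking = as.character(smoking),
    atrial_fibrillation = as.logical(atrial_fibrillation),
    lvh = as.logical(lvh),
    family_history_stroke_or_mi = as.logical(family_history_stroke_or_mi),
    non_caucasian = as.logical(non_caucasian),
    poor_diet = as.logical(poor_diet),
    high_alcohol = as.logical(high_alcohol),
    low_physical_activity = as.logical(low_physical_activity),
    stress = as.logical(stress),
    previous_stroke_or_tia = as.logical(previous_stroke_or_tia),
    cognitive_problems = as.logical(cognitive_problems),
    memory_problems = as.logical(memory_problems),
    previous_tbi = as.logical(previous_tbi),
    whr = as.numeric(whr), bmi = as.numeric(bmi),
    waist_circumference_cm = as.numeric(waist_circumference_cm),
    ethnic_group = as.character(ethnic_group),
    stringsAsFactors = FALSE
  )
  problems <- validate_profiles(df)
  if (nrow(problems) > 0L) {
    stop("invalid risk profile: ", paste(problems$message, collapse = "; "),
         call. = FALSE)
  }
  class(df) <- c("risk_profile", class(df))
  df
}

#' Validate a data frame of risk profiles
#'
#' Checks every row of `profiles` against the schema invariants and returns a
#' data frame of problems (zero rows when everything is valid). Missing
#' optional columns are tolerated; missing required columns are a problem for
#' every row.
#'
#' @param profiles a data frame with columns named as in [risk_profile()].
#' @return a `data.frame` with columns `row` and `message`.
#' @export
validate_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  problems <- list()
  note <- function(rows, msg) {
    if (length(rows) > 0L) {
      problems[[length(problems) + 1L]] <<- data.frame(
        row = rows, message = msg, stringsAsFactors = FALSE)
    }
  }
  n <- nrow(profiles)
  required <- c("age", "sex", "sbp")
  for (col in required) {
    if (!col %in% names(profiles)) {
      note(seq_len(n), sprintf("required column '%s' is missing", col))
    }
  }
  unknown <- setdiff(names(profiles),
                     c(.profile_fields, "follow_up_years", "event", "true_risk"))
  if (length(unknown) > 0L) {
    note(seq_len(n), sprintf("unknown column(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  if (length(problems) > 0L) {
    return(do.call(rbind, problems))
  }
  note(which(!is.finite(profiles$age) | profiles$age < 20),
       "age must be a number >= 20")
  note(which(!profiles$sex %in% c("male", "female")),
       "sex must be 'male' or 'female'")
  note(which(!is.finite(profiles$sbp) | profiles$sbp <= 0),
       "sbp must be a positive number")
  if ("smoking" %in% names(profiles)) {
    note(which(!profiles$smoking %in% .smoking_levels),
         "smoking must be one of never/ex/current")
  }
  if ("ethnic_group" %in% names(profiles)) {
    note(which(!is.na(profiles$ethnic_group) &
                 !profiles$ethnic_group %in% .ethnic_levels),
         "ethnic_group must be one of chinese/south_asian/other")
  }
  for (col in intersect(.profile_logical_fields, names(profiles))) {
    v <- profiles[[col]]
    if (!is.logical(v)) {
      ok <- v %in% c(0, 1, NA)
      note(which(!ok), sprintf("%s must be logical or 0/1", col))
    }
    note(which(is.na(v)), sprintf("%s must not be missing", col))
  }
  if (all(c("cognitive_problems", "memory_problems") %in% names(profiles))) {
    both <- which(as.logical(profiles$cognitive_problems) &
                    as.logical(profiles$memory_problems))
    note(both, "cognitive_problems and memory_problems cannot both be TRUE")
  }
  for (col in intersect(c("whr", "bmi", "waist_circumference_cm"),
                        names(profiles))) {
    v <- profiles[[col]]
    note(which(!is.na(v) & v <= 0), sprintf("%s must be positive when present", col))
  }
  if (length(problems) == 0L) {
    return(data.frame(row = integer(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, problems)
  out[order(out$row), , drop = FALSE]
}

# Coerce a partial profile data frame to the full schema, filling defaults.
# Used by the CSV reader and the cohort generator.
complete_profiles <- function(df) {
  defaults <- list(
    smoking = "never", ethnic_group = "other",
    whr = NA_real_, bmi = NA_real_, waist_circumference_cm = NA_real_
  )
  for (col in .profile_logical_fields) defaults[[col]] <- FALSE
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  for (col in .profile_logical_fields) df[[col]] <- as.logical(df[[col]])
  for (col in intersect(c(.profile_numeric_fields, "follow_up_years",
                          "true_risk"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  keep <- c(.profile_fields, intersect(c("follow_up_years", "event", "true_risk"),
                                       names(df)))
  df[, keep, drop = FALSE]
}

# Derived covariate matrix consumed by the base (Framingham-style) model.
# Smoking enters as current-smoker; an ex-smoker column is available for
# coefficient sets that declare one.
derive_covariates <- function(profiles) {
  cbind(
    age = profiles$age,
    sbp = profiles$sbp,
    antihypertensive_treatment = as.numeric(profiles$antihypertensive_treatment),
    diabetes = as.numeric(profiles$diabetes),
    cvd_history = as.numeric(profiles$cvd_history),
    current_smoker = as.numeric(profiles$smoking == "current"),
    ex_smoker = as.numeric(profiles$smoking == "ex"),
    atrial_fibrillation = as.numeric(profiles$atrial_fibrillation),
    lvh = as.numeric(profiles$lvh)
  )
}
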