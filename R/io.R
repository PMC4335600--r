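# Cohort CSV dialect: header row, columns named as the profile fields,
# booleans as 0/1, sex as "male"/"female", missing optionals empty,
# decimal point. Optional outcome columns follow_up_years and event.

csv_columns <- function() c(.profile_fields, "follow_up_years", "event", "true_risk")

#' Write a cohort to CSV
#'
#' @param cohort data frame of profiles (plus optional outcome columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (col in intersect(.profile_logical_fields, names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if ("event" %in% names(df)) df$event <- as.integer(df$event)
  df <- df[, intersect(csv_columns(), names(df)), drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates columns against the profile schema (unknown columns are an
#' error) and every row against the profile invariants. Invalid rows
#' either abort (`on_error = "fail"`) with line numbers, or are dropped
#' with a warning (`on_error = "skip"`).
#'
#' An optional convenience column `drinks_per_day` is accepted and
#' converted to the `high_alcohol` flag using the two-or-more-per-day
#' convention (>= 2).
#'
#' @param path CSV file path.
#' @param on_error `"fail"` or `"skip"`.
#' @return a `data.frame` of validated profiles (plus any outcome columns).
#' @export
read_cohort_csv <- function(path, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in cohort file: ", path, call. = FALSE)
  if ("drinks_per_day" %in% names(df)) {
    message("converting drinks_per_day to high_alcohol with the >= 2 rule")
    df$high_alcohol <- as.integer(df$drinks_per_day >= 2)
    df$drinks_per_day <- NULL
  }
  unknown <- setdiff(names(df), csv_columns())
  if (length(unknown) > 0L) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df <- complete_profiles(df)
  problems <- validate_profiles(df)
  if (nrow(problems) > 0L) {
    msg <- paste(sprintf("line %d: %s", problems$row + 1L, problems$message),
                 collapse = "\n  ")
    if (on_error == "fail") {
      stop("invalid rows in ", path, ":\n  ", msg, call. = FALSE)
    }
    warning("dropped ", length(unique(problems$row)), " invalid row(s):\n  ",
            msg, call. = FALSE)
    df <- df[-unique(problems$row), , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df) == 0L) stop("no valid rows left in ", path, call. = FALSE)
  }
  df
}

# Fixed-precision JSON so identical analyses produce byte-identical
# reports: numbers rendered at 12 significant digits.
report_json <- function(x) {
  jsonlite::toJSON(x, digits = I(12), auto_unbox = TRUE, pretty = TRUE,
                   na = "null")
}

#' Write a validation report (or any result list) to JSON
#'
#' Numbers are rendered at 12 significant digits, making reports
#' byte-identical across reruns with identical inputs and seeds.
#'
#' @param report a `"validation_report"` (or any list of results).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  writeLines(report_json(unclass(report)), path)
  invisible(path)
}
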