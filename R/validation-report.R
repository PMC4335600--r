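# Orchestration: score one or more models on a cohort and assemble the
# full validation battery, sex-stratified by default (pooled behind a
# flag), mirroring how external validations of risk scores are reported.

#' Run the full validation battery on a cohort
#'
#' For every model and horizon, and within each sex stratum (or pooled),
#' computes discrimination (AUROC with DeLong CI, Harrell's C and Somers'
#' D when follow-up times are present, Nagelkerke pseudo R-squared),
#' calibration (Hosmer-Lemeshow over deciles of risk, calibration points),
#' classification performance at accuracy targets, and a high/low
#' cross-tabulation of each model against the first (reference) model
#' using each model's own cut-point at the classification accuracy target.
#' A DeLong paired test against the reference model is included per
#' stratum. Strata without both an event and a non-event have their
#' discrimination cells marked unavailable and the run continues.
#'
#' @param cohort data frame with profile columns plus `event` (0/1) and
#'   optionally `follow_up_years`.
#' @param models character vector of models to score (`"riskometer"`,
#'   `"fsrs"`, `"comparator"`); the first is the reference model.
#' @param config a `"model_config"` shared by the models.
#' @param horizons numeric vector within {5, 10}.
#' @param pooled `FALSE` (default) stratifies by sex.
#' @param accuracy_targets accuracy targets in percent for the threshold
#'   scan.
#' @param classification_target the accuracy target whose threshold defines
#'   the high/low split used in the cross-tabulations (default 80).
#' @param g number of calibration groups (default 10).
#' @param seed recorded in the metadata (the battery itself is
#'   deterministic).
#' @return a list of class `"validation_report"`: `metadata` plus one
#'   entry per model/horizon/stratum with the statistics above.
#' @export
run_validation <- function(cohort, models = c("riskometer", "fsrs"),
                           config = default_model_config(),
                           horizons = 5, pooled = FALSE,
                           accuracy_targets = c(50, 70, 80, 85, 90),
                           classification_target = 80,
                           g = 10, seed = NULL) {
  cohort <- as.data.frame(cohort)
  if (!"event" %in% names(cohort)) {
    stop("cohort must have an 'event' column", call. = FALSE)
  }
  stopifnot(length(models) >= 1L)
  strata <- if (pooled) list(pooled = rep(TRUE, nrow(cohort))) else
    list(male = cohort$sex == "male", female = cohort$sex == "female")
  scored <- list()
  for (m in models) {
    for (h in horizons) {
      scored[[paste(m, h, sep = "_")]] <-
        score_cohort(cohort, model = m, config = config, horizon = h)
    }
  }
  results <- list()
  for (mi in seq_along(models)) {
    m <- models[mi]
    for (h in horizons) {
      risks <- scored[[paste(m, h, sep = "_")]]
      ref_risks <- scored[[paste(models[1L], h, sep = "_")]]
      for (s in names(strata)) {
        idx <- strata[[s]] & !is.na(risks)
        ev <- cohort$event[idx]
        rk <- risks[idx]
        cell <- list(model = m, horizon = h, stratum = s,
                     n = sum(idx), n_events = sum(ev))
        if (sum(ev == 1) >= 2 && sum(ev == 0) >= 2) {
          roc <- delong_ci(rk, ev)
          cell$auroc <- roc$auroc
          cell$auroc_ci <- c(roc$ci_low, roc$ci_high)
          cell$pseudo_r2_pct <- pseudo_r2(rk / 100, ev)
          if ("follow_up_years" %in% names(cohort)) {
            cc <- harrell_c(rk, cohort$follow_up_years[idx], ev)
            cell$c_statistic <- cc$c_statistic
            cell$somers_d <- cc$somers_d
          }
          cal <- tryCatch(hosmer_lemeshow(rk / 100, ev, g = g,
                                          merge_sparse = TRUE),
                          error = function(e) NULL)
          if (!is.null(cal)) {
            cell$hl_chi2 <- cal$hl_chi2
            cell$hl_df <- cal$df
            cell$hl_p <- cal$p_value
            cell$calibration <- cal$groups
          }
          cell$thresholds <- lapply(accuracy_targets, function(t) {
            tp <- tryCatch(threshold_for_accuracy(rk, ev, t),
                           error = function(e) NULL)
            if (is.null(tp)) list(accuracy_target = t, achievable = FALSE)
            else c(unclass(tp), achievable = TRUE)
          })
          if (mi != 1L) {
            rr <- ref_risks[idx]
            cell$delong_vs_reference <-
              delong_paired_test(rk, rr, ev)[c("z", "p_two_sided")]
            thr_m <- tryCatch(
              threshold_for_accuracy(rk, ev, classification_target)$threshold,
              error = function(e) NULL)
            thr_r <- tryCatch(
              threshold_for_accuracy(rr, ev, classification_target)$threshold,
              error = function(e) NULL)
            if (!is.null(thr_m) && !is.null(thr_r)) {
              ct <- cross_tabulate(classify_high_low(rk, thr_m),
                                   classify_high_low(rr, thr_r))
              cell$cross_tab_vs_reference <- ct$counts
            }
          }
        } else {
          cell$unavailable <- "stratum lacks both outcome classes"
        }
        key <- paste(m, h, s, sep = "_")
        if (!is.null(results[[key]])) key <- paste(key, mi, sep = "_")
        results[[key]] <- cell
      }
    }
  }
  structure(
    list(
      metadata = list(
        package_version = as.character(utils::packageVersion("riskometer")),
        models = models, horizons = horizons, pooled = pooled,
        reference_model = models[1L],
        config_name = config$model_name, config_hash = config$config_hash,
        n = nrow(cohort), seed = seed,
        accuracy_targets = accuracy_targets,
        classification_target = classification_target, g = g
      ),
      results = results
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$metadata$n, "subjects;",
      length(x$results), "model x horizon x stratum cells\n")
  for (cell in x$results) {
    if (!is.null(cell$unavailable)) {
      cat(sprintf("  %s %dyr %s: unavailable (%s)\n", cell$model,
                  cell$horizon, cell$stratum, cell$unavailable))
    } else {
      cat(sprintf(
        "  %s %dyr %-6s: AUROC %.3f (%.3f-%.3f)%s  HL p %.3g\n",
        cell$model, cell$horizon, cell$stratum, cell$auroc,
        cell$auroc_ci[1], cell$auroc_ci[2],
        if (!is.null(cell$c_statistic))
          sprintf("  C %.3f D %.3f", cell$c_statistic, cell$somers_d) else "",
        if (!is.null(cell$hl_p)) cell$hl_p else NA))
    }
  }
  invisible(x)
}
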