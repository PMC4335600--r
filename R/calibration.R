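# Calibration (Hosmer-Lemeshow over quantile groups of predicted risk) and
# threshold-based classification (accuracy-targeted cut-points, high/low
# cross-tabulation between two scores).

# Quantile grouping with ties assigned to the lower group. Groups can be
# unequal-sized (or empty, then dropped) under heavy ties.
quantile_groups <- function(pred, g) {
  q <- quantile(pred, probs = seq_len(g - 1) / g, type = 7, names = FALSE)
  grp <- 1L + rowSums(outer(pred, q, ">"))
  match(grp, sort(unique(grp)))              # renumber, dropping empties
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Splits subjects into `g` groups by quantiles of predicted risk and
#' compares observed with expected event counts:
#' \eqn{\chi^2 = \sum_g (O-E)^2/E + (O'-E')^2/E'} over events and
#' non-events, with expected counts from the summed predicted risks.
#'
#' The reference distribution depends on where the predictions came from.
#' This package validates *fixed, externally derived* algorithms, so by
#' default the statistic is referred to \eqn{\chi^2(g)} (`fitted = FALSE`),
#' which is the correct null when no parameter was estimated from the data
#' at hand; `fitted = TRUE` applies the familiar \eqn{g - 2} degrees of
#' freedom appropriate when the risks come from a model fitted to the same
#' data. Simulation under faithful predictions confirms the `g` choice
#' holds the 5% level, while `g - 2` over-rejects (see the package
#' vignette).
#'
#' @param pred_risks predicted risks as fractions in \[0, 1\].
#' @param events 0/1 outcomes.
#' @param g number of groups (default 10, i.e. deciles of risk); requires
#'   `n >= 2 g`.
#' @param merge_sparse when a group has an expected count of zero the test
#'   is undefined; `TRUE` merges such a group into its upper neighbour,
#'   `FALSE` (default) raises an error.
#' @param fitted `FALSE` (default): degrees of freedom = number of groups
#'   (external validation); `TRUE`: groups minus 2 (development data).
#' @return a list of class `"calibration_table"`: per-group table
#'   (`group`, `n`, `mean_pred_pct`, `expected_events`, `observed_events`,
#'   `observed_rate_pct`), plus `hl_chi2`, `df`, `p_value`.
#' @export
hosmer_lemeshow <- function(pred_risks, events, g = 10, merge_sparse = FALSE,
                            fitted = FALSE) {
  if (length(pred_risks) != length(events)) {
    stop("pred_risks and events must have equal length", call. = FALSE)
  }
  if (any(pred_risks < 0 | pred_risks > 1)) {
    stop("pred_risks must be fractions in [0, 1] (divide percents by 100)",
         call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  if (length(pred_risks) < 2 * g) {
    stop("need at least 2 observations per group (n >= 2g)", call. = FALSE)
  }
  grp <- quantile_groups(pred_risks, g)
  agg <- function(grp) {
    data.frame(
      group = sort(unique(grp)),
      n = as.vector(table(grp)),
      expected_events = as.vector(tapply(pred_risks, grp, sum)),
      observed_events = as.vector(tapply(events, grp, sum))
    )
  }
  tab <- agg(grp)
  degenerate <- function(tab) tab$expected_events == 0 |
    (tab$n - tab$expected_events) == 0
  while (any(degenerate(tab))) {
    if (!merge_sparse) {
      stop("group with zero expected events (or non-events); ",
           "set merge_sparse = TRUE to merge", call. = FALSE)
    }
    k <- which(degenerate(tab))[1L]
    target <- if (k < nrow(tab)) tab$group[k + 1L] else tab$group[k - 1L]
    grp[grp == tab$group[k]] <- target
    grp <- match(grp, sort(unique(grp)))
    tab <- agg(grp)
    if (nrow(tab) < 3L) {
      stop("too few groups left after merging", call. = FALSE)
    }
  }
  o <- tab$observed_events
  e <- tab$expected_events
  chi2 <- sum((o - e)^2 / e + ((tab$n - o) - (tab$n - e))^2 / (tab$n - e))
  df <- if (fitted) nrow(tab) - 2L else nrow(tab)
  tab$mean_pred_pct <- 100 * e / tab$n
  tab$observed_rate_pct <- 100 * o / tab$n
  structure(
    list(groups = tab[, c("group", "n", "mean_pred_pct", "expected_events",
                          "observed_events", "observed_rate_pct")],
         hl_chi2 = chi2, df = df,
         p_value = pchisq(chi2, df, lower.tail = FALSE)),
    class = "calibration_table"
  )
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi2 = %.2f, df = %d, p = %.4g\n",
              x$hl_chi2, x$df, x$p_value))
  print(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Calibration points by decile of predicted risk
#'
#' Mean predicted risk versus observed event rate in quantile groups of
#' predicted risk (the data behind a calibration plot).
#'
#' @inheritParams hosmer_lemeshow
#' @return a `data.frame` with `group`, `n`, `mean_pred_pct`,
#'   `observed_rate_pct`.
#' @export
calibration_by_decile <- function(pred_risks, events, g = 10) {
  if (length(pred_risks) < g) stop("need n >= g", call. = FALSE)
  if (any(pred_risks < 0 | pred_risks > 1)) {
    stop("pred_risks must be fractions in [0, 1]", call. = FALSE)
  }
  grp <- quantile_groups(pred_risks, g)
  data.frame(
    group = sort(unique(grp)),
    n = as.vector(table(grp)),
    mean_pred_pct = 100 * as.vector(tapply(pred_risks, grp, mean)),
    observed_rate_pct = 100 * as.vector(tapply(events, grp, mean))
  )
}

#' Classification performance at a fixed threshold
#'
#' Calls a subject high-risk when its predicted risk is greater than or
#' equal to the threshold (the boundary value counts as high) and
#' tabulates the resulting 2x2 confusion matrix.
#'
#' @param pred_risks numeric predicted risks (any units; the threshold must
#'   be in the same units).
#' @param events 0/1 outcomes.
#' @param threshold classification cut-point.
#' @param accuracy_target optional annotation carried into the result.
#' @return a list of class `"threshold_performance"`: `threshold`,
#'   `accuracy_target`, `n_high`, `pct_high`, `sensitivity`, `specificity`,
#'   `accuracy` (all rates in percent).
#' @export
confusion_at_threshold <- function(pred_risks, events, threshold,
                                   accuracy_target = NA_real_) {
  if (length(pred_risks) != length(events)) {
    stop("pred_risks and events must have equal length", call. = FALSE)
  }
  high <- pred_risks >= threshold
  tp <- sum(high & events == 1)
  fp <- sum(high & events == 0)
  fn <- sum(!high & events == 1)
  tn <- sum(!high & events == 0)
  n <- length(events)
  structure(
    list(threshold = threshold, accuracy_target = accuracy_target,
         n_high = tp + fp, pct_high = 100 * (tp + fp) / n,
         sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
         specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
         accuracy = 100 * (tp + tn) / n),
    class = "threshold_performance"
  )
}

#' @export
print.threshold_performance <- function(x, ...) {
  cat(sprintf(
    "threshold %.4g: %d high (%.1f%%), sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
    x$threshold, x$n_high, x$pct_high, x$sensitivity, x$specificity,
    x$accuracy))
  invisible(x)
}

#' Lowest threshold reaching a target accuracy
#'
#' Scans every distinct score as a candidate cut-point and returns the
#' lowest one whose accuracy is at least `target_accuracy` -- i.e. the
#' most sensitive classification subject to the accuracy constraint
#' (`mode = "lowest"`, default). `mode = "closest"` instead returns the
#' cut-point whose accuracy is nearest the target.
#'
#' @inheritParams confusion_at_threshold
#' @param target_accuracy target accuracy in percent (e.g. 80).
#' @param mode `"lowest"` or `"closest"`.
#' @return a `"threshold_performance"`, as from [confusion_at_threshold()].
#' @export
threshold_for_accuracy <- function(pred_risks, events, target_accuracy,
                                   mode = c("lowest", "closest")) {
  mode <- match.arg(mode)
  check_scores_events(pred_risks, events)
  cand <- sort(unique(pred_risks))
  acc <- vapply(cand, function(t) {
    high <- pred_risks >= t
    100 * mean((high & events == 1) | (!high & events == 0))
  }, numeric(1))
  if (mode == "lowest") {
    ok <- which(acc >= target_accuracy)
    if (length(ok) == 0L) {
      stop(sprintf(
        "target accuracy %.1f%% unachievable; maximum achievable is %.1f%%",
        target_accuracy, max(acc)), call. = FALSE)
    }
    pick <- ok[1L]
  } else {
    pick <- which.min(abs(acc - target_accuracy))
  }
  confusion_at_threshold(pred_risks, events, cand[pick],
                         accuracy_target = target_accuracy)
}

#' Classify predictions as high/low risk
#'
#' @param pred_risks numeric predicted risks.
#' @param threshold cut-point in the same units; a prediction equal to the
#'   threshold is classified high.
#' @return character vector of `"high"` / `"low"`.
#' @seealso [default_high_risk_thresholds()] for the shipped defaults.
#' @export
classify_high_low <- function(pred_risks, threshold) {
  ifelse(pred_risks >= threshold, "high", "low")
}

#' Default high-risk thresholds (percent)
#'
#' The published cut-points (selected for 80% accuracy and >80%
#' specificity on the original validation cohorts) separating "high" from
#' "low" risk, per model, sex and horizon. These are descriptive defaults;
#' on a new cohort derive cut-points with [threshold_for_accuracy()].
#'
#' @return a `data.frame` with columns `model`, `sex`, `horizon`,
#'   `threshold`.
#' @export
default_high_risk_thresholds <- function() {
  data.frame(
    model = rep(c("fsrs", "riskometer", "qstroke"), each = 4),
    sex = rep(c("male", "male", "female", "female"), 3),
    horizon = rep(c(5, 10), 6),
    threshold = c(13.0, 32.0, 19.5, 42.0,
                  21.5, 43.0, 22.0, 45.0,
                  8.6, 22.0, 23.0, 48.0)
  )
}

#' Cross-tabulate two high/low classifications
#'
#' @param labels_a,labels_b character vectors of `"high"` / `"low"` of equal
#'   length (e.g. from [classify_high_low()] under two models).
#' @return a list of class `"cross_tab"`: `counts` (a `data.frame` of the
#'   four cells with counts and percents of n) and `n`.
#' @export
cross_tabulate <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  stopifnot(all(labels_a %in% c("high", "low")),
            all(labels_b %in% c("high", "low")))
  n <- length(labels_a)
  cells <- expand.grid(a = c("low", "high"), b = c("low", "high"),
                       stringsAsFactors = FALSE)
  cells$count <- mapply(function(a, b) sum(labels_a == a & labels_b == b),
                        cells$a, cells$b)
  cells$percent <- 100 * cells$count / n
  structure(list(counts = cells, n = n), class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %s/%s: %d (%.2f%%)\n", x$counts$a[i], x$counts$b[i],
                x$counts$count[i], x$counts$percent[i]))
  }
  invisible(x)
}
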