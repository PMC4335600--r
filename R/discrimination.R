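# Discrimination statistics for a risk score against binary or censored
# outcomes. All ties receive 0.5 credit (pair estimators) throughout.

check_scores_events <- function(scores, events, min_each = 1L) {
  if (length(scores) != length(events)) {
    stop("scores and events must have equal length", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("events must be 0/1", call. = FALSE)
  }
  n1 <- sum(events == 1)
  n0 <- sum(events == 0)
  if (n1 < min_each) {
    stop("need at least ", min_each, " event(s); got ", n1, call. = FALSE)
  }
  if (n0 < min_each) {
    stop("need at least ", min_each, " non-event(s); got ", n0, call. = FALSE)
  }
  invisible(list(n1 = n1, n0 = n0))
}

#' ROC curve
#'
#' One point per distinct threshold, in descending score order (tied scores
#' share a point); a subject is called positive when its score is greater
#' than or equal to the threshold. The curve starts at (0, 0) (threshold
#' `Inf`) and ends at (1, 1) (the minimum score, at which everyone is
#' called positive).
#'
#' @param scores numeric predicted risks (any monotone scale).
#' @param events 0/1 outcome indicators; at least one of each class.
#' @return a `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, events) {
  check_scores_events(scores, events)
  n1 <- sum(events == 1)
  n0 <- sum(events == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  e <- events[ord]
  keep <- !duplicated(s)                      # last index of each tie block
  tp <- cumsum(e)
  fp <- cumsum(1 - e)
  block_end <- c(which(keep)[-1] - 1L, length(s))
  data.frame(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp[block_end] / n0),
    tpr = c(0, tp[block_end] / n1)
  )
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Mean over all (event, non-event) pairs of 1 if the event's score is
#' higher, 0.5 on a tie, 0 otherwise. Equals the trapezoidal area of
#' [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return the AUROC as a fraction in \[0, 1\].
#' @export
auroc <- function(scores, events) {
  check_scores_events(scores, events)
  n1 <- sum(events == 1)
  n0 <- sum(events == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[events == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components (placement values) via midranks: V10[i] is
# the placement of event i among non-events, V01[j] of non-event j among
# events (reversed), so mean(V10) == mean(V01) == AUROC.
delong_placements <- function(scores, events) {
  pos <- scores[events == 1]
  neg <- scores[events == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUROC with DeLong confidence interval
#'
#' Variance from the DeLong structural components; normal-approximation
#' interval, truncated to \[0, 1\] (or computed on the logit scale with
#' `scale = "logit"`).
#'
#' @inheritParams roc_curve
#' @param level confidence level, default 0.95.
#' @param scale `"linear"` (truncated) or `"logit"`.
#' @return a list of class `"roc_summary"`: `auroc`, `ci_low`, `ci_high`,
#'   `level`, `variance`, and the `curve` from [roc_curve()].
#' @export
delong_ci <- function(scores, events, level = 0.95,
                      scale = c("linear", "logit")) {
  scale <- match.arg(scale)
  check_scores_events(scores, events, min_each = 2L)
  pl <- delong_placements(scores, events)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  z <- qnorm(1 - (1 - level) / 2)
  auc <- pl$auc
  if (scale == "linear" || auc <= 0 || auc >= 1 || v == 0) {
    lo <- max(0, auc - z * sqrt(v))
    hi <- min(1, auc + z * sqrt(v))
  } else {
    lv <- log(auc / (1 - auc))
    se <- sqrt(v) / (auc * (1 - auc))
    lo <- plogis(lv - z * se)
    hi <- plogis(lv + z * se)
  }
  structure(
    list(auroc = auc, ci_low = lo, ci_high = hi, level = level, variance = v,
         curve = roc_curve(scores, events)),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%.0f%% CI %.3f-%.3f)\n", x$auroc, 100 * x$level,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUROCs of two scores computed on the *same* subjects, using
#' the paired DeLong covariance. Identical or order-equivalent scores give
#' z = 0, p = 1.
#'
#' @param scores_a,scores_b numeric scores for the two models, same subjects.
#' @param events shared 0/1 outcomes.
#' @return a list with `auroc_a`, `auroc_b`, `z`, `p_two_sided`, `variance`.
#' @export
delong_paired_test <- function(scores_a, scores_b, events) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must have equal length", call. = FALSE)
  }
  check_scores_events(scores_a, events, min_each = 2L)
  pa <- delong_placements(scores_a, events)
  pb <- delong_placements(scores_b, events)
  v <- var(pa$v10 - pb$v10) / length(pa$v10) +
    var(pa$v01 - pb$v01) / length(pa$v01)
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- 0
  } else {
    z <- d / sqrt(v)
  }
  list(auroc_a = pa$auc, auroc_b = pb$auc, z = z,
       p_two_sided = if (z == 0) 1 else 2 * pnorm(-abs(z)), variance = v)
}

#' Harrell's concordance for (possibly censored) follow-up data
#'
#' A pair (i, j) is comparable when subject i had an event strictly before
#' subject j's observed time (whether j's time is an event or a censoring
#' time). A comparable pair is concordant when the earlier-event subject has
#' the higher score; score ties earn 0.5. Pairs tied on time with both
#' events are excluded by default (`tied_times = "exclude"`); with
#' `tied_times = "half"` they count as comparable with 0.5 credit.
#' Somers' D is reported as exactly `2 * C - 1`.
#'
#' @param scores numeric risk scores.
#' @param times follow-up times (years), non-negative.
#' @param events 0/1 indicators (1 = stroke at `times`).
#' @param tied_times `"exclude"` or `"half"`.
#' @return a list of class `"concordance_summary"`: `c_statistic`,
#'   `somers_d`, `n_comparable_pairs`.
#' @export
harrell_c <- function(scores, times, events, tied_times = c("exclude", "half")) {
  tied_times <- match.arg(tied_times)
  if (length(unique(c(length(scores), length(times), length(events)))) != 1L) {
    stop("scores, times and events must have equal length", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  conc <- 0
  npairs <- 0
  for (i in which(events == 1)) {
    comp <- times > times[i]
    if (any(comp)) {
      npairs <- npairs + sum(comp)
      conc <- conc + sum(scores[i] > scores[comp]) +
        0.5 * sum(scores[i] == scores[comp])
    }
    if (tied_times == "half") {
      # tied event times: count each unordered pair once, at half credit
      tied <- which(times == times[i] & events == 1)
      tied <- tied[tied > i]
      npairs <- npairs + length(tied)
      conc <- conc + 0.5 * length(tied)
    }
  }
  if (npairs == 0) stop("no comparable pairs", call. = FALSE)
  cstat <- conc / npairs
  structure(
    list(c_statistic = cstat, somers_d = 2 * cstat - 1,
         n_comparable_pairs = npairs),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Harrell's C %.3f  Somers' D %.3f  (%d comparable pairs)\n",
              x$c_statistic, x$somers_d, x$n_comparable_pairs))
  invisible(x)
}

#' Pseudo R-squared of predicted risks against binary outcomes
#'
#' Bernoulli log-likelihood of the outcomes under the predicted risks (L1)
#' versus under the event prevalence (L0). Cox-Snell
#' \eqn{1 - \exp(2 (L_0 - L_1)/n)}; Nagelkerke rescales by its maximum
#' \eqn{1 - \exp(2 L_0 / n)}. No refitting is performed: the risks are taken
#' as the fixed algorithm emits them.
#'
#' @param pred_risks predicted risks as fractions in \[0, 1\]; clipped to
#'   `[clip, 1 - clip]` before taking logs.
#' @param events 0/1 outcomes.
#' @param type `"nagelkerke"` (default) or `"coxsnell"`.
#' @param clip clipping bound for the likelihood, default `1e-12`.
#' @return the pseudo R-squared in percent.
#' @export
pseudo_r2 <- function(pred_risks, events, type = c("nagelkerke", "coxsnell"),
                      clip = 1e-12) {
  type <- match.arg(type)
  if (length(pred_risks) == 0L) stop("zero-length input", call. = FALSE)
  if (length(pred_risks) != length(events)) {
    stop("pred_risks and events must have equal length", call. = FALSE)
  }
  if (any(pred_risks < 0 | pred_risks > 1)) {
    stop("pred_risks must be fractions in [0, 1] (divide percents by 100)",
         call. = FALSE)
  }
  n <- length(events)
  p <- pmin(pmax(pred_risks, clip), 1 - clip)
  p0 <- pmin(pmax(mean(events), clip), 1 - clip)
  l1 <- sum(events * log(p) + (1 - events) * log(1 - p))
  l0 <- sum(events * log(p0) + (1 - events) * log(1 - p0))
  cs <- 1 - exp(2 * (l0 - l1) / n)
  r2 <- switch(type,
               coxsnell = cs,
               nagelkerke = cs / (1 - exp(2 * l0 / n)))
  100 * r2
}
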