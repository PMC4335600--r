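test_that("roc_curve handles separation, ties, and matches a threshold sweep", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_equal(perfect$fpr[1], 0)
  expect_equal(perfect$tpr[1], 0)
  expect_equal(perfect$fpr[nrow(perfect)], 1)
  expect_equal(perfect$tpr[nrow(perfect)], 1)

  flat <- roc_curve(rep(2, 6), c(1, 0, 1, 0, 0, 1))
  expect_equal(nrow(flat), 2L)
  expect_equal(flat$fpr, c(0, 1))
  expect_equal(flat$tpr, c(0, 1))

  withr::with_seed(5, {
    s <- round(runif(10), 1)  # force some ties
    e <- rbinom(10, 1, 0.5)
    e[1] <- 1; e[2] <- 0
  })
  curve <- roc_curve(s, e)
  # oracle: sweep every distinct threshold
  for (i in seq_len(nrow(curve))) {
    t <- curve$threshold[i]
    expect_equal(curve$tpr[i], sum(s >= t & e == 1) / sum(e == 1))
    expect_equal(curve$fpr[i], sum(s >= t & e == 0) / sum(e == 0))
  }
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  expect_error(roc_curve(1:4, rep(1, 4)), "non-event")
})

test_that("auroc equals the all-pairs estimator and the trapezoid area", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(7, {
    for (rep in 1:10) {
      s <- sample(round(runif(12), 1))
      e <- c(1, 0, rbinom(10, 1, 0.4))
      expect_equal(auroc(s, e), auc_pairs_oracle(s, e), tolerance = 1e-12)
      curve <- roc_curve(s, e)
      trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
      expect_equal(auroc(s, e), trap, tolerance = 1e-12)
      # invariance under strictly increasing transforms
      expect_equal(auroc(exp(3 * s), e), auroc(s, e), tolerance = 1e-12)
    }
  })
})

test_that("DeLong variance matches the hand-expanded structural components", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      s <- round(runif(10), 1)
      e <- c(1, 1, 0, 0, rbinom(6, 1, 0.5))
      got <- delong_ci(s, e)
      want <- delong_oracle(s, e)
      expect_equal(got$auroc, want$auc, tolerance = 1e-12)
      expect_equal(got$variance, want$var, tolerance = 1e-12)
      expect_lte(got$ci_low, got$auroc)
      expect_gte(got$ci_high, got$auroc)
      expect_gte(got$ci_low, 0)
      expect_lte(got$ci_high, 1)
    }
  })
  # balanced duplication leaves the point estimate unchanged
  s <- c(0.1, 0.4, 0.35, 0.8, 0.7)
  e <- c(0, 0, 1, 1, 1)
  expect_equal(delong_ci(rep(s, 2), rep(e, 2))$auroc, delong_ci(s, e)$auroc,
               tolerance = 1e-12)
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("paired DeLong test: identity, monotone invariance, permutation oracle", {
  withr::with_seed(9, {
    s <- runif(30)
    e <- c(rep(1, 10), rep(0, 20))
  })
  same <- delong_paired_test(s, s, e)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)
  mono <- delong_paired_test(s, plogis(5 * s - 1), e)
  expect_equal(mono$z, 0)

  # permutation oracle: swap the two models' scores per subject
  withr::with_seed(31, {
    a <- e * 0.8 + runif(30)
    b <- runif(30)
    got <- delong_paired_test(a, b, e)
    d_obs <- auroc(a, e) - auroc(b, e)
    reps <- 10000
    d_perm <- numeric(reps)
    for (k in seq_len(reps)) {
      swap <- runif(30) < 0.5
      a2 <- ifelse(swap, b, a)
      b2 <- ifelse(swap, a, b)
      d_perm[k] <- auroc(a2, e) - auroc(b2, e)
    }
    p_perm <- mean(abs(d_perm) >= abs(d_obs))
    expect_equal(sign(got$z), sign(d_obs))
    expect_lt(abs(got$p_two_sided - p_perm), 0.1)
  })
  expect_error(delong_paired_test(s[-1], s[-1], e), "equal length")
})

test_that("Harrell's C matches exhaustive pair enumeration", {
  # all events, scores perfectly rank-inverse to times
  times <- 1:6
  scores <- 6:1
  ev <- rep(1, 6)
  res <- harrell_c(scores, times, ev)
  expect_equal(res$c_statistic, 1)
  expect_equal(res$somers_d, 1)

  flat <- harrell_c(rep(3, 6), times, ev)
  expect_equal(flat$c_statistic, 0.5)
  expect_equal(flat$somers_d, 0)

  # 8 subjects, 3 censored, fixed by hand
  t8 <- c(1.2, 3.4, 2.2, 5.0, 0.8, 4.1, 2.9, 3.4)
  e8 <- c(1, 0, 1, 1, 0, 1, 1, 0)
  s8 <- c(9, 2, 7, 1, 5, 4, 7, 3)
  got <- harrell_c(s8, t8, e8)
  want <- harrell_oracle(s8, t8, e8)
  expect_equal(got$c_statistic, want$c, tolerance = 1e-12)
  expect_equal(got$n_comparable_pairs, want$pairs)
  expect_equal(got$somers_d, 2 * got$c_statistic - 1)

  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- 40
      tt <- round(rexp(n, 0.3), 1)   # some tied times
      ee <- rbinom(n, 1, 0.6)
      ss <- round(runif(n), 1)
      ee[1] <- 1
      got <- harrell_c(ss, tt, ee)
      want <- harrell_oracle(ss, tt, ee)
      expect_equal(got$c_statistic, want$c, tolerance = 1e-12)
    }
  })
  expect_error(harrell_c(1, 2, 1), "no comparable pairs")
})

test_that("Harrell's C agrees with survival::concordance on tie-free data", {
  withr::with_seed(23, {
    n <- 60
    tt <- rexp(n)
    ee <- rbinom(n, 1, 0.7)
    ss <- rnorm(n)
    ee[1:2] <- c(1, 1)
  })
  got <- harrell_c(ss, tt, ee)
  ref <- survival::concordance(survival::Surv(tt, ee) ~ ss, reverse = TRUE)
  expect_equal(got$c_statistic, unname(ref$concordance), tolerance = 1e-12)
})

test_that("pseudo R2 follows the Bernoulli likelihood construction", {
  withr::with_seed(3, {
    e <- rbinom(20, 1, 0.4)
    e[1] <- 1; e[2] <- 0
    p <- runif(20, 0.05, 0.9)
  })
  # independent hand computation
  n <- 20
  l1 <- sum(e * log(p) + (1 - e) * log(1 - p))
  p0 <- mean(e)
  l0 <- sum(e * log(p0) + (1 - e) * log(1 - p0))
  cs <- 1 - exp(2 * (l0 - l1) / n)
  expect_equal(pseudo_r2(p, e, type = "coxsnell"), 100 * cs, tolerance = 1e-12)
  expect_equal(pseudo_r2(p, e), 100 * cs / (1 - exp(2 * l0 / n)),
               tolerance = 1e-12)

  expect_equal(pseudo_r2(rep(mean(e), 20), e), 0, tolerance = 1e-9)
  expect_equal(pseudo_r2(e, e), 100, tolerance = 1e-6)  # saturated limit
  expect_error(pseudo_r2(numeric(0), numeric(0)), "zero-length")
  expect_error(pseudo_r2(c(5, 40), c(0, 1)), "fractions")
})
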