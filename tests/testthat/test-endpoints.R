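test_that("response rates reproduce exact fractions with valid intervals", {
  resp <- c(rep("CR", 43), rep("PR", 15), rep("SD", 3), rep("PD", 13),
            rep(NA, 2))
  rs <- response_rates(resp)
  expect_equal(rs$n, 76)
  expect_equal(rs$cr_rate, 43 / 76)
  expect_equal(rs$orr, 58 / 76)
  expect_equal(rs$n_missing, 2)
  # interval contains the point estimate, bounds within [0, 1]
  expect_true(rs$cr_ci[1] <= rs$cr_rate && rs$cr_rate <= rs$cr_ci[2])
  expect_true(all(rs$orr_ci >= 0 & rs$orr_ci <= 1))
  # exact interval agrees with binom.test (the Clopper-Pearson reference)
  bt <- stats::binom.test(43, 76)$conf.int
  expect_equal(rs$cr_ci, as.numeric(bt), tolerance = 1e-10)
  # degenerate: no responders
  z <- response_rates(rep("PD", 10))
  expect_equal(z$cr_rate, 0)
  expect_equal(z$cr_ci[1], 0)
  expect_error(response_rates(character()), "no records")
  # Wald interval is centred on the estimate
  w <- response_rates(resp, ci_method = "wald")
  expect_equal(mean(w$cr_ci), w$cr_rate, tolerance = 1e-12)
})

test_that("Clopper-Pearson coverage is at least nominal", {
  # 10,000 replicates at each true p; exact intervals must cover >= 95%
  n <- 76
  for (p in c(0.10, 0.36, 0.56)) {
    set.seed(1000 + round(100 * p))
    x <- stats::rbinom(10000, n, p)
    lo <- ifelse(x == 0, 0, stats::qbeta(0.025, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(0.975, x + 1, n - x))
    covered <- mean(lo <= p & p <= hi)
    expect_gte(covered, 0.95)
    # spot-check the vectorised intervals against response_rates
    rs <- response_rates(c(rep("CR", x[1]), rep("PD", n - x[1])))
    expect_equal(rs$cr_ci, c(lo[1], hi[1]), tolerance = 1e-12)
  }
})

test_that("product-limit estimator matches hand-worked and counting oracles", {
  # all censored: S(t) = 1 everywhere
  km0 <- km_estimate(c(3, 7, 11), c(FALSE, FALSE, FALSE))
  expect_equal(length(km0$time), 0)
  expect_equal(survival_at(km0, 24), 1)
  # three events, no censoring: S = 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(survival_at(km1, 2), 1 / 3)
  expect_equal(survival_at(km1, 2.5), 1 / 3)  # right-continuous step
  expect_equal(survival_at(km1, 0.5), 1)
  # with censoring: against the direct risk-set-counting oracle
  set.seed(88)
  t <- round(rexp(60, 0.08), 1); e <- runif(60) < 0.6
  km <- km_estimate(t, e)
  for (t0 in c(2, 10, 24, 50)) {
    expect_equal(survival_at(km, t0), km_oracle_at(t, e, t0),
                 tolerance = 1e-12)
  }
  # no censoring: KM equals the empirical survival function exactly
  t2 <- sample(1:30, 25, replace = TRUE)
  km2 <- km_estimate(t2, rep(TRUE, 25))
  for (t0 in c(5, 15, 29)) {
    expect_equal(survival_at(km2, t0), mean(t2 > t0), tolerance = 1e-12)
  }
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("KM and Greenwood SE agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(52)
  t <- rexp(80, 0.05); e <- runif(80) < 0.65
  km <- km_estimate(t, e)
  sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1))
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$greenwood_se, sf$std.err, tolerance = 1e-10)
  expect_equal(km$n_risk, sf$n.risk)
})

test_that("log-rank test matches its algebraic and package references", {
  set.seed(19)
  ta <- rexp(30, 0.1); ea <- runif(30) < 0.7
  tb <- rexp(35, 0.2); eb <- runif(35) < 0.7
  lr <- logrank_test(ta, ea, tb, eb)
  # label swap leaves the statistic unchanged
  lr_swap <- logrank_test(tb, eb, ta, ea)
  expect_equal(lr$chi_square, lr_swap$chi_square, tolerance = 1e-12)
  # identical groups give 0 / p = 1
  lr0 <- logrank_test(ta, ea, ta, ea)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  # common rescaling of all times changes nothing
  lr_scaled <- logrank_test(ta * 3.7, ea, tb * 3.7, eb)
  expect_equal(lr$chi_square, lr_scaled$chi_square, tolerance = 1e-12)
  # no events at all: convention 0 / 1
  lrz <- logrank_test(c(1, 2), c(FALSE, FALSE), c(3), c(FALSE))
  expect_equal(lrz$p, 1)
  # single shared event time: the statistic is the uncorrected 2x2
  # Pearson chi-square times (n-1)/n (hypergeometric variance)
  t1 <- c(5, 9, 9, 9); e1 <- c(TRUE, FALSE, FALSE, FALSE)
  t2 <- c(5, 5, 9, 9); e2 <- c(TRUE, TRUE, FALSE, FALSE)
  lr1 <- logrank_test(t1, e1, t2, e2)
  m <- matrix(c(1, 3, 2, 2), 2, byrow = TRUE)
  cs <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(lr1$chi_square, unname(cs$statistic) * 7 / 8,
               tolerance = 1e-10)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~
                             rep(1:2, c(30, 35)))
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)
})

test_that("Cox estimate matches the brute-force partial likelihood", {
  # <= 8 patients, no ties: grid search over the written-out likelihood
  t <- c(2, 4, 5, 7, 9, 12, 15, 20)
  e <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  fit <- cox_univariate(t, e, x)
  expect_equal(fit$log_hr, breslow_grid_mle(t, e, x), tolerance = 1e-3)
  expect_true(fit$converged)
  # invariants: hr > 0, CI = exp(log_hr +/- z se)
  expect_gt(fit$hr, 0)
  z <- stats::qnorm(0.975)
  expect_equal(fit$ci,
               exp(c(fit$log_hr - z * fit$se_log_hr,
                     fit$log_hr + z * fit$se_log_hr)), tolerance = 1e-12)
  # group swap gives the reciprocal hazard ratio
  fit_swap <- cox_univariate(t, e, 1 - x)
  expect_equal(fit_swap$hr, 1 / fit$hr, tolerance = 1e-6)
  expect_error(cox_univariate(t, e, rep(1, 8)), "constant")
  expect_error(cox_univariate(t, rep(FALSE, 8), x), "no events")
})

test_that("Cox agrees with coxph under Breslow ties and flags separation", {
  skip_if_not_installed("survival")
  set.seed(31)
  t <- round(rexp(60, 0.1), 0) + 1; e <- runif(60) < 0.7
  x <- rep(0:1, 30)
  fit <- cox_univariate(t, e, x)
  ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = "breslow")
  expect_equal(fit$log_hr, unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se_log_hr, sqrt(stats::vcov(ref)[1, 1]),
               tolerance = 1e-6)
  # monotone likelihood: all events in one arm, bounded estimate + warning
  ts <- c(1, 2, 3, 10, 11, 12); es <- c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                        FALSE)
  xs <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit_sep <- cox_univariate(ts, es, xs), "monotone")
  expect_true(fit_sep$monotone)
  expect_true(is.finite(fit_sep$hr))
})

test_that("Cox recovers null and non-null hazard ratios from simulation", {
  # null case: covariate independent of the hazard
  set.seed(77)
  n <- 500
  x <- rep(0:1, n / 2)
  t <- rexp(n, 0.1); cens <- runif(n, 5, 40)
  fit0 <- cox_univariate(pmin(t, cens), t <= cens, x)
  expect_true(fit0$ci[1] <= 1 && 1 <= fit0$ci[2])
  # true HR = 3 at n = 2000: recovered within 3 SE
  set.seed(78)
  n <- 2000
  x <- rep(0:1, n / 2)
  rate <- 0.05 * 3^x
  t <- rexp(n, rate); cens <- runif(n, 5, 60)
  fit3 <- cox_univariate(pmin(t, cens), t <= cens, x)
  expect_lt(abs(fit3$log_hr - log(3)), 3 * fit3$se_log_hr)
})

test_that("safety table counts any-grade and grade>=3 per event and arm", {
  ae <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3", "S3", "S4"),
    event = c("neutropenia", "anemia", "neutropenia", "neutropenia",
              "neutropenia", "anemia"),
    grade = c(4, 2, 3, 2, 3, 1),
    arm = c("A", "A", "A", "B", "B", "B"))
  tab <- safety_table(ae, n_patients = c(all = 10, A = 5, B = 5))
  neu <- tab[tab$arm == "all" & tab$event == "neutropenia", ]
  expect_equal(neu$n_any, 3)        # S3's two rows count once
  expect_equal(neu$n_grade3plus, 3)
  expect_equal(neu$rate_any, 0.3)
  arm_a <- tab[tab$arm == "A" & tab$event == "neutropenia", ]
  expect_equal(arm_a$n_any, 2)
  expect_equal(arm_a$rate_any, 0.4)
  expect_error(safety_table(data.frame(sample_id = "S1", event = "x",
                                       grade = 6)), "grade")
  expect_equal(nrow(safety_table(ae[0, ])), 0)
})
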