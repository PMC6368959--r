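# Kaplan-Meier, log-rank, Cox and the proportional-hazards score test

test_that("product-limit estimates match hand computation", {
  all_ev <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all_ev$curve$survival, c(2 / 3, 1 / 3, 0))
  with_cens <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(with_cens$curve$survival, c(2 / 3, 0))
  expect_equal(long_term_estimate(with_cens), 0)
  all_cens <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(all_cens$curve), 0L)
  expect_equal(long_term_estimate(all_cens), 1)
  expect_error(kaplan_meier(numeric(0), numeric(0)),
               class = "curescan_bad_input")
})

test_that("KM with no censoring equals one minus the empirical CDF", {
  set.seed(4)
  tt <- round(rexp(60, 0.3), 2) + 0.01
  km <- kaplan_meier(tt, rep(1, 60))
  for (j in seq_len(nrow(km$curve))) {
    expect_equal(km$curve$survival[j], mean(tt > km$curve$time[j]))
  }
})

test_that("long-term estimate is the plateau at the group's own last follow-up", {
  set.seed(33)
  # last subject is an event -> 0; event-free group -> 1
  expect_equal(long_term_estimate(kaplan_meier(c(2, 5), c(0, 1))), 0)
  expect_equal(long_term_estimate(kaplan_meier(runif(10, 1, 5),
                                               rep(0, 10))), 1)
  # internal fast plateau equals the survfit-based value on random data
  for (i in 1:10) {
    tt <- rexp(40, 0.2); ee <- rbinom(40, 1, 0.5)
    if (!any(ee == 1)) ee[1] <- 1
    expect_equal(long_term_estimate(kaplan_meier(tt, ee)),
                 oracle_km_last(tt, ee))
  }
})

test_that("log-rank statistic matches the hand-computed (O-E)^2/V", {
  fx <- fixture_six()
  lr <- log_rank_test(fx$time, fx$event, fx$group)
  expect_equal(lr$statistic, oracle_logrank2(fx$time, fx$event, fx$group))
  expect_equal(lr$df, 1L)
  # relabeling invariance
  lr2 <- log_rank_test(fx$time, fx$event,
                       ifelse(fx$group == "a", "z", "y"))
  expect_equal(lr2$statistic, lr$statistic)
  # identical groups -> statistic 0, p 1
  same <- log_rank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                        rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_error(log_rank_test(1:3, c(1, 1, 0), rep("a", 3)),
               class = "curescan_bad_input")
})

test_that("complete separation of groups in time is detected by the log-rank test", {
  tt <- c(runif(12, 0, 1), runif(12, 5, 6))
  ev <- c(rep(1, 12), rep(0, 12))
  grp <- rep(c("early", "late"), each = 12)
  expect_lt(log_rank_test(tt, ev, grp)$p_value, 0.05)
})

test_that("Cox coefficient is consistent for a two-sample exponential contrast", {
  set.seed(210)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.5 * 3^x)            # rate ratio 3, no censoring
  cf <- cox_fit(tt, rep(1, n), data.frame(x = x))
  se <- cf$terms$std_error[1]
  expect_lt(abs(cf$terms$estimate[1] - log(3)), 3 * se)
  expect_true(cf$converged)
  expect_false(cf$monotone_likelihood)
  expect_gte(cf$loglik[2], cf$loglik[1])
})

test_that("doubling a dataset keeps the Breslow coefficient and shrinks its SE by sqrt(2)", {
  set.seed(11)
  n <- 150
  x <- rnorm(n)
  tt <- rexp(n, 0.2 * exp(0.4 * x)); ee <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(tt, ee, data.frame(x = x), ties = "breslow")
  f2 <- cox_fit(c(tt, tt), c(ee, ee), data.frame(x = c(x, x)),
                ties = "breslow")
  expect_equal(f2$terms$estimate, f1$terms$estimate, tolerance = 1e-6)
  expect_equal(f2$terms$std_error, f1$terms$std_error / sqrt(2),
               tolerance = 1e-6)
})

test_that("degenerate Cox inputs raise distinct signals", {
  expect_error(cox_fit(1:4, rep(0, 4), data.frame(x = rnorm(4))),
               class = "curescan_no_events")
  set.seed(2)
  x <- rnorm(30)
  tt <- rexp(30); ee <- rbinom(30, 1, 0.7)
  expect_error(cox_fit(tt, ee, data.frame(a = x, b = 2 * x)),
               class = "curescan_collinear")
  # all events in one group precede the other group's: monotone likelihood
  tt2 <- c(runif(15, 0, 1), runif(15, 2, 3))
  g <- rep(c(1, 0), each = 15)
  f <- cox_fit(tt2, rep(1, 30), data.frame(g = g))
  expect_true(f$monotone_likelihood)
})

test_that("two-group log-rank agrees with the Cox score test", {
  set.seed(61)
  n <- 500
  x <- rbinom(n, 1, 0.4)
  tt <- rexp(n, 0.3 * exp(0.3 * x)); ee <- rbinom(n, 1, 0.85)
  lr <- log_rank_test(tt, ee, x)
  cf <- cox_fit(tt, ee, data.frame(x = x), ties = "breslow")
  sc <- cf$coxph$score
  expect_lt(abs(lr$p_value - stats::pchisq(sc, 1, lower.tail = FALSE)),
            0.01)
})

test_that("the PH score statistic equals an independent evaluation of the residual algebra", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  tt <- rexp(n, 0.2 * exp(0.5 * x)); cc <- runif(n, 0, 8)
  ee <- as.numeric(tt <= cc); tt <- pmin(tt, cc)
  cf <- cox_fit(tt, ee, data.frame(x = x), ties = "breslow")
  pt <- ph_score_test(cf, transform = "identity")
  expect_equal(pt$statistic[1],
               oracle_ph_score(tt, ee, x, cf$coefficients), tolerance = 1e-8)
  expect_equal(pt$term, c("x", "GLOBAL"))
  expect_true(all(pt$statistic >= 0))
  expect_true(all(pt$p_value > 0 & pt$p_value <= 1))
})

test_that("a hazard ratio crossing 1 in time is rejected by the PH test", {
  set.seed(40)
  rejections <- 0L
  for (r in 1:20) {
    n <- 379
    g <- rbinom(n, 1, 0.3)
    # exposed: fast early hazard, then none (time-reversing effect)
    t0 <- rexp(n, 0.15)
    t1 <- ifelse(runif(n) < 0.5, rexp(n, 2), 8 + rexp(n, 0.02))
    tt <- ifelse(g == 1, t1, t0)
    cc <- runif(n, 6, 10)
    ee <- as.numeric(tt <= cc); tt <- pmin(tt, cc)
    cf <- cox_fit(tt, ee, data.frame(g = g))
    pt <- ph_score_test(cf)
    rejections <- rejections + (pt$p_value[1] < 0.05)
  }
  expect_gt(rejections, 10)
})
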