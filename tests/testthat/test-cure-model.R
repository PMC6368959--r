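# mixture cure model: E/M steps, observed likelihood, EM fit, bootstrap

sim_binary_cure <- function(n, or = 1, hr = 1, seed = 1,
                            base_pi = 0.35) {
  spec <- cohort_spec(
    n = n, maf = c(g = 0.0), covariates = list(grp = c(a = 0.5, b = 0.5)),
    incidence_intercept = qlogis(base_pi),
    incidence_covariate = list(grp = c(b = log(or))),
    latency_covariate = list(grp = c(b = log(hr)))
  )
  co <- simulate_cohort(spec, seed = seed)
  dplyr::mutate(co$clinical, x = as.numeric(.data$grp == "b"))
}

test_that("the E-step weights follow the posterior susceptibility formula", {
  expect_equal(cure_e_step(1, 0.2, 0.9), 1)           # events are susceptible
  expect_equal(cure_e_step(0, 0.5, 0.5), 1 / 3)       # direct formula
  expect_equal(cure_e_step(0, 0.7, 0), 0)             # zero-tail limit
  expect_equal(cure_e_step(c(0, 1), c(0.3, 0.3), c(0.25, 1)),
               c(0.3 * 0.25 / (0.7 + 0.3 * 0.25), 1))
  expect_error(cure_e_step(0, NaN, 0.5), class = "curescan_nonfinite")
})

test_that("with all weights 1 the latency update equals a plain Cox fit", {
  set.seed(14)
  n <- 200
  x <- cbind(g = rbinom(n, 1, 0.4))
  tt <- rexp(n, 0.2 * exp(0.6 * x[, 1])); ee <- rbinom(n, 1, 0.8)
  # all-one weights drive the incidence intercept to +infinity; it must
  # be capped with a warning, and the latency update must reduce to Cox
  expect_warning(ms <- cure_m_step(rep(1, n), tt, ee, Z = cbind(1, x),
                                   X = x),
                 "capped")
  cf <- cox_fit(tt, ee, as.data.frame(x), ties = "breslow")
  expect_equal(unname(ms$latency_coefs), unname(cf$coefficients),
               tolerance = 1e-6)
  expect_equal(max(abs(ms$incidence_coefs)), 15)
  expect_error(cure_m_step(rep(0, n), tt, ee, cbind(1, x), x),
               class = "curescan_bad_input")
  expect_error(cure_m_step(rep(1, n), tt, rep(0, n), cbind(1, x), x),
               class = "curescan_no_events")
  expect_error(cure_m_step(rep(1, n), tt, ee, cbind(1, x, x), cbind(x)),
               class = "curescan_collinear")
})

test_that("the M-step maximizes the weighted complete-data objective", {
  set.seed(25)
  n <- 120
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  tt <- rexp(n, 0.3 * exp(0.4 * X[, 1])); ee <- rbinom(n, 1, 0.75)
  w <- ifelse(ee == 1, 1, runif(n, 0.1, 0.9))
  ms <- cure_m_step(w, tt, ee, Z = cbind(1, X), X = X)
  # latency oracle: direct maximization of the weighted Breslow partial
  # log-likelihood (log-weights as offsets)
  wplik <- function(beta) {
    eta <- as.vector(X %*% beta) + log(w)
    s <- 0
    for (i in which(ee == 1)) {
      rs <- tt >= tt[i]
      s <- s + eta[i] - log(sum(exp(eta[rs])))
    }
    -s
  }
  opt_lat <- optim(c(0, 0), wplik, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(ms$latency_coefs), opt_lat$par, tolerance = 1e-4)
  # incidence oracle: direct maximization of the weighted Bernoulli
  # log-likelihood
  wbern <- function(b) {
    p <- plogis(as.vector(cbind(1, X) %*% b))
    -sum(w * log(p) + (1 - w) * log(1 - p))
  }
  opt_inc <- optim(c(0, 0, 0), wbern, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(ms$incidence_coefs), opt_inc$par, tolerance = 1e-4)
})

test_that("the observed log-likelihood equals direct summation on a 5-patient fixture", {
  tt <- c(1, 2, 3, 4, 6)
  ee <- c(1, 0, 1, 0, 0)
  Z <- cbind(1, c(0, 1, 1, 0, 1))
  X <- cbind(g = c(0, 1, 1, 0, 1))
  b <- c(-0.4, 0.8); beta <- 0.5
  baseline <- tibble::tibble(time = c(1, 3), hazard = c(0.2, 0.35))
  got <- cure_loglik(tt, ee, Z, X, b, beta, baseline)
  # direct per-patient evaluation
  pi_i <- plogis(Z %*% b)[, 1]
  H <- function(t) 0.2 * (t >= 1) + 0.35 * (t >= 3)
  exb <- exp(X[, 1] * beta)
  Su <- exp(-vapply(tt, H, 1) * exb)
  Su[tt > 3] <- 0
  h <- c(0.2, NA, 0.35, NA, NA)
  want <- log(pi_i[1] * h[1] * exb[1] * Su[1]) +
    log(1 - pi_i[2] + pi_i[2] * Su[2]) +
    log(pi_i[3] * h[3] * exb[3] * Su[3]) +
    log(1 - pi_i[4] + pi_i[4] * Su[4]) +
    log(1 - pi_i[5] + pi_i[5] * Su[5])
  expect_equal(got, want)
})

test_that("EM ascends the observed likelihood and nesting never hurts it", {
  for (s in 1:5) {
    dat <- sim_binary_cure(250, or = 1.5, hr = 2, seed = s)
    f1 <- fit_mixture_cure(dat, time_years, event, incidence = ~ x,
                           latency = ~ x)
    expect_true(all(diff(f1$loglik_trace) > -1e-8))
    f0 <- fit_mixture_cure(dat, time_years, event)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
    # zero-tail: weights for subjects censored past the last event are 0
    late <- dat$event == 0 & dat$time_years > f1$tmax_event
    if (any(late)) expect_true(all(f1$weights[late] == 0))
    expect_true(all(f1$weights[dat$event == 1] == 1))
  }
})

test_that("a fitted model is an EM fixed point", {
  dat <- sim_binary_cure(300, or = 2, hr = 2, seed = 7)
  fit <- fit_mixture_cure(dat, time_years, event, incidence = ~ x,
                          latency = ~ x, tol = 1e-9)
  md <- fit$model_data
  ms <- cure_m_step(fit$weights, md$time, md$event, md$Z, md$X)
  ll2 <- cure_loglik(md$time, md$event, md$Z, md$X,
                     ms$incidence_coefs, ms$latency_coefs, ms$baseline)
  expect_lt(abs(ll2 - fit$loglik), 1e-5)
})

test_that("intercept-only incidence recovers the generating cure fraction", {
  # susceptibility 0.29 at the reference cohort scale
  ests <- vapply(1:12, function(s) {
    co <- simulate_cohort(cohort_spec(n = 379), seed = 400 + s)
    f <- fit_mixture_cure(co$clinical, time_years, event)
    plogis(f$incidence$estimate[1])
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.29), 3 * mc_se + 0.01)
})

test_that("identifiability and degenerate inputs are reported", {
  set.seed(3)
  tt <- rexp(50, 0.5); ee <- rep(1L, 50)  # everyone events
  dat <- tibble::tibble(time_years = tt, event = ee)
  expect_warning(fit_mixture_cure(dat, time_years, event),
                 "weakly identified")
  expect_error(
    fit_mixture_cure(tibble::tibble(time_years = rexp(20), event = 0L),
                     time_years, event),
    class = "curescan_no_events")
})

test_that("bootstrap intervals are seed-deterministic and cover a null effect", {
  dat <- sim_binary_cure(200, or = 1, hr = 1, seed = 42)
  fit <- fit_mixture_cure(dat, time_years, event, incidence = ~ x,
                          latency = ~ x)
  b1 <- cure_se(fit, n_boot = 49, seed = 9)
  b2 <- cure_se(fit, n_boot = 49, seed = 9)
  expect_identical(b1$incidence, b2$incidence)
  expect_identical(b1$latency, b2$latency)
  b3 <- cure_se(fit, n_boot = 49, seed = 10)
  expect_false(identical(b3$latency$conf_low, b1$latency$conf_low))
  # reduced-scale coverage: the 95% interval for the null latency effect
  covered <- 0L
  for (r in 1:20) {
    d <- sim_binary_cure(200, or = 1, hr = 1, seed = 100 + r)
    f <- fit_mixture_cure(d, time_years, event, incidence = ~ x,
                          latency = ~ x, se_method = "bootstrap",
                          n_boot = 39, seed = r)
    covered <- covered +
      (f$latency$conf_low[1] <= 1 && f$latency$conf_high[1] >= 1)
  }
  expect_gte(covered, 16L)   # nominal 95%, wide Monte-Carlo slack
})

test_that("the Weibull latency cross-check recovers its generating model", {
  dat <- sim_binary_cure(800, or = 1.8, hr = 2.5, seed = 77)
  fw <- fit_mixture_cure(dat, time_years, event, incidence = ~ x,
                         latency = ~ x, latency_form = "weibull",
                         se_method = "hessian")
  fs <- fit_mixture_cure(dat, time_years, event, incidence = ~ x,
                         latency = ~ x)
  expect_equal(fw$flags$weibull$shape, 1.2, tolerance = 0.25)
  # the two latency estimates agree within joint uncertainty
  expect_lt(abs(fw$latency$estimate[1] - fs$latency$estimate[1]), 0.35)
  expect_true(all(is.finite(fw$latency$std_error)))
  expect_true(all(fw$latency$conf_low < fw$latency$conf_high))
  # hessian SEs are refused for the semiparametric form
  expect_error(cure_se(fs, method = "hessian"),
               class = "curescan_bad_input")
})
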