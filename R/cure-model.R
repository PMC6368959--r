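# Semiparametric mixture cure model
#
# Population survival decomposes as
#   S_pop(t | z, x) = 1 - pi(z) + pi(z) * S_u(t | x),
# where pi(z) = expit(b'z) is the probability of being susceptible
# (incidence component, reported as odds ratios) and S_u the survival of
# susceptibles (latency component, proportional hazards with a
# nonparametric Breslow baseline, reported as hazard ratios). The cure
# fraction is identified through the zero-tail constraint: S_u is set to
# exactly 0 beyond the largest observed event time, so late censored
# subjects are cured with certainty.

# ---- EM engine (internal) -------------------------------------------------

# time/event/Z/X in caller order; returns everything in caller order.
cure_em_engine <- function(time, event, Z, X,
                           ties = "breslow", tol = 1e-6, max_iter = 500L,
                           coef_cap = 15) {
  n <- length(time)
  if (sum(event) < 1) stop_curescan("no events", "curescan_no_events")
  if (n < 2L) stop_curescan("need >= 2 subjects", "curescan_bad_input")
  storage.mode(Z) <- "double"; storage.mode(X) <- "double"

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  Z_s <- Z[ord, , drop = FALSE]; X_s <- X[ord, , drop = FALSE]
  tmax_ev <- max(t_s[e_s == 1])
  identifiable <- any(e_s == 0 & t_s > tmax_ev)

  uev <- unique(t_s[e_s == 1])
  d <- as.numeric(table(factor(t_s[e_s == 1], levels = uev)))
  first_at_risk <- findInterval(uev, t_s, left.open = TRUE) + 1L
  n_ev_le <- findInterval(t_s, uev)          # event times <= own time
  ev_idx <- match(t_s[e_s == 1], uev)        # own event-time slot

  has_x <- ncol(X_s) > 0L
  w <- e_s + (1 - e_s) * mean(e_s)
  w[e_s == 0 & t_s > tmax_ev] <- 0
  b <- rep(0, ncol(Z_s)); beta <- rep(0, max(ncol(X_s), 0L))
  ll_old <- -Inf; ll_trace <- numeric(0)
  separation <- FALSE; latency_failed <- FALSE; converged <- FALSE
  it <- 0L

  repeat {
    it <- it + 1L
    # --- M-step: incidence (weighted logistic with fractional responses)
    gf <- suppressWarnings(glm.fit(Z_s, w, family = quasibinomial()))
    b <- gf$coefficients
    if (any(!is.finite(b)) || any(abs(b) > coef_cap)) {
      b[!is.finite(b)] <- sign(b[!is.finite(b)]) * coef_cap
      b <- pmin(pmax(b, -coef_cap), coef_cap)
      separation <- TRUE
    }
    pi_s <- as.vector(plogis(Z_s %*% b))

    # --- M-step: latency (partial likelihood with log-weight offset;
    #     subjects with w = 0 leave the risk set)
    if (has_x) {
      keep <- w > 0
      cf <- tryCatch(
        suppressWarnings(survival::coxph.fit(
          X_s[keep, , drop = FALSE],
          survival::Surv(t_s[keep], e_s[keep]),
          strata = NULL, offset = log(w[keep]), init = beta,
          control = survival::coxph.control(), weights = NULL,
          method = ties, rownames = NULL)),
        error = function(e) NULL)
      if (is.null(cf) || any(!is.finite(cf$coefficients))) {
        latency_failed <- TRUE
        break
      }
      beta <- cf$coefficients
      exb <- exp(as.vector(X_s %*% beta))
    } else {
      exb <- rep(1, n)
    }

    # --- M-step: weighted Breslow baseline hazard, zero tail
    r <- w * exb
    denom <- rev(cumsum(rev(r)))[first_at_risk]
    h0 <- d / denom
    H0 <- cumsum(h0)
    H0_i <- c(0, H0)[n_ev_le + 1L]
    Su <- exp(-H0_i * exb)
    Su[t_s > tmax_ev] <- 0

    # --- observed-data log-likelihood at the updated parameters
    ll_terms <- numeric(n)
    ev <- e_s == 1
    ll_terms[ev] <- log(pi_s[ev]) + log(h0[ev_idx]) + log(exb[ev]) -
      H0_i[ev] * exb[ev]
    ll_terms[!ev] <- log(pmax(1 - pi_s[!ev] + pi_s[!ev] * Su[!ev], 1e-300))
    ll <- sum(ll_terms)
    if (!is.finite(ll)) {
      stop_curescan(paste0(
        "non-finite observed log-likelihood; incidence = ",
        paste(signif(b, 4), collapse = ","), "; latency = ",
        paste(signif(beta, 4), collapse = ",")), "curescan_nonfinite")
    }
    ll_trace <- c(ll_trace, ll)

    # --- E-step
    w <- e_s + (1 - e_s) * pi_s * Su / pmax(1 - pi_s + pi_s * Su, 1e-300)
    w[e_s == 0 & t_s > tmax_ev] <- 0

    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }

  inv <- order(ord)
  list(
    incidence_coefs = setNames(b, colnames(Z)),
    latency_coefs = if (has_x) setNames(beta, colnames(X)) else numeric(0),
    baseline = tibble::tibble(time = uev, hazard = h0, cum_hazard = H0,
                              survival = exp(-H0)),
    tmax_event = tmax_ev,
    loglik = if (length(ll_trace)) ll_trace[length(ll_trace)] else NA_real_,
    loglik_trace = ll_trace,
    em_iterations = it,
    converged = converged && !latency_failed,
    flags = list(separation = separation, latency_failed = latency_failed,
                 identifiable = identifiable),
    weights = w[inv], susceptibility = pi_s[inv], survival_u = Su[inv],
    n = n, n_event = sum(event)
  )
}

# ---- exported E/M steps ---------------------------------------------------

#' E-step of the mixture cure EM
#'
#' Posterior probability of being susceptible. Subjects with the event
#' are susceptible with certainty (weight 1); censored subjects get
#' `pi * S_u / (1 - pi + pi * S_u)` evaluated at their censoring time.
#' Under the zero-tail constraint, `S_u = 0` past the last event time,
#' so late censored subjects get weight exactly 0.
#'
#' @param event 0/1 indicators.
#' @param susceptibility Per-subject `pi(z)` in (0, 1).
#' @param survival_u Per-subject susceptible survival `S_u(t | x)` at the
#'   subject's own time.
#' @return Weights in `[0, 1]`.
#' @examples
#' cure_e_step(event = 0, susceptibility = 0.5, survival_u = 0.5)  # 1/3
#' @export
cure_e_step <- function(event, susceptibility, survival_u) {
  if (any(!is.finite(susceptibility)) || any(!is.finite(survival_u))) {
    stop_curescan("non-finite E-step inputs", "curescan_nonfinite")
  }
  denom <- 1 - susceptibility + susceptibility * survival_u
  w <- event + (1 - event) * susceptibility * survival_u / pmax(denom, 1e-300)
  pmin(pmax(w, 0), 1)
}

#' M-step of the mixture cure EM
#'
#' One maximization pass given susceptibility weights: logistic
#' regression of the fractional weights on the incidence design, a
#' weighted Cox partial-likelihood update of the latency coefficients
#' (the log-weight enters as an offset, so zero-weight subjects leave the
#' risk set), and a weighted Breslow baseline-hazard update with the
#' zero-tail constraint.
#'
#' @param weights Susceptibility weights in `[0, 1]` (1 for events).
#' @param time,event Follow-up times and 0/1 indicators.
#' @param Z Incidence design matrix including an intercept column.
#' @param X Latency design matrix (no intercept; may have 0 columns).
#' @param ties Tie method for the latency partial likelihood.
#' @return List with `incidence_coefs`, `latency_coefs` and `baseline`
#'   (tibble of `time`, `hazard`, `cum_hazard`, `survival`).
#' @export
cure_m_step <- function(weights, time, event, Z, X, ties = "breslow") {
  if (all(weights == 0)) stop_curescan("degenerate weights (all zero)",
                                       "curescan_bad_input")
  if (sum(event) < 1) stop_curescan("no events", "curescan_no_events")
  Z <- as.matrix(Z); X <- as.matrix(X)
  storage.mode(Z) <- "double"; storage.mode(X) <- "double"
  if (qr(Z)$rank < ncol(Z) ||
      (ncol(X) > 0 && qr(cbind(X))$rank < ncol(X))) {
    stop_curescan("collinear design", "curescan_collinear")
  }
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; w_s <- weights[ord]
  Z_s <- Z[ord, , drop = FALSE]; X_s <- X[ord, , drop = FALSE]
  gf <- suppressWarnings(glm.fit(Z_s, w_s, family = quasibinomial()))
  b <- pmin(pmax(gf$coefficients, -15), 15)
  if (any(abs(gf$coefficients) > 15, na.rm = TRUE) ||
      any(!is.finite(gf$coefficients))) {
    b[!is.finite(gf$coefficients)] <- 15
    warning("incidence coefficients capped at |b| = 15 (separation)")
  }
  if (ncol(X_s) > 0) {
    keep <- w_s > 0
    cf <- suppressWarnings(survival::coxph.fit(
      X_s[keep, , drop = FALSE], survival::Surv(t_s[keep], e_s[keep]),
      strata = NULL, offset = log(w_s[keep]), init = rep(0, ncol(X_s)),
      control = survival::coxph.control(), weights = NULL,
      method = ties, rownames = NULL))
    beta <- cf$coefficients
    exb <- exp(as.vector(X_s %*% beta))
  } else {
    beta <- numeric(0); exb <- rep(1, length(t_s))
  }
  uev <- unique(t_s[e_s == 1])
  d <- as.numeric(table(factor(t_s[e_s == 1], levels = uev)))
  first_at_risk <- findInterval(uev, t_s, left.open = TRUE) + 1L
  r <- w_s * exb
  denom <- rev(cumsum(rev(r)))[first_at_risk]
  h0 <- d / denom
  list(incidence_coefs = setNames(b, colnames(Z)),
       latency_coefs = setNames(beta, colnames(X)),
       baseline = tibble::tibble(time = uev, hazard = h0,
                                 cum_hazard = cumsum(h0),
                                 survival = exp(-cumsum(h0))))
}

#' Observed-data log-likelihood of a mixture cure parameter set
#'
#' Sum over patients of
#' `log( [pi h_u S_u]^event * [1 - pi + pi S_u]^(1 - event) )` with a
#' discrete baseline hazard and the zero-tail constraint (`S_u = 0`
#' beyond the last baseline event time).
#'
#' @param time,event Follow-up data.
#' @param Z,X Incidence (with intercept) and latency designs.
#' @param incidence_coefs,latency_coefs Coefficient vectors.
#' @param baseline Tibble with `time` and `hazard` at event times.
#' @return Scalar log-likelihood.
#' @export
cure_loglik <- function(time, event, Z, X, incidence_coefs, latency_coefs,
                        baseline) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  pi_i <- as.vector(plogis(Z %*% incidence_coefs))
  exb <- if (ncol(X) > 0) exp(as.vector(X %*% latency_coefs)) else
    rep(1, length(time))
  bt <- baseline$time; bh <- baseline$hazard
  o <- order(bt); bt <- bt[o]; bh <- bh[o]
  H0 <- cumsum(bh)
  H0_i <- c(0, H0)[findInterval(time, bt) + 1L]
  Su <- exp(-H0_i * exb)
  Su[time > max(bt)] <- 0
  h_idx <- match(time, bt)
  ll <- numeric(length(time))
  ev <- event == 1
  if (any(ev & is.na(h_idx))) {
    stop_curescan("event time absent from baseline hazard",
                  "curescan_bad_input")
  }
  ll[ev] <- log(pi_i[ev]) + log(bh[h_idx[ev]]) + log(exb[ev]) -
    H0_i[ev] * exb[ev]
  ll[!ev] <- log(pmax(1 - pi_i[!ev] + pi_i[!ev] * Su[!ev], 1e-300))
  out <- sum(ll)
  if (!is.finite(out)) stop_curescan("non-finite log-likelihood",
                                     "curescan_nonfinite")
  out
}

# ---- user-facing fit ------------------------------------------------------

#' Fit a mixture cure model
#'
#' Logistic incidence (probability of being susceptible, odds ratios)
#' and proportional-hazards latency among susceptibles (hazard ratios),
#' fitted by EM with a nonparametric Breslow baseline under the
#' zero-tail constraint. Convergence is declared when the observed-data
#' log-likelihood changes by less than `tol`; non-convergence is
#' recorded on the fit, not raised. A Weibull parametric latency is
#' available as a cross-check (`latency_form = "weibull"`, fitted by
#' direct likelihood maximization).
#'
#' @param data Data frame with one row per patient.
#' @param time,event Columns of `data` (tidy-eval) giving follow-up in
#'   years and the 0/1 indicator.
#' @param incidence One-sided formula for the incidence component; an
#'   intercept is required (default `~ 1`, a pure cure-fraction model).
#' @param latency One-sided formula for the latency component (default
#'   `~ 1`, no covariates: baseline hazard only).
#' @param latency_form `"semiparametric"` (default) or `"weibull"`.
#' @param ties Tie method inside the EM latency update. `"breslow"`
#'   (default) keeps the M-step exactly aligned with the observed-data
#'   likelihood whose monotone ascent the EM guarantees.
#' @param tol Absolute change in observed log-likelihood declaring
#'   convergence.
#' @param max_iter Maximum EM iterations.
#' @param se_method `"none"` (default; point estimates and LR tests
#'   only), `"bootstrap"` (percentile CIs and Wald-from-bootstrap-SE
#'   p-values), or `"hessian"` (Weibull latency only).
#' @param n_boot,seed Bootstrap controls (see [cure_se()]).
#' @return Object of class `cure_fit`; see [tidy.cure_fit()] and
#'   [glance.cure_fit()].
#' @examples
#' spec <- cohort_spec(n = 200, maf = c(rs1 = 0.3),
#'                     incidence_snp = c(rs1 = log(2)))
#' cohort <- simulate_cohort(spec, seed = 1)
#' dat <- dplyr::mutate(cohort$clinical,
#'                      g = as.integer(cohort$genotypes$codes["rs1", ]))
#' fit <- fit_mixture_cure(dat, time_years, event,
#'                         incidence = ~ g, latency = ~ g)
#' tidy(fit)
#' @export
fit_mixture_cure <- function(data, time, event, incidence = ~ 1,
                             latency = ~ 1,
                             latency_form = c("semiparametric", "weibull"),
                             ties = c("breslow", "efron"),
                             tol = 1e-6, max_iter = 500L,
                             se_method = c("none", "bootstrap", "hessian"),
                             n_boot = 200L, seed = NULL) {
  latency_form <- match.arg(latency_form)
  ties <- match.arg(ties)
  se_method <- match.arg(se_method)
  data <- tibble::as_tibble(data)
  tt <- rlang::eval_tidy(rlang::enquo(time), data)
  ee <- rlang::eval_tidy(rlang::enquo(event), data)

  Z <- model.matrix(incidence, data)
  if (!"(Intercept)" %in% colnames(Z)) {
    stop_curescan("incidence design must include an intercept",
                  "curescan_bad_input")
  }
  X <- model.matrix(latency, data)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]

  ok <- !is.na(tt) & !is.na(ee) & complete.cases(Z) & complete.cases(X)
  n_dropped <- sum(!ok)
  tt <- tt[ok]; ee <- ee[ok]
  Z <- Z[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]

  if (latency_form == "weibull") {
    eng <- cure_weibull_engine(tt, ee, Z, X)
  } else {
    eng <- cure_em_engine(tt, ee, Z, X, ties = ties, tol = tol,
                          max_iter = max_iter)
    if (!eng$flags$identifiable) {
      warning("no censored subjects beyond the last event time; ",
              "the cure fraction is weakly identified")
    }
  }

  coef_tbl <- function(coefs, ratio_name) {
    tibble::tibble(term = names(coefs) %||% character(0),
                   estimate = unname(coefs),
                   "{ratio_name}" := exp(unname(coefs)),
                   std_error = NA_real_, conf_low = NA_real_,
                   conf_high = NA_real_, p_value = NA_real_)
  }
  fit <- structure(list(
    incidence = coef_tbl(eng$incidence_coefs, "or"),
    latency = coef_tbl(eng$latency_coefs, "hr"),
    baseline = eng$baseline,
    tmax_event = eng$tmax_event,
    loglik = eng$loglik, loglik_trace = eng$loglik_trace,
    em_iterations = eng$em_iterations, converged = eng$converged,
    flags = eng$flags,
    weights = eng$weights, susceptibility = eng$susceptibility,
    survival_u = eng$survival_u,
    n = eng$n, n_event = eng$n_event, n_dropped = n_dropped,
    latency_form = latency_form, ties = ties, tol = tol,
    max_iter = max_iter,
    model_data = list(time = tt, event = ee, Z = Z, X = X),
    se_method = "none"
  ), class = "cure_fit")

  if (se_method != "none") {
    fit <- cure_se(fit, method = se_method, n_boot = n_boot, seed = seed)
  }
  fit
}

#' @export
print.cure_fit <- function(x, ...) {
  cat(sprintf(
    "<cure_fit> %s latency; n = %d, events = %d; loglik = %.3f (%d EM iterations%s)\n",
    x$latency_form, x$n, x$n_event, x$loglik, x$em_iterations,
    if (x$converged) "" else ", NOT converged"))
  cat("Incidence (odds of susceptibility):\n")
  print(x$incidence)
  if (nrow(x$latency)) {
    cat("Latency (hazard among susceptibles):\n")
    print(x$latency)
  }
  invisible(x)
}

#' Tidy and summarize mixture cure fits
#'
#' `tidy()` returns the coefficient table of one or both components;
#' `glance()` a one-row fit summary.
#'
#' @param x A `cure_fit`.
#' @param component `"all"`, `"incidence"` or `"latency"`.
#' @param ... Unused.
#' @export
tidy.cure_fit <- function(x, component = c("all", "incidence", "latency"),
                          ...) {
  component <- match.arg(component)
  inc <- dplyr::mutate(dplyr::rename(x$incidence, ratio = "or"),
                       component = "incidence", .before = 1)
  lat <- dplyr::mutate(dplyr::rename(x$latency, ratio = "hr"),
                       component = "latency", .before = 1)
  switch(component, incidence = inc, latency = lat,
         all = dplyr::bind_rows(inc, lat))
}

#' @rdname tidy.cure_fit
#' @export
glance.cure_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 em_iterations = x$em_iterations, converged = x$converged,
                 latency_form = x$latency_form,
                 separation = isTRUE(x$flags$separation),
                 se_method = x$se_method)
}

# refit helper used by the bootstrap: same design, resampled rows
cure_refit <- function(fit, idx) {
  md <- fit$model_data
  if (fit$latency_form == "weibull") {
    cure_weibull_engine(md$time[idx], md$event[idx],
                        md$Z[idx, , drop = FALSE], md$X[idx, , drop = FALSE])
  } else {
    cure_em_engine(md$time[idx], md$event[idx], md$Z[idx, , drop = FALSE],
                   md$X[idx, , drop = FALSE], ties = fit$ties,
                   tol = fit$tol, max_iter = fit$max_iter)
  }
}

#' Confidence intervals and p-values for a mixture cure fit
#'
#' Default: nonparametric bootstrap — patients are resampled with
#' replacement, the model refitted, and percentile 2.5/97.5 intervals
#' taken; p-values are Wald statistics against the bootstrap standard
#' error. The semiparametric baseline makes the analytic information
#' matrix unreliable, hence the resampling default; `"hessian"`
#' (numeric-Hessian Wald) is available for the parametric Weibull
#' latency. Fully deterministic given `seed`.
#'
#' @param fit A [fit_mixture_cure()] result.
#' @param method `"bootstrap"` or `"hessian"`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the resampling.
#' @return `fit` with `std_error`, `conf_low`, `conf_high` and `p_value`
#'   populated in both coefficient tables, plus bootstrap bookkeeping
#'   (`n_boot`, `n_boot_failed`). Warns if more than 20% of refits fail
#'   to converge.
#' @export
cure_se <- function(fit, method = c("bootstrap", "hessian"),
                    n_boot = 200L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "cure_fit"))
  if (method == "hessian") {
    if (fit$latency_form != "weibull") {
      stop_curescan(paste0("numeric-hessian standard errors are only ",
                           "supported for the Weibull latency; use the ",
                           "bootstrap for the semiparametric fit"),
                    "curescan_bad_input")
    }
    return(cure_weibull_wald(fit))
  }
  n <- fit$n
  k_inc <- nrow(fit$incidence); k_lat <- nrow(fit$latency)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      eng <- tryCatch(cure_refit(fit, idx), error = function(e) NULL)
      if (is.null(eng) || !eng$converged) return(NULL)
      c(eng$incidence_coefs, eng$latency_coefs)
    })
  })
  failed <- sum(vapply(draws, is.null, logical(1)))
  if (failed > 0.2 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits did not converge",
                    failed, n_boot))
  }
  mat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  attach_se <- function(tbl, cols) {
    if (!length(cols)) return(tbl)
    sub <- mat[, cols, drop = FALSE]
    tbl$std_error <- apply(sub, 2, sd)
    tbl$conf_low <- exp(apply(sub, 2, stats::quantile, probs = 0.025))
    tbl$conf_high <- exp(apply(sub, 2, stats::quantile, probs = 0.975))
    tbl$p_value <- 2 * pnorm(-abs(tbl$estimate / tbl$std_error))
    tbl
  }
  fit$incidence <- attach_se(fit$incidence, seq_len(k_inc))
  fit$latency <- attach_se(fit$latency, k_inc + seq_len(k_lat))
  fit$se_method <- "bootstrap"
  fit$n_boot <- n_boot
  fit$n_boot_failed <- failed
  fit$boot_seed <- seed
  fit
}

#' Likelihood-ratio test between nested mixture cure fits
#'
#' Compares observed-data log-likelihoods of two fits on the same data;
#' degrees of freedom are the difference in total parameter count
#' (incidence plus latency coefficients). The statistic is floored at 0.
#'
#' @param full,reduced `cure_fit` objects, `reduced` nested in `full`.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
cure_lr_test <- function(full, reduced) {
  df <- (nrow(full$incidence) + nrow(full$latency)) -
    (nrow(reduced$incidence) + nrow(reduced$latency))
  if (df < 1) stop_curescan("models are not nested (df < 1)",
                            "curescan_bad_input")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE))
}
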