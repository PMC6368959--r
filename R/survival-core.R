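#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return An object of class `km_curve`: `curve` is a tibble restricted
#'   to event times (`time`, `n_risk`, `n_event`, `survival`),
#'   `max_followup` is the largest observed time (event or censored),
#'   `n`/`n_event` are totals. A censored-only sample yields survival
#'   identically 1 (empty event table).
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
#' long_term_estimate(km)
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop_curescan("empty input", "curescan_bad_input")
  if (any(is.na(time)) || any(is.na(event))) {
    stop_curescan("missing time/event", "curescan_bad_input")
  }
  if (any(time <= 0)) stop_curescan("times must be positive",
                                    "curescan_bad_input")
  if (!all(event %in% 0:1)) stop_curescan("event must be 0/1",
                                          "curescan_bad_input")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  structure(list(
    curve = tibble::tibble(time = sf$time[keep], n_risk = sf$n.risk[keep],
                           n_event = sf$n.event[keep],
                           survival = sf$surv[keep]),
    max_followup = max(time),
    last_survival = if (any(event == 1)) min(sf$surv) else 1,
    n = length(time), n_event = sum(event)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, follow-up <= %.3g, long-term S = %.3f\n",
              x$n, x$n_event, x$max_followup, long_term_estimate(x)))
  invisible(x)
}

#' @describeIn kaplan_meier the per-event-time tibble.
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) x$curve

#' Long-term (plateau) survival estimate of a Kaplan-Meier curve
#'
#' The KM survival evaluated at the group's own last follow-up time,
#' i.e. the value of the final plateau. This is the routing quantity: a
#' value strictly between 0 and 1 signals a mixed cured/susceptible
#' group, 0 signals that everyone at risk eventually had the event, and
#' 1 an event-free group.
#'
#' @param curve A [kaplan_meier()] fit.
#' @return Survival probability in `[0, 1]`.
#' @export
long_term_estimate <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$last_survival
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank test across two or more groups.
#'
#' @param time,event Follow-up times and 0/1 indicators.
#' @param group Group labels (coerced to factor; each group must be
#'   non-empty and at least two groups must be present).
#' @return One-row tibble: `statistic` (chi-square), `df`, `p_value`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) {
    stop_curescan("log-rank test needs >= 2 non-empty groups",
                  "curescan_bad_input")
  }
  if (length(time) != length(group)) {
    stop_curescan("time and group lengths differ", "curescan_dim_mismatch")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  tibble::tibble(statistic = unname(sd_$chisq), df = df,
                 p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Fits a Cox model by partial likelihood (Newton-Raphson, through
#' `survival::coxph()`), with Wald confidence intervals and p-values per
#' covariate. Monotone partial likelihood (separation) and
#' non-convergence are flagged on the returned object rather than
#' silently returned.
#'
#' @param time,event Follow-up times and 0/1 indicators.
#' @param design Numeric matrix or data frame of covariates (no
#'   intercept; the Cox baseline absorbs it).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit` with elements `coefficients`,
#'   `vcov`, `terms` (tidy per-covariate table with `hr` and 95% Wald
#'   CI), `loglik` (c(null, fitted) partial log-likelihoods),
#'   `converged`, `monotone_likelihood`, `n`, `n_event`, and the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, design, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  design <- as.data.frame(design)
  if (sum(event) < 1) stop_curescan("no events", "curescan_no_events")
  dat <- cbind(data.frame(.time = time, .event = event), design)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")
  ))
  monotone <- FALSE; ran_out <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties, x = TRUE),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        monotone <<- TRUE
      }
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        ran_out <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  if (any(is.na(beta))) {
    stop_curescan("collinear design: some coefficients not estimable",
                  "curescan_collinear")
  }
  se <- sqrt(diag(fit$var))
  z <- qnorm(0.975)
  structure(list(
    coefficients = beta,
    vcov = fit$var,
    terms = tibble::tibble(
      term = names(beta), estimate = unname(beta), std_error = se,
      hr = exp(unname(beta)),
      conf_low = exp(unname(beta) - z * se),
      conf_high = exp(unname(beta) + z * se),
      p_value = 2 * pnorm(-abs(unname(beta) / se))
    ),
    loglik = fit$loglik,
    converged = !ran_out,
    monotone_likelihood = monotone,
    n = fit$n, n_event = fit$nevent,
    ties = ties, coxph = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n", x$n,
              x$n_event, x$ties,
              if (x$monotone_likelihood) " [monotone likelihood]" else ""))
  print(x$terms)
  invisible(x)
}

#' @describeIn cox_fit per-covariate tidy table.
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @describeIn cox_fit one-row model summary.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event,
                 loglik_null = x$loglik[1], loglik = x$loglik[2],
                 converged = x$converged,
                 monotone_likelihood = x$monotone_likelihood)
}

#' Proportional-hazards score test (scaled Schoenfeld residuals)
#'
#' Grambsch-Therneau score test for a time trend in the scaled
#' Schoenfeld residuals, per covariate plus a global test (through
#' `survival::cox.zph()`). The time transform defaults to the KM
#' transform; the identity and log transforms are available because the
#' appropriate choice is data-dependent.
#'
#' @param fit A converged [cox_fit()].
#' @param transform `"km"`, `"identity"` or `"log"`.
#' @return Object of class `ph_test`: a tibble (`term`, `statistic`,
#'   `df`, `p_value`) whose last row is `GLOBAL`, with the transform in
#'   attribute `transform`.
#' @export
ph_score_test <- function(fit, transform = c("km", "identity", "log")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop_curescan("ph_score_test needs a converged fit",
                                    "curescan_not_converged")
  if (fit$n_event < 1) stop_curescan("no events", "curescan_no_events")
  zp <- survival::cox.zph(fit$coxph, transform = transform, global = TRUE)
  tab <- zp$table
  out <- tibble::tibble(term = rownames(tab),
                        statistic = unname(tab[, "chisq"]),
                        df = unname(tab[, "df"]),
                        p_value = unname(tab[, "p"]))
  attr(out, "transform") <- transform
  class(out) <- c("ph_test", class(out))
  out
}
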