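# Baseline-characteristic selection, separately per model family.
# Screening admits covariates at a liberal univariable threshold
# (default p < 0.10); backward selection then removes, one at a time,
# the non-forced variable with the largest p until everything remaining
# is below the exit threshold (default 0.05). Forced variables are never
# removed. For the mixture-cure family a variable matters if it is
# associated with either the long-term risk (incidence) or the timing
# (latency) of the event, so its selection p-value combines the two
# component p-values; for the Cox family only timing is modelled.

# design matrix (no intercept) for one categorical covariate, patients
# with unknown/missing level excluded
covariate_design <- function(clinical, vars) {
  ok <- rep(TRUE, nrow(clinical))
  for (v in vars) {
    x <- clinical[[v]]
    ok <- ok & !is.na(x) & x != "unknown"
  }
  dat <- clinical[ok, vars, drop = FALSE]
  dat[] <- lapply(dat, function(x) droplevels(factor(x)))
  constant <- vapply(dat, function(x) nlevels(x) < 2, logical(1))
  if (any(constant)) {
    return(list(ok = ok, C = NULL, constant = names(dat)[constant]))
  }
  C <- model.matrix(~ ., data = dat)
  C <- C[, setdiff(colnames(C), "(Intercept)"), drop = FALSE]
  groups <- rep(vars, vapply(dat, function(x) nlevels(x) - 1L, integer(1)))
  list(ok = ok, C = C, groups = groups, constant = character(0))
}

# component-wise LR p-values for one variable inside a cure-family fit
cure_component_p <- function(time, event, Z, X, full_ll, cols) {
  p_inc <- tryCatch({
    eng <- cure_em_engine(time, event, Z[, -(1 + cols), drop = FALSE], X,
                          ties = "breslow")
    pchisq(max(0, 2 * (full_ll - eng$loglik)), length(cols),
           lower.tail = FALSE)
  }, error = function(e) NA_real_)
  p_lat <- tryCatch({
    eng <- cure_em_engine(time, event, Z, X[, -cols, drop = FALSE],
                          ties = "breslow")
    pchisq(max(0, 2 * (full_ll - eng$loglik)), length(cols),
           lower.tail = FALSE)
  }, error = function(e) NA_real_)
  c(incidence = p_inc, latency = p_lat)
}

#' Univariable screening of baseline characteristics
#'
#' One model per covariate, on the patients with a known level for that
#' covariate. Under the mixture-cure family a covariate qualifies when
#' associated with the long-term risk or the timing of the event
#' (incidence or latency component); under the Cox family, with timing.
#' Constant covariates are excluded with a note.
#'
#' @param clinical Clinical tibble with `time_years` and `event`.
#' @param covariates Character vector of categorical covariate columns.
#' @param family `"mixture-cure"` or `"cox"`.
#' @param entry_p Liberal entry threshold (default 0.10).
#' @param combine For the cure family, `"either"` (default; the
#'   screening p is the smaller of the incidence and latency p-values)
#'   or `"both"` (the larger).
#' @return Tibble with one row per covariate: `n_used`, the component
#'   p-values where applicable, the combined `p_value`, `candidate`
#'   flag and `note`.
#' @export
univariable_screen <- function(clinical, covariates,
                               family = c("mixture-cure", "cox"),
                               entry_p = 0.10,
                               combine = c("either", "both")) {
  family <- match.arg(family)
  combine <- match.arg(combine)
  clinical <- tibble::as_tibble(clinical)
  rows <- lapply(covariates, function(v) {
    d <- covariate_design(clinical, v)
    out <- tibble::tibble(covariate = v, n_used = sum(d$ok),
                          p_incidence = NA_real_, p_latency = NA_real_,
                          p_value = NA_real_, candidate = FALSE,
                          note = NA_character_)
    if (length(d$constant)) {
      out$note <- "constant covariate; excluded"
      return(out)
    }
    tt <- clinical$time_years[d$ok]
    ee <- as.numeric(clinical$event[d$ok])
    if (family == "cox") {
      p <- tryCatch({
        cf <- cox_fit(tt, ee, d$C)
        beta <- cf$coefficients
        stat <- drop(t(beta) %*% solve(cf$vcov, beta))
        pchisq(stat, length(beta), lower.tail = FALSE)
      }, error = function(e) NA_real_)
      out$p_value <- p
    } else {
      Z <- cbind("(Intercept)" = 1, d$C)
      full <- tryCatch(cure_em_engine(tt, ee, Z, d$C, ties = "breslow"),
                       error = function(e) NULL)
      if (is.null(full)) { out$note <- "fit failed"; return(out) }
      ps <- cure_component_p(tt, ee, Z, d$C, full$loglik,
                             seq_len(ncol(d$C)))
      out$p_incidence <- ps["incidence"]
      out$p_latency <- ps["latency"]
      out$p_value <- if (combine == "either") min(ps, na.rm = TRUE) else
        max(ps, na.rm = TRUE)
    }
    out$candidate <- !is.na(out$p_value) && out$p_value < entry_p
    out
  })
  dplyr::bind_rows(rows)
}

#' Backward selection of baseline characteristics
#'
#' Starting from the candidate set plus the forced variables, repeatedly
#' removes the non-forced variable with the largest selection p-value at
#' or above `exit_p`, refitting after each removal, until every
#' non-forced variable falls below `exit_p`. Forced variables are never
#' removed (and their p-values are reported). Removal p-values are the
#' joint Wald test across a variable's levels for the Cox family and
#' component-wise likelihood-ratio tests (combined as in
#' [univariable_screen()]) for the mixture-cure family. Patients with an
#' unknown level in any participating variable are excluded once, up
#' front, so every step fits on the same patients. Ties on the largest
#' p-value drop the variable occurring later in the given order.
#'
#' Non-convergence at any step aborts with a classed condition
#' (`curescan_selection_abort`) carrying the trace so far.
#'
#' @param clinical Clinical tibble with `time_years` and `event`.
#' @param candidates Character vector of candidate covariates (screen
#'   survivors).
#' @param forced Covariates kept regardless of significance.
#' @param family `"mixture-cure"` or `"cox"`.
#' @param exit_p Exit threshold (default 0.05).
#' @param combine Cure-family component combination (see
#'   [univariable_screen()]).
#' @return Object of class `selection_trace`: `family`, `candidates`,
#'   `forced`, `n_used`, `steps` (tibble of removals with the p at each
#'   removal) and `final` (tibble of retained variables with final
#'   p-values).
#' @export
backward_select <- function(clinical, candidates, forced = character(0),
                            family = c("mixture-cure", "cox"),
                            exit_p = 0.05, combine = c("either", "both")) {
  family <- match.arg(family)
  combine <- match.arg(combine)
  clinical <- tibble::as_tibble(clinical)
  vars <- unique(c(candidates, forced))
  order_ref <- vars
  d0 <- covariate_design(clinical, vars)
  if (length(d0$constant)) {
    vars <- setdiff(vars, setdiff(d0$constant, forced))
  }
  d0 <- covariate_design(clinical, vars)
  tt <- clinical$time_years[d0$ok]
  ee <- as.numeric(clinical$event[d0$ok])
  steps <- tibble::tibble(step = integer(0), dropped = character(0),
                          p_at_removal = numeric(0))
  step <- 0L
  current <- vars
  var_p <- function(current) {
    d <- covariate_design(clinical[d0$ok, ], current)
    C <- d$C; groups <- d$groups
    if (family == "cox") {
      cf <- cox_fit(tt, ee, C)
      vapply(current, function(v) {
        idx <- which(groups == v)
        beta <- cf$coefficients[idx]
        V <- cf$vcov[idx, idx, drop = FALSE]
        stat <- drop(t(beta) %*% solve(V, beta))
        pchisq(stat, length(idx), lower.tail = FALSE)
      }, numeric(1))
    } else {
      Z <- cbind("(Intercept)" = 1, C)
      full <- cure_em_engine(tt, ee, Z, C, ties = "breslow")
      vapply(current, function(v) {
        ps <- cure_component_p(tt, ee, Z, C, full$loglik,
                               which(groups == v))
        if (combine == "either") min(ps, na.rm = TRUE) else
          max(ps, na.rm = TRUE)
      }, numeric(1))
    }
  }
  final_p <- NULL
  repeat {
    if (length(current) == 0L) { final_p <- numeric(0); break }
    ps <- tryCatch(var_p(current), error = function(e) {
      stop(structure(
        class = c("curescan_selection_abort", "curescan_error", "error",
                  "condition"),
        list(message = paste0("selection aborted: ", conditionMessage(e)),
             call = NULL,
             trace = list(steps = steps, remaining = current))))
    })
    final_p <- ps
    removable <- setdiff(current, forced)
    cand <- removable[!is.na(ps[removable]) & ps[removable] >= exit_p]
    if (length(cand) == 0L) break
    worst_p <- max(ps[cand])
    tied <- cand[ps[cand] == worst_p]
    drop_var <- tied[which.max(match(tied, order_ref))]
    step <- step + 1L
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = step, dropped = drop_var, p_at_removal = ps[[drop_var]]))
    current <- setdiff(current, drop_var)
  }
  structure(list(
    family = family, candidates = candidates, forced = forced,
    entry_vars = vars, n_used = sum(d0$ok), exit_p = exit_p,
    steps = steps,
    final = tibble::tibble(variable = current,
                           p_final = unname(final_p[current]),
                           forced = current %in% forced)
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s family, n = %d\n", x$family, x$n_used))
  if (nrow(x$steps)) {
    cat("Removals:\n"); print(x$steps)
  } else cat("No removals.\n")
  cat("Final model:\n"); print(x$final)
  invisible(x)
}

#' @describeIn backward_select the final-model table with the drop
#'   sequence in attribute `steps`.
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @export
tidy.selection_trace <- function(x, ...) {
  out <- x$final
  attr(out, "steps") <- x$steps
  out
}
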