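# Genome-wide univariable scan: per SNP x genetic model, route by
# long-term KM estimates, fit the routed method, flag significance at a
# Bonferroni threshold; downstream, genetic-model validity tests and
# multivariable refits on the hits.

# shared cure-branch machinery -------------------------------------------

# fit the null (intercept-only incidence, no latency covariate) cure
# model once per complete-case pattern; keyed by the excluded indices
null_cure_cache <- function() new.env(parent = emptyenv())

null_cure_loglik <- function(cache, time, event, used, ties, tol, max_iter) {
  key <- paste0("cc_", paste(which(!used), collapse = ","))
  if (!is.null(cache[[key]])) return(cache[[key]])
  eng <- cure_em_engine(time[used], event[used],
                        Z = matrix(1, sum(used), 1,
                                   dimnames = list(NULL, "(Intercept)")),
                        X = matrix(numeric(0), sum(used), 0),
                        ties = ties, tol = tol, max_iter = max_iter)
  cache[[key]] <- eng$loglik
  eng$loglik
}

# pick the reported term for multi-column encodings: the largest
# absolute latency log-hazard (ties favour the minor homozygote)
pick_term <- function(design_cols, latency_coefs) {
  if (length(design_cols) == 1L) return(1L)
  which.max(abs(latency_coefs) + 1e-12 * (design_cols == "hom_minor"))
}

scan_row_template <- function(snp_id, model) {
  tibble::tibble(
    snp_id = snp_id, model = model, method = NA_character_,
    skip_reason = NA_character_, n_used = NA_integer_,
    n_event = NA_integer_, counts = NA_character_,
    plateau_min = NA_real_, plateau_max = NA_real_,
    tested_category = NA_character_, genotype_freq = NA_real_,
    or = NA_real_, or_conf_low = NA_real_, or_conf_high = NA_real_,
    p_incidence = NA_real_,
    hr = NA_real_, hr_conf_low = NA_real_, hr_conf_high = NA_real_,
    p_latency = NA_real_,
    statistic = NA_real_, df = NA_real_, p_value = NA_real_,
    ph_p = NA_real_, significant = FALSE, converged = NA,
    note = NA_character_
  )
}

#' Genome-wide univariable scan
#'
#' For every SNP and requested genetic model: encode the genotype,
#' apply the small-category guard, route by the per-category long-term
#' Kaplan-Meier estimates ([route_snp()]), fit the routed method, and
#' flag significance at the Bonferroni threshold `alpha / n_tests`
#' (`n_tests` defaults to the number of SNPs, not SNP-model pairs,
#' matching the usual genome-wide convention). Per-SNP fit failures are
#' captured in the result row, never aborting the scan. For significant
#' Cox-branch rows the proportional-hazards score test is run and its
#' global p-value reported.
#'
#' Cure-branch p-values are joint likelihood-ratio tests of the SNP
#' terms in both components against the intercept-only cure model
#' (`p_method = "lr"`, the default, with point-estimate ORs/HRs);
#' `p_method = "bootstrap"` adds percentile CIs and
#' Wald-from-bootstrap-SE per-component p-values at substantial
#' computational cost and is intended for candidate sets, not full
#' scans.
#'
#' @param genotypes A [genotype_matrix()] (after [snp_qc()]).
#' @param outcome Data frame with `patient_id`, `time_years`, `event`
#'   covering the genotyped patients.
#' @param models Character subset of
#'   `c("additive", "dominant", "recessive", "codominant")`.
#' @param alpha Family-wise error rate.
#' @param n_tests Bonferroni denominator; default `NULL` means the
#'   number of SNPs scanned.
#' @param p_method `"lr"` or `"bootstrap"` for the cure branch.
#' @param ties Tie method for Cox-branch fits.
#' @param n_boot,seed Bootstrap controls when `p_method = "bootstrap"`.
#' @param ph_transform Time transform for the PH score test on
#'   significant Cox rows.
#' @return A tibble with one row per SNP x model; see the package
#'   vignette for the column dictionary.
#' @export
univariable_scan <- function(genotypes, outcome,
                             models = genetic_models,
                             alpha = 0.05, n_tests = NULL,
                             p_method = c("lr", "bootstrap"),
                             ties = c("efron", "breslow"),
                             n_boot = 200L, seed = NULL,
                             ph_transform = "km") {
  p_method <- match.arg(p_method)
  ties <- match.arg(ties)
  models <- match.arg(models, genetic_models, several.ok = TRUE)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  outcome <- tibble::as_tibble(outcome)
  req <- c("patient_id", "time_years", "event")
  if (!all(req %in% names(outcome))) {
    stop_curescan("outcome needs columns patient_id, time_years, event",
                  "curescan_bad_input")
  }
  ids <- intersect(genotypes$patients, outcome$patient_id)
  if (length(ids) < length(genotypes$patients)) {
    warning(sprintf("%d genotyped patients lack outcome data and are dropped",
                    length(genotypes$patients) - length(ids)))
  }
  om <- outcome[match(ids, outcome$patient_id), ]
  if (any(is.na(om$time_years)) || any(is.na(om$event))) {
    stop_curescan("outcome must be complete (run apply_cohort_filters first)",
                  "curescan_bad_input")
  }
  codes_all <- genotypes$codes[, ids, drop = FALSE]
  time <- om$time_years; event <- as.numeric(om$event)
  n_snps <- nrow(codes_all)
  threshold <- bonferroni_threshold(alpha, n_tests %||% n_snps)
  cache <- null_cure_cache()

  rows <- vector("list", n_snps * length(models))
  k <- 0L
  for (i in seq_len(n_snps)) {
    codes <- codes_all[i, ]
    for (model in models) {
      k <- k + 1L
      rows[[k]] <- scan_one(genotypes$snps$snp_id[i], codes, model,
                            time, event, p_method, ties, n_boot,
                            if (is.null(seed)) NULL else seed + k,
                            cache)
    }
  }
  res <- dplyr::bind_rows(rows)
  res$significant <- !is.na(res$p_value) & res$p_value < threshold
  # PH score test for significant cox-branch rows
  idx <- which(res$significant & res$method == "cox")
  for (j in idx) {
    codes <- codes_all[match(res$snp_id[j], genotypes$snps$snp_id), ]
    enc <- encode_genotype(codes, res$model[j])
    ph <- tryCatch({
      cf <- cox_fit(time[enc$used], event[enc$used], enc$design,
                    ties = ties)
      pt <- ph_score_test(cf, transform = ph_transform)
      pt$p_value[pt$term == "GLOBAL"]
    }, error = function(e) NA_real_)
    res$ph_p[j] <- ph
  }
  attr(res, "threshold") <- threshold
  attr(res, "n_tests") <- n_tests %||% n_snps
  attr(res, "alpha") <- alpha
  res
}

# one SNP x model row (internal)
scan_one <- function(snp_id, codes, model, time, event, p_method, ties,
                     n_boot, seed, cache) {
  row <- scan_row_template(snp_id, model)
  enc <- encode_genotype(codes, model)
  row$counts <- paste(enc$raw_counts, collapse = "/")
  row$n_used <- sum(enc$used)
  if (enc$skip) {
    row$method <- "skipped"
    row$skip_reason <- enc$skip_reason
    return(row)
  }
  tt <- time[enc$used]; ee <- event[enc$used]
  row$n_event <- as.integer(sum(ee))
  grp <- enc$routing_group
  plateaus <- vapply(names(enc$routing_counts), function(g) {
    sel <- grp == g
    km_last(tt[sel], ee[sel])
  }, numeric(1))
  row$plateau_min <- min(plateaus); row$plateau_max <- max(plateaus)
  method <- if (any(plateaus == 1)) "log-rank"
    else if (any(plateaus == 0)) "cox"
    else "mixture-cure"
  row$method <- method
  row$tested_category <- enc$tested$label
  row$genotype_freq <- enc$tested$freq

  out <- tryCatch({
    if (method == "mixture-cure") {
      scan_fit_cure(row, enc, tt, ee, p_method, ties, n_boot, seed, cache,
                    time, event)
    } else if (method == "cox") {
      scan_fit_cox(row, enc, tt, ee, ties)
    } else {
      lr <- log_rank_test(tt, ee, droplevels(grp))
      row$statistic <- lr$statistic; row$df <- lr$df
      row$p_value <- lr$p_value
      row$converged <- TRUE
      row
    }
  }, error = function(e) {
    row$note <- conditionMessage(e)
    row$converged <- FALSE
    row
  })
  out
}

scan_fit_cure <- function(row, enc, tt, ee, p_method, ties, n_boot, seed,
                          cache, time_all, event_all) {
  D <- enc$design
  Z <- cbind("(Intercept)" = 1, D)
  eng <- cure_em_engine(tt, ee, Z, D, ties = "breslow")
  row$converged <- eng$converged
  sel <- pick_term(colnames(D), eng$latency_coefs)
  row$or <- exp(unname(eng$incidence_coefs[1 + sel]))
  row$hr <- exp(unname(eng$latency_coefs[sel]))
  if (ncol(D) > 1L) {
    row$tested_category <- c(het = "1 vs 0",
                             hom_minor = "2 vs 0")[colnames(D)[sel]]
    row$genotype_freq <- mean(D[, sel])
  }
  if (p_method == "lr") {
    ll0 <- null_cure_loglik(cache, time_all, event_all, enc$used,
                            "breslow", 1e-6, 500L)
    stat <- max(0, 2 * (eng$loglik - ll0))
    row$statistic <- stat
    row$df <- 2 * ncol(D)
    row$p_value <- pchisq(stat, row$df, lower.tail = FALSE)
  } else {
    dat <- tibble::as_tibble(as.data.frame(D))
    dat$.time <- tt; dat$.event <- ee
    fml <- stats::as.formula(paste("~", paste(sprintf("`%s`", colnames(D)),
                                              collapse = "+")))
    fit <- fit_mixture_cure(dat, .time, .event, incidence = fml,
                            latency = fml, ties = "breslow",
                            se_method = "bootstrap", n_boot = n_boot,
                            seed = seed)
    row$or_conf_low <- fit$incidence$conf_low[1 + sel]
    row$or_conf_high <- fit$incidence$conf_high[1 + sel]
    row$p_incidence <- fit$incidence$p_value[1 + sel]
    row$hr_conf_low <- fit$latency$conf_low[sel]
    row$hr_conf_high <- fit$latency$conf_high[sel]
    row$p_latency <- fit$latency$p_value[sel]
    row$p_value <- min(row$p_incidence, row$p_latency)
    row$df <- 1
  }
  if (isTRUE(eng$flags$separation)) row$note <- "incidence separation (capped)"
  row
}

scan_fit_cox <- function(row, enc, tt, ee, ties) {
  D <- enc$design
  cf <- cox_fit(tt, ee, D, ties = ties)
  row$converged <- cf$converged
  sel <- pick_term(colnames(D), cf$coefficients)
  row$hr <- cf$terms$hr[sel]
  row$hr_conf_low <- cf$terms$conf_low[sel]
  row$hr_conf_high <- cf$terms$conf_high[sel]
  row$p_latency <- cf$terms$p_value[sel]
  if (ncol(D) > 1L) {
    row$tested_category <- c(het = "1 vs 0",
                             hom_minor = "2 vs 0")[colnames(D)[sel]]
    row$genotype_freq <- mean(D[, sel])
    beta <- cf$coefficients
    stat <- drop(t(beta) %*% solve(cf$vcov, beta))   # joint Wald
    row$statistic <- stat
    row$df <- length(beta)
    row$p_value <- pchisq(stat, length(beta), lower.tail = FALSE)
  } else {
    z2 <- (cf$terms$estimate[1] / cf$terms$std_error[1])^2
    row$statistic <- z2; row$df <- 1
    row$p_value <- cf$terms$p_value[1]
  }
  if (cf$monotone_likelihood) row$note <- "monotone partial likelihood"
  row
}

#' Genetic-model validity via nested likelihood-ratio test
#'
#' Additive, dominant and recessive encodings are nested in the
#' co-dominant model, so a likelihood-ratio test of the co-dominant fit
#' against the identified model assesses whether the identified genetic
#' model is plausible. The observed-data log-likelihood is used on the
#' mixture-cure branch and the partial likelihood on the Cox branch.
#' Degrees of freedom are the added parameter count (co-dominant columns
#' that are constant in the data are dropped, so when no minor
#' homozygotes exist the dominant and co-dominant models coincide and
#' the statistic is 0 with df 0). The per-term coefficient comparison
#' between the identified and co-dominant fits is attached.
#'
#' @param genotypes,outcome As in [univariable_scan()].
#' @param snp_id SNP to test.
#' @param model Identified model (`"additive"`, `"dominant"` or
#'   `"recessive"`).
#' @param method Branch the SNP was analyzed under; `NULL` re-routes.
#' @param alpha Rejection level for the validity call.
#' @param ties Cox-branch tie method.
#' @return One-row tibble: `snp_id`, `model`, `method`, `validity`
#'   (`plausible` / `rejected` / `not-applicable`), `statistic`, `df`,
#'   `p_value`, and `coef_comparison` (list-column tibble of identified
#'   vs co-dominant coefficients).
#' @export
model_validity <- function(genotypes, outcome, snp_id, model,
                           method = NULL, alpha = 0.05,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!model %in% c("additive", "dominant", "recessive")) {
    stop_curescan("identified model must be additive, dominant or recessive",
                  "curescan_bad_input")
  }
  stopifnot(inherits(genotypes, "genotype_matrix"))
  outcome <- tibble::as_tibble(outcome)
  i <- match(snp_id, genotypes$snps$snp_id)
  if (is.na(i)) stop_curescan(paste0("unknown snp_id: ", snp_id),
                              "curescan_bad_input")
  om <- outcome[match(intersect(genotypes$patients, outcome$patient_id),
                      outcome$patient_id), ]
  codes <- genotypes$codes[i, om$patient_id]
  time <- om$time_years; event <- as.numeric(om$event)
  enc <- encode_genotype(codes, model)
  if (is.null(method)) {
    method <- route_snp(codes, model, time, event)$method
  }
  na_row <- tibble::tibble(snp_id = snp_id, model = model, method = method,
                           validity = "not-applicable",
                           statistic = NA_real_, df = NA_real_,
                           p_value = NA_real_, coef_comparison = list(NULL))
  if (!method %in% c("mixture-cure", "cox")) return(na_row)
  tt <- time[enc$used]; ee <- event[enc$used]
  D1 <- enc$design
  x <- as.numeric(codes[enc$used])
  D2 <- cbind(het = as.numeric(x == 1), hom_minor = as.numeric(x == 2))
  D2 <- D2[, apply(D2, 2, function(c) length(unique(c)) > 1), drop = FALSE]
  if (ncol(D2) == 0L) return(na_row)

  fits <- tryCatch({
    if (method == "mixture-cure") {
      f1 <- cure_em_engine(tt, ee, cbind("(Intercept)" = 1, D1), D1,
                           ties = "breslow")
      f2 <- cure_em_engine(tt, ee, cbind("(Intercept)" = 1, D2), D2,
                           ties = "breslow")
      list(ll1 = f1$loglik, ll2 = f2$loglik,
           df = 2 * (ncol(D2) - ncol(D1)),
           cmp = tibble::tibble(
             component = rep(c("incidence", "latency"),
                             times = c(ncol(D1) + ncol(D2),
                                       ncol(D1) + ncol(D2))),
             fit = rep(rep(c("identified", "codominant"),
                           c(ncol(D1), ncol(D2))), 2),
             term = rep(c(colnames(D1), colnames(D2)), 2),
             estimate = c(f1$incidence_coefs[-1], f2$incidence_coefs[-1],
                          f1$latency_coefs, f2$latency_coefs)))
    } else {
      f1 <- cox_fit(tt, ee, D1, ties = ties)
      f2 <- cox_fit(tt, ee, D2, ties = ties)
      list(ll1 = f1$loglik[2], ll2 = f2$loglik[2],
           df = ncol(D2) - ncol(D1),
           cmp = tibble::tibble(
             component = "latency",
             fit = rep(c("identified", "codominant"),
                       c(ncol(D1), ncol(D2))),
             term = c(colnames(D1), colnames(D2)),
             estimate = c(f1$coefficients, f2$coefficients)))
    }
  }, error = function(e) NULL)
  if (is.null(fits)) return(na_row)
  stat <- max(0, 2 * (fits$ll2 - fits$ll1))
  p <- if (fits$df <= 0) 1 else pchisq(stat, fits$df, lower.tail = FALSE)
  tibble::tibble(snp_id = snp_id, model = model, method = method,
                 validity = if (p < alpha) "rejected" else "plausible",
                 statistic = stat, df = max(fits$df, 0),
                 p_value = p, coef_comparison = list(fits$cmp))
}

#' Multivariable refit of a scan hit
#'
#' Refits the routed method for one SNP with baseline-characteristic
#' adjustment. Patients with missing genotype or an `"unknown"`/missing
#' level in any requested covariate are excluded (complete case). On the
#' mixture-cure branch the covariates enter both the incidence and
#' latency components; on the Cox branch they join the SNP terms in the
#' linear predictor. The log-rank branch cannot be covariate-adjusted.
#'
#' @param genotypes,outcome As in [univariable_scan()]; `outcome` here
#'   is the clinical table carrying the covariate columns.
#' @param snp_id,model The hit to refit.
#' @param covariates Character vector of clinical column names.
#' @param method Branch; `NULL` re-routes on the complete-case subset.
#' @param p_method `"lr"` (joint LR for the SNP terms, default) or
#'   `"bootstrap"` (percentile CIs and Wald p-values).
#' @param ties,n_boot,seed Passed through to the fits.
#' @return One-row tibble with adjusted estimates; non-convergence is
#'   recorded in `converged`, not raised.
#' @export
multivariable_refit <- function(genotypes, outcome, snp_id, model,
                                covariates, method = NULL,
                                p_method = c("lr", "bootstrap"),
                                ties = c("efron", "breslow"),
                                n_boot = 200L, seed = NULL) {
  p_method <- match.arg(p_method)
  ties <- match.arg(ties)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  outcome <- tibble::as_tibble(outcome)
  i <- match(snp_id, genotypes$snps$snp_id)
  if (is.na(i)) stop_curescan(paste0("unknown snp_id: ", snp_id),
                              "curescan_bad_input")
  miss <- setdiff(covariates, names(outcome))
  if (length(miss)) {
    stop_curescan(paste0("covariates absent from outcome table: ",
                         paste(miss, collapse = ", ")),
                  "curescan_bad_input")
  }
  ids <- intersect(genotypes$patients, outcome$patient_id)
  om <- outcome[match(ids, outcome$patient_id), ]
  codes <- genotypes$codes[i, ids]
  # complete case: known level in every covariate, genotype present
  ok <- !is.na(codes)
  for (v in covariates) {
    x <- om[[v]]
    ok <- ok & !is.na(x) & x != "unknown"
  }
  om <- om[ok, ]; codes <- codes[ok]
  time <- om$time_years; event <- as.numeric(om$event)
  enc <- encode_genotype(codes, model)
  if (enc$skip) {
    stop_curescan("SNP fails the small-category guard on the complete-case subset",
                  "curescan_bad_input")
  }
  if (is.null(method)) method <- route_snp(codes, model, time, event)$method
  if (method == "log-rank") {
    stop_curescan("log-rank branch cannot be covariate-adjusted",
                  "curescan_bad_input")
  }
  cov_df <- om[covariates]
  cov_df[] <- lapply(cov_df, function(x) droplevels(factor(x)))
  # a covariate can become constant after complete-case exclusion; it
  # then carries no adjustment information and is dropped
  cov_df <- cov_df[vapply(cov_df, nlevels, integer(1)) >= 2L]
  if (ncol(cov_df)) {
    C <- model.matrix(~ ., data = cov_df)
    C <- C[, setdiff(colnames(C), "(Intercept)"), drop = FALSE]
  } else {
    C <- matrix(numeric(0), nrow(om), 0)
  }
  D <- enc$design
  tt <- time[enc$used]; ee <- event[enc$used]
  C <- C[enc$used, , drop = FALSE]
  sel <- NULL
  row <- scan_row_template(snp_id, model)
  row$method <- method
  row$n_used <- length(tt); row$n_event <- as.integer(sum(ee))
  row$tested_category <- enc$tested$label
  row$genotype_freq <- enc$tested$freq

  if (method == "mixture-cure") {
    Zf <- cbind("(Intercept)" = 1, D, C)
    Xf <- cbind(D, C)
    eng <- tryCatch(cure_em_engine(tt, ee, Zf, Xf, ties = "breslow"),
                    error = function(e) NULL)
    if (is.null(eng)) { row$converged <- FALSE; row$note <- "fit failed"
                        return(row) }
    row$converged <- eng$converged
    sel <- pick_term(colnames(D), eng$latency_coefs[seq_len(ncol(D))])
    row$or <- exp(unname(eng$incidence_coefs[1 + sel]))
    row$hr <- exp(unname(eng$latency_coefs[sel]))
    if (ncol(D) > 1L) {
      row$tested_category <- c(het = "1 vs 0",
                               hom_minor = "2 vs 0")[colnames(D)[sel]]
      row$genotype_freq <- mean(D[, sel])
    }
    if (p_method == "lr") {
      eng0 <- tryCatch(
        cure_em_engine(tt, ee, cbind("(Intercept)" = 1, C), C,
                       ties = "breslow"),
        error = function(e) NULL)
      if (!is.null(eng0)) {
        stat <- max(0, 2 * (eng$loglik - eng0$loglik))
        row$statistic <- stat
        row$df <- 2 * ncol(D)
        row$p_value <- pchisq(stat, row$df, lower.tail = FALSE)
      }
    } else {
      dat <- tibble::as_tibble(as.data.frame(cbind(D, C)))
      dat$.time <- tt; dat$.event <- ee
      fml <- stats::as.formula(
        paste("~", paste(sprintf("`%s`", colnames(cbind(D, C))),
                         collapse = "+")))
      fit <- fit_mixture_cure(dat, .time, .event, incidence = fml,
                              latency = fml, ties = "breslow",
                              se_method = "bootstrap", n_boot = n_boot,
                              seed = seed)
      row$or_conf_low <- fit$incidence$conf_low[1 + sel]
      row$or_conf_high <- fit$incidence$conf_high[1 + sel]
      row$p_incidence <- fit$incidence$p_value[1 + sel]
      row$hr_conf_low <- fit$latency$conf_low[sel]
      row$hr_conf_high <- fit$latency$conf_high[sel]
      row$p_latency <- fit$latency$p_value[sel]
      row$p_value <- min(row$p_incidence, row$p_latency)
      row$df <- 1
    }
  } else {
    Df <- cbind(D, C)
    cf <- tryCatch(cox_fit(tt, ee, Df, ties = ties),
                   error = function(e) NULL)
    if (is.null(cf)) { row$converged <- FALSE; row$note <- "fit failed"
                       return(row) }
    row$converged <- cf$converged
    sel <- pick_term(colnames(D), cf$coefficients[seq_len(ncol(D))])
    row$hr <- cf$terms$hr[sel]
    row$hr_conf_low <- cf$terms$conf_low[sel]
    row$hr_conf_high <- cf$terms$conf_high[sel]
    row$p_latency <- cf$terms$p_value[sel]
    if (ncol(D) > 1L) {
      row$tested_category <- c(het = "1 vs 0",
                               hom_minor = "2 vs 0")[colnames(D)[sel]]
      row$genotype_freq <- mean(D[, sel])
      beta <- cf$coefficients[seq_len(ncol(D))]
      V <- cf$vcov[seq_len(ncol(D)), seq_len(ncol(D)), drop = FALSE]
      stat <- drop(t(beta) %*% solve(V, beta))
      row$statistic <- stat; row$df <- ncol(D)
      row$p_value <- pchisq(stat, ncol(D), lower.tail = FALSE)
    } else {
      row$statistic <- (cf$terms$estimate[1] / cf$terms$std_error[1])^2
      row$df <- 1
      row$p_value <- cf$terms$p_value[1]
    }
  }
  row$note <- paste0("adjusted for: ", paste(covariates, collapse = ", "))
  row
}
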