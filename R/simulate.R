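# Synthetic cohorts with the statistical structure the analysis
# assumes: Hardy-Weinberg genotypes, baseline covariates drawn from the
# reference cohort's marginals, and cure-mixture outcomes (Bernoulli
# susceptibility on a logistic scale; Weibull proportional-hazards event
# times among susceptibles; censoring as the minimum of an
# administrative follow-up window and random dropout). Cured patients
# are always censored. The latent truth is returned alongside but never
# consumed by the analysis functions.

#' Default covariate marginals from the reference cohort
#'
#' Level frequencies for each baseline characteristic, taken from the
#' reference baseline table ([baseline_reference()]) counts.
#'
#' @return Named list of named probability vectors.
#' @export
table1_marginals <- function() {
  ref <- baseline_reference()
  split(ref, ref$variable) |>
    lapply(function(d) setNames(d$n / sum(d$n), d$level))
}

#' Specify a synthetic cohort
#'
#' Defaults emulate a stage I-III MSI-L/MSS cohort of 379 patients with
#' a long-term metastasis-free plateau of 0.71 (susceptibility 0.29),
#' early events among susceptibles (Weibull shape 1.2, scale 2.5 years:
#' about 90% of susceptible events within 5 years), an administrative
#' follow-up window of 7.0 to 10.9 years (a 4-year accrual window with
#' follow-up closing 10.9 years after the first enrolment) and random
#' dropout at 0.15/year, which together give an expected event fraction
#' of 21%.
#'
#' @param n Number of patients.
#' @param maf Named vector of per-SNP minor-allele frequencies in
#'   `[0, 0.5]`.
#' @param missing_rate Genotype missingness, completely at random.
#' @param covariates Named list of level-probability vectors (default
#'   [table1_marginals()]); each must sum to 1.
#' @param incidence_intercept Log-odds of susceptibility at baseline.
#' @param incidence_snp,latency_snp Named per-SNP log-OR / log-HR
#'   applied to the encoded SNP dose.
#' @param snp_model Named per-SNP genetic model under which the effects
#'   act (default additive dose for every SNP with an effect).
#' @param incidence_covariate,latency_covariate Named lists
#'   (covariate -> named per-level coefficient vector, reference level
#'   0) for confounding scenarios.
#' @param latency_shape,latency_scale Weibull baseline among
#'   susceptibles (scale in years).
#' @param admin_min,admin_max Administrative censoring window (years).
#' @param dropout_rate Exponential dropout hazard (1/years).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 379L, maf = c(snp_1 = 0.3),
                        missing_rate = 0,
                        covariates = table1_marginals(),
                        incidence_intercept = qlogis(0.29),
                        incidence_snp = NULL, latency_snp = NULL,
                        snp_model = NULL,
                        incidence_covariate = NULL,
                        latency_covariate = NULL,
                        latency_shape = 1.2, latency_scale = 2.5,
                        admin_min = 7.0, admin_max = 10.9,
                        dropout_rate = 0.15) {
  if (any(maf < 0 | maf > 0.5)) {
    stop_curescan("MAFs must lie in [0, 0.5]", "curescan_bad_input")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_curescan("missing_rate must lie in [0, 1)", "curescan_bad_input")
  }
  if (admin_max <= 0 || admin_max < admin_min) {
    stop_curescan("censoring horizon must be positive and >= admin_min",
                  "curescan_bad_input")
  }
  for (v in names(covariates)) {
    p <- covariates[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_curescan(paste0("level frequencies of '", v,
                           "' must be non-negative and sum to 1"),
                    "curescan_bad_input")
    }
  }
  structure(list(
    n = as.integer(n), maf = maf, missing_rate = missing_rate,
    covariates = covariates,
    incidence_intercept = incidence_intercept,
    incidence_snp = incidence_snp %||% setNames(rep(0, length(maf)),
                                                names(maf)),
    latency_snp = latency_snp %||% setNames(rep(0, length(maf)),
                                            names(maf)),
    snp_model = snp_model,
    incidence_covariate = incidence_covariate,
    latency_covariate = latency_covariate,
    latency_shape = latency_shape, latency_scale = latency_scale,
    admin_min = admin_min, admin_max = admin_max,
    dropout_rate = dropout_rate
  ), class = "cohort_spec")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent SNPs with genotype probabilities `(1-q)^2, 2q(1-q), q^2`
#' for minor-allele frequency `q`; missingness completely at random.
#'
#' @param n Number of patients.
#' @param maf Named vector of MAFs in `[0, 0.5]`.
#' @param missing_rate Per-call missing probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with synthetic metadata (chromosome,
#'   position, alleles).
#' @export
simulate_genotypes <- function(n, maf, missing_rate = 0, seed = NULL) {
  if (is.null(names(maf))) {
    names(maf) <- sprintf("snp_%d", seq_along(maf))
  }
  if (any(maf < 0 | maf > 0.5)) {
    stop_curescan("MAFs must lie in [0, 0.5]", "curescan_bad_input")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_curescan("missing_rate must lie in [0, 1)", "curescan_bad_input")
  }
  with_seed(seed, {
    m <- length(maf)
    codes <- matrix(rbinom(m * n, 2L, rep(maf, each = n)),
                    nrow = m, ncol = n, byrow = TRUE)
    if (missing_rate > 0) {
      codes[matrix(runif(m * n) < missing_rate, m, n)] <- NA_integer_
    }
    snps <- tibble::tibble(
      snp_id = names(maf),
      chrom = as.character(1L + (seq_len(m) - 1L) %% 22L),
      pos = 1000000L * seq_len(m),
      allele_minor = "A", allele_major = "G"
    )
    genotype_matrix(codes, snps, sprintf("P%04d", seq_len(n)))
  })
}

#' Simulate cure-mixture outcomes for given designs
#'
#' Susceptibility is Bernoulli on a logistic scale
#' (`expit(intercept + Z b)`); susceptible event times are Weibull
#' proportional hazards with linear predictor `X beta`; censoring is the
#' minimum of a uniform administrative time and exponential dropout.
#' Cured patients are censored at their censoring time.
#'
#' @param Z,X Numeric incidence / latency design matrices (no
#'   intercept; the intercept is `incidence_intercept`).
#' @param incidence_coefs,latency_coefs Coefficient vectors matching
#'   `Z` / `X` columns.
#' @param spec A [cohort_spec()] providing intercept, baseline and
#'   censoring parameters.
#' @param seed Integer seed.
#' @return Tibble: `time_years`, `event`, `susceptible`,
#'   `true_event_time`, `censor_time`.
#' @export
simulate_outcomes <- function(Z, X, incidence_coefs, latency_coefs, spec,
                              seed = NULL) {
  n <- spec$n
  with_seed(seed, {
    lp_inc <- spec$incidence_intercept +
      if (length(incidence_coefs)) as.vector(Z %*% incidence_coefs) else 0
    susceptible <- rbinom(n, 1L, plogis(lp_inc))
    lp_lat <- if (length(latency_coefs)) as.vector(X %*% latency_coefs)
      else rep(0, n)
    # Weibull PH: S(t) = exp(-(t/scale)^shape * e^lp)
    scale_i <- spec$latency_scale * exp(-lp_lat / spec$latency_shape)
    t_event <- rweibull(n, shape = spec$latency_shape, scale = scale_i)
    admin <- runif(n, spec$admin_min, spec$admin_max)
    cens <- if (spec$dropout_rate > 0) {
      pmin(admin, rexp(n, spec$dropout_rate))
    } else admin
    time <- ifelse(susceptible == 1, pmin(t_event, cens), cens)
    event <- as.integer(susceptible == 1 & t_event <= cens)
    tibble::tibble(time_years = time, event = event,
                   susceptible = as.integer(susceptible),
                   true_event_time = ifelse(susceptible == 1, t_event,
                                            Inf),
                   censor_time = cens)
  })
}

# encoded dose for the generating model of one SNP
snp_dose <- function(codes, model) {
  switch(model %||% "additive",
         additive = as.numeric(codes),
         dominant = as.numeric(codes >= 1),
         recessive = as.numeric(codes == 2),
         stop_curescan("snp_model must be additive, dominant or recessive",
                       "curescan_bad_input"))
}

#' Simulate a full synthetic cohort
#'
#' Genotypes, baseline covariates and cure-mixture outcomes per
#' [cohort_spec()]. SNP and covariate effects act on the incidence
#' (log-odds of susceptibility) and/or latency (log-hazard among
#' susceptibles) linear predictors. The latent truth is test-only
#' output.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the whole cohort is deterministic given
#'   `spec` and `seed`.
#' @return List of `genotypes` ([genotype_matrix()]), `clinical`
#'   (analysis-facing tibble, including `stage` and `msi_status` levels
#'   that pass [apply_cohort_filters()]), `truth` (latent tibble) and
#'   `spec`.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n
    gm <- simulate_genotypes(n, spec$maf, spec$missing_rate, seed = NULL)
    cov_tbl <- tibble::as_tibble(lapply(spec$covariates, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    }))
    # incidence / latency designs: SNP doses (effects act on the true,
    # unmasked genotypes) plus covariate level indicators
    z_cols <- list(); zc <- numeric(0)
    x_cols <- list(); xc <- numeric(0)
    truth_codes <- matrix(rbinom(length(spec$maf) * n, 2L,
                                 rep(spec$maf, each = n)),
                          nrow = length(spec$maf), byrow = TRUE)
    # reuse the drawn genotypes (pre-masking) as effect carriers: take
    # the simulated matrix and fill its missing cells from HWE draws
    codes_eff <- gm$codes
    nas <- which(is.na(codes_eff), arr.ind = TRUE)
    if (nrow(nas)) codes_eff[nas] <- truth_codes[nas]
    for (s in names(spec$maf)) {
      b <- spec$incidence_snp[[s]] %||% 0
      g <- spec$latency_snp[[s]] %||% 0
      if (b != 0 || g != 0) {
        dose <- snp_dose(codes_eff[s, ], spec$snp_model[[s]])
        if (b != 0) { z_cols[[s]] <- dose; zc <- c(zc, b) }
        if (g != 0) { x_cols[[s]] <- dose; xc <- c(xc, g) }
      }
    }
    for (v in names(spec$incidence_covariate %||% list())) {
      for (lev in names(spec$incidence_covariate[[v]])) {
        z_cols[[paste(v, lev, sep = ":")]] <-
          as.numeric(cov_tbl[[v]] == lev)
        zc <- c(zc, spec$incidence_covariate[[v]][[lev]])
      }
    }
    for (v in names(spec$latency_covariate %||% list())) {
      for (lev in names(spec$latency_covariate[[v]])) {
        x_cols[[paste(v, lev, sep = ":")]] <-
          as.numeric(cov_tbl[[v]] == lev)
        xc <- c(xc, spec$latency_covariate[[v]][[lev]])
      }
    }
    Z <- if (length(z_cols)) do.call(cbind, z_cols) else
      matrix(numeric(0), n, 0)
    X <- if (length(x_cols)) do.call(cbind, x_cols) else
      matrix(numeric(0), n, 0)
    oc <- simulate_outcomes(Z, X, zc, xc, spec, seed = NULL)
    clinical <- dplyr::bind_cols(
      tibble::tibble(patient_id = gm$patients),
      cov_tbl,
      tibble::tibble(
        msi_status = sample(c("MSS", "MSI-L"), n, replace = TRUE,
                            prob = c(0.85, 0.15)),
        time_years = oc$time_years, event = oc$event
      )
    )
    if (!"stage" %in% names(clinical)) clinical$stage <- "II"
    truth <- tibble::tibble(patient_id = gm$patients,
                            susceptible = oc$susceptible,
                            true_event_time = oc$true_event_time,
                            censor_time = oc$censor_time)
    list(genotypes = gm, clinical = clinical, truth = truth, spec = spec)
  })
}

#' Adversarial routing fixtures
#'
#' Small constructed cohorts exercising every routing branch:
#' \describe{
#'   \item{cure_crossing}{a recessive SNP whose minor-homozygote group
#'     has a higher cure fraction but a much faster event rate among
#'     susceptibles, so the survival curves cross and every category
#'     plateaus strictly inside (0, 1) — the mixture-cure branch;}
#'   \item{cox_zero_plateau}{a SNP whose minor homozygotes all have the
#'     event within about two years (plateau 0) — the Cox branch;}
#'   \item{logrank_event_free}{a SNP whose minor-homozygote group is
#'     event-free (plateau 1) — the log-rank branch;}
#'   \item{skipped_rare}{a SNP with exactly one minor homozygote —
#'     skipped under the recessive and co-dominant models.}
#' }
#'
#' @param seed Integer seed.
#' @return Named list; each element has `genotypes`, `clinical`,
#'   `model` and `expected_method`.
#' @export
routing_fixtures <- function(seed = 1L) {
  base_spec <- cohort_spec(n = 379L, maf = c(snp_1 = 0.38))
  fx <- list()
  with_seed(seed, {
    # (i) crossing curves, all plateaus in (0, 1): the minor-homozygote
    # group gets a slightly lower event fraction but all its events
    # within the first two years, so its survival drops fast and then
    # plateaus above the slowly declining majority curve
    co <- simulate_cohort(base_spec, seed = NULL)
    hom1 <- which(co$genotypes$codes["snp_1", ] == 2L)
    d1 <- max(2L, round(0.19 * length(hom1)))
    ev1 <- hom1[seq_len(d1)]
    co$clinical$time_years[ev1] <- seq(0.15, 1.2, length.out = d1)
    co$clinical$event[ev1] <- 1L
    late <- setdiff(hom1, ev1)
    co$clinical$time_years[late] <- runif(length(late), 7.0, 10.9)
    co$clinical$event[late] <- 0L
    fx$cure_crossing <- list(genotypes = co$genotypes,
                             clinical = co$clinical,
                             model = "recessive",
                             expected_method = "mixture-cure")

    # (ii) zero plateau: every minor homozygote has an early event
    co2 <- simulate_cohort(base_spec, seed = NULL)
    hom <- which(co2$genotypes$codes["snp_1", ] == 2L)
    co2$clinical$time_years[hom] <- runif(length(hom), 0.2, 2.0)
    co2$clinical$event[hom] <- 1L
    fx$cox_zero_plateau <- list(genotypes = co2$genotypes,
                                clinical = co2$clinical,
                                model = "recessive",
                                expected_method = "cox")

    # (iii) event-free group: every minor homozygote censored late
    co3 <- simulate_cohort(base_spec, seed = NULL)
    hom3 <- which(co3$genotypes$codes["snp_1", ] == 2L)
    co3$clinical$time_years[hom3] <- runif(length(hom3), 8.0, 10.9)
    co3$clinical$event[hom3] <- 0L
    fx$logrank_event_free <- list(genotypes = co3$genotypes,
                                  clinical = co3$clinical,
                                  model = "recessive",
                                  expected_method = "log-rank")

    # (iv) a single minor homozygote: skipped for recessive/co-dominant
    co4 <- simulate_cohort(base_spec, seed = NULL)
    codes <- co4$genotypes$codes
    hom4 <- which(codes["snp_1", ] == 2L)
    if (length(hom4) == 0L) {
      codes["snp_1", 1L] <- 2L
    } else if (length(hom4) > 1L) {
      codes["snp_1", hom4[-1L]] <- 1L
    }
    co4$genotypes <- genotype_matrix(codes, co4$genotypes$snps,
                                     co4$genotypes$patients)
    fx$skipped_rare <- list(genotypes = co4$genotypes,
                            clinical = co4$clinical,
                            model = "recessive",
                            expected_method = "skipped")
  })
  fx
}
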