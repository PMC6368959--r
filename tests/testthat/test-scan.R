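# genetic-model encoding, routing, the univariable scan, validity tests
# and multivariable refits

test_that("the four encodings map minor-allele counts as defined", {
  enc_r <- encode_genotype(c(0, 1, 2), "recessive")
  expect_equal(unname(enc_r$design[, 1]), c(0, 0, 1))
  enc_c <- encode_genotype(c(0, 1, 2), "codominant")
  expect_equal(unname(enc_c$design[, "het"]), c(0, 1, 0))
  expect_equal(unname(enc_c$design[, "hom_minor"]), c(0, 0, 1))
  enc_a <- encode_genotype(c(0, 1, 2, NA), "additive")
  expect_equal(unname(enc_a$design[, 1]), c(0, 1, 2))
  expect_equal(sum(enc_a$used), 3L)
  enc_d <- encode_genotype(c(0, 0, 1, 2), "dominant")
  expect_equal(unname(enc_d$design[, 1]), c(0, 0, 1, 1))
  expect_equal(enc_d$tested$freq, 0.5)
  # no minor homozygotes: recessive tested-category count 0 -> skip
  enc0 <- encode_genotype(c(0, 1, 1, 0), "recessive")
  expect_true(enc0$skip)
  expect_match(enc0$skip_reason, "< 2 patients")
})

test_that("routing follows the plateau rules with log-rank precedence", {
  # categories: 0 -> mixed (plateau in (0,1)); construct per scenario
  n_per <- 30
  tt_mix <- c(runif(10, 0.5, 4), runif(20, 7, 10))
  ee_mix <- c(rep(1, 10), rep(0, 20))
  # (a) both categories mixed -> mixture-cure
  codes <- rep(c(0, 2), each = n_per)
  r <- route_snp(codes, "recessive", c(tt_mix, tt_mix), c(ee_mix, ee_mix))
  expect_equal(r$method, "mixture-cure")
  expect_true(all(r$plateaus[[1]] > 0 & r$plateaus[[1]] < 1))
  # (b) minor homozygotes all events -> cox
  r2 <- route_snp(codes, "recessive", c(tt_mix, runif(n_per, 0.2, 2)),
                  c(ee_mix, rep(1, n_per)))
  expect_equal(r2$method, "cox")
  # (c) minor homozygotes event-free -> log-rank
  r3 <- route_snp(codes, "recessive", c(tt_mix, runif(n_per, 7, 10)),
                  c(ee_mix, rep(0, n_per)))
  expect_equal(r3$method, "log-rank")
  # (d) precedence: one category at plateau 1 and another at 0 -> log-rank
  codes3 <- rep(c(0, 1, 2), each = n_per)
  tt <- c(tt_mix, runif(n_per, 0.2, 2), runif(n_per, 7, 10))
  ee <- c(ee_mix, rep(1, n_per), rep(0, n_per))
  r4 <- route_snp(codes3, "codominant", tt, ee)
  expect_equal(r4$method, "log-rank")
  # (e) < 2 patients in a routing category -> skipped
  r5 <- route_snp(c(rep(0, 50), rep(1, 20), 2), "recessive",
                  runif(71, 1, 9), rbinom(71, 1, 0.3))
  expect_equal(r5$method, "skipped")
})

test_that("the Bonferroni threshold is alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 810622), 2), 6.2e-8)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  expect_error(bonferroni_threshold(0.05, 0), class = "curescan_bad_input")
  expect_error(bonferroni_threshold(1.2, 10), class = "curescan_bad_input")
})

test_that("a planted latency effect is detected under its generating model", {
  hits <- 0L
  for (s in 1:8) {
    spec <- cohort_spec(n = 379, maf = c(s1 = 0.35, s2 = 0.3),
                        latency_snp = c(s1 = log(3), s2 = 0))
    co <- simulate_cohort(spec, seed = 300 + s)
    sc <- univariable_scan(co$genotypes, co$clinical, models = "additive",
                           alpha = 0.05, n_tests = 2)
    row <- sc[sc$snp_id == "s1", ]
    hits <- hits + isTRUE(row$significant)
    expect_equal(row$method, "mixture-cure")
  }
  expect_gte(hits, 5L)
})

test_that("scan rows for rare homozygotes are skipped exactly where mandated", {
  # one minor homozygote: recessive/codominant skipped, additive/dominant kept
  set.seed(88)
  n <- 120
  codes <- matrix(c(rep(0L, 70), rep(1L, 49), 2L), nrow = 1)
  gm <- genotype_matrix(codes,
                        tibble::tibble(snp_id = "rs9", chrom = "1",
                                       pos = 1L, allele_minor = "A",
                                       allele_major = "G"),
                        sprintf("P%03d", 1:n))
  outcome <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                            time_years = c(runif(40, 0.5, 5),
                                           runif(80, 6, 10)),
                            event = c(rep(1L, 40), rep(0L, 80)))
  sc <- univariable_scan(gm, outcome)
  expect_equal(sc$method[sc$model == "recessive"], "skipped")
  expect_equal(sc$method[sc$model == "codominant"], "skipped")
  expect_false(any(sc$method[sc$model %in% c("additive", "dominant")] ==
                     "skipped"))
})

test_that("scan output is deterministic and routing is exhaustive", {
  spec <- cohort_spec(n = 250, maf = c(a = 0.25, b = 0.4, c = 0.1))
  co <- simulate_cohort(spec, seed = 15)
  s1 <- univariable_scan(co$genotypes, co$clinical, seed = 2)
  s2 <- univariable_scan(co$genotypes, co$clinical, seed = 2)
  expect_identical(s1, s2)
  expect_true(all(s1$method %in%
                    c("mixture-cure", "cox", "log-rank", "skipped")))
  expect_equal(nrow(s1), 3L * 4L)
})

test_that("additive and dominant rows stay off the cox branch at common MAFs", {
  spec <- cohort_spec(n = 379,
                      maf = setNames(runif(30, 0.25, 0.45) |>
                                       round(2), sprintf("c%02d", 1:30)))
  co <- simulate_cohort(spec, seed = 51)
  sc <- univariable_scan(co$genotypes, co$clinical,
                         models = c("additive", "dominant"))
  expect_false(any(sc$method == "cox"))
})

test_that("coinciding nested models are plausible with a zero LR statistic", {
  # no minor homozygotes: dominant and co-dominant encodings coincide
  set.seed(19)
  n <- 160
  codes <- matrix(sample(c(0L, 1L), n, TRUE), nrow = 1)
  gm <- genotype_matrix(codes,
                        tibble::tibble(snp_id = "rs1", chrom = "1",
                                       pos = 1L, allele_minor = "A",
                                       allele_major = "G"),
                        sprintf("P%03d", 1:n))
  outcome <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                            time_years = runif(n, 0.3, 10),
                            event = rbinom(n, 1, 0.3))
  v <- model_validity(gm, outcome, "rs1", "dominant")
  expect_equal(v$validity, "plausible")
  expect_equal(v$statistic, 0, tolerance = 1e-6)
  expect_equal(v$df, 0)
})

test_that("model validity has near-nominal size and real power", {
  # size: data generated truly dominant -> dominant rarely rejected
  rej_size <- 0L
  for (s in 1:25) {
    spec <- cohort_spec(n = 379, maf = c(g = 0.35),
                        latency_snp = c(g = log(2.5)),
                        snp_model = list(g = "dominant"))
    co <- simulate_cohort(spec, seed = 700 + s)
    v <- model_validity(co$genotypes, co$clinical, "g", "dominant",
                        method = "mixture-cure")
    rej_size <- rej_size + (v$validity == "rejected")
  }
  expect_lte(rej_size, 5L)    # nominal 5% of 25, generous slack
  # power: heterozygote-only effect makes the recessive encoding wrong
  rej_pow <- 0L
  for (s in 1:12) {
    co <- simulate_cohort(cohort_spec(n = 400, maf = c(g = 0.45)),
                          seed = 800 + s)
    het <- co$genotypes$codes["g", ] == 1L
    # impose an early-event excess only among heterozygotes
    idx <- which(het & runif(400) < 0.25)
    co$clinical$time_years[idx] <- runif(length(idx), 0.2, 1.5)
    co$clinical$event[idx] <- 1L
    v <- model_validity(co$genotypes, co$clinical, "g", "recessive",
                        method = "mixture-cure")
    rej_pow <- rej_pow + (v$validity == "rejected")
  }
  expect_gte(rej_pow, 7L)
})

test_that("multivariable adjustment leaves an unconfounded effect and fixes a confounded one", {
  # outcome-neutral covariates: adjusted close to univariable
  spec <- cohort_spec(n = 379, maf = c(g = 0.35),
                      latency_snp = c(g = log(3)))
  co <- simulate_cohort(spec, seed = 21)
  un <- univariable_scan(co$genotypes, co$clinical, models = "additive")
  ad <- multivariable_refit(co$genotypes, co$clinical, "g", "additive",
                            covariates = c("sex", "location"))
  expect_lt(abs(log(ad$hr) - log(un$hr)), 0.4)
  expect_match(ad$note, "sex, location")
  # a covariate driving both genotype and outcome biases the crude fit;
  # adjustment moves the estimate toward the truth (null)
  biases <- replicate(6, {
    s <- sample.int(1e6, 1)
    n <- 500
    set.seed(s)
    u <- rbinom(n, 1, 0.5)  # binary confounder
    g <- rbinom(n, 2, ifelse(u == 1, 0.45, 0.15))
    spec2 <- cohort_spec(n = n, maf = c(g = 0.3),
                         covariates = list(
                           risk = c(lo = 0.5, hi = 0.5)),
                         latency_covariate = list(risk = c(hi = log(3))))
    co2 <- simulate_cohort(spec2, seed = s)
    # overwrite: genotype tied to the risk covariate, null SNP effect
    u2 <- as.numeric(co2$clinical$risk == "hi")
    g2 <- rbinom(n, 2, ifelse(u2 == 1, 0.45, 0.15))
    codes <- matrix(as.integer(g2), nrow = 1,
                    dimnames = list("g", co2$genotypes$patients))
    gm2 <- genotype_matrix(codes, co2$genotypes$snps,
                           co2$genotypes$patients)
    crude <- univariable_scan(gm2, co2$clinical, models = "additive")
    adj <- multivariable_refit(gm2, co2$clinical, "g", "additive",
                               covariates = "risk",
                               method = "mixture-cure")
    c(crude = abs(log(crude$hr)), adj = abs(log(adj$hr)))
  })
  expect_lt(median(biases["adj", ]), median(biases["crude", ]))
})

test_that("complete-case exclusion shrinks the refit sample accordingly", {
  spec <- cohort_spec(n = 379, maf = c(g = 0.35))
  co <- simulate_cohort(spec, seed = 30)
  clin <- co$clinical
  clin$treatment_5fu <- "treated"
  clin$treatment_5fu[1:30] <- "unknown"
  ad <- multivariable_refit(co$genotypes, clin, "g", "additive",
                            covariates = "treatment_5fu",
                            method = "mixture-cure")
  expect_equal(ad$n_used, 349L)
})
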