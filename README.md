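# curescan

Adaptive genome-wide association analysis for time-to-event outcomes in
cohorts that contain long-term event-free survivors — the situation of
time-to-metastasis in stage I–III colorectal cancer with
microsatellite-stable/MSI-low tumors, where the Kaplan–Meier curve
plateaus at a non-zero value (≈ 0.71) because a large fraction of
patients will never metastasize.

## Who this is for

Statistical geneticists and biostatisticians running survival GWAS on
registry-style cohorts (hundreds of patients, hundreds of thousands of
SNPs) where a cured fraction makes the plain Cox model the wrong
default, and methodologists who want a tested reference implementation
of the semiparametric mixture cure model with EM fitting.

## The model

Population survival decomposes as a two-component mixture,

    S_pop(t | z, x) = 1 − π(z) + π(z) · S_u(t | x)

with logistic **incidence** π(z) = expit(b′z), the probability of being
susceptible (effects reported as odds ratios), and proportional-hazards
**latency** S_u(t | x) = S_0(t)^exp(β′x) among susceptibles (hazard
ratios), fitted by EM: posterior susceptibility weights in the E-step;
fractional-response logistic regression, an offset-weighted Cox partial
likelihood and a weighted Breslow baseline under the zero-tail
constraint (S_u ≡ 0 past the last event time) in the M-step.

The model is fitted per SNP only where it applies. For every SNP ×
genetic model (additive, dominant, recessive, co-dominant), the
long-term Kaplan–Meier estimates of the genotype categories route the
analysis: all plateaus strictly in (0, 1) → mixture cure; a category
at 1 → log-rank test (precedence); a category at 0 → Cox model with a
proportionality score test on hits; categories with fewer than two
patients → skipped. Around the scan sit genotype QC (exact
Hardy–Weinberg, missingness, MAF), genetic-model validity via nested
likelihood-ratio tests against the co-dominant encoding,
covariate screening/backward selection with forced-in variables, a
Bonferroni threshold of α over the SNP count, and a calibrated
synthetic cohort generator.

## Worked example

```r
library(curescan)
library(dplyr)

spec <- cohort_spec(                 # defaults: n = 379, 21% events,
  maf = c(rs_null = 0.30,            # KM plateau 0.71, follow-up <= 10.9 y
          rs_hit = 0.35),
  latency_snp = c(rs_hit = log(3))   # rs_hit: HR 3 among susceptibles
)
cohort <- simulate_cohort(spec, seed = 2026)

mean(cohort$clinical$event)
#> [1] 0.2163588
long_term_estimate(kaplan_meier(cohort$clinical$time_years,
                                cohort$clinical$event))
#> [1] 0.7331559

scan <- univariable_scan(cohort$genotypes, cohort$clinical,
                         models = c("additive", "recessive"), seed = 1)
scan |> select(snp_id, model, method, or, hr, p_value, significant)
#> # A tibble: 4 × 7
#>   snp_id  model     method          or    hr     p_value significant
#>   <chr>   <chr>     <chr>        <dbl> <dbl>       <dbl> <lgl>
#> 1 rs_null additive  mixture-cure 1.12  0.890 0.791       FALSE
#> 2 rs_null recessive mixture-cure 0.877 0.623 0.550       FALSE
#> 3 rs_hit  additive  mixture-cure 1.20  3.12  0.000000126 TRUE
#> 4 rs_hit  recessive mixture-cure 1.22  3.34  0.00844     TRUE
```

Every cohort routed to the cure branch here (all genotype plateaus in
(0, 1)); the planted SNP is recovered under its generating (additive)
model with HR ≈ 3, while the null SNP stays null. `p_value` is the
joint likelihood-ratio test of the SNP in both model components.
Bootstrap confidence intervals for a candidate hit:

```r
dat <- mutate(cohort$clinical,
              g = as.integer(cohort$genotypes$codes["rs_hit", ]))
fit <- fit_mixture_cure(dat, time_years, event,
                        incidence = ~ g, latency = ~ g,
                        se_method = "bootstrap", n_boot = 199, seed = 7)
tidy(fit)
#> # A tibble: 3 × 8
#>   component term        estimate ratio std_error conf_low conf_high  p_value
#>   <chr>     <chr>          <dbl> <dbl>     <dbl>    <dbl>     <dbl>    <dbl>
#> 1 incidence (Intercept)   -1.13  0.324     0.211    0.223     0.492 8.75e- 8
#> 2 incidence g              0.184 1.20      0.187    0.840     1.64  3.26e- 1
#> 3 latency   g              1.14  3.12      0.184    2.24      4.56  6.23e-10
```

The odds of being susceptible are unchanged by the genotype (OR 1.20,
CI spans 1) while the event rate among susceptibles triples per minor
allele (HR 3.12, CI 2.24–4.56) — the separation of "whether" from
"when" that the mixture cure model provides. `autoplot()` methods
exist for Kaplan–Meier curves and cure fits, `plot_km_groups()` draws
per-genotype curves with their plateaus, and `plot_scan()` gives a
Manhattan-style overview. A thin command-line front end
(`inst/scripts/curescan.R`, subcommands `run`, `select-covariates`,
`simulate`) wraps the same functions for shell pipelines.

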