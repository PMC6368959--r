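---
title: "Adaptive survival GWAS with a mixture cure model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive survival GWAS with a mixture cure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curescan)
library(dplyr)
```

## The problem

In many cancer cohorts a substantial fraction of patients never
experiences the outcome of interest — here, distant metastasis in stage
I–III colorectal cancer patients with microsatellite-stable or MSI-low
tumors — no matter how long they are followed. The Kaplan–Meier curve
of such a cohort plateaus at a non-zero value (about 0.71 in the cohort
this package is calibrated to), which standard survival models do not
represent: a Cox model assumes everyone is eventually at risk, so a
covariate that only shifts *when* susceptible patients fail, or only
*whether* a patient is susceptible at all, is diluted or missed
entirely.

The mixture cure model decomposes the population survival as

$$ S_{pop}(t \mid z, x) \;=\; 1 - \pi(z) \;+\; \pi(z)\, S_u(t \mid x), $$

where $\pi(z) = \operatorname{expit}(b'z)$ is the probability of being
susceptible (the **incidence** component, reported as odds ratios) and
$S_u$ is the survival of susceptible patients (the **latency**
component, a proportional-hazards model reported as hazard ratios).
`curescan` fits this model per SNP across a genome-wide panel, but only
where it is the right tool; elsewhere it falls back to conventional
methods.

## Adaptive routing

For each SNP and genetic model (additive, dominant, recessive,
co-dominant), the long-term Kaplan–Meier estimate — the survival value
at each genotype category's own last follow-up — decides the method:

* all category plateaus strictly in $(0, 1)$ → **mixture cure model**;
* some category plateaus at 1 (an event-free genotype group) →
  **log-rank test**, which takes precedence;
* otherwise some category plateaus at 0 (everyone susceptible) →
  **Cox proportional hazards**, with a scaled-Schoenfeld-residual score
  test of proportionality on significant hits.

Routing categories are the categories the fitted model sees: the two
collapsed groups for dominant and recessive, the three raw genotypes
for co-dominant. The additive trend is checked on the raw genotypes,
but raw cells with fewer than two patients neither block the 1-df fit
nor take part in the plateau check; encodings whose defining categories
have fewer than two patients are skipped outright. This keeps the
additive and dominant models available genome-wide while rare
homozygote cells rule out only the recessive and co-dominant
encodings, the behaviour the reference analysis reports.

## Fitting: EM with a zero-tail Breslow baseline

The semiparametric fit alternates:

* **E-step** — posterior susceptibility weights
  $w_i = \pi_i S_u(t_i)/(1 - \pi_i + \pi_i S_u(t_i))$ for censored
  patients ($w_i = 1$ for events);
* **M-step** — a fractional-response logistic regression of $w$ on the
  incidence design; a weighted Cox partial-likelihood update in which
  $\log w_i$ enters as an offset (so $w_i = 0$ leaves the risk set);
  and a weighted Breslow baseline-hazard update under the **zero-tail
  constraint** ($S_u \equiv 0$ beyond the largest event time), which is
  what makes the cure fraction identifiable.

Because the M-step exactly maximizes the observed-data likelihood
profiled over the discrete baseline, the observed log-likelihood ascends
monotonically; the package asserts this in its tests at every iteration.
For exact coherence between the partial-likelihood update and the
likelihood being monitored, the EM uses Breslow tie handling internally;
`cox_fit()` itself defaults to Efron, the survival-ecosystem standard.
Convergence is an absolute observed-log-likelihood change below `1e-6`
(or 500 iterations, recorded as non-convergence rather than raised).
Incidence separation (a genotype cell that is all-event or
all-censored) is capped at $|b| = 15$ with a flag rather than allowed
to diverge. When no censored subject lies beyond the last event time
the cure fraction is weakly identified and the fit carries a warning.

A parametric Weibull-latency variant (`latency_form = "weibull"`,
fitted by direct likelihood maximization) serves as a cross-check and
supports numeric-Hessian Wald intervals; the reference formulation
whose exact latency form is not recoverable from the source material is
the semiparametric default, the canonical choice matching an OR + HR
output table.

## Inference choices

The semiparametric baseline makes the analytic information matrix
unreliable, so confidence intervals default to a patient-resampling
bootstrap (percentile 2.5/97.5, Wald p-values against the bootstrap SE,
fully seeded). A bootstrap per SNP is far too expensive for a scan,
so the **scan's cure-branch p-value is a joint likelihood-ratio test**
of the SNP terms in both components against the intercept-only cure
model (df = twice the number of SNP design columns). Simulation at the
reference cohort scale (n = 379, 21% events) shows this LR p-value is
well calibrated: rejection at 0.05 near 0.050 and far-tail rejection
near nominal at $5\times10^{-4}$, which is what the family-wise-error
suite verifies. Bootstrap inference remains available
(`p_method = "bootstrap"`, `cure_se()`) and is the intended tool for
candidate hits and multivariable refits, not full panels.

Genetic-model validity uses the nesting of additive/dominant/recessive
in the co-dominant model: a likelihood-ratio test (observed-data
likelihood on the cure branch, partial likelihood on the Cox branch) at
$\alpha = 0.05$ (configurable; the reference analysis does not state
its level), with constant co-dominant columns dropped so coinciding
models yield a zero statistic with zero degrees of freedom. The
Bonferroni denominator is the number of SNPs, not SNP × model pairs,
matching the genome-wide convention of dividing 0.05 by the post-QC SNP
count.

## Covariate selection

Baseline characteristics are screened univariably at a liberal
$p < 0.10$, separately per model family: under the cure family a
covariate qualifies if associated with either the long-term risk
(incidence) or the timing (latency) of metastasis; under the Cox
family, with timing. Backward selection then removes the worst
non-forced variable at $p \ge 0.05$ per round, with forced variables
(such as 5-FU treatment status) never removed. Patients with an unknown
level in any participating variable are excluded once, up front, so all
steps fit on the same patients; ties drop the variable later in the
given order, making the trace deterministic.

Removal p-values are the joint Wald test across a variable's levels for
the Cox family. For the cure family no analytic covariance is
available without bootstrap, so the package uses component-wise
likelihood-ratio p-values instead, combined as the minimum over
incidence and latency (`combine = "either"`: a variable is kept if it
matters in either component; `"both"` uses the maximum). How the
reference analysis combined the two component p-values is not stated;
this is the package's documented choice.

## The synthetic cohort generator

`cohort_spec()` defaults encode the cohort the analysis is calibrated
to: 379 stage I–III MSI-L/MSS patients; covariate marginals drawn from
the shipped baseline table (36.7% female, stage I/II/III at
21.4/41.7/36.9%, and so on); susceptibility intercept
$\operatorname{qlogis}(0.29)$, the complement of the 0.71 plateau;
Weibull(shape 1.2, scale 2.5 y) latency, putting roughly 90% of
susceptible events inside 5 years as the early-metastasis pattern
requires; administrative censoring uniform on 7.0–10.9 years (a 4-year
accrual window closing 10.9 years after first enrolment, the longest
follow-up in the reference cohort); and exponential dropout at
0.15/year, solved numerically once so the expected event fraction is
21% under the other defaults. MSI status is drawn 85% MSS / 15% MSI-L,
a realistic split for a stage I–III MSI-L/MSS cohort; the analysis
never models it. Genotypes are independent HWE draws with
missingness completely at random; SNP and covariate effects enter the
incidence and/or latency linear predictors; the latent cure status and
true event times are returned for tests only.

What the generator deliberately does **not** emulate: genome-wide LD
structure (an optional copy-with-flip-noise construction serves the LD
tests), population stratification, genotyping batch effects,
informative censoring, and covariate-covariate correlation (Table-1
marginals are sampled independently unless a confounding scenario wires
a covariate into both the genotype and outcome models). Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated generative model, not robustness to those real-data
features.

`routing_fixtures()` adds adversarial constructions exercising every
routing branch, including a crossing-curves SNP whose minor-homozygote
group has all its events inside two years but a higher long-term
plateau (about 0.8) — the configuration where the cure branch finds a
strong latency signal while a forced Cox fit, its early excess
cancelled by the later deficit, sees nothing. The suite checks both
halves of that claim.

## Numerical and scale choices

Problem sizes in the test suite are chosen to keep the full suite in
the tens of minutes on a single core while leaving Monte-Carlo error
well inside the asserted bands: parameter recovery uses 200 replicates
at n = 2000; the proportional-hazards type-I suite 1000 replicates at
n = 200; the family-wise-error suite 200 scans of 100 SNPs at n = 379
under the additive model with the joint LR p-value. The exact
Hardy-Weinberg test enumerates the conditional heterozygote
distribution in log space (stable into the thousands of samples);
monomorphic SNPs return 1, and the QC boundary rules are: exclude MAF
< 1%, exclude missingness > 5%, exclude HWE p below `1e-6` — the
conventional genome-wide QC level, configurable because the reference
analysis prints no threshold. LD is the composite genotype-correlation
$r^2$, not the EM-phased haplotype $r^2$; the two agree in the
near-complete-LD regime reported on, which is the documented limitation
of that shortcut.

## Known limitations

Semiparametric cure models are fragile when few censored observations
lie beyond the last event time; the package warns rather than refuses.
The scan's LR p-values lean on chi-square asymptotics that weaken in
very small genotype cells (the small-category guard removes the worst
cases). No imputation, sample-level QC, time-varying covariates,
frailty, left truncation, or non-mixture (promotion-time) cure models
are provided, and multi-allelic variants are rejected at parse time.
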