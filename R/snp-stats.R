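#' Minor allele frequency of a genotype vector
#'
#' Frequency of the counted allele, `sum(codes) / (2 * non-missing)`,
#' folded to `min(f, 1 - f)` so the result is always the rarer allele's
#' frequency. Missing codes are excluded from numerator and denominator.
#'
#' @param codes Vector of minor-allele counts in `{0, 1, 2, NA}`.
#' @return A frequency in `[0, 0.5]`.
#' @examples
#' minor_allele_frequency(c(0, 1, 1, 2))  # 0.5
#' @export
minor_allele_frequency <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) {
    stop_curescan("all genotype codes missing", "curescan_undefined_input")
  }
  f <- sum(codes) / (2 * length(codes))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test of HWE from genotype counts: the p-value is the total
#' probability, under the conditional distribution of the heterozygote
#' count given the allele counts, of all outcomes no more probable than
#' the observed one (no mid-p adjustment). Monomorphic SNPs return 1.
#' The exact form is preferred over the chi-square approximation because
#' rare-genotype categories make asymptotics unreliable.
#'
#' @param n_major_hom,n_het,n_minor_hom Non-negative genotype counts.
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_major_hom, n_het, n_minor_hom) {
  counts <- c(n_major_hom, n_het, n_minor_hom)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_curescan("genotype counts must be non-negative", "curescan_bad_input")
  }
  n <- sum(counts)
  if (n < 1L) stop_curescan("total genotype count must be >= 1",
                            "curescan_bad_input")
  n_minor <- 2 * n_minor_hom + n_het
  n_minor <- min(n_minor, 2 * n - n_minor)  # fold to the rarer allele
  if (n_minor == 0) return(1)
  # heterozygote counts share the parity of the minor-allele count
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_minor) up to a constant:
  # n! 2^h / (n_aa! h! n_bb!), with n_bb = (n_minor - h)/2 minor homozygotes
  lp <- vapply(hs, function(h) {
    n_bb <- (n_minor - h) / 2
    n_aa <- n - h - n_bb
    h * log(2) - lfactorial(n_aa) - lfactorial(h) - lfactorial(n_bb)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hs == n_het)
  if (length(obs) == 0L) {
    stop_curescan("heterozygote count inconsistent with allele count parity",
                  "curescan_bad_input")
  }
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Squared-correlation linkage disequilibrium between two SNPs
#'
#' Composite (genotype-correlation) r-squared: the squared Pearson
#' correlation of minor-allele counts over jointly non-missing patients.
#' This is the genotype-based definition, not EM-phased haplotype
#' r-squared; the two agree in the near-complete-LD regime this package
#' reports on.
#'
#' @param codes_a,codes_b Genotype vectors over the same patients.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) {
    stop_curescan("genotype vectors must cover the same patients",
                  "curescan_dim_mismatch")
  }
  ok <- !is.na(codes_a) & !is.na(codes_b)
  a <- codes_a[ok]; b <- codes_b[ok]
  if (length(a) < 2L || stats::var(a) == 0 || stats::var(b) == 0) {
    stop_curescan("zero variance among jointly non-missing genotypes",
                  "curescan_undefined_input")
  }
  stats::cor(a, b)^2
}

#' Per-SNP summary statistics
#'
#' MAF, missing fraction and exact HWE p-value for every SNP in a
#' genotype matrix.
#'
#' @param gm A [genotype_matrix()].
#' @return Tibble with columns `snp_id`, `maf`, `missing_frac`, `hwe_p`.
#' @export
snp_summary <- function(gm) {
  codes <- gm$codes
  n_miss <- rowSums(is.na(codes))
  n_obs <- ncol(codes) - n_miss
  tibble::tibble(
    snp_id = gm$snps$snp_id,
    maf = vapply(seq_len(nrow(codes)), function(i) {
      if (n_obs[i] == 0L) NA_real_ else minor_allele_frequency(codes[i, ])
    }, numeric(1)),
    missing_frac = n_miss / ncol(codes),
    hwe_p = vapply(seq_len(nrow(codes)), function(i) {
      x <- codes[i, ]
      if (n_obs[i] == 0L) return(NA_real_)
      hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                     sum(x == 2, na.rm = TRUE))
    }, numeric(1))
  )
}

#' SNP quality-control filter
#'
#' Retains SNPs that pass all three marker-level filters: exact HWE
#' p-value at least `hwe_alpha`, missing fraction at most `max_missing`,
#' and MAF at least `min_maf` (boundary values are retained; rare SNPs
#' with MAF below 1% are excluded by default, as are SNPs with more than
#' 5% missing codes). The HWE significance level defaults to the
#' conventional genome-wide QC value 1e-6 and is configurable.
#'
#' @param gm A [genotype_matrix()].
#' @param hwe_alpha HWE exclusion level in (0, 1).
#' @param max_missing Maximum tolerated missing fraction in (0, 1).
#' @param min_maf Minimum MAF in (0, 1).
#' @return A list with `genotypes` (the filtered [genotype_matrix()]),
#'   `report` (one-row tibble of counts per filter plus thresholds; SNPs
#'   can fail several filters, so failure counts need not sum to the
#'   number removed) and `per_snp` (the [snp_summary()] table with
#'   pass/fail flags).
#' @export
snp_qc <- function(gm, hwe_alpha = 1e-6, max_missing = 0.05,
                   min_maf = 0.01) {
  for (th in c(hwe_alpha, max_missing, min_maf)) {
    if (!is.finite(th) || th <= 0 || th >= 1) {
      stop_curescan("QC thresholds must lie in (0, 1)", "curescan_bad_input")
    }
  }
  s <- snp_summary(gm)
  fail_hwe <- !is.na(s$hwe_p) & s$hwe_p < hwe_alpha
  fail_miss <- s$missing_frac > max_missing
  fail_maf <- is.na(s$maf) | s$maf < min_maf
  keep <- !(fail_hwe | fail_miss | fail_maf)
  per_snp <- dplyr::mutate(s, fail_hwe = fail_hwe,
                           fail_missingness = fail_miss,
                           fail_maf = fail_maf, retained = keep)
  filtered <- genotype_matrix(gm$codes[keep, , drop = FALSE],
                              gm$snps[keep, , drop = FALSE], gm$patients)
  report <- tibble::tibble(
    n_input_snps = nrow(gm$codes),
    n_failed_hwe = sum(fail_hwe),
    n_failed_missingness = sum(fail_miss),
    n_failed_maf = sum(fail_maf),
    n_retained = sum(keep),
    hwe_alpha = hwe_alpha, max_missing = max_missing, min_maf = min_maf
  )
  list(genotypes = filtered, report = report, per_snp = per_snp)
}
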