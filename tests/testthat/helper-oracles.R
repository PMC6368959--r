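# Independent oracles used across the suite. These deliberately share no
# code with the package: brute-force enumeration, explicit loops and
# textbook formulas only.

# exact HWE test by direct summation over the conditional heterozygote
# distribution with an explicit multinomial normalizing constant
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nB <- 2 * n_bb + n_ab          # minor-allele count (fold below)
  nB <- min(nB, 2 * n - nB)
  if (nB == 0) return(1)
  hs <- seq(nB %% 2, nB, by = 2)
  logp <- sapply(hs, function(h) {
    bb <- (nB - h) / 2
    aa <- n - h - bb
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) +
      lfactorial(nB) + lfactorial(2 * n - nB) - lfactorial(2 * n)
  })
  p <- exp(logp)
  p_obs <- p[hs == n_ab]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# product-limit estimator by explicit loop over distinct event times
oracle_km_last <- function(time, event) {
  s <- 1
  for (u in sort(unique(time[event == 1]))) {
    d <- sum(event == 1 & time == u)
    r <- sum(time >= u)
    s <- s * (1 - d / r)
  }
  s
}

# two-group log-rank (O-E)^2/V via hypergeometric moments at each
# distinct event time
oracle_logrank2 <- function(time, event, group) {
  g1 <- unique(group)[1]
  O <- 0; E <- 0; V <- 0
  for (u in sort(unique(time[event == 1]))) {
    d <- sum(event == 1 & time == u)
    n_tot <- sum(time >= u)
    n1 <- sum(time >= u & group == g1)
    d1 <- sum(event == 1 & time == u & group == g1)
    O <- O + d1
    E <- E + d * n1 / n_tot
    if (n_tot > 1) {
      V <- V + d * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d) / (n_tot - 1)
    }
  }
  (O - E)^2 / V
}

# independent PLINK .bed writer: per-SNP loop packing two-bit fields by
# string arithmetic, structurally unlike the package's vectorized writer
oracle_write_plink <- function(prefix, codes, snps, patients) {
  m <- nrow(codes); n <- ncol(codes)
  bim <- sprintf("%s\t%s\t0\t%d\t%s\t%s", snps$chrom, snps$snp_id,
                 snps$pos, snps$allele_minor, snps$allele_major)
  writeLines(bim, paste0(prefix, ".bim"))
  writeLines(sprintf("%s\t%s\t0\t0\t0\t-9", patients, patients),
             paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bits_of <- function(v) {       # little-endian two-bit field per sample
    if (is.na(v)) return(c(1L, 0L))
    switch(as.character(v),
           "0" = c(1L, 1L), "1" = c(0L, 1L), "2" = c(0L, 0L))
  }
  for (i in seq_len(m)) {
    bitvec <- unlist(lapply(codes[i, ], bits_of))
    pad <- 8 * ceiling(length(bitvec) / 8) - length(bitvec)
    bitvec <- c(bitvec, rep(0L, pad))
    bytes <- vapply(seq(1, length(bitvec), by = 8), function(j) {
      sum(bitvec[j:(j + 7)] * 2^(0:7))
    }, numeric(1))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

# classical proportional-hazards score test for one covariate
# (identity time transform, Breslow baseline, untied data): the exact
# information-based form
oracle_ph_score <- function(time, event, x, beta) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
  evt <- which(e_s == 1)
  r <- exp(x_s * beta)
  gs <- t_s[evt]
  gbar <- mean(gs)
  u <- 0; A <- 0; B <- 0; Vsum <- 0
  for (k in seq_along(evt)) {
    i <- evt[k]
    rs <- i:length(t_s)
    wk <- r[rs] / sum(r[rs])
    xbar <- sum(wk * x_s[rs])
    Vk <- sum(wk * (x_s[rs] - xbar)^2)
    g <- gs[k] - gbar
    u <- u + g * (x_s[i] - xbar)
    A <- A + g^2 * Vk
    B <- B + g * Vk
    Vsum <- Vsum + Vk
  }
  u^2 / (A - B^2 / Vsum)
}

# small deterministic survival fixture used by several files
fixture_six <- function() {
  list(time = c(1, 2, 3, 4, 5, 6),
       event = c(1, 1, 0, 1, 1, 0),
       group = c("a", "b", "a", "b", "a", "b"))
}
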