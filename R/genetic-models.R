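# Genetic-model encodings of a biallelic genotype (minor-allele count x):
#   additive    -> one trend column, the count itself
#   dominant    -> indicator of carrying any minor allele (x >= 1)
#   recessive   -> indicator of the minor homozygote (x == 2)
#   co-dominant -> two free indicators (x == 1) and (x == 2); nests the
#                  other three models
# Routing categories are the categories the fitted model actually sees:
# the two collapsed groups for dominant/recessive, the three raw
# genotypes for co-dominant; the additive trend is checked on the raw
# genotypes but small raw cells (< 2 patients) neither block the 1-df
# fit nor take part in the plateau check.

#' The four genetic models
#'
#' Character vector of the supported genetic-model names, in the order
#' the scan fits them.
#' @export
genetic_models <- c("additive", "dominant", "recessive", "codominant")

#' Encode genotypes under a genetic model
#'
#' @param codes Minor-allele counts in `{0, 1, 2, NA}`; missing codes
#'   are excluded from the design (complete-case per SNP) and reported
#'   via `used`.
#' @param model One of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"codominant"`.
#' @return A list: `design` (numeric matrix over used patients),
#'   `used` (logical over input patients), `raw_counts` (patients per
#'   raw genotype 0/1/2), `routing_group` (factor over used patients
#'   defining the routing categories), `routing_counts`,
#'   `skip` / `skip_reason` (the small-category guard), and
#'   `tested` (label and frequency of the encoding's exposed category).
#' @examples
#' encode_genotype(c(0, 1, 2), "recessive")$design[, 1]
#' @export
encode_genotype <- function(codes, model = genetic_models) {
  model <- match.arg(model)
  used <- !is.na(codes)
  x <- as.numeric(codes[used])
  raw_counts <- c(`0` = sum(x == 0), `1` = sum(x == 1), `2` = sum(x == 2))
  n <- length(x)
  out <- switch(model,
    additive = {
      grp <- factor(x, levels = 0:2)
      big <- raw_counts >= 2
      list(design = cbind(dose = x), routing_group = grp,
           routing_counts = raw_counts[big],
           skip = sum(big) < 2,
           tested = list(label = "per minor allele",
                         freq = if (n) sum(x) / (2 * n) else NA_real_))
    },
    dominant = {
      grp <- factor(ifelse(x >= 1, "carrier", "non-carrier"),
                    levels = c("non-carrier", "carrier"))
      cnt <- table(grp)
      list(design = cbind(carrier = as.numeric(x >= 1)),
           routing_group = grp, routing_counts = c(cnt),
           skip = any(cnt < 2),
           tested = list(label = "1/2 vs 0",
                         freq = if (n) mean(x >= 1) else NA_real_))
    },
    recessive = {
      grp <- factor(ifelse(x == 2, "hom_minor", "other"),
                    levels = c("other", "hom_minor"))
      cnt <- table(grp)
      list(design = cbind(hom_minor = as.numeric(x == 2)),
           routing_group = grp, routing_counts = c(cnt),
           skip = any(cnt < 2),
           tested = list(label = "2 vs 0/1",
                         freq = if (n) mean(x == 2) else NA_real_))
    },
    codominant = {
      grp <- factor(x, levels = 0:2)
      cnt <- table(grp)
      list(design = cbind(het = as.numeric(x == 1),
                          hom_minor = as.numeric(x == 2)),
           routing_group = grp, routing_counts = c(cnt),
           skip = any(cnt < 2),
           tested = list(label = "2 vs 0",
                         freq = if (n) mean(x == 2) else NA_real_))
    }
  )
  out$used <- used
  out$raw_counts <- raw_counts
  out$model <- model
  out$skip_reason <- if (out$skip) "category with < 2 patients" else
    NA_character_
  out
}

#' Route a SNP x genetic model to its analysis method
#'
#' Computes the long-term Kaplan-Meier survival estimate (the plateau
#' value at each group's own last follow-up) for every routing category
#' of the encoding and applies the adaptive rule: all plateaus strictly
#' inside (0, 1) call for the mixture cure model; a category whose
#' plateau is 1 (no events in the group) calls for the log-rank test,
#' taking precedence; otherwise a zero plateau (everyone in a category
#' susceptible) calls for the Cox model. Encodings failing the
#' small-category guard are skipped.
#'
#' @param codes Minor-allele counts (with `NA` for missing).
#' @param model Genetic model name.
#' @param time,event Follow-up data aligned with `codes`.
#' @return One-row tibble: `model`, `method` (`mixture-cure`, `cox`,
#'   `log-rank` or `skipped`), `skip_reason`, `n_used`, and `plateaus`
#'   (list-column of the per-category long-term estimates).
#' @export
route_snp <- function(codes, model, time, event) {
  enc <- encode_genotype(codes, model)
  if (enc$skip) {
    return(tibble::tibble(model = model, method = "skipped",
                          skip_reason = enc$skip_reason,
                          n_used = sum(enc$used),
                          plateaus = list(NULL)))
  }
  tt <- time[enc$used]; ee <- event[enc$used]
  grp <- enc$routing_group
  cats <- names(enc$routing_counts)
  plateaus <- vapply(cats, function(g) {
    sel <- grp == g
    km_last(tt[sel], ee[sel])
  }, numeric(1))
  method <- if (any(plateaus == 1)) "log-rank"
    else if (any(plateaus == 0)) "cox"
    else "mixture-cure"
  tibble::tibble(model = model, method = method,
                 skip_reason = NA_character_, n_used = sum(enc$used),
                 plateaus = list(plateaus))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (for a genome-wide scan, the number of
#'   SNPs).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 810622)  # 6.2e-08 at two significant figures
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_curescan("alpha must lie in (0, 1)", "curescan_bad_input")
  }
  if (!is.finite(n_tests) || n_tests < 1) {
    stop_curescan("n_tests must be >= 1", "curescan_bad_input")
  }
  alpha / n_tests
}
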