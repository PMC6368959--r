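# ggplot2 visualisations for the main result types

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate, dropping to the long-term
#' plateau value at the last follow-up.
#'
#' @param object A [kaplan_meier()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$curve[c("time", "survival")],
    tibble::tibble(time = object$max_followup,
                   survival = long_term_estimate(object))
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years from diagnosis",
                  y = "Event-free survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by genotype category
#'
#' One product-limit curve per group, e.g. the categories of a genetic
#' model encoding, with the per-group long-term estimates in the legend.
#'
#' @param time,event Follow-up data.
#' @param group Group labels.
#' @return A ggplot.
#' @export
plot_km_groups <- function(time, event, group) {
  group <- factor(group)
  steps <- purrr::map_dfr(levels(group), function(g) {
    sel <- group == g
    km <- kaplan_meier(time[sel], event[sel])
    lab <- sprintf("%s (plateau %.2f)", g, long_term_estimate(km))
    dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1),
      km$curve[c("time", "survival")],
      tibble::tibble(time = km$max_followup,
                     survival = long_term_estimate(km))
    ) |> dplyr::mutate(group = lab)
  })
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years from diagnosis",
                  y = "Event-free survival probability", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a fitted mixture cure model
#'
#' The fitted population survival `1 - pi + pi * S_u(t)` at reference
#' covariates (all zero), together with the susceptible-only baseline
#' survival, illustrating the cure plateau.
#'
#' @param object A [fit_mixture_cure()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cure_fit
#' @export
autoplot.cure_fit <- function(object, ...) {
  pi0 <- plogis(object$incidence$estimate[1])
  base <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$baseline[c("time", "survival")]
  )
  dat <- dplyr::bind_rows(
    dplyr::mutate(base, curve = "susceptible baseline S_u"),
    dplyr::mutate(base, survival = 1 - pi0 + pi0 * .data$survival,
                  curve = "population (with cured fraction)")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 1 - pi0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability", colour = NULL,
                  caption = sprintf("cure fraction at reference: %.2f",
                                    1 - pi0)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Manhattan-style plot of a scan result
#'
#' `-log10` p-values by SNP order, coloured by routed method, with the
#' Bonferroni threshold drawn.
#'
#' @param scan A [univariable_scan()] result.
#' @return A ggplot.
#' @export
plot_scan <- function(scan) {
  thr <- attr(scan, "threshold")
  dat <- dplyr::filter(scan, !is.na(.data$p_value))
  dat$snp_index <- match(dat$snp_id, unique(scan$snp_id))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$snp_index,
                                         y = -log10(.data$p_value),
                                         colour = .data$method,
                                         shape = .data$model)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "SNP", y = expression(-log[10](p)),
                  colour = "method", shape = "model") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", colour = "red")
  }
  p
}
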