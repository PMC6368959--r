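# clinical table handling: one row per patient, categorical baseline
# characteristics with an explicit "unknown" level, follow-up in years

clinical_categoricals <- c(
  "stage", "msi_status", "sex", "age_group", "familial_risk",
  "treatment_5fu", "location", "histology", "vascular_invasion",
  "lymphatic_invasion", "braf_v600e"
)

#' Read a per-patient clinical table
#'
#' Expects a CSV with one row per patient. Required columns:
#' `patient_id`, `stage` (I/II/III/IV/unknown), `msi_status`
#' (MSI-H/MSI-L/MSS/unknown), `time_years` (non-negative follow-up in
#' years from diagnosis) and `event` (0/1 indicator). The remaining
#' baseline characteristics (`sex`, `age_group`, `familial_risk`,
#' `treatment_5fu`, `location`, `histology`, `vascular_invasion`,
#' `lymphatic_invasion`, `braf_v600e`) are optional categoricals; absent
#' values become the explicit level `"unknown"`.
#'
#' @param path CSV file path.
#' @return A tibble with categoricals as character columns (explicit
#'   `"unknown"`), `time_years` numeric and `event` integer.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_curescan(paste0("no such file: ", path),
                                        "curescan_io")
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  validate_clinical(tab)
}

#' @rdname read_clinical
#' @param clinical A data frame already in memory to validate/normalize
#'   the same way `read_clinical()` does.
#' @export
validate_clinical <- function(clinical) {
  tab <- tibble::as_tibble(clinical)
  req <- c("patient_id", "stage", "msi_status", "time_years", "event")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop_curescan(paste0("clinical table missing columns: ",
                         paste(miss, collapse = ", ")), "curescan_bad_input")
  }
  tab$patient_id <- as.character(tab$patient_id)
  for (v in intersect(clinical_categoricals, names(tab))) {
    x <- as.character(tab[[v]])
    x[is.na(x) | x == ""] <- "unknown"
    tab[[v]] <- x
  }
  tab$time_years <- as.numeric(tab$time_years)
  tab$event <- as.integer(tab$event)
  if (any(!is.na(tab$time_years) & tab$time_years < 0)) {
    stop_curescan("negative time_years", "curescan_bad_input")
  }
  if (any(!is.na(tab$event) & !(tab$event %in% 0:1))) {
    stop_curescan("event must be 0/1", "curescan_bad_input")
  }
  tab
}

#' Apply the cohort exclusion cascade
#'
#' Restricts a clinical table to the analysis cohort: stage I-III,
#' MSI-L or MSS tumors, with non-missing follow-up time and event
#' indicator. Exclusions are tallied sequentially in the order: stage IV
#' (or unknown stage), unknown MSI status, missing recurrence data,
#' MSI-H.
#'
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @return A list with `cohort` (the retained tibble) and `exclusions`
#'   (tibble of `reason`, `n_excluded`). An empty cohort is a valid
#'   result.
#' @examples
#' roster <- tibble::tibble(
#'   patient_id = as.character(1:4),
#'   stage = c("II", "IV", "III", "I"),
#'   msi_status = c("MSS", "MSS", "MSI-H", "MSI-L"),
#'   time_years = c(5, 1, 3, 2), event = c(0L, 1L, 0L, 1L)
#' )
#' apply_cohort_filters(roster)$exclusions
#' @export
apply_cohort_filters <- function(clinical) {
  tab <- validate_clinical(clinical)
  steps <- list(
    stage_iv_or_unknown = function(d) !(d$stage %in% c("I", "II", "III")),
    msi_unknown = function(d) d$msi_status == "unknown",
    recurrence_missing = function(d) is.na(d$time_years) | is.na(d$event),
    msi_high = function(d) d$msi_status == "MSI-H"
  )
  tally <- integer(length(steps))
  names(tally) <- names(steps)
  for (s in names(steps)) {
    drop <- steps[[s]](tab)
    tally[s] <- sum(drop)
    tab <- tab[!drop, , drop = FALSE]
  }
  list(
    cohort = tab,
    exclusions = tibble::tibble(reason = names(tally),
                                n_excluded = unname(tally))
  )
}

#' Reference baseline-characteristics table
#'
#' The cohort's printed baseline table: per characteristic level, the
#' number of patients, the percentage of the cohort, the number with the
#' event, and the within-level event percentage. Shipped as plain text in
#' `inst/extdata/baseline_characteristics.tsv`; used both as the default
#' covariate marginals of the synthetic generator and for consistency
#' checks between counts and percentages.
#'
#' @return Tibble with columns `variable`, `level`, `n`, `pct_total`,
#'   `n_event`, `pct_event`.
#' @export
baseline_reference <- function() {
  path <- system.file("extdata", "baseline_characteristics.tsv",
                      package = "curescan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Recompute the baseline table percentages from its counts
#'
#' Recomputes, from the printed counts alone, the percent-of-cohort and
#' percent-with-event columns of [baseline_reference()] (or any table in
#' the same layout), for comparison against the printed percentages.
#'
#' @param ref A table in the [baseline_reference()] layout.
#' @return `ref` with added columns `pct_total_recomputed` and
#'   `pct_event_recomputed` (rounded to 1 decimal, as printed).
#' @export
baseline_recompute <- function(ref = baseline_reference()) {
  ref |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(pct_total_recomputed = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pct_event_recomputed = round(100 * .data$n_event / .data$n, 1))
}
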