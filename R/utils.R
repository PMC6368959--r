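# shared internal helpers

# stop with a classed condition so tests can assert on error types
stop_curescan <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "curescan_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Kaplan-Meier survival at the group's own last follow-up time
# (product-limit over event times; censorings only shrink risk sets).
# Equivalent to min(survfit(...)$surv); kept as plain arithmetic because the
# scan evaluates it for every SNP x model x category.
km_last <- function(time, event) {
  if (length(time) == 0L) return(NA_real_)
  if (!any(event == 1)) return(1)
  ot <- order(time, -event)
  time <- time[ot]; event <- event[ot]
  n <- length(time)
  # risk set at t = subjects with time >= t; with sorted times the subject
  # at position i has n - i + 1 subjects at risk (ties handled by grouping)
  ut <- unique(time[event == 1])
  d <- vapply(ut, function(u) sum(event == 1 & time == u), numeric(1))
  r <- vapply(ut, function(u) sum(time >= u), numeric(1))
  prod(1 - d / r)
}

# seed scoping: run code under a seed without clobbering the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- rlang::`%||%`
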