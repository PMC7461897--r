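# Synthetic multistate onset simulator: competing exponential clocks with
# piecewise-constant, history-dependent hazards.

# Per-person stream splitting: person i gets seed (48271 * i + seed) mod
# (2^31 - 1). 48271 is a primitive root modulo the Mersenne prime 2^31 - 1,
# so the map i -> seed_i is injective over person ids; products stay exact in
# double precision for any realistic cohort size. This makes person i's
# covariates and event history depend only on (seed, i), so cohorts are
# reproducible under resizing.
person_seed <- function(seed, person_id) {
  as.integer((48271 * as.numeric(person_id) + as.numeric(seed)) %% 2147483647)
}

# inverse-CDF draw from a truncated normal using one uniform
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(mean)
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + stats::runif(1L) * (b - a), mean, sd)
}

#' Simulate a synthetic claims-like cohort
#'
#' Draws covariates, an administrative censoring time and a sequence of
#' condition onsets for each person by a next-event scheme over competing
#' exponential clocks. At each state every unacquired condition `c` has rate
#' `baseline_rate[c] * exp(sum of covariate log-HRs) * prod(progression
#' multipliers of acquired conditions on c)`; the waiting time to the next
#' onset is exponential with the total rate, the onsetting condition is drawn
#' proportionally to the per-condition rates, the state updates and rates are
#' re-evaluated. The process runs over
#' `[-baseline_lookback_years, censor_time]`; onsets with `onset_time <= 0`
#' are pre-baseline history (consumed by [screen_baseline_free()]), and
#' events beyond the censoring time are discarded.
#'
#' Each person has their own pseudo-random stream derived from
#' `(spec$seed, person_id)`, so identical `(spec, hazards)` yield
#' bit-identical output across processes and the first `n` persons of a
#' larger cohort equal the `n`-person cohort. The caller's RNG state is
#' restored on exit.
#'
#' @param spec An [cohort_spec()] object.
#' @param hazards An [hazard_spec()] object.
#' @return An object of class `mm_cohort`: a list with data frames
#'   `persons` (person_id, covariate columns, censor_time) and `events`
#'   (person_id, condition, onset_time).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(200, seed = 1), hazard_spec())
#' head(coh$events)
simulate_cohort <- function(spec, hazards) {
  if (!inherits(spec, "mm_cohort_spec")) stop("spec must be a cohort_spec()")
  if (!inherits(hazards, "mm_hazard_spec")) stop("hazards must be a hazard_spec()")

  n <- spec$n_persons
  K <- length(MM_CONDITIONS)
  base <- hazards$baseline_rate
  mult <- hazards$progression_multiplier
  cov_model <- spec$covariate_model
  cov_names <- names(cov_model)
  loghr <- hazards$covariate_loghr
  for (cov in names(loghr)) {
    if (!cov %in% cov_names)
      stop("covariate_loghr references unknown covariate '", cov, "'")
    bad <- setdiff(names(loghr[[cov]]), names(cov_model[[cov]]))
    if (length(bad))
      stop("covariate_loghr references unknown level(s) of '", cov, "': ",
           paste(bad, collapse = ", "))
  }
  cum_probs <- lapply(cov_model, cumsum)
  lookback <- spec$baseline_lookback_years

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }

  cov_mat <- matrix(NA_character_, n, length(cov_names),
                    dimnames = list(NULL, cov_names))
  censor <- numeric(n)
  ev_pid <- vector("list", n)
  ev_cond <- vector("list", n)
  ev_time <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(person_seed(spec$seed, i))

    # covariates
    eta <- numeric(K)
    for (j in seq_along(cov_names)) {
      cp <- cum_probs[[j]]
      lvl <- names(cp)[min(which(stats::runif(1L) <= cp + 1e-15))]
      cov_mat[i, j] <- lvl
      eff <- loghr[[cov_names[j]]][[lvl]]
      if (!is.null(eff)) eta <- eta + eff
    }
    censor[i] <- rtruncnorm1(spec$followup_years, spec$followup_sd,
                             spec$followup_range[1], spec$followup_range[2])

    # next-event simulation
    rates <- base * exp(eta)
    active <- rep(TRUE, K)
    t <- -lookback
    onsets <- numeric(0)
    conds <- integer(0)
    repeat {
      r <- rates[active]
      tot <- sum(r)
      if (tot <= 0) break
      t <- t + stats::rexp(1L, tot)
      if (t > censor[i]) break
      idx <- which(active)
      u <- stats::runif(1L) * tot
      j <- idx[min(findInterval(u, cumsum(r)) + 1L, length(idx))]
      active[j] <- FALSE
      conds <- c(conds, j)
      onsets <- c(onsets, t)
      rates <- rates * mult[j, ]
    }
    if (length(conds)) {
      ev_pid[[i]] <- rep.int(i, length(conds))
      ev_cond[[i]] <- conds
      ev_time[[i]] <- onsets
    }
  }

  persons <- data.frame(person_id = seq_len(n),
                        as.data.frame(cov_mat, stringsAsFactors = FALSE),
                        censor_time = censor)
  events <- data.frame(
    person_id = as.integer(unlist(ev_pid)),
    condition = MM_CONDITIONS[unlist(ev_cond)],
    onset_time = as.numeric(unlist(ev_time)),
    stringsAsFactors = FALSE
  )
  if (nrow(events) == 0L)
    events <- data.frame(person_id = integer(0), condition = character(0),
                         onset_time = numeric(0), stringsAsFactors = FALSE)
  structure(list(persons = persons, events = events), class = "mm_cohort")
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$persons), "persons,",
      nrow(x$events), "onset events\n")
  pre <- sum(x$events$onset_time <= 0)
  if (pre > 0) cat("  (", pre, " pre-baseline events; run screen_baseline_free())\n",
                   sep = "")
  invisible(x)
}

#' Exclude persons with pre-baseline disease
#'
#' Removes every person with any onset at or before time 0 (baseline) and
#' keeps only post-baseline events for the survivors, emulating the
#' exclusion of participants with any of the tracked chronic conditions at
#' study entry.
#'
#' @param persons Either an `mm_cohort` (then `events` is taken from it) or
#'   a persons data frame.
#' @param events Events data frame (person_id, condition, onset_time); may
#'   contain negative onset times.
#' @return An `mm_cohort` with the screened persons and their post-baseline
#'   events.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(200, seed = 1), hazard_spec())
#' screen_baseline_free(coh)
screen_baseline_free <- function(persons, events = NULL) {
  if (inherits(persons, "mm_cohort")) {
    events <- persons$events
    persons <- persons$persons
  }
  if (is.null(events)) stop("events table required")
  prevalent <- unique(events$person_id[events$onset_time <= 0])
  keep_p <- !(persons$person_id %in% prevalent)
  keep_e <- !(events$person_id %in% prevalent) & events$onset_time > 0
  structure(list(persons = persons[keep_p, , drop = FALSE],
                 events = events[keep_e, , drop = FALSE]),
            class = "mm_cohort")
}
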