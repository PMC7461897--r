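# Shared fixtures: tiny event tables and quick simulated cohorts.

make_events <- function(...) {
  # make_events(1, "CVD", 2.0, 1, "ASTHMA", 0.5, ...)
  args <- list(...)
  stopifnot(length(args) %% 3 == 0)
  idx <- seq(1, length(args), by = 3)
  data.frame(
    person_id = as.integer(unlist(args[idx])),
    condition = as.character(unlist(args[idx + 1])),
    onset_time = as.numeric(unlist(args[idx + 2])),
    stringsAsFactors = FALSE
  )
}

# cohort with a single active condition at a flat rate, fixed horizon
single_condition_spec <- function(n, rate, years, seed = 1L, lookback = 0) {
  rates <- stats::setNames(numeric(10), condition_codes())
  rates["CVD"] <- rate
  list(
    spec = cohort_spec(n, followup_years = years, followup_sd = 0,
                       followup_range = c(years, years),
                       baseline_lookback_years = lookback, seed = seed),
    hazards = hazard_spec(baseline_rate = rates,
                          covariate_loghr = list(),
                          progression_multiplier = 1)
  )
}

# homogeneous null cohort: all conditions at default rates, no covariate
# effects, no progression acceleration
null_hazards <- function(multiplier = 1) {
  hazard_spec(covariate_loghr = list(),
              progression_multiplier = multiplier)
}

quick_cohort <- function(n = 2000, seed = 1L, hazards = hazard_spec()) {
  coh <- screen_baseline_free(simulate_cohort(cohort_spec(n, seed = seed),
                                              hazards))
  list(cohort = coh, traj = build_trajectories(coh$events))
}
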