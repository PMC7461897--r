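# Cohort and hazard specifications for the synthetic multistate generator.

#' Default covariate model
#'
#' Gender and age-band frequencies loosely matching a community cohort of
#' 45--64 year olds (56.5% female, ~59% aged 45--54). Each element is a named
#' probability vector over the covariate's levels.
#'
#' @return Named list of probability vectors.
#' @export
default_covariate_model <- function() {
  list(
    gender   = c(F = 0.565, M = 0.435),
    age_band = c(`45-54` = 0.59, `55-64` = 0.41)
  )
}

#' Default baseline onset rates
#'
#' Illustrative per-condition onset rates (events per person-year) for the
#' synthetic generator. They are not estimates from any data source; they are
#' chosen so that roughly half of a disease-free cohort acquires a first
#' condition over about nine years of follow-up, with hypertension and
#' dyslipidemia the most frequent onsets and neurodegenerative disorders the
#' rarest, a plausible ordering for a middle-aged population.
#'
#' @return Named numeric vector over [condition_codes()].
#' @export
default_baseline_rates <- function() {
  c(
    CANCER          = 0.0060,
    CVD             = 0.0060,
    HYPERTENSION    = 0.0150,
    DYSLIPIDEMIA    = 0.0135,
    DIABETES        = 0.0038,
    ASTHMA          = 0.0045,
    MENTAL          = 0.0075,
    NEURODEGEN      = 0.0008,
    HIP_REPLACEMENT = 0.0015,
    OSTEOARTHRITIS  = 0.0090
  )
}

#' Default covariate log hazard ratios
#'
#' Illustrative covariate effects applied uniformly across conditions: being
#' in the older age band multiplies every onset hazard by 1.5 and being male
#' by 1.1. Reference levels (`45-54`, `F`) carry no effect.
#'
#' @return Nested list: covariate -> level -> log hazard ratio (scalar
#'   applied to all conditions, or a named vector by condition).
#' @export
default_covariate_loghr <- function() {
  list(
    age_band = list(`55-64` = log(1.5)),
    gender   = list(M = log(1.1))
  )
}

#' Cohort specification
#'
#' Describes the population to simulate: its size, the administrative
#' censoring distribution, the pre-baseline lookback window used for
#' baseline screening, the covariate model and the random seed.
#'
#' Censoring times are drawn from a normal distribution truncated to
#' `followup_range`, emulating staggered study entry against a fixed
#' administrative end date; with `followup_sd = 0` every person is censored
#' at exactly `followup_years`.
#'
#' @param n_persons Number of persons to simulate (positive integer).
#' @param followup_years Mean administrative censoring time in years.
#' @param followup_sd Standard deviation of the censoring time (0 for a
#'   fixed horizon).
#' @param followup_range Truncation range for the censoring time.
#' @param baseline_lookback_years Length of the pre-baseline window on which
#'   the same onset process runs; persons with any onset in it are removed by
#'   [screen_baseline_free()].
#' @param covariate_model Named list of probability vectors, one per
#'   categorical covariate; each must sum to 1.
#' @param seed Integer seed; per-person streams are derived from it (see
#'   [simulate_cohort()]).
#' @return An object of class `mm_cohort_spec`.
#' @export
#' @examples
#' cohort_spec(1000, seed = 42)
cohort_spec <- function(n_persons,
                        followup_years = 9,
                        followup_sd = 0.9,
                        followup_range = c(7, 11.5),
                        baseline_lookback_years = 2,
                        covariate_model = default_covariate_model(),
                        seed = 1L) {
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons <= 0L)
    stop("n_persons must be a positive integer")
  if (followup_years <= 0) stop("followup_years must be positive")
  if (followup_sd < 0) stop("followup_sd must be nonnegative")
  if (baseline_lookback_years < 0)
    stop("baseline_lookback_years must be nonnegative")
  if (length(followup_range) != 2L || followup_range[1] > followup_range[2])
    stop("followup_range must be an increasing pair")
  if (followup_range[1] <= 0) stop("followup_range must be positive")
  if (!length(covariate_model) || is.null(names(covariate_model)) ||
      any(names(covariate_model) == ""))
    stop("covariate_model must be a named list of probability vectors")
  for (nm in names(covariate_model)) {
    p <- covariate_model[[nm]]
    if (is.null(names(p)) || any(names(p) == ""))
      stop("covariate '", nm, "' levels must be named")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("probabilities for covariate '", nm, "' must be nonnegative and sum to 1")
  }
  structure(
    list(n_persons = n_persons,
         followup_years = followup_years,
         followup_sd = followup_sd,
         followup_range = as.numeric(followup_range),
         baseline_lookback_years = baseline_lookback_years,
         covariate_model = covariate_model,
         seed = as.integer(seed)),
    class = "mm_cohort_spec"
  )
}

#' Hazard specification
#'
#' Ground-truth onset hazards for the synthetic multistate process. Each
#' unacquired condition `c` has instantaneous rate
#' `baseline_rate[c] * exp(sum of covariate log-HRs) * prod(progression
#' multipliers of acquired conditions on c)`; hazards are piecewise constant
#' between onsets.
#'
#' @param baseline_rate Named numeric vector of per-condition rates
#'   (events/person-year, all > 0 allowed to be 0 for switched-off
#'   conditions), covering all of [condition_codes()].
#' @param covariate_loghr Nested list `covariate -> level -> effect`, where
#'   effect is a scalar log hazard ratio applied to every condition or a
#'   named numeric vector by condition. Levels absent from the list have no
#'   effect.
#' @param progression_multiplier Either a single nonnegative scalar applied
#'   to every ordered pair of distinct conditions, or a 10x10 numeric matrix
#'   with `dimnames` equal to [condition_codes()], where entry `[a, b]`
#'   multiplies condition `b`'s hazard once `a` has occurred. The diagonal is
#'   ignored (a condition occurs at most once per person). Multipliers
#'   combine multiplicatively across acquired conditions.
#' @return An object of class `mm_hazard_spec`.
#' @export
#' @examples
#' # a null process: no acceleration after a first onset
#' hazard_spec(progression_multiplier = 1)
hazard_spec <- function(baseline_rate = default_baseline_rates(),
                        covariate_loghr = default_covariate_loghr(),
                        progression_multiplier = 1.5) {
  if (is.null(names(baseline_rate)))
    stop("baseline_rate must be a named vector")
  missing_c <- setdiff(MM_CONDITIONS, names(baseline_rate))
  if (length(missing_c))
    stop("baseline_rate missing condition(s): ", paste(missing_c, collapse = ", "))
  check_conditions(names(baseline_rate), "baseline_rate")
  baseline_rate <- baseline_rate[MM_CONDITIONS]
  if (any(!is.finite(baseline_rate)) || any(baseline_rate < 0))
    stop("baseline rates must be finite and nonnegative")

  K <- length(MM_CONDITIONS)
  if (is.matrix(progression_multiplier)) {
    m <- progression_multiplier
    if (!identical(dim(m), c(K, K)))
      stop("progression_multiplier matrix must be ", K, "x", K)
    if (is.null(dimnames(m)))
      dimnames(m) <- list(MM_CONDITIONS, MM_CONDITIONS)
    check_conditions(rownames(m), "progression_multiplier row")
    check_conditions(colnames(m), "progression_multiplier column")
    m <- m[MM_CONDITIONS, MM_CONDITIONS]
  } else {
    if (length(progression_multiplier) != 1L)
      stop("progression_multiplier must be a scalar or a matrix")
    m <- matrix(progression_multiplier, K, K,
                dimnames = list(MM_CONDITIONS, MM_CONDITIONS))
  }
  diag(m) <- 1  # self-multiplier is ignored: a condition occurs at most once
  if (any(!is.finite(m)) || any(m < 0))
    stop("progression multipliers must be finite and nonnegative")

  if (!is.list(covariate_loghr)) stop("covariate_loghr must be a list")
  for (cov in names(covariate_loghr)) {
    for (lvl in names(covariate_loghr[[cov]])) {
      eff <- covariate_loghr[[cov]][[lvl]]
      if (length(eff) == 1L && is.null(names(eff))) {
        eff <- stats::setNames(rep(as.numeric(eff), K), MM_CONDITIONS)
      } else {
        check_conditions(names(eff), paste0("covariate_loghr[", cov, "][", lvl, "]"))
        full <- stats::setNames(numeric(K), MM_CONDITIONS)
        full[names(eff)] <- as.numeric(eff)
        eff <- full
      }
      if (any(!is.finite(eff))) stop("covariate log hazard ratios must be finite")
      covariate_loghr[[cov]][[lvl]] <- eff
    }
  }

  structure(
    list(baseline_rate = baseline_rate,
         covariate_loghr = covariate_loghr,
         progression_multiplier = m),
    class = "mm_hazard_spec"
  )
}

#' Set one progression multiplier
#'
#' Convenience helper returning a copy of `hazards` with the multiplier that
#' condition `from` applies to condition `to` set to `value`.
#'
#' @param hazards An `mm_hazard_spec`.
#' @param from,to Condition codes (distinct).
#' @param value Nonnegative multiplier.
#' @return Modified `mm_hazard_spec`.
#' @export
set_multiplier <- function(hazards, from, to, value) {
  stopifnot(inherits(hazards, "mm_hazard_spec"))
  check_conditions(c(from, to))
  if (from == to) stop("self-multipliers are ignored; 'from' and 'to' must differ")
  hazards$progression_multiplier[from, to] <- value
  hazards
}

#' @export
print.mm_cohort_spec <- function(x, ...) {
  cat("Cohort specification\n")
  cat("  persons:       ", x$n_persons, "\n")
  cat(sprintf("  follow-up:      %.1f y (sd %.1f, range %.1f-%.1f)\n",
              x$followup_years, x$followup_sd,
              x$followup_range[1], x$followup_range[2]))
  cat("  lookback:      ", x$baseline_lookback_years, "y\n")
  cat("  covariates:    ", paste(names(x$covariate_model), collapse = ", "), "\n")
  cat("  seed:          ", x$seed, "\n")
  invisible(x)
}

#' @export
print.mm_hazard_spec <- function(x, ...) {
  cat("Hazard specification (events/person-year)\n")
  print(round(x$baseline_rate, 4))
  m <- x$progression_multiplier
  off <- m[row(m) != col(m)]
  if (length(unique(off)) == 1L) {
    cat("progression multiplier:", unique(off), "for all ordered pairs\n")
  } else {
    cat("progression multipliers: pair-specific (range",
        paste(round(range(off), 3), collapse = "-"), ")\n")
  }
  invisible(x)
}
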