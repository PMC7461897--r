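# Progression relative-risk design: risk of developing condition X as the
# next-ranked condition after an existing primary condition (or a primary +
# secondary pair), versus X's incidence as a primary condition in the
# disease-free population, within fixed windows.

#' Define a progression contrast
#'
#' A contrast compares one exposure -- a primary condition, or an ordered
#' (primary, secondary) pair -- against the reference incidence of `outcome`
#' as a first condition in the disease-free population.
#'
#' @param primary Condition code of the primary (first-onset) condition.
#' @param secondary Optional condition code of the secondary condition (for
#'   tertiary-outcome contrasts); order matters.
#' @param outcome Outcome condition code; must not be part of the exposure.
#' @param window_years Risk window in years (default 5).
#' @return An object of class `mm_contrast`.
#' @export
#' @examples
#' progression_contrast("HYPERTENSION", outcome = "CVD")
progression_contrast <- function(primary, secondary = NULL, outcome,
                                 window_years = 5) {
  check_conditions(c(primary, secondary, outcome))
  if (!is.null(secondary) && secondary == primary)
    stop("secondary must differ from primary")
  if (outcome %in% c(primary, secondary))
    stop("outcome must not be one of the exposure conditions")
  if (window_years <= 0) stop("window_years must be positive")
  structure(list(primary = primary, secondary = secondary, outcome = outcome,
                 window_years = window_years),
            class = "mm_contrast")
}

#' @export
print.mm_contrast <- function(x, ...) {
  expo <- paste(c(x$primary, x$secondary), collapse = " -> ")
  cat(sprintf("Progression contrast: [%s] => %s within %g y\n",
              expo, x$outcome, x$window_years))
  invisible(x)
}

# wide per-person view of the first three onsets + covariates
person_summary <- function(trajectories, persons) {
  ps <- persons
  for (r in 1:3) {
    rows <- trajectories[trajectories$rank == r, , drop = FALSE]
    idx <- match(ps$person_id, rows$person_id)
    ps[[paste0("cond", r)]] <- rows$condition[idx]
    ps[[paste0("t", r)]] <- rows$onset_time[idx]
  }
  ps
}

#' Reference arm of a progression contrast
#'
#' One row per eligible person in the disease-free population: persons with
#' at least `window` years of follow-up, with a binary response equal to 1
#' iff `outcome` occurred as that person's primary (rank-1) condition within
#' `window` years of study entry. Onsets of `outcome` at later ranks do not
#' count: the reference is the incidence of the condition as a first
#' condition.
#'
#' @param trajectories An `mm_trajectories` data frame (screened cohort).
#' @param persons Persons data frame (screened cohort).
#' @param outcome Outcome condition code.
#' @param window Risk window in years (default 5).
#' @return Data frame with person_id, exposed = 0, y, and the persons
#'   covariate columns.
#' @export
build_reference <- function(trajectories, persons, outcome, window = 5) {
  check_conditions(outcome)
  if (window <= 0) stop("window must be positive")
  ps <- person_summary(trajectories, persons)
  build_reference_ps(ps, outcome, window)
}

build_reference_ps <- function(ps, outcome, window) {
  eligible <- ps$censor_time >= window
  if (!any(eligible)) stop("no eligible persons in reference arm")
  ps <- ps[eligible, , drop = FALSE]
  y <- !is.na(ps$cond1) & ps$cond1 == outcome & ps$t1 <= window
  out <- ps[setdiff(names(ps), c("cond1", "t1", "cond2", "t2", "cond3", "t3"))]
  out$exposed <- rep(0L, nrow(out))
  out$y <- as.integer(y)
  rownames(out) <- NULL
  out
}

#' Exposed arm of a progression contrast
#'
#' Selects persons whose primary condition (and, for pair exposures, whose
#' secondary condition in the stated order) matches the contrast's exposure
#' and occurred within `window` years of entry; persons with fewer than
#' `window` years of follow-up remaining after the last exposure onset are
#' excluded. The binary response is 1 iff the outcome occurs as the
#' next-ranked condition within `window` years of the last exposure onset
#' (with `anchor = "entry"`, within `window` years of study entry instead;
#' with `allow_intervening = TRUE` the outcome may occur at any later rank).
#'
#' @param trajectories An `mm_trajectories` data frame (screened cohort).
#' @param persons Persons data frame.
#' @param contrast An [progression_contrast()].
#' @param window Risk window in years; defaults to the contrast's.
#' @param anchor Start of the outcome clock: `"onset"` (default; the last
#'   exposure condition's onset) or `"entry"`.
#' @param allow_intervening Count the outcome even when another condition
#'   intervenes between exposure and outcome (default FALSE: strict
#'   next-rank semantics).
#' @return Data frame with person_id, exposed = 1, y, covariate columns;
#'   zero rows when no person matches the exposure.
#' @export
build_exposed <- function(trajectories, persons, contrast,
                          window = contrast$window_years,
                          anchor = c("onset", "entry"),
                          allow_intervening = FALSE) {
  stopifnot(inherits(contrast, "mm_contrast"))
  anchor <- match.arg(anchor)
  ps <- person_summary(trajectories, persons)
  if (allow_intervening) {
    out_rows <- trajectories[trajectories$condition == contrast$outcome, ,
                             drop = FALSE]
    idx <- match(ps$person_id, out_rows$person_id)
    ps$outcome_t <- out_rows$onset_time[idx]
    ps$outcome_rank <- out_rows$rank[idx]
  }
  build_exposed_ps(ps, contrast, window, anchor, allow_intervening)
}

build_exposed_ps <- function(ps, contrast, window, anchor = "onset",
                             allow_intervening = FALSE) {
  pair <- !is.null(contrast$secondary)
  sel <- !is.na(ps$cond1) & ps$cond1 == contrast$primary & ps$t1 <= window
  if (pair)
    sel <- sel & !is.na(ps$cond2) & ps$cond2 == contrast$secondary &
      ps$t2 <= window
  t_last <- if (pair) ps$t2 else ps$t1
  sel <- sel & (ps$censor_time - t_last) >= window
  sel[is.na(sel)] <- FALSE
  ps <- ps[sel, , drop = FALSE]
  t_last <- t_last[sel]

  next_cond <- if (pair) ps$cond3 else ps$cond2
  next_t <- if (pair) ps$t3 else ps$t2
  origin <- if (anchor == "onset") t_last else 0
  if (allow_intervening) {
    y <- !is.na(ps$outcome_t) & ps$outcome_rank > (1L + pair) &
      (ps$outcome_t - origin) <= window
  } else {
    y <- !is.na(next_cond) & next_cond == contrast$outcome &
      (next_t - origin) <= window
  }
  drop_cols <- intersect(names(ps), c("cond1", "t1", "cond2", "t2", "cond3",
                                      "t3", "outcome_t", "outcome_rank"))
  out <- ps[setdiff(names(ps), drop_cols)]
  out$exposed <- rep(1L, nrow(out))
  out$y <- as.integer(y)
  rownames(out) <- NULL
  out
}

# aggregate identical design rows into weighted rows and fit poisson_rr
fit_rr_model <- function(dat, covariates, tol = 1e-8, max_iter = 100L) {
  keep <- c("y", "exposed", covariates)
  dat <- dat[keep]
  key <- do.call(paste, c(dat, sep = "\r"))
  agg <- dat[!duplicated(key), , drop = FALSE]
  w <- as.integer(table(key)[unique(key)])
  fmla <- stats::as.formula(paste("~ exposed",
                                  paste(c("", covariates), collapse = " + ")))
  X <- stats::model.matrix(fmla, data = agg)
  poisson_rr(agg$y, X, weights = w, tol = tol, max_iter = max_iter)
}

#' Estimate the relative risk of one progression contrast
#'
#' Stacks the contrast's reference and exposed arms (the arms are disjoint:
#' persons selected into the exposed arm are removed from the reference),
#' fits a modified Poisson model on the exposure indicator plus the
#' configured covariates, and returns the relative risk with a robust Wald
#' 95% confidence interval. With no covariates the estimate equals the ratio
#' of the two stratum risks.
#'
#' Contrasts with an empty exposed arm or with no outcome events in either
#' arm are returned as inestimable (`estimable = FALSE`, NA estimates)
#' rather than dropped. Contrasts where either arm has fewer than `min_cell`
#' persons carry a `suppressed` flag (small-cell confidentiality).
#'
#' @inheritParams build_exposed
#' @param covariates Character vector of persons columns to adjust for
#'   (default none: unadjusted).
#' @param min_cell Suppression threshold on arm sizes (default 5).
#' @param level Confidence level (default 0.95).
#' @return An object of class `mm_rr`.
#' @export
estimate_rr <- function(trajectories, persons, contrast,
                        covariates = character(),
                        window = contrast$window_years,
                        min_cell = 5L, level = 0.95,
                        anchor = c("onset", "entry"),
                        allow_intervening = FALSE) {
  stopifnot(inherits(contrast, "mm_contrast"))
  anchor <- match.arg(anchor)
  ps <- person_summary(trajectories, persons)
  estimate_rr_ps(ps, contrast, covariates, window, min_cell, level, anchor,
                 allow_intervening)
}

estimate_rr_ps <- function(ps, contrast, covariates = character(),
                           window = contrast$window_years, min_cell = 5L,
                           level = 0.95, anchor = "onset",
                           allow_intervening = FALSE) {
  exposed <- build_exposed_ps(ps, contrast, window, anchor, allow_intervening)
  ref <- build_reference_ps(ps, contrast$outcome, window)
  ref <- ref[!ref$person_id %in% exposed$person_id, , drop = FALSE]

  res <- list(contrast = contrast,
              n_exposed = nrow(exposed), n_reference = nrow(ref),
              events_exposed = sum(exposed$y), events_reference = sum(ref$y),
              rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p_value = NA_real_, q_value = NA_real_,
              estimable = FALSE,
              suppressed = nrow(exposed) < min_cell || nrow(ref) < min_cell,
              fit = NULL)
  class(res) <- "mm_rr"
  if (nrow(exposed) == 0L || nrow(ref) == 0L ||
      sum(exposed$y) == 0L || sum(ref$y) == 0L)
    return(res)

  dat <- rbind(exposed, ref)
  fit <- fit_rr_model(dat, covariates)
  cf <- coef(fit)["exposed"]
  se <- sqrt(vcov(fit)["exposed", "exposed"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  res$rr <- exp(unname(cf))
  res$ci_low <- exp(unname(cf) - z * se)
  res$ci_high <- exp(unname(cf) + z * se)
  res$p_value <- 2 * stats::pnorm(-abs(unname(cf) / se))
  res$estimable <- fit$converged
  res$fit <- fit
  res
}

#' @export
print.mm_rr <- function(x, ...) {
  print(x$contrast)
  if (!x$estimable) {
    cat("inestimable (exposed:", x$n_exposed, "persons,",
        x$events_exposed, "events; reference:", x$n_reference, "persons,",
        x$events_reference, "events)\n")
  } else {
    cat(sprintf("RR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                x$rr, x$ci_low, x$ci_high, x$p_value))
    cat(sprintf("exposed %d/%d vs reference %d/%d%s\n",
                x$events_exposed, x$n_exposed,
                x$events_reference, x$n_reference,
                if (x$suppressed) "  [suppressed: small cells]" else ""))
  }
  invisible(x)
}

#' Full progression contrast grid with FDR control
#'
#' Evaluates every primary -> secondary contrast (10 x 9 ordered pairs of
#' distinct conditions) and, optionally, every observed (primary, secondary)
#' -> tertiary contrast whose exposed arm has at least `min_exposed`
#' persons, then applies Benjamini-Hochberg across the p-values of all
#' estimable contrasts at level `q`. The `reported` view retains only
#' FDR-significant, unsuppressed contrasts; the full raw grid is always
#' available.
#'
#' @inheritParams estimate_rr
#' @param q FDR level (default 0.05).
#' @param min_exposed Minimum exposed-arm size for a pair contrast to enter
#'   the grid (default 5).
#' @param include_tertiary Evaluate (primary, secondary) -> tertiary
#'   contrasts as well (default TRUE).
#' @return Data frame of class `mm_progression` with one row per contrast:
#'   exposure_primary, exposure_secondary (NA for single exposures),
#'   outcome, n_exposed, n_reference, events_exposed, events_reference, rr,
#'   ci_low, ci_high, p, q, estimable, suppressed, reported.
#' @export
progression_grid <- function(trajectories, persons,
                             covariates = character(), q = 0.05,
                             window = 5, min_cell = 5L, min_exposed = 5L,
                             include_tertiary = TRUE, level = 0.95,
                             anchor = c("onset", "entry"),
                             allow_intervening = FALSE) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  anchor <- match.arg(anchor)
  ps <- person_summary(trajectories, persons)

  contrasts <- list()
  for (p1 in MM_CONDITIONS)
    for (oc in setdiff(MM_CONDITIONS, p1))
      contrasts[[length(contrasts) + 1L]] <-
        progression_contrast(p1, outcome = oc, window_years = window)

  if (include_tertiary) {
    ok <- !is.na(ps$cond2) & ps$t1 <= window & ps$t2 <= window &
      (ps$censor_time - ps$t2) >= window
    pair_tab <- table(paste(ps$cond1[ok], ps$cond2[ok], sep = "\r"))
    pair_tab <- pair_tab[pair_tab >= min_exposed]
    for (key in names(pair_tab)) {
      pr <- strsplit(key, "\r", fixed = TRUE)[[1]]
      for (oc in setdiff(MM_CONDITIONS, pr))
        contrasts[[length(contrasts) + 1L]] <-
          progression_contrast(pr[1], pr[2], outcome = oc,
                               window_years = window)
    }
  }

  rows <- lapply(contrasts, function(ct) {
    r <- estimate_rr_ps(ps, ct, covariates, window, min_cell, level, anchor,
                        allow_intervening)
    data.frame(exposure_primary = ct$primary,
               exposure_secondary = ct$secondary %||% NA_character_,
               outcome = ct$outcome,
               n_exposed = r$n_exposed, n_reference = r$n_reference,
               events_exposed = r$events_exposed,
               events_reference = r$events_reference,
               rr = r$rr, ci_low = r$ci_low, ci_high = r$ci_high,
               p = r$p_value, estimable = r$estimable,
               suppressed = r$suppressed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$reported <- FALSE
  est <- which(out$estimable)
  if (length(est)) {
    bh <- benjamini_hochberg(out$p[est], q = q)
    out$q[est] <- bh$q_value
    out$reported[est] <- bh$reject & !out$suppressed[est]
  }
  attr(out, "fdr_level") <- q
  attr(out, "window") <- window
  attr(out, "covariates") <- covariates
  class(out) <- c("mm_progression", "data.frame")
  out
}

#' Reported view of a progression grid
#'
#' FDR-significant, unsuppressed contrasts of a [progression_grid()] result.
#'
#' @param x An `mm_progression` data frame.
#' @return Data frame subset.
#' @export
reported <- function(x) {
  stopifnot(inherits(x, "mm_progression"))
  out <- as.data.frame(x)[x$reported, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mm_progression <- function(x, ...) {
  cat(sprintf("Progression grid: %d contrasts (%d estimable, %d reported at FDR %.2g, window %g y)\n",
              nrow(x), sum(x$estimable), sum(x$reported),
              attr(x, "fdr_level"), attr(x, "window")))
  rep_rows <- reported(x)
  if (nrow(rep_rows)) {
    cols <- c("exposure_primary", "exposure_secondary", "outcome",
              "n_exposed", "rr", "ci_low", "ci_high", "p", "q")
    print(utils::head(rep_rows[cols][order(rep_rows$p), ], 15L), digits = 3)
  }
  invisible(x)
}

#' @export
summary.mm_progression <- function(object, ...) {
  data.frame(
    contrasts = nrow(object),
    secondary = sum(is.na(object$exposure_secondary)),
    tertiary = sum(!is.na(object$exposure_secondary)),
    estimable = sum(object$estimable),
    suppressed = sum(object$suppressed),
    reported = sum(object$reported)
  )
}
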