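# Ordinal sequencing of onsets: ranks (primary, secondary, ...), gap times,
# cumulative incidence and gap-time summaries.

#' Build ordinal trajectories from onset events
#'
#' Sorts each person's onsets by time and assigns ordinal ranks
#' (1 = primary, 2 = secondary, 3 = tertiary, 4 = quaternary, ...). The gap
#' time at rank 1 is the onset time itself (time from study entry) and at
#' rank k >= 2 the difference from the previous onset.
#'
#' Exact ties (same-day onsets, possible in loaded claims data though not in
#' the continuous-time simulator) are resolved by `tie_rule`:
#' `"canonical"` (default) orders tied events by the canonical condition
#' order and flags them; `"collapse"` keeps only the canonically first event
#' of each tied set (flagged). After tie resolution onset times are strictly
#' increasing within person, so all gap times are positive.
#'
#' @param events Events data frame (person_id, condition, onset_time) with
#'   strictly positive onset times, or an `mm_cohort` (its events are used).
#' @param tie_rule `"canonical"` or `"collapse"`.
#' @return Data frame of class `mm_trajectories` with columns person_id,
#'   rank, condition, onset_time, gap_time, tied.
#' @export
#' @examples
#' ev <- data.frame(person_id = 1L,
#'                  condition = c("CVD", "ASTHMA", "CANCER"),
#'                  onset_time = c(2.0, 0.5, 3.1))
#' build_trajectories(ev)
build_trajectories <- function(events, tie_rule = c("canonical", "collapse")) {
  tie_rule <- match.arg(tie_rule)
  if (inherits(events, "mm_cohort")) events <- events$events
  need <- c("person_id", "condition", "onset_time")
  if (!all(need %in% names(events)))
    stop("events must have columns ", paste(need, collapse = ", "))
  check_conditions(events$condition)
  if (nrow(events) == 0L) {
    out <- data.frame(person_id = integer(0), rank = integer(0),
                      condition = character(0), onset_time = numeric(0),
                      gap_time = numeric(0), tied = logical(0))
    class(out) <- c("mm_trajectories", "data.frame")
    return(out)
  }
  if (any(!is.finite(events$onset_time)))
    stop("onset times must be finite")
  if (any(events$onset_time <= 0))
    stop("events must be post-baseline (onset_time > 0); run screen_baseline_free() first")
  if (anyDuplicated(events[c("person_id", "condition")]))
    stop("duplicate (person_id, condition) pair in events")

  ci <- match(events$condition, MM_CONDITIONS)
  o <- order(events$person_id, events$onset_time, ci)
  pid <- events$person_id[o]
  tm <- events$onset_time[o]
  cond <- events$condition[o]

  key <- paste(pid, tm)
  tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (tie_rule == "collapse" && any(tied)) {
    keep <- !duplicated(key)
    pid <- pid[keep]; tm <- tm[keep]; cond <- cond[keep]; tied <- tied[keep]
  }

  new_person <- c(TRUE, pid[-1] != pid[-length(pid)])
  rank <- sequence(diff(c(which(new_person), length(pid) + 1L)))
  prev <- c(0, tm[-length(tm)])
  prev[new_person] <- 0
  gap <- tm - prev  # zero only for canonical-rule ties, which stay flagged

  out <- data.frame(person_id = pid, rank = as.integer(rank),
                    condition = cond, onset_time = tm, gap_time = gap,
                    tied = tied, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mm_trajectories", "data.frame")
  out
}

#' Cumulative incidence of the k-th condition
#'
#' Proportion of the population at risk that acquired at least `k`
#' conditions: the incidence of a primary (k = 1), secondary (k = 2),
#' tertiary (k = 3) or quaternary (k = 4) condition.
#'
#' @param trajectories An `mm_trajectories` data frame.
#' @param n_at_risk Size of the population at risk (must be at least the
#'   number of persons with any onset).
#' @param k Ordinal rank(s); in strict mode restricted to 1..4.
#' @param strict If TRUE (default), `k` outside 1..4 is an error.
#' @param empty_as_zero If TRUE an empty cohort (`n_at_risk = 0`) returns 0
#'   instead of erroring.
#' @return Numeric vector of proportions, one per element of `k`.
#' @export
cumulative_incidence <- function(trajectories, n_at_risk, k = 1:4,
                                 strict = TRUE, empty_as_zero = FALSE) {
  if (strict && any(k < 1 | k > 4))
    stop("k must be in 1..4 (set strict = FALSE to allow higher ranks)")
  if (any(k < 1)) stop("k must be >= 1")
  if (n_at_risk == 0) {
    if (empty_as_zero) return(rep(0, length(k)))
    stop("empty population at risk")
  }
  n_with <- length(unique(trajectories$person_id))
  if (n_at_risk < n_with)
    stop("n_at_risk is smaller than the number of persons with onsets")
  max_rank <- tapply(trajectories$rank, trajectories$person_id, max)
  vapply(k, function(kk) sum(max_rank >= kk) / n_at_risk, numeric(1))
}

#' Gap-time summary at one rank
#'
#' Median and quartiles of the time to develop the condition at a given rank
#' (the gap from the previous onset; for rank 1 the time from study entry),
#' over all persons in the stratum. Quartiles use linear interpolation
#' between closest ranks (type 7), a fixed convention.
#'
#' @param trajectories An `mm_trajectories` data frame.
#' @param rank Ordinal rank (integer >= 1).
#' @param person_ids Optional stratum filter: only gaps of these persons.
#' @return Named numeric vector (median, q1, q3, n).
#' @export
gap_summary <- function(trajectories, rank, person_ids = NULL) {
  g <- trajectories$gap_time[trajectories$rank == rank &
                               (is.null(person_ids) |
                                  trajectories$person_id %in% person_ids)]
  if (!length(g)) stop("no trajectories at rank ", rank, " in stratum")
  q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3], n = length(g))
}

#' Stratified gap-time summary table
#'
#' Gap-time medians and quartiles at ranks 1..4 (and a pooled "5+" row for
#' higher ranks), overall and stratified by the requested covariates.
#'
#' @param trajectories An `mm_trajectories` data frame.
#' @param persons Persons data frame carrying the stratification covariates.
#' @param by Character vector of covariate column names (default gender and
#'   age_band); use `character(0)` for the overall summary only.
#' @return Data frame with columns stratum, rank, median, q1, q3, n.
#' @export
gap_summary_table <- function(trajectories, persons,
                              by = c("gender", "age_band")) {
  by <- intersect(by, names(persons))
  rank_lab <- ifelse(trajectories$rank >= 5, "5+",
                     as.character(trajectories$rank))
  strata <- list(overall = persons$person_id)
  if (length(by)) {
    grp <- interaction(persons[by], sep = ":", drop = TRUE)
    strata <- c(strata, split(persons$person_id, grp))
  }
  rows <- list()
  for (snm in names(strata)) {
    sel <- trajectories$person_id %in% strata[[snm]]
    for (rl in intersect(c("1", "2", "3", "4", "5+"), unique(rank_lab[sel]))) {
      g <- trajectories$gap_time[sel & rank_lab == rl]
      q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = snm, rank = rl, median = q[2], q1 = q[1],
                   q3 = q[3], n = length(g), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
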