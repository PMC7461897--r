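make_persons <- function(n, censor = 9) {
  data.frame(person_id = seq_len(n), gender = rep(c("F", "M"), length.out = n),
             age_band = "45-54", censor_time = rep(censor, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("reference arm counts only rank-1 outcomes within the window", {
  persons <- make_persons(4)
  ev <- rbind(
    make_events(1, "CANCER", 3.0),                      # primary cancer in window
    make_events(2, "CVD", 1.0, 2, "CANCER", 2.0),       # cancer only at rank 2
    make_events(3, "CANCER", 6.0)                       # primary cancer after window
  )                                                     # person 4: no events
  tr <- build_trajectories(ev)
  ref <- build_reference(tr, persons, "CANCER", window = 5)
  expect_equal(nrow(ref), 4)
  expect_equal(ref$y[match(1:4, ref$person_id)], c(1L, 0L, 0L, 0L))
  expect_true(all(ref$exposed == 0))

  short <- make_persons(2, censor = 4)  # < window follow-up: excluded
  expect_error(build_reference(tr[tr$person_id == 9, ], short, "CANCER", 5),
               "no eligible")
})

test_that("exposed arm applies order, window and follow-up exclusions", {
  persons <- make_persons(6)
  ev <- rbind(
    make_events(1, "HYPERTENSION", 1.0, 1, "CVD", 3.0),   # response 1
    make_events(2, "HYPERTENSION", 1.0, 2, "CANCER", 2.0),# other next cond
    make_events(3, "CVD", 1.0, 3, "HYPERTENSION", 2.0),   # wrong order
    make_events(4, "HYPERTENSION", 4.9),                  # 4.1y left < window
    make_events(5, "HYPERTENSION", 6.0),                  # exposure after window
    make_events(6, "HYPERTENSION", 1.0, 6, "CVD", 6.5)    # next cond too late
  )
  tr <- build_trajectories(ev)
  ct <- progression_contrast("HYPERTENSION", outcome = "CVD")
  ex <- build_exposed(tr, persons, ct)
  expect_setequal(ex$person_id, c(1L, 2L, 6L))
  expect_equal(ex$y[match(c(1, 2, 6), ex$person_id)], c(1L, 0L, 0L))
  expect_true(all(ex$exposed == 1))
})

test_that("pair exposures are order-sensitive and anchor the clock at the second onset", {
  persons <- make_persons(3, censor = 12)
  ev <- rbind(
    make_events(1, "CVD", 1.0, 1, "MENTAL", 2.0, 1, "CANCER", 5.5),
    make_events(2, "MENTAL", 1.0, 2, "CVD", 2.0, 2, "CANCER", 5.5),
    make_events(3, "CVD", 1.0, 3, "MENTAL", 2.0)
  )
  tr <- build_trajectories(ev)
  ct <- progression_contrast("CVD", "MENTAL", outcome = "CANCER")
  ex <- build_exposed(tr, persons, ct)
  # person 2 has MENTAL first: wrong order, not selected
  expect_setequal(ex$person_id, c(1L, 3L))
  # cancer at 5.5 is 3.5y after the secondary onset: within the window
  expect_equal(ex$y[ex$person_id == 1], 1L)
  expect_equal(ex$y[ex$person_id == 3], 0L)

  # entry-anchored alternative: cancer at 5.5y from entry is outside 5y
  ex2 <- build_exposed(tr, persons, ct, anchor = "entry")
  expect_equal(ex2$y[ex2$person_id == 1], 0L)
})

test_that("intervening conditions disqualify unless allowed", {
  persons <- make_persons(1, censor = 12)
  ev <- make_events(1, "HYPERTENSION", 1.0, 1, "ASTHMA", 2.0, 1, "CVD", 3.0)
  tr <- build_trajectories(ev)
  ct <- progression_contrast("HYPERTENSION", outcome = "CVD")
  strict <- build_exposed(tr, persons, ct)
  expect_equal(strict$y, 0L)
  loose <- build_exposed(tr, persons, ct, allow_intervening = TRUE)
  expect_equal(loose$y, 1L)
})

test_that("unadjusted progression RR equals the ratio of stratum risks", {
  persons <- make_persons(120)
  ev <- list()
  # 20 exposed persons (hypertension primary at 1y), 8 progress to CVD
  for (p in 1:20) {
    ev[[length(ev) + 1L]] <- make_events(p, "HYPERTENSION", 1.0)
    if (p <= 8) ev[[length(ev) + 1L]] <- make_events(p, "CVD", 2.5)
  }
  # 10 reference persons with CVD as primary within the window
  for (p in 21:30) ev[[length(ev) + 1L]] <- make_events(p, "CVD", 3.0)
  tr <- build_trajectories(do.call(rbind, ev))
  ct <- progression_contrast("HYPERTENSION", outcome = "CVD")
  est <- estimate_rr(tr, persons, ct)
  expect_true(est$estimable)
  expect_equal(est$n_exposed, 20)
  expect_equal(est$n_reference, 100)
  expect_equal(est$rr, (8 / 20) / (10 / 100), tolerance = 1e-8)
  expect_true(est$ci_low <= est$rr && est$rr <= est$ci_high)
})

test_that("arms are disjoint and the estimate ignores person relabeling and row order", {
  res <- quick_cohort(3000, seed = 41)
  tr <- res$traj; persons <- res$cohort$persons
  ct <- progression_contrast("HYPERTENSION", outcome = "CVD")
  ex <- build_exposed(tr, persons, ct)
  ref <- build_reference(tr, persons, "CVD", 5)
  ref <- ref[!ref$person_id %in% ex$person_id, ]
  expect_length(intersect(ex$person_id, ref$person_id), 0)

  est1 <- estimate_rr(tr, persons, ct)
  # relabel persons and shuffle rows
  set.seed(1)
  relab <- sample(100000L, nrow(persons))
  map <- stats::setNames(relab, persons$person_id)
  persons2 <- persons[sample.int(nrow(persons)), ]
  persons2$person_id <- unname(map[as.character(persons2$person_id)])
  tr2 <- as.data.frame(tr)[sample.int(nrow(tr)), ]
  tr2$person_id <- unname(map[as.character(tr2$person_id)])
  est2 <- estimate_rr(structure(tr2, class = class(tr)), persons2, ct)
  expect_equal(est1$rr, est2$rr, tolerance = 1e-12)
  expect_equal(est1$n_exposed, est2$n_exposed)
})

test_that("empty or event-free arms are reported inestimable, small arms suppressed", {
  persons <- make_persons(30)
  ev <- list()
  for (p in 1:3) {
    ev[[length(ev) + 1L]] <- make_events(p, "NEURODEGEN", 1.0)
    if (p == 1) ev[[length(ev) + 1L]] <- make_events(p, "CANCER", 2.0)
  }
  for (p in 4:9) ev[[length(ev) + 1L]] <- make_events(p, "CANCER", 1.5)
  tr <- build_trajectories(do.call(rbind, ev))

  none <- estimate_rr(tr, persons,
                      progression_contrast("ASTHMA", outcome = "CANCER"))
  expect_false(none$estimable)
  expect_equal(none$n_exposed, 0)

  small <- estimate_rr(tr, persons,
                       progression_contrast("NEURODEGEN", outcome = "CANCER"))
  expect_true(small$estimable)
  expect_true(small$suppressed)  # 3 exposed persons < 5
})

test_that("adjusted model recovers the exposure RR with a covariate in the design", {
  res <- quick_cohort(4000, seed = 51,
                      hazards = set_multiplier(hazard_spec(), "HYPERTENSION",
                                               "CVD", 4))
  est <- estimate_rr(res$traj, res$cohort$persons,
                     progression_contrast("HYPERTENSION", outcome = "CVD"),
                     covariates = c("gender", "age_band"))
  expect_true(est$estimable)
  expect_gt(est$rr, 1)
  expect_equal(names(coef(est$fit))[1:2], c("(Intercept)", "exposed"))
  expect_equal(length(coef(est$fit)), 4)  # intercept, exposed, 2 dummies
})

test_that("the progression grid covers all contrasts and controls reporting", {
  res <- quick_cohort(4000, seed = 61,
                      hazards = set_multiplier(null_hazards(), "HYPERTENSION",
                                               "CVD", 6))
  grid <- progression_grid(res$traj, res$cohort$persons, q = 0.05)
  expect_equal(sum(is.na(grid$exposure_secondary)), 90)
  expect_true(all(grid$outcome != grid$exposure_primary))
  pair_rows <- !is.na(grid$exposure_secondary)
  expect_true(all(grid$outcome[pair_rows] != grid$exposure_secondary[pair_rows]))
  # q-values only for estimable rows; reported implies estimable & unsuppressed
  expect_true(all(is.na(grid$q[!grid$estimable])))
  expect_true(all(grid$estimable[grid$reported]))
  expect_false(any(grid$suppressed[grid$reported]))
  expect_identical(reported(grid)$outcome, grid$outcome[grid$reported])
  # the injected effect is detected
  hit <- grid$exposure_primary == "HYPERTENSION" & grid$outcome == "CVD" &
    is.na(grid$exposure_secondary)
  expect_true(grid$reported[hit])
  expect_gt(grid$rr[hit], 1)
})
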