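test_that("ordered and unordered pattern counts match direct enumeration", {
  # three two-condition persons: A->B, B->A, A->B with A = ASTHMA, B = CVD
  ev <- make_events(1, "ASTHMA", 1, 1, "CVD", 2,
                    2, "CVD", 1, 2, "ASTHMA", 2,
                    3, "ASTHMA", 1, 3, "CVD", 2)
  tr <- build_trajectories(ev)
  perm <- pattern_table(tr, 2, ordered = TRUE, min_count = 1)
  expect_equal(perm$pattern, c("ASTHMA|CVD", "CVD|ASTHMA"))
  expect_equal(perm$count, c(2L, 1L))
  expect_equal(perm$pct, c(200 / 3, 100 / 3))

  comb <- pattern_table(tr, 2, ordered = FALSE, min_count = 1)
  expect_equal(comb$pattern, "CVD|ASTHMA")  # canonical order: CVD before ASTHMA
  expect_equal(comb$count, 3L)
  expect_equal(comb$pct, 100)
})

test_that("two cardiometabolic conditions form a CMD|CMD multiset key", {
  ev <- make_events(1, "HYPERTENSION", 1, 1, "DYSLIPIDEMIA", 2)
  tr <- build_trajectories(ev)
  g <- pattern_table(tr, 2, level = "group", ordered = FALSE, min_count = 1)
  expect_equal(g$pattern, "CMD|CMD")
  expect_equal(g$count, 1L)
})

test_that("permutation counts partition combination counts at every k and level", {
  tr <- quick_cohort(4000, seed = 13,
                     hazards = hazard_spec(progression_multiplier = 2))$traj
  for (k in 2:4) for (level in c("condition", "group")) {
    perm <- pattern_table(tr, k, level = level, ordered = TRUE, min_count = 1)
    comb <- pattern_table(tr, k, level = level, ordered = FALSE, min_count = 1)
    vocab <- if (level == "condition") condition_codes() else group_codes()
    sort_key <- vapply(strsplit(perm$pattern, "|", fixed = TRUE),
                       function(p) paste(p[order(match(p, vocab))],
                                         collapse = "|"), "")
    agg <- tapply(perm$count, sort_key, sum)
    expect_equal(sort(as.vector(agg)), sort(comb$count))
    expect_equal(sum(perm$count), sum(comb$count))
    # counts total the eligible population; percentages total 100
    n_elig <- attr(comb, "n_eligible")
    expect_equal(sum(comb$count), n_elig)
    expect_equal(sum(comb$pct), 100, tolerance = 1e-9)
    expect_equal(sum(perm$pct), 100, tolerance = 1e-9)
  }
})

test_that("group-level tables are a deterministic rollup of condition-level tables", {
  tr <- quick_cohort(3000, seed = 17)$traj
  cond <- pattern_table(tr, 2, level = "condition", ordered = TRUE,
                        min_count = 1)
  grp <- pattern_table(tr, 2, level = "group", ordered = TRUE, min_count = 1)
  rolled_key <- vapply(strsplit(cond$pattern, "|", fixed = TRUE),
                       function(p) paste(condition_to_group(p), collapse = "|"),
                       "")
  rolled <- tapply(cond$count, rolled_key, sum)
  expect_equal(as.vector(rolled[grp$pattern]), grp$count)
})

test_that("exchangeable conditions yield symmetric permutation counts", {
  rates <- stats::setNames(numeric(10), condition_codes())
  rates[c("ASTHMA", "CVD")] <- 0.08
  coh <- screen_baseline_free(simulate_cohort(
    cohort_spec(20000, followup_sd = 0, followup_range = c(9, 9),
                baseline_lookback_years = 0, seed = 23),
    hazard_spec(baseline_rate = rates, covariate_loghr = list(),
                progression_multiplier = 1)))
  tr <- build_trajectories(coh$events)
  perm <- pattern_table(tr, 2, ordered = TRUE, min_count = 1)
  n <- sum(perm$count)
  ab <- perm$count[perm$pattern == "CVD|ASTHMA"]
  se <- sqrt(n * 0.25)
  expect_lt(abs(ab - n / 2), 4 * se)
})

test_that("small-count patterns are suppressed from public output only", {
  ev <- rbind(
    do.call(rbind, lapply(1:6, function(p) make_events(p, "CVD", 1, p, "CANCER", 2))),
    make_events(7, "ASTHMA", 1, 7, "MENTAL", 2))
  tr <- build_trajectories(ev)
  pt <- pattern_table(tr, 2, ordered = TRUE, min_count = 5)
  expect_equal(pt$suppressed, c(FALSE, TRUE))
  expect_equal(sum(pt$pct), 100)
  f <- tempfile(fileext = ".csv")
  write_pattern_table(pt, f)
  pub <- read.csv(f)
  expect_equal(nrow(pub), 1L)
  expect_equal(pub$pattern, "CVD|CANCER")
  unlink(f)
})

test_that("contribution by rank gives per-rank percentages summing to 100", {
  ev <- make_events(1, "ASTHMA", 1, 1, "CVD", 2,
                    2, "CVD", 1, 2, "ASTHMA", 2)
  ct <- contribution_by_rank(build_trajectories(ev))
  a1 <- ct$pct[ct$condition == "ASTHMA" & ct$rank == 1]
  expect_equal(a1, 50)
  for (r in 1:2) expect_equal(sum(ct$pct[ct$rank == r]), 100)

  one <- contribution_by_rank(build_trajectories(
    make_events(1, "ASTHMA", 1, 1, "CVD", 2)))
  expect_equal(one$pct[one$condition == "ASTHMA" & one$rank == 1], 100)
  expect_equal(one$pct[one$condition == "CVD" & one$rank == 2], 100)
})

test_that("an injected first-onset asymmetry shifts rank contributions", {
  h <- null_hazards()
  h <- set_multiplier(h, "ASTHMA", "CVD", 5)
  tr <- quick_cohort(8000, seed = 29, hazards = h)$traj
  ct <- contribution_by_rank(tr)
  asthma1 <- ct$pct[ct$condition == "ASTHMA" & ct$rank == 1]
  asthma2 <- ct$pct[ct$condition == "ASTHMA" & ct$rank == 2]
  expect_gt(asthma1, asthma2)
})

test_that("chi-square statistic matches the Pearson formula and stats oracle", {
  h <- chi_square_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(unname(h$statistic), 0)
  expect_equal(h$p.value, 1)

  h2 <- chi_square_test(rbind(c(20, 10), c(10, 20)))
  expect_equal(unname(h2$statistic), 60 * (20 * 20 - 10 * 10)^2 / (30^4),
               tolerance = 1e-12)
  expect_equal(unname(h2$parameter), 1)

  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    mine <- chi_square_test(tab)
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-8)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
  }
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Cochran-Armitage trend statistic behaves and matches prop.trend.test", {
  flat <- cochran_armitage(c(10, 10, 10), c(100, 100, 100))
  expect_equal(unname(flat$statistic), 0, tolerance = 1e-12)

  up <- cochran_armitage(c(5, 15, 30), c(100, 100, 100))
  expect_gt(unname(up$statistic), 0)

  set.seed(7)
  for (i in 1:20) {
    n <- rpois(4, 50) + 10
    x <- rbinom(4, n, runif(1, 0.2, 0.8))
    if (sum(x) == 0 || sum(x) == sum(n)) next
    mine <- cochran_armitage(x, n)
    ref <- suppressWarnings(stats::prop.trend.test(x, n))
    expect_equal(unname(mine$statistic)^2, unname(ref$statistic),
                 tolerance = 1e-8)
  }
  expect_error(cochran_armitage(c(0, 0, 0), c(5, 5, 5)), "all-")
  expect_error(cochran_armitage(c(1, 2), c(5, 5)), "3 ordered levels")
})
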