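# mmtraj

Multimorbidity trajectory analysis: in what order do chronic conditions
accumulate, how fast do people progress from one to the next, and does an
existing condition (or pair of conditions) raise the risk of a specific
subsequent one?

The package is written for epidemiologists and biostatisticians working
with claims-linked cohort data. It tracks ten chronic conditions (cancer,
CVD, hypertension, dyslipidemia, diabetes, asthma, mental disorders,
neurodegenerative disorders, hip replacement, osteoarthritis; the four
cardiometabolic ones roll up into a CMD group, the last two into a
musculoskeletal group) and provides:

- **Sequencing** — each person's onsets ordered into primary, secondary,
  tertiary and quaternary conditions, with gap times
  (`build_trajectories()`, `cumulative_incidence()`, `gap_summary()`).
- **Pattern mining** — combinations (unordered) and permutations
  (onset-ordered) of the first 2–4 conditions at condition or group level,
  with contribution-by-rank tables and small-cell suppression
  (`pattern_table()`, `contribution_by_rank()`).
- **Progression relative risks** — the core design. For outcome *X* and
  exposure *P* (or ordered pair *P, S*): among persons whose first
  condition(s) match the exposure within a 5-year window and who have 5
  more years of follow-up, the risk that *X* is the *next* condition within
  5 years of the last exposure onset, versus the 5-year risk of *X* as a
  *first* condition in the disease-free population:

  RR = Pr(X next within w | exposure) / Pr(X first within w | disease-free),

  estimated by modified Poisson regression with a robust sandwich variance
  (so exp(β) is a risk ratio with valid Wald CIs on binary outcomes), over
  the full grid of contrasts with Benjamini–Hochberg FDR control
  (`estimate_rr()`, `progression_grid()`).
- **A synthetic cohort generator** — a continuous-time multistate process
  with competing exponential clocks. Each unacquired condition *c* has
  hazard λ⁰c·exp(Σ covariate log-HRs)·Π m\[a,c\] over acquired conditions
  *a*; the multipliers m are the ground truth the analysis should recover
  (`simulate_cohort()`, `cohort_spec()`, `hazard_spec()`).
- **Self-contained classical procedures** used by the stages — Wilcoxon
  rank-sum (exact by enumeration up to pooled n = 12), Mann–Kendall,
  chi-square, Cochran–Armitage, Cox regression (Breslow ties),
  Benjamini–Hochberg — each validated against independent oracles in the
  test suite.

## Worked example

```r
library(mmtraj)

coh <- simulate_cohort(cohort_spec(20000, seed = 1), hazard_spec())
coh
#> Synthetic cohort: 20000 persons, 21822 onset events
#>   (3459 pre-baseline events; run screen_baseline_free())

scr <- screen_baseline_free(coh)          # disease-free at baseline
tr  <- build_trajectories(scr$events)     # ordinal trajectories

round(100 * cumulative_incidence(tr, nrow(scr$persons)), 1)
#> [1] 52.7 21.1  7.8  2.8
```

About half the screened cohort develops a first condition over ~9 years of
follow-up, a fifth a second one, and so on — the counts are hierarchical by
construction. Gap times shorten as conditions accumulate (the default
generator applies a progression multiplier of 1.5 after every onset):

```r
gap_summary_table(tr, scr$persons, by = character(0))
#>   stratum rank median    q1   q3    n
#> 1 overall    1  3.716 1.706 6.04 8900
#> 2 overall    2  2.257 1.021 4.04 3569
#> 3 overall    3  1.683 0.711 2.99 1320
#> 4 overall    4  1.279 0.571 2.36  472
#> 5 overall   5+  0.918 0.439 1.82  231

pattern_table(tr, k = 2, level = "group")
#> Unordered patterns of the first 2 conditions (group level), 3569 persons with >= 2 conditions
#>               pattern count    pct suppressed
#> 1             CMD|CMD   915 25.637      FALSE
#> 2 CMD|MUSCULOSKELETAL   732 20.510      FALSE
#> 3          CMD|MENTAL   545 15.270      FALSE
#> 4          CMD|CANCER   400 11.208      FALSE
#> 5          CMD|ASTHMA   322  9.022      FALSE
#> ... and 12 more patterns
```

Two cardiometabolic conditions are the leading two-condition pattern
(25.6% of persons with ≥ 2 conditions), followed by CMD paired with
musculoskeletal and mental disorders. One progression contrast:

```r
est <- estimate_rr(tr, scr$persons,
                   progression_contrast("HYPERTENSION", outcome = "CVD"))
est
#> Progression contrast: [HYPERTENSION] => CVD within 5 y
#> RR 1.336 (95% CI 0.996-1.794), p = 0.05345
#> exposed 46/1018 vs reference 537/15883
```

46 of 1,018 hypertension-first persons developed CVD as their next
condition within 5 years, against a 3.4% five-year first-condition CVD
risk in the disease-free reference — a risk ratio of 1.34 (the default
multiplier 1.5 plus the design's mild structural excess). The full grid
with FDR control: `progression_grid(tr, scr$persons, q = 0.05)`; the
end-to-end pipeline with all published CSV outputs and a reproducibility
manifest: `run_all(default_config(20000, seed = 1), "out/")`. A thin CLI
(`inst/cli/mmtraj`) wraps the same functions for shell use.

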