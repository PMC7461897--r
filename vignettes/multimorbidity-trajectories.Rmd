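---
title: "Methods: multimorbidity trajectories, patterns and progression risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimorbidity trajectories, patterns and progression risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtraj)
```

## The analysis in one paragraph

`mmtraj` studies how chronic conditions accumulate in a middle-aged cohort
that is disease-free at study entry. Ten conditions are tracked (cancer,
CVD, hypertension, dyslipidemia, diabetes, asthma, mental disorders,
neurodegenerative disorders, hip replacement, osteoarthritis), rolled up
into six groups for pattern work (the four cardiometabolic conditions form
the CMD group; hip replacement and osteoarthritis form the musculoskeletal
group). Each person's onsets are ordered in time into an ordinal
trajectory: the 1st (primary) through 4th (quaternary) condition, with the
gap time to each. On top of the trajectories the package computes
cumulative incidence by ordinal rank, gap-time summaries, pattern tables
(combinations and permutations of the first 2--4 conditions), and a
fixed-window progression design: the relative risk of developing condition
X as the *next* condition after an existing condition (or ordered pair of
conditions), versus X's incidence as a *first* condition in the
disease-free population, estimated by modified Poisson regression with a
robust sandwich variance and screened through Benjamini--Hochberg FDR
control. Because the linked claims data this design was built for are
restricted, the package ships a synthetic multistate cohort generator with
known ground-truth hazards, so every stage can be tested against what was
injected.

## The synthetic cohort generator

The generator simulates, per person, a continuous-time multistate onset
process by competing exponential clocks. While a person's acquired-condition
set is fixed, each unacquired condition $c$ has a constant hazard

$$\lambda_c(\text{person}, \text{history}) \;=\;
  \lambda^0_c \times \exp\!\Big(\textstyle\sum_{v} \beta_{v,c}\Big) \times
  \prod_{a \in \text{history}} m_{a c},$$

where $\lambda^0_c$ is the baseline rate (events per person-year),
$\beta_{v,c}$ are covariate log hazard ratios for the person's covariate
levels, and $m_{ac}$ is the progression multiplier that an acquired
condition $a$ applies to condition $c$. The waiting time to the next onset
is exponential with the total rate; the onsetting condition is chosen
proportionally to the per-condition rates; the state updates and the rates
are re-evaluated (the process is Markov in history and the time-invariant
covariates, with piecewise-constant hazards between onsets). Simultaneous
onsets are impossible in continuous time; tie handling exists downstream
only for externally loaded data.

The process runs from $-L$ (a pre-baseline lookback of $L = 2$ years by
default) to the person's administrative censoring time. Onsets at or
before time 0 represent prevalent disease: `screen_baseline_free()`
removes those persons entirely, emulating the exclusion of participants
with any of the ten conditions at baseline. Real claims-linked cohorts
typically screen on self-reported history plus a claims lookback; the
generator instead runs the same onset process over the lookback window —
an emulation of that screening step, not a replication of it.

**Reproducibility.** Person $i$ draws covariates, censoring time and
events from its own stream, seeded with $(48271\, i + \text{seed}) \bmod
(2^{31}-1)$; 48271 is a primitive root of the Mersenne prime $2^{31}-1$,
so distinct persons always get distinct seeds. Identical `(spec, hazards)`
give bit-identical cohorts across processes, and the first $n$ persons of
a larger cohort equal the $n$-person cohort (reproducibility under
resizing). The caller's RNG state is untouched.

### Default parameters and why

All defaults are *illustrative*: restricted claims linkages publish no
incidence-rate inputs that could be copied, so values were chosen once to
make the default cohort behave like a plausible community cohort of 45--64
year olds, and are not revisited.

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| baseline rates $\lambda^0_c$ | 0.0008--0.015, sum 0.0675 | /person-year | roughly half the cohort acquires a first condition over ~9 years; hypertension and dyslipidemia most frequent, neurodegenerative disorders rarest |
| progression multiplier $m_{ac}$ | 1.5 (all ordered pairs) | -- | encodes the qualitative acceleration of subsequent onsets after a first condition; 1 = null process |
| covariate log-HRs | log 1.5 (age 55--64), log 1.1 (male) | -- | older age and male sex raise every onset hazard moderately |
| censoring time | Normal(9, 0.9) truncated to [7, 11.5] | years | ~9 years of claims follow-up with staggered entry |
| lookback $L$ | 2 | years | pre-baseline window used for baseline screening |
| gender, age band | 56.5% F; 59% aged 45--54 | -- | community-cohort frequencies |

With these defaults a 20,000-person cohort yields cumulative incidences of
roughly 53/21/8/3% for the primary through quaternary condition and
two-CMDs as the leading two-condition pattern — magnitudes in the range
reported for large mid-life claims cohorts. These magnitudes are emergent,
not fitted; no attempt is made to reproduce any specific cohort's numbers.

### What the generator does *not* emulate

No mortality or competing-death process, no dropout (censoring is purely
administrative), no time-varying covariates, no seasonality or calendar
structure, no claim-code noise (conditions are emitted as resolved labels,
not MBS/PBS item numbers), and no same-day ties. Consequently, passing
tests demonstrate that the analysis code recovers structure *that the
generator can express*; they cannot certify behaviour under measurement
error, differential ascertainment or informative censoring found in real
claims data.

## Sequencing and gap times

`build_trajectories()` sorts each person's post-baseline onsets and
assigns ranks $1, 2, 3, \ldots$; the gap time at rank 1 is the onset time
itself (time from study entry — a fixed convention; claims settings often
leave the choice between questionnaire date and linkage start open), and at
rank $k\ge 2$ the difference from the previous onset. Gap times therefore
telescope to the last onset time, a conservation law asserted in the
tests. Ranks beyond 4 are computed and stored; summaries label them "5+".

**Ties.** Exact ties cannot arise from the simulator but can occur in
loaded claims-like data (same-day records). Under the default
`tie_rule = "canonical"` tied events are ordered by the fixed canonical
condition order and flagged, so sensitivity reruns can find them; under
`"collapse"` only the canonically first event of a tied set is kept
(also flagged). The canonical order is a package-wide constant used for
all tie-breaking and output sorting.

**Quartiles.** Gap-time summaries use linear interpolation between closest
order statistics (R's type 7), fixed and documented because no convention
was inherited.

## Pattern mining

For every person with at least $k$ conditions ($k = 2, 3, 4$), the
conditions at ranks $1..k$ form a pattern: ordered (permutation) or sorted
into canonical order (combination, aggregating all orderings). At group
level, conditions are first mapped to the six groups and keys are
**multisets**: two distinct cardiometabolic conditions form `CMD|CMD`
rather than collapsing to one `CMD`, because "two concurrent CMDs" is
itself the leading clinical pattern and collapsing would destroy it.
Percentages are over the persons with $\ge k$ conditions. Patterns rarer
than `min_count` (default 5) persons are flagged and omitted from public
CSV output — mirroring small-cell confidentiality suppression — but kept
internally so counts and percentages always total the eligible population.
Two invariants connect the tables: permutation counts partition combination
counts, and the group-level table is a deterministic rollup of the
condition-level table; both are asserted in the tests.

`contribution_by_rank()` tabulates how often each condition appears at
each rank; a chi-square test compares each condition's share between
primary and secondary onsets and a Cochran--Armitage test (equally spaced
integer scores, a choice made here since none was inherited) assesses the
trend of its contribution across ranks.

## The classical procedures

The module implements the procedures it relies on self-contained, each
validated in the test suite against an independent oracle (full
enumeration, brute force, or a reference library used *only* in tests):

- **Wilcoxon rank-sum** with midranks; exact p-values by full enumeration
  of $\binom{N}{n_x}$ rank assignments when the pooled size is at most 12
  (valid with ties), otherwise a normal approximation with tie-corrected
  variance and continuity correction.
- **Mann--Kendall** trend test with tie-corrected variance and continuity
  correction.
- **Pearson chi-square** (no continuity correction) and
  **Cochran--Armitage** trend with the pooled-proportion null variance;
  increasing proportions give $Z > 0$.
- **Cox regression** maximizing the Breslow partial likelihood by
  Newton--Raphson with step halving. Breslow (rather than Efron) tie
  handling was chosen for its closed-form score and information.
  Degenerate designs are reported, not
  silently returned: constant covariates raise a singular-information
  error and monotone likelihoods (complete separation; detected when
  coefficients pass $|\beta| > 20$) raise an explicit error.
- **Modified Poisson regression** by IRLS with the sandwich covariance
  $I^{-1}\big(\sum_i w_i (y_i-\mu_i)^2 x_i x_i^\top\big) I^{-1}$, so that
  on binary outcomes $\exp(\beta)$ is a risk ratio with valid Wald
  inference. Identical design rows are aggregated into weighted rows
  before fitting, which is exact for both the likelihood and the sandwich.
- **Benjamini--Hochberg** step-up with the monotone cumulative-minimum
  adjusted values; ties share a rank.

Numerical conventions throughout: convergence when the score max-norm
falls below $10^{-8}$ within 100 iterations; Wald (not likelihood-ratio)
intervals, matching standard claims-epidemiology reporting; all p-values
two-sided.

## The progression design

A contrast compares an **exposure** — a primary condition $P$, or an
ordered pair (primary $P$, secondary $S$) — against the **reference**
incidence of an outcome $X$ within a $w$-year window ($w = 5$ by
default):

- *Reference arm*: every person with at least $w$ years of follow-up;
  response 1 iff $X$ occurred as that person's **rank-1** condition within
  $w$ years of entry. Later-rank onsets of $X$ do not count.
- *Exposed arm*: persons whose rank-1 condition is $P$ (and rank-2 is $S$,
  in that order, for pair exposures), each exposure onset within $w$ years
  of entry; persons with less than $w$ years of follow-up remaining after
  the last exposure onset are excluded, so the response window is fully
  observed. Response 1 iff $X$ occurs as the **next-ranked** condition
  within $w$ years of the last exposure onset.

Both arms yield one binary response per person — a $w$-year cumulative
incidence proportion, not a person-time rate — which is what makes the
Poisson-with-robust-variance model a risk-ratio estimator. Three genuinely
open design choices were resolved as follows, each exposed as a switch:

- **Outcome clock** (`anchor`): starts at the last exposure onset
  (`"onset"`, default) rather than study entry, because the gap of
  interest is from the *existing* condition to the subsequent one;
  `"entry"` gives the entry-anchored alternative.
- **Next-rank semantics** (`allow_intervening`): by default an intervening
  other condition disqualifies (the outcome must be the immediately
  following condition); `allow_intervening = TRUE` relaxes this for
  sensitivity analyses.
- **Disjoint arms**: persons selected into a contrast's exposed arm are
  removed from its reference arm, so no person contributes to both sides
  of the same comparison — the stricter of the two possible conventions,
  adopted so each contrast compares non-overlapping populations.

`progression_grid()` evaluates all $10 \times 9$ primary-to-secondary
contrasts plus every observed pair-to-tertiary contrast with at least
`min_exposed` (default 5) exposed persons, applies Benjamini--Hochberg
across the p-values of all estimable contrasts in one family (secondary
and tertiary combined; the family is a configuration choice), and reports
only FDR-significant,
unsuppressed rows in the published view while always retaining the full
raw grid. Contrasts with an empty exposed arm or no outcome events in
either arm are flagged inestimable rather than dropped; arms below
`min_cell` (default 5) persons are suppressed from the reported view,
after the small-cell confidentiality convention. The quaternary level is
not analysed: with ten conditions and realistic rates almost all
three-condition histories are too rare for meaningful inference.

### Known calibration caveats

Two structural features mean the design's null is not *exactly* RR = 1
even when all progression multipliers are 1. First, an exposed person has
one (or two) fewer conditions competing to be the next onset, which
inflates the conditional probability that the next onset is the outcome by
roughly $\Lambda/(\Lambda - \lambda_P)$ — about 3--5% for the most common
primaries at the default rates. Second, Wald inference on the log scale is
anti-conservative when the exposed arm has only a handful of outcome
events, as is typical for pair-to-tertiary contrasts near the suppression
threshold; occasional extreme RRs with nominally tiny p-values can
therefore pass the FDR screen under the null. The acceptance property
tested is the one that matters for the published view — the reported
fraction of the grid stays at the nominal level (well under
$q + 3\,\mathrm{SE}$ in the null simulations) and the single-contrast 95%
CI covers 1 in at least 90% of replicates — not exact frequentist
calibration of every small-cell Wald interval.

## Problem sizes used in the tests

The test suite and acceptance script size their simulations as follows,
chosen so Monte-Carlo error is small relative to the tolerances being
asserted: simulator calibration at $n = 50{,}000$ (closed-form exponential
CDF and symmetry checks at 3 standard errors); null calibration of the
progression design at $n = 20{,}000$ with 50 replicates for the
single-contrast CI coverage and 5 replicates for the full grid; injected
parameter recovery (multiplier 4 on hypertension-to-CVD) at $n = 4{,}000$
over 50 replicates; structural conservation and end-to-end determinism at
$n$ = 1,000--4,000.

## Limitations

All conditions are weighted equally (a count-based multimorbidity
definition); the ten-condition vocabulary is fixed; the generator's
defaults are illustrative rather than estimated; onsets are treated as
exact dates (no interval censoring); there is no mediation analysis of
intermediate conditions; and the synthetic process omits mortality, which
in real cohorts competes with — and truncates — late-rank onsets.
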