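---
title: "Age-stage two-sex life tables with predation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage two-sex life tables with predation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The data model

The unit of observation is one individual on one day. A cohort starts as
`n_01` eggs laid on day 0 and every individual is followed daily until
death: its stage (egg, L1–L4, pupa, then female or male — sex is fixed at
emergence), the eggs it laid (females only) and the prey it consumed
(feeding stages only; eggs and pupae do not feed). Censoring is not
supported: a record must end in exactly one death-day row, because every
downstream quantity (life expectancy, net predation, bootstrap resampling
of whole individuals) assumes complete lifetimes.

The census convention is "alive at the start of the day": an individual
observed alive on day `x` counts toward age `x`, and the death day itself
is the first day not counted. This makes `l_0 = 1` exact, makes stage
durations equal counts of days spent in the stage, and assigns the
death-day row zero eggs and zero prey, so it never enters a numerator or a
denominator. A day with a fresh moult belongs to the *new* stage, which
keeps stage durations integral and additive to the total preadult time.

## Life-table quantities

All grids are indexed by age `x` (days from oviposition) and stage `j`.
From the count grid `n_xj`:

* `s_xj = n_xj / n_01` and `l_x = Σ_j s_xj` (exact decomposition, checked
  on every fit);
* `m_x` divides the day's eggs by *all* survivors — the two-sex
  convention; males and undetermined-sex preadults dilute per-capita
  fecundity. Where `l_x = 0` we define `m_x = 0` so the net maternity
  `l_x m_x` is always summable;
* `R0 = Σ l_x m_x` equals total eggs over `n_01` by construction, which
  yields the exact identity `R0 = F · N_female / n_01` used as a
  consistency check on every cohort;
* `r` solves `Σ_x e^{−r(x+1)} l_x m_x = 1`. The exponent uses `x + 1`
  with age indexed from 0 — a convention, but one that shifts `r`
  materially if mixed up, so the reproductive-value grid uses the same
  `(x+1)` discounting. The left side is strictly decreasing in `r`, so we
  use bracketing bisection starting from `[−1, 5]` (expanded geometrically
  when needed) down to a residual below `1e−12`. `r < 0` is legitimate
  (declining cohorts); only `R0 = 0` leaves `r`, `λ`, `T` undefined.

`e_xj` is estimated from the sub-cohort observed alive in `(x, j)`: the
mean number of remaining alive days, i.e. the forward schedule conditioned
on being alive in the cell. Its newborn value `e_{0,egg}` equals the
cohort's mean lifespan exactly, preadult deaths included.

For the reproductive value we use the equivalent empirical form

`v_xj = e^{r(x+1)} · mean over the (x,j) sub-cohort of Σ_{i≥x} e^{−r(i+1)} eggs_i`,

the discounted expected future reproduction of a cell occupant. Written
with the conditional forward schedule `s′` this is
`e^{r(x+1)} Σ_i e^{−r(i+1)} Σ_y s′_iy f_iy`; formulations that divide an
already-conditional `s′` by `s_xj` double-condition and fail simple toy
checks (a cell with survival one half and two eggs per survivor must have
value two, not four). Our form satisfies the structural identity
`v_{0,egg} = λ` to 1e−9 on every cohort with reproduction, which the test
suite asserts.

## Predation quantities

`c_xj` is the mean daily prey consumption of the cell's occupants (zero by
structure for egg and pupa cells — the familiar two gaps in predation
curves), `k_x` its survivor-weighted age average, and `q_x = l_x k_x` the
survivorship-weighted rate whose sum `C0` is, exactly, total prey consumed
divided by `n_01`. `Qp = C0/R0` converts lifetime predation into prey per
offspring produced.

The stable age-stage distribution is taken in closed form,
`a_xj ∝ λ^{−x} s_xj`, truncated at the cohort's maximum observed age
(beyond which `s_xj = 0`) and renormalised; an explicit growth-matrix
eigendecomposition would give the same limit, and the equivalence is
guarded by a projection-convergence test (total-variation distance below
`1e−3` after a burn-in of three maximum lifespans). `ψ = Σ a_xj c_xj` and
`ω = λψ` hold to machine precision by construction; `ω = λψ` is also the
printed identity linking the published estimates, and it is
truncation-independent.

## Bootstrap inference

The resampling unit is the whole individual with its complete daily
history; anything finer would destroy within-individual correlation
between survival, fecundity and predation. Each replicate draws `n_01`
individuals with replacement and recomputes every requested parameter.
Replicates with no eggs contribute `R0 = 0` and are excluded — with a
reported count — from `r`, `λ`, `T`, `Qp`, `ψ`, `ω`, keeping SEs finite;
the count lets users judge how often that happened. The published
convention is `B = 100,000`; computations here vectorise replicates in
blocks (count matrices against precomputed per-individual summaries, and a
row-wise bisection for `r`), so that is feasible, but examples and tests
run at `B` in the hundreds to thousands, which is ample for SEs of these
magnitudes.

Paired tests form `B` independent replicate pairs and use the percentile
2.5%/97.5% interval of the difference; significance at 5% means the
interval excludes zero. Each cohort's replicate stream is seeded by the
user seed plus a checksum of the cohort's content, which makes the test
exactly antisymmetric under argument swap and self-comparisons exactly
null, while two different cohorts get independent streams. Under the null
(two cohorts generated from the same scenario) the empirical size at
`B = 2000` sits close to the nominal 0.05 — the percentile interval is
mildly anti-conservative at `n_01 = 50`, as percentile intervals are —
and the suite asserts it within ±0.02 over 200 trials.

Projection bands use the bootstrap life-table samples attaining the
`⌈0.025B⌉`-th and `⌈0.975B⌉`-th order statistics of `λ` (undefined
replicates excluded before sorting), projected as cohorts in their own
right.

## Projection

The projection is the expected-value (real-mass) recursion: each cell's
mass moves by the cohort's empirical one-day transition frequencies,
newborn eggs enter at `(0, egg)` the next day at `Σ f_xj n_xj(t)`
(post-breeding census, consistent with the `(x+1)` discounting), and the
predation potential is `P(t) = Σ c_xj n_xj(t)`. Growth is deliberately
unsuppressed — no density dependence or prey depletion. Because the state
includes age, projecting the cohort's own initial condition reproduces
`n_xj` exactly, and asymptotically `N(t+1)/N(t) → λ`, the composition
converges to `a_xj`, and `P(t)/N(t) → ψ`; these three limits are the
adopted correctness criteria for the projection bookkeeping.

The conventional "10 pairs" start places ten females and ten males at
their sex's first observed adult age; starting from 20 newly laid eggs is
available as an option since "pairs" fixes no age. For confidence-band
runs the pairs are placed at each percentile cohort's *own* first adult
ages — a shared initial vector could otherwise address cells a resample
never visits and spuriously extinguish a band.

## The synthetic generator

The generator emulates the four-temperature design: cohorts of 50 eggs;
per-stage development times from a gamma distribution matched to the
published means with individual spread `sd = SE·√n` (the published errors
are cohort-level; treating them this way is an assumption, not the
published intent), rounded to whole days with a floor of one day; a single
completion Bernoulli at stage entry, with per-stage completion
probabilities derived from the published stage-by-stage sample sizes so
their product reproduces the published preadult survival (0.92, 0.92,
0.82, 0.76); sex at emergence with the observed female fractions; gamma
adult lifespans by sex; Poisson daily predation around the published
per-stage means; and a fecundity model — geometric pre-oviposition period,
then zero-inflated Poisson counts over a triangular daily-mean profile
peaking at one third of the reproductive life — scaled so the expected
lifetime total and the expected number of laying days match the published
`F` and `Od` targets.

What it does *not* emulate: within-stage mortality timing (deaths land
uniformly inside the fatal stage), between-trait correlations (a female's
longevity, fecundity and appetite are drawn independently),
temperature as a mechanism (scenarios are labels with targets, not a
thermal model), and the exact shape of the daily fecundity curve, which is
unpublished. One visible consequence: the *observed* pre-oviposition
period runs a few days above the geometric draw's mean because early
low-mean laying days often produce zeros, so scenario APOP/TPOP summaries
sit slightly above their targets. Passing tests therefore demonstrate that
the estimators recover the generator's schedules, not that the generator
reproduces every moment of the real trial; absolute published values are
matched only in the quantities the generator explicitly targets.

Discretisation of the gamma draws biases stage-duration means by at most
~0.01 d under the default scenarios — well inside the Monte-Carlo
tolerance (3 SEs at `n = 5000`) used by the recovery suite.

## Numerical and design choices

* Euler–Lotka: scalar bisection (tolerance `1e−12` residual) for fits; an
  independent vectorised row-wise bisection (`1e−10`) inside the
  bootstrap. The two agree to ~`1e−8` in `λ`, which is the comparison
  tolerance tests use between them.
* Unreached `(x, j)` cells are `NA` in `e_xj`/`v_xj` (no smoothing of the
  conditional schedules); unoccupied cells are 0 in `c_xj` so sums stay
  defined.
* Reported rounding follows the field convention — 4 decimals for rates,
  2 for days and counts — while full precision is kept internally.
* Compact letter display uses greedy insert-and-absorb over the pairwise
  significance matrix, letters assigned in scenario order.
* Reproducibility: one Mersenne-Twister stream per generated cohort,
  seeded from the scenario; pipeline outputs carry seed, `B`, package
  version and an input checksum in their metadata headers.

## Problem sizes used by the test suite

Deterministic identities run on 50-egg cohorts. Monte-Carlo checks use
10,000 draws for the schedule samplers; parameter recovery uses
5,000-individual cohorts per scenario (3-SE tolerance) and a
deterministic-schedule scenario whose analytic `r` (via the closed-form
expected fecundity profile) must be matched within ±0.002 d⁻¹; the
paired-test size check runs 200 null trials at `B = 2000`. These sizes
make the statistical assertions sharp while keeping a full run of the
suite around a minute.

## Known limitations

Daily resolution only (twice-daily observations must be pre-aggregated);
no support for censored or clutch-level records; no functional-response
or prey-density modelling (the emulated trial fed ad libitum); the
projection is deterministic — demographic stochasticity enters only
through the bootstrap bands; and absolute reproduction of the original
trial's full tables is out of reach by design, since the raw
per-individual data are not public and the generator is calibrated to
summary targets only.
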