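---
title: "Methods: multi-state projection, urbanization curves, and gridded downscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-state projection, urbanization curves, and gridded downscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popproj)
library(dplyr)
```

This vignette documents the models behind `popproj`, the parameters that
matter, the numerical choices, and the design decisions taken where the
methodology was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The multi-state cohort-component model

The population state is a count array indexed by province, sex, single-year
age (0–99 plus an open "100+" group) and seven education stages (illiterate,
primary, junior high, senior high, college, bachelor, master+). Two
equations advance the state one calendar year.

**Births.** Newborns of each sex are the previous year's women aged 15–49,
across all education stages, multiplied by the current year's age-by-education
fertility rates and the newborn sex fractions $B_m = r/(1+r)$, $B_f = 1/(1+r)$
with $r$ the sex ratio at birth. Newborns enter at age 0 in the illiterate
stage. Using last year's exposure with this year's rates keeps the engine a
pure function of the previous state and the current rate set; newborns are
not exposed to migration in their birth year (migration applies from the
first full projection year of life).

**Cohort advancement.** For each cell, survivors (factor $1 - MOR$) are
scaled by provincial migration ($1 + NetPIM$), then either remain in their
education stage (probability $1 - G$) or progress along a stage transition
(probability $G$), and the whole result is scaled by national international
migration ($1 + NetGIM$). The multiplication order — survival, provincial
migration, education, international migration — follows the multiplicative
structure of the state equations; because all factors commute scalar-wise,
the order matters only for interpretation of the logged factors.

Three boundary rules:

* the illiterate stage has no feeder stream;
* the open "100+" group receives survivors of age 99 *and* of "100+" itself;
* education transitions fire only at stage *gate ages*: the transition into
  a stage happens in the year a cohort reaches the stage's entry age
  (6/13/16/19/19/23 for primary/junior/senior/college/bachelor/master), i.e.
  at previous-year ages 5/12/15/18/18/22.

**Why a stage DAG rather than a linear chain.** A strictly linear
"edu − 1 feeds edu" chain cannot express that senior high school feeds both
the college track and the bachelor track, yet the progression-rate caps are
stated separately for both destinations. The engine therefore generalizes
the feeder term to a small DAG — senior→college, senior→bachelor,
bachelor→master — with an independent progression probability per edge.
With both senior-high out-edges active, the stay probability is
$1 - G_{college} - G_{bachelor}$; the caps (0.30 and 0.60) keep this
positive. This is a faithful generalization, and the scalar-loop oracle in
the test suite implements it independently.

**Calibration.** Every projected year:

* fertility is rescaled by a single scalar so the implied national TFR
  (female-population-weighted across education stages and provinces, summed
  over ages 15–49) equals the scenario target. TFR is linear in the scale,
  so the scalar is closed-form and the round-trip is exact to 1e-9.
* each province-by-sex mortality schedule is rescaled by one scalar found by
  bisection so its period life expectancy matches the scenario target to
  1e-6 years. Scalar scaling preserves the base-year age profile, which is
  the point: scenario levels move the *level* of mortality, not its shape.
* provincial migration rates are multiplied by the scenario scaling and then
  rebalanced (Section 3).

## 2. Scenario paths and their anchors

All paths are total functions on 2010–2100; interpolation between stated
anchors is linear in calendar year unless a rule says otherwise.

* **TFR** (national, births/woman). Medium: 1.6 (2010) → 1.8 (2020) → 1.65
  (2030), then compounding at the constant annual factor
  $(1.802/1.706)^{1/70}$ — the UN-medium growth between its 2030 and 2100
  values applied multiplicatively, because only those two values are
  available as anchors. High: 2.0 in 2020, 1.25 × medium(2050) in 2050,
  constant after. Low: follows the medium rise to 2020 (the near-term rise
  is driven by the same current policy in both), then linear to
  0.75 × medium(2050), constant after. Whether the post-2030 medium level
  should jump to the UN level rather than grow from 1.65 is ambiguous; we
  compound from 1.65 and assert no 2100 TFR value.
* **Life expectancy** (province × sex, years). Annual increment
  $= (rate/10) \times LE^{nat}_{2010} / LE^{prov}_{2010}$ with rate 1.0
  (medium), 0.5 (high mortality), 1.5 (low mortality). The adjustment uses
  the *national/provincial* ratio — the convergence direction — so provinces
  below the national level catch up and high-LE, high-weight provinces grow
  more slowly; the alternative (provincial/national) would make leaders pull
  away, which contradicts the intended population-weighted national mean
  growth being slightly below the base rate.
* **Provincial migration** (scaling of the base-year NetPIM). A 3 × 3
  anchor grid by income category × scenario level: high-income provinces
  phase migration to zero (population-ceiling policies) by 2010/2020/2030;
  medium-income provinces decay to 50% by an intermediate year and to zero
  by 2100; low-income provinces move to 150%/100%/50% of the current rate by
  2050 and hold. Paths are piecewise linear through the anchors and constant
  after the last one.
* **International migration** (national, ‰). Medium: −0.3015‰ (the mean of
  the 2005–2010 and 2010–2015 estimates) held constant through 2050, then
  linear to 0 at 2100 — "constant over the first half of the century,
  decaying in the second" read as a 2050 breakpoint. High/low: ±50% in
  magnitude throughout.
* **Sex ratio at birth**: linear from the base-year provincial value to the
  1.07 policy target in 2050, constant after.
* **Education progression**: medium grows each rate at its province-specific
  historical annual growth rate (an input, supplied by the synthetic world);
  low freezes at base; high applies the largest cross-province rate per
  transition everywhere. Caps: 99.9% for the three compulsory-education
  transitions, 30%/60%/30% for senior→college/senior→bachelor/
  bachelor→master; a rate stays at its cap once reached. The
  income-dependent pattern (SSP4) routes high/medium/low-income provinces
  through the high/medium/low path.

The SSP level assignments are table-driven (`ssp_levels()`): SSP1
low/low/medium/high (fertility/mortality/migration/education), SSP2 all
medium, SSP3 high/high/low/low, SSP4 low/medium/medium/income-dependent,
SSP5 low/low/high/high.

## 3. Migration rebalancing

Scenario assumptions are stated as migration *rates*, and rates need not
produce flows that cancel nationally. The engine converts rates to implied
person-flows (rate × previous-year cell population, summed per province) and
scales down whichever side — total inflows or total outflows — is larger, by
the ratio of the smaller side to the larger, leaving relative proportions
within that side intact. The at-risk population is the previous-year
population (not the survived one): rebalancing is a correction to the
assumption inputs, not part of the within-year demography, and this choice
keeps it independent of the calibration order. One-sided migration (inflows
with no outflows) cannot balance and is suppressed entirely.

## 4. Urbanization curves

The provincial urban share follows $PU(T) = b / (1 + e^{-c(T-d)})$ with $T$
in years since 1995. With $b$ fixed, the curve is linear on the logit scale,
so $(c, d)$ come from OLS of $\log(PU/(b-PU))$ on $T$: the slope is $c$ and
$d = -\text{intercept}/c$. The upper limit $b$ comes from a rule grid on the
2015 share (≥70%: 100% everywhere; [60, 70): 90/80/75% fast/medium/slow;
<60%: 85/80/70%; lower bounds inclusive).

Under the medium pace each province is fitted to its own history. Under
fast/slow, reference provinces are selected within ±5 percentage points of
the target's 2015 share (above for fast, below for slow), excluding those
with a less extreme 1995–2015 increase. The pooled reference observations
are logit-transformed *with the target's b* and fitted in one OLS for $c$
(pooling, rather than averaging per-reference fits, weights every
observation equally and is isolated in one function); $d$ is then re-anchored
so the curve passes through the target's own 2015 observation. Reference
observations at or above the target's $b$ have no logit and are dropped with
a warning; an empty or unusable pool falls back to the own-history fit.

The default SSP→pace mapping is SSP1/SSP5 fast, SSP2 medium, SSP3 slow, and
SSP4 fast in high-income provinces, slow elsewhere — chosen to match each
SSP narrative's urbanization storyline and overridable via the `assumption`
argument.

Urban population is total × PU; rural is the remainder, so the split is
exactly additive by construction.

## 5. Gridded downscaling

The 2010 base weight grid is the raw population weight layer with water
pixels zeroed and two *epsilon layers* added: inverse distance to roads and
the population gravity field, each min–max rescaled into [1.0e-5, 1.1e-5].
The epsilons exist to make all non-water pixel values pairwise distinct so
that ranking pixels is deterministic; they perturb any provincial sum by
less than 2.2e-5 persons per pixel.

Each year, every coarse cell (default 12 × 12 fine pixels, standing in for
the real 0.5°-on-30″ ratio of 60) is assigned
`round_half_up(fraction × pixels)` urban pixels — the cell's highest-valued
pixels in the previous year's grid, ties broken by fixed pixel order.
"Nearest integer" is implemented as round-half-up and centralized in one
helper. Provincial urban totals are then spread over each province's urban
pixels proportionally to the previous grid, rural totals over its non-urban
non-water pixels, which conserves provincial mass exactly (up to float
roundoff; the acceptance suite bounds it at 1e-6 persons over a 91-year
run). Allocation is per province overall — not per province-within-coarse-
cell — because provincial mass conservation is the product's own stated
consistency check. A province with urban population but no urban pixels
falls back to its top 1% highest-valued pixels with a warning. Coarse urban
fractions are stored on decadal epochs and interpolated linearly between
them. Only the 15 SSP–RCP pairs with nonzero probability in the scenario
matrix are accepted for a run.

With constant totals and constant fractions the recursion reaches a fixed
point (allocation proportional to itself), which the test suite checks; with
growing urban fractions the urban mask expands along the previous year's
density ranking, concentrating growth near existing centres.

## 6. The synthetic world: what it does and does not emulate

The generator produces every input the real pipeline would read from a
census, statistical yearbooks, a gridded-population product, road data and
coarse urban-fraction grids — with known ground truth so calibrations are
testable as parameter recovery:

* **Base population**: per-province totals drawn in 2–8 million, a smooth
  gamma-shaped age pyramid (shape 2.2, scale 18; peak exposure in the 20s)
  with ±10% age noise, ~51.2% male share at birth ages, and education
  shares masked by stage entry ages (nobody below 19 holds a bachelor's
  degree).
* **Mortality**: Gompertz–Makeham hazards per sex
  ($q_x = 1 - e^{-(A + B e^{\theta x})}$, $A = 2\times10^{-4}$,
  $\theta = 0.095$, sex-specific $B$, an infant bump), scaled by the
  package's own life-table bisection to hit ground-truth life expectancies
  (male 70–76, female +3–6 years). Gompertz–Makeham gives realistic age
  patterns and a monotone LE–scale relationship, so root-finding is
  well-posed. Mortality is constant across education stages in the synthetic
  world; the engine carries the full education index regardless.
* **Fertility**: a normal-shaped schedule over ages 15–49 (peak 27, sd 6),
  education multipliers declining from 1.3 (illiterate) to 0.55 (master+),
  scaled per province to ground-truth TFRs in 1.3–2.0.
* **Urbanization histories**: exact logistic curves (b in 0.65–0.95, c in
  0.04–0.09, d 10–30 years after 1995) with optional Gaussian noise on the
  logit scale (default sd 0.05), which keeps values strictly inside (0, b).
* **Raster world**: a Voronoi partition of the grid into provinces, a
  smooth-field water mask (~6% of pixels), population density decaying from
  province centres with lognormal texture, roads as segments joining
  centres, gravity as inverse distance to the province's population-weighted
  centroid, and coarse urban fractions that start higher in denser cells and
  ramp linearly upward over the century.

It does **not** emulate: real age heaping or cohort scars (war/famine
notches), education-differential mortality, age-structured emigration
surges, coastline geometry, or road-network topology. A green test
therefore establishes that the *machinery* — calibration, recursion,
allocation, accounting — is correct, not that any real country's trajectory
is reproduced. Realistic national headline numbers require the real census
and raster inputs, which are deliberately out of scope.

All randomness flows from one integer seed; each generator uses a fixed
offset of it, so components are independently reproducible.

## 7. Numerical choices

* Life table: $a_x = 0.5$ for closed ages; the open 100+ interval
  contributes $\min(1/m_{100}, 10)$ years, so zero mortality gives a finite
  $e_0 = 110$ and LE is continuous in $m$.
* Mortality bisection: scale bracket [0, 10], tolerance 1e-9 years
  (tighter than the 1e-6 contract), 200-iteration cap; targets outside the
  bracket raise an error naming the achievable range.
* Fertility calibration is closed-form (linearity of TFR in the scale).
* Round-half-up for urban pixel counts, centralized in `round_half_up()`.
* Grids are row-major matrices with origin top-left; ASCII-grid export
  stores water as nodata −1 (plain text; no binary raster formats).
* Negative cohort counts (possible only with out-of-contract inputs) are
  clamped to zero with a warning; NetPIM ≤ −1 is rejected outright.

## 8. Known limitations

* Projection is deterministic: no stochastic intervals around the paths.
* TFR is a national target; provincial fertility keeps base-year relative
  differentials and shares one national scaling factor per year.
* The urbanization model cannot represent declining urban shares (the
  logistic is monotone for $c > 0$); a declining fitted pace triggers a
  warning, not a model switch.
* Within-year ordering of migration and education is a modelling convention;
  alternatives would change yearly flows at second order.
* The downscaler redistributes along historical density patterns only; new
  planned districts or relocation policies are not modelled.
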