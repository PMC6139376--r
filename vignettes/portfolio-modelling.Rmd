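---
title: "Portfolio-to-impact modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Portfolio-to-impact modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p2i)
```

## The model in one paragraph

`p2i` is a deterministic, expected-value model of product-development
pipelines. A portfolio is a list of project rows; each row puts a number
of identical candidates of one of eleven product archetypes into a
development phase at a calendar time. Candidates traverse the four-phase
pipeline (preclinical, phase 1, phase 2, phase 3) in continuous time;
each phase has an archetype-specific cost, probability of success (PoS),
and duration. The model propagates *expectations*, not samples: the
expected candidate mass entering each phase is the product of the prior
phases' PoS, expected costs are allocated to calendar years, and the
expected number of launches is a floating-point number that is rounded
only in reports. Health impact of launches is valued as burden times a
user-estimated fractional reduction, with DALYs priced at $500 each by
default.

## Parameters

The registry (`default_params()`) holds, for every archetype and phase:

| field        | units    | meaning                                          |
|--------------|----------|--------------------------------------------------|
| `cost_low/point/high` | $M | development cost of the phase (direct, site, and internal-FTE trial costs; excludes basic research, CMC/GMP, registration, post-market) |
| `pos`        | fraction | probability a candidate entering the phase advances |
| `duration`   | years    | cycle time of the phase                          |
| `applicable` | logical  | whether the archetype traverses the phase        |

Model-level constants: `daly_value` ($/DALY averted, default 500 — a
deliberately conservative valuation used for comparing products, not for
estimating "true" economic value) and the calendar horizon
(`horizon_start = 2017`, `horizon_end = 2030`; the horizon is a plain
argument and extends naturally, e.g. to 2040).

Point estimates drive all central results. The low/high cost bounds
produce a deterministic range (`estimate = "low"`/`"high"`), not an
uncertainty interval: the model has no stochastic component.

Percentages are stored as fractions and money in $M throughout; dollars
appear only in reported impact values. The registry can be exported to a
flat CSV, edited, and re-imported (`write_params_csv()` /
`read_params_csv()`); the round trip is bit-exact and re-validated on
import, so users can change any assumption without touching code.

### Phase-slot conventions

Two conventions keep one uniform four-slot engine for all archetypes:

* **Pass-through phases.** Phases an archetype never traverses (the
  preclinical and phase-1 slots of simple repurposed drugs, slot 0 of the
  platform diagnostic, slot 3 of both diagnostics) are modelled with
  cost 0, duration 0, PoS 1. They are transparent to every computation.
  We treat the diagnostics' missing phase-3 cells as absent stages rather
  than zero-cost stages with elapsed time; the pass-through encoding
  realizes that reading.
* **Diagnostics stage mapping.** The three named diagnostic stages
  (selection and validation of markers; development; regulated trials
  beyond EUO/CE) occupy ordinals 0–2, with ordinal 3 pass-through.

Default entry phases follow applicability: phase 2 for simple repurposed
drugs (sufficient safety data exists to start in phase 2), slot 1 for
platform diagnostics, the preclinical slot otherwise.

## The engine's accounting choices

Several conventions are genuinely open in a model of this kind; the ones
chosen here are:

* **Attrition timing.** The full expected phase cost is incurred by every
  candidate that *enters* a phase; success is evaluated at phase end.
  PoS is a per-phase transition probability, and failing candidates still
  spend the phase's budget.
* **Cost spreading.** A phase's expected cost is spread uniformly over
  its duration and apportioned to calendar years by interval overlap. An
  alternative convention books the whole phase cost at phase start; both
  conserve totals, but annual budget profiles differ. Uniform spreading
  makes annual disbursement needs well defined, which is the quantity a
  funder plans against. Zero-duration phases book their (normally zero)
  cost at the instant of entry.
* **Time.** Continuous decimal years; calendar buckets are half-open
  `[Y, Y+1)`. Occupancy reported for a year is the time-averaged expected
  number of candidates in the phase during that year.
* **Launch crediting.** Expected launches are credited to the calendar
  year containing the launch instant (the end of the last applicable
  phase).
* **Rounding.** `round_launches()` rounds half away from zero and is used
  only in reports, never in computation.
* **Capacity.** `capacity_factor` multiplies a row's expected masses,
  costs, and launches (it scales the row, rather than gating new starts
  per year); constraints are therefore applied per project row. In the
  Monte Carlo oracle it becomes an independent absorption probability,
  which reproduces the same expectations.
* **Portfolio size.** Portfolios beyond 150 rows trigger a warning, not
  an error — the cap mirrors the intended scale of use, not a numerical
  limit.

## Planning

* *Prospective* (`plan_prospective()`): an entry schedule (archetype,
  phase, year, entrants/year) expands into project rows and aggregates.
  Entrants may be fractional — expected-value semantics; an integerized
  ceiling is reported alongside where relevant.
* *Retrospective* (`solve_entrants()`): a target expected count at a
  phase (or expected launches) divides by the cumulative PoS of the
  traversed chain and backdates the entry year by the summed cycle times.
  Targets whose entry year falls before the horizon start are infeasible
  and rejected.
* *Steady state* (`steady_state()`): with constant entrants, the flow
  into phase *k* equilibrates at entrants × cumulative PoS of prior
  phases, and occupancy is flow × duration (Little's law). The analytic
  values match a long-run constant-entrant plan to machine precision once
  ramp-up has passed; the test suite verifies this decades past the
  longest (~12.5-year) cycle time.

## Funding scenarios

Seven built-in fund sizes (1, 5, 15, 50, 100, 300, 500 $M/year) mirror
the spectrum from passive coordination (the $1M and $5M funds are
non-operational: they fund no development projects) to a global fund.
`fit_portfolio_to_budget()` scales a strategy's archetype mix so that the
*steady-state* annual cost exactly meets the fund size; because cost is
linear in entrants the fit is a single division, deterministic, and never
exceeds the budget (ramp-up years underspend, which the budget trace
shows). Fitting against steady-state cost rather than year-1 cost matches
the notion of a sustained annual disbursement capacity. The full fund
size is treated as disbursable for operational scenarios; coordination
overhead inside project-funding scenarios is not modelled separately.

The three named strategies are archetype-mix templates: `quick_wins`
(70% simple repurposed, 20% complex repurposed, 10% diagnostic assays),
`innovation` (novel vaccines/NCEs/biologics and platform diagnostics),
and `mixed` (their 50/50 blend). The strategy *names* are established;
the specific weights are this package's illustrative defaults — published
scenario analyses do not print their exact mixes, so scenario runs
reproduce structure, not any particular reported launch counts. Any
explicit named weight vector can be supplied instead.

## Health impact

The impact calculation is a single multiplication per launched
intervention — burden × expected fractional reduction, identically for
every archetype — kept deliberately simple: no adoption curve, coverage
ramp, or discounting. Burden data are user inputs (the natural source is
a global burden-of-disease estimate for the diseases of interest), not
bundled with the package. `portfolio_impact()` exposes two views: the
expectation-weighted view (per-launch impact × expected fractional
launches) and the per-whole-launch view, since "impact of a single
launched intervention" is the usual reporting unit and it is a judgement
call whether fractional expected launches should scale impact.

## Validation oracles

The deterministic engine is validated two independent ways:

1. `enumerate_paths()` exhaustively enumerates the ≤ 2⁴ survive/fail
   paths of a single candidate and computes exact expected launches and
   cost. Engine expectations must agree to 1e-12 relative for every
   archetype.
2. `simulate_attrition()` realizes the minimal stochastic model
   consistent with the expectations (independent Bernoulli phase
   outcomes, deterministic costs given entry; seeded, replicate-level
   outputs retained). At 10⁵ replicates the simulated means must fall
   within three standard errors of the exact expectations.

## Synthetic fixtures

`random_portfolio()` generates seeded, always-valid portfolios (entry
phases respect archetype applicability; multiplicities are small
integers so the same fixtures feed the Monte Carlo oracle), and
`perturb_params()` applies seeded multiplicative jitter that preserves
every registry invariant. These fixtures emulate *structurally* valid
portfolios for property testing — conservation, linearity, round trips —
across many seeds. They do not emulate real pipelines: real portfolios
have correlated archetype mixes, disease-specific entry timing, and
heterogeneous per-project characteristics that an archetype-averaged
model deliberately ignores. Passing tests therefore demonstrate internal
consistency of the accounting, not predictive accuracy for any actual
portfolio.

## Problem sizes used in the test suite

Unit and acceptance tests run single projects and portfolios of 5–8
projects over ~100 seeds; oracle comparisons use 10⁵ Monte Carlo
replicates per archetype; steady-state verification uses constant
entrants over a 40-year schedule probed decades past ramp-up. These sizes
were chosen so every check is decisive for a model whose state space is
11 archetypes × 4 phases while keeping the full suite fast.

## Known limitations

* Deterministic single-point estimates: no uncertainty or risk
  propagation (the Monte Carlo module exists to *test* the engine, not to
  quantify portfolio risk; costs and durations are never sampled).
* All projects of an archetype share the same averaged cost/PoS/cycle
  parameters; individual product prediction is out of scope.
* No market dimensions (price, demand, sales, profits) and no cost
  discounting.
* Excluded cost categories (basic research through lead optimization,
  CMC/GMP, registration, post-market) mean cost-per-launch figures are
  lower than full private-sector development cost estimates.
* Impact estimates inherit all the uncertainty of the user's
  burden-reduction guess.
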