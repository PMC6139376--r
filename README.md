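# p2i — portfolio-to-impact modelling of health product R&D pipelines

`p2i` is an R implementation of the Portfolio-To-Impact (P2I) model, a
deterministic financial portfolio tool for global health product R&D. It
is aimed at funders of research on poverty-related and neglected diseases
(product development partnerships, foundations, multilateral agencies) who
need to answer questions like: *how much annual funding does a given
portfolio of candidates need, how many product launches can it be expected
to deliver by 2030, and what health impact would those launches have?*

## The model

Candidate products are classified into **11 archetypes** — simple/complex
vaccines, simple/innovative/complex new chemical entities (NCEs),
simple/complex repurposed drugs, simple/complex biologics, and two
diagnostic archetypes (assay development, technical platform development).
Each archetype carries per-phase assumptions for the four development
phases (preclinical, phase 1, phase 2, phase 3; diagnostics map their
three named stages onto the same slots):

* development cost per phase, in $M (lower bound, upper bound, point
  estimate),
* probability of success (PoS) per phase — the complement of attrition,
* cycle time per phase, in years.

The engine is an **expected-value model**: a project row with multiplicity
*m* and capacity factor *c* entering at phase *e* contributes an expected
mass of candidates to phase *k* of

&nbsp;&nbsp;&nbsp;&nbsp;*n(k) = m · c · ∏<sub>j=e</sub><sup>k−1</sup> PoS(j)*

Every candidate entering a phase incurs that phase's full cost (attrition
is resolved at phase end), so the expected cost of phase *k* is
*n(k) · cost(k)*, spread uniformly over the phase's time interval and
apportioned to calendar years by overlap. The expected number of launches
is *n(3) · PoS(3)* — a floating-point expectation, rounded (half away from
zero) only for presentation. The attrition-adjusted **expected cost per
launch** of an archetype is

&nbsp;&nbsp;&nbsp;&nbsp;*E\[cost\] / ∏<sub>j=e</sub><sup>3</sup> PoS(j)*,

which stays below $1 billion for every archetype (maximum: the complex
vaccine at ≈ $0.94B).

Health impact of a launch is a deliberately simple valuation:
DALYs averted = disease burden × user-estimated fractional reduction
(likewise deaths averted), and economic value = DALYs averted × $500.

A seeded Monte Carlo attrition simulator (`simulate_attrition()`) and an
exhaustive path enumerator (`enumerate_paths()`) are included purely to
validate the deterministic engine: the simulated means must match the
deterministic expectations.

## Worked example

```r
library(p2i)
ps <- default_params()          # the archetype parameter registry

pf <- read_portfolio_csv(system.file("extdata", "synthetic_portfolio.csv",
                                     package = "p2i"), ps)
tl <- aggregate_portfolio(pf, ps)
tl
#> p2i portfolio timeline, 2017-2030
#>   total expected cost: $119.72M
#>   total expected launches: 2.544 (3 rounded)
head(tl$years, 5)
#>   year      cost launches cumulative_launches
#> 1 2017 14.857186 0.000000            0.000000
#> 2 2018 22.851233 0.000000            0.000000
#> 3 2019 20.819266 0.000000            0.000000
#> 4 2020 20.990639 0.000000            0.000000
#> 5 2021  8.227726 2.244868            2.244868
```

The portfolio (4 simple repurposed drugs and 2 NCEs entering 2017, a
simple vaccine and 2 diagnostic assays entering 2018) needs about $15–23M
per year in its early years and is expected to yield 2.54 launches
(reported as 3): the repurposed drugs and assays arrive in 2021, the NCE
and vaccine expectations trickle in around 2027.

Retrospective ("outcome-based") planning inverts the attrition chain:

```r
solve_entrants("vaccine_simple", "launch", 1, by_year = 2030, ps = ps)
#> $entrants          11.0 (ceiling 11)
#> $entry_year        2020.51
#> $lead_time         9.49 years
```

i.e. one expected simple-vaccine launch by 2030 requires ~11 preclinical
entrants starting in 2020 (the full chain PoS is 0.0911 over a 9.49-year
cycle).

Funding-scenario analysis fits a strategy mix to an annual fund size:

```r
run_scenario(builtin_scenarios("quick_wins")[[5]], ps)
#> scenario 5: medium sized fund (US$ 100m/yr)
#>   new projects initiated per year: 7.806
#>   steady-state active projects: 26.51 (annual cost $100M)
#>   expected launches by 2030: 22.58 (23 rounded)
```

Health impact joins user-supplied burden/reduction estimates to launches
(the burden figures in `synthetic_impacts.csv` are illustrative
placeholders, not sourced estimates):

```r
imp <- read_impacts_csv(system.file("extdata", "synthetic_impacts.csv",
                                    package = "p2i"))
portfolio_impact(pf, imp, ps)$by_year
#>   year launch_mass dalys_averted deaths_averted economic_value
#> 1 2021   2.2448680    740806.440    11583.51888      370403220
#> 2 2027   0.2080786      5722.162       83.23145        2861081
```

A thin command-line interface over the same functions is installed at
`system.file("cli", "p2i.R", package = "p2i")` with subcommands
`params export|validate`, `plan`, `solve`, `scenario list|run`, `impact`,
and `simulate`.

## Package layout

* `R/params.R` — parameter registry, validation, CSV export/import
* `R/engine.R` — expected-value progression, cost allocation, launches
* `R/planner.R` — prospective/retrospective planning, steady state
* `R/impact.R` — DALYs averted, deaths averted, economic value
* `R/oracle.R` — Monte Carlo simulator and exact path enumeration
* `R/scenarios.R` — strategy templates, the seven built-in fund scenarios
* `R/fixtures.R` — seeded synthetic portfolios and parameter perturbation
* `vignettes/portfolio-modelling.Rmd` — methods and design notes
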