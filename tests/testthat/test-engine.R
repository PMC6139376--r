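test_that("single-project timeline walks phases in continuous time", {
  # simple repurposed drug enters directly at phase 2
  prj <- project("repurposed_simple", 2017, ps = PS)
  tl <- project_timeline(prj, PS)
  expect_equal(tl$phases$start, c(2017.0, 2019.14))
  expect_equal(tl$phases$end, c(2019.14, 2021.28))
  expect_equal(tl$phases$entry_mass, c(1, 0.457))
  expect_equal(tl$launch_time, 2021.28)
  expect_equal(tl$launch_mass, 0.457 * 0.681, tolerance = 1e-12)
  expect_identical(tl$launch_year, 2021L)

  # simple vaccine from preclinical
  tlv <- project_timeline(project("vaccine_simple", 2017, ps = PS), PS)
  expect_equal(tlv$launch_time, 2017 + 3.36 + 1.57 + 2.23 + 2.33)
  expect_equal(tlv$launch_mass, cumulative_pos(PS, "vaccine_simple", 0, 3))

  # phase intervals partition [entry, launch): abutting, no gaps
  for (a in archetype_ids()) {
    t <- project_timeline(project(a, 2020, ps = PS), PS)
    expect_equal(t$phases$start[-1],
                 t$phases$end[-nrow(t$phases)])
    expect_equal(t$phases$start[1] +
                   sum(t$phases$end - t$phases$start),
                 t$launch_time)
    expect_true(all(diff(t$phases$entry_mass) <= 0))
  }
})

test_that("capacity factor 0 zeroes masses, costs, and launches", {
  prj <- project("nce_simple", 2018, capacity_factor = 0, ps = PS)
  tl <- project_timeline(prj, PS)
  expect_equal(tl$launch_mass, 0)
  expect_equal(sum(tl$yearly_cost$cost), 0)
  expect_true(all(tl$phases$entry_mass == 0))
})

test_that("uniform cost spreading conserves each phase's expected cost", {
  prj <- project("repurposed_simple", 2017, ps = PS)
  tl <- project_timeline(prj, PS)
  # first calendar year of a 2.14-year phase gets 1/2.14 of its cost
  expect_equal(tl$yearly_cost$cost[tl$yearly_cost$year == 2017],
               5.8 / 2.14, tolerance = 1e-12)
  expect_equal(sum(tl$yearly_cost$cost),
               5.8 + 0.457 * 17.6, tolerance = 1e-12)
})

test_that("expected phase cost chains attrition through prior phases", {
  prj <- project("nce_simple", 2017, ps = PS)
  expect_equal(expected_phase_cost(prj, 3, PS),
               0.65 * 0.597 * 0.388 * 32.8, tolerance = 1e-12)
  # entry phase has entry probability 1: cost is the point estimate itself
  expect_equal(expected_phase_cost(prj, 0, PS), 5.0)
  # non-applicable phase costs nothing
  prj2 <- project("repurposed_simple", 2017, ps = PS)
  expect_equal(expected_phase_cost(prj2, 0, PS), 0)
  # low/high bounds
  expect_equal(expected_phase_cost(prj, 0, PS, estimate = "low"), 2.5)
  expect_equal(expected_phase_cost(prj, 0, PS, estimate = "high"), 7.5)
})

test_that("cost per launch matches hand-computed archetype figures", {
  # diagnostics assay: (3.0 + 0.5*2.0 + 0.5*3.5) / 0.5
  expect_equal(expected_cost_per_launch("dx_assay", PS), 11.5,
               tolerance = 1e-12)
  cpl <- vapply(archetype_ids(), expected_cost_per_launch, numeric(1),
                ps = PS)
  # the most expensive route to launch is the complex vaccine
  expect_equal(unname(cpl["vaccine_complex"]), 936.6, tolerance = 1e-3)
  expect_identical(names(which.max(cpl)), "vaccine_complex")
  expect_true(all(is.finite(cpl) & cpl > 0))
  # consistency with the attrition-weighted enumeration oracle
  for (a in archetype_ids()) {
    h <- hand_expectations(a)
    expect_equal(unname(cpl[a]), h$cost / h$launches, tolerance = 1e-12)
  }
})

test_that("portfolio aggregation is linear and conserves totals", {
  prj <- project("repurposed_simple", 2017, ps = PS)
  one <- aggregate_portfolio(prj, PS)
  two <- aggregate_portfolio(rbind(prj, prj), PS)
  expect_equal(two$years$cost, 2 * one$years$cost)
  expect_equal(two$years$launches, 2 * one$years$launches)
  expect_equal(two$occupancy[paste0("phase", 0:3)],
               one$occupancy[paste0("phase", 0:3)] * 2)

  # doubling multiplicity or capacity is the same scaling
  prj_m2 <- project("repurposed_simple", 2017, multiplicity = 2, ps = PS)
  expect_equal(aggregate_portfolio(prj_m2, PS)$years$cost,
               two$years$cost)
  prj_c <- project("repurposed_simple", 2017, multiplicity = 4,
                   capacity_factor = 0.5, ps = PS)
  expect_equal(aggregate_portfolio(prj_c, PS)$total_launches,
               two$total_launches)

  # cumulative launches by 2030 for the single project
  expect_equal(one$years$cumulative_launches[one$years$year == 2030],
               0.457 * 0.681, tolerance = 1e-12)

  # empty portfolio: all-zero timeline over the horizon
  empty <- aggregate_portfolio(NULL, PS)
  expect_equal(empty$total_cost, 0)
  expect_equal(empty$total_launches, 0)
  expect_equal(range(empty$years$year),
               c(PS$horizon_start, PS$horizon_end))
})

test_that("calendar-year cost allocations conserve expected phase costs", {
  for (seed in 1:25) {
    pf <- random_portfolio(6, seed = seed, ps = PS)
    tl <- aggregate_portfolio(pf, PS)
    direct <- sum(vapply(seq_len(nrow(pf)), function(i) {
      sum(vapply(0:3, function(k) {
        expected_phase_cost(pf[i, ], k, PS)
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(tl$total_cost, direct, tolerance = 1e-9)
  }
})

test_that("occupancy is time-averaged candidates in phase", {
  # one repurposed candidate: in phase 2 for all of 2017 and 2018
  tl <- aggregate_portfolio(project("repurposed_simple", 2017, ps = PS), PS)
  occ2 <- tl$occupancy$phase2
  expect_equal(occ2[tl$occupancy$year == 2017], 1)
  expect_equal(occ2[tl$occupancy$year == 2018], 1)
  # 2019: in phase 2 until 2019.14, then 0.457 candidates in phase 3
  expect_equal(occ2[tl$occupancy$year == 2019], 0.14, tolerance = 1e-9)
  expect_equal(tl$occupancy$phase3[tl$occupancy$year == 2019],
               0.457 * 0.86, tolerance = 1e-9)
})

test_that("funded-phase selection limits which costs the fund bears", {
  full <- project("nce_simple", 2017, ps = PS)
  p3only <- project("nce_simple", 2017, funded_phases = 3, ps = PS)
  tl <- aggregate_portfolio(p3only, PS)
  expect_equal(tl$total_cost, expected_phase_cost(full, 3, PS),
               tolerance = 1e-12)
  # launches are unaffected by who pays
  expect_equal(tl$total_launches,
               aggregate_portfolio(full, PS)$total_launches)
})

test_that("launch rounding is nearest-integer, half away from zero", {
  expect_identical(round_launches(0.3112), 0L)
  expect_identical(round_launches(10.5), 11L)
  expect_identical(round_launches(3.49), 3L)
  expect_identical(round_launches(c(0.5, 1.5, 2.5)), c(1L, 2L, 3L))
  expect_error(round_launches(-0.1), ">= 0")
})

test_that("entry phases are validated against archetype applicability", {
  expect_error(project("repurposed_simple", 2017, entry_phase = 0,
                       ps = PS), "not applicable")
  expect_error(project("dx_platform", 2017, entry_phase = 0, ps = PS),
               "not applicable")
  expect_silent(project("dx_platform", 2017, entry_phase = 1, ps = PS))
  expect_error(project("vaccine_simple", 2017, capacity_factor = 1.2,
                       ps = PS), "capacity_factor")
  expect_error(project("vaccine_simple", 2017, multiplicity = -1,
                       ps = PS), "multiplicity")
})
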