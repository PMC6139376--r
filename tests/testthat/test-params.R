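test_that("registry holds the published cost assumptions", {
  ph <- PS$phases
  cell <- function(a, k) ph[ph$archetype_id == a & ph$phase_ordinal == k, ]

  # vaccines
  expect_equal(cell("vaccine_simple", 0)$cost_point, 6.7)
  expect_equal(cell("vaccine_simple", 3)[, c("cost_low", "cost_high",
                                             "cost_point")],
               data.frame(cost_low = 56.6, cost_high = 165.6,
                          cost_point = 111.1),
               ignore_attr = TRUE)
  expect_equal(cell("vaccine_complex", 0)$cost_point, 16.6)
  expect_equal(cell("vaccine_complex", 3)$cost_point, 133.3)
  # NCEs
  expect_equal(cell("nce_simple", 3)$cost_point, 32.8)
  expect_equal(cell("nce_innovative", 1)$cost_point, 4.8)
  expect_equal(cell("nce_complex", 0)$cost_point, 10.0)
  expect_equal(cell("nce_complex", 3)$cost_high, 59.6)
  # repurposed drugs: simple has no preclinical/phase-1 stage
  expect_false(cell("repurposed_simple", 0)$applicable)
  expect_false(cell("repurposed_simple", 1)$applicable)
  expect_equal(cell("repurposed_simple", 2)$cost_point, 5.8)
  expect_equal(cell("repurposed_complex", 3)$cost_point, 17.6)
  # biologics
  expect_equal(cell("biologic_simple", 0)$cost_point, 10.8)
  expect_equal(cell("biologic_complex", 3)$cost_point, 59.5)
  # diagnostics: three named stages on slots 0-2, slot 3 pass-through
  expect_equal(cell("dx_assay", 0)$cost_point, 3.0)
  expect_false(cell("dx_assay", 3)$applicable)
  expect_equal(cell("dx_platform", 1)[, c("cost_low", "cost_high",
                                          "cost_point")],
               data.frame(cost_low = 50.0, cost_high = 150.0,
                          cost_point = 100.0),
               ignore_attr = TRUE)
  expect_false(cell("dx_platform", 0)$applicable)
})

test_that("registry holds the published PoS and cycle-time assumptions", {
  ph <- PS$phases
  cell <- function(a, k) ph[ph$archetype_id == a & ph$phase_ordinal == k, ]

  expect_equal(cell("vaccine_simple", 3)$pos, 0.708)
  expect_equal(cell("vaccine_simple", 3)$duration, 2.33)
  expect_equal(cell("vaccine_simple", 0)$duration, 3.36)
  expect_equal(cell("vaccine_complex", 2)$pos, 0.216)
  expect_equal(cell("nce_simple", 0)$pos, 0.650)
  expect_equal(cell("nce_innovative", 2)$duration, 3.35)
  expect_equal(cell("nce_complex", 3)$pos, 0.403)
  expect_equal(cell("repurposed_simple", 2)$pos, 0.457)
  expect_equal(cell("repurposed_simple", 0)$duration, 0)
  expect_equal(cell("repurposed_simple", 0)$pos, 1)
  expect_equal(cell("repurposed_complex", 0)$pos, 0.750)
  expect_equal(cell("biologic_simple", 3)$pos, 0.709)
  expect_equal(cell("biologic_complex", 2)$duration, 4.16)
  expect_equal(cell("dx_assay", 0)$pos, 0.50)
  expect_equal(cell("dx_platform", 1)$pos, 0.75)
  expect_equal(cell("dx_platform", 1)$duration, 2.50)
})

test_that("registry structure: 11 archetypes x 4 ordered phases", {
  expect_identical(nrow(PS$archetypes), 11L)
  expect_identical(nrow(PS$phases), 44L)
  expect_setequal(unique(PS$phases$archetype_id), archetype_ids())
  expect_identical(validate_params(PS), character(0))
  # default entry phases: phase 2 for simple repurposed (safety data in
  # hand), slot 1 for the platform diagnostic, earliest phase otherwise
  expect_identical(entry_phase_default(PS, "repurposed_simple"), 2L)
  expect_identical(entry_phase_default(PS, "dx_platform"), 1L)
  expect_identical(entry_phase_default(PS, "vaccine_simple"), 0L)
})

test_that("validate_params reports each broken invariant by name", {
  bad <- PS
  bad$phases$pos[bad$phases$archetype_id == "vaccine_simple" &
                   bad$phases$phase_ordinal == 2] <- 1.2
  v <- validate_params(bad)
  expect_length(v, 1)
  expect_match(v, "vaccine_simple phase 2.*pos")

  bad2 <- PS
  i <- which(bad2$phases$archetype_id == "nce_simple" &
               bad2$phases$phase_ordinal == 3)
  bad2$phases$cost_point[i] <- bad2$phases$cost_high[i] + 1
  v2 <- validate_params(bad2)
  expect_length(v2, 1)
  expect_match(v2, "nce_simple phase 3.*cost_point")

  bad3 <- PS
  bad3$daly_value <- -1
  expect_match(validate_params(bad3), "daly_value")

  # non-applicable phases must stay pass-through
  bad4 <- PS
  i <- which(bad4$phases$archetype_id == "repurposed_simple" &
               bad4$phases$phase_ordinal == 0)
  bad4$phases$duration[i] <- 1
  expect_match(validate_params(bad4), "pass-through")
})

test_that("cumulative PoS multiplies the printed per-phase values", {
  expect_equal(cumulative_pos(PS, "vaccine_simple", 0, 3),
               0.410 * 0.684 * 0.459 * 0.708, tolerance = 1e-12)
  expect_equal(cumulative_pos(PS, "dx_assay", 0, 3), 0.5)
  # empty chain is the empty product
  expect_identical(cumulative_pos(PS, "nce_simple", 2, 1), 1.0)
  expect_error(cumulative_pos(PS, "nce_simple", 3, 1), "inverted")
  expect_error(cumulative_pos(PS, "not_a_thing", 0, 3), "unknown archetype")

  for (a in archetype_ids()) {
    rows <- PS$phases[PS$phases$archetype_id == a, ]
    full <- prod(rows$pos)
    expect_equal(cumulative_pos(PS, a, 0, 3), full, tolerance = 1e-12)
    # monotonically non-increasing as the chain extends
    chain <- vapply(0:3, function(k) cumulative_pos(PS, a, 0, k),
                    numeric(1))
    expect_true(all(diff(chain) <= 0))
  }
})

test_that("total cycle time sums the printed phase durations", {
  expect_equal(total_cycle_time(PS, "vaccine_simple", 0, 3),
               3.36 + 1.57 + 2.23 + 2.33)
  expect_equal(total_cycle_time(PS, "repurposed_simple"), 2.14 + 2.14)
  for (a in archetype_ids()) {
    rows <- PS$phases[PS$phases$archetype_id == a, ]
    expect_equal(total_cycle_time(PS, a, 0, 3), sum(rows$duration))
  }
})

test_that("parameter CSV export/import round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_params_csv(PS, f)
  back <- read_params_csv(f)
  for (col in c("cost_low", "cost_high", "cost_point", "pos", "duration")) {
    expect_identical(back$phases[[col]], PS$phases[[col]])
  }
  expect_identical(back$phases$archetype_id, PS$phases$archetype_id)
  expect_identical(back$phases$applicable, PS$phases$applicable)
  expect_identical(validate_params(back), character(0))

  # a perturbed (irregular-decimal) set also survives the round trip
  pp <- perturb_params(PS, 0.3, seed = 11)
  write_params_csv(pp, f)
  back2 <- read_params_csv(f)
  expect_identical(back2$phases$cost_point, pp$phases$cost_point)
  expect_identical(back2$phases$pos, pp$phases$pos)

  # imports that break invariants are refused
  ph <- PS$phases
  ph$pos[1] <- 2
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ph, f2, row.names = FALSE)
  expect_error(read_params_csv(f2), "validation")
})
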