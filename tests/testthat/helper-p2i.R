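# Shared fixtures: one default parameter set per test run.
PS <- default_params()

# Expected-value totals for one candidate of an archetype, computed the
# spreadsheet way (attrition-weighted sums), independent of the engine's
# interval bookkeeping. Used as an oracle in several files.
hand_expectations <- function(archetype, ps = PS) {
  rows <- ps$phases[ps$phases$archetype_id == archetype, ]
  rows <- rows[order(rows$phase_ordinal), ]
  e <- entry_phase_default(ps, archetype)
  mass <- 1
  cost <- 0
  for (k in e:3) {
    r <- rows[rows$phase_ordinal == k, ]
    cost <- cost + mass * r$cost_point
    mass <- mass * r$pos
  }
  list(launches = mass, cost = cost)
}
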