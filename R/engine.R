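#' Define a portfolio project row
#'
#' A project is one row of a portfolio: a number of identical candidates of
#' one archetype entering the pipeline at a given phase and calendar time.
#' The model is an expected-value model, so `multiplicity` may be
#' fractional; `capacity_factor` scales the whole row to reflect how much
#' of it the R&D system can absorb (1 = fully absorbed).
#'
#' @param archetype Archetype id (see [archetype_ids()]).
#' @param entry_year Decimal calendar year at which the candidates enter
#'   their first phase (e.g. `2017.0`).
#' @param entry_phase Phase ordinal 0-3 at which development starts.
#'   Defaults to the archetype's default entry phase. Must be an applicable
#'   phase of the archetype.
#' @param multiplicity Number of identical candidates started (>= 0; may be
#'   fractional under expected-value semantics).
#' @param capacity_factor Fraction in \[0, 1\] of the row the system can
#'   absorb. Default 1.
#' @param funded_phases Integer vector of phase ordinals whose costs the
#'   fund bears. Default all four.
#' @param disease Optional disease label used to join health-impact inputs.
#' @param ps Parameter set used for validation.
#' @return One-row data frame with class-stable portfolio columns;
#'   `funded_phases` is stored as a semicolon-separated string.
#' @export
#' @examples
#' project("repurposed_simple", 2017)
project <- function(archetype, entry_year,
                    entry_phase = NULL,
                    multiplicity = 1,
                    capacity_factor = 1,
                    funded_phases = 0:3,
                    disease = NA_character_,
                    ps = default_params()) {
  .check_archetype(ps, archetype)
  if (is.null(entry_phase)) entry_phase <- entry_phase_default(ps, archetype)
  entry_phase <- as.integer(entry_phase)
  rows <- .phases_of(ps, archetype)
  if (entry_phase < 0 || entry_phase > 3) stop("entry_phase must be 0..3")
  if (!rows$applicable[rows$phase_ordinal == entry_phase]) {
    stop(archetype, ": entry at phase ", entry_phase,
         " is not applicable (first applicable phase is ",
         min(rows$phase_ordinal[rows$applicable]), ")")
  }
  if (multiplicity < 0) stop("multiplicity must be >= 0")
  if (capacity_factor < 0 || capacity_factor > 1) {
    stop("capacity_factor must be in [0, 1]")
  }
  funded_phases <- sort(unique(as.integer(funded_phases)))
  if (length(funded_phases) > 0 &&
      (min(funded_phases) < 0 || max(funded_phases) > 3)) {
    stop("funded_phases must be phase ordinals 0..3")
  }
  data.frame(
    archetype = archetype,
    entry_phase = entry_phase,
    entry_year = as.numeric(entry_year),
    multiplicity = as.numeric(multiplicity),
    capacity_factor = as.numeric(capacity_factor),
    funded_phases = paste(funded_phases, collapse = ";"),
    disease = disease,
    stringsAsFactors = FALSE
  )
}

.parse_funded <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}

# Fraction of [a, b) that falls inside calendar year bucket [year, year+1).
.year_overlap <- function(a, b, year) {
  pmax(0, pmin(b, year + 1) - pmax(a, year))
}

#' Expected timeline of a single project
#'
#' Propagates the project's candidates through its phases in continuous
#' time. Each phase interval starts where the previous one ends; the
#' expected number of candidates entering phase k is
#' `multiplicity * capacity_factor * prod(PoS of prior traversed phases)`
#' (attrition is applied at phase end, so every entrant incurs the full
#' expected phase cost). Funded phase costs are spread uniformly over the
#' phase interval and apportioned to calendar years by interval overlap;
#' a zero-duration phase books its cost at the instant of entry.
#'
#' @param prj One-row project data frame from [project()].
#' @param ps A `p2i_params` object.
#' @param estimate Which cost column drives the result: `"point"` (default),
#'   `"low"`, or `"high"`.
#' @return List of class `p2i_project_timeline` with elements
#'   `phases` (data frame: ordinal, start, end, entry_mass, cost_total,
#'   funded), `yearly_cost` (data frame: year, cost), `launch_time`
#'   (decimal year), `launch_year` (integer), and `launch_mass`
#'   (expected launches, floating point).
#' @export
#' @examples
#' ps <- default_params()
#' project_timeline(project("repurposed_simple", 2017, ps = ps), ps)
project_timeline <- function(prj, ps, estimate = c("point", "low", "high")) {
  estimate <- match.arg(estimate)
  cost_col <- switch(estimate, point = "cost_point",
                     low = "cost_low", high = "cost_high")
  rows <- .phases_of(ps, prj$archetype)
  funded <- .parse_funded(prj$funded_phases)
  ords <- prj$entry_phase:3
  scale <- prj$multiplicity * prj$capacity_factor

  t0 <- prj$entry_year
  mass <- scale
  ph <- data.frame(ordinal = ords, start = NA_real_, end = NA_real_,
                   entry_mass = NA_real_, cost_total = NA_real_,
                   funded = ords %in% funded)
  for (i in seq_along(ords)) {
    k <- ords[i]
    r <- rows[rows$phase_ordinal == k, ]
    ph$start[i] <- t0
    ph$end[i] <- t0 + r$duration
    ph$entry_mass[i] <- mass
    ph$cost_total[i] <- if (k %in% funded) mass * r[[cost_col]] else 0
    t0 <- t0 + r$duration
    mass <- mass * r$pos
  }
  launch_time <- t0
  launch_mass <- mass

  yrs <- seq(floor(prj$entry_year), floor(launch_time))
  cost <- numeric(length(yrs))
  for (i in seq_len(nrow(ph))) {
    if (ph$cost_total[i] == 0) next
    dur <- ph$end[i] - ph$start[i]
    if (dur > 0) {
      cost <- cost + ph$cost_total[i] *
        .year_overlap(ph$start[i], ph$end[i], yrs) / dur
    } else {
      cost[yrs == floor(ph$start[i])] <-
        cost[yrs == floor(ph$start[i])] + ph$cost_total[i]
    }
  }
  structure(
    list(phases = ph,
         yearly_cost = data.frame(year = yrs, cost = cost),
         launch_time = launch_time,
         launch_year = as.integer(floor(launch_time)),
         launch_mass = launch_mass),
    class = "p2i_project_timeline"
  )
}

#' Expected cost of one phase of a project
#'
#' Expected candidates entering the phase times the phase cost estimate.
#' Non-applicable phases cost 0.
#'
#' @inheritParams project_timeline
#' @param phase Phase ordinal 0-3.
#' @return Expected cost in $M.
#' @export
expected_phase_cost <- function(prj, phase, ps,
                                estimate = c("point", "low", "high")) {
  estimate <- match.arg(estimate)
  cost_col <- switch(estimate, point = "cost_point",
                     low = "cost_low", high = "cost_high")
  rows <- .phases_of(ps, prj$archetype)
  if (phase < prj$entry_phase) return(0)
  mass <- prj$multiplicity * prj$capacity_factor *
    cumulative_pos(ps, prj$archetype, prj$entry_phase, phase - 1L)
  mass * rows[[cost_col]][rows$phase_ordinal == phase]
}

#' Attrition-adjusted expected R&D cost per launch
#'
#' For one candidate of an archetype entering at `entry_phase`, the
#' expected total development spend (each phase cost weighted by the
#' probability of reaching that phase) divided by the overall probability
#' of success from entry through phase 3. This is the model's headline
#' "cost per launch" figure.
#'
#' @param archetype Archetype id.
#' @param ps A `p2i_params` object.
#' @param entry_phase Phase ordinal; defaults to the archetype's default
#'   entry phase.
#' @param estimate `"point"` (default), `"low"`, or `"high"` cost column.
#' @return Expected cost per launch in $M.
#' @export
#' @examples
#' ps <- default_params()
#' expected_cost_per_launch("dx_assay", ps)  # 11.5
expected_cost_per_launch <- function(archetype, ps,
                                     entry_phase =
                                       entry_phase_default(ps, archetype),
                                     estimate = c("point", "low", "high")) {
  estimate <- match.arg(estimate)
  prj <- project(archetype, entry_year = 0, entry_phase = entry_phase,
                 ps = ps)
  total <- sum(vapply(entry_phase:3, function(k) {
    expected_phase_cost(prj, k, ps, estimate = estimate)
  }, numeric(1)))
  total / cumulative_pos(ps, archetype, entry_phase, 3L)
}

#' Aggregate a portfolio into a calendar-year timeline
#'
#' Sums the expected timelines of all projects into per-calendar-year
#' expected costs, phase occupancies (time-averaged expected active
#' candidates per phase), incremental expected launches (credited to the
#' year containing the launch instant), and cumulative expected launches.
#' The year range covers the parameter-set horizon extended to include all
#' project activity, so totals are conserved.
#'
#' @param portfolio Data frame of project rows ([project()] /
#'   [read_portfolio_csv()]); may be empty.
#' @param ps A `p2i_params` object.
#' @param estimate Cost column, as in [project_timeline()].
#' @return Object of class `p2i_timeline`: list with `years` (data frame:
#'   year, cost, launches, cumulative_launches), `occupancy` (data frame:
#'   year, one column per phase ordinal `phase0..phase3`), and
#'   `total_cost`, `total_launches` scalars.
#' @export
aggregate_portfolio <- function(portfolio, ps,
                                estimate = c("point", "low", "high")) {
  estimate <- match.arg(estimate)
  n <- if (is.null(portfolio)) 0L else nrow(portfolio)
  if (n > 150) {
    warning("portfolio has ", n, " rows; the model is intended for ",
            "portfolios of up to 150 projects")
  }
  tls <- if (n > 0) {
    lapply(seq_len(n), function(i) {
      project_timeline(portfolio[i, ], ps, estimate = estimate)
    })
  } else list()

  y0 <- ps$horizon_start
  y1 <- ps$horizon_end
  if (n > 0) {
    y0 <- min(y0, vapply(tls, function(t) min(t$yearly_cost$year),
                         numeric(1)))
    y1 <- max(y1, vapply(tls, function(t) max(t$yearly_cost$year),
                         numeric(1)),
              vapply(tls, function(t) t$launch_year, numeric(1)))
  }
  yrs <- seq(y0, y1)
  cost <- numeric(length(yrs))
  launches <- numeric(length(yrs))
  occ <- matrix(0, nrow = length(yrs), ncol = 4,
                dimnames = list(NULL, paste0("phase", 0:3)))
  for (t in tls) {
    idx <- match(t$yearly_cost$year, yrs)
    cost[idx] <- cost[idx] + t$yearly_cost$cost
    launches[yrs == t$launch_year] <-
      launches[yrs == t$launch_year] + t$launch_mass
    for (i in seq_len(nrow(t$phases))) {
      k <- t$phases$ordinal[i] + 1
      occ[, k] <- occ[, k] + t$phases$entry_mass[i] *
        .year_overlap(t$phases$start[i], t$phases$end[i], yrs)
    }
  }
  structure(
    list(years = data.frame(year = yrs, cost = cost, launches = launches,
                            cumulative_launches = cumsum(launches)),
         occupancy = data.frame(year = yrs, occ),
         total_cost = sum(cost),
         total_launches = sum(launches)),
    class = "p2i_timeline"
  )
}

#' @export
print.p2i_timeline <- function(x, ...) {
  cat("p2i portfolio timeline, ", min(x$years$year), "-",
      max(x$years$year), "\n", sep = "")
  cat("  total expected cost: $", round(x$total_cost, 2), "M\n", sep = "")
  cat("  total expected launches: ", signif(x$total_launches, 4),
      " (", round_launches(x$total_launches), " rounded)\n", sep = "")
  invisible(x)
}

#' Round expected launches for presentation
#'
#' Expected launches are floating-point numbers inside the model; an
#' actual launch is binary, so reports round to the nearest integer, halves
#' away from zero. Never used in computation.
#'
#' @param x Non-negative expected launch count(s).
#' @return Integer vector.
#' @export
#' @examples
#' round_launches(c(0.3112, 10.5, 3.49))  # 0 11 3
round_launches <- function(x) {
  if (any(x < 0)) stop("expected launches must be >= 0")
  as.integer(floor(x + 0.5))
}
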