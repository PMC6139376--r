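#' Named portfolio strategy templates
#'
#' Archetype-mix weights for the three financing focus strategies:
#' `quick_wins` emphasizes repurposed drugs and cheap diagnostics (short,
#' high-PoS paths), `innovation` emphasizes novel vaccines, NCEs,
#' biologics, and platform diagnostics, and `mixed` is an equal blend of
#' the two. The strategies are named after portfolio emphases discussed in
#' the field; the specific weights are illustrative defaults and can be
#' overridden with any explicit mix.
#'
#' @return Named list of named numeric weight vectors, each summing to 1.
#' @export
strategy_templates <- function() {
  quick <- c(repurposed_simple = 0.7, repurposed_complex = 0.2,
             dx_assay = 0.1)
  innov <- c(vaccine_complex = 0.2, nce_innovative = 0.3,
             nce_complex = 0.2, biologic_complex = 0.2,
             dx_platform = 0.1)
  ids <- union(names(quick), names(innov))
  mixed <- stats::setNames(numeric(length(ids)), ids)
  mixed[names(quick)] <- mixed[names(quick)] + quick / 2
  mixed[names(innov)] <- mixed[names(innov)] + innov / 2
  list(quick_wins = quick, innovation = innov, mixed = mixed)
}

#' Build a funding scenario configuration
#'
#' @param name Scenario label.
#' @param annual_fund_size Annual disbursement capacity, $M/year (> 0).
#' @param strategy Either the name of a template in
#'   [strategy_templates()] or an explicit named weight vector summing
#'   to 1.
#' @param operational If `FALSE`, the fund supports only coordination or
#'   prioritization of R&D and funds no development projects.
#' @param horizon_start,horizon_end Calendar-year horizon; defaults taken
#'   from the parameter set at run time when `NULL`.
#' @return List of class `p2i_scenario`.
#' @export
scenario_config <- function(name, annual_fund_size, strategy = "mixed",
                            operational = TRUE,
                            horizon_start = NULL, horizon_end = NULL) {
  if (annual_fund_size <= 0) stop("annual_fund_size must be > 0")
  if (is.character(strategy)) {
    if (!strategy %in% names(strategy_templates())) {
      stop("unknown strategy template: ", strategy)
    }
  } else {
    if (is.null(names(strategy)) || abs(sum(strategy) - 1) > 1e-9) {
      stop("explicit strategy mix must be a named vector summing to 1")
    }
  }
  structure(
    list(name = name, annual_fund_size = annual_fund_size,
         strategy = strategy, operational = operational,
         horizon_start = horizon_start, horizon_end = horizon_end),
    class = "p2i_scenario"
  )
}

#' The seven built-in funding scenarios
#'
#' Fund sizes 1, 5, 15, 50, 100, 300, and 500 $M/year: up-to-$1M passive
#' coordination and up-to-$5M prioritization funds (non-operational — they
#' fund no development projects), then operational funds from a small $15M
#' fund through a PDP-sized $50M fund, a medium $100M fund, a large $300M
#' fund, and a global $500M fund.
#'
#' @param strategy Strategy applied to the operational scenarios
#'   (template name or explicit mix), default `"mixed"`.
#' @return List of 7 `p2i_scenario` objects.
#' @export
#' @examples
#' builtin_scenarios()[[4]]$annual_fund_size  # 50
builtin_scenarios <- function(strategy = "mixed") {
  sizes <- c(1, 5, 15, 50, 100, 300, 500)
  names <- c("passive coordination of R&D",
             "prioritization of R&D",
             "small fund",
             "PDP-sized fund",
             "medium sized fund",
             "large fund",
             "global fund")
  lapply(1:7, function(i) {
    scenario_config(
      name = sprintf("scenario %d: %s (US$ %gm/yr)", i, names[i], sizes[i]),
      annual_fund_size = sizes[i],
      strategy = strategy,
      operational = i >= 3)
  })
}

# Steady-state annual cost of 1 entrant/yr for each archetype in a mix.
.mix_unit_cost <- function(mix, ps) {
  sum(vapply(names(mix), function(a) {
    mix[[a]] * steady_state(stats::setNames(1, a), ps)$annual_cost
  }, numeric(1)))
}

.resolve_mix <- function(strategy) {
  if (is.character(strategy)) strategy_templates()[[strategy]] else strategy
}

#' Fit a scenario's portfolio to its budget
#'
#' Scales the strategy template's per-archetype annual entrants by the
#' largest factor such that the steady-state annual cost does not exceed
#' the annual fund size (cost is linear in entrants, so the factor is
#' simply fund size divided by the mix's unit steady-state cost). Returns
#' the resulting entry schedule: the fitted entrants for every archetype
#' in the mix, every year of the horizon, entering at each archetype's
#' default phase.
#'
#' @param cfg A `p2i_scenario` from [scenario_config()].
#' @param ps A `p2i_params` object.
#' @return Entry schedule data frame (`archetype`, `entry_phase`,
#'   `entry_year`, `entrants`) suitable for [plan_prospective()], plus an
#'   attribute `entrants_per_year` (named vector).
#' @export
fit_portfolio_to_budget <- function(cfg, ps) {
  if (!cfg$operational) {
    stop("scenario '", cfg$name, "' is non-operational: it funds ",
         "coordination, not development projects")
  }
  mix <- .resolve_mix(cfg$strategy)
  unit <- .mix_unit_cost(mix, ps)
  scale <- cfg$annual_fund_size / unit
  rates <- mix * scale
  y0 <- if (is.null(cfg$horizon_start)) ps$horizon_start else
    cfg$horizon_start
  y1 <- if (is.null(cfg$horizon_end)) ps$horizon_end else cfg$horizon_end
  sched <- expand.grid(archetype = names(rates), entry_year = y0:y1,
                       stringsAsFactors = FALSE)
  sched$entry_phase <- vapply(sched$archetype, function(a) {
    entry_phase_default(ps, a)
  }, integer(1))
  sched$entrants <- rates[sched$archetype]
  sched <- sched[sched$entrants > 0,
                 c("archetype", "entry_phase", "entry_year", "entrants")]
  rownames(sched) <- NULL
  attr(sched, "entrants_per_year") <- rates
  sched
}

#' Run a funding scenario end to end
#'
#' Fits the scenario's strategy mix to its annual fund size, runs the
#' prospective plan over the horizon, and assembles a report: new projects
#' initiated per year, steady-state portfolio size, the annual budget
#' trace, expected launches per year and cumulative at horizon end
#' (floating point and rounded for presentation), and a per-archetype
#' launch breakdown. Non-operational scenarios report zero projects and a
#' budget equal to the coordination fund size.
#'
#' @param cfg A `p2i_scenario`.
#' @param ps A `p2i_params` object.
#' @return List of class `p2i_scenario_report`.
#' @export
#' @examples
#' ps <- default_params()
#' run_scenario(builtin_scenarios()[[4]], ps)
run_scenario <- function(cfg, ps) {
  y0 <- if (is.null(cfg$horizon_start)) ps$horizon_start else
    cfg$horizon_start
  y1 <- if (is.null(cfg$horizon_end)) ps$horizon_end else cfg$horizon_end
  if (!cfg$operational) {
    return(structure(
      list(config = cfg, operational = FALSE,
           entrants_per_year = numeric(0),
           new_projects_per_year = 0,
           steady_state = list(total_active = 0, annual_cost = 0),
           budget = data.frame(year = y0:y1,
                               cost = rep(cfg$annual_fund_size,
                                          y1 - y0 + 1)),
           launches = data.frame(year = y0:y1,
                                 launches = 0,
                                 cumulative_launches = 0),
           cumulative_launches = 0,
           cumulative_launches_rounded = 0L,
           by_archetype = data.frame(archetype = character(0),
                                     launches = numeric(0))),
      class = "p2i_scenario_report"))
  }
  sched <- fit_portfolio_to_budget(cfg, ps)
  rates <- attr(sched, "entrants_per_year")
  ss <- steady_state(rates, ps)
  tl <- plan_prospective(sched, ps)
  in_h <- tl$years$year >= y0 & tl$years$year <= y1
  launches <- tl$years[in_h, c("year", "launches")]
  launches$cumulative_launches <- cumsum(launches$launches)
  cum <- sum(launches$launches)
  by_arch <- do.call(rbind, lapply(names(rates)[rates > 0], function(a) {
    s <- sched[sched$archetype == a, ]
    tla <- plan_prospective(s, ps)
    ok <- tla$years$year >= y0 & tla$years$year <= y1
    data.frame(archetype = a,
               entrants_per_year = rates[[a]],
               launches = sum(tla$years$launches[ok]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_arch) <- NULL
  structure(
    list(config = cfg, operational = TRUE,
         entrants_per_year = rates,
         new_projects_per_year = sum(rates),
         steady_state = ss,
         budget = data.frame(year = tl$years$year[in_h],
                             cost = tl$years$cost[in_h]),
         launches = launches,
         cumulative_launches = cum,
         cumulative_launches_rounded = round_launches(cum),
         by_archetype = by_arch,
         timeline = tl),
    class = "p2i_scenario_report")
}

#' @export
print.p2i_scenario_report <- function(x, ...) {
  cat(x$config$name, "\n")
  if (!x$operational) {
    cat("  non-operational: coordination/prioritization only, no ",
        "development projects funded\n", sep = "")
    return(invisible(x))
  }
  cat("  new projects initiated per year: ",
      signif(x$new_projects_per_year, 4), "\n", sep = "")
  cat("  steady-state active projects: ",
      signif(x$steady_state$total_active, 4),
      " (annual cost $", round(x$steady_state$annual_cost, 1),
      "M)\n", sep = "")
  cat("  expected launches by ", max(x$launches$year), ": ",
      signif(x$cumulative_launches, 4), " (", x$cumulative_launches_rounded,
      " rounded)\n", sep = "")
  invisible(x)
}
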