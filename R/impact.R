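#' Health-impact inputs for one target disease
#'
#' The model does not bundle disease burden data: users supply the annual
#' burden (DALYs and deaths, e.g. 2012 LMIC estimates from WHO Global
#' Health Estimates) and their own informed estimate of the fractional
#' reduction a launched product would achieve.
#'
#' @param disease Disease label (joins impact inputs to portfolio rows).
#' @param burden_dalys Baseline disease burden, DALYs/year (>= 0).
#' @param burden_deaths Baseline mortality, deaths/year (>= 0).
#' @param reduction_dalys Expected fractional reduction in DALY burden
#'   attributable to the launched product, in \[0, 1\].
#' @param reduction_deaths Expected fractional reduction in deaths,
#'   in \[0, 1\].
#' @return One-row data frame of validated impact inputs.
#' @export
impact_input <- function(disease, burden_dalys, burden_deaths = 0,
                         reduction_dalys = 0, reduction_deaths = 0) {
  if (burden_dalys < 0 || burden_deaths < 0) {
    stop("disease burdens must be >= 0")
  }
  if (reduction_dalys < 0 || reduction_dalys > 1 ||
      reduction_deaths < 0 || reduction_deaths > 1) {
    stop("expected reductions must be fractions in [0, 1]")
  }
  data.frame(disease = disease,
             burden_dalys = burden_dalys,
             burden_deaths = burden_deaths,
             reduction_dalys = reduction_dalys,
             reduction_deaths = reduction_deaths,
             stringsAsFactors = FALSE)
}

#' Health impact of a single launched intervention
#'
#' DALYs averted = burden x expected fractional reduction; the same for
#' deaths averted; economic value = DALYs averted x the value of a DALY
#' (default $500, a deliberately conservative valuation). The calculation
#' is identical for every product archetype.
#'
#' @param inp One-row data frame from [impact_input()].
#' @param ps A `p2i_params` object (supplies `daly_value`).
#' @return List with `dalys_averted` (DALYs/year), `deaths_averted`
#'   (deaths/year), and `economic_value` (USD/year).
#' @export
#' @examples
#' ps <- default_params()
#' estimate_impact(impact_input("x", 5e6, reduction_dalys = 0.1), ps)
estimate_impact <- function(inp, ps) {
  dalys <- inp$burden_dalys * inp$reduction_dalys
  deaths <- inp$burden_deaths * inp$reduction_deaths
  list(dalys_averted = dalys,
       deaths_averted = deaths,
       economic_value = dalys * ps$daly_value)
}

#' Expected health impact of a portfolio's launches, by calendar year
#'
#' Joins per-disease impact inputs to portfolio rows by disease label and
#' credits each project's per-launch impact to its launch year. Two views
#' are returned: the expectation-weighted view multiplies each per-launch
#' impact by the project's expected (fractional) launch mass; the
#' per-whole-launch view reports the impact of one whole launched
#' intervention per project, which is how the impact of "a single launched
#' intervention" is usually quoted.
#'
#' @param portfolio Portfolio data frame with a `disease` column.
#' @param impacts Data frame of impact inputs (rows as from
#'   [impact_input()]).
#' @param ps A `p2i_params` object.
#' @return List with `by_year` (data frame: year, launch_mass,
#'   dalys_averted, deaths_averted, economic_value — expectation-weighted)
#'   and `per_launch` (data frame: one row per matched project with its
#'   launch year and whole-launch impact).
#' @export
portfolio_impact <- function(portfolio, impacts, ps) {
  n <- if (is.null(portfolio)) 0L else nrow(portfolio)
  rows <- list()
  for (i in seq_len(n)) {
    prj <- portfolio[i, ]
    if (is.na(prj$disease)) next
    m <- impacts[impacts$disease == prj$disease, , drop = FALSE]
    if (nrow(m) == 0) next
    est <- estimate_impact(m[1, ], ps)
    tl <- project_timeline(prj, ps)
    rows[[length(rows) + 1]] <- data.frame(
      archetype = prj$archetype, disease = prj$disease,
      launch_year = tl$launch_year, launch_mass = tl$launch_mass,
      dalys_averted = est$dalys_averted,
      deaths_averted = est$deaths_averted,
      economic_value = est$economic_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    empty <- data.frame(year = integer(0), launch_mass = numeric(0),
                        dalys_averted = numeric(0),
                        deaths_averted = numeric(0),
                        economic_value = numeric(0))
    return(list(by_year = empty,
                per_launch = data.frame()))
  }
  per <- do.call(rbind, rows)
  yrs <- sort(unique(per$launch_year))
  by_year <- do.call(rbind, lapply(yrs, function(y) {
    m <- per[per$launch_year == y, ]
    data.frame(year = y,
               launch_mass = sum(m$launch_mass),
               dalys_averted = sum(m$launch_mass * m$dalys_averted),
               deaths_averted = sum(m$launch_mass * m$deaths_averted),
               economic_value = sum(m$launch_mass * m$economic_value))
  }))
  list(by_year = by_year, per_launch = per)
}
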