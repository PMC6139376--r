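#' Write a portfolio to CSV
#'
#' Columns: `archetype, entry_phase, entry_year, multiplicity,
#' capacity_factor, funded_phases` (semicolon-separated ordinals) and
#' optionally `disease`.
#'
#' @param portfolio Portfolio data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_portfolio_csv <- function(portfolio, path) {
  utils::write.csv(portfolio, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a portfolio from CSV
#'
#' Accepts the schema written by [write_portfolio_csv()]; missing optional
#' columns get defaults (multiplicity 1, capacity 1, all phases funded,
#' archetype-default entry phase). Every row is validated against the
#' registry.
#'
#' @param path CSV file path.
#' @param ps A `p2i_params` object used for validation.
#' @return Portfolio data frame.
#' @export
read_portfolio_csv <- function(path, ps = default_params()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("funded_phases" %in% names(raw)) {
    raw$funded_phases <- as.character(raw$funded_phases)
  }
  if ("disease" %in% names(raw)) raw$disease <- as.character(raw$disease)
  portfolio_from_list(split(raw, seq_len(nrow(raw))), ps)
}

#' Read a portfolio from a JSON config
#'
#' The JSON document is an array of project objects with fields
#' `archetype`, `entry_year`, and optionally `entry_phase`,
#' `multiplicity`, `capacity_factor`, `funded_phases` (array of
#' ordinals), `disease`.
#'
#' @param path JSON file path.
#' @param ps A `p2i_params` object used for validation.
#' @return Portfolio data frame.
#' @export
read_portfolio_json <- function(path, ps = default_params()) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  portfolio_from_list(raw, ps)
}

#' Build a validated portfolio from a list of project records
#'
#' @param records List of lists/one-row data frames with project fields.
#' @param ps A `p2i_params` object.
#' @return Portfolio data frame.
#' @export
portfolio_from_list <- function(records, ps = default_params()) {
  rows <- lapply(records, function(r) {
    fp <- r$funded_phases
    fp <- if (is.null(fp) || (length(fp) == 1 && is.na(fp))) {
      0:3
    } else if (is.character(fp)) {
      .parse_funded(fp)
    } else as.integer(fp)
    ep <- r$entry_phase
    if (!is.null(ep) && length(ep) == 1 && is.na(ep)) ep <- NULL
    project(r$archetype,
            entry_year = r$entry_year,
            entry_phase = ep,
            multiplicity = if (is.null(r$multiplicity)) 1 else
              r$multiplicity,
            capacity_factor = if (is.null(r$capacity_factor)) 1 else
              r$capacity_factor,
            funded_phases = fp,
            disease = if (is.null(r$disease) || is.na(r$disease) ||
                          !nzchar(r$disease))
              NA_character_ else r$disease,
            ps = ps)
  })
  do.call(rbind, rows)
}

#' Write a portfolio timeline as tidy CSV
#'
#' Long format: one row per (year, metric, phase, value), with
#' metrics `cost` ($M), `occupancy` (expected active candidates, per
#' phase), `launches`, and `cumulative_launches`.
#'
#' @param timeline A `p2i_timeline`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  yr <- timeline$years
  long <- rbind(
    data.frame(year = yr$year, metric = "cost", phase = NA_integer_,
               value = yr$cost),
    do.call(rbind, lapply(0:3, function(k) {
      data.frame(year = timeline$occupancy$year, metric = "occupancy",
                 phase = k,
                 value = timeline$occupancy[[paste0("phase", k)]])
    })),
    data.frame(year = yr$year, metric = "launches", phase = NA_integer_,
               value = yr$launches),
    data.frame(year = yr$year, metric = "cumulative_launches",
               phase = NA_integer_, value = yr$cumulative_launches)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read health-impact inputs from CSV
#'
#' Columns: `disease, burden_dalys, burden_deaths, reduction_dalys,
#' reduction_deaths`. Each row is validated through [impact_input()].
#'
#' @param path CSV file path.
#' @return Data frame of impact inputs.
#' @export
read_impacts_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    impact_input(r$disease, r$burden_dalys,
                 if (is.null(r$burden_deaths)) 0 else r$burden_deaths,
                 if (is.null(r$reduction_dalys)) 0 else r$reduction_dalys,
                 if (is.null(r$reduction_deaths)) 0 else r$reduction_deaths)
  }))
}

#' Read a scenario configuration from JSON or YAML
#'
#' Fields as in [scenario_config()]; `strategy` may be a template name or
#' an object of archetype weights. YAML is read when the file extension is
#' `.yml`/`.yaml` (requires the yaml package).
#'
#' @param path Config file path.
#' @return A `p2i_scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  strategy <- cfg$strategy
  if (is.list(strategy)) strategy <- unlist(strategy)
  scenario_config(
    name = cfg$name,
    annual_fund_size = cfg$annual_fund_size,
    strategy = if (is.null(strategy)) "mixed" else strategy,
    operational = if (is.null(cfg$operational)) TRUE else cfg$operational,
    horizon_start = cfg$horizon_start,
    horizon_end = cfg$horizon_end)
}
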