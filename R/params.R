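#' Development phase ordinals and labels
#'
#' Every archetype moves through the same four-slot phase structure:
#' ordinal 0 = preclinical, 1 = phase 1, 2 = phase 2, 3 = phase 3.
#' Diagnostics map their three named stages ("selection and validation of
#' markers", "development", "regulated trials beyond EUO/CE") onto ordinals
#' 0-2, with ordinal 3 a pass-through slot, so one uniform engine serves
#' all archetypes.
#'
#' @return Named integer vector mapping phase labels to ordinals 0-3.
#' @export
#' @examples
#' phase_ordinals()
phase_ordinals <- function() {
  c(preclinical = 0L, phase1 = 1L, phase2 = 2L, phase3 = 3L)
}

#' The eleven product archetype identifiers
#'
#' @return Character vector of archetype ids in registry order.
#' @export
archetype_ids <- function() {
  c("vaccine_simple", "vaccine_complex",
    "nce_simple", "nce_innovative", "nce_complex",
    "repurposed_simple", "repurposed_complex",
    "biologic_simple", "biologic_complex",
    "dx_assay", "dx_platform")
}

# Archetype metadata: broad category, subtype, and the earliest phase at
# which development of that archetype can start (simple repurposed drugs
# carry enough safety data to enter directly at phase 2; the diagnostic
# platform archetype has no marker-selection stage and enters at slot 1).
.archetype_meta <- function() {
  data.frame(
    archetype_id = archetype_ids(),
    category = c("vaccine", "vaccine", "NCE", "NCE", "NCE",
                 "repurposed drug", "repurposed drug",
                 "biologic", "biologic", "diagnostic", "diagnostic"),
    subtype = c("simple", "complex", "simple", "innovative", "complex",
                "simple", "complex", "simple", "complex",
                "assay development", "simple technical platform development"),
    entry_default = c(0L, 0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# Per-archetype, per-phase parameter table: development cost in $M
# (lower bound, upper bound, point estimate), probability of success as a
# fraction, and cycle time in years. Phases a given archetype never
# traverses (e.g. preclinical for a simple repurposed drug) are marked
# non-applicable and modelled as pass-through: cost 0, duration 0, PoS 1.
.phase_table <- function() {
  # columns: cost_low, cost_high, cost_point, pos, duration, applicable
  row <- function(id, k, cl, ch, cp, pos, dur, app = TRUE) {
    data.frame(archetype_id = id, phase_ordinal = k,
               cost_low = cl, cost_high = ch, cost_point = cp,
               pos = pos, duration = dur, applicable = app,
               stringsAsFactors = FALSE)
  }
  na_row <- function(id, k) row(id, k, 0, 0, 0, 1, 0, FALSE)
  rbind(
    row("vaccine_simple", 0L, 3.3, 10.0, 6.7, 0.410, 3.36),
    row("vaccine_simple", 1L, 1.8, 2.7, 2.2, 0.684, 1.57),
    row("vaccine_simple", 2L, 7.4, 19.0, 13.2, 0.459, 2.23),
    row("vaccine_simple", 3L, 56.6, 165.6, 111.1, 0.708, 2.33),

    row("vaccine_complex", 0L, 8.3, 24.9, 16.6, 0.410, 3.33),
    row("vaccine_complex", 1L, 1.9, 3.0, 2.5, 0.500, 1.97),
    row("vaccine_complex", 2L, 7.8, 20.0, 13.9, 0.216, 3.71),
    row("vaccine_complex", 3L, 67.9, 198.7, 133.3, 0.636, 3.50),

    row("nce_simple", 0L, 2.5, 7.5, 5.0, 0.650, 2.49),
    row("nce_simple", 1L, 1.8, 2.7, 2.2, 0.597, 1.80),
    row("nce_simple", 2L, 3.7, 7.9, 5.8, 0.388, 3.38),
    row("nce_simple", 3L, 11.5, 54.1, 32.8, 0.691, 3.18),

    row("nce_innovative", 0L, 5.0, 10.0, 7.5, 0.600, 2.70),
    row("nce_innovative", 1L, 4.4, 5.3, 4.8, 0.519, 1.81),
    row("nce_innovative", 2L, 3.9, 8.3, 6.1, 0.284, 3.35),
    row("nce_innovative", 3L, 12.1, 55.4, 34.5, 0.578, 3.10),

    row("nce_complex", 0L, 7.5, 12.5, 10.0, 0.550, 2.87),
    row("nce_complex", 1L, 6.9, 7.9, 7.4, 0.572, 1.93),
    row("nce_complex", 2L, 4.1, 8.7, 6.4, 0.197, 3.51),
    row("nce_complex", 3L, 12.6, 59.6, 36.1, 0.403, 2.80),

    na_row("repurposed_simple", 0L),
    na_row("repurposed_simple", 1L),
    row("repurposed_simple", 2L, 3.7, 7.9, 5.8, 0.457, 2.14),
    row("repurposed_simple", 3L, 10.0, 25.2, 17.6, 0.681, 2.14),

    row("repurposed_complex", 0L, 2.5, 7.5, 5.0, 0.750, 2.33),
    row("repurposed_complex", 1L, 1.7, 2.7, 2.2, 0.585, 1.63),
    row("repurposed_complex", 2L, 3.7, 7.9, 5.8, 0.457, 2.14),
    row("repurposed_complex", 3L, 10.0, 25.2, 17.6, 0.681, 2.14),

    row("biologic_simple", 0L, 5.4, 16.2, 10.8, 0.750, 3.29),
    row("biologic_simple", 1L, 1.9, 3.0, 2.4, 0.662, 1.62),
    row("biologic_simple", 2L, 4.5, 10.5, 7.5, 0.443, 2.47),
    row("biologic_simple", 3L, 27.7, 80.5, 54.1, 0.709, 2.10),

    row("biologic_complex", 0L, 16.2, 27.0, 21.6, 0.770, 3.24),
    row("biologic_complex", 1L, 7.0, 8.3, 7.6, 0.696, 1.49),
    row("biologic_complex", 2L, 5.0, 11.6, 8.3, 0.322, 4.16),
    row("biologic_complex", 3L, 30.5, 88.5, 59.5, 0.625, 3.38),

    row("dx_assay", 0L, 1.0, 5.0, 3.0, 0.500, 1.00),
    row("dx_assay", 1L, 1.0, 3.0, 2.0, 1.000, 1.25),
    row("dx_assay", 2L, 1.0, 6.0, 3.5, 1.000, 1.33),
    na_row("dx_assay", 3L),

    na_row("dx_platform", 0L),
    row("dx_platform", 1L, 50.0, 150.0, 100.0, 0.750, 2.50),
    row("dx_platform", 2L, 1.0, 6.0, 3.5, 1.000, 2.00),
    na_row("dx_platform", 3L)
  )
}

#' Default model parameter set
#'
#' Builds the registry of per-phase development costs ($M; lower bound,
#' upper bound, point estimate), probabilities of success (fractions), and
#' cycle times (years) for the eleven product archetypes, together with the
#' model-level constants: the economic value of a DALY averted (default
#' 500 USD) and the modelling horizon (default calendar years 2017-2030,
#' extensible to 2040).
#'
#' @param daly_value Economic value of one DALY averted, USD. Default 500.
#' @param horizon_start First calendar year of the modelling horizon.
#' @param horizon_end Last calendar year of the modelling horizon.
#' @return Object of class `p2i_params`: a list with elements `archetypes`
#'   (metadata data frame), `phases` (44-row parameter data frame),
#'   `daly_value`, `horizon_start`, `horizon_end`.
#' @export
#' @examples
#' ps <- default_params()
#' subset(ps$phases, archetype_id == "vaccine_simple")
default_params <- function(daly_value = 500,
                           horizon_start = 2017,
                           horizon_end = 2030) {
  ps <- structure(
    list(archetypes = .archetype_meta(),
         phases = .phase_table(),
         daly_value = daly_value,
         horizon_start = horizon_start,
         horizon_end = horizon_end),
    class = "p2i_params"
  )
  bad <- validate_params(ps)
  if (length(bad) > 0) {
    stop("parameter registry failed integrity checks:\n  ",
         paste(bad, collapse = "\n  "))
  }
  ps
}

#' @export
print.p2i_params <- function(x, ...) {
  cat("p2i parameter set:", nrow(x$archetypes), "archetypes,",
      nrow(x$phases), "phase entries\n")
  cat("  DALY value: $", x$daly_value, "; horizon ",
      x$horizon_start, "-", x$horizon_end, "\n", sep = "")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every structural and range invariant of a `p2i_params` object:
#' probabilities of success in (0, 1], cost bounds ordered
#' (low <= point <= high), non-negative durations, pass-through convention
#' for non-applicable phases (cost 0, duration 0, PoS 1), positive DALY
#' value, and a well-ordered horizon.
#'
#' @param ps A `p2i_params` object.
#' @return Character vector of violation descriptions; `character(0)` if
#'   the set is valid. Each violation names the archetype, phase, and field.
#' @export
#' @examples
#' validate_params(default_params())  # character(0)
validate_params <- function(ps) {
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))
  if (!is.list(ps) || is.null(ps$phases) || is.null(ps$archetypes)) {
    return("not a p2i_params object (missing archetypes/phases)")
  }
  if (!isTRUE(ps$daly_value > 0)) say("daly_value must be > 0")
  if (!isTRUE(ps$horizon_end > ps$horizon_start)) {
    say("horizon_end must exceed horizon_start")
  }
  ph <- ps$phases
  need <- c("archetype_id", "phase_ordinal", "cost_low", "cost_high",
            "cost_point", "pos", "duration", "applicable")
  if (!all(need %in% names(ph))) {
    return(paste("phase table missing columns:",
                 paste(setdiff(need, names(ph)), collapse = ", ")))
  }
  for (a in unique(ph$archetype_id)) {
    rows <- ph[ph$archetype_id == a, ]
    if (!identical(sort(rows$phase_ordinal), 0:3)) {
      say(a, ": phase ordinals must be exactly 0,1,2,3")
      next
    }
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      at <- paste0(a, " phase ", r$phase_ordinal, ": ")
      if (!(r$pos > 0 && r$pos <= 1)) say(at, "pos must be in (0,1]")
      if (r$cost_low < 0) say(at, "cost_low must be >= 0")
      if (r$cost_high < r$cost_low) say(at, "cost_high must be >= cost_low")
      if (r$cost_point < r$cost_low || r$cost_point > r$cost_high) {
        say(at, "cost_point must lie in [cost_low, cost_high]")
      }
      if (r$duration < 0) say(at, "duration must be >= 0")
      if (!r$applicable &&
          !(r$cost_point == 0 && r$cost_low == 0 && r$cost_high == 0 &&
            r$duration == 0 && r$pos == 1)) {
        say(at, "non-applicable phase must be pass-through ",
            "(cost 0, duration 0, pos 1)")
      }
    }
  }
  am <- ps$archetypes
  for (i in seq_len(nrow(am))) {
    a <- am$archetype_id[i]
    rows <- ph[ph$archetype_id == a, ]
    if (nrow(rows) == 0) {
      say(a, ": no phase rows")
      next
    }
    e <- am$entry_default[i]
    r <- rows[rows$phase_ordinal == e, ]
    if (nrow(r) == 1 && !r$applicable) {
      say(a, ": entry_default phase ", e, " is not applicable")
    }
  }
  v
}

.check_archetype <- function(ps, archetype) {
  if (!archetype %in% ps$archetypes$archetype_id) {
    stop("unknown archetype id: ", archetype)
  }
  invisible(archetype)
}

# Phase parameter rows for one archetype, ordered by ordinal.
.phases_of <- function(ps, archetype) {
  .check_archetype(ps, archetype)
  rows <- ps$phases[ps$phases$archetype_id == archetype, ]
  rows[order(rows$phase_ordinal), ]
}

#' Default entry phase for an archetype
#'
#' @param ps A `p2i_params` object.
#' @param archetype Archetype id.
#' @return Integer phase ordinal (0-3) at which development of this
#'   archetype starts by default (its earliest applicable phase; phase 2
#'   for simple repurposed drugs).
#' @export
entry_phase_default <- function(ps, archetype) {
  .check_archetype(ps, archetype)
  ps$archetypes$entry_default[ps$archetypes$archetype_id == archetype]
}

#' Cumulative probability of success across a phase range
#'
#' Product of the per-phase probabilities of success from `from_phase`
#' through `through_phase` inclusive. The empty range
#' (`through_phase == from_phase - 1`) returns 1 (empty product), which is
#' the probability of "reaching" the entry phase itself.
#'
#' @param ps A `p2i_params` object.
#' @param archetype Archetype id.
#' @param from_phase First phase ordinal in the chain (0-3).
#' @param through_phase Last phase ordinal, inclusive. May be
#'   `from_phase - 1` for the empty product.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' ps <- default_params()
#' cumulative_pos(ps, "vaccine_simple", 0, 3)  # ~0.0911
cumulative_pos <- function(ps, archetype, from_phase = 0L,
                           through_phase = 3L) {
  rows <- .phases_of(ps, archetype)
  if (through_phase == from_phase - 1) return(1.0)
  if (through_phase < from_phase) {
    stop("inverted phase range: from ", from_phase,
         " through ", through_phase)
  }
  if (from_phase < 0 || through_phase > 3) stop("phase ordinal out of 0..3")
  prod(rows$pos[rows$phase_ordinal >= from_phase &
                  rows$phase_ordinal <= through_phase])
}

#' Total cycle time across a phase range
#'
#' @param ps A `p2i_params` object.
#' @param archetype Archetype id.
#' @param from_phase First phase ordinal (default: archetype's entry phase).
#' @param through_phase Last phase ordinal, inclusive.
#' @return Years, the sum of the phase durations in the range
#'   (pass-through phases contribute 0).
#' @export
total_cycle_time <- function(ps, archetype,
                             from_phase = entry_phase_default(ps, archetype),
                             through_phase = 3L) {
  rows <- .phases_of(ps, archetype)
  if (through_phase < from_phase) return(0)
  sum(rows$duration[rows$phase_ordinal >= from_phase &
                      rows$phase_ordinal <= through_phase])
}

#' Export the phase parameter table to CSV
#'
#' Writes the per-archetype, per-phase parameters in a flat CSV with
#' columns `archetype_id, phase_ordinal, cost_low, cost_high, cost_point,
#' pos, duration, applicable`. The default registry round-trips through
#' [read_params_csv()] bit-exactly, so users can export, edit any
#' assumption, and re-import.
#'
#' @param ps A `p2i_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params_csv <- function(ps, path) {
  ph <- ps$phases
  # format() at 17 significant digits preserves doubles exactly on re-read
  out <- data.frame(
    archetype_id = ph$archetype_id,
    phase_ordinal = ph$phase_ordinal,
    cost_low = format(ph$cost_low, digits = 17, trim = TRUE,
                      scientific = FALSE),
    cost_high = format(ph$cost_high, digits = 17, trim = TRUE,
                       scientific = FALSE),
    cost_point = format(ph$cost_point, digits = 17, trim = TRUE,
                        scientific = FALSE),
    pos = format(ph$pos, digits = 17, trim = TRUE, scientific = FALSE),
    duration = format(ph$duration, digits = 17, trim = TRUE,
                      scientific = FALSE),
    applicable = ph$applicable,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a phase parameter table from CSV
#'
#' Reads a CSV written by [write_params_csv()] (or hand-edited in that
#' schema) and rebuilds a full parameter set. Archetype metadata (category,
#' subtype, default entry phase) is taken from the default registry for
#' known archetype ids; unknown ids get category "custom" and entry at
#' their earliest applicable phase. The resulting set is validated.
#'
#' @param path CSV file path.
#' @param daly_value,horizon_start,horizon_end Model-level constants, as in
#'   [default_params()].
#' @return A `p2i_params` object.
#' @export
read_params_csv <- function(path, daly_value = 500,
                            horizon_start = 2017, horizon_end = 2030) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  ph$phase_ordinal <- as.integer(ph$phase_ordinal)
  ph$applicable <- as.logical(ph$applicable)
  meta <- .archetype_meta()
  ids <- unique(ph$archetype_id)
  known <- meta[meta$archetype_id %in% ids, ]
  unknown <- setdiff(ids, meta$archetype_id)
  if (length(unknown) > 0) {
    entry <- vapply(unknown, function(a) {
      rows <- ph[ph$archetype_id == a, ]
      rows <- rows[order(rows$phase_ordinal), ]
      min(rows$phase_ordinal[rows$applicable])
    }, integer(1))
    known <- rbind(known, data.frame(
      archetype_id = unknown, category = "custom", subtype = "custom",
      entry_default = entry, stringsAsFactors = FALSE))
  }
  ps <- structure(
    list(archetypes = known[order(match(known$archetype_id, ids)), ],
         phases = ph,
         daly_value = daly_value,
         horizon_start = horizon_start,
         horizon_end = horizon_end),
    class = "p2i_params"
  )
  bad <- validate_params(ps)
  if (length(bad) > 0) {
    stop("imported parameters failed validation:\n  ",
         paste(bad, collapse = "\n  "))
  }
  ps
}
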