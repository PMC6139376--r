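#' Generate a random but valid synthetic portfolio
#'
#' Deterministic (seeded) generator of portfolios for tests and examples.
#' Entry phases are drawn only from phases applicable to the sampled
#' archetype at or after its default entry phase, so every generated
#' project passes the engine's preconditions.
#'
#' @param n_projects Number of project rows (>= 0).
#' @param seed Integer seed.
#' @param pool Archetype ids to sample from (default: all 11).
#' @param years Integer vector of candidate entry years.
#' @param max_multiplicity Multiplicities are sampled uniformly from
#'   `1:max_multiplicity` (integral, so the portfolio is also valid for
#'   the Monte Carlo simulator).
#' @param ps A `p2i_params` object.
#' @return Portfolio data frame with `n_projects` rows.
#' @export
#' @examples
#' random_portfolio(3, seed = 42)
random_portfolio <- function(n_projects, seed, pool = archetype_ids(),
                             years = 2017:2025, max_multiplicity = 5,
                             ps = default_params()) {
  if (n_projects < 0) stop("n_projects must be >= 0")
  if (n_projects > 0 && length(pool) == 0) {
    stop("archetype pool is empty")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(seq_len(n_projects), function(i) {
    a <- sample(pool, 1)
    phs <- .phases_of(ps, a)
    ok <- phs$phase_ordinal[phs$applicable &
                              phs$phase_ordinal >= entry_phase_default(ps, a)]
    project(a,
            entry_year = sample(years, 1),
            entry_phase = if (length(ok) == 1) ok else sample(ok, 1),
            multiplicity = sample.int(max_multiplicity, 1),
            ps = ps)
  })
  if (n_projects == 0) {
    return(project("vaccine_simple", 2017, ps = ps)[0, ])
  }
  do.call(rbind, rows)
}

#' Randomly perturb a parameter set
#'
#' Applies seeded multiplicative jitter to the costs and durations of
#' every applicable phase (the three cost columns of a phase share one
#' factor, so the low <= point <= high ordering is preserved) and to the
#' probabilities of success, which are clamped back into (0, 1].
#' Pass-through phases are left untouched, so the perturbed set always
#' passes [validate_params()].
#'
#' @param ps A `p2i_params` object.
#' @param scale Jitter half-width as a fraction, in \[0, 0.5\]: each
#'   multiplier is drawn uniformly from `[1 - scale, 1 + scale]`.
#' @param seed Integer seed.
#' @return A perturbed `p2i_params` object.
#' @export
perturb_params <- function(ps, scale, seed) {
  if (scale < 0 || scale > 0.5) stop("scale must be in [0, 0.5]")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ph <- ps$phases
  for (i in seq_len(nrow(ph))) {
    if (!ph$applicable[i]) next
    f_cost <- stats::runif(1, 1 - scale, 1 + scale)
    f_dur <- stats::runif(1, 1 - scale, 1 + scale)
    f_pos <- stats::runif(1, 1 - scale, 1 + scale)
    ph$cost_low[i] <- ph$cost_low[i] * f_cost
    ph$cost_point[i] <- ph$cost_point[i] * f_cost
    ph$cost_high[i] <- ph$cost_high[i] * f_cost
    ph$duration[i] <- ph$duration[i] * f_dur
    ph$pos[i] <- min(1, max(1e-6, ph$pos[i] * f_pos))
  }
  out <- ps
  out$phases <- ph
  bad <- validate_params(out)
  if (length(bad) > 0) {
    stop("perturbation produced an invalid parameter set:\n  ",
         paste(bad, collapse = "\n  "))
  }
  out
}
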