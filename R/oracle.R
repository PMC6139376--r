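#' Monte Carlo attrition simulation of a portfolio
#'
#' The portfolio engine is deterministic: it propagates expectations. This
#' simulator realizes the minimal stochastic model consistent with those
#' expectations — each candidate independently survives each phase with
#' that phase's probability of success and incurs the funded phase cost
#' for every phase it enters — and is used to validate the engine (the
#' simulated means must match the deterministic expectations).
#'
#' A row's `capacity_factor` is treated as an independent probability that
#' a candidate is absorbed into the pipeline at all, which reproduces the
#' engine's multiplicative scaling in expectation.
#'
#' @param portfolio Portfolio data frame with integral multiplicities.
#' @param ps A `p2i_params` object.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return List of class `p2i_sim`: `launches` (integer per replicate),
#'   `cost` ($M per replicate), `mean_launches`, `se_launches`,
#'   `mean_cost`, `se_cost`, `n_reps`, `seed`.
#' @export
#' @examples
#' ps <- default_params()
#' sim <- simulate_attrition(project("dx_assay", 2017, ps = ps), ps,
#'                           n_reps = 1000, seed = 1)
#' sim$mean_launches  # ~0.5
simulate_attrition <- function(portfolio, ps, n_reps, seed) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  n <- if (is.null(portfolio)) 0L else nrow(portfolio)
  mult <- portfolio$multiplicity
  if (n > 0 && any(abs(mult - round(mult)) > 1e-9)) {
    stop("Monte Carlo simulation requires integral multiplicities")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  launches <- integer(n_reps)
  cost <- numeric(n_reps)
  for (i in seq_len(n)) {
    prj <- portfolio[i, ]
    rows <- .phases_of(ps, prj$archetype)
    funded <- .parse_funded(prj$funded_phases)
    m <- as.integer(round(prj$multiplicity))
    if (m == 0) next
    alive <- if (prj$capacity_factor < 1) {
      stats::rbinom(n_reps, m, prj$capacity_factor)
    } else rep.int(m, n_reps)
    for (k in prj$entry_phase:3) {
      r <- rows[rows$phase_ordinal == k, ]
      if (k %in% funded) cost <- cost + alive * r$cost_point
      if (r$pos < 1) alive <- stats::rbinom(n_reps, alive, r$pos)
    }
    launches <- launches + alive
  }
  structure(
    list(launches = launches, cost = cost,
         mean_launches = mean(launches),
         se_launches = stats::sd(launches) / sqrt(n_reps),
         mean_cost = mean(cost),
         se_cost = stats::sd(cost) / sqrt(n_reps),
         n_reps = n_reps, seed = seed),
    class = "p2i_sim"
  )
}

#' @export
print.p2i_sim <- function(x, ...) {
  cat("p2i Monte Carlo attrition simulation (", x$n_reps, " replicates, ",
      "seed ", x$seed, ")\n", sep = "")
  cat("  launches: ", signif(x$mean_launches, 5), " +/- ",
      signif(x$se_launches, 3), " (SE)\n", sep = "")
  cat("  cost ($M): ", signif(x$mean_cost, 6), " +/- ",
      signif(x$se_cost, 4), " (SE)\n", sep = "")
  invisible(x)
}

#' Exact outcome distribution for a single candidate
#'
#' Exhaustively enumerates the survive/fail paths of one candidate of an
#' archetype (at most 2^4): failure at each traversed phase, or launch.
#' Outcomes with identical (launch, cost) are merged. The exact expected
#' launches and expected cost computed here are ground truth for both the
#' deterministic engine and the Monte Carlo simulator.
#'
#' @param archetype Archetype id.
#' @param ps A `p2i_params` object.
#' @param entry_phase Entry phase ordinal; defaults to the archetype's
#'   default.
#' @param funded_phases Phase ordinals whose costs are counted
#'   (default all).
#' @return List with `outcomes` (data frame: launch 0/1, cost, prob),
#'   `expected_launches`, `expected_cost`.
#' @export
#' @examples
#' ps <- default_params()
#' enumerate_paths("repurposed_simple", ps)$outcomes  # 3 distinct outcomes
enumerate_paths <- function(archetype, ps,
                            entry_phase = entry_phase_default(ps, archetype),
                            funded_phases = 0:3) {
  rows <- .phases_of(ps, archetype)
  ords <- entry_phase:3
  res <- data.frame(launch = integer(0), cost = numeric(0),
                    prob = numeric(0))
  reach <- 1
  cost_so_far <- 0
  for (k in ords) {
    r <- rows[rows$phase_ordinal == k, ]
    c_k <- if (k %in% funded_phases) r$cost_point else 0
    cost_so_far <- cost_so_far + c_k
    fail_p <- reach * (1 - r$pos)
    if (fail_p > 0) {
      res <- rbind(res, data.frame(launch = 0L, cost = cost_so_far,
                                   prob = fail_p))
    }
    reach <- reach * r$pos
  }
  res <- rbind(res, data.frame(launch = 1L, cost = cost_so_far,
                               prob = reach))
  # merge identical (launch, cost) outcomes
  key <- paste(res$launch, format(res$cost, digits = 15))
  agg <- stats::aggregate(res$prob, by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  out <- data.frame(launch = res$launch[first], cost = res$cost[first],
                    prob = agg$x[match(key[first], agg$key)])
  out <- out[order(out$launch, out$cost), ]
  rownames(out) <- NULL
  list(outcomes = out,
       expected_launches = sum(out$launch * out$prob),
       expected_cost = sum(out$cost * out$prob))
}
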