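# Discrete-time Markov cohort engine. Five states: event_free, three
# post-event states (mi, stroke, revasc) and absorbing cv_death. Every
# alive state carries the same per-cycle composite-event hazard, split
# across destinations by the event mix (recurrence allowed); the cohort
# starts fully event-free. Costs: a per-cycle drug cost for alive
# states and a one-time payoff on each incident event transition
# (hospitalization, or the premature-death cost on entry to cv_death),
# both discounted at the annual rate with an end-of-cycle convention.

markov_states <- c("event_free", "mi", "stroke", "revasc", "cv_death")

#' Markov model specification
#'
#' @param p_event_per_cycle Per-cycle probability of a composite event
#'   for every alive state, typically from [per_cycle_probability()].
#' @param event_split An [event_mix()] dividing events across
#'   destinations.
#' @param horizon_cycles Number of cycles (default 10).
#' @param cycle_length Years per cycle (default 1).
#' @param discount_rate Annual discount rate (default 0.05).
#' @param effectiveness `"event_free_at_horizon"` (default): probability
#'   of never experiencing a composite event over the horizon;
#'   `"discounted_event_free_years"`: discounted sum of event-free state
#'   occupancy across cycles.
#' @param half_cycle If `TRUE`, per-cycle drug costs use the mean of
#'   start- and end-of-cycle alive occupancy discounted at mid-cycle.
#'   Off by default.
#' @return An object of class `markov_spec`.
#' @export
markov_spec <- function(p_event_per_cycle,
                        event_split = event_mix_default(),
                        horizon_cycles = 10,
                        cycle_length = 1,
                        discount_rate = 0.05,
                        effectiveness = c("event_free_at_horizon",
                                          "discounted_event_free_years"),
                        half_cycle = FALSE) {
  check_number(p_event_per_cycle, "p_event_per_cycle", min = 0, max = 1)
  check_number(horizon_cycles, "horizon_cycles", min = 1)
  check_number(cycle_length, "cycle_length", min = 1e-12)
  check_number(discount_rate, "discount_rate", min = -1 + 1e-12)
  check_flag(half_cycle, "half_cycle")
  if (!inherits(event_split, "event_mix")) {
    event_split <- do.call(event_mix, as.list(unname(event_split)))
  }
  structure(
    list(states = markov_states,
         p_event_per_cycle = p_event_per_cycle,
         event_split = event_split,
         horizon_cycles = as.integer(horizon_cycles),
         cycle_length = cycle_length,
         discount_rate = discount_rate,
         effectiveness = arg_match(effectiveness),
         half_cycle = half_cycle),
    class = "markov_spec"
  )
}

#' Convert a cumulative risk to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - R)^(1/horizon_cycles)`, so the
#' probability of surviving all cycles event-free round-trips to
#' `1 - R`.
#'
#' @param cum_risk_10y Cumulative risk over the horizon, in percent.
#' @param horizon_cycles Number of cycles in the horizon.
#' @return Per-cycle event probability.
#' @export
#' @examples
#' per_cycle_probability(35, 10)
per_cycle_probability <- function(cum_risk_10y, horizon_cycles = 10) {
  check_number(cum_risk_10y, "cum_risk_10y", min = 0, max = 100)
  check_number(horizon_cycles, "horizon_cycles", min = 1)
  1 - (1 - cum_risk_10y / 100)^(1 / horizon_cycles)
}

#' Discount factor
#'
#' `(1 + rate)^(-cycle)`; cycle 0 gives 1.
#'
#' @param cycle Cycle index (>= 0, fractional allowed for half-cycle
#'   accounting).
#' @param rate Annual discount rate (> -1).
#' @return Unitless factor.
#' @export
#' @examples
#' discount_factor(10, 0.05)
discount_factor <- function(cycle, rate = 0.05) {
  if (any(cycle < 0)) abort_field("cycle", "must be non-negative")
  check_number(rate, "rate", min = -1 + 1e-12)
  (1 + rate)^(-cycle)
}

# transition matrix implied by a markov_spec; rows sum to 1 exactly
transition_matrix <- function(spec) {
  p <- spec$p_event_per_cycle
  w <- spec$event_split
  k <- length(markov_states)
  mat <- matrix(0, k, k, dimnames = list(markov_states, markov_states))
  for (s in c("event_free", "mi", "stroke", "revasc")) {
    mat[s, c("mi", "stroke", "revasc", "cv_death")] <- p * w
    mat[s, s] <- mat[s, s] + (1 - p)
  }
  mat["cv_death", "cv_death"] <- 1
  bad <- abs(rowSums(mat) - 1) > 1e-12
  if (any(bad)) {
    abort_field("transition matrix",
                paste("rows do not sum to 1:", paste(markov_states[bad], collapse = ", ")))
  }
  mat
}

#' Run a Markov cohort trace
#'
#' Iterates the cohort distribution over the horizon and accumulates
#' discounted drug and event costs.
#'
#' @param spec A [markov_spec()].
#' @param drug_cost_per_cycle BRL accrued per cycle by each alive
#'   cohort member (regimen cost / horizon for annual cycles).
#' @param event_costs Named vector of one-time costs on entry to `mi`,
#'   `stroke`, `revasc`, `cv_death`, e.g. from the unit cost inputs with
#'   the premature-death cost for `cv_death`.
#' @return An object of class `cohort_trace`: a list with `occupancy`
#'   (tibble, cycles 0..H by state), `per_cycle_cost` (tibble with
#'   discounted drug/event cost per cycle), `total_discounted_cost`,
#'   `effectiveness` and the `spec`.
#' @export
#' @examples
#' sp <- markov_spec(per_cycle_probability(35, 10))
#' tr <- run_trace(sp, drug_cost_per_cycle = 730,
#'                 event_costs = event_state_costs())
#' tr$effectiveness # 0.65
run_trace <- function(spec, drug_cost_per_cycle, event_costs) {
  check_number(drug_cost_per_cycle, "drug_cost_per_cycle", min = 0)
  if (!all(markov_states[-1] %in% names(event_costs))) {
    abort_field("event_costs",
                "must be named with mi, stroke, revasc, cv_death")
  }
  event_costs <- event_costs[markov_states[-1]]
  if (any(event_costs < 0)) abort_field("event_costs", "must be non-negative")

  mat <- transition_matrix(spec)
  h <- spec$horizon_cycles
  alive <- c("event_free", "mi", "stroke", "revasc")

  occ <- matrix(0, h + 1, length(markov_states),
                dimnames = list(NULL, markov_states))
  occ[1, "event_free"] <- 1
  drug_cost <- event_cost <- numeric(h)

  for (t in seq_len(h)) {
    x <- occ[t, ]
    # incident events this cycle: alive mass x hazard, split by mix
    # (self-transitions like mi -> mi recurrences are included: each
    # carries a fresh event payoff)
    flows <- sum(x[alive]) * spec$p_event_per_cycle * spec$event_split
    names(flows) <- markov_states[-1]
    occ[t + 1, ] <- as.numeric(x %*% mat)

    df_end <- discount_factor(t * spec$cycle_length, spec$discount_rate)
    if (spec$half_cycle) {
      alive_mass <- (sum(x[alive]) + sum(occ[t + 1, alive])) / 2
      df_drug <- discount_factor((t - 0.5) * spec$cycle_length, spec$discount_rate)
    } else {
      alive_mass <- sum(x[alive])
      df_drug <- df_end
    }
    drug_cost[t] <- drug_cost_per_cycle * alive_mass * df_drug
    event_cost[t] <- sum(flows * event_costs) * df_end
  }

  eff <- switch(spec$effectiveness,
    event_free_at_horizon = occ[h + 1, "event_free"],
    discounted_event_free_years =
      sum(occ[-1, "event_free"] *
            discount_factor(seq_len(h) * spec$cycle_length, spec$discount_rate)) *
      spec$cycle_length
  )

  structure(
    list(
      occupancy = dplyr::bind_cols(tibble(cycle = 0:h), as_tibble(occ)),
      per_cycle_cost = tibble(
        cycle = seq_len(h),
        drug_cost = drug_cost,
        event_cost = event_cost,
        total = drug_cost + event_cost
      ),
      total_discounted_cost = sum(drug_cost) + sum(event_cost),
      effectiveness = unname(eff),
      spec = spec
    ),
    class = "cohort_trace"
  )
}

#' Totals of a completed trace
#'
#' @param trace A [run_trace()] result, or `NULL` when `cost` and
#'   `effectiveness` are supplied directly (externally supplied totals,
#'   e.g. replication inputs).
#' @param name Strategy label.
#' @param cost,effectiveness Override totals.
#' @return An object of class `strategy_result` (list with `name`,
#'   `cost`, `effectiveness`).
#' @export
strategy_result <- function(trace = NULL, name = "strategy",
                            cost = NULL, effectiveness = NULL) {
  if (is.null(trace)) {
    check_number(cost, "cost", min = 0)
    check_number(effectiveness, "effectiveness")
  } else {
    if (!inherits(trace, "cohort_trace")) abort_field("trace", "must be a cohort_trace")
    cost <- cost %||% trace$total_discounted_cost
    effectiveness <- effectiveness %||% trace$effectiveness
  }
  structure(list(name = name, cost = cost, effectiveness = effectiveness),
            class = "strategy_result")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf(
    "<cohort_trace> %d cycles, p_event=%.6f, discount=%.1f%%\n",
    x$spec$horizon_cycles, x$spec$p_event_per_cycle, 100 * x$spec$discount_rate
  ))
  cat(sprintf("  total discounted cost: %.2f BRL\n", x$total_discounted_cost))
  cat(sprintf("  effectiveness (%s): %.4f\n", x$spec$effectiveness, x$effectiveness))
  invisible(x)
}
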