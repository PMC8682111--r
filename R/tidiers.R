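# broom-style tidiers

#' Tidy an incremental cost-effectiveness comparison
#'
#' @param x A [icer()] result.
#' @param ... Unused.
#' @return A two-row tibble (one per strategy) with `strategy`, `cost`,
#'   `effectiveness`.
#' @export
tidy.cea_result <- function(x, ...) {
  tibble(
    strategy = c(x$name_a, x$name_b),
    cost = c(x$cost_a, x$cost_b),
    effectiveness = c(x$eff_a, x$eff_b)
  )
}

#' @rdname tidy.cea_result
#' @return `glance()`: a one-row tibble with `delta_cost`, `delta_eff`,
#'   `icer`, `dominance`.
#' @export
glance.cea_result <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_eff = x$delta_eff,
         icer = x$icer, dominance = x$dominance)
}

#' Tidy a Markov cohort trace
#'
#' @param x A [run_trace()] result.
#' @param ... Unused.
#' @return A long tibble with `cycle`, `state`, `occupancy`.
#' @export
tidy.cohort_trace <- function(x, ...) {
  tidyr::pivot_longer(x$occupancy, -"cycle",
                      names_to = "state", values_to = "occupancy")
}

#' @rdname tidy.cohort_trace
#' @return `glance()`: one-row tibble with `total_discounted_cost`,
#'   `effectiveness`, `horizon_cycles`, `p_event_per_cycle`.
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble(
    total_discounted_cost = x$total_discounted_cost,
    effectiveness = x$effectiveness,
    horizon_cycles = x$spec$horizon_cycles,
    p_event_per_cycle = x$spec$p_event_per_cycle
  )
}

#' Glance at a base-case run
#'
#' @param x A [run_base_case()] result.
#' @param ... Unused.
#' @return One-row tibble with the headline quantities.
#' @export
glance.base_case_result <- function(x, ...) {
  tibble(
    baseline_risk_10y = x$risk$baseline_risk_10y,
    treated_risk_10y = x$risk$treated_risk_10y,
    rrr = x$risk$rrr,
    arr = x$risk$arr,
    cost_standard = x$strategies$standard$cost,
    cost_combined = x$strategies$combined$cost,
    eff_standard = x$strategies$standard$effectiveness,
    eff_combined = x$strategies$combined$effectiveness,
    delta_cost = x$cea$delta_cost,
    delta_eff = x$cea$delta_eff,
    icer = x$cea$icer
  )
}
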