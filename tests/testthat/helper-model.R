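# shared fixtures built in code

# a patient row with every field explicit; override any field by name
make_patient <- function(...) {
  base <- tibble::tibble(
    id = "pt00001", age = 60, sex = "male",
    hypertension = TRUE, diabetes = FALSE, smoking = FALSE,
    prior_mi = TRUE, prior_stroke = FALSE, ckd = FALSE, pad = FALSE,
    recent_acs = TRUE, familial_hyperchol = FALSE, ezetimibe = FALSE,
    ldl = 111, hdl = 45, tg = 159
  )
  dplyr::mutate(base, ...)
}

# brute-force path-enumeration oracle for short Markov traces:
# enumerates every state path of length `cycles`, accumulating path
# probability, end-state occupancy and end-of-cycle discounted costs,
# independently of the engine's matrix iteration. For an alive origin,
# the transition-matrix entry into `dest` is p_event * w_dest, plus
# (1 - p_event) on the diagonal; the incident (payoff-bearing) part
# excludes that diagonal survival term.
enumerate_trace <- function(mat, cycles, drug_cost_per_cycle, event_costs,
                            rate, p_event) {
  states <- rownames(mat)
  alive <- setdiff(states, "cv_death")
  occ_total <- stats::setNames(numeric(length(states)), states)
  cost_total <- 0

  recurse <- function(state, prob, t) {
    if (t == cycles) {
      occ_total[state] <<- occ_total[state] + prob
      return(invisible())
    }
    df <- (1 + rate)^(-(t + 1))
    if (state %in% alive) {
      cost_total <<- cost_total + prob * drug_cost_per_cycle * df
      for (dest in names(event_costs)) {
        incident <- prob * (mat[state, dest] - (1 - p_event) * (dest == state))
        cost_total <<- cost_total + incident * event_costs[[dest]] * df
      }
    }
    for (nxt in states) {
      if (mat[state, nxt] > 0) recurse(nxt, prob * mat[state, nxt], t + 1)
    }
  }
  recurse("event_free", 1, 0)
  list(occupancy = occ_total, cost = cost_total)
}
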