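test_that("constant-hazard conversion round-trips the cumulative risk", {
  p <- per_cycle_probability(35, 10)
  expect_equal((1 - p)^10, 0.65, tolerance = 1e-12)
  expect_equal(round(p, 6), 0.042164)
  expect_equal(round(per_cycle_probability(22.75, 10), 6), 0.025482)
  expect_equal(per_cycle_probability(0, 10), 0)
  expect_equal(per_cycle_probability(100, 10), 1)
  expect_error(per_cycle_probability(120, 10), "cum_risk")
})

test_that("discount factors follow the annual convention", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(round(discount_factor(10, 0.05), 6), 0.613913)
  expect_equal(discount_factor(7, 0), 1)
  expect_error(discount_factor(3, -1), "rate")
  expect_error(discount_factor(-1, 0.05), "cycle")
})

test_that("null-risk trace accrues only discounted drug cost", {
  sp <- markov_spec(0, discount_rate = 0)
  tr <- run_trace(sp, drug_cost_per_cycle = 730,
                  event_costs = event_state_costs())
  expect_equal(tr$effectiveness, 1)
  expect_equal(tr$total_discounted_cost, 7300) # undiscounted regimen cost
  sp5 <- markov_spec(0, discount_rate = 0.05)
  tr5 <- run_trace(sp5, 730, event_state_costs())
  expect_equal(tr5$total_discounted_cost, 730 * sum(1.05^-(1:10)))
  expect_lt(tr5$total_discounted_cost, tr$total_discounted_cost)
})

test_that("single-step trace matches the hand computation", {
  sp <- markov_spec(0.5, event_split = event_mix(1, 0, 0, 0),
                    horizon_cycles = 1, discount_rate = 0)
  tr <- run_trace(sp, 0, event_state_costs())
  final <- as.numeric(tr$occupancy[2, -1])
  expect_equal(final, c(0.5, 0.5, 0, 0, 0))
})

test_that("occupancy rows conserve probability and death is monotone", {
  sp <- markov_spec(per_cycle_probability(35, 10))
  tr <- run_trace(sp, 730, event_state_costs())
  occ <- as.matrix(tr$occupancy[, -1])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_true(all(diff(occ[, "cv_death"]) >= 0))
  expect_true(tr$effectiveness >= 0 && tr$effectiveness <= 1)
  # event-free occupancy at the horizon equals the cumulative survival
  expect_equal(tr$effectiveness, 0.65, tolerance = 1e-12)
})

test_that("trace matches the brute-force path-enumeration oracle", {
  ev_costs <- c(mi = 588.12, stroke = 463.21, revasc = 6756.37,
                cv_death = 170385.60)
  grid <- expand.grid(p = c(0.1, 0.042), cycles = c(1, 2, 3),
                      rate = c(0, 0.05))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sp <- markov_spec(g$p, horizon_cycles = g$cycles, discount_rate = g$rate)
    tr <- run_trace(sp, drug_cost_per_cycle = 730, event_costs = ev_costs)
    oracle <- enumerate_trace(evocea:::transition_matrix(sp), g$cycles,
                              730, ev_costs, g$rate, g$p)
    engine_final <- as.numeric(tr$occupancy[g$cycles + 1, -1])
    expect_equal(engine_final, unname(oracle$occupancy), tolerance = 1e-12)
    expect_equal(tr$total_discounted_cost, oracle$cost, tolerance = 1e-12)
  }
})

test_that("higher event hazard lowers effectiveness and raises cost", {
  ev_costs <- event_state_costs()
  runs <- lapply(c(0.01, 0.05, 0.1, 0.2), function(p) {
    run_trace(markov_spec(p), 730, ev_costs)
  })
  effs <- vapply(runs, `[[`, numeric(1), "effectiveness")
  costs <- vapply(runs, `[[`, numeric(1), "total_discounted_cost")
  expect_true(all(diff(effs) < 0))
  # event payoffs dominate the small drug cost here
  expect_true(all(diff(costs) > 0))
})

test_that("discounted event-free years and half-cycle options behave", {
  p <- per_cycle_probability(35, 10)
  sp <- markov_spec(p, effectiveness = "discounted_event_free_years")
  tr <- run_trace(sp, 0, event_state_costs())
  manual <- sum((1 - p)^(1:10) * 1.05^-(1:10))
  expect_equal(tr$effectiveness, manual, tolerance = 1e-12)

  sp_hc <- markov_spec(p, half_cycle = TRUE)
  tr_hc <- run_trace(sp_hc, 730, event_state_costs())
  tr_std <- run_trace(markov_spec(p), 730, event_state_costs())
  # mid-cycle discounting of drug costs raises their present value
  expect_gt(tr_hc$total_discounted_cost, 0)
  expect_false(isTRUE(all.equal(tr_hc$total_discounted_cost,
                                tr_std$total_discounted_cost)))
})

test_that("strategy_result extracts totals or accepts supplied pairs", {
  tr <- run_trace(markov_spec(0, discount_rate = 0), 730, event_state_costs())
  sr <- strategy_result(tr, name = "standard")
  expect_equal(sr$cost, 7300)
  expect_equal(sr$effectiveness, 1)
  ext <- strategy_result(cost = 46522.44, effectiveness = 0.54, name = "ext")
  expect_equal(ext$cost, 46522.44)
  expect_error(strategy_result(cost = -1, effectiveness = 0.5), "cost")
})
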