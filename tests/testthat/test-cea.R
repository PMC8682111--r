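test_that("icer arithmetic and dominance classification", {
  a <- strategy_result(cost = 46522.44, effectiveness = 0.54, name = "standard")
  b <- strategy_result(cost = 236141.85, effectiveness = 0.73, name = "combined")
  res <- icer(a, b)
  expect_equal(res$delta_cost, 189619.41)
  expect_equal(res$delta_eff, 0.19)
  expect_equal(res$icer, 189619.41 / 0.19) # 997996.8947
  expect_equal(round(res$icer, 2), 997996.89)
  expect_equal(res$dominance, "none")

  dom <- icer(strategy_result(cost = 100, effectiveness = 0.5),
              strategy_result(cost = 50, effectiveness = 0.6))
  expect_equal(dom$dominance, "b_dominates")

  same <- icer(a, a)
  expect_equal(same$delta_cost, 0)
  expect_false(same$icer_defined)
  expect_true(is.na(same$icer))

  # tidier round trip
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_equal(glance(res)$icer, res$icer)
})

test_that("one-way DSA brackets the base case and orders the tornado", {
  cfg <- default_run_config()
  dsa <- one_way_dsa(cfg, fraction = 0.20)
  base <- attr(dsa, "base_icer")
  expect_true(min(dsa$icer_min) <= base)
  expect_true(max(dsa$icer_max) >= base)
  expect_true(all(diff(dsa$range) <= 1e-9)) # sorted widest first
  # a parameter the ICER does not depend on: identical low/high
  # (stroke cost with zero stroke weight in the event mix)
  cfg_ns <- run_config(event_mix = list(w_mi = 0.427, w_stroke = 0,
                                        w_revasc = 0.458, w_death = 0.115))
  flat <- one_way_dsa(cfg_ns, parameters = "c_stroke")
  expect_equal(flat$icer_low, flat$icer_high)
  expect_equal(flat$range, 0)
  # zero variation collapses every range onto the base ICER
  dsa0 <- one_way_dsa(cfg, fraction = 0)
  expect_true(all(abs(dsa0$icer_low - base) < 1e-9))
  expect_true(all(abs(dsa0$icer_high - base) < 1e-9))
})

test_that("DSA clamps out-of-domain parameter excursions with a warning", {
  cfg <- run_config(replication = list(baseline_risk = 90))
  expect_warning(one_way_dsa(cfg, fraction = 0.2, parameters = "baseline_risk"),
                 "clamped")
  expect_error(one_way_dsa(default_run_config(), parameters = "nope"), "unknown")
})

test_that("PSA is seed-deterministic and degenerates to the base case", {
  cfg <- default_run_config()
  s1 <- run_psa(cfg, n_draws = 50, seed = 7)
  s2 <- run_psa(cfg, n_draws = 50, seed = 7)
  expect_identical(s1, s2)
  s3 <- run_psa(cfg, n_draws = 50, seed = 8)
  expect_false(identical(s1, s3))

  # zero-variance distributions: every draw equals the base case
  fixed <- lapply(evocea:::model_params(cfg), function(v) list(dist = "fixed", mean = v))
  # scale handling: baseline_risk is stored in percent on the flat list
  fixed$baseline_risk$scale <- 1
  cfg_fixed <- run_config(replication = list(baseline_risk = 35),
                          psa = list(distributions = fixed))
  s0 <- run_psa(cfg_fixed, n_draws = 20, seed = 1)
  base <- evocea:::evaluate_model(evocea:::model_params(cfg), cfg)
  expect_true(all(abs(s0$cost_standard - base$standard$cost) < 1e-9))
  expect_true(all(abs(s0$cost_combined - base$combined$cost) < 1e-9))
  expect_true(all(abs(s0$eff_standard - base$standard$effectiveness) < 1e-12))
  expect_true(all(abs(s0$icer - base$icer) < 1e-6))
})

test_that("unknown distribution names or parameters are config errors", {
  cfg_bad <- run_config(psa = list(distributions = list(
    c_mi = list(dist = "cauchy")
  )))
  expect_error(run_psa(cfg_bad, n_draws = 2, seed = 1), "unknown distribution")
  cfg_bad2 <- run_config(psa = list(distributions = list(
    not_a_param = list(dist = "gamma")
  )))
  expect_error(run_psa(cfg_bad2, n_draws = 2, seed = 1), "unknown parameter")
})

test_that("PSA summary uses interpolated percentiles in the published layout", {
  # constant samples: all summary columns collapse to the constant
  const <- tibble::tibble(cost_standard = rep(5, 10), eff_standard = rep(1, 10),
                          cost_combined = rep(7, 10), eff_combined = rep(2, 10))
  s <- summarize_psa(const)
  row <- dplyr::filter(s, strategy == "standard", attribute == "cost")
  expect_equal(row$mean, 5)
  expect_equal(row$median, 5)
  expect_equal(row$p2.5, 5)
  expect_equal(row$p97.5, 5)

  # 1..100 under linear interpolation between closest ranks (type 7)
  seq100 <- tibble::tibble(cost_standard = 1:100, eff_standard = 1:100,
                           cost_combined = 1:100, eff_combined = 1:100)
  s2 <- summarize_psa(seq100)
  row2 <- dplyr::filter(s2, strategy == "combined", attribute == "cost")
  expect_equal(row2$median, 50.5)
  expect_equal(row2$p2.5, 3.475)
  expect_equal(row2$p97.5, 97.525)

  # ordering invariant on random sample sets
  psa <- run_psa(default_run_config(), n_draws = 100, seed = 3)
  s3 <- summarize_psa(psa)
  expect_true(all(s3$p2.5 <= s3$p10 & s3$p10 <= s3$median &
                    s3$median <= s3$p90 & s3$p90 <= s3$p97.5))
  expect_error(summarize_psa(psa[0, ]), "non-empty")
})

test_that("PSA propagates a calibrated dispersion through to the cost SD", {
  # put all uncertainty on the syringe price, scaled so the combined
  # strategy's cost SD is ~1450 BRL, and check the draws recover it
  cfg <- default_run_config()
  base <- evocea:::model_params(cfg)
  bump <- base
  bump$syringe_price <- base$syringe_price + 1
  k <- evocea:::evaluate_model(bump, cfg)$combined$cost -
    evocea:::evaluate_model(base, cfg)$combined$cost
  target_sd <- 1450
  dists <- lapply(base, function(v) list(dist = "fixed", mean = v))
  dists$syringe_price <- list(dist = "gamma", mean = base$syringe_price,
                              sd = target_sd / k)
  cfg2 <- run_config(psa = list(distributions = dists))
  draws <- run_psa(cfg2, n_draws = 1000, seed = 11)
  expect_lt(abs(sd(draws$cost_combined) - target_sd) / target_sd, 0.10)
})

test_that("CEAC is monotone with crossover at the median draw ICER", {
  psa <- run_psa(default_run_config(), n_draws = 400, seed = 5)
  expect_true(all(psa$delta_eff > 0))
  curve <- ceac(psa, wtp_grid = seq(0, max(psa$icer) + 1e4, by = 5e3))
  expect_true(all(diff(curve$prob_combined) >= 0))
  expect_equal(curve$prob_combined + curve$prob_standard,
               rep(1, nrow(curve)))
  # at zero willingness to pay, the combined strategy wins only when cheaper
  expect_equal(curve$prob_combined[1], mean(psa$delta_cost < 0))
  # far beyond every draw's ICER the probability reaches 1
  expect_equal(dplyr::last(curve$prob_combined), 1)
  # the 50% crossing sits at the draws' median ICER
  med <- stats::median(psa$icer)
  crossing <- curve$wtp[which(curve$prob_combined >= 0.5)[1]]
  expect_lt(abs(crossing - med), 5e3 + 0.05 * med)
  expect_error(ceac(psa, numeric(0)), "wtp_grid")
})
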