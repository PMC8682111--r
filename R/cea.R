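# Incremental cost-effectiveness and sensitivity analysis: ICER with
# dominance classification, one-way deterministic sensitivity (tornado),
# probabilistic sensitivity analysis (second-order Monte Carlo over the
# cohort model) and the cost-effectiveness acceptability curve.

#' Incremental cost-effectiveness ratio
#'
#' Compares strategy `b` (typically the combined therapy) against
#' strategy `a` (the comparator). The ICER is `delta_cost / delta_eff`,
#' defined only when the effectiveness difference is non-zero; a
#' strategy that is both cheaper and more effective dominates.
#'
#' @param a,b [strategy_result()] objects (or lists with `cost` and
#'   `effectiveness`).
#' @return An object of class `cea_result` with fields `cost_a`,
#'   `cost_b`, `eff_a`, `eff_b`, `delta_cost`, `delta_eff`, `icer`
#'   (`NA` when undefined) and `dominance` (`"none"`, `"a_dominates"`,
#'   `"b_dominates"`).
#' @export
#' @examples
#' icer(
#'   strategy_result(cost = 46522.44, effectiveness = 0.54, name = "atorvastatin"),
#'   strategy_result(cost = 236141.85, effectiveness = 0.73, name = "combined")
#' )
icer <- function(a, b) {
  for (s in list(a, b)) {
    if (!is.finite(s$cost) || !is.finite(s$effectiveness)) {
      abort_field("strategy", "cost and effectiveness must be finite")
    }
  }
  delta_cost <- b$cost - a$cost
  delta_eff <- b$effectiveness - a$effectiveness
  dominance <- if (delta_cost < 0 && delta_eff > 0) {
    "b_dominates"
  } else if (delta_cost > 0 && delta_eff < 0) {
    "a_dominates"
  } else {
    "none"
  }
  structure(
    list(
      name_a = a$name %||% "a", name_b = b$name %||% "b",
      cost_a = a$cost, cost_b = b$cost,
      eff_a = a$effectiveness, eff_b = b$effectiveness,
      delta_cost = delta_cost, delta_eff = delta_eff,
      icer = if (delta_eff != 0) delta_cost / delta_eff else NA_real_,
      icer_defined = delta_eff != 0,
      dominance = dominance
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$name_b, x$name_a))
  cat(sprintf("  cost:          %12.2f vs %12.2f  (delta %.2f)\n",
              x$cost_b, x$cost_a, x$delta_cost))
  cat(sprintf("  effectiveness: %12.4f vs %12.4f  (delta %.4f)\n",
              x$eff_b, x$eff_a, x$delta_eff))
  if (x$icer_defined) {
    cat(sprintf("  ICER: %.2f BRL per outcome avoided\n", x$icer))
  } else {
    cat("  ICER: undefined (no effectiveness difference)\n")
  }
  if (x$dominance != "none") cat(sprintf("  dominance: %s\n", x$dominance))
  invisible(x)
}

#' One-way deterministic sensitivity analysis
#'
#' Varies each model parameter to `(1 - fraction)` and `(1 + fraction)`
#' of its base value, holding the others fixed, and recomputes the
#' ICER. Values that would leave their domain (risks above 100%, a
#' relative risk reduction above 1) are clamped with a warning.
#'
#' @param config A [run_config()].
#' @param fraction Relative variation (default 0.20).
#' @param parameters Character vector of parameter names to vary;
#'   default all of `baseline_risk`, `rrr`, the unit costs, drug prices,
#'   annual income and the discount rate.
#' @return A tibble of class `dsa_result`, one row per parameter with
#'   the low/high parameter values, the ICERs at each, and the range
#'   width, ordered for a tornado display (widest first). Attributes
#'   `base_icer`, `icer_min`, `icer_max` give the base case and the
#'   overall envelope.
#' @export
one_way_dsa <- function(config = default_run_config(), fraction = 0.20,
                        parameters = NULL) {
  check_number(fraction, "fraction", min = 0)
  base <- model_params(config)
  parameters <- parameters %||% names(base)
  bad <- setdiff(parameters, names(base))
  if (length(bad)) abort_field("parameters", paste("unknown:", paste(bad, collapse = ", ")))
  base_icer <- evaluate_model(base, config)$icer

  rows <- purrr::map(parameters, function(pn) {
    vals <- base[[pn]] * c(1 - fraction, 1 + fraction)
    icers <- vapply(vals, function(v) {
      p <- base
      p[[pn]] <- clamp_param(pn, v)
      evaluate_model(p, config)$icer
    }, numeric(1))
    tibble(
      parameter = pn, base_value = base[[pn]],
      low_value = vals[1], high_value = vals[2],
      icer_low = icers[1], icer_high = icers[2],
      icer_min = min(icers), icer_max = max(icers),
      range = abs(icers[2] - icers[1])
    )
  })
  out <- arrange(bind_rows(rows), desc(range))
  structure(out,
            class = c("dsa_result", class(out)),
            base_icer = base_icer,
            icer_min = min(c(attr(out, "icer_min"), out$icer_min, base_icer)),
            icer_max = max(c(out$icer_max, base_icer)))
}

clamp_param <- function(name, value) {
  if (name == "baseline_risk" && value > 100) {
    warn(sprintf("baseline_risk %.2f clamped to 100", value))
    return(100)
  }
  if (name == "rrr" && value > 1) {
    warn(sprintf("rrr %.4f clamped to 1", value))
    return(1)
  }
  value
}

# ---- probabilistic sensitivity analysis ------------------------------

# default second-order distributions: gamma for monetary parameters,
# beta for probability-scale parameters, with SD anchored so that +/-20%
# of the mean is a 95% interval; the discount rate is held fixed.
default_psa_distributions <- function(base, dispersion = 0.20) {
  sd_of <- function(m) dispersion * m / qnorm(0.975)
  dist <- list()
  for (pn in c("c_mi", "c_stroke", "c_revasc", "tablet_price",
               "syringe_price", "annual_income")) {
    dist[[pn]] <- list(dist = "gamma", mean = base[[pn]], sd = sd_of(base[[pn]]))
  }
  dist$baseline_risk <- list(dist = "beta", mean = base$baseline_risk / 100,
                             sd = sd_of(base$baseline_risk / 100), scale = 100)
  dist$rrr <- list(dist = "beta", mean = base$rrr, sd = sd_of(base$rrr), scale = 1)
  dist$discount_rate <- list(dist = "fixed", mean = base$discount_rate)
  dist
}

sample_param <- function(d, n) {
  m <- d$mean
  s <- d$sd %||% 0
  scale <- d$scale %||% 1
  x <- switch(d$dist,
    fixed = rep(m, n),
    gamma = {
      if (m == 0 || s == 0) rep(m, n)
      else rgamma(n, shape = (m / s)^2, rate = m / s^2)
    },
    beta = {
      if (s == 0) rep(m, n)
      else {
        v <- s^2
        if (v >= m * (1 - m)) {
          abort_field("distributions", "beta sd too large for its mean")
        }
        nu <- m * (1 - m) / v - 1
        rbeta(n, m * nu, (1 - m) * nu)
      }
    },
    abort_field("distributions", paste("unknown distribution", d$dist))
  )
  x * scale
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: samples the model parameters from their
#' uncertainty distributions and re-runs the full cost/effectiveness
#' pipeline for every draw. Defaults: gamma distributions for monetary
#' parameters and beta for probability-scale parameters, with the SD set
#' so that 20% of the mean spans a 95% interval; override per parameter
#' via `config$psa$distributions` entries of the form
#' `list(dist = "gamma"|"beta"|"fixed", mean =, sd =)`.
#'
#' @param config A [run_config()].
#' @param n_draws Number of draws (default `config$psa$n_draws`, 1000).
#' @param seed Seed (default `config$psa$seed`); the chain is fully
#'   reproducible and leaves the global RNG untouched.
#' @return A tibble of class `psa_result`, one row per draw, with the
#'   sampled parameters, per-strategy `cost_standard`/`eff_standard`/
#'   `cost_combined`/`eff_combined`, and `delta_cost`, `delta_eff`,
#'   `icer`.
#' @export
run_psa <- function(config = default_run_config(), n_draws = NULL, seed = NULL) {
  n_draws <- n_draws %||% config$psa$n_draws
  seed <- seed %||% config$psa$seed
  check_number(n_draws, "n_draws", min = 1)
  base <- model_params(config)
  dists <- default_psa_distributions(base)
  for (pn in names(config$psa$distributions)) {
    if (!pn %in% names(base)) {
      abort_field("psa$distributions", paste("unknown parameter", pn))
    }
    ov <- config$psa$distributions[[pn]]
    if (!is.null(ov$dist) && !identical(ov$dist, dists[[pn]]$dist)) {
      # a different family replaces the default outright (in particular
      # its scale), rather than inheriting stale fields
      dists[[pn]] <- ov
    } else {
      dists[[pn]] <- utils::modifyList(dists[[pn]], ov)
    }
  }

  draws <- withr::with_seed(seed, {
    as_tibble(purrr::map(dists, sample_param, n = as.integer(n_draws)))
  })

  results <- purrr::pmap(draws, function(...) {
    p <- list(...)
    res <- evaluate_model(p, config)
    tibble(
      cost_standard = res$standard$cost,
      eff_standard = res$standard$effectiveness,
      cost_combined = res$combined$cost,
      eff_combined = res$combined$effectiveness
    )
  })
  out <- dplyr::bind_cols(tibble(draw_id = seq_len(nrow(draws))), draws,
                          bind_rows(results))
  out <- mutate(out,
                delta_cost = .data$cost_combined - .data$cost_standard,
                delta_eff = .data$eff_combined - .data$eff_standard,
                icer = ifelse(.data$delta_eff != 0,
                              .data$delta_cost / .data$delta_eff, NA_real_))
  structure(out, class = c("psa_result", class(out)))
}

#' Summarise PSA draws in the published table layout
#'
#' Mean, SD, median and the 2.5/10/90/97.5 percentiles of cost and
#' effectiveness per strategy. Percentiles use linear interpolation
#' between closest ranks ([stats::quantile()] type 7).
#'
#' @param samples A [run_psa()] result.
#' @return A tibble of class `psa_summary` with columns `strategy`,
#'   `attribute`, `mean`, `sd`, `median`, `p2.5`, `p10`, `p90`, `p97.5`.
#' @export
summarize_psa <- function(samples) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0L) abort_field("samples", "must be non-empty")
  long <- tidyr::pivot_longer(
    select(samples, dplyr::any_of(c("cost_standard", "eff_standard",
                                    "cost_combined", "eff_combined"))),
    dplyr::everything(),
    names_to = c("attribute", "strategy"), names_sep = "_"
  )
  out <- long %>%
    mutate(attribute = ifelse(.data$attribute == "eff", "effectiveness",
                              .data$attribute)) %>%
    group_by(.data$strategy, .data$attribute) %>%
    summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      median = quantile(.data$value, 0.5, type = 7, names = FALSE),
      p2.5 = quantile(.data$value, 0.025, type = 7, names = FALSE),
      p10 = quantile(.data$value, 0.10, type = 7, names = FALSE),
      p90 = quantile(.data$value, 0.90, type = 7, names = FALSE),
      p97.5 = quantile(.data$value, 0.975, type = 7, names = FALSE),
      .groups = "drop"
    )
  structure(out, class = c("psa_summary", class(out)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in
#' which the combined strategy has positive incremental net benefit
#' (`wtp * delta_eff - delta_cost > 0`); the comparator's probability is
#' the complement.
#'
#' @param samples A [run_psa()] result (needs `delta_cost`,
#'   `delta_eff`).
#' @param wtp_grid Willingness-to-pay grid in BRL per composite outcome
#'   avoided (default 0 to 2,000,000 in 10,000 steps).
#' @return A tibble of class `ceac_curve` with columns `wtp`,
#'   `prob_combined`, `prob_standard`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 2e6, by = 1e4)) {
  if (length(wtp_grid) == 0L) abort_field("wtp_grid", "must be non-empty")
  samples <- as_tibble(samples)
  if (nrow(samples) == 0L) abort_field("samples", "must be non-empty")
  prob <- vapply(
    wtp_grid,
    function(l) mean(l * samples$delta_eff - samples$delta_cost > 0),
    numeric(1)
  )
  structure(
    tibble(wtp = wtp_grid, prob_combined = prob, prob_standard = 1 - prob),
    class = c("ceac_curve", class(tibble()))
  )
}
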