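# End-to-end pipeline: flat model parameters -> strategy traces -> ICER.
# DSA and PSA perturb the same flat parameter list so every analysis
# runs through one evaluation path.

# flat scalar parameters the sensitivity analyses vary
model_params <- function(config = default_run_config()) {
  baseline <- config$replication$baseline_risk
  if (is.null(baseline)) {
    cohort <- generate_cohort(do.call(cohort_spec, config$cohort))
    baseline <- cohort_baseline_risk(cohort)
  }
  tp <- do.call(translation_params, config$translation)
  chain <- translate_risk(config$cohort$mean_ldl, baseline, tp)
  list(
    baseline_risk = baseline,
    rrr = chain$rrr,
    c_mi = config$costs$c_mi,
    c_stroke = config$costs$c_stroke,
    c_revasc = config$costs$c_revasc,
    tablet_price = config$costs$atorvastatin_tablet_40mg,
    syringe_price = config$costs$evolocumab_syringe_140mg,
    annual_income = config$costs$annual_income_adjusted,
    discount_rate = config$markov$discount_rate
  )
}

# run both strategies for one flat parameter set
evaluate_model <- function(params, config = default_run_config()) {
  mk <- config$markov
  mix <- do.call(event_mix, unname(config$event_mix))
  yll <- years_of_life_lost(do.call(death_cost_params, config$death))
  death_cost <- yll * params$annual_income
  ev_costs <- c(mi = params$c_mi, stroke = params$c_stroke,
                revasc = params$c_revasc, cv_death = death_cost)

  drug_per_cycle <- function(reg) {
    (reg$atorvastatin_tablets_per_day * 365 * params$tablet_price +
       reg$evolocumab_doses_per_year * params$syringe_price) * mk$cycle_length
  }

  treated <- params$baseline_risk * (1 - params$rrr)
  risks <- c(standard = params$baseline_risk, combined = treated)
  traces <- purrr::imap(risks, function(risk, nm) {
    spec <- markov_spec(
      p_event_per_cycle = per_cycle_probability(risk, mk$horizon_cycles),
      event_split = mix,
      horizon_cycles = mk$horizon_cycles,
      cycle_length = mk$cycle_length,
      discount_rate = params$discount_rate,
      effectiveness = mk$effectiveness,
      half_cycle = mk$half_cycle
    )
    reg <- config$regimens[[nm]]
    run_trace(spec, drug_per_cycle(reg), ev_costs)
  })
  standard <- strategy_result(traces$standard, name = config$regimens$standard$name)
  combined <- strategy_result(traces$combined, name = config$regimens$combined$name)
  cea <- icer(standard, combined)
  list(standard = standard, combined = combined,
       icer = cea$icer, cea = cea, traces = traces,
       death_cost = death_cost, treated_risk = treated)
}

#' Run the base-case analysis
#'
#' Executes the full pipeline under a configuration: synthetic cohort,
#' risk assignment, the LDL-to-risk translation chain, all cost inputs,
#' the two Markov traces, and the incremental comparison. When the
#' configuration carries replication overrides for the per-strategy
#' global totals, those replace the model-computed totals in the ICER
#' (the model traces are still run and reported).
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `report.json`
#'   (every intermediate quantity), `cohort.csv`, `cohort_summary.csv`,
#'   `trace_standard.csv`, `trace_combined.csv`.
#' @return An object of class `base_case_result`: a list with `cohort`,
#'   `cohort_summary`, `risk` (translation chain tibble), `costs`
#'   (drug totals, years of life lost, death cost, expected event
#'   cost), `traces`, `strategies`, and `cea` (the [icer()] result).
#' @export
#' @examples
#' res <- run_base_case(default_run_config())
#' res$cea
run_base_case <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(do.call(cohort_spec, config$cohort))
  cohort <- assign_category(cohort)
  baseline <- cohort_baseline_risk(cohort,
                                   override = config$replication$baseline_risk)

  tp <- do.call(translation_params, config$translation)
  chain <- translate_risk(config$cohort$mean_ldl, baseline, tp)

  costs <- do.call(cost_inputs, config$costs)
  reg_std <- do.call(regimen, config$regimens$standard)
  reg_cmb <- do.call(regimen, config$regimens$combined)
  dp <- do.call(death_cost_params, config$death)
  mix <- do.call(event_mix, unname(config$event_mix))
  death_cost <- premature_death_cost(dp, costs)
  cost_block <- tibble(
    drug_cost_standard = regimen_cost(reg_std, costs),
    drug_cost_combined = regimen_cost(reg_cmb, costs),
    years_of_life_lost = years_of_life_lost(dp),
    premature_death_cost = death_cost,
    expected_event_cost = expected_event_cost(mix, costs, death_cost)
  )

  params <- model_params(config)
  eval <- evaluate_model(params, config)

  standard <- eval$standard
  combined <- eval$combined
  ov <- config$replication
  if (!is.null(ov$strategy_standard)) {
    standard <- strategy_result(name = standard$name,
                                cost = ov$strategy_standard$cost,
                                effectiveness = ov$strategy_standard$effectiveness)
  }
  if (!is.null(ov$strategy_combined)) {
    combined <- strategy_result(name = combined$name,
                                cost = ov$strategy_combined$cost,
                                effectiveness = ov$strategy_combined$effectiveness)
  }
  cea <- icer(standard, combined)

  result <- structure(
    list(
      config = config,
      cohort = cohort,
      cohort_summary = summarize_cohort(cohort),
      risk = chain,
      costs = cost_block,
      params = params,
      traces = eval$traces,
      strategies = list(standard = standard, combined = combined),
      model_cea = eval$cea,
      cea = cea
    ),
    class = "base_case_result"
  )
  if (!is.null(out_dir)) write_base_case(result, out_dir)
  result
}

write_base_case <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, file) {
    write.csv(as.data.frame(df), file.path(out_dir, file), row.names = FALSE)
  }
  w(result$cohort, "cohort.csv")
  w(result$cohort_summary, "cohort_summary.csv")
  w(result$traces$standard$occupancy, "trace_standard.csv")
  w(result$traces$combined$occupancy, "trace_combined.csv")
  report <- list(
    risk = as.list(result$risk),
    costs = as.list(result$costs),
    params = result$params,
    strategies = list(
      standard = unclass(result$strategies$standard),
      combined = unclass(result$strategies$combined)
    ),
    model_cea = unclass(result$model_cea),
    cea = unclass(result$cea),
    per_cycle_cost = list(
      standard = as.list(result$traces$standard$per_cycle_cost),
      combined = as.list(result$traces$combined$per_cycle_cost)
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("<base_case_result>\n")
  cat(sprintf("  cohort: n=%d, baseline risk %.2f%%, treated %.2f%% (RRR %.0f%%)\n",
              nrow(x$cohort), x$risk$baseline_risk_10y,
              x$risk$treated_risk_10y, 100 * x$risk$rrr))
  cat(sprintf("  drug totals: %.2f / %.2f BRL; death cost %.2f BRL\n",
              x$costs$drug_cost_standard, x$costs$drug_cost_combined,
              x$costs$premature_death_cost))
  print(x$cea)
  invisible(x)
}

#' Check the model against packaged reference-case values
#'
#' Recomputes the desk-checkable quantities of the reference SUS
#' evaluation this model encodes (drug totals, years of life lost,
#' death cost, the LDL-to-risk chain, and the incremental cost of the
#' published global totals) and flags each against its packaged
#' expectation.
#'
#' @param config A [run_config()]; defaults to the replication
#'   configuration.
#' @return A tibble with columns `quantity`, `expected`, `computed`,
#'   `tolerance` (half a unit in the expectation's last printed place)
#'   and `pass`.
#' @export
check_reference_values <- function(config = default_run_config(replicate_globals = TRUE)) {
  res <- run_base_case(config)
  printed_cea <- icer(
    strategy_result(cost = 46522.44, effectiveness = 0.54, name = "standard"),
    strategy_result(cost = 236141.85, effectiveness = 0.73, name = "combined")
  )
  rows <- tibble(
    quantity = c("drug_cost_standard", "drug_cost_combined",
                 "years_of_life_lost", "premature_death_cost",
                 "ldl_on_treatment", "rrr_percent", "treated_risk_10y",
                 "arr", "incremental_cost_published_globals"),
    expected = c(7300.00, 223686.40, 7.7, 170385.60, 45.5, 35, 22.75,
                 12.25, 189619.41),
    computed = c(res$costs$drug_cost_standard, res$costs$drug_cost_combined,
                 res$costs$years_of_life_lost, res$costs$premature_death_cost,
                 res$risk$ldl_treated, 100 * res$risk$rrr,
                 res$risk$treated_risk_10y, res$risk$arr,
                 printed_cea$delta_cost),
    # half a unit in the last place each expectation is printed to
    tolerance = c(0.005, 0.005, 0.05, 0.005, 0.05, 0.5, 0.005, 0.005, 0.005)
  )
  mutate(rows, pass = abs(.data$expected - .data$computed) <= .data$tolerance)
}
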