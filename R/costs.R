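# Monetary payoffs, all in constant 2017 BRL: drug-regimen costs over
# the horizon, SUS hospitalization reimbursements per event, and the
# human-capital indirect cost of premature cardiovascular death
# (years of life lost x unemployment-adjusted mean annual income).

#' Unit cost inputs
#'
#' Defaults are the reference analysis' unit costs in 2017 BRL: SUS
#' hospitalization reimbursements for myocardial infarction (588.12),
#' ischemic stroke (463.21) and myocardial revascularization (6756.37);
#' wholesale atorvastatin 40 mg tablet (1.00); retail evolocumab 140 mg
#' syringe (901.61); mean annual income adjusted for unemployment
#' (22128.00).
#'
#' @param c_mi,c_stroke,c_revasc Hospitalization cost per event, BRL.
#' @param atorvastatin_tablet_40mg,evolocumab_syringe_140mg Unit drug
#'   prices, BRL.
#' @param annual_income_adjusted BRL per year, human-capital valuation.
#' @param currency_year Calendar year of the price basis.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(c_mi = 588.12,
                        c_stroke = 463.21,
                        c_revasc = 6756.37,
                        atorvastatin_tablet_40mg = 1.00,
                        evolocumab_syringe_140mg = 901.61,
                        annual_income_adjusted = 22128.00,
                        currency_year = 2017) {
  out <- list(
    c_mi = c_mi, c_stroke = c_stroke, c_revasc = c_revasc,
    atorvastatin_tablet_40mg = atorvastatin_tablet_40mg,
    evolocumab_syringe_140mg = evolocumab_syringe_140mg,
    annual_income_adjusted = annual_income_adjusted,
    currency_year = currency_year
  )
  for (f in setdiff(names(out), "currency_year")) check_number(out[[f]], f, min = 0)
  structure(out, class = "cost_inputs")
}

#' Drug regimen
#'
#' @param name Label.
#' @param atorvastatin_tablets_per_day 40 mg tablets per day (80 mg/day
#'   standard therapy = 2).
#' @param evolocumab_doses_per_year 140 mg syringes per year (0 for
#'   monotherapy; 24 for twice-monthly dosing).
#' @param horizon Years (default 10).
#' @return An object of class `regimen`.
#' @export
#' @examples
#' regimen_atorvastatin()
#' regimen_combined()
regimen <- function(name,
                    atorvastatin_tablets_per_day = 2,
                    evolocumab_doses_per_year = 0,
                    horizon = 10) {
  check_number(atorvastatin_tablets_per_day, "atorvastatin_tablets_per_day", min = 0)
  check_number(evolocumab_doses_per_year, "evolocumab_doses_per_year", min = 0)
  check_number(horizon, "horizon", min = 0)
  structure(
    list(name = name,
         atorvastatin_tablets_per_day = atorvastatin_tablets_per_day,
         evolocumab_doses_per_year = evolocumab_doses_per_year,
         horizon = horizon),
    class = "regimen"
  )
}

#' @rdname regimen
#' @param strict_interval If `TRUE`, twice-monthly evolocumab is dosed
#'   every 15 calendar days (365/15 = 24.33 doses/year) instead of the
#'   24 doses/year the reference costing used.
#' @export
regimen_atorvastatin <- function(horizon = 10) {
  regimen("atorvastatin", 2, 0, horizon)
}

#' @rdname regimen
#' @export
regimen_combined <- function(horizon = 10, strict_interval = FALSE) {
  doses <- if (strict_interval) 365 / 15 else 24
  regimen("atorvastatin_evolocumab", 2, doses, horizon)
}

#' Undiscounted drug cost of a regimen over its horizon
#'
#' Atorvastatin: tablets/day x 365 x years x tablet price. Evolocumab:
#' doses/year x years x syringe price. Discounting, when enabled, is
#' applied by the Markov engine, not here.
#'
#' @param reg A [regimen()].
#' @param costs [cost_inputs()].
#' @return Total BRL.
#' @export
#' @examples
#' regimen_cost(regimen_atorvastatin()) # 7300
#' regimen_cost(regimen_combined())     # 223686.40
regimen_cost <- function(reg, costs = cost_inputs()) {
  ator <- reg$atorvastatin_tablets_per_day * 365 * reg$horizon *
    costs$atorvastatin_tablet_40mg
  evo <- reg$evolocumab_doses_per_year * reg$horizon *
    costs$evolocumab_syringe_140mg
  ator + evo
}

#' Parameters of the premature-death costing
#'
#' The reference analysis assumes death occurs on average at year 5 of
#' the 10-year horizon (cohort mean age 63, so death at 68) and uses the
#' sample's sex-adjusted life expectancy of 75 years 8 months.
#'
#' @param mean_age Cohort mean age, years.
#' @param mean_age_at_death Assumed mean age at cardiovascular death.
#' @param life_expectancy Sex-adjusted life expectancy, years.
#' @param rounding_yll Decimals to which years of life lost are rounded
#'   before monetisation (default 1, the reference convention).
#' @return An object of class `death_cost_params`.
#' @export
death_cost_params <- function(mean_age = 63,
                              mean_age_at_death = 68,
                              life_expectancy = 75 + 8 / 12,
                              rounding_yll = 1) {
  check_number(mean_age, "mean_age", min = 0)
  check_number(mean_age_at_death, "mean_age_at_death", min = mean_age)
  check_number(life_expectancy, "life_expectancy", min = mean_age_at_death)
  check_number(rounding_yll, "rounding_yll", min = 0)
  structure(
    list(mean_age = mean_age, mean_age_at_death = mean_age_at_death,
         life_expectancy = life_expectancy, rounding_yll = rounding_yll),
    class = "death_cost_params"
  )
}

#' Years of life lost to premature cardiovascular death
#'
#' `life_expectancy - mean_age_at_death`, rounded half-up to
#' `rounding_yll` decimals.
#'
#' @param p [death_cost_params()].
#' @return Years.
#' @export
#' @examples
#' years_of_life_lost() # 7.7
years_of_life_lost <- function(p = death_cost_params()) {
  round_half_up(p$life_expectancy - p$mean_age_at_death, p$rounding_yll)
}

#' Human-capital cost of a premature cardiovascular death
#'
#' Years of life lost multiplied by the unemployment-adjusted mean
#' annual income.
#'
#' @param p [death_cost_params()].
#' @param costs [cost_inputs()].
#' @return BRL.
#' @export
#' @examples
#' premature_death_cost() # 170385.60
premature_death_cost <- function(p = death_cost_params(), costs = cost_inputs()) {
  years_of_life_lost(p) * costs$annual_income_adjusted
}

#' Composite-endpoint event mix
#'
#' Weights of the four composite-endpoint components (myocardial
#' infarction, ischemic stroke, revascularization, cardiovascular
#' death); must lie on the simplex. The packaged default,
#' [event_mix_default()], is externally sourced: first-event counts in
#' the placebo arm of the FOURIER trial, normalized.
#'
#' @param w_mi,w_stroke,w_revasc,w_death Non-negative weights summing
#'   to 1 (tolerance 1e-9).
#' @return An object of class `event_mix` (named numeric vector).
#' @export
event_mix <- function(w_mi, w_stroke, w_revasc, w_death) {
  w <- c(mi = w_mi, stroke = w_stroke, revasc = w_revasc, cv_death = w_death)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort_field("event_mix", "weights must be finite and non-negative")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    abort_field("event_mix", sprintf("weights must sum to 1, got %.12f", sum(w)))
  }
  structure(w, class = c("event_mix", "numeric"))
}

#' @rdname event_mix
#' @export
event_mix_default <- function() {
  path <- system.file("extdata", "event_mix_fourier_placebo.csv", package = "evocea")
  counts <- read.csv(path, stringsAsFactors = FALSE)
  w <- counts$count / sum(counts$count)
  names(w) <- counts$event
  event_mix(w[["mi"]], w[["stroke"]], w[["revasc"]], w[["cv_death"]])
}

#' Expected cost of one composite event
#'
#' Mix-weighted mean of the per-component costs, with cardiovascular
#' death valued at the human-capital death cost.
#'
#' @param mix An [event_mix()].
#' @param costs [cost_inputs()].
#' @param death_cost BRL per cardiovascular death, by default
#'   [premature_death_cost()] under the default parameters.
#' @return BRL per composite event.
#' @export
expected_event_cost <- function(mix = event_mix_default(),
                                costs = cost_inputs(),
                                death_cost = premature_death_cost(costs = costs)) {
  if (!inherits(mix, "event_mix")) mix <- do.call(event_mix, as.list(unname(mix)))
  sum(mix * c(costs$c_mi, costs$c_stroke, costs$c_revasc, death_cost))
}

# per-destination event costs used by the Markov engine
event_state_costs <- function(costs = cost_inputs(),
                              death_cost = premature_death_cost(costs = costs)) {
  c(mi = costs$c_mi, stroke = costs$c_stroke,
    revasc = costs$c_revasc, cv_death = death_cost)
}
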