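# Translation of LDL-c lowering into 10-year composite-event risk.
#
# The effect of adding evolocumab to high-intensity statin therapy is
# modelled in two steps: the trial-observed additional 59% reduction in
# LDL-c, and the meta-analytic dose-response of 21% fewer major
# cardiovascular events per 39 mg/dL of LDL-c lowering, extrapolated to
# the 10-year horizon.

#' Parameters of the LDL-to-risk translation
#'
#' @param ldl_reduction_fraction Additional proportional LDL-c reduction
#'   attributed to evolocumab on top of statin therapy (default 0.59).
#' @param rrr_per_block Relative risk reduction per block of LDL-c
#'   lowering (default 0.21).
#' @param block_size Size of the block in mg/dL (default 39).
#' @param scaling `"linear"` (default) scales the per-block effect
#'   proportionally, capped at 1; `"compounding"` applies it
#'   multiplicatively, `1 - (1 - rrr_per_block)^(delta/block)`.
#' @param rounding `"reference"` (default) rounds the relative risk
#'   reduction to the nearest whole percent before use, matching the
#'   reference analysis' arithmetic; `"raw"` keeps full precision.
#' @return An object of class `translation_params`.
#' @export
#' @examples
#' translation_params()
translation_params <- function(ldl_reduction_fraction = 0.59,
                               rrr_per_block = 0.21,
                               block_size = 39,
                               scaling = c("linear", "compounding"),
                               rounding = c("reference", "raw")) {
  # 0 is the degenerate no-treatment case and is allowed
  check_number(ldl_reduction_fraction, "ldl_reduction_fraction",
               min = 0, max = 1 - 1e-12)
  check_number(rrr_per_block, "rrr_per_block", min = 1e-12, max = 1 - 1e-12)
  check_number(block_size, "block_size", min = 1e-12)
  structure(
    list(
      ldl_reduction_fraction = ldl_reduction_fraction,
      rrr_per_block = rrr_per_block,
      block_size = block_size,
      scaling = arg_match(scaling),
      rounding = arg_match(rounding)
    ),
    class = "translation_params"
  )
}

#' Mean baseline 10-year risk of a cohort
#'
#' The mean of per-patient category midpoints, or a fixed override in
#' replication mode (the reference analysis reports the cohort mean,
#' 35%, directly).
#'
#' @param patients Patient tibble; passed through [assign_category()] if
#'   the `risk_10y` column is absent. Ignored when `override` is given.
#' @param override Optional risk in percent returned unchanged.
#' @return Baseline 10-year risk in percent.
#' @export
#' @examples
#' cohort_baseline_risk(override = 35)
cohort_baseline_risk <- function(patients = NULL, override = NULL) {
  if (!is.null(override)) {
    check_number(override, "override", min = 0, max = 100)
    return(override)
  }
  if (is.null(patients) || nrow(as_tibble(patients)) == 0L) {
    abort_field("patients", "must be non-empty when no override is given")
  }
  patients <- as_tibble(patients)
  if (!"risk_10y" %in% names(patients)) patients <- assign_category(patients)
  mean(patients$risk_10y)
}

#' On-treatment LDL-c
#'
#' @param ldl LDL-c in mg/dL (> 0), scalar or vector.
#' @param params [translation_params()].
#' @return LDL-c after the proportional reduction, mg/dL.
#' @export
#' @examples
#' ldl_on_treatment(111) # 45.5
ldl_on_treatment <- function(ldl, params = translation_params()) {
  if (!is.numeric(ldl) || any(is.na(ldl)) || any(ldl <= 0)) {
    abort_field("ldl", "must be positive")
  }
  ldl * (1 - params$ldl_reduction_fraction)
}

#' Relative risk reduction from an LDL-c decrement
#'
#' Linear scaling (default): `rrr_per_block * delta_ldl / block_size`,
#' capped at 1. Compounding: `1 - (1 - rrr_per_block)^(delta_ldl /
#' block_size)`. With `rounding = "reference"` the result is rounded to
#' the nearest whole percent, the convention under which the reference
#' analysis' chain 111 -> 45.5 mg/dL -> 35% RRR is exact.
#'
#' @param delta_ldl Achieved LDL-c reduction in mg/dL (>= 0).
#' @param params [translation_params()].
#' @return Relative risk reduction as a fraction in `[0, 1]`.
#' @export
#' @examples
#' relative_risk_reduction(65.5)                                      # 0.35
#' relative_risk_reduction(65.5, translation_params(rounding = "raw")) # 0.3527
relative_risk_reduction <- function(delta_ldl, params = translation_params()) {
  if (!is.numeric(delta_ldl) || any(is.na(delta_ldl)) || any(delta_ldl < 0)) {
    abort_field("delta_ldl", "must be non-negative")
  }
  blocks <- delta_ldl / params$block_size
  rrr <- switch(params$scaling,
    linear = pmin(params$rrr_per_block * blocks, 1),
    compounding = 1 - (1 - params$rrr_per_block)^blocks
  )
  if (params$rounding == "reference") rrr <- round_half_up(rrr * 100, 0) / 100
  rrr
}

#' Treated risk, relative and absolute risk reduction
#'
#' @param baseline Baseline 10-year risk in percent.
#' @param rrr Relative risk reduction as a fraction in `[0, 1]`.
#' @return A one-row tibble with `baseline_risk_10y`, `treated_risk_10y`
#'   (percent), `rrr` (fraction), `arr` (percentage points, exactly
#'   `baseline - treated`) and `delta_ldl` if supplied via attribute.
#' @export
#' @examples
#' treated_risk(35, 0.35) # treated 22.75, arr 12.25
treated_risk <- function(baseline, rrr) {
  check_number(baseline, "baseline", min = 0, max = 100)
  check_number(rrr, "rrr", min = 0, max = 1)
  treated <- baseline * (1 - rrr)
  tibble(
    baseline_risk_10y = baseline,
    treated_risk_10y = treated,
    rrr = rrr,
    arr = baseline - treated
  )
}

#' Full risk-translation chain
#'
#' Applies [ldl_on_treatment()], [relative_risk_reduction()] and
#' [treated_risk()] in sequence, starting from a baseline LDL-c and a
#' baseline 10-year risk.
#'
#' @param ldl Baseline LDL-c, mg/dL. The reference analysis applies the
#'   chain to the cohort mean (111), not per patient.
#' @param baseline_risk Baseline 10-year risk, percent.
#' @param params [translation_params()].
#' @return One-row tibble: `ldl_baseline`, `ldl_treated`, `delta_ldl`,
#'   `rrr`, `baseline_risk_10y`, `treated_risk_10y`, `arr`.
#' @export
#' @examples
#' translate_risk(111, 35)
translate_risk <- function(ldl, baseline_risk, params = translation_params()) {
  ldl_t <- ldl_on_treatment(ldl, params)
  delta <- ldl - ldl_t
  rrr <- relative_risk_reduction(delta, params)
  est <- treated_risk(baseline_risk, rrr)
  dplyr::bind_cols(
    tibble(ldl_baseline = ldl, ldl_treated = ldl_t, delta_ldl = delta),
    est
  )
}
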