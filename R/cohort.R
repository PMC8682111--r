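# Synthetic secondary-prevention cohort generator. Emulates the marginal
# structure of the 61-patient outpatient CAD sample the model was built
# on: comorbidity flags drawn independently at their reported
# prevalences, continuous variables from moment-matched truncated
# normals under the trial eligibility bounds (age 40-85, LDL-c >= 70).

#' Specification of a synthetic cohort
#'
#' Collects the marginal parameters of the cohort to generate. Defaults
#' reproduce the published 61-patient secondary-prevention sample: age
#' 63 (SD 11) years, 52% male, 83% hypertension, 42% diabetes, 31%
#' current smoking, 54% prior myocardial infarction, no prior stroke,
#' 10% on ezetimibe, LDL-c 111 (SD 34) mg/dL floored at 70, HDL-c 45
#' (13), triglycerides 159 (97). All members have an acute coronary
#' syndrome within the past year (`prop_recent_acs = 1`), the cohort's
#' inclusion criterion; chronic kidney disease, peripheral artery
#' disease and familial hypercholesterolemia were not reported and
#' default to prevalence 0 but are configurable.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param mean_age,sd_age Age distribution (years), truncated to
#'   `[age_min, age_max]`.
#' @param age_min,age_max Trial eligibility age bounds (years).
#' @param prop_male,prop_htn,prop_dm,prop_smoking,prop_prior_mi,prop_prior_stroke,prop_ezetimibe,prop_ckd,prop_pad,prop_fh,prop_recent_acs
#'   Marginal prevalences in `[0, 1]`.
#' @param mean_ldl,sd_ldl LDL-c (mg/dL), truncated normal with floor
#'   `ldl_floor`.
#' @param ldl_floor Eligibility floor for LDL-c (mg/dL).
#' @param mean_hdl,sd_hdl,mean_tg,sd_tg HDL-c and triglycerides (mg/dL),
#'   floored at 0.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' cohort_spec(n = 61, seed = 1)
cohort_spec <- function(n = 61,
                        seed = 1L,
                        mean_age = 63, sd_age = 11,
                        age_min = 40, age_max = 85,
                        prop_male = 0.52,
                        prop_htn = 0.83,
                        prop_dm = 0.42,
                        prop_smoking = 0.31,
                        prop_prior_mi = 0.54,
                        prop_prior_stroke = 0,
                        prop_ezetimibe = 0.10,
                        prop_ckd = 0,
                        prop_pad = 0,
                        prop_fh = 0,
                        prop_recent_acs = 1,
                        mean_ldl = 111, sd_ldl = 34, ldl_floor = 70,
                        mean_hdl = 45, sd_hdl = 13,
                        mean_tg = 159, sd_tg = 97) {
  spec <- list(
    n = n, seed = seed,
    mean_age = mean_age, sd_age = sd_age, age_min = age_min, age_max = age_max,
    prop_male = prop_male, prop_htn = prop_htn, prop_dm = prop_dm,
    prop_smoking = prop_smoking, prop_prior_mi = prop_prior_mi,
    prop_prior_stroke = prop_prior_stroke, prop_ezetimibe = prop_ezetimibe,
    prop_ckd = prop_ckd, prop_pad = prop_pad, prop_fh = prop_fh,
    prop_recent_acs = prop_recent_acs,
    mean_ldl = mean_ldl, sd_ldl = sd_ldl, ldl_floor = ldl_floor,
    mean_hdl = mean_hdl, sd_hdl = sd_hdl,
    mean_tg = mean_tg, sd_tg = sd_tg
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  check_number(spec$n, "n", min = 1)
  if (spec$n != as.integer(spec$n)) abort_field("n", "must be a whole number")
  check_number(spec$seed, "seed")
  for (f in c("prop_male", "prop_htn", "prop_dm", "prop_smoking",
              "prop_prior_mi", "prop_prior_stroke", "prop_ezetimibe",
              "prop_ckd", "prop_pad", "prop_fh", "prop_recent_acs")) {
    check_number(spec[[f]], f, min = 0, max = 1)
  }
  for (f in c("sd_age", "sd_ldl", "sd_hdl", "sd_tg")) {
    check_number(spec[[f]], f, min = 0)
  }
  check_number(spec$mean_age, "mean_age", min = spec$age_min, max = spec$age_max)
  check_number(spec$age_min, "age_min", min = 0)
  if (spec$age_min >= spec$age_max) abort_field("age_min", "must be below `age_max`")
  check_number(spec$ldl_floor, "ldl_floor", min = 0)
  check_number(spec$mean_ldl, "mean_ldl", min = spec$ldl_floor)
  check_number(spec$mean_hdl, "mean_hdl", min = 1e-9)
  check_number(spec$mean_tg, "mean_tg", min = 1e-9)
  invisible(spec)
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n` patients with independent comorbidity flags at the
#' specified prevalences and continuous variables from truncated
#' normals whose parents are moment-matched (see [fit_truncnorm()]) so
#' the truncated distributions reproduce the specified means and SDs.
#' Identical `(spec, seed)` give identical cohorts; the global RNG
#' state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient and columns `id`, `age`,
#'   `sex` (`"male"`/`"female"`), the logical flags `hypertension`,
#'   `diabetes`, `smoking`, `prior_mi`, `prior_stroke`, `ckd`, `pad`,
#'   `recent_acs`, `familial_hyperchol`, `ezetimibe`, and `ldl`, `hdl`,
#'   `tg` in mg/dL.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 61, seed = 1))
#' dplyr::count(cohort, sex)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, as.list(spec))
  validate_cohort_spec(spec)
  n <- as.integer(spec$n)

  fit_age <- fit_truncnorm(spec$mean_age, spec$sd_age, spec$age_min, spec$age_max)
  fit_ldl <- fit_truncnorm(spec$mean_ldl, spec$sd_ldl, lower = spec$ldl_floor)
  fit_hdl <- fit_truncnorm(spec$mean_hdl, spec$sd_hdl, lower = 0)
  fit_tg  <- fit_truncnorm(spec$mean_tg, spec$sd_tg, lower = 0)

  withr::with_seed(spec$seed, {
    tibble(
      id = sprintf("pt%05d", seq_len(n)),
      age = rtruncnorm_fitted(n, fit_age),
      sex = ifelse(runif(n) < spec$prop_male, "male", "female"),
      hypertension = runif(n) < spec$prop_htn,
      diabetes = runif(n) < spec$prop_dm,
      smoking = runif(n) < spec$prop_smoking,
      prior_mi = runif(n) < spec$prop_prior_mi,
      prior_stroke = runif(n) < spec$prop_prior_stroke,
      ckd = runif(n) < spec$prop_ckd,
      pad = runif(n) < spec$prop_pad,
      recent_acs = runif(n) < spec$prop_recent_acs,
      familial_hyperchol = runif(n) < spec$prop_fh,
      ezetimibe = runif(n) < spec$prop_ezetimibe,
      ldl = rtruncnorm_fitted(n, fit_ldl),
      hdl = rtruncnorm_fitted(n, fit_hdl),
      tg = rtruncnorm_fitted(n, fit_tg)
    )
  })
}

#' Summarise a cohort in the published table layout
#'
#' Means and SDs for continuous variables, counts and percentages for
#' flags, plus LDL-c strata (70-99, >= 100 mg/dL).
#'
#' @param patients Patient tibble from [generate_cohort()].
#' @return A tibble with columns `variable`, `type`
#'   (`"continuous"`/`"count"`), `mean`, `sd`, `n`, `pct`.
#' @export
#' @examples
#' summarize_cohort(generate_cohort(cohort_spec(n = 61, seed = 1)))
summarize_cohort <- function(patients) {
  patients <- as_tibble(patients)
  if (nrow(patients) == 0L) abort_field("patients", "must be non-empty")
  cont <- function(var, x) {
    tibble(variable = var, type = "continuous",
           mean = mean(x), sd = sd(x), n = NA_real_, pct = NA_real_)
  }
  flag <- function(var, x) {
    tibble(variable = var, type = "count",
           mean = NA_real_, sd = NA_real_,
           n = sum(x), pct = 100 * mean(x))
  }
  bind_rows(
    cont("age", patients$age),
    flag("male", patients$sex == "male"),
    flag("hypertension", patients$hypertension),
    flag("diabetes", patients$diabetes),
    flag("smoking", patients$smoking),
    flag("prior_mi", patients$prior_mi),
    flag("prior_stroke", patients$prior_stroke),
    flag("ezetimibe", patients$ezetimibe),
    cont("ldl", patients$ldl),
    flag("ldl_70_99", patients$ldl >= 70 & patients$ldl < 100),
    flag("ldl_ge_100", patients$ldl >= 100),
    cont("hdl", patients$hdl),
    cont("tg", patients$tg)
  )
}
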