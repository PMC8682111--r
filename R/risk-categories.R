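# 10-year risk categories for statin-treated secondary-prevention
# patients, with the eligibility rule each category encodes. The bands
# ship as a plain CSV (inst/extdata/risk_categories.csv) with columns
# name, low, high; row order is the published table order and breaks
# midpoint ties.

#' Published 10-year cardiovascular risk categories
#'
#' Returns the table of high-risk categories for patients on statin
#' therapy, each with a projected 10-year composite-event risk band
#' (percent). A patient's risk is the midpoint of the highest-midpoint
#' band they qualify for (see [assign_category()]).
#'
#' @return A tibble with columns `name`, `low`, `high` and `midpoint`
#'   (all risks in percent), in table order.
#' @export
#' @examples
#' risk_categories()
risk_categories <- function() {
  path <- system.file("extdata", "risk_categories.csv", package = "evocea")
  cats <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  cats$midpoint <- purrr::map2_dbl(cats$low, cats$high, category_midpoint)
  cats
}

#' Midpoint of a risk band
#'
#' The point estimate for a risk category is the arithmetic mean of its
#' band ends.
#'
#' @param low,high Band ends in percent, `0 < low <= high <= 100`.
#' @return Midpoint in percent.
#' @export
#' @examples
#' category_midpoint(28, 38) # 33
category_midpoint <- function(low, high) {
  if (length(low) != 1L || length(high) != 1L) {
    abort_field("low/high", "must be single numbers")
  }
  check_number(low, "low", min = 1e-12, max = 100)
  check_number(high, "high", min = 1e-12, max = 100)
  if (low > high) abort_field("low", "must not exceed `high`")
  (low + high) / 2
}

# eligibility predicates, one per category row; each takes the cohort
# tibble and returns a logical vector. All cohort members have clinical
# ASCVD (CAD with prior ACS) by construction.
category_rules <- list(
  ascvd_diabetes_ckd            = function(p) p$diabetes & p$ckd,
  ascvd_diabetes_no_ckd         = function(p) p$diabetes & !p$ckd,
  ascvd_ckd                     = function(p) p$ckd,
  recent_acs                    = function(p) p$recent_acs,
  # "poorly controlled risk factors": current smoking despite secondary
  # prevention counts; hypertension/diabetes under treatment do not.
  cad_uncontrolled_risk_factors = function(p) p$smoking,
  cad_peripheral_artery_disease = function(p) p$pad,
  cad_age_65_plus               = function(p) p$age >= 65,
  ischemic_stroke_male          = function(p) p$prior_stroke & p$sex == "male",
  cad_familial_hypercholesterolemia =
    function(p) p$familial_hyperchol | p$ldl >= 190
)

#' Assign each patient the highest-risk category they qualify for
#'
#' Evaluates every category's eligibility rule against each patient and
#' keeps the qualifying category with the highest band midpoint;
#' midpoint ties break by table order. Every secondary-prevention
#' patient qualifies for at least one category (a patient matching none
#' signals malformed input and raises an error).
#'
#' @param patients A patient tibble as produced by [generate_cohort()]
#'   (columns `age`, `sex`, `diabetes`, `smoking`, `prior_stroke`,
#'   `ckd`, `pad`, `recent_acs`, `familial_hyperchol`, `ldl` are used).
#' @param categories Category table, by default [risk_categories()].
#' @return The input tibble with columns `category`, `risk_low`,
#'   `risk_high` and `risk_10y` (the midpoint, percent) appended.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' assign_category(cohort)
assign_category <- function(patients, categories = risk_categories()) {
  patients <- as_tibble(patients)
  if (nrow(patients) == 0L) abort_field("patients", "must be non-empty")
  elig <- vapply(
    categories$name,
    function(nm) {
      rule <- category_rules[[nm]]
      if (is.null(rule)) abort_field("categories", paste("unknown category", nm))
      as.logical(rule(patients))
    },
    logical(nrow(patients))
  )
  elig <- matrix(elig, nrow = nrow(patients))
  if (any(rowSums(elig) == 0L)) {
    abort(
      "patient matches no risk category; malformed input for a secondary-prevention cohort",
      class = "evocea_no_category_error"
    )
  }
  # highest midpoint among eligible; ties -> earliest table row
  pick <- apply(elig, 1L, function(ok) {
    mids <- ifelse(ok, categories$midpoint, -Inf)
    which.max(mids)
  })
  patients$category <- categories$name[pick]
  patients$risk_low <- categories$low[pick]
  patients$risk_high <- categories$high[pick]
  patients$risk_10y <- categories$midpoint[pick]
  patients
}
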