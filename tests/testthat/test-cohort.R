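test_that("identical spec and seed give identical cohorts", {
  spec <- cohort_spec(n = 61, seed = 1)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 61)
  expect_false(identical(a, generate_cohort(cohort_spec(n = 61, seed = 2))))
})

test_that("degenerate proportions are honoured exactly", {
  co <- generate_cohort(cohort_spec(n = 10, seed = 5, prop_dm = 1))
  expect_true(all(co$diabetes))
  co0 <- generate_cohort(cohort_spec(n = 10, seed = 5, prop_dm = 0))
  expect_false(any(co0$diabetes))
})

test_that("generated marginals converge to spec values", {
  co <- generate_cohort(cohort_spec(n = 100000, seed = 7))
  n <- nrow(co)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex == "male") - 0.52), 3 * se(0.52))
  expect_lt(abs(mean(co$hypertension) - 0.83), 3 * se(0.83))
  expect_lt(abs(mean(co$diabetes) - 0.42), 3 * se(0.42))
  expect_lt(abs(mean(co$smoking) - 0.31), 3 * se(0.31))
  # moment-matched truncated normal reproduces the target LDL moments
  expect_lt(abs(mean(co$ldl) - 111), 1)
  expect_lt(abs(sd(co$ldl) - 34), 1)
  expect_lt(abs(mean(co$age) - 63), 0.2)
  expect_lt(abs(mean(co$tg) - 159), 1.5)
})

test_that("LDL stratum above 100 mg/dL is consistent with the observed 35/61", {
  co <- generate_cohort(cohort_spec(n = 100000, seed = 11))
  p_ge_100 <- mean(co$ldl >= 100)
  # the fitted truncated normal implies ~0.53; the study observed 57%
  # of 61 patients, so agreement is judged at that sample's binomial SE
  expect_lt(abs(p_ge_100 - 0.57), 3 * sqrt(0.57 * 0.43 / 61))
})

test_that("every generated patient satisfies the profile invariants", {
  specs <- list(
    cohort_spec(n = 200, seed = 1),
    cohort_spec(n = 200, seed = 2, mean_age = 70, sd_age = 9),
    cohort_spec(n = 200, seed = 3, mean_ldl = 90, sd_ldl = 15),
    cohort_spec(n = 200, seed = 4, mean_tg = 200, sd_tg = 120,
                prop_ckd = 0.5, prop_pad = 0.5, prop_fh = 0.2)
  )
  for (spec in specs) {
    co <- generate_cohort(spec)
    expect_true(all(co$age >= spec$age_min & co$age <= spec$age_max))
    expect_true(all(co$ldl >= spec$ldl_floor))
    expect_true(all(co$hdl > 0) && all(co$tg > 0))
    flags <- c("hypertension", "diabetes", "smoking", "prior_mi",
               "prior_stroke", "ckd", "pad", "recent_acs",
               "familial_hyperchol", "ezetimibe")
    expect_true(all(vapply(co[flags], is.logical, logical(1))))
    expect_true(all(co$sex %in% c("male", "female")))
  }
})

test_that("unattainable truncated-normal moments are rejected", {
  # a normal truncated at 0 cannot have CV above sqrt(pi/2 - 1) ~ 0.7555,
  # so mean 100 / sd 150 at floor 0 has no moment-matched parent
  expect_error(fit_truncnorm(100, 150, lower = 0), "moments")
})

test_that("invalid cohort specs are rejected with the offending field", {
  expect_error(cohort_spec(n = 0), "n")
  expect_error(cohort_spec(prop_dm = 1.2), "prop_dm")
  expect_error(cohort_spec(sd_ldl = -1), "sd_ldl")
  expect_error(cohort_spec(mean_ldl = 60, ldl_floor = 70), "mean_ldl")
})

test_that("category assignment picks the highest-midpoint eligible band", {
  # diabetic with clinical ASCVD, no CKD, nothing else: the diabetes
  # band without kidney disease (26-29)
  p <- make_patient(diabetes = TRUE, recent_acs = FALSE)
  expect_equal(assign_category(p)$category, "ascvd_diabetes_no_ckd")
  expect_equal(assign_category(p)$risk_10y, 27.5)

  # age 70 with CAD and recent ACS: 21-54 (midpoint 37.5) beats 32
  p <- make_patient(age = 70)
  expect_equal(assign_category(p)$category, "cad_age_65_plus")
  expect_equal(assign_category(p)$risk_10y, 37.5)

  # CAD + peripheral artery disease: 43-55 dominates everything
  p <- make_patient(age = 70, pad = TRUE, diabetes = TRUE)
  expect_equal(assign_category(p)$category, "cad_peripheral_artery_disease")
  expect_equal(assign_category(p)$risk_10y, 49)

  # no qualifying band signals malformed input
  p <- make_patient(recent_acs = FALSE)
  expect_error(assign_category(p), class = "evocea_no_category_error")
})

test_that("category assignment is total and idempotent over generated cohorts", {
  co <- generate_cohort(cohort_spec(n = 500, seed = 9, prop_ckd = 0.3,
                                    prop_pad = 0.2, prop_prior_stroke = 0.2,
                                    prop_fh = 0.1))
  a <- assign_category(co)
  expect_equal(nrow(a), 500)
  expect_false(anyNA(a$category))
  expect_identical(assign_category(a[names(co)]), a)
  cats <- risk_categories()
  expect_true(all(a$risk_10y %in% cats$midpoint))
})

test_that("cohort summary has the published table structure", {
  co <- generate_cohort(cohort_spec(n = 61, seed = 1))
  s <- summarize_cohort(co)
  expect_setequal(
    s$variable,
    c("age", "male", "hypertension", "diabetes", "smoking", "prior_mi",
      "prior_stroke", "ezetimibe", "ldl", "ldl_70_99", "ldl_ge_100",
      "hdl", "tg")
  )
  counts <- dplyr::filter(s, type == "count")
  expect_true(all(counts$n >= 0 & counts$n <= 61))
  expect_true(all(counts$pct >= 0 & counts$pct <= 100))

  one <- summarize_cohort(make_patient(ldl = 80))
  expect_equal(dplyr::filter(one, variable == "ldl_70_99")$n, 1)
  expect_equal(dplyr::filter(one, variable == "ldl_70_99")$pct, 100)
  expect_error(summarize_cohort(make_patient()[0, ]), "non-empty")
})
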