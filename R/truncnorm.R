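# Truncated-normal sampling and moment matching.
#
# Published cohort tables report the mean and SD of variables that are
# subject to hard eligibility bounds (e.g. LDL-c >= 70 mg/dL). Sampling a
# normal with those moments and then truncating shifts the realised mean,
# so the generator moment-matches: it solves for the parent (mu, sigma)
# whose *truncated* distribution has the requested mean and SD.

# mean and sd of N(mu, sigma) truncated to [lower, upper]
truncnorm_moments <- function(mu, sigma, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  lam <- (da - db) / z
  m <- mu + sigma * lam
  # a*dnorm(a) -> 0 as a -> -Inf, likewise at +Inf
  ad <- if (is.finite(a)) a * da else 0
  bd <- if (is.finite(b)) b * db else 0
  v <- sigma^2 * (1 + (ad - bd) / z - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Fit a truncated normal by moment matching
#'
#' Finds the parent `(mu, sigma)` such that a normal truncated to
#' `[lower, upper]` has the target mean and SD. Used by the cohort
#' generator so that published sample moments are reproduced in
#' expectation despite eligibility floors (LDL-c >= 70 mg/dL, age in
#' 40-85).
#'
#' @param mean,sd Target mean and SD of the truncated distribution.
#' @param lower,upper Truncation bounds (either may be infinite).
#' @return A list with elements `mu`, `sigma`, `lower`, `upper`.
#' @export
#' @examples
#' fit <- fit_truncnorm(111, 34, lower = 70)
#' # the truncated distribution of the fitted parent has mean 111, sd 34
fit_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  check_number(mean, "mean")
  check_number(sd, "sd", min = 0)
  if (lower >= upper) abort_field("lower", "must be below `upper`")
  if (sd == 0) {
    mu <- min(max(mean, lower), upper)
    return(list(mu = mu, sigma = 0, lower = lower, upper = upper))
  }
  obj <- function(par) {
    st <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (st[["mean"]] - mean)^2 + (st[["sd"]] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-6) {
    abort_field("mean/sd", "no truncated normal attains the requested moments")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower, upper = upper)
}

# inverse-CDF sampler for the fitted truncated normal
rtruncnorm_fitted <- function(n, fit) {
  if (fit$sigma == 0) return(rep(fit$mu, n))
  plo <- pnorm(fit$lower, fit$mu, fit$sigma)
  phi <- pnorm(fit$upper, fit$mu, fit$sigma)
  qnorm(runif(n, plo, phi), fit$mu, fit$sigma)
}
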