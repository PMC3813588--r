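# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use centered-covariance arithmetic, not the
# cumulative-share formulas used by the package.

# unweighted concentration index: 2 * population cov(y, r) / mean(y)
oracle_rci <- function(y, r) {
  n <- length(y)
  cov_pop <- sum((y - mean(y)) * (r - mean(r))) / n
  2 * cov_pop / mean(y)
}

# weighted analogue with explicitly centered products
oracle_rci_weighted <- function(y, r, w) {
  w <- w / sum(w)
  mu <- sum(w * y)
  rbar <- sum(w * r)
  2 * sum(w * (y - mu) * (r - rbar)) / mu
}

# trapezoid area between the concentration curve and the diagonal, doubled
oracle_curve_area <- function(curve) {
  x <- curve$pop_share
  y <- curve$outcome_share
  dx <- diff(x)
  heights <- (y[-1] + y[-length(y)]) / 2 - (x[-1] + x[-length(x)]) / 2
  -2 * sum(dx * heights)   # curve below the diagonal => positive index
}

quiet <- function(expr) suppressMessages(expr)

small_survey <- function(n, seed, ...) {
  quiet(generate_survey(survey_config(n_children = n, seed = seed, ...)))
}

# generator settings with a nearly linear latent-to-score map (negligible
# floor/ceiling censoring), used wherever exact coefficient recovery matters
recovery_config <- function(n, seed, ...) {
  survey_config("2000", n_children = n, seed = seed,
                noise_sd = 0.5, score_scale = 2.5, score_center = 6,
                age_slope = 0.25, ...)
}
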