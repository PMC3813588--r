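#' Recover the mean from a minimum, median, maximum and sample size
#'
#' Point estimate of a sample mean from its extremes and median, after Hozo,
#' Djulbegovic and Hozo (2005): the weighted combination `(a + 2m + b) / 4`
#' for small samples, and the median itself once the sample is large enough
#' that the extremes carry little information (`n > mean_cutoff`).
#'
#' @param a,m,b Sample minimum, median and maximum (vectorized; recycled to a
#'   common length).
#' @param n Sample size(s).
#' @param mean_cutoff Size above which the median is used directly; default 25
#'   is the published recommendation.
#' @return Numeric vector of estimated means.
#' @export
#' @examples
#' hozo_mean(0, 10, 12, 20)   # (0 + 20 + 12) / 4 = 8
#' hozo_mean(0, 10, 12, 50)   # large n: the median, 10
hozo_mean <- function(a, m, b, n, mean_cutoff = 25) {
  check_hozo(a, m, b, n)
  ifelse(n <= mean_cutoff, (a + 2 * m + b) / 4, m)
}

#' Recover the standard deviation from a minimum, median, maximum and sample size
#'
#' Hozo et al.'s size-dependent rules: for very small samples the variance
#' formula `(1/12) * ((a - 2m + b)^2 / 4 + (b - a)^2)`; for moderate samples
#' range/4; for large samples range/6.
#'
#' @inheritParams hozo_mean
#' @param small_cutoff,large_cutoff Branch thresholds: the variance formula is
#'   used for `n <= small_cutoff` (default 15), range/4 up to `large_cutoff`
#'   (default 70), range/6 beyond.
#' @return Numeric vector of estimated standard deviations; 0 when `a == b`.
#' @export
#' @examples
#' hozo_sd(0, 6, 12, 50)    # range/4 = 3
#' hozo_sd(0, 6, 12, 100)   # range/6 = 2
hozo_sd <- function(a, m, b, n, small_cutoff = 15, large_cutoff = 70) {
  check_hozo(a, m, b, n)
  small <- sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12)
  ifelse(n <= small_cutoff, small,
         ifelse(n <= large_cutoff, (b - a) / 4, (b - a) / 6))
}

check_hozo <- function(a, m, b, n) {
  if (any(!is.finite(a) | !is.finite(m) | !is.finite(b))) {
    abort("summary values must be finite", class = "cogineq_domain_error")
  }
  if (any(a > b) || any(m < a) || any(m > b)) {
    abort("need minimum <= median <= maximum", class = "cogineq_domain_error")
  }
  if (any(!is.finite(n) | n < 1)) {
    abort("sample size must be >= 1", class = "cogineq_domain_error")
  }
  invisible(NULL)
}
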