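#' Weighted fractional ranks of a living-standards variable
#'
#' The fractional rank of an observation is the midpoint of its cumulative
#' weight interval after sorting by the ranking variable: with weights
#' normalized to sum 1 and rows sorted, `R_i = sum(w_j, j < i) + w_i / 2`.
#' The weighted mean of the returned ranks is exactly 1/2 for every input.
#'
#' @param x Numeric ranking variable (no missing values).
#' @param w Positive weights; `NULL` for equal weights.
#' @param ties `"stable"` (default) gives each tied row its own
#'   cumulative-weight rank in stable input order; `"average"` assigns every
#'   row in a tie group the group's weighted mean rank. Both keep the weighted
#'   mean rank at 1/2.
#' @return Numeric vector of ranks in `(0, 1)`, in the original row order.
#' @export
#' @examples
#' fractional_ranks(c(10, 20, 30, 40))          # 0.125 0.375 0.625 0.875
#' fractional_ranks(c(10, 20), w = c(1, 3))     # 0.125 0.625
fractional_ranks <- function(x, w = NULL, ties = c("stable", "average")) {
  ties <- match.arg(ties)
  if (any(is.na(x))) {
    abort("ranking variable has missing values", class = "cogineq_domain_error")
  }
  n <- length(x)
  w <- if (is.null(w)) rep(1 / n, n) else normalize_weights(w)
  ord <- order(x)                      # stable for ties
  ws <- w[ord]
  cum <- cumsum(ws)
  r_sorted <- cum - ws / 2
  if (ties == "average") {
    grp <- match(x[ord], x[ord])       # first index of each tie group
    r_sorted <- stats::ave(r_sorted * ws, grp, FUN = sum) /
      stats::ave(ws, grp, FUN = sum)
  }
  r <- numeric(n)
  r[ord] <- r_sorted
  r
}

#' Build a ranked sample for concentration-index computations
#'
#' Bundles the outcome, normalized weights, weighted fractional ranks over the
#' living-standards variable, and the weighted mean outcome.
#'
#' @param data A data frame.
#' @param outcome,rank_by,weight Column names (strings) of the outcome, the
#'   ranking variable (e.g. log per-capita expenditure) and the sampling
#'   weight; `weight = NULL` for equal weights. Rows with a missing outcome or
#'   ranking value are dropped with a message.
#' @param ties Passed to [fractional_ranks()].
#' @return A list of class `"ranked_sample"` with elements `y`, `w` (summing
#'   to 1), `rank`, `mu` and `n`.
#' @export
ranked_sample <- function(data, outcome = "z", rank_by = "log_pce",
                          weight = "weight", ties = c("stable", "average")) {
  cols <- c(outcome, rank_by, weight)
  check_columns(data, cols)
  keep <- !is.na(data[[outcome]]) & !is.na(data[[rank_by]])
  if (!is.null(weight)) keep <- keep & !is.na(data[[weight]])
  if (!all(keep)) {
    inform(sprintf("dropping %d rows with missing outcome, rank or weight",
                   sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0) abort("no usable rows", class = "cogineq_domain_error")
  w <- if (is.null(weight)) rep(1 / nrow(data), nrow(data)) else {
    normalize_weights(data[[weight]])
  }
  y <- as.numeric(data[[outcome]])
  r <- fractional_ranks(data[[rank_by]], w, ties = match.arg(ties))
  structure(list(y = y, w = w, rank = r, mu = sum(w * y), n = length(y)),
            class = "ranked_sample")
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat(sprintf("<ranked_sample> n = %d, weighted mean outcome = %.4g\n",
              x$n, x$mu))
  invisible(x)
}

#' Relative concentration index
#'
#' Twice the weighted covariance between the outcome and its fractional
#' living-standards rank, divided by the weighted mean outcome:
#' `C = (2 / mu) * sum(w * y * (rank - 0.5))`. Equivalently, twice the area
#' between the concentration curve and the line of equality. Positive values
#' indicate that the outcome is concentrated among the better-off.
#'
#' @param sample A [ranked_sample()].
#' @return The index as a single number.
#' @export
#' @examples
#' d <- data.frame(y = 1:8, pce = 1:8)
#' rci(ranked_sample(d, "y", "pce", weight = NULL))
rci <- function(sample) {
  stopifnot(inherits(sample, "ranked_sample"))
  if (sample$mu == 0) {
    abort("relative concentration index undefined: mean outcome is zero",
          class = "cogineq_undefined_index_error")
  }
  if (abs(sample$mu) < 1e-6) {
    warn("mean outcome is within 1e-6 of zero; the relative index is unstable")
  }
  2 * sum(sample$w * sample$y * (sample$rank - 0.5)) / sample$mu
}

# unscaled (generalized) concentration index: 2 * weighted cov(y, rank)
generalized_ci <- function(y, rank, w) {
  2 * sum(w * y * (rank - 0.5))
}

#' Delta-method standard error of the relative concentration index
#'
#' Kakwani, Wagstaff and van Doorslaer's delta-method variance estimator in
#' its weighted ("conindex"-style) form. With rows sorted by rank,
#' `q_i` the cumulative weighted outcome share, and
#' `a_i = (y_i/mu) * (2 R_i - 1 - C) + 2 - q_{i-1} - q_i`, the variance is
#' `(sum(w_i a_i^2) - (1 + C)^2) / n`.
#'
#' @param sample A [ranked_sample()].
#' @return The standard error; a numerically negative variance is clipped to
#'   zero with a warning.
#' @export
rci_se_delta <- function(sample) {
  stopifnot(inherits(sample, "ranked_sample"))
  if (sample$n < 3) abort("need at least 3 observations", class = "cogineq_domain_error")
  C <- rci(sample)
  ord <- order(sample$rank)
  y <- sample$y[ord]; w <- sample$w[ord]; r <- sample$rank[ord]
  q <- cumsum(w * y) / sample$mu
  qlag <- c(0, head(q, -1))
  a <- (y / sample$mu) * (2 * r - 1 - C) + 2 - qlag - q
  v <- (sum(w * a^2) - (1 + C)^2) / sample$n
  if (v < 0) {
    warn(sprintf("delta-method variance numerically negative (%.3g); clipped to 0", v))
    v <- 0
  }
  sqrt(v)
}

#' Bootstrap standard error of the relative concentration index
#'
#' Simple nonparametric bootstrap over rows (re-ranking within each resample),
#' offered as a cross-check on [rci_se_delta()]; the delta method is the
#' default throughout the package.
#'
#' @inheritParams ranked_sample
#' @param reps Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return The bootstrap SE (SD of the resampled index).
#' @export
rci_se_bootstrap <- function(data, outcome = "z", rank_by = "log_pce",
                             weight = "weight", reps = 200, seed = 1) {
  check_columns(data, c(outcome, rank_by, weight))
  with_private_seed(seed, {
    stats::sd(vapply(seq_len(reps), function(i) {
      idx <- sample.int(nrow(data), replace = TRUE)
      rci(ranked_sample(data[idx, , drop = FALSE], outcome, rank_by, weight))
    }, numeric(1)))
  })
}

#' Estimate the relative concentration index from a data frame
#'
#' One-stop estimation: builds the ranked sample, computes the index, its
#' delta-method SE and a normal-approximation confidence interval, optionally
#' within groups.
#'
#' @inheritParams ranked_sample
#' @param by Optional grouping column name (e.g. the survey round); when
#'   given, a tibble with one result row per group is returned.
#' @param conf_level Confidence level for the normal-approximation interval.
#' @return An `"rci_result"` object (see [tidy.rci_result()]), or a tibble of
#'   per-group results when `by` is given.
#' @export
#' @examples
#' tab <- generate_survey(survey_config(n_children = 1000, seed = 3))
#' tab <- apply_zscore(tab, fit_zscore_model(tab))
#' estimate_rci(tab, outcome = "z")
estimate_rci <- function(data, outcome = "z", rank_by = "log_pce",
                         weight = "weight", by = NULL, conf_level = 0.95) {
  if (!is.null(by)) {
    check_columns(data, by)
    return(
      data |>
        dplyr::group_by(.data[[by]]) |>
        dplyr::group_modify(~ tidy(estimate_rci(.x, outcome, rank_by, weight,
                                                conf_level = conf_level))) |>
        dplyr::ungroup()
    )
  }
  s <- ranked_sample(data, outcome, rank_by, weight)
  est <- rci(s)
  se <- rci_se_delta(s)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  new_rci_result(estimate = est, se = se, ci_low = est - zq * se,
                 ci_high = est + zq * se, mu = s$mu, n = s$n,
                 conf_level = conf_level, method = "delta")
}

new_rci_result <- function(estimate, se, ci_low, ci_high, mu, n, conf_level,
                           method, m = NA_integer_, df = Inf) {
  structure(list(estimate = estimate, se = se, ci_low = ci_low,
                 ci_high = ci_high, mu = mu, n = n, conf_level = conf_level,
                 method = method, m = m, df = df),
            class = "rci_result")
}

#' @export
print.rci_result <- function(x, ...) {
  cat(sprintf("Relative concentration index: %.4f (SE %.4f, %d%% CI %.4f to %.4f)\n",
              x$estimate, x$se, round(100 * x$conf_level), x$ci_low, x$ci_high))
  cat(sprintf("  n = %d, mean outcome = %.4f, method = %s\n", x$n, x$mu, x$method))
  invisible(x)
}

#' Tidy and glance methods for concentration-index results
#'
#' @param x An `"rci_result"`.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with `estimate`, `std.error`,
#'   `conf.low`, `conf.high`; `glance()` adds `mu`, `n`, `conf.level`,
#'   `method`.
#' @method tidy rci_result
#' @export
tidy.rci_result <- function(x, ...) {
  tibble::tibble(term = "rci", estimate = x$estimate, std.error = x$se,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.rci_result
#' @method glance rci_result
#' @export
glance.rci_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$se, mu = x$mu,
                 n = x$n, conf.level = x$conf_level, method = x$method)
}

#' Concentration curve points
#'
#' Cumulative outcome share against cumulative population share, population
#' ranked from poorest to richest. The curve runs from (0, 0) to (1, 1);
#' twice the signed area between it and the diagonal is the relative
#' concentration index.
#'
#' @param data A data frame, or a [ranked_sample()].
#' @inheritParams ranked_sample
#' @return A tibble of class `"concentration_curve"` with columns `pop_share`
#'   and `outcome_share`, starting at (0, 0) and ending at (1, 1).
#' @export
concentration_curve <- function(data, outcome = "z", rank_by = "log_pce",
                                weight = "weight") {
  s <- if (inherits(data, "ranked_sample")) data else {
    ranked_sample(data, outcome, rank_by, weight)
  }
  ord <- order(s$rank)
  out <- tibble::tibble(
    pop_share = c(0, cumsum(s$w[ord])),
    outcome_share = c(0, cumsum(s$w[ord] * s$y[ord]) / s$mu)
  )
  out$pop_share[nrow(out)] <- 1       # guard rounding in the last partial sum
  out$outcome_share[nrow(out)] <- 1
  class(out) <- c("concentration_curve", class(out))
  out
}

#' Pool concentration-index estimates across multiple imputations
#'
#' Rubin's rules: the pooled estimate is the mean of the per-imputation
#' estimates; the total variance is the mean within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance. The interval uses a t
#' reference with Barnard-Rubin small-sample degrees of freedom (reducing to
#' the classic Rubin df when `dfcom = Inf`, and to a normal interval when the
#' between-imputation variance is zero). With `m = 1` the total variance
#' falls back to the single within-imputation variance.
#'
#' @param estimates,ses Equal-length numeric vectors of per-imputation
#'   estimates and standard errors.
#' @param conf_level Confidence level.
#' @param dfcom Complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment; `Inf` (default) gives the classic large-sample df.
#' @return An `"rci_result"` with the pooled estimate, SE and interval.
#' @export
#' @examples
#' pool_rubin(c(0.28, 0.31, 0.30), c(0.03, 0.03, 0.03))
pool_rubin <- function(estimates, ses, conf_level = 0.95, dfcom = Inf) {
  m <- length(estimates)
  if (m == 0) abort("need at least one imputation", class = "cogineq_domain_error")
  if (length(ses) != m) abort("estimates and ses differ in length",
                              class = "cogineq_domain_error")
  qbar <- mean(estimates)
  wbar <- mean(ses^2)
  b <- if (m > 1) stats::var(estimates) else 0
  total <- wbar + (1 + 1 / m) * b
  se <- sqrt(total)

  if (b > 0 && total > 0) {
    lambda <- (1 + 1 / m) * b / total
    nu_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      nu_old * nu_obs / (nu_old + nu_obs)
    } else nu_old
  } else {
    df <- Inf
  }
  tq <- if (is.finite(df)) qt(1 - (1 - conf_level) / 2, df) else {
    qnorm(1 - (1 - conf_level) / 2)
  }
  new_rci_result(estimate = qbar, se = se, ci_low = qbar - tq * se,
                 ci_high = qbar + tq * se, mu = NA_real_, n = NA_integer_,
                 conf_level = conf_level, method = "rubin", m = m, df = df)
}
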