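#' Configuration for the Gibbs-sampled Bayesian regression
#'
#' Conjugate normal-inverse-gamma prior for the weighted linear model:
#' `beta ~ N(prior_beta_mean, prior_beta_precision^-1 * I)` and
#' `sigma^2 ~ InvGamma(prior_sigma_shape, prior_sigma_rate)`. The defaults
#' are vague (`N(0, 1e6)` slabs, `InvGamma(1e-3, 1e-3)`) with 5000 retained
#' draws after 1000 burn-in.
#'
#' @param n_draws Retained posterior draws.
#' @param burn_in Discarded initial sweeps.
#' @param seed Integer seed.
#' @param prior_beta_mean Scalar or vector prior mean for the coefficients
#'   (intercept included, recycled as needed).
#' @param prior_beta_precision Scalar isotropic prior precision.
#' @param prior_sigma_shape,prior_sigma_rate Inverse-gamma hyperparameters
#'   for the residual variance.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_draws = 5000, burn_in = 1000, seed = 1L,
                        prior_beta_mean = 0, prior_beta_precision = 1e-6,
                        prior_sigma_shape = 1e-3, prior_sigma_rate = 1e-3) {
  check_number(n_draws, "n_draws", lower = 0, strict_lower = TRUE,
               integerish = TRUE)
  check_number(burn_in, "burn_in", lower = 0, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  check_number(prior_beta_precision, "prior_beta_precision", lower = 0)
  check_number(prior_sigma_shape, "prior_sigma_shape", lower = 0,
               strict_lower = TRUE)
  check_number(prior_sigma_rate, "prior_sigma_rate", lower = 0,
               strict_lower = TRUE)
  if (!is.numeric(prior_beta_mean) || anyNA(prior_beta_mean)) {
    stop_field("prior_beta_mean", "must be numeric")
  }
  structure(list(n_draws = as.integer(n_draws), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), prior_beta_mean = prior_beta_mean,
                 prior_beta_precision = prior_beta_precision,
                 prior_sigma_shape = prior_sigma_shape,
                 prior_sigma_rate = prior_sigma_rate),
            class = "mcmc_config")
}

#' Gibbs sampler for the weighted Bayesian linear regression
#'
#' Samples the posterior of `(beta, sigma^2)` under the weighted Gaussian
#' likelihood `prod_i N(y_i; x_i' beta, sigma^2 / w_i)` (weights scaled to
#' mean 1, so the likelihood carries `n` effective observations) and the
#' conjugate prior of [mcmc_config()]. Alternates
#' `beta | sigma^2 ~ Normal` and `sigma^2 | beta ~ InvGamma`; the chain is
#' initialized at the weighted least-squares solution and is fully
#' deterministic given the seed.
#'
#' @param y Outcome vector (complete cases).
#' @param X Design matrix of contributors (an intercept column is added).
#' @param w Positive weights.
#' @param config An [mcmc_config()].
#' @return A list of class `"posterior_draws"`: `betas` (draws x contributors
#'   matrix, intercept column first), `sigma2` (vector), `config`.
#' @export
gibbs_regression <- function(y, X, w, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) {
    abort("gibbs_regression requires complete cases", class = "cogineq_domain_error")
  }
  ols <- weighted_ols(y, X, w)         # also screens for rank deficiency
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  wn <- normalize_weights(w) * n       # mean-1 weights
  XtWX <- crossprod(Xi * sqrt(wn))
  XtWy <- crossprod(Xi, wn * y)
  m0 <- rep_len(config$prior_beta_mean, p)
  tau0 <- config$prior_beta_precision
  a0 <- config$prior_sigma_shape
  b0 <- config$prior_sigma_rate

  n_total <- config$burn_in + config$n_draws
  betas <- matrix(NA_real_, n_total, p, dimnames = list(NULL, colnames(Xi)))
  sigma2 <- numeric(n_total)

  with_private_seed(config$seed, {
    beta <- c(ols$intercept, ols$betas)
    sig2 <- ols$sigma2
    for (it in seq_len(n_total)) {
      prec <- XtWX / sig2 + diag(tau0, p)
      ch <- tryCatch(chol(prec), error = function(e) {
        abort("posterior precision is singular", class = "cogineq_singular_design_error")
      })
      mean_beta <- backsolve(ch, forwardsolve(t(ch), XtWy / sig2 + tau0 * m0))
      beta <- drop(mean_beta + backsolve(ch, rnorm(p)))
      resid <- y - drop(Xi %*% beta)
      sig2 <- 1 / rgamma(1, shape = a0 + n / 2,
                         rate = b0 + sum(wn * resid^2) / 2)
      betas[it, ] <- beta
      sigma2[it] <- sig2
    }
  })
  keep <- seq.int(config$burn_in + 1L, n_total)
  structure(list(betas = betas[keep, , drop = FALSE], sigma2 = sigma2[keep],
                 config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws x %d coefficients\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' @rdname tidy.rci_result
#' @method tidy posterior_draws
#' @export
tidy.posterior_draws <- function(x, ...) {
  est <- colMeans(x$betas)
  tibble::tibble(term = colnames(x$betas), estimate = unname(est),
                 std.error = unname(apply(x$betas, 2, stats::sd)))
}

#' Export posterior draws for external diagnostics
#'
#' Writes one row per retained draw: the coefficient columns followed by
#' `sigma2`, suitable for trace inspection outside the package.
#'
#' @param draws A `"posterior_draws"`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  out <- tibble::as_tibble(draws$betas, .name_repair = "minimal")
  out$sigma2 <- draws$sigma2
  readr::write_csv(out, path)
  invisible(path)
}

#' Equal-tail credible intervals for contribution shares
#'
#' Propagates the posterior coefficient draws into the decomposition: per
#' draw, each contributor's contribution `beta_k * GC_k / mu` and share
#' (divided by the total index) are recomputed with the contributor
#' concentration indices, means and ranks held fixed at their sample values.
#' The interval is the (2.5th, 97.5th) percentile pair of the share draws
#' (linear-interpolation order statistics).
#'
#' @param draws A `"posterior_draws"` from [gibbs_regression()].
#' @param decomposition The `"rci_decomposition"` the draws refer to.
#' @param level Credible level (default 0.95, i.e. the 2.5-97.5 equal-tail
#'   interval).
#' @return A tibble with columns `contributor`, `share`, `ci_low`, `ci_high`
#'   (share scale, residual excluded).
#' @export
contribution_intervals <- function(draws, decomposition, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(decomposition, "rci_decomposition"))
  s <- attr(decomposition, "sample")
  X <- attr(decomposition, "X")
  total <- attr(decomposition, "total_rci")
  gc_k <- vapply(seq_len(ncol(X)),
                 function(j) generalized_ci(X[, j], s$rank, s$w), numeric(1))
  B <- draws$betas[, decomposition$contributor, drop = FALSE]
  share_draws <- sweep(B, 2, gc_k / (s$mu * total), `*`)
  alpha <- (1 - level) / 2
  tibble::tibble(
    contributor = decomposition$contributor,
    share = decomposition$share,
    ci_low = unname(apply(share_draws, 2, quantile, probs = alpha,
                          names = FALSE)),
    ci_high = unname(apply(share_draws, 2, quantile, probs = 1 - alpha,
                           names = FALSE))
  )
}

#' Decomposition with Gibbs-sampled credible intervals
#'
#' Convenience wrapper: runs [decompose_rci()], then [gibbs_regression()] on
#' the same complete-case design, and attaches equal-tail contribution-share
#' intervals.
#'
#' @inheritParams decompose_rci
#' @param mcmc An [mcmc_config()].
#' @return The `"rci_decomposition"` with columns `ci_low` and `ci_high`
#'   appended and the draws stored in the `"draws"` attribute.
#' @export
decompose_rci_with_intervals <- function(data, outcome = "z",
                                         contributors = cognitive_contributors()$contributor,
                                         rank_by = "log_pce", weight = "weight",
                                         mcmc = mcmc_config()) {
  dec <- decompose_rci(data, outcome = outcome, contributors = contributors,
                       rank_by = rank_by, weight = weight)
  s <- attr(dec, "sample")
  draws <- gibbs_regression(s$y, attr(dec, "X"), s$w, mcmc)
  ints <- contribution_intervals(draws, dec)
  dec$ci_low <- ints$ci_low
  dec$ci_high <- ints$ci_high
  attr(dec, "draws") <- draws
  dec
}
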