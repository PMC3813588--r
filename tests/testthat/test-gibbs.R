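sim_regression <- function(n, seed) {
  set.seed(seed)
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  y <- 1 + 0.5 * X[, "a"] - 0.8 * X[, "b"] + 0.2 * X[, "c"] + rnorm(n, 0, 0.7)
  w <- rgamma(n, 4, 4)
  list(y = y, X = X, w = w)
}

test_that("vague-prior posterior means agree with weighted least squares", {
  d <- sim_regression(2000, seed = 41)
  draws <- gibbs_regression(d$y, d$X, d$w,
                            mcmc_config(n_draws = 1000, burn_in = 200, seed = 1))
  ols <- weighted_ols(d$y, d$X, d$w)
  post_mean <- colMeans(draws$betas)
  expect_lt(max(abs(post_mean[-1] - ols$betas)), 0.02)
  expect_lt(abs(post_mean[1] - ols$intercept), 0.02)
  # posterior spread agrees with the sampling SE to first order
  post_sd <- apply(draws$betas, 2, sd)[-1]
  expect_lt(max(abs(post_sd / ols$se - 1)), 0.35)
})

test_that("the chain is reproducible and seed-sensitive", {
  d <- sim_regression(300, seed = 42)
  cfg <- mcmc_config(n_draws = 50, burn_in = 10, seed = 7)
  d1 <- gibbs_regression(d$y, d$X, d$w, cfg)
  d2 <- gibbs_regression(d$y, d$X, d$w, cfg)
  expect_identical(d1$betas, d2$betas)
  expect_identical(d1$sigma2, d2$sigma2)
  d3 <- gibbs_regression(d$y, d$X, d$w, mcmc_config(n_draws = 50, burn_in = 10,
                                                    seed = 8))
  expect_false(identical(d1$betas, d3$betas))
  expect_equal(nrow(d1$betas), 50)   # burn-in discarded
})

test_that("an overwhelming prior pins the coefficients at its mean", {
  d <- sim_regression(500, seed = 43)
  draws <- gibbs_regression(d$y, d$X, d$w,
                            mcmc_config(n_draws = 200, burn_in = 50, seed = 2,
                                        prior_beta_mean = 0,
                                        prior_beta_precision = 1e10))
  expect_lt(max(abs(colMeans(draws$betas))), 1e-3)
})

test_that("contribution intervals are percentile order statistics of the draws", {
  tab <- small_survey(1200, seed = 44)
  dec <- quiet(decompose_rci(tab, outcome = "raw_score"))
  s <- attr(dec, "sample")
  draws <- gibbs_regression(s$y, attr(dec, "X"), s$w,
                            mcmc_config(n_draws = 400, burn_in = 100, seed = 3))
  ints <- contribution_intervals(draws, dec)
  # direct recomputation for one contributor
  j <- match("mother_hs", dec$contributor)
  gc_j <- 2 * sum(s$w * attr(dec, "X")[, j] * (s$rank - 0.5))
  share_draws <- draws$betas[, "mother_hs"] * gc_j /
    (s$mu * attr(dec, "total_rci"))
  expect_equal(ints$ci_low[j], quantile(share_draws, 0.025, names = FALSE))
  expect_equal(ints$ci_high[j], quantile(share_draws, 0.975, names = FALSE))
  expect_true(all(ints$ci_low <= ints$ci_high))
  # plug-in shares sit inside their intervals
  expect_true(all(dec$share >= ints$ci_low - 1e-8 &
                    dec$share <= ints$ci_high + 1e-8))
})

test_that("degenerate (zero-variance) draws collapse the interval to a point", {
  tab <- small_survey(400, seed = 45)
  dec <- quiet(decompose_rci(tab, outcome = "raw_score"))
  fit <- attr(dec, "fit")
  const <- matrix(rep(c(fit$intercept, fit$betas), each = 10), nrow = 10,
                  dimnames = list(NULL, c("(Intercept)", names(fit$betas))))
  degenerate <- structure(list(betas = const, sigma2 = rep(fit$sigma2, 10),
                               config = mcmc_config(n_draws = 10, burn_in = 0)),
                          class = "posterior_draws")
  ints <- contribution_intervals(degenerate, dec)
  expect_equal(ints$ci_low, dec$share, tolerance = 1e-10)
  expect_equal(ints$ci_high, dec$share, tolerance = 1e-10)
})

test_that("decompose_rci_with_intervals attaches interval columns", {
  tab <- small_survey(800, seed = 46)
  dec <- quiet(decompose_rci_with_intervals(
    tab, outcome = "raw_score",
    mcmc = mcmc_config(n_draws = 200, burn_in = 50, seed = 4)))
  expect_true(all(c("ci_low", "ci_high") %in% names(dec)))
  rep_tab <- decomposition_report(
    dec, intervals = tibble::tibble(contributor = dec$contributor,
                                    ci_low = dec$ci_low, ci_high = dec$ci_high))
  expect_true(all(c("ci_low_pct", "ci_high_pct") %in% names(rep_tab)))
})

test_that("posterior draws export to CSV with one row per draw", {
  d <- sim_regression(150, seed = 48)
  draws <- gibbs_regression(d$y, d$X, d$w,
                            mcmc_config(n_draws = 25, burn_in = 5, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_posterior_draws(draws, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 25)
  expect_equal(back$sigma2, draws$sigma2)
  expect_equal(back[["a"]], unname(draws$betas[, "a"]))
})

test_that("invalid sampler configurations are rejected", {
  expect_error(mcmc_config(n_draws = 0), "n_draws",
               class = "cogineq_config_error")
  expect_error(mcmc_config(burn_in = -1), "burn_in",
               class = "cogineq_config_error")
  d <- sim_regression(100, seed = 47)
  expect_error(gibbs_regression(d$y, cbind(d$X, dup = d$X[, "a"]), d$w,
                                mcmc_config(n_draws = 10, burn_in = 0)),
               class = "cogineq_singular_design_error")
})
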