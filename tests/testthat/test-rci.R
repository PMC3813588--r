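test_that("fractional ranks match hand-computed cumulative-weight midpoints", {
  expect_equal(fractional_ranks(c(1, 2, 3, 4)), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(fractional_ranks(c(1, 2), w = c(1, 3)), c(0.125, 0.625))
  # returned in original row order
  expect_equal(fractional_ranks(c(4, 3, 2, 1)), c(0.875, 0.625, 0.375, 0.125))
  expect_error(fractional_ranks(1:3, w = c(1, 0, 1)),
               class = "cogineq_domain_error")
  expect_error(fractional_ranks(c(1, NA)), class = "cogineq_domain_error")
})

test_that("weighted mean rank is exactly one half, for both tie policies", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:40, 1)
    x <- sample(round(rnorm(n), 1), n, replace = TRUE)   # induces ties
    w <- rgamma(n, 2, 2)
    for (ties in c("stable", "average")) {
      r <- fractional_ranks(x, w, ties = ties)
      expect_true(all(r > 0 & r < 1))
      expect_equal(sum(w / sum(w) * r), 0.5, tolerance = 1e-12)
    }
  }
  # averaged ranks are constant within tie groups
  r <- fractional_ranks(c(1, 1, 2), w = c(1, 2, 1), ties = "average")
  expect_equal(r[1], r[2])
})

test_that("rci matches the brute-force covariance oracle on small inputs", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(3:12, 1)
    y <- rnorm(n, mean = 3)
    x <- rnorm(n)
    d <- data.frame(y = y, x = x)
    s <- ranked_sample(d, "y", "x", weight = NULL)
    expect_equal(rci(s), oracle_rci(y, s$rank), tolerance = 1e-12)
  }
})

test_that("rci limiting cases and sign conventions hold", {
  # constant outcome: no inequality
  d <- data.frame(y = rep(2, 50), x = rnorm(50))
  expect_equal(rci(ranked_sample(d, "y", "x", weight = NULL)), 0)
  # y equal to its own rank: closed form 2 var(U)/E[U] = 1/3
  n <- 20000
  d <- data.frame(x = seq_len(n))
  d$y <- fractional_ranks(d$x)
  expect_equal(rci(ranked_sample(d, "y", "x", weight = NULL)), 1 / 3,
               tolerance = 2e-3)
  # perfect negative rank association with positive y
  d <- data.frame(y = 10:1, x = 1:10)
  expect_lt(rci(ranked_sample(d, "y", "x", weight = NULL)), 0)
  # zero mean outcome is undefined
  d <- data.frame(y = c(-1, 1), x = 1:2)
  expect_error(rci(ranked_sample(d, "y", "x", weight = NULL)),
               class = "cogineq_undefined_index_error")
})

test_that("rci is scale invariant in y and invariant to monotone rank transforms", {
  set.seed(4)
  d <- data.frame(y = rlnorm(200), x = rnorm(200), w = rgamma(200, 2, 2))
  base <- rci(ranked_sample(d, "y", "x", "w"))
  d2 <- transform(d, y = 7 * y)
  expect_equal(rci(ranked_sample(d2, "y", "x", "w")), base, tolerance = 1e-12)
  # the relative index divides by the mean, so any nonzero rescaling of y --
  # negative included -- cancels; only the *generalized* index flips sign
  d3 <- transform(d, y = -2 * y)
  expect_equal(rci(ranked_sample(d3, "y", "x", "w")), base, tolerance = 1e-12)
  s <- ranked_sample(d, "y", "x", "w")
  s3 <- ranked_sample(d3, "y", "x", "w")
  expect_equal(cogineq:::generalized_ci(s3$y, s3$rank, s3$w),
               -2 * cogineq:::generalized_ci(s$y, s$rank, s$w),
               tolerance = 1e-12)
  d4 <- transform(d, x = exp(x / 2) + 5)     # strictly increasing transform
  expect_equal(rci(ranked_sample(d4, "y", "x", "w")), base, tolerance = 1e-12)
  expect_equal(rci_se_delta(ranked_sample(d4, "y", "x", "w")),
               rci_se_delta(ranked_sample(d, "y", "x", "w")), tolerance = 1e-12)
})

test_that("delta-method SE is computable at the null and scales as 1/sqrt(n)", {
  d <- data.frame(y = rep(1, 100), x = rnorm(100))
  s <- ranked_sample(d, "y", "x", weight = NULL)
  expect_equal(rci(s), 0)
  # at exactly zero inequality the variance is 0 up to roundoff, which the
  # estimator clips (warning allowed)
  se0 <- suppressWarnings(rci_se_delta(s))
  expect_gte(se0, 0)
  expect_lt(se0, 1e-6)
  # matched simulations: SE at n vs 4n should shrink by about 2
  set.seed(8)
  ratio <- replicate(40, {
    mk <- function(n) {
      d <- data.frame(y = rlnorm(n), x = rnorm(n))
      rci_se_delta(ranked_sample(d, "y", "x", weight = NULL))
    }
    mk(400) / mk(1600)
  })
  expect_lt(abs(mean(ratio) - 2), 0.3)
})

test_that("delta and bootstrap SEs broadly agree", {
  set.seed(9)
  d <- data.frame(y = rlnorm(400, 1), x = rnorm(400), w = rgamma(400, 4, 4))
  d$y <- d$y * (1 + 0.5 * pnorm(d$x))        # mild rank gradient
  s <- ranked_sample(d, "y", "x", "w")
  se_d <- rci_se_delta(s)
  se_b <- rci_se_bootstrap(d, "y", "x", "w", reps = 200, seed = 10)
  expect_lt(abs(se_b / se_d - 1), 0.5)
})

test_that("concentration curve has exact endpoints and integrates to the index", {
  set.seed(5)
  d <- data.frame(y = rlnorm(500), x = rnorm(500), w = rgamma(500, 2, 2))
  cv <- concentration_curve(d, "y", "x", "w")
  expect_equal(cv$pop_share[1], 0)
  expect_equal(cv$outcome_share[1], 0)
  expect_equal(cv$pop_share[nrow(cv)], 1)
  expect_equal(cv$outcome_share[nrow(cv)], 1)
  # twice the signed area between curve and diagonal equals the index
  est <- rci(ranked_sample(d, "y", "x", "w"))
  expect_equal(oracle_curve_area(cv), est, tolerance = 1e-6)
  # constant outcome lies on the diagonal
  dc <- data.frame(y = rep(3, 40), x = rnorm(40))
  cvc <- concentration_curve(dc, "y", "x", weight = NULL)
  expect_equal(cvc$outcome_share, cvc$pop_share, tolerance = 1e-12)
})

test_that("Rubin pooling matches a direct spreadsheet-style computation", {
  set.seed(6)
  est <- rnorm(20, 0.3, 0.02)
  ses <- runif(20, 0.02, 0.04)
  pooled <- pool_rubin(est, ses)
  wbar <- mean(ses^2)
  b <- sum((est - mean(est))^2) / 19
  total <- wbar + (1 + 1 / 20) * b
  expect_equal(pooled$estimate, mean(est))
  expect_equal(pooled$se, sqrt(total), tolerance = 1e-12)
  lambda <- (1 + 1 / 20) * b / total
  expect_equal(pooled$df, 19 / lambda^2, tolerance = 1e-12)
  # one imputation: falls back to the within variance
  p1 <- pool_rubin(0.25, 0.05)
  expect_equal(p1$estimate, 0.25)
  expect_equal(p1$se, 0.05)
  # identical estimates: between variance vanishes, normal interval
  p0 <- pool_rubin(rep(0.3, 5), rep(0.04, 5))
  expect_equal(p0$se, 0.04)
  expect_equal(p0$ci_high - p0$estimate, qnorm(0.975) * 0.04, tolerance = 1e-12)
  expect_error(pool_rubin(numeric(0), numeric(0)), class = "cogineq_domain_error")
})

test_that("estimate_rci returns tidy results, also per group", {
  tab0 <- small_survey(500, seed = 13)
  tab1 <- quiet(generate_survey(survey_config("2007", n_children = 500, seed = 14)))
  both <- dplyr::bind_rows(tab0, tab1)
  both <- quiet(apply_zscore(both, fit_zscore_model(both, mean_cutoff = Inf)))
  one <- estimate_rci(dplyr::filter(both, round == "2000"), outcome = "z")
  expect_s3_class(one, "rci_result")
  expect_true(one$ci_low <= one$estimate & one$estimate <= one$ci_high)
  td <- tidy(one)
  expect_equal(td$estimate, one$estimate)
  grouped <- estimate_rci(both, outcome = "z", by = "round")
  expect_equal(nrow(grouped), 2)
  expect_equal(grouped$estimate[grouped$round == "2000"], one$estimate)
})
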