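test_that("weighted OLS recovers exact and oracle solutions", {
  set.seed(1)
  n <- 60
  X <- cbind(a = rnorm(n), b = runif(n))
  # noiseless: exact coefficients and zero residuals
  y <- 2 - 1.5 * X[, "a"] + 3 * X[, "b"]
  fit <- weighted_ols(y, X, rep(1, n))
  expect_equal(unname(fit$betas), c(-1.5, 3), tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  # equal weights match an independent normal-equations solve
  y2 <- y + rnorm(n)
  fit2 <- weighted_ols(y2, X, rep(2, n))
  Xi <- cbind(1, X)
  beta_ne <- solve(t(Xi) %*% Xi, t(Xi) %*% y2)
  expect_equal(c(fit2$intercept, fit2$betas), drop(beta_ne),
               tolerance = 1e-8, ignore_attr = TRUE)
  # residuals have weighted mean zero with an intercept present
  w <- rgamma(n, 2, 2)
  fit3 <- weighted_ols(y2, X, w)
  expect_equal(sum(w / sum(w) * fit3$residuals), 0, tolerance = 1e-10)
  # duplicated column is reported as singular
  expect_error(weighted_ols(y2, cbind(X, a2 = X[, "a"]), rep(1, n)),
               "a2", class = "cogineq_singular_design_error")
})

test_that("contributor concentration has closed-form and degenerate values", {
  n <- 10000
  d <- data.frame(x = seq_len(n), y = rep(1, n))
  s <- ranked_sample(d, "y", "x", weight = NULL)
  top_half <- as.numeric(seq_len(n) > n / 2)
  expect_equal(contributor_concentration(top_half, s), 0.5, tolerance = 1e-3)
  bottom_half <- 1 - top_half
  expect_equal(contributor_concentration(bottom_half, s), -0.5, tolerance = 1e-3)
  expect_equal(contributor_concentration(rep(1, n), s), 0)
  expect_error(contributor_concentration(rep(0, n), s),
               class = "cogineq_undefined_index_error")
})

test_that("decomposition terms reproduce the index exactly (additivity)", {
  for (seed in c(2, 3, 4)) {
    tab <- small_survey(400, seed = seed)
    dec <- quiet(decompose_rci(tab, outcome = "raw_score"))
    total_direct <- rci(ranked_sample(tab, "raw_score", "log_pce", "weight"))
    expect_equal(sum(dec$contribution) + attr(dec, "residual"), total_direct,
                 tolerance = 1e-10)
    expect_equal(sum(dec$share) + attr(dec, "residual_share"), 1,
                 tolerance = 1e-10)
  }
})

test_that("saturated single-contributor model assigns the whole index", {
  set.seed(5)
  d <- data.frame(y = rlnorm(200), x = rnorm(200), w = rgamma(200, 2, 2))
  d$xk <- d$y
  dec <- decompose_rci(d, outcome = "y", contributors = "xk",
                       rank_by = "x", weight = "w")
  expect_equal(dec$share, 1, tolerance = 1e-10)
  expect_equal(attr(dec, "residual_share"), 0, tolerance = 1e-10)
})

test_that("elasticity and contribution are invariant to contributor rescaling", {
  tab <- small_survey(800, seed = 6)
  dec1 <- quiet(decompose_rci(tab, outcome = "raw_score"))
  tab2 <- dplyr::mutate(tab, log_pce_scaled = 10 * log_pce)
  contribs <- sub("^log_pce$", "log_pce_scaled",
                  cognitive_contributors()$contributor)
  dec2 <- quiet(decompose_rci(tab2, outcome = "raw_score",
                              contributors = contribs))
  i1 <- match("log_pce", dec1$contributor)
  i2 <- match("log_pce_scaled", dec2$contributor)
  expect_equal(dec2$beta[i2], dec1$beta[i1] / 10, tolerance = 1e-10)
  expect_equal(dec2$elasticity[i2], dec1$elasticity[i1], tolerance = 1e-10)
  expect_equal(dec2$contribution[i2], dec1$contribution[i1], tolerance = 1e-10)
})

test_that("a contributor unrelated to expenditure rank contributes nothing", {
  tab <- small_survey(5000, seed = 7)      # male gradient is zero by default
  dec <- quiet(decompose_rci(tab, outcome = "raw_score"))
  i <- match("male", dec$contributor)
  expect_lt(abs(dec$ck[i]), 0.05)
  expect_lt(abs(dec$share[i]), 0.05)
})

test_that("the dominant constructed contributor ranks first", {
  zero_b <- setNames(rep(0, 16), cognitive_contributors()$contributor)
  zero_b[["mother_hs"]] <- 0.5
  g <- survey_config()$covariate_gradients
  g[] <- 0
  g[["mother_edu"]] <- 2.5
  cfg <- survey_config("2000", n_children = 8000, seed = 8, true_betas = zero_b,
                       covariate_gradients = g, noise_sd = 0.5)
  tab <- generate_survey(cfg)
  dec <- quiet(decompose_rci(tab, outcome = "raw_score"))
  expect_equal(dec$contributor[which.max(dec$share)], "mother_hs")
})

test_that("complete-case handling and report formatting behave", {
  cfg <- survey_config("2000", n_children = 600, seed = 9, missing_rate = 0.1)
  tab <- inject_missingness(generate_survey(cfg), cfg)
  expect_message(dec <- decompose_rci(tab, outcome = "raw_score"),
                 "complete-case")
  expect_equal(attr(dec, "n") + attr(dec, "n_dropped"), 600)
  rep_tab <- decomposition_report(dec)
  expect_equal(nrow(rep_tab), 17)
  expect_identical(rep_tab$contributor[17], "Residual")
  # sorted by descending contribution
  expect_true(all(diff(rep_tab$contribution_pct[1:16]) <= 0))
  expect_error(decompose_rci(tab, outcome = "raw_score",
                             contributors = c("log_pce", "not_a_column")),
               "not_a_column", class = "cogineq_schema_error")
})
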