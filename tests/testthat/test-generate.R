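test_that("identical configuration yields an identical table", {
  cfg <- survey_config("2000", n_children = 300, seed = 42)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  cfg2 <- survey_config("2000", n_children = 300, seed = 43)
  expect_false(identical(generate_survey(cfg), generate_survey(cfg2)))
})

test_that("generated tables respect the schema invariants", {
  tab <- small_survey(800, seed = 7)
  expect_equal(nrow(tab), 800)
  expect_true(all(tab$raw_score >= 0 & tab$raw_score <= 12))
  expect_true(all(tab$weight > 0))
  expect_true(all(tab$age >= 7 & tab$age <= 14))
  expect_true(all(levels(tab$father_edu) ==
                    c("none/primary", "high school", "university")))
  expect_true(all(tab$male %in% 0:1))
  expect_identical(unique(tab$round), "2000")
  # no missingness before injection
  expect_false(anyNA(tab))
  # scores increase with age on average
  by_age <- tapply(tab$raw_score, tab$age, mean)
  expect_gt(by_age[["14"]], by_age[["7"]])
  # left skew: within older ages the mass sits near the ceiling
  expect_lt(mean(tab$raw_score[tab$age >= 12]),
            median(tab$raw_score[tab$age >= 12]) + 0.5)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(survey_config(n_children = 0), "n_children",
               class = "cogineq_config_error")
  expect_error(survey_config(log_pce_sd = -1), "log_pce_sd",
               class = "cogineq_config_error")
  expect_error(survey_config(missing_rate = 1), "missing_rate",
               class = "cogineq_config_error")
  expect_error(survey_config(noise_sd = 0), "noise_sd",
               class = "cogineq_config_error")
  expect_error(survey_config(true_betas = c(nonsense = 1)), "true_betas",
               class = "cogineq_config_error")
  expect_error(survey_config(age_range = c(14, 7)), "age_range",
               class = "cogineq_config_error")
})

test_that("null model (all gradients and betas zero) shows no inequality", {
  zero_b <- setNames(rep(0, 16), cognitive_contributors()$contributor)
  g0 <- survey_config("2000", n_children = 5000, seed = 21)$covariate_gradients
  g0[] <- 0
  cfg <- survey_config("2000", n_children = 5000, seed = 21,
                       true_betas = zero_b, covariate_gradients = g0)
  tab <- generate_survey(cfg)
  tz <- quiet(apply_zscore(tab, fit_zscore_model(tab, mean_cutoff = Inf)))
  est <- estimate_rci(tz, outcome = "z")
  expect_lt(abs(est$estimate), 3 * est$se)
})

test_that("rank-gradient fidelity: configured gradients give the configured sign", {
  tab <- small_survey(5000, seed = 33)
  s <- ranked_sample(tab, outcome = "raw_score")
  tab <- add_education_dummies(tab)
  # positive gradient covariates concentrate among the rich
  for (col in c("mother_hs", "improved_sanitation", "electricity")) {
    expect_gt(contributor_concentration(tab[[col]], s), 0)
  }
  # rural residence and parental depression concentrate among the poor
  for (col in c("rural", "father_cesd")) {
    expect_lt(contributor_concentration(tab[[col]], s), 0)
  }
  # concentration matches a brute-force weighted covariance on the same table
  expect_equal(contributor_concentration(tab$mother_hs, s),
               oracle_rci_weighted(tab$mother_hs, s$rank, tab$weight),
               tolerance = 1e-12)
})

test_that("missingness injection is MAR, calibrated and reproducible", {
  cfg <- survey_config("2000", n_children = 6000, seed = 5, missing_rate = 0.3)
  tab <- generate_survey(cfg)
  masked <- inject_missingness(tab, cfg)
  eligible <- masked[, cogineq:::missingness_columns()]
  realized <- mean(is.na(as.data.frame(eligible)))
  n_cells <- prod(dim(eligible))
  se <- sqrt(0.3 * 0.7 / n_cells)
  expect_lt(abs(realized - 0.3), 3 * se)
  # outcome, ranking variable and weight are never masked
  expect_false(anyNA(masked$raw_score))
  expect_false(anyNA(masked$log_pce))
  expect_false(anyNA(masked$weight))
  # the mechanism leans on expenditure: the poorest tercile loses more cells
  poor <- masked$log_pce < quantile(masked$log_pce, 1 / 3)
  frac_by <- function(rows) mean(is.na(as.data.frame(eligible[rows, ])))
  expect_gt(frac_by(poor), frac_by(!poor))
  # reproducible, and a no-op at rate zero
  expect_identical(masked, inject_missingness(tab, cfg))
  cfg0 <- survey_config("2000", n_children = 100, seed = 5, missing_rate = 0)
  tab0 <- generate_survey(cfg0)
  expect_identical(inject_missingness(tab0, cfg0), tab0)
})

test_that("generator configs round-trip through JSON", {
  cfg <- survey_config("2007", n_children = 123, seed = 9, missing_rate = 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_survey_config(cfg, path)
  cfg2 <- read_survey_config(path)
  expect_equal(cfg2, cfg)
  expect_identical(generate_survey(cfg2), generate_survey(cfg))
})
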