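#' Generate a synthetic child-level household-survey table
#'
#' Draws a seeded table with the statistical structure the inequality analysis
#' assumes: log per-capita expenditure sets a living-standards rank; every
#' binary and categorical covariate follows a logistic model monotone in that
#' rank with the configured gradient and a calibrated marginal prevalence;
#' parental depression scores are gamma-distributed with a rank-dependent log
#' mean; and the 0-12 raw cognitive score comes from censoring and rounding a
#' latent linear index (contributor effects + age trend + noise), which makes
#' the score distribution left-skewed and increasing with age. Sampling
#' weights are gamma-shaped with mean 1.
#'
#' Missingness is not injected here; apply [inject_missingness()] to the
#' generated table when `missing_rate > 0`.
#'
#' @param config A [survey_config()] object.
#' @return A tibble with one row per child and columns `raw_score`, `age`,
#'   `male`, `in_school`, `father_edu`, `mother_edu`, `father_working`,
#'   `mother_working`, `father_cesd`, `mother_cesd`, `rural`, `javabali`,
#'   `electricity`, `improved_water`, `improved_sanitation`, `log_pce`,
#'   `weight`, `round`.
#' @export
#' @examples
#' tab <- generate_survey(survey_config(n_children = 200, seed = 7))
#' dplyr::count(tab, age)
generate_survey <- function(config) {
  if (!inherits(config, "survey_config")) {
    abort("`config` must be a survey_config object",
          class = "cogineq_config_error")
  }
  with_private_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(config) {
  n <- config$n_children
  g <- config$covariate_gradients
  p0 <- config$covariate_prevalence

  log_pce <- rnorm(n, config$log_pce_mean, config$log_pce_sd)
  # equal-weight fractional rank of the expenditure draw, rescaled to (-1, 1)
  u <- (rank(log_pce, ties.method = "first") - 0.5) / n
  s <- 2 * u - 1

  draw_binary <- function(name) {
    a <- calibrate_logit_intercept(p0[[name]], g[[name]])
    rbinom(n, 1L, plogis(a + g[[name]] * s))
  }
  draw_education <- function(parent) {
    grad <- g[[paste0(parent, "_edu")]]
    c_hs <- -calibrate_logit_intercept(p0[[paste0(parent, "_hs_or_more")]], grad)
    c_uni <- -calibrate_logit_intercept(p0[[paste0(parent, "_uni")]], grad)
    v <- runif(n)
    lev <- ifelse(v < plogis(grad * s - c_uni), "university",
                  ifelse(v < plogis(grad * s - c_hs), "high school",
                         "none/primary"))
    factor(lev, levels = edu_levels)
  }
  draw_cesd <- function(name) {
    m0 <- config$cesd_mean[[name]]
    mu <- exp(log(m0) + g[[name]] * s)
    mu <- mu * m0 / mean(mu)            # keep the configured marginal mean
    shape <- 0.5                        # heavy right tail, as in CES-D counts
    rgamma(n, shape = shape, rate = shape / mu)
  }

  tab <- tibble::tibble(
    age = sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE),
    male = draw_binary("male"),
    in_school = draw_binary("in_school"),
    father_edu = draw_education("father"),
    mother_edu = draw_education("mother"),
    father_working = draw_binary("father_working"),
    mother_working = draw_binary("mother_working"),
    father_cesd = draw_cesd("father_cesd"),
    mother_cesd = draw_cesd("mother_cesd"),
    rural = draw_binary("rural"),
    javabali = draw_binary("javabali"),
    electricity = draw_binary("electricity"),
    improved_water = draw_binary("improved_water"),
    improved_sanitation = draw_binary("improved_sanitation"),
    log_pce = log_pce
  )

  betas <- config$true_betas
  X <- as.matrix(add_education_dummies(tab)[names(betas)])
  lin <- drop(X %*% betas)
  age_mid <- mean(config$age_range)
  latent <- config$score_center +
    config$age_slope * (tab$age - age_mid) +
    config$score_scale * (lin - mean(lin) + rnorm(n, 0, config$noise_sd))
  tab$raw_score <- as.integer(pmin(12, pmax(0, round(latent))))

  tab$weight <- if (config$weight_dispersion <= 0) {
    rep(1, n)
  } else {
    shape <- 1 / config$weight_dispersion^2
    rgamma(n, shape = shape, rate = shape)
  }
  tab$round <- config$round_label

  tab[, c("raw_score", "age", "male", "in_school", "father_edu", "mother_edu",
          "father_working", "mother_working", "father_cesd", "mother_cesd",
          "rural", "javabali", "electricity", "improved_water",
          "improved_sanitation", "log_pce", "weight", "round")]
}

# intercept a such that the marginal prevalence of plogis(a + grad * s),
# s uniform on (-1, 1), equals `target`
calibrate_logit_intercept <- function(target, grad) {
  if (abs(grad) < 1e-12) return(stats::qlogis(target))
  sgrid <- seq(-1 + 1e-3, 1 - 1e-3, length.out = 501)
  f <- function(a) mean(plogis(a + grad * sgrid)) - target
  stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
}

#' Inject missing-at-random gaps into a survey table
#'
#' Masks covariate cells with a probability that depends only on the always
#' observed `log_pce` and `age` columns (a missing-at-random mechanism), with
#' the marginal per-cell rate calibrated to `config$missing_rate`. The raw
#' score, age, expenditure, weight, round, sex and residence columns are never
#' masked. The mask is seeded from the configuration, so repeated calls give
#' identical results.
#'
#' @param data A survey table from [generate_survey()] (or with the same
#'   columns).
#' @param config The [survey_config()] carrying `missing_rate`,
#'   `missing_gradient` and `seed`.
#' @return `data` with eligible cells set to `NA` (explicitly encoded, never
#'   dropped).
#' @export
inject_missingness <- function(data, config) {
  if (!inherits(config, "survey_config")) {
    abort("`config` must be a survey_config object",
          class = "cogineq_config_error")
  }
  if (config$missing_rate <= 0) return(data)
  check_columns(data, c("log_pce", "age", missingness_columns()))

  zsc <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
  zp <- zsc(data$log_pce)
  za <- zsc(data$age)
  f <- plogis(config$missing_gradient[1] * zp + config$missing_gradient[2] * za)
  p <- pmin(config$missing_rate * f / mean(f), 0.995)

  with_private_seed(config$seed + 1L, {
    for (col in missingness_columns()) {
      mask <- runif(nrow(data)) < p
      data[[col]][mask] <- NA
    }
  })
  data
}

# covariates eligible for missingness; the outcome, the ranking variable and
# the weight stay observed so that ranks and missingness models are well-posed
missingness_columns <- function() {
  c("in_school", "father_edu", "mother_edu", "father_working",
    "mother_working", "father_cesd", "mother_cesd", "electricity",
    "improved_water", "improved_sanitation")
}
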