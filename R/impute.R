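#' Configuration for chained-equations multiple imputation
#'
#' @param m Number of imputed datasets (default 20).
#' @param cycles Regression-switching sweeps per dataset (default 50).
#' @param seed Integer seed.
#' @param drop_no_parent Apply the exclusion rule that removes children
#'   without a resident parent before imputation. The rule looks for logical
#'   or 0/1 columns `father_present` / `mother_present` and drops rows where
#'   either is 0; tables without those columns are unaffected.
#' @return A list of class `"imputation_config"`.
#' @export
imputation_config <- function(m = 20, cycles = 50, seed = 1L,
                              drop_no_parent = TRUE) {
  check_number(m, "m", lower = 1, integerish = TRUE)
  check_number(cycles, "cycles", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (!is.logical(drop_no_parent) || length(drop_no_parent) != 1L) {
    stop_field("drop_no_parent", "must be TRUE or FALSE")
  }
  structure(list(m = as.integer(m), cycles = as.integer(cycles),
                 seed = as.integer(seed), drop_no_parent = drop_no_parent),
            class = "imputation_config")
}

apply_exclusion_rules <- function(data, config) {
  if (!config$drop_no_parent) return(data)
  present_cols <- intersect(c("father_present", "mother_present"), names(data))
  if (!length(present_cols)) return(data)
  keep <- rep(TRUE, nrow(data))
  for (col in present_cols) keep <- keep & (as.integer(data[[col]]) == 1L)
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("excluding %d children without a resident parent", dropped))
  }
  data[keep, , drop = FALSE]
}

#' Chained-equations multiple imputation of a survey table
#'
#' A transparent regression-switching sampler assuming data are missing at
#' random: each incomplete column is regressed in turn on all other model
#' columns over the rows where it was observed, and the missing cells are
#' replaced by posterior-style draws — for continuous columns a linear model
#' with coefficient and residual-variance draws plus Gaussian noise; for
#' binary and ordered categorical columns a latent linear score with noise,
#' thresholded to the nearest level. Cells observed in the input are never
#' altered. Initial gaps are filled by sampling each column's observed
#' empirical distribution. Imputation is performed within each survey round
#' separately; the sampling weight is not used as a predictor.
#'
#' Predictive-mean-matching parity with survey-software implementations is
#' deliberately not attempted.
#'
#' @param data A survey table (typically after [apply_zscore()], so the
#'   outcome `z` can serve as a predictor).
#' @param config An [imputation_config()].
#' @param columns Columns participating in the imputation model; defaults to
#'   the outcome, score, age and all analysis covariates present in `data`.
#' @param round Round column name (`NULL` to impute the table as one block).
#' @return A list of `m` completed tibbles.
#' @export
chained_impute <- function(data, config = imputation_config(),
                           columns = NULL, round = "round") {
  stopifnot(inherits(config, "imputation_config"))
  data <- apply_exclusion_rules(data, config)
  default_cols <- intersect(
    c("z", "raw_score", "age", "male", "in_school", "father_edu", "mother_edu",
      "father_working", "mother_working", "father_cesd", "mother_cesd",
      "rural", "javabali", "electricity", "improved_water",
      "improved_sanitation", "log_pce"),
    names(data))
  columns <- columns %||% default_cols
  check_columns(data, columns)

  none_observed <- columns[vapply(columns,
                                  function(cl) all(is.na(data[[cl]])),
                                  logical(1))]
  if (length(none_observed)) {
    abort(sprintf("column(s) with no observed values cannot be imputed: %s",
                  paste(none_observed, collapse = ", ")),
          class = "cogineq_unimputable_column_error")
  }

  groups <- if (!is.null(round) && round %in% names(data)) {
    split(seq_len(nrow(data)), data[[round]])
  } else list(seq_len(nrow(data)))

  with_private_seed(config$seed, {
    purrr::map(seq_len(config$m), function(i) {
      out <- data
      for (idx in groups) {
        out[idx, columns] <- impute_block(data[idx, columns, drop = FALSE],
                                          config$cycles)
      }
      out
    })
  })
}

# one completed copy of a single-round block (runs inside the seeded stream)
impute_block <- function(block, cycles) {
  cols <- names(block)
  miss <- purrr::map(block, is.na)
  incomplete <- cols[vapply(miss, any, logical(1))]
  if (!length(incomplete)) return(block)

  is_factor <- vapply(block, function(x) is.factor(x) || is.character(x),
                      logical(1))
  levels_of <- purrr::map(block[is_factor],
                          ~ if (is.factor(.x)) levels(.x) else sort(unique(.x[!is.na(.x)])))
  # numeric working copy: factors as 0-based level codes
  num <- purrr::imap(block, function(x, nm) {
    if (is_factor[[nm]]) as.numeric(factor(x, levels = levels_of[[nm]])) - 1
    else as.numeric(x)
  })
  num <- as.data.frame(num, check.names = FALSE)

  # initial fill: draws from the observed empirical distribution
  for (cl in incomplete) {
    obs <- num[[cl]][!miss[[cl]]]
    num[[cl]][miss[[cl]]] <- sample(obs, sum(miss[[cl]]), replace = TRUE)
  }

  binary_like <- function(x) all(x %in% c(0, 1))
  for (cycle in seq_len(cycles)) {
    for (cl in incomplete) {
      obs_rows <- !miss[[cl]]
      preds <- setdiff(cols, cl)
      Xall <- cbind(1, as.matrix(num[preds]))
      yobs <- num[[cl]][obs_rows]
      draw <- draw_regression_imputation(yobs, Xall[obs_rows, , drop = FALSE],
                                         Xall[!obs_rows, , drop = FALSE])
      yobs_vals <- num[[cl]][obs_rows]
      if (is_factor[[cl]] || binary_like(yobs_vals)) {
        k <- if (is_factor[[cl]]) length(levels_of[[cl]]) - 1 else 1
        num[[cl]][!obs_rows] <- pmin(k, pmax(0, round(draw)))
      } else {
        num[[cl]][!obs_rows] <- draw
      }
    }
  }

  for (cl in cols) {
    filled <- num[[cl]]
    if (is_factor[[cl]]) {
      filled <- factor(levels_of[[cl]][filled + 1], levels = levels_of[[cl]])
      if (is.character(block[[cl]])) filled <- as.character(filled)
    } else if (is.integer(block[[cl]])) {
      filled <- as.integer(round(filled))
    }
    # observed cells are restored verbatim, never the regression draws
    filled[!miss[[cl]]] <- block[[cl]][!miss[[cl]]]
    block[[cl]] <- filled
  }
  block
}

# proper imputation draw: sigma^2 from its scaled inverse-chi-square posterior,
# beta from its normal posterior given sigma^2, plus residual noise
draw_regression_imputation <- function(yobs, Xobs, Xmis) {
  qr_x <- qr(Xobs)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]   # drop collinear predictors
  Xo <- Xobs[, keep, drop = FALSE]
  Xm <- Xmis[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yobs)
  dfres <- max(length(yobs) - ncol(Xo), 1)
  sigma2_hat <- sum(fit$residuals^2) / dfres
  sigma2_star <- sigma2_hat * dfres / rchisq(1, dfres)
  XtXinv <- chol2inv(qr.R(qr(Xo)))
  beta_star <- fit$coefficients +
    drop(t(chol(sigma2_star * XtXinv + diag(1e-12, ncol(Xo)))) %*% rnorm(ncol(Xo)))
  drop(Xm %*% beta_star) + rnorm(nrow(Xm), 0, sqrt(sigma2_star))
}

#' Concentration index under multiple imputation
#'
#' Runs [chained_impute()], estimates the relative concentration index and
#' its delta-method SE on each completed dataset, and pools the results with
#' Rubin's rules. Imputation is used only for index estimation, never for the
#' decomposition.
#'
#' @inheritParams chained_impute
#' @inheritParams estimate_rci
#' @return An `"rci_result"` (pooled), with the per-imputation estimates in
#'   the `"imputations"` attribute.
#' @export
rci_with_imputation <- function(data, config = imputation_config(),
                                outcome = "z", rank_by = "log_pce",
                                weight = "weight", columns = NULL,
                                round = "round", conf_level = 0.95) {
  completed <- chained_impute(data, config, columns = columns, round = round)
  per <- purrr::map_dfr(completed, function(tab) {
    s <- ranked_sample(tab, outcome, rank_by, weight)
    tibble::tibble(estimate = rci(s), se = rci_se_delta(s), n = s$n)
  })
  pooled <- pool_rubin(per$estimate, per$se, conf_level = conf_level,
                       dfcom = per$n[1] - 1)
  pooled$n <- per$n[1]
  attr(pooled, "imputations") <- per
  pooled
}
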