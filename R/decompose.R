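#' Weighted least-squares fit of the outcome on its contributors
#'
#' Minimizes `sum(w_i * (y_i - alpha - x_i' beta)^2)` with an intercept.
#' Coefficient standard errors use the weights scaled to sum to the number of
#' rows, matching `lm(..., weights = )`.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric design matrix (contributors in columns, no intercept
#'   column; one is added).
#' @param w Positive weights.
#' @return A list of class `"weighted_ols"`: `betas` (named), `intercept`,
#'   `se` (contributor SEs), `residuals`, `fitted`, `xbar` (weighted column
#'   means), `mu` (weighted mean of `y`), `sigma2`, `n`.
#' @export
weighted_ols <- function(y, X, w) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n || length(w) != n) {
    abort("y, X and w must have matching rows", class = "cogineq_domain_error")
  }
  if (anyNA(y) || anyNA(X)) {
    abort("weighted_ols requires complete cases", class = "cogineq_domain_error")
  }
  wn <- normalize_weights(w)
  p <- ncol(X) + 1L
  if (n <= p - 1L) abort("more columns than rows", class = "cogineq_domain_error")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.wfit(x = Xi, y = y, w = wn * n)
  if (any(is.na(fit$coefficients))) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")),
          class = "cogineq_singular_design_error")
  }
  coefs <- fit$coefficients
  resid <- y - drop(Xi %*% coefs)
  sigma2 <- sum(wn * n * resid^2) / (n - p)
  XtWX <- crossprod(Xi * sqrt(wn * n))
  vcov <- sigma2 * solve(XtWX)
  structure(
    list(betas = coefs[-1L], intercept = coefs[[1L]],
         se = sqrt(diag(vcov))[-1L], residuals = resid,
         fitted = drop(Xi %*% coefs), xbar = drop(wn %*% X),
         mu = sum(wn * y), sigma2 = sigma2, vcov = vcov, n = n),
    class = "weighted_ols"
  )
}

#' @export
print.weighted_ols <- function(x, ...) {
  cat(sprintf("<weighted_ols> n = %d, %d contributors, sigma = %.4g\n",
              x$n, length(x$betas), sqrt(x$sigma2)))
  invisible(x)
}

#' @rdname tidy.rci_result
#' @method tidy weighted_ols
#' @export
tidy.weighted_ols <- function(x, ...) {
  tibble::tibble(term = names(x$betas), estimate = unname(x$betas),
                 std.error = unname(x$se))
}

#' Concentration index of a single contributor
#'
#' The relative concentration index of a contributor over the same
#' living-standards ranks as the outcome: `2 * sum(w * x * (rank - 0.5)) /
#' weighted.mean(x)`.
#'
#' @param x Numeric contributor vector, aligned with `sample`.
#' @param sample A [ranked_sample()] providing ranks and weights.
#' @return The contributor's concentration index.
#' @export
contributor_concentration <- function(x, sample) {
  stopifnot(inherits(sample, "ranked_sample"))
  if (length(x) != sample$n) abort("contributor length mismatch",
                                   class = "cogineq_domain_error")
  xbar <- sum(sample$w * x)
  if (xbar == 0) {
    abort("contributor has zero weighted mean; its relative index is undefined",
          class = "cogineq_undefined_index_error")
  }
  generalized_ci(x, sample$rank, sample$w) / xbar
}

#' Decompose the concentration index into contributor shares
#'
#' Regression-based (Wagstaff-type) decomposition. A weighted linear model of
#' the outcome on the contributors gives coefficients `beta_k`; with
#' elasticities `eta_k = beta_k * xbar_k / mu` and contributor concentration
#' indices `C_k`, the outcome's index decomposes exactly as
#' `C = sum(eta_k * C_k) + GC_eps / mu`, where `GC_eps` is the generalized
#' concentration index of the regression residual. Each contributor's share
#' is its term divided by the total index; shares are signed and, with the
#' residual share, sum to one.
#'
#' Rows with a missing value in any model variable are dropped (complete-case
#' analysis) with a message; weights are renormalized on the retained rows.
#'
#' @param data A survey table for a single round (education dummy columns are
#'   derived automatically from `father_edu` / `mother_edu` when needed).
#' @param outcome Outcome column name (default the age-standardized `z`).
#' @param contributors Character vector of contributor column names; defaults
#'   to `cognitive_contributors()$contributor`.
#' @inheritParams ranked_sample
#' @return An object of class `"rci_decomposition"`: a tibble with one row
#'   per contributor (`contributor`, `label`, `beta`, `se`, `xbar`,
#'   `elasticity`, `ck`, `contribution`, `share`) carrying the fit and sample
#'   as attributes (`total_rci`, `residual`, `residual_share`, `mu`, `n`,
#'   `n_dropped`, `fit`, `sample`, `X`).
#' @export
#' @examples
#' tab <- generate_survey(survey_config(n_children = 2000, seed = 4))
#' tab <- apply_zscore(tab, fit_zscore_model(tab))
#' dec <- decompose_rci(tab)
#' glance(dec)
decompose_rci <- function(data, outcome = "z",
                          contributors = cognitive_contributors()$contributor,
                          rank_by = "log_pce", weight = "weight",
                          ties = c("stable", "average")) {
  needs_dummies <- any(c("father_hs", "father_uni", "mother_hs", "mother_uni")
                       %in% contributors) &&
    !all(contributors %in% names(data))
  if (needs_dummies) data <- add_education_dummies(data)
  cols <- c(outcome, contributors, rank_by, weight)
  check_columns(data, cols)

  cc <- complete.cases(data[cols])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("complete-case decomposition: dropping %d of %d rows",
                   n_dropped, nrow(data)))
    data <- data[cc, , drop = FALSE]
  }

  s <- ranked_sample(data, outcome, rank_by, weight, ties = match.arg(ties))
  X <- as.matrix(dplyr::mutate(data[contributors],
                               dplyr::across(dplyr::everything(), as.numeric)))
  fit <- weighted_ols(s$y, X, s$w)

  total <- rci(s)
  gc_k <- vapply(seq_along(contributors),
                 function(j) generalized_ci(X[, j], s$rank, s$w), numeric(1))
  xbar <- fit$xbar
  beta <- fit$betas
  elasticity <- beta * xbar / s$mu
  ck <- ifelse(xbar == 0, NA_real_, gc_k / xbar)
  contribution <- beta * gc_k / s$mu           # eta_k * C_k, safe when xbar = 0
  residual <- generalized_ci(fit$residuals, s$rank, s$w) / s$mu

  if (total == 0) {
    warn("total concentration index is zero: shares undefined, raw contributions returned")
    share <- rep(NA_real_, length(contribution))
    residual_share <- NA_real_
  } else {
    share <- contribution / total
    residual_share <- residual / total
  }

  labels <- cognitive_contributors()
  out <- tibble::tibble(
    contributor = contributors,
    label = dplyr::coalesce(labels$label[match(contributors, labels$contributor)],
                            contributors),
    beta = unname(beta), se = unname(fit$se), xbar = unname(xbar),
    elasticity = unname(elasticity), ck = unname(ck),
    contribution = unname(contribution), share = unname(share)
  )
  structure(out,
            class = c("rci_decomposition", class(out)),
            total_rci = total, residual = residual,
            residual_share = residual_share, mu = s$mu, n = s$n,
            n_dropped = n_dropped, fit = fit, sample = s, X = X,
            outcome = outcome)
}

#' @export
print.rci_decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of RCI = %.4f (n = %d, %d dropped as incomplete)\n",
              attr(x, "total_rci"), attr(x, "n"), attr(x, "n_dropped")))
  print(decomposition_report(x), n = Inf)
  invisible(x)
}

#' @rdname tidy.rci_result
#' @method tidy rci_decomposition
#' @export
tidy.rci_decomposition <- function(x, ...) {
  out <- x
  attributes(out)[c("total_rci", "residual", "residual_share", "mu", "n",
                    "n_dropped", "fit", "sample", "X", "outcome")] <- NULL
  class(out) <- setdiff(class(out), "rci_decomposition")
  out
}

#' @rdname tidy.rci_result
#' @method glance rci_decomposition
#' @export
glance.rci_decomposition <- function(x, ...) {
  tibble::tibble(total_rci = attr(x, "total_rci"),
                 residual = attr(x, "residual"),
                 residual_share = attr(x, "residual_share"),
                 mu = attr(x, "mu"), n = attr(x, "n"),
                 n_dropped = attr(x, "n_dropped"))
}

#' Presentation table for a decomposition
#'
#' Formats a decomposition the way published contribution tables are laid
#' out: rows sorted by descending contribution share, columns for the
#' coefficient, elasticity, concentration index and integer percent
#' contribution (plus credible-interval bounds when supplied), with the
#' residual row last.
#'
#' @param x An `"rci_decomposition"`.
#' @param intervals Optional tibble from [contribution_intervals()] with
#'   columns `contributor`, `ci_low`, `ci_high` (share scale).
#' @param digits Decimals for the coefficient/elasticity/index columns.
#' @return A tibble, one row per contributor plus a `Residual` row.
#' @export
decomposition_report <- function(x, intervals = NULL, digits = 2) {
  stopifnot(inherits(x, "rci_decomposition"))
  tab <- tidy(x) |>
    dplyr::mutate(contribution_pct = round(100 * .data$share)) |>
    dplyr::arrange(dplyr::desc(.data$share)) |>
    dplyr::select("label", "beta", "elasticity", ck = "ck", "contribution_pct")
  tab <- dplyr::mutate(tab, dplyr::across(c("beta", "elasticity", "ck"),
                                          ~ round(.x, digits)))
  names(tab) <- c("contributor", "beta", "elasticity", "concentration_index",
                  "contribution_pct")
  if (!is.null(intervals)) {
    labels <- cognitive_contributors()
    ints <- intervals |>
      dplyr::mutate(
        contributor = dplyr::coalesce(
          labels$label[match(.data$contributor, labels$contributor)],
          .data$contributor),
        ci_low_pct = round(100 * .data$ci_low),
        ci_high_pct = round(100 * .data$ci_high)) |>
      dplyr::select("contributor", "ci_low_pct", "ci_high_pct")
    tab <- dplyr::left_join(tab, ints, by = "contributor")
  }
  dplyr::bind_rows(
    tab,
    tibble::tibble(contributor = "Residual", beta = NA_real_,
                   elasticity = NA_real_, concentration_index = NA_real_,
                   contribution_pct = round(100 * attr(x, "residual_share"))))
}
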