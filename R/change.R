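#' Oaxaca-type decomposition of the change in inequality between two rounds
#'
#' Splits the change in the outcome's concentration index between a base and a
#' later round into, per contributor, a changing-inequality term and a
#' changing-elasticity term. With elasticities `eta_kt` and contributor
#' indices `C_kt`, the default weighting is
#' `eta_kt * (C_kt - C_k,t-1) + C_k,t-1 * (eta_kt - eta_k,t-1)`; the mirrored
#' and symmetric (average-weight) variants are available via `weighting`. All
#' variants satisfy the exact identity that contributor totals plus the
#' residual change sum to the difference of the two total indices.
#'
#' Percent-of-change is each contributor's total divided by the total change
#' (residual included), so a contributor that moves the index in the same
#' direction as the overall change gets a positive percent. Percents are
#' computed from unrounded terms.
#'
#' @param before,after `"rci_decomposition"` objects for the base and later
#'   round, fitted on the same contributor set.
#' @param weighting `"current-inequality"` (default: current-period elasticity
#'   on the inequality change, base-period inequality on the elasticity
#'   change), `"base-inequality"` (the mirror), or `"average"` (symmetric
#'   two-fold weights).
#' @return A tibble of class `"rci_change"`, one row per contributor with
#'   `d_inequality`, `d_elasticity`, `total`, `percent_of_change`, carrying
#'   attributes `total_change`, `residual_change`, `rci_before`, `rci_after`,
#'   `weighting`.
#' @export
#' @examples
#' cfg0 <- survey_config("2000", n_children = 2000, seed = 5)
#' cfg1 <- survey_config("2007", n_children = 2000, seed = 6)
#' t0 <- generate_survey(cfg0); t1 <- generate_survey(cfg1)
#' zm <- fit_zscore_model(dplyr::bind_rows(t0, t1))
#' d0 <- decompose_rci(apply_zscore(t0, zm))
#' d1 <- decompose_rci(apply_zscore(t1, zm))
#' oaxaca_change(d0, d1)
oaxaca_change <- function(before, after,
                          weighting = c("current-inequality",
                                        "base-inequality", "average")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(before, "rci_decomposition"),
            inherits(after, "rci_decomposition"))
  if (!setequal(before$contributor, after$contributor)) {
    only_b <- setdiff(before$contributor, after$contributor)
    only_a <- setdiff(after$contributor, before$contributor)
    abort(sprintf(
      "contributor sets differ: only in `before`: %s; only in `after`: %s",
      paste(only_b, collapse = ", "), paste(only_a, collapse = ", ")),
      class = "cogineq_schema_error")
  }
  b <- tidy(before)
  a <- tidy(after)[match(before$contributor, after$contributor), ]
  if (anyNA(b$ck) || anyNA(a$ck)) {
    abort("a contributor has zero weighted mean in one round; its concentration index is undefined",
          class = "cogineq_undefined_index_error")
  }

  terms <- switch(
    weighting,
    "current-inequality" = list(
      d_ineq = a$elasticity * (a$ck - b$ck),
      d_elas = b$ck * (a$elasticity - b$elasticity)),
    "base-inequality" = list(
      d_ineq = b$elasticity * (a$ck - b$ck),
      d_elas = a$ck * (a$elasticity - b$elasticity)),
    "average" = list(
      d_ineq = (a$elasticity + b$elasticity) / 2 * (a$ck - b$ck),
      d_elas = (a$ck + b$ck) / 2 * (a$elasticity - b$elasticity))
  )

  rci_before <- attr(before, "total_rci")
  rci_after <- attr(after, "total_rci")
  total_change <- rci_after - rci_before
  residual_change <- attr(after, "residual") - attr(before, "residual")
  total_k <- terms$d_ineq + terms$d_elas

  out <- tibble::tibble(
    contributor = b$contributor, label = b$label,
    d_inequality = terms$d_ineq, d_elasticity = terms$d_elas,
    total = total_k,
    percent_of_change = if (total_change == 0) NA_real_ else {
      total_k / total_change
    }
  )
  structure(out, class = c("rci_change", class(out)),
            total_change = total_change, residual_change = residual_change,
            residual_percent = if (total_change == 0) NA_real_ else {
              residual_change / total_change
            },
            rci_before = rci_before, rci_after = rci_after,
            weighting = weighting)
}

#' @export
print.rci_change <- function(x, ...) {
  cat(sprintf("Change in RCI: %.4f -> %.4f (change %.4f, weighting: %s)\n",
              attr(x, "rci_before"), attr(x, "rci_after"),
              attr(x, "total_change"), attr(x, "weighting")))
  print(change_report(x), n = Inf)
  invisible(x)
}

#' @rdname tidy.rci_result
#' @method tidy rci_change
#' @export
tidy.rci_change <- function(x, ...) {
  out <- x
  attributes(out)[c("total_change", "residual_change", "residual_percent",
                    "rci_before", "rci_after", "weighting")] <- NULL
  class(out) <- setdiff(class(out), "rci_change")
  out
}

#' @rdname tidy.rci_result
#' @method glance rci_change
#' @export
glance.rci_change <- function(x, ...) {
  tibble::tibble(rci_before = attr(x, "rci_before"),
                 rci_after = attr(x, "rci_after"),
                 total_change = attr(x, "total_change"),
                 residual_change = attr(x, "residual_change"),
                 weighting = attr(x, "weighting"))
}

#' Presentation table for a change decomposition
#'
#' Rows sorted by descending percent of the total change, a `Residual` row,
#' and a bottom `Total` row holding the column sums; terms are rounded to two
#' decimals and percents to integers (percents are computed before rounding
#' the terms).
#'
#' @param x An `"rci_change"`.
#' @param digits Decimals for the term columns.
#' @return A tibble with columns `contributor`, `change_in_inequality`,
#'   `change_in_elasticity`, `total`, `percent`.
#' @export
change_report <- function(x, digits = 2) {
  stopifnot(inherits(x, "rci_change"))
  rows <- tidy(x) |>
    dplyr::arrange(dplyr::desc(.data$percent_of_change)) |>
    dplyr::transmute(
      contributor = .data$label,
      change_in_inequality = round(.data$d_inequality, digits),
      change_in_elasticity = round(.data$d_elasticity, digits),
      total = round(.data$total, digits),
      percent = round(100 * .data$percent_of_change))
  resid_row <- tibble::tibble(
    contributor = "Residual",
    change_in_inequality = NA_real_, change_in_elasticity = NA_real_,
    total = round(attr(x, "residual_change"), digits),
    percent = round(100 * attr(x, "residual_percent")))
  total_row <- tibble::tibble(
    contributor = "Total",
    change_in_inequality = round(sum(tidy(x)$d_inequality), digits),
    change_in_elasticity = round(sum(tidy(x)$d_elasticity), digits),
    total = round(attr(x, "total_change"), digits),
    percent = round(100 * (sum(tidy(x)$percent_of_change) +
                             attr(x, "residual_percent"))))
  dplyr::bind_rows(rows, resid_row, total_row)
}
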