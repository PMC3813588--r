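#' Plot a concentration curve
#'
#' Cumulative outcome share against cumulative population share (poorest to
#' richest) with the line of equality; the curve lying below the diagonal
#' indicates the outcome is concentrated among the better-off.
#'
#' @param object A `"concentration_curve"` from [concentration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concentration_curve
#' @export
autoplot.concentration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pop_share,
                                       y = .data$outcome_share)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative population share (ranked by per-capita expenditure)",
      y = "Cumulative outcome share") +
    ggplot2::theme_minimal()
}

#' Plot decomposition contribution shares
#'
#' Horizontal bars of the signed percent contribution of each contributor to
#' the total concentration index, residual included, ordered by contribution.
#'
#' @param object An `"rci_decomposition"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rci_decomposition
#' @export
autoplot.rci_decomposition <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::select("label", "share") |>
    dplyr::add_row(label = "Residual", share = attr(object, "residual_share")) |>
    dplyr::mutate(label = stats::reorder(.data$label, .data$share))
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$share, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "Contribution to total inequality (%)", y = NULL,
                  title = sprintf("Decomposition of RCI = %.3f",
                                  attr(object, "total_rci"))) +
    ggplot2::theme_minimal()
}

#' Plot a change decomposition
#'
#' Diverging bars of each contributor's changing-inequality and
#' changing-elasticity terms, ordered by the contributor's total share of the
#' between-round change.
#'
#' @param object An `"rci_change"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rci_change
#' @export
autoplot.rci_change <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(label = stats::reorder(.data$label, .data$total)) |>
    tidyr::pivot_longer(c("d_inequality", "d_elasticity"),
                        names_to = "component", values_to = "term") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            d_inequality = "Change in inequality",
                                            d_elasticity = "Change in elasticity"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$label,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "Contribution to change in RCI", y = NULL,
                  fill = NULL,
                  title = sprintf("Change in RCI: %.3f",
                                  attr(object, "total_change"))) +
    ggplot2::theme_minimal()
}
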