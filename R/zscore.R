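#' Fit an age-specific z-score model for the raw cognitive score
#'
#' Because raw item-count scores are skewed, the per-cell mean and SD are not
#' taken from the sample moments but recovered from the minimum, median,
#' maximum and size of each (round, age) cell with [hozo_mean()] and
#' [hozo_sd()]. The summaries are computed unweighted: they are order
#' statistics, for which no weighted variant is defined here.
#'
#' @param data Survey table with non-missing `raw_score` and `age` (rows with
#'   either missing are ignored with a message).
#' @param score,age,round Column names (strings) of the raw score, age and
#'   round label.
#' @param mean_cutoff,small_cutoff,large_cutoff Branch thresholds passed to
#'   [hozo_mean()] and [hozo_sd()].
#' @return A tibble of class `"zscore_model"`: one row per (round, age) cell
#'   with columns `round`, `age`, `n`, `min`, `median`, `max`, `est_mean`,
#'   `est_sd`.
#' @export
#' @examples
#' tab <- generate_survey(survey_config(n_children = 400, seed = 2))
#' fit_zscore_model(tab)
fit_zscore_model <- function(data, score = "raw_score", age = "age",
                             round = "round", mean_cutoff = 25,
                             small_cutoff = 15, large_cutoff = 70) {
  check_columns(data, c(score, age, round))
  keep <- !is.na(data[[score]]) & !is.na(data[[age]])
  if (!all(keep)) {
    inform(sprintf("dropping %d rows with missing score or age from the z-score fit",
                   sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  if (!nrow(data)) abort("no complete rows to fit on", class = "cogineq_domain_error")

  cells <- data |>
    dplyr::group_by(round = .data[[round]], age = .data[[age]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data[[score]]),
      median = stats::median(.data[[score]]),
      max = max(.data[[score]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      est_mean = hozo_mean(.data$min, .data$median, .data$max, .data$n,
                           mean_cutoff = mean_cutoff),
      est_sd = hozo_sd(.data$min, .data$median, .data$max, .data$n,
                       small_cutoff = small_cutoff,
                       large_cutoff = large_cutoff)
    )

  degenerate <- cells$est_sd <= 0
  if (any(degenerate)) {
    bad <- cells[degenerate, ]
    abort(sprintf("degenerate z-score cell(s) with zero spread: %s",
                  paste(sprintf("round %s age %s", bad$round, bad$age),
                        collapse = "; ")),
          class = "cogineq_degenerate_cell_error")
  }
  class(cells) <- c("zscore_model", class(cells))
  cells
}

#' Apply an age-specific z-score model
#'
#' Adds a `z` column, `(raw_score - est_mean) / est_sd`, looked up in the
#' (round, age) cell of `model`. Original columns are untouched; rows with a
#' missing raw score get a missing `z`.
#'
#' @param data Survey table.
#' @param model A `"zscore_model"` from [fit_zscore_model()] covering every
#'   (round, age) cell present in `data`.
#' @inheritParams fit_zscore_model
#' @return `data` with a `z` column appended.
#' @export
apply_zscore <- function(data, model, score = "raw_score", age = "age",
                         round = "round") {
  check_columns(data, c(score, age, round))
  if (!inherits(model, "zscore_model")) {
    abort("`model` must come from fit_zscore_model()", class = "cogineq_schema_error")
  }
  key <- paste(data[[round]], data[[age]], sep = "\r")
  mkey <- paste(model$round, model$age, sep = "\r")
  idx <- match(key, mkey)
  has_age <- !is.na(data[[age]])
  if (any(is.na(idx) & has_age)) {
    miss <- unique(key[is.na(idx) & has_age])
    abort(sprintf("no z-score cell for: %s",
                  paste(gsub("\r", " age ", miss), collapse = "; ")),
          class = "cogineq_lookup_error")
  }
  data$z <- (data[[score]] - model$est_mean[idx]) / model$est_sd[idx]
  data
}

#' Serialize / restore a z-score model as JSON
#'
#' @param model A `"zscore_model"`.
#' @param path File path; for `write_zscore_model()` the destination, for
#'   `read_zscore_model()` the source.
#' @return `read_zscore_model()` returns the restored model;
#'   `write_zscore_model()` returns `path` invisibly.
#' @export
write_zscore_model <- function(model, path) {
  jsonlite::write_json(as.data.frame(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_zscore_model
#' @export
read_zscore_model <- function(path) {
  cells <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  cells$round <- as.character(cells$round)
  class(cells) <- c("zscore_model", class(cells))
  cells
}
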