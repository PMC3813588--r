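#' Read and write survey tables as CSV
#'
#' Comma-separated UTF-8 with a header row, one child per line, empty field =
#' missing. Education columns are restored as factors with the declared
#' levels and `round` as character.
#'
#' @param data A survey table.
#' @param path File path.
#' @return `read_survey_csv()` returns a tibble; `write_survey_csv()` returns
#'   `path` invisibly.
#' @export
write_survey_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  for (col in intersect(c("father_edu", "mother_edu"), names(out))) {
    out[[col]] <- factor(out[[col]], levels = edu_levels)
  }
  if ("round" %in% names(out)) out$round <- as.character(out$round)
  out
}

#' Read and write generator configurations as JSON
#'
#' @param config A [survey_config()].
#' @param path File path.
#' @return `read_survey_config()` returns the restored `survey_config`;
#'   `write_survey_config()` returns `path` invisibly.
#' @export
write_survey_config <- function(config, path) {
  stopifnot(inherits(config, "survey_config"))
  out <- unclass(config)
  for (nm in c("true_betas", "covariate_gradients", "covariate_prevalence",
               "cesd_mean")) {
    out[[nm]] <- as.list(out[[nm]])     # keep the names in the JSON object
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_survey_config
#' @export
read_survey_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(survey_config, c(
    list(round_label = raw$round_label, n_children = raw$n_children,
         seed = raw$seed, log_pce_mean = raw$log_pce_mean,
         log_pce_sd = raw$log_pce_sd, noise_sd = raw$noise_sd,
         score_scale = raw$score_scale, score_center = raw$score_center,
         age_slope = raw$age_slope,
         weight_dispersion = raw$weight_dispersion,
         missing_rate = raw$missing_rate,
         missing_gradient = raw$missing_gradient,
         age_range = raw$age_range),
    list(true_betas = unlist(raw$true_betas),
         covariate_gradients = unlist(raw$covariate_gradients),
         covariate_prevalence = unlist(raw$covariate_prevalence),
         cesd_mean = unlist(raw$cesd_mean))))
}

#' Configuration for the end-to-end pipeline
#'
#' @param rounds A named list (names = round labels) whose elements are
#'   either [survey_config()] objects (tables are generated) or file paths to
#'   survey CSVs (tables are read). Exactly two rounds are required for the
#'   change-decomposition stage.
#' @param outcome,rank_by,weight Analysis column names; the outcome is the
#'   z-score column created by the standardization stage.
#' @param contributors Contributor set for the decompositions.
#' @param hozo_mean_cutoff Hozo mean branch threshold passed to
#'   [fit_zscore_model()]. The pipeline default `Inf` applies the quartic
#'   `(a + 2m + b) / 4` formula in every cell: with left-skewed scores the
#'   large-sample branch (the median itself) would center every cell above
#'   its mean, forcing a negative mean z-score and destabilizing the relative
#'   index, whereas the quartic formula keeps the mean z positive — the
#'   behaviour reported for this outcome.
#' @param mcmc Optional [mcmc_config()]; when supplied, decomposition tables
#'   carry equal-tail credible intervals.
#' @param imputation Optional [imputation_config()]; when supplied, the
#'   multiply-imputed pooled index is reported next to the complete-case one.
#' @param out_dir Output directory for artifacts (created if absent).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(rounds = list("2000" = survey_config("2000", seed = 1L),
                                          "2007" = survey_config("2007", seed = 2L)),
                            outcome = "z", rank_by = "log_pce",
                            weight = "weight",
                            contributors = cognitive_contributors()$contributor,
                            hozo_mean_cutoff = Inf,
                            mcmc = NULL, imputation = NULL,
                            out_dir = tempfile("cogineq-run-")) {
  if (!is.list(rounds) || is.null(names(rounds)) || any(!nzchar(names(rounds)))) {
    stop_field("rounds", "must be a fully named list")
  }
  if (length(rounds) != 2L) {
    stop_field("rounds", "exactly two rounds are required for the change stage")
  }
  ok <- vapply(rounds, function(r) inherits(r, "survey_config") ||
                 is_scalar_character(r), logical(1))
  if (!all(ok)) {
    stop_field("rounds", "each element must be a survey_config or a CSV path")
  }
  if (!is.null(mcmc)) stopifnot(inherits(mcmc, "mcmc_config"))
  if (!is.null(imputation)) stopifnot(inherits(imputation, "imputation_config"))
  if (!is.numeric(hozo_mean_cutoff) || length(hozo_mean_cutoff) != 1L ||
      is.na(hozo_mean_cutoff) || hozo_mean_cutoff < 0) {
    stop_field("hozo_mean_cutoff", "must be a single non-negative number (Inf allowed)")
  }
  structure(list(rounds = rounds, outcome = outcome, rank_by = rank_by,
                 weight = weight, contributors = contributors,
                 hozo_mean_cutoff = hozo_mean_cutoff, mcmc = mcmc,
                 imputation = imputation, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full inequality-analysis pipeline
#'
#' Orchestrates, per round: table acquisition (generation or CSV read),
#' missing-data injection for generated rounds with a positive
#' `missing_rate`, age-specific z-scoring, the complete-case concentration
#' index with delta-method interval, the optional multiply-imputed pooled
#' index, the Wagstaff-type decomposition (with optional Gibbs credible
#' intervals) and concentration-curve points; then the Oaxaca-type change
#' decomposition across the two rounds. All artifacts are written to
#' `config$out_dir` (JSON for machine-readable results, CSV for report
#' tables and curves) together with `run_log.json` recording seeds and
#' row-accounting per stage. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-round results (`tables`, `rci`,
#'   `rci_mi`, `decompositions`, `curves`), the `change` decomposition and
#'   the `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(rounds = list())

  tables <- list()
  for (label in names(config$rounds)) {
    spec <- config$rounds[[label]]
    if (inherits(spec, "survey_config")) {
      tab <- generate_survey(spec)
      if (spec$missing_rate > 0) tab <- inject_missingness(tab, spec)
      log$rounds[[label]] <- list(source = "generated", seed = spec$seed,
                                  rows_in = nrow(tab))
    } else {
      if (!file.exists(spec)) {
        abort(sprintf("input file not found: %s", spec),
              class = "cogineq_io_error")
      }
      tab <- read_survey_csv(spec)
      log$rounds[[label]] <- list(source = spec, rows_in = nrow(tab))
    }
    tables[[label]] <- tab
  }

  combined <- dplyr::bind_rows(tables)
  zmodel <- fit_zscore_model(combined, mean_cutoff = config$hozo_mean_cutoff)
  write_zscore_model(zmodel, file.path(config$out_dir, "zscore_model.json"))
  tables <- purrr::map(tables, apply_zscore, model = zmodel)

  results <- list()
  for (label in names(tables)) {
    tab <- tables[[label]]
    model_cols <- c(config$outcome, config$contributors, config$rank_by,
                    config$weight)
    tab_x <- add_education_dummies(tab)
    check_columns(tab_x, model_cols, where = sprintf("the round %s table", label))
    cc <- complete.cases(tab_x[model_cols])
    log$rounds[[label]]$rows_complete <- sum(cc)
    log$rounds[[label]]$rows_excluded_incomplete <- sum(!cc)

    est <- estimate_rci(tab_x[cc, , drop = FALSE], config$outcome,
                        config$rank_by, config$weight)
    jsonlite::write_json(glance(est),
                         file.path(config$out_dir, sprintf("rci_%s.json", label)),
                         digits = NA, auto_unbox = TRUE)

    est_mi <- NULL
    if (!is.null(config$imputation)) {
      est_mi <- rci_with_imputation(tab, config$imputation,
                                    outcome = config$outcome,
                                    rank_by = config$rank_by,
                                    weight = config$weight)
      jsonlite::write_json(
        dplyr::mutate(glance(est_mi), m = est_mi$m),
        file.path(config$out_dir, sprintf("rci_mi_%s.json", label)),
        digits = NA, auto_unbox = TRUE)
    }

    dec <- if (is.null(config$mcmc)) {
      decompose_rci(tab_x, config$outcome, config$contributors,
                    config$rank_by, config$weight)
    } else {
      decompose_rci_with_intervals(tab_x, config$outcome, config$contributors,
                                   config$rank_by, config$weight,
                                   mcmc = config$mcmc)
    }
    ints <- if (!is.null(config$mcmc)) {
      tibble::tibble(contributor = dec$contributor, ci_low = dec$ci_low,
                     ci_high = dec$ci_high)
    }
    readr::write_csv(decomposition_report(dec, intervals = ints),
                     file.path(config$out_dir,
                               sprintf("decomposition_%s.csv", label)), na = "")
    jsonlite::write_json(list(terms = tidy(dec), summary = glance(dec)),
                         file.path(config$out_dir,
                                   sprintf("decomposition_%s.json", label)),
                         digits = NA, auto_unbox = TRUE)

    curve <- concentration_curve(tab_x[cc, , drop = FALSE], config$outcome,
                                 config$rank_by, config$weight)
    readr::write_csv(curve,
                     file.path(config$out_dir, sprintf("curve_%s.csv", label)))
    results[[label]] <- list(rci = est, rci_mi = est_mi, decomposition = dec,
                             curve = curve)
  }

  labs <- names(config$rounds)
  change <- oaxaca_change(results[[labs[1]]]$decomposition,
                          results[[labs[2]]]$decomposition)
  readr::write_csv(change_report(change),
                   file.path(config$out_dir, "change.csv"), na = "")
  jsonlite::write_json(list(terms = tidy(change), summary = glance(change)),
                       file.path(config$out_dir, "change.json"),
                       digits = NA, auto_unbox = TRUE)

  # additivity audit: decomposition terms must reproduce the index exactly
  for (label in labs) {
    dec <- results[[label]]$decomposition
    gap <- abs(sum(dec$contribution) + attr(dec, "residual") -
                 attr(dec, "total_rci"))
    if (gap > 1e-8) {
      abort(sprintf("additivity identity violated in round %s (gap %.3g)",
                    label, gap), class = "cogineq_internal_error")
    }
    log$rounds[[label]]$additivity_gap <- gap
  }
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE)

  invisible(list(tables = tables,
                 rci = purrr::map(results, "rci"),
                 rci_mi = purrr::map(results, "rci_mi"),
                 decompositions = purrr::map(results, "decomposition"),
                 curves = purrr::map(results, "curve"),
                 change = change, log = log, out_dir = config$out_dir))
}
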