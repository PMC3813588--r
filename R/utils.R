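# internal helpers shared across modules

edu_levels <- c("none/primary", "high school", "university")

# evaluate `expr` under a private RNG stream; never disturbs the caller's RNG
with_private_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister")
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "cogineq_config_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_field(field, "must be a whole number")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop_field(field, sprintf("must be in %s%s, %s]",
                              if (strict_lower) "(" else "[", lower, upper))
  }
  invisible(x)
}

check_columns <- function(data, cols, where = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("column%s %s not found in %s",
                  if (length(missing_cols) > 1) "s" else "",
                  paste0("`", missing_cols, "`", collapse = ", "), where),
          class = "cogineq_schema_error")
  }
  invisible(data)
}

# weights normalized to sum to one (within whatever grouping the caller chose)
normalize_weights <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("all weights must be finite and > 0", class = "cogineq_domain_error")
  }
  w / sum(w)
}

#' Canonical contributor set
#'
#' The sixteen child, parental and household contributors used in the
#' decomposition of cognitive-function inequality, with the display labels
#' used in report tables. Parental education enters as high-school and
#' university attendance indicators with none/primary as the reference level.
#'
#' @return A tibble with columns `contributor` (column name used in design
#'   matrices) and `label` (report label).
#' @export
#' @examples
#' cognitive_contributors()
cognitive_contributors <- function() {
  tibble::tribble(
    ~contributor,          ~label,
    "log_pce",             "Log per capita expenditures",
    "improved_sanitation", "Use improved sanitation",
    "mother_hs",           "Mother attended high school",
    "father_uni",          "Father attended university",
    "mother_uni",          "Mother attended university",
    "electricity",         "Has electricity",
    "rural",               "Living in rural",
    "in_school",           "Child is attending school",
    "javabali",            "Living in Java/Bali",
    "father_cesd",         "Father's mental health scores",
    "mother_cesd",         "Mother's mental health scores",
    "father_hs",           "Father attended high school",
    "father_working",      "Father is working",
    "mother_working",      "Mother is working",
    "improved_water",      "Use improved drinking water",
    "male",                "Child is male"
  )
}

#' Expand a survey table into the decomposition design columns
#'
#' Adds the education dummy columns (`father_hs`, `father_uni`, `mother_hs`,
#' `mother_uni`) derived from the categorical `father_edu` / `mother_edu`
#' variables, leaving every other column untouched. The none/primary category
#' is the reference and gets no column.
#'
#' @param data A survey table with `father_edu` and `mother_edu` columns
#'   (character or factor with levels none/primary, high school, university).
#' @return `data` with the four indicator columns appended.
#' @export
add_education_dummies <- function(data) {
  check_columns(data, c("father_edu", "mother_edu"))
  for (parent in c("father", "mother")) {
    edu <- as.character(data[[paste0(parent, "_edu")]])
    bad <- !is.na(edu) & !edu %in% edu_levels
    if (any(bad)) {
      abort(sprintf("`%s_edu` contains undeclared levels: %s", parent,
                    paste(unique(edu[bad]), collapse = ", ")),
            class = "cogineq_schema_error")
    }
    data[[paste0(parent, "_hs")]] <- as.integer(edu == "high school")
    data[[paste0(parent, "_uni")]] <- as.integer(edu == "university")
  }
  data
}
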