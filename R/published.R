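#' Published inequality estimates for Indonesian children's cognitive function
#'
#' Bundled plain-text copies of published complete-case results from the
#' 2000 and 2007 IFLS rounds: the headline relative concentration indices
#' (complete-case and multiply-imputed), the per-round decomposition tables
#' (coefficient, elasticity, contributor concentration index, integer percent
#' contribution, equal-tail 95% interval bounds) and the Oaxaca-type change
#' table. These serve as worked inputs for internal-arithmetic checks — e.g.
#' recomputing a percent contribution as
#' `elasticity * concentration_index / total RCI` — since the underlying
#' microdata are not redistributable.
#'
#' @param table One of `"decomposition_2000"`, `"decomposition_2007"`,
#'   `"change"`, `"rci"`.
#' @return A tibble.
#' @export
#' @examples
#' published_table("rci")
published_table <- function(table = c("decomposition_2000",
                                      "decomposition_2007", "change", "rci")) {
  table <- match.arg(table)
  file <- switch(table,
                 decomposition_2000 = "published_decomposition_2000.csv",
                 decomposition_2007 = "published_decomposition_2007.csv",
                 change = "published_change_decomposition.csv",
                 rci = "published_rci.csv")
  path <- system.file("extdata", file, package = "cogineq", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
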