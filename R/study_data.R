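#' Bundled cloud-forest stream study tables
#'
#' The package ships the printed summary tables of a tropical montane
#' (cloud-forest) stream food-web study in eastern Mexico: two basal
#' resources (biofilm, leaf litter) and ten consumer taxa sampled across
#' three watershed land uses (forest, coffee plantation, pasture).
#'
#' `study_summary_table()` returns per-category isotopic means, SDs and
#' sample sizes — the template from which [make_study_fixture()] rebuilds a
#' synthetic per-individual dataset. `study_contribution_table()` returns
#' the study's per-cell posterior report (mode, mean and 2.5–97.5% credible
#' interval of each source contribution, trophic-level and trophic
#' enrichment factor means), the layout that [build_cell_table()] emits.
#'
#' @return A data frame; `study_summary_table()` carries the
#'   `summary_rows` class.
#' @seealso [make_study_fixture()], [allochthony_grand_mean()]
#' @export
study_summary_table <- function() {
  path <- system.file("extdata", "study_isotope_summaries.csv",
                      package = "allomix", mustWork = TRUE)
  read_summary_table(path)
}

#' @rdname study_summary_table
#' @export
study_contribution_table <- function() {
  path <- system.file("extdata", "study_contributions.csv",
                      package = "allomix", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-land-use leaf-litter summaries from a summary table
#'
#' Convenience extractor used to set the litter endmember in stage 1 and
#' the leaf-litter source prior in stage 2.
#'
#' @param rows A `summary_rows` data frame (default: the bundled study
#'   table).
#' @return Data frame with one row per land use: mean and sd per tracer.
#' @keywords internal
litter_summaries <- function(rows = study_summary_table()) {
  lit <- rows[rows$category == "leaf_litter", , drop = FALSE]
  if (nrow(lit) == 0) stop("no leaf_litter rows in summary table", call. = FALSE)
  data.frame(
    land_use = lit$land_use,
    d13C_mean = lit$d13C_mean, d13C_sd = lit$d13C_sd,
    d15N_mean = lit$d15N_mean, d15N_sd = lit$d15N_sd,
    row.names = NULL
  )
}
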