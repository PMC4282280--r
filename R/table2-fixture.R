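#' Published index scores of the 30 extreme nations
#'
#' The printed vulnerability, sensitivity, exposure and adaptive-capacity
#' ranks and scores of the 15 most- and 15 least-vulnerable nations of
#' the published 148-nation minimal additive model (its upper and lower
#' tenth percentiles), together with the climate-only and population-only
#' variant scores.  These are the only per-nation numbers the source
#' prints, and they anchor the model-reconstruction checks: feeding the
#' 30 (S, E, AC) triples through [vulnerability_additive()] reproduces
#' every printed vulnerability score to within the 2-decimal rounding of
#' the inputs.
#'
#' Ranks refer to the full 148-nation cohort; scores are 2-decimal.
#'
#' @return A 30-row tibble: `nation`, `extreme` (`"most"`/`"least"`),
#'   and rank/score pairs `v_rank, v, s_rank, s, e_rank, e, ac_rank, ac,
#'   v_climate_rank, v_climate, v_population_rank, v_population`.
#' @examples
#' tab2 <- table2_fixture()
#' subset(tab2, nation == "Kenya")
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_scores.csv", package = "livevuln",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccidididididid")
}

#' Index-score table from the published fixture
#'
#' Reshapes [table2_fixture()] into the `nation_id, S, E, AC` layout the
#' model stage consumes, so the printed index scores can drive
#' [vulnerability_additive()] directly (the indicator-preparation stage is
#' bypassed; component category scores are not printed).
#'
#' @return A tibble `nation_id, S, E, AC` with 30 rows.
#' @export
table2_index_scores <- function() {
  tab <- table2_fixture()
  tibble::tibble(nation_id = tab$nation, S = tab$s, E = tab$e, AC = tab$ac)
}
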