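#' Run the full vulnerability analysis pipeline
#'
#' Wires the stages end to end: read (or synthesise) the nation table,
#' validate it, score the indicator categories, compose and rescale the
#' indices, compute vulnerability under the requested models and scenario
#' variants, produce the aggregation reports (percentile extremes,
#' population-weighted group summaries, indicator influence, model
#' agreement) and the perturbation grid.  With an output directory the
#' stage outputs are written as CSV/JSON together with a manifest
#' recording the seed and a configuration hash; the run is idempotent
#' given the same inputs and seed.
#'
#' Exactly one of `input` and `synth` must be supplied.  `index_scores`
#' instead accepts a pre-composed `nation_id, S, E, AC` table (for
#' example [table2_index_scores()]) and bypasses the indicator stage, in
#' which case only the combined models and the grid run.
#'
#' @param input Path to an indicator CSV, or an indicator tibble.
#' @param synth A [synth_config()] to generate the cohort instead.
#' @param index_scores Optional pre-composed index-score table
#'   (bypasses indicator preparation; mutually exclusive with the above).
#' @param config Category configuration; defaults to the synthetic
#'   generator's own configuration when `synth` is used.
#' @param models,variants Passed to [vulnerability_models()].
#' @param missing Missing-data policy, see [handle_missing()].
#' @param grid_floor Near-zero baseline floor for [scenario_grid()].
#' @param out_dir Optional output directory.
#' @return A list with elements `table`, `validation`, `scores`,
#'   `indices`, `results`, `extremes`, `group_summaries`, `influence`,
#'   `model_agreement`, `grid`, `truth` (synthetic runs only) and
#'   `manifest`.
#' @export
run_pipeline <- function(input = NULL, synth = NULL, index_scores = NULL,
                         config = NULL,
                         models = c("additive", "multiplicative"),
                         variants = c("combined", "climate_only",
                                      "population_only"),
                         missing = "exclude", grid_floor = 0.01,
                         out_dir = NULL) {
  provided <- c(!is.null(input), !is.null(synth), !is.null(index_scores))
  if (sum(provided) != 1) {
    abort("Provide exactly one of 'input', 'synth' or 'index_scores'.",
          class = "livevuln_config_error")
  }

  truth <- NULL
  if (!is.null(index_scores)) {
    indices <- index_scores
    check_index_scores(indices)
    table <- validation <- scores <- NULL
    results <- dplyr::bind_rows(lapply(intersect(models,
        c("additive", "multiplicative")), function(m) {
      if (m == "additive") vulnerability_additive(indices)
      else vulnerability_multiplicative(indices)
    }))
    seed <- NULL
  } else {
    if (!is.null(synth)) {
      gen <- generate_nations(synth)
      table <- gen$table
      truth <- gen$truth
      config <- config %||% gen$config
      seed <- synth$seed
    } else {
      config <- config %||% default_category_config()
      table <- if (is.character(input)) read_indicator_csv(input, config)
               else input
      seed <- NULL
    }
    validation <- validate_table(table, config)
    scores <- score_indicators(table, config, missing = missing)
    indices <- compose_indices(scores, config)
    results <- vulnerability_models(indices, models = models,
                                    variants = variants, config = config)
  }

  combined_add <- dplyr::filter(results, .data$model == "additive",
                                .data$variant == "combined")
  if (nrow(combined_add) == 0) {
    combined_add <- dplyr::filter(results, .data$variant == "combined")
    combined_add <- dplyr::filter(combined_add,
                                  .data$model == combined_add$model[1])
  }

  extremes <- percentile_extremes(combined_add, 0.1)

  group_summaries <- influence <- NULL
  if (!is.null(scores)) {
    joined <- dplyr::left_join(
      combined_add,
      scores[intersect(c(META_COLS), names(scores))],
      by = "nation_id")
    group_summaries <- dplyr::bind_rows(lapply(
      c("region", "income_group", "developed_status"),
      function(g) weighted_group_mean(joined, g)))
    cat_cols <- setdiff(names(config$categories), character(0))
    influence <- spearman_influence(
      indices[c(cat_cols, "S", "E", "AC")],
      tibble::tibble(v = combined_add$v[match(indices$nation_id,
                                              combined_add$nation_id)]))
  }

  model_agreement <- NULL
  both <- c("additive", "multiplicative")
  if (all(both %in% unique(results$model))) {
    a <- dplyr::filter(results, .data$model == "additive",
                       .data$variant == "combined")
    b <- dplyr::filter(results, .data$model == "multiplicative",
                       .data$variant == "combined")
    b <- b[match(a$nation_id, b$nation_id), ]
    model_agreement <- wilcoxon_model_compare(a$v, b$v)
  }

  grid <- scenario_grid(indices, model = "additive", floor = grid_floor)

  manifest <- list(
    seed = seed,
    n_nations = nrow(indices),
    models = models, variants = variants,
    config_hash = rlang::hash(config),
    files = character(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(results = "results.csv", grid = "grid.csv")
    write_results(results, file.path(out_dir, "results.csv"))
    readr::write_csv(grid, file.path(out_dir, "grid.csv"), progress = FALSE)
    if (!is.null(group_summaries)) {
      readr::write_csv(group_summaries,
                       file.path(out_dir, "group_summaries.csv"),
                       progress = FALSE)
      files <- c(files, group_summaries = "group_summaries.csv")
    }
    if (!is.null(influence)) {
      jsonlite::write_json(influence, file.path(out_dir, "influence.json"),
                           dataframe = "rows", auto_unbox = TRUE, na = "null")
      files <- c(files, influence = "influence.json")
    }
    manifest$files <- as.list(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, na = "null", digits = NA)
  }

  list(table = table, validation = validation, scores = scores,
       indices = indices, results = results, extremes = extremes,
       group_summaries = group_summaries, influence = influence,
       model_agreement = model_agreement, grid = grid, truth = truth,
       manifest = manifest)
}
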