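#' Read a nation indicator table from CSV
#'
#' The file must carry a header row with the seven metadata columns
#' (`nation_id, name, region, income_group, developed_status, food_deficit,
#' population`) followed by one numeric column per raw indicator.  Every
#' non-metadata column must be declared by the category configuration;
#' missing cells are kept as `NA` (flagged later by [validate_table()]),
#' never silently dropped.
#'
#' @param path CSV file path.
#' @param config A `livevuln_config` declaring every indicator column.
#' @return A tibble with the metadata columns followed by the indicator
#'   columns in configuration order.
#' @seealso [write_indicator_csv()], [validate_table()]
#' @export
read_indicator_csv <- function(path, config) {
  validate_category_config(config)
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path), class = "livevuln_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_meta <- setdiff(META_COLS, names(tbl))
  if (length(missing_meta) > 0) {
    abort(sprintf("Mandatory metadata column(s) missing: %s",
                  paste(missing_meta, collapse = ", ")),
          class = "livevuln_schema_error")
  }
  indicator_cols <- setdiff(names(tbl), META_COLS)
  declared <- config_indicators(config)
  undeclared <- setdiff(indicator_cols, declared)
  if (length(undeclared) > 0) {
    abort(sprintf("Indicator column(s) not declared in the configuration: %s",
                  paste(undeclared, collapse = ", ")),
          class = "livevuln_config_error")
  }
  absent <- setdiff(declared, indicator_cols)
  if (length(absent) > 0) {
    abort(sprintf("Configured indicator column(s) absent from the file: %s",
                  paste(absent, collapse = ", ")),
          class = "livevuln_schema_error")
  }

  for (col in indicator_cols) {
    vals <- tbl[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d.",
                    vals[bad[1]], col, bad[1]),
            class = "livevuln_parse_error")
    }
    tbl[[col]] <- parsed
  }

  tbl$population <- {
    p <- suppressWarnings(as.numeric(tbl$population))
    if (anyNA(p) || any(p < 0, na.rm = TRUE)) {
      abort("Column 'population' must be numeric and non-negative.",
            class = "livevuln_schema_error")
    }
    p
  }
  tbl$food_deficit <- parse_flag(tbl$food_deficit)
  check_vocabulary(tbl$region, WB_REGIONS, "region")
  check_vocabulary(tbl$income_group, INCOME_GROUPS, "income_group")
  check_vocabulary(tbl$developed_status, DEVELOPED_STATUS, "developed_status")
  if (anyDuplicated(tbl$nation_id)) {
    abort("Duplicate nation_id values in input.", class = "livevuln_schema_error")
  }
  dplyr::select(tbl, dplyr::all_of(c(META_COLS, declared)))
}

parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(v, c("true", "t", "1", "yes") ~ TRUE,
                           c("false", "f", "0", "no") ~ FALSE,
                           .default = NA)
  if (anyNA(out[!is.na(x)])) {
    abort("Column 'food_deficit' must be logical (TRUE/FALSE).",
          class = "livevuln_schema_error")
  }
  out
}

check_vocabulary <- function(x, vocab, column) {
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) > 0) {
    abort(sprintf("Column '%s' has value(s) outside the declared vocabulary: %s",
                  column, paste(bad, collapse = "; ")),
          class = "livevuln_schema_error")
  }
  invisible(x)
}

#' Write a nation indicator table to CSV
#'
#' @param table An indicator table as returned by [read_indicator_csv()] or
#'   [generate_nations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_csv <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Completeness report for an indicator table
#'
#' Report-only screening: lists every (nation, indicator) pair with a
#' missing value, every indicator with fewer than two observed values, and
#' every indicator that is constant (zero range) across the observed
#' nations.  The table itself is never modified; the caller decides whether
#' to exclude or impute (see [handle_missing()]).
#'
#' @param table An indicator table.
#' @param config A `livevuln_config`.
#' @return A list of class `livevuln_validation` with tibbles
#'   `missing_cells` (`nation_id`, `indicator`), `sparse_indicators` and
#'   `zero_range_indicators`, and logical `ok`.
#' @export
validate_table <- function(table, config) {
  indicators <- config_indicators(config)
  missing_cells <- purrr::map_dfr(indicators, function(ind) {
    idx <- which(is.na(table[[ind]]))
    tibble::tibble(nation_id = table$nation_id[idx], indicator = rep(ind, length(idx)))
  })
  n_obs <- vapply(indicators, function(ind) sum(!is.na(table[[ind]])), integer(1))
  sparse <- tibble::tibble(indicator = indicators[n_obs < 2],
                           n_observed = n_obs[n_obs < 2])
  rng <- vapply(indicators, function(ind) {
    v <- table[[ind]][!is.na(table[[ind]])]
    if (length(v) == 0) NA_real_ else diff(range(v))
  }, numeric(1))
  zero_range <- tibble::tibble(
    indicator = indicators[!is.na(rng) & rng == 0 & n_obs >= 2])

  structure(list(missing_cells = missing_cells,
                 sparse_indicators = sparse,
                 zero_range_indicators = zero_range,
                 ok = nrow(missing_cells) == 0 && nrow(sparse) == 0 &&
                   nrow(zero_range) == 0),
            class = "livevuln_validation")
}

#' @export
print.livevuln_validation <- function(x, ...) {
  cat("<indicator table validation>\n")
  cat(sprintf("  missing cells:         %d\n", nrow(x$missing_cells)))
  cat(sprintf("  sparse indicators:     %d\n", nrow(x$sparse_indicators)))
  cat(sprintf("  zero-range indicators: %d\n", nrow(x$zero_range_indicators)))
  invisible(x)
}

#' Apply the missing-data policy
#'
#' Default policy is listwise exclusion: any nation missing any configured
#' indicator is dropped (the published analysis excluded incomplete nations
#' rather than imputing).  The alternative imputes each missing cell with
#' the cohort median of that indicator.
#'
#' @param table An indicator table.
#' @param config A `livevuln_config`.
#' @param policy `"exclude"` (default) or `"impute_median"`.
#' @return The table with the policy applied; the number of dropped nations
#'   (or imputed cells) is reported via a message when non-zero.
#' @export
handle_missing <- function(table, config,
                           policy = c("exclude", "impute_median")) {
  policy <- rlang::arg_match(policy)
  indicators <- config_indicators(config)
  if (policy == "exclude") {
    keep <- complete.cases(table[indicators])
    if (any(!keep)) {
      inform(sprintf("Excluding %d nation(s) with missing indicator values.",
                     sum(!keep)))
    }
    table[keep, , drop = FALSE]
  } else {
    n_imputed <- 0L
    for (ind in indicators) {
      miss <- is.na(table[[ind]])
      if (any(miss)) {
        table[[ind]][miss] <- median(table[[ind]], na.rm = TRUE)
        n_imputed <- n_imputed + sum(miss)
      }
    }
    if (n_imputed > 0) {
      inform(sprintf("Imputed %d cell(s) with indicator medians.", n_imputed))
    }
    table
  }
}

#' Write vulnerability results to CSV
#'
#' One row per nation and model variant, with the raw and rescaled
#' vulnerability, the rank (1 = most vulnerable) and the three rescaled
#' index scores.  Rows are ordered deterministically by model, variant,
#' rank, then nation_id; columns are in a stable order.
#'
#' @param results A vulnerability result tibble (see [vulnerability_additive()])
#'   or a row-bound collection of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("No results to write.", class = "livevuln_io_error")
  }
  cols <- c("nation_id", "model", "variant", "S", "E", "AC",
            "v_raw", "v", "rank")
  missing <- setdiff(cols, names(results))
  if (length(missing) > 0) {
    abort(sprintf("Results are missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "livevuln_io_error")
  }
  out <- dplyr::arrange(results[cols], .data$model, .data$variant,
                        .data$rank, .data$nation_id)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Long-format export for joining to country boundaries
#'
#' Pivot a result collection to one row per (nation, measure), a layout
#' that joins directly onto any country-boundary attribute table (for
#' example a GeoJSON property sheet) on `nation_id`.
#'
#' @inheritParams write_results
#' @return A tibble `nation_id, model, variant, measure, value`.
#' @export
results_long <- function(results) {
  tidyr::pivot_longer(
    results[c("nation_id", "model", "variant", "S", "E", "AC", "v")],
    cols = c("S", "E", "AC", "v"),
    names_to = "measure", values_to = "value")
}
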