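#' Extract the upper and lower percentile extremes
#'
#' Returns the `k = ceiling(fraction * n)` most- and least-vulnerable
#' nations of a result collection, each ordered by rank.  With the tenth
#' percentile on a 148-nation cohort this yields 15 nations per extreme.
#'
#' @param results A vulnerability tibble for a single model/variant.
#' @param fraction Proportion in (0, 0.5).
#' @return A list with tibbles `top` (most vulnerable, rank ascending) and
#'   `bottom` (least vulnerable, rank ascending within the tail), plus `k`.
#' @export
percentile_extremes <- function(results, fraction = 0.1) {
  if (is.null(results) || nrow(results) == 0) {
    abort("Empty result collection.", class = "livevuln_value_error")
  }
  if (!(fraction > 0 && fraction < 0.5)) {
    abort("fraction must lie in (0, 0.5).", class = "livevuln_value_error")
  }
  if (length(unique(paste(results$model, results$variant))) > 1) {
    abort("percentile_extremes expects a single model/variant.",
          class = "livevuln_value_error")
  }
  n <- nrow(results)
  k <- ceiling(fraction * n)
  ordered <- dplyr::arrange(results, .data$rank, .data$nation_id)
  list(top = head(ordered, k), bottom = tail(ordered, k), k = k)
}

#' Population-weighted group summaries
#'
#' Mean vulnerability and index scores per group (World Bank region,
#' income group or developed status), weighted by population size so that
#' smaller nations do not contribute disproportionately.  Groups are
#' ranked by weighted mean vulnerability, rank 1 = most vulnerable.
#'
#' @param data A tibble carrying the grouping column, a weight column and
#'   the score columns (typically a vulnerability result joined back to
#'   nation metadata).
#' @param grouping Name of the grouping column, e.g. `"region"`.
#' @param weight Name of the weight column (default `"population"`).
#' @param score_cols Score columns to summarise; the first is used for
#'   ranking.
#' @return A tibble `grouping, group, n_nations, <weighted means>, rank`.
#' @export
weighted_group_mean <- function(data, grouping, weight = "population",
                                score_cols = c("v", "S", "E", "AC")) {
  missing_cols <- setdiff(c(grouping, weight, score_cols), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) missing from data: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "livevuln_value_error")
  }
  if (any(data[[weight]] < 0, na.rm = TRUE)) {
    abort("Weights must be non-negative.", class = "livevuln_value_error")
  }
  out <- data |>
    dplyr::group_by(group = .data[[grouping]]) |>
    dplyr::summarise(
      n_nations = dplyr::n(),
      dplyr::across(dplyr::all_of(score_cols),
                    ~ weighted.mean(.x, w = .data[[weight]])),
      .groups = "drop")
  zero_w <- data |>
    dplyr::group_by(group = .data[[grouping]]) |>
    dplyr::summarise(total_w = sum(.data[[weight]]), .groups = "drop")
  bad <- zero_w$group[zero_w$total_w <= 0]
  if (length(bad) > 0) {
    abort(sprintf("Group(s) with no positive weight: %s",
                  paste(bad, collapse = ", ")),
          class = "livevuln_value_error")
  }
  out$rank <- as.integer(rank(-out[[score_cols[1]]], ties.method = "min"))
  dplyr::bind_cols(tibble::tibble(grouping = grouping), out) |>
    dplyr::arrange(.data$rank)
}

#' Influence of indicators and indices on a target score
#'
#' Spearman rank correlation (midranks for ties) of each component column
#' against each target column, with a two-sided p-value, quantifying how
#' strongly each indicator or index drives the vulnerability score.
#' Constant vectors give an undefined rho, reported as `NA` with a note.
#'
#' @param components Tibble of component scores (indicators or indices),
#'   one row per nation.
#' @param targets Tibble of target scores (same row order).
#' @param alpha Significance level recorded in the report (default 0.05).
#' @return A tibble `component, target, rho, p_value, n, significant, note`.
#' @export
spearman_influence <- function(components, targets, alpha = 0.05) {
  components <- tibble::as_tibble(components)
  components <- components[vapply(components, is.numeric, logical(1))]
  targets <- tibble::as_tibble(targets)
  targets <- targets[vapply(targets, is.numeric, logical(1))]
  if (nrow(components) != nrow(targets)) {
    abort("components and targets must have the same number of rows.",
          class = "livevuln_value_error")
  }
  if (nrow(components) < 3) {
    abort("Need at least 3 paired observations.",
          class = "livevuln_value_error")
  }
  grid <- tidyr::expand_grid(component = names(components),
                             target = names(targets))
  purrr::pmap_dfr(grid, function(component, target) {
    x <- components[[component]]
    y <- targets[[target]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(tibble::tibble(component = component, target = target,
                            rho = NA_real_, p_value = NA_real_,
                            n = length(x), significant = NA,
                            note = "undefined: constant vector"))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    alternative = "two.sided",
                                    exact = FALSE))
    tibble::tibble(component = component, target = target,
                   rho = unname(ct$estimate), p_value = ct$p.value,
                   n = length(x), significant = ct$p.value < alpha,
                   note = NA_character_)
  })
}

#' Wilcoxon signed-rank comparison of two paired score vectors
#'
#' Compares the scores (or ranks) two vulnerability models assign the same
#' cohort using the Wilcoxon signed-rank test.  Zero differences are
#' dropped before ranking (classic procedure) and reported; `n` counts the
#' non-zero pairs.  The p-value is exact for n <= 15 when the absolute
#' differences are untied, otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param on `"score"` to compare the values as given (default), `"rank"`
#'   to compare their descending ranks.
#' @return A tibble `statistic, p_value, n_used, n_zero, method, note`;
#'   when every difference is zero the comparison is degenerate and
#'   `p_value` is `NA`.
#' @export
wilcoxon_model_compare <- function(a, b, on = c("score", "rank")) {
  on <- rlang::arg_match(on)
  if (length(a) != length(b)) {
    abort("Paired vectors must have equal length.",
          class = "livevuln_value_error")
  }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (on == "rank") {
    a <- rank(-a, ties.method = "average")
    b <- rank(-b, ties.method = "average")
  }
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_used = 0L, n_zero = n_zero,
                          method = "degenerate",
                          note = "all paired differences are zero"))
  }
  exact <- n <= 15 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", mu = 0,
                exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_used = n, n_zero = n_zero,
                 method = if (exact) "exact" else "normal approximation",
                 note = if (n_zero > 0)
                   sprintf("%d zero difference(s) dropped", n_zero)
                 else NA_character_)
}
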