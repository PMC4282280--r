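#' Perturbation lattice for the robustness analysis
#'
#' Sensitivity and adaptive capacity are varied from -100% to +100% of
#' their main-model values at 10% increments: 21 levels per axis, all
#' pairwise combinations, 441 cells in total.  Levels are exact decimals
#' (computed as integers / 10) so the origin cell is exactly (0, 0).
#'
#' @return A tibble `delta_s, delta_ac` with 441 rows.
#' @export
build_grid <- function() {
  levels <- seq(-10L, 10L) / 10
  tidyr::expand_grid(delta_s = levels, delta_ac = levels)
}

#' Apply a proportional perturbation to the S and AC indices
#'
#' `S' = S * (1 + delta_s)` and `AC' = AC * (1 + delta_ac)`, each clamped
#' to \[0, 1\]; exposure is left untouched (the projected climate and
#' population changes stay in force).  Clamping events are reported via a
#' message and counted in attribute `"n_clamped"`.
#'
#' @param scores Tibble with `S`, `E`, `AC` columns.
#' @param delta_s,delta_ac Fractional offsets in \[-1, 1\].
#' @return `scores` with perturbed `S` and `AC`.
#' @export
apply_perturbation <- function(scores, delta_s, delta_ac) {
  if (abs(delta_s) > 1 || abs(delta_ac) > 1) {
    abort("Perturbations must lie in [-1, 1].", class = "livevuln_value_error")
  }
  s_new <- scores$S * (1 + delta_s)
  ac_new <- scores$AC * (1 + delta_ac)
  n_clamped <- sum(s_new > 1 | s_new < 0 | ac_new > 1 | ac_new < 0)
  if (n_clamped > 0) {
    inform(sprintf("Clamped %d perturbed score(s) to [0, 1].", n_clamped))
  }
  scores$S <- pmin(1, pmax(0, s_new))
  scores$AC <- pmin(1, pmax(0, ac_new))
  structure(scores, n_clamped = n_clamped)
}

# Raw (pre-rescale) vulnerability for a given model, vectorised over nations.
raw_vulnerability <- function(S, E, AC, model, form = "product",
                              epsilon = 0.01) {
  switch(model,
         additive = S + E - AC,
         multiplicative = if (form == "product") S * E * (1 - AC)
                          else S * E / (AC + epsilon),
         abort(sprintf("Unknown model '%s'.", model),
               class = "livevuln_config_error"))
}

#' Median percent change in vulnerability over the perturbation grid
#'
#' For every cell of the 21 x 21 lattice the S and AC indices are
#' perturbed ([apply_perturbation()]), raw vulnerability is recomputed
#' under projected exposure, and the per-nation percentage change relative
#' to the unperturbed baseline raw score is summarised by its median.
#' Percent change is computed on baseline-anchored raw values with no
#' per-cell rescaling: per-cell rescaling is affine-invariant and would
#' nullify uniform cohort-wide perturbations, so anchoring is the only
#' reading under which the grid can show non-zero medians.
#'
#' Nations whose baseline sits too close to zero (|rescaled baseline
#' score| below `floor`; for a single-nation cohort, |raw baseline| below
#' `floor`) are excluded from every cell's median to keep it finite; the
#' exclusion count is attached as attribute `"n_excluded"`.
#'
#' @param scores Tibble with complete `nation_id`, `S`, `E`, `AC`.
#' @param model `"additive"` (default) or `"multiplicative"`.
#' @param floor Near-zero baseline exclusion threshold (default 0.01).
#' @param form,epsilon Multiplicative-model options, see
#'   [vulnerability_multiplicative()].
#' @return A 441-row tibble `delta_s, delta_ac, median_pct_change, n_used`
#'   with attribute `"n_excluded"`.  A cell where every nation is excluded
#'   carries `NA` (flagged undefined).
#' @export
scenario_grid <- function(scores, model = c("additive", "multiplicative"),
                          floor = 0.01, form = "product", epsilon = 0.01) {
  model <- rlang::arg_match(model)
  check_index_scores(scores)
  v_base <- raw_vulnerability(scores$S, scores$E, scores$AC, model,
                              form, epsilon)
  include <- if (length(v_base) >= 2) {
    v_resc <- rescale_index(v_base)
    abs(v_resc) >= floor & v_base != 0
  } else {
    abs(v_base) >= floor
  }
  n_excluded <- sum(!include)
  if (n_excluded > 0) {
    inform(sprintf(
      "Excluding %d nation(s) with near-zero baseline vulnerability from the grid medians.",
      n_excluded))
  }
  grid <- build_grid()
  S <- scores$S[include]; E <- scores$E[include]; AC <- scores$AC[include]
  vb <- v_base[include]
  med <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s_p <- pmin(1, pmax(0, S * (1 + grid$delta_s[i])))
    ac_p <- pmin(1, pmax(0, AC * (1 + grid$delta_ac[i])))
    v_sim <- raw_vulnerability(s_p, E, ac_p, model, form, epsilon)
    med[i] <- if (length(vb) == 0) NA_real_
              else median(100 * (v_sim - vb) / vb)
  }
  out <- dplyr::mutate(grid, median_pct_change = med,
                       n_used = sum(include))
  structure(out, n_excluded = n_excluded)
}
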