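#' Compose the sensitivity, exposure and adaptive-capacity indices
#'
#' Sensitivity is the mean of the self-sufficiency, food-insecurity and
#' nutritional-contribution scores; exposure the mean of the climate and
#' population-growth scores; adaptive capacity the mean of the health,
#' economy and governance scores.  Each index is then rescaled from zero
#' to one across the cohort ([rescale_index()]).
#'
#' @param scores A category-score tibble from [score_indicators()] (or any
#'   tibble carrying `nation_id` and the configured category columns).
#' @param config A `livevuln_config`; its `index` fields decide which
#'   categories feed which index.
#' @return `scores` with columns `S`, `E`, `AC` appended (rescaled to
#'   \[0, 1\]).
#' @export
compose_indices <- function(scores, config = default_category_config()) {
  cats <- config$categories
  index_cols <- c(sensitivity = "S", exposure = "E", adaptive_capacity = "AC")
  for (idx_name in names(index_cols)) {
    idx <- index_cols[[idx_name]]
    members <- names(cats)[vapply(cats, function(x) x$index == idx_name,
                                  logical(1))]
    if (length(members) == 0) {
      abort(sprintf("No category feeds the %s index.", idx_name),
            class = "livevuln_config_error")
    }
    missing_cols <- setdiff(members, names(scores))
    if (length(missing_cols) > 0) {
      abort(sprintf("Category score column(s) missing: %s",
                    paste(missing_cols, collapse = ", ")),
            class = "livevuln_config_error")
    }
    raw <- rowMeans(as.matrix(scores[members]))
    scores[[idx]] <- rescale_index(raw)
  }
  scores
}

#' Sensitivity index (pre-rescale)
#'
#' @param ss,fs,nc Self-sufficiency, food-insecurity and
#'   nutritional-contribution scores in \[0, 1\].
#' @return `(ss + fs + nc) / 3`; `NA` propagates per nation.
#' @export
compose_sensitivity <- function(ss, fs, nc) (ss + fs + nc) / 3

#' Exposure index (pre-rescale)
#' @param cc,pg Climate-composite and population-growth scores in \[0, 1\].
#' @return `(cc + pg) / 2`.
#' @export
compose_exposure <- function(cc, pg) (cc + pg) / 2

#' Adaptive-capacity index (pre-rescale)
#' @param he,ec,gv Health, economy and governance scores in \[0, 1\].
#' @return `(he + ec + gv) / 3`.
#' @export
compose_adaptive_capacity <- function(he, ec, gv) (he + ec + gv) / 3

#' Rescale an index from zero to one across the cohort
#'
#' Min-max rescaling (delegating to [scale_minmax()] with polarity
#' `"higher"`), applied to the averaged index values so each index again
#' spans \[0, 1\] over the cohort.
#'
#' @param values Numeric vector of unrescaled index values.
#' @return Rescaled scores in \[0, 1\].
#' @export
rescale_index <- function(values) scale_minmax(values, "higher")

# Shared tail of the vulnerability constructors: rescale, rank, assemble.
finish_vulnerability <- function(scores, v_raw, model, variant) {
  v <- rescale_index(v_raw)
  rank <- rank(-v, ties.method = "min")
  if (anyDuplicated(rank)) {
    inform(sprintf("Tied vulnerability scores: %d nation(s) share a rank (minimum-rank convention).",
                   sum(duplicated(rank) | duplicated(rank, fromLast = TRUE))))
  }
  tibble::tibble(
    nation_id = scores$nation_id,
    model = model,
    variant = variant,
    S = scores$S, E = scores$E, AC = scores$AC,
    v_raw = v_raw, v = v, rank = as.integer(rank))
}

#' Additive vulnerability model
#'
#' Raw vulnerability is `S + E - AC`, in which the three indices contribute
#' equally: higher sensitivity or exposure raises vulnerability, higher
#' adaptive capacity lowers it.  The raw score is min-max rescaled over
#' the cohort so 0 is the least and 1 the most vulnerable nation.  Any
#' affine-equivalent combination (for example `(S + E + (1 - AC)) / 3`)
#' yields the identical rescaled score.
#'
#' @param scores A tibble with columns `nation_id`, `S`, `E`, `AC`
#'   (rescaled, complete), e.g. from [compose_indices()].
#' @param variant Label recorded in the output (`"combined"` for the full
#'   model; the scenario variants set their own label).
#' @return A tibble `nation_id, model, variant, S, E, AC, v_raw, v, rank`
#'   with rank 1 = most vulnerable (ties share the minimum rank).
#' @export
vulnerability_additive <- function(scores, variant = "combined") {
  check_index_scores(scores)
  finish_vulnerability(scores, scores$S + scores$E - scores$AC,
                       "additive", variant)
}

#' Multiplicative vulnerability model
#'
#' Raw vulnerability is by default `S * E * (1 - AC)`, so an extreme value
#' in any one index dominates the product rather than being offset by the
#' others.  An alternative ratio form `S * E / (AC + epsilon)` is
#' available; both are min-max rescaled, so the two forms differ only in
#' ordering.
#'
#' @inheritParams vulnerability_additive
#' @param form `"product"` for `S * E * (1 - AC)` (default) or `"ratio"`
#'   for `S * E / (AC + epsilon)`.
#' @param epsilon Small positive guard for the ratio form denominator.
#' @return As [vulnerability_additive()], with `model = "multiplicative"`.
#' @export
vulnerability_multiplicative <- function(scores, variant = "combined",
                                         form = c("product", "ratio"),
                                         epsilon = 0.01) {
  form <- rlang::arg_match(form)
  check_index_scores(scores)
  v_raw <- if (form == "product") {
    scores$S * scores$E * (1 - scores$AC)
  } else {
    if (epsilon <= 0) {
      abort("epsilon must be > 0 for the ratio form.",
            class = "livevuln_config_error")
    }
    scores$S * scores$E / (scores$AC + epsilon)
  }
  finish_vulnerability(scores, v_raw, "multiplicative", variant)
}

check_index_scores <- function(scores) {
  missing_cols <- setdiff(c("nation_id", "S", "E", "AC"), names(scores))
  if (length(missing_cols) > 0) {
    abort(sprintf("Index score column(s) missing: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "livevuln_value_error")
  }
  if (anyNA(scores[c("S", "E", "AC")])) {
    abort("S, E and AC must be complete; apply the missing-data policy first.",
          class = "livevuln_value_error")
  }
  invisible(scores)
}

#' Scenario variants: climate-only and population-only exposure
#'
#' Re-runs a vulnerability model with one of the two exposure components
#' held constant, to isolate the influence of projected climate change or
#' population growth acting individually.  Under the default
#' `hold = "cohort_mean"` policy the non-varying component is replaced by
#' its cohort mean, so it contributes no between-nation variance while E
#' stays on the combined model's scale; `hold = "drop"` removes the term
#' (E becomes the varying component alone).  Exposure is then recomposed
#' and rescaled and vulnerability recomputed.
#'
#' @param scores A category-score tibble carrying `cc` and `pg` columns
#'   plus everything [compose_indices()] needs.
#' @param vary `"climate"` (population growth held constant) or
#'   `"population"` (climate held constant).
#' @param model `"additive"` or `"multiplicative"`.
#' @param config A `livevuln_config`.
#' @param hold Hold-constant policy, `"cohort_mean"` or `"drop"`.
#' @param ... Passed to the multiplicative model (`form`, `epsilon`).
#' @return A vulnerability tibble labelled `variant = "climate_only"` or
#'   `"population_only"`.
#' @export
scenario_variant <- function(scores, vary = c("climate", "population"),
                             model = c("additive", "multiplicative"),
                             config = default_category_config(),
                             hold = c("cohort_mean", "drop"), ...) {
  vary <- rlang::arg_match(vary)
  model <- rlang::arg_match(model)
  hold <- rlang::arg_match(hold)
  held <- if (vary == "climate") "pg" else "cc"
  if (!all(c("cc", "pg") %in% names(scores))) {
    abort("Scenario variants need the 'cc' and 'pg' category scores.",
          class = "livevuln_value_error")
  }
  mod <- scores
  if (hold == "cohort_mean") {
    mod[[held]] <- mean(scores[[held]])
    mod <- compose_indices(mod, config)
  } else {
    varying <- if (vary == "climate") "cc" else "pg"
    mod <- compose_indices(mod, config)
    mod$E <- rescale_index(scores[[varying]])
  }
  variant <- paste0(vary, "_only")
  if (model == "additive") {
    vulnerability_additive(mod, variant = variant)
  } else {
    vulnerability_multiplicative(mod, variant = variant, ...)
  }
}

#' Run every requested model / variant combination
#'
#' Convenience wrapper producing a single row-bound result collection for
#' the additive and/or multiplicative model under the combined,
#' climate-only and population-only variants.
#'
#' @inheritParams scenario_variant
#' @param models Character subset of `c("additive", "multiplicative")`.
#' @param variants Character subset of
#'   `c("combined", "climate_only", "population_only")`.
#' @return Row-bound vulnerability tibble.
#' @export
vulnerability_models <- function(scores,
                                 models = c("additive", "multiplicative"),
                                 variants = c("combined", "climate_only",
                                              "population_only"),
                                 config = default_category_config(),
                                 hold = "cohort_mean", ...) {
  models <- match.arg(models, several.ok = TRUE)
  variants <- match.arg(variants, several.ok = TRUE)
  composed <- if (all(c("S", "E", "AC") %in% names(scores))) scores else
    compose_indices(scores, config)
  out <- list()
  for (m in models) {
    for (v in variants) {
      out[[paste(m, v)]] <- if (v == "combined") {
        if (m == "additive") vulnerability_additive(composed)
        else vulnerability_multiplicative(composed, ...)
      } else {
        scenario_variant(scores,
                         vary = sub("_only", "", v), model = m,
                         config = config, hold = hold, ...)
      }
    }
  }
  dplyr::bind_rows(out)
}
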