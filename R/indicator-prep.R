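#' Min-max scale an indicator across nations
#'
#' Linear absolute scaling to \[0, 1\]: the lowest observed value maps to 0
#' and the highest to 1, `(x - min) / (max - min)`.  Values are deliberately
#' *not* normalised to any distribution, so the true spread of the raw
#' indicator carries through to the final scores.  With
#' `polarity = "lower"` the scaled score is reversed (`1 - scaled`) so that
#' a higher score always means more of the index construct.
#'
#' @param x Numeric vector, one value per nation.  `NA`s propagate.
#' @param polarity `"higher"` (default) if larger raw values mean more of
#'   the construct, `"lower"` if they mean less.
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' scale_minmax(c(2, 4, 10))        # 0.00 0.25 1.00
#' scale_minmax(c(2, 4, 10), "lower")
#' @export
scale_minmax <- function(x, polarity = c("higher", "lower")) {
  polarity <- rlang::arg_match(polarity)
  obs <- x[!is.na(x)]
  if (length(obs) < 2) {
    abort("Min-max scaling needs at least 2 non-missing values.",
          class = "livevuln_scaling_error")
  }
  rng <- range(obs)
  if (rng[1] == rng[2]) {
    abort("Cannot min-max scale a constant (zero-range) indicator.",
          class = "livevuln_zero_range_error")
  }
  s <- (x - rng[1]) / (rng[2] - rng[1])
  if (polarity == "lower") 1 - s else s
}

#' Default livestock-unit coefficients
#'
#' Species-standardised headcount coefficients (reference cow = 1.0,
#' sheep = 0.15) used to compare herds across the grazing species —
#' ruminants and equids dependent on forage and pasture.  The cattle and
#' sheep values are the reference ones; the remaining species carry
#' commonly used default coefficients and can be overridden with a
#' two-column CSV (`species, coefficient`).
#'
#' @param path Optional CSV path overriding the built-in defaults.
#' @return Named numeric vector of coefficients.
#' @export
livestock_unit_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "livestock_units.csv",
                        package = "livevuln", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species", "coefficient") %in% names(tbl))) {
    abort("Coefficient file needs columns 'species' and 'coefficient'.",
          class = "livevuln_config_error")
  }
  coeffs <- setNames(as.numeric(tbl$coefficient), tolower(tbl$species))
  if (any(is.na(coeffs)) || any(coeffs <= 0)) {
    abort("Livestock-unit coefficients must be positive numbers.",
          class = "livevuln_config_error")
  }
  coeffs
}

#' Convert species head counts to livestock units
#'
#' @param counts Named numeric vector of head counts by species.
#' @param coeffs Named coefficient vector, see
#'   [livestock_unit_coefficients()].
#' @return Total livestock units, `sum(count_s * coeff_s)`.
#' @examples
#' to_livestock_units(c(cattle = 10, sheep = 100))  # 25
#' @export
to_livestock_units <- function(counts, coeffs = livestock_unit_coefficients()) {
  if (length(counts) == 0) return(0)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("Head counts must be non-negative.", class = "livevuln_value_error")
  }
  species <- tolower(names(counts))
  unknown <- setdiff(species, names(coeffs))
  if (length(unknown) > 0) {
    abort(sprintf("No livestock-unit coefficient for species: %s",
                  paste(unknown, collapse = ", ")),
          class = "livevuln_coefficient_error")
  }
  sum(counts * coeffs[species])
}

#' Self-sufficiency ratio for grazing-animal food products
#'
#' Consumption of home-produced grazing-animal food products as a
#' proportion of all consumed animal-based food products:
#' `(production - exports) / (production - exports + imports)`.  When
#' re-exports push exports above production, the ratio is clamped to
#' \[0, 1\] with a warning.
#'
#' @param production,exports,imports Non-negative quantities in common
#'   units (vectorised).
#' @return Ratio in \[0, 1\]; errors when the denominator is not positive.
#' @examples
#' self_sufficiency_ratio(100, 20, 80)  # 0.5
#' @export
self_sufficiency_ratio <- function(production, exports, imports) {
  if (any(c(production, exports, imports) < 0, na.rm = TRUE)) {
    abort("Quantities must be non-negative.", class = "livevuln_value_error")
  }
  num <- production - exports
  den <- production - exports + imports
  # net exporters (num < 0) are fully self-reliant on paper but the ratio
  # is a re-export artefact there: clamp to 0 with a warning.  A
  # non-positive denominator with non-negative net production means no
  # animal-product supply at all - the ratio is undefined.
  if (any(num >= 0 & den <= 0, na.rm = TRUE)) {
    abort("Self-sufficiency ratio undefined: non-positive denominator; flag the nation as missing.",
          class = "livevuln_undefined_ratio_error")
  }
  if (any(num < 0, na.rm = TRUE)) {
    warn("production < exports for some nation(s); ratio clamped to 0 (re-export artefact).")
  }
  ratio <- ifelse(num < 0, 0, num / den)
  pmin(1, pmax(0, ratio))
}

#' Climate-impact composite
#'
#' Single climate-change value per nation: the absolute projected change
#' in annual average temperature multiplied by the absolute projected
#' change in annual average precipitation, weighted by the percentage of
#' the population affected by droughts, flooding and extreme weather:
#' `cc_raw = |delta_t| * |delta_p| * w`.  The greater the projected change
#' — an increase or a decrease — the higher the score, so only magnitudes
#' enter.  Raw values are then min-max scaled across nations.
#'
#' Nations with `w = 0` score `cc_raw = 0` whatever the projected change
#' (the composite is purely multiplicative); such nations are reported via
#' a message.
#'
#' @param delta_t Signed projected temperature change (degrees C).
#' @param delta_p Signed projected precipitation change (native units).
#' @param w Percentage of population affected by extreme weather (>= 0).
#' @param scale If `TRUE` (default) return min-max scaled scores, else the
#'   raw products.
#' @return Numeric vector: scaled climate scores (or raw products).
#' @examples
#' climate_impact(c(2, 1), c(-0.5, 3), c(10, 5), scale = FALSE)  # 10 15
#' @export
climate_impact <- function(delta_t, delta_p, w, scale = TRUE) {
  n <- length(delta_t)
  if (length(delta_p) != n || length(w) != n) {
    abort("delta_t, delta_p and w must have equal length.",
          class = "livevuln_value_error")
  }
  if (any(w < 0, na.rm = TRUE)) {
    abort("w (% population affected) must be non-negative.",
          class = "livevuln_value_error")
  }
  raw <- abs(delta_t) * abs(delta_p) * w
  zero_w <- which(!is.na(w) & w == 0)
  if (length(zero_w) > 0) {
    inform(sprintf(
      "%d nation(s) have w = 0 and receive a zero climate composite regardless of projected change.",
      length(zero_w)))
  }
  if (!scale) return(raw)
  scale_minmax(raw, "higher")
}

#' Reduce a category to its most representative indicator
#'
#' Within a subject category every member indicator is correlated with
#' every other using Spearman rank correlation (midranks for ties,
#' pairwise-complete observations).  The member with the largest mean
#' absolute rho against the others is retained; the rest are discarded
#' from the minimal model.  A single-member category returns that member.
#' Exact ties (including the unavoidable symmetric tie of a two-member
#' category) are broken by configuration order — first listed wins — and
#' reported via a message.
#'
#' By default correlations enter as absolute values, since an indicator
#' inversely tracking its category is equally informative; set
#' `absolute = FALSE` for signed correlations.
#'
#' @param table An indicator table containing the member columns.
#' @param members Character vector of member indicator names, in
#'   configuration order.
#' @param absolute Use |rho| (default) or signed rho.
#' @return The retained indicator name (length-1 character), with the mean
#'   correlations attached as attribute `"mean_rho"`.
#' @export
reduce_category <- function(table, members, absolute = TRUE) {
  stopifnot(length(members) >= 1)
  missing_cols <- setdiff(members, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("Member column(s) absent from table: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "livevuln_config_error")
  }
  if (length(members) == 1) {
    return(structure(members, mean_rho = setNames(NA_real_, members)))
  }
  mat <- as.matrix(table[members])
  rho <- suppressWarnings(cor(mat, method = "spearman",
                              use = "pairwise.complete.obs"))
  if (absolute) rho <- abs(rho)
  diag(rho) <- NA
  mean_rho <- rowMeans(rho, na.rm = TRUE)
  if (all(is.nan(mean_rho)) || all(is.na(mean_rho))) {
    abort("All pairwise correlations undefined; cannot reduce category.",
          class = "livevuln_reduction_error")
  }
  best <- max(mean_rho, na.rm = TRUE)
  tied <- members[!is.na(mean_rho) & abs(mean_rho - best) < 1e-12]
  if (length(tied) > 1) {
    inform(sprintf("Reduction tie between {%s}; retaining first-listed '%s'.",
                   paste(tied, collapse = ", "), tied[1]))
  }
  structure(tied[1], mean_rho = mean_rho)
}

#' Score every category of an indicator table
#'
#' Runs the full indicator-preparation stage: applies the missing-data
#' policy, then for each configured category either computes the climate
#' composite ([climate_impact()]), reduces to the most representative
#' member ([reduce_category()]) and min-max scales it with its polarity,
#' or averages the scaled members (rule `"mean"`).  The result is one 0-1
#' score per nation per category.
#'
#' @param table An indicator table.
#' @param config A `livevuln_config`.
#' @param missing Missing-data policy, see [handle_missing()].
#' @return A tibble: metadata columns plus one score column per category,
#'   with attribute `"retained"` naming the indicator kept for each
#'   reduced category.
#' @export
score_indicators <- function(table, config,
                             missing = c("exclude", "impute_median")) {
  validate_category_config(config)
  if (nrow(table) < 2) {
    abort("At least 2 nations are required for scaling.",
          class = "livevuln_scaling_error")
  }
  table <- handle_missing(table, config, missing)
  if (nrow(table) < 2) {
    abort("Fewer than 2 complete nations remain after the missing-data policy.",
          class = "livevuln_scaling_error")
  }
  scores <- table[intersect(META_COLS, names(table))]
  retained <- character(0)
  for (nm in names(config$categories)) {
    cat <- config$categories[[nm]]
    members <- names(cat$members)
    if (cat$reduce == "climate_composite") {
      scores[[nm]] <- climate_impact(table$delta_t, table$delta_p,
                                     table$extreme_weather_w)
    } else if (cat$reduce == "spearman_max") {
      keep <- reduce_category(table, members)
      retained[nm] <- keep
      scores[[nm]] <- scale_minmax(table[[keep]], cat$members[[keep]])
    } else { # mean
      scaled <- vapply(members, function(mb) {
        scale_minmax(table[[mb]], cat$members[[mb]])
      }, numeric(nrow(table)))
      scores[[nm]] <- rowMeans(scaled)
    }
  }
  attr(scores, "retained") <- retained
  scores
}
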