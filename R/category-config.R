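#' Category configuration
#'
#' A category configuration declares, for every non-metadata column of an
#' indicator table, which subject category it belongs to, which index the
#' category feeds (sensitivity, exposure or adaptive capacity), the polarity
#' of each indicator with respect to that index construct, and the rule used
#' to collapse the category to a single 0-1 score:
#'
#' * `"spearman_max"` — retain the member that rank-correlates most strongly
#'   (mean absolute Spearman rho) with the other members, then min-max scale
#'   it (the minimal-model reduction rule).
#' * `"mean"` — min-max scale every member and average the scaled scores.
#' * `"climate_composite"` — members must be exactly `delta_t`, `delta_p`
#'   and `extreme_weather_w`; the category score is the min-max scaled
#'   product |delta_t| * |delta_p| * w.
#'
#' `default_category_config()` builds the eight-category minimal-model
#' layout: three sensitivity categories (self-sufficiency `ss`, food
#' insecurity `fs`, nutritional contribution `nc`), two exposure categories
#' (climate impact `cc`, population growth `pg`) and three adaptive-capacity
#' categories (health `he`, economy `ec`, governance `gv`).  Member columns
#' are named `<category>_1 ... <category>_m`, except the climate category
#' whose members are always the three named climate inputs.
#'
#' @param indicators_per_category Number of member indicators generated per
#'   non-climate category (the governance category of the published layout
#'   carries six members; any count >= 1 is legal here).
#' @param reduce Reduction rule applied to non-climate categories.
#' @param lower_polarity Character vector of member indicator names to mark
#'   as `"lower"` polarity (more of the raw value means *less* of the index
#'   construct, so the scaled score is reversed).  Defaults to the second
#'   health member when present, mimicking a mortality-type indicator.
#' @return A `livevuln_config` object: a list with element `categories`,
#'   itself a named list of `list(index, reduce, members)` entries where
#'   `members` is a named character vector of polarities.
#' @examples
#' cfg <- default_category_config(indicators_per_category = 2)
#' names(cfg$categories)
#' @export
default_category_config <- function(indicators_per_category = 3,
                                    reduce = c("spearman_max", "mean"),
                                    lower_polarity = NULL) {
  reduce <- rlang::arg_match(reduce)
  stopifnot(indicators_per_category >= 1)
  m <- indicators_per_category
  if (is.null(lower_polarity) && m >= 2) lower_polarity <- "he_2"

  categories <- lapply(names(INDEX_OF_CATEGORY), function(cat) {
    if (cat == "cc") {
      members <- setNames(rep("higher", 3), CLIMATE_MEMBERS)
      list(index = "exposure", reduce = "climate_composite",
           members = members)
    } else {
      nm <- paste0(cat, "_", seq_len(m))
      pol <- ifelse(nm %in% lower_polarity, "lower", "higher")
      list(index = unname(INDEX_OF_CATEGORY[cat]), reduce = reduce,
           members = setNames(pol, nm))
    }
  })
  names(categories) <- names(INDEX_OF_CATEGORY)
  new_category_config(categories)
}

new_category_config <- function(categories) {
  cfg <- structure(list(categories = categories), class = "livevuln_config")
  validate_category_config(cfg)
  cfg
}

validate_category_config <- function(config) {
  if (!is.list(config$categories) || length(config$categories) == 0) {
    abort("Configuration must declare at least one category.",
          class = "livevuln_config_error")
  }
  all_members <- character(0)
  for (nm in names(config$categories)) {
    cat <- config$categories[[nm]]
    if (!all(c("index", "reduce", "members") %in% names(cat))) {
      abort(sprintf("Category '%s' must declare index, reduce and members.", nm),
            class = "livevuln_config_error")
    }
    if (!cat$index %in% c("sensitivity", "exposure", "adaptive_capacity")) {
      abort(sprintf("Category '%s': unknown index '%s'.", nm, cat$index),
            class = "livevuln_config_error")
    }
    if (!cat$reduce %in% c("spearman_max", "mean", "climate_composite")) {
      abort(sprintf("Category '%s': unknown reduction rule '%s'.", nm, cat$reduce),
            class = "livevuln_config_error")
    }
    if (cat$reduce == "climate_composite" &&
        !identical(sort(names(cat$members)), sort(CLIMATE_MEMBERS))) {
      abort(sprintf(
        "Category '%s': climate_composite members must be exactly {%s}.",
        nm, paste(CLIMATE_MEMBERS, collapse = ", ")),
        class = "livevuln_config_error")
    }
    if (!all(cat$members %in% c("higher", "lower"))) {
      abort(sprintf("Category '%s': polarities must be 'higher' or 'lower'.", nm),
            class = "livevuln_config_error")
    }
    all_members <- c(all_members, names(cat$members))
  }
  if (anyDuplicated(all_members)) {
    abort(sprintf("Indicator(s) assigned to more than one category: %s",
                  paste(unique(all_members[duplicated(all_members)]),
                        collapse = ", ")),
          class = "livevuln_config_error")
  }
  invisible(config)
}

#' All indicator columns declared by a configuration
#' @param config A `livevuln_config`.
#' @return Character vector of member indicator names, in declaration order.
#' @export
config_indicators <- function(config) {
  unlist(lapply(config$categories, function(cat) names(cat$members)),
         use.names = FALSE)
}

#' Read / write a category configuration as YAML
#'
#' The on-disk format mirrors the in-memory layout:
#' ```yaml
#' categories:
#'   ss:
#'     index: sensitivity
#'     reduce: spearman_max
#'     members: {ss_1: higher, ss_2: higher}
#' ```
#'
#' @param path File path.
#' @return `read_category_config()` returns a validated `livevuln_config`;
#'   `write_category_config()` returns `path` invisibly.
#' @export
read_category_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Configuration file not found: %s", path),
          class = "livevuln_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories)) {
    abort("Configuration file has no 'categories' block.",
          class = "livevuln_config_error")
  }
  categories <- lapply(raw$categories, function(cat) {
    list(index = cat$index, reduce = cat$reduce,
         members = unlist(cat$members))
  })
  new_category_config(categories)
}

#' @rdname read_category_config
#' @param config A `livevuln_config` to serialize.
#' @export
write_category_config <- function(config, path) {
  validate_category_config(config)
  out <- list(categories = lapply(config$categories, function(cat) {
    list(index = cat$index, reduce = cat$reduce,
         members = as.list(cat$members))
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.livevuln_config <- function(x, ...) {
  cat("<livevuln category configuration>\n")
  for (nm in names(x$categories)) {
    cat(sprintf("  %-3s [%s, %s]: %s\n", nm, x$categories[[nm]]$index,
                x$categories[[nm]]$reduce,
                paste(names(x$categories[[nm]]$members), collapse = ", ")))
  }
  invisible(x)
}
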