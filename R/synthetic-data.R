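#' Configuration for the synthetic-nation generator
#'
#' Describes a cohort with the statistical structure the vulnerability
#' analysis assumes: three latent indices per nation (sensitivity,
#' exposure, adaptive capacity), eight indicator categories whose member
#' columns are noisy monotone transforms of the relevant latent index,
#' climate-change projections with mixed-sign precipitation deltas,
#' projected population growth allowing negative values, and group labels
#' drawn from the World Bank vocabularies.  Latent adaptive capacity is
#' negatively correlated with latent sensitivity (default -0.4), so
#' synthetic extremes resemble observed cohorts in which high-sensitivity
#' nations also have low capacity to adapt.
#'
#' The default cohort size and group frequencies mirror the published
#' 148-nation analysis (7 regions with 17/47/24/13/2/5/40 nations; income
#' groups 28/39/42/39; developed status 36/77/35).
#'
#' @param n_nations Cohort size (>= 2).
#' @param seed Integer seed; the same configuration and seed always yield
#'   an identical table.
#' @param indicators_per_category Member indicators per non-climate
#'   category.
#' @param intra_category_rho Target pairwise Spearman correlation between
#'   members of the same category, in \[0, 1\] (honoured when
#'   `noise_sd > 0`; a noiseless run emits exact monotone transforms).
#' @param noise_sd Standard deviation of the observation noise linking a
#'   category to its latent index (on the standard-normal latent scale);
#'   0 gives noiseless indicators.
#' @param s_ac_correlation Latent correlation between sensitivity and
#'   adaptive capacity (default -0.4).
#' @param population_meanlog,population_sdlog Log-normal parameters for
#'   national population size.
#' @param region_probs,income_probs,status_probs Category probabilities
#'   for the group labels (named or in vocabulary order).
#' @param food_deficit_prob Baseline probability of the food-deficit flag
#'   (modulated downward for high-adaptive-capacity nations).
#' @return A `livevuln_synth_config` list.
#' @export
synth_config <- function(n_nations = 148, seed = 1,
                         indicators_per_category = 3,
                         intra_category_rho = 0.8,
                         noise_sd = 0.05,
                         s_ac_correlation = -0.4,
                         population_meanlog = 16,
                         population_sdlog = 1.5,
                         region_probs = c(17, 47, 24, 13, 2, 5, 40) / 148,
                         income_probs = c(28, 39, 42, 39) / 148,
                         status_probs = c(36, 77, 35) / 148,
                         food_deficit_prob = 0.4) {
  if (n_nations < 2) {
    abort("n_nations must be >= 2.", class = "livevuln_config_error")
  }
  if (intra_category_rho < 0 || intra_category_rho > 1) {
    abort("intra_category_rho must lie in [0, 1].",
          class = "livevuln_config_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0.", class = "livevuln_config_error")
  }
  if (abs(s_ac_correlation) > 1) {
    abort("s_ac_correlation must lie in [-1, 1].",
          class = "livevuln_config_error")
  }
  structure(list(
    n_nations = as.integer(n_nations), seed = seed,
    indicators_per_category = as.integer(indicators_per_category),
    intra_category_rho = intra_category_rho, noise_sd = noise_sd,
    s_ac_correlation = s_ac_correlation,
    population_meanlog = population_meanlog,
    population_sdlog = population_sdlog,
    region_probs = region_probs, income_probs = income_probs,
    status_probs = status_probs, food_deficit_prob = food_deficit_prob),
    class = "livevuln_synth_config")
}

# Monotone marginal transforms giving each indicator plausible native
# units.  `y` is a standard-normal latent score already oriented so that
# larger y = more of the index construct; lower-polarity indicators
# receive -y so the raw column runs the other way.
synth_marginal <- function(category, j, y) {
  u <- pnorm(y)
  switch(category,
    ss = u,                              # self-sufficiency ratio, 0-1
    fs = 100 * plogis(1.3 * y - 0.9),    # % prevalence of food inadequacy
    nc = 40 * plogis(1.1 * y),           # % dietary energy from grazing products
    pg = -15 + 110 * u,                  # projected % population change
    he = 45 + 38 * u,                    # life-expectancy-like, years
    ec = exp(22 + 2.2 * y),              # GDP-like, USD
    gv = 2.5 * tanh(0.8 * y),            # governance estimate, [-2.5, 2.5]
    abort(sprintf("No marginal transform for category '%s'.", category)))
}

#' Generate a synthetic nation table with known latent truth
#'
#' Indicators are drawn from a Gaussian copula: each category has a
#' latent factor `c = (z + noise_sd * u) / sqrt(1 + noise_sd^2)` around
#' its parent index `z`, and each member indicator is
#' `(c + tau * e) / sqrt(1 + tau^2)` pushed through a monotone marginal
#' transform into native units.  `tau` is set from the target
#' intra-category Spearman correlation via the normal-score relation
#' `rho_pearson = 2 sin(pi rho_s / 6)`.  When `noise_sd = 0` all noise is
#' switched off and every indicator is an exact monotone transform of its
#' latent index, so the pipeline recovers the latent ordering exactly.
#'
#' The climate category always emits `delta_t` (degrees C, warming),
#' `delta_p` (mm, mixed signs) and `extreme_weather_w` (% population
#' affected); the population-growth category emits percentage changes
#' including negative (European-style) values.
#'
#' The returned truth holds each nation's latent index levels
#' (`s_true`, `e_true`, `ac_true` = normal CDF of the latent z) and the
#' additive-model vulnerability ordering implied by the noiseless forward
#' model, against which pipeline recovery can be scored.
#'
#' @param config A [synth_config()].
#' @return A list with elements `table` (indicator tibble in the
#'   [read_indicator_csv()] schema), `truth` (tibble `nation_id, s_true,
#'   e_true, ac_true, v_raw_true, v_rank_true`) and `config` (the category
#'   configuration describing the generated columns).
#' @export
generate_nations <- function(config = synth_config()) {
  if (!inherits(config, "livevuln_synth_config")) {
    abort("config must come from synth_config().",
          class = "livevuln_config_error")
  }
  cat_config <- default_category_config(config$indicators_per_category)
  withr::with_seed(config$seed, {
    n <- config$n_nations
    # Latent indices on the standard-normal scale; AC tied to S.
    z_s <- rnorm(n)
    r <- config$s_ac_correlation
    z_ac <- r * z_s + sqrt(1 - r^2) * rnorm(n)
    z_e <- rnorm(n)
    z_of <- list(sensitivity = z_s, exposure = z_e, adaptive_capacity = z_ac)

    rho_p <- 2 * sin(pi * config$intra_category_rho / 6)
    tau <- if (config$noise_sd == 0 || config$intra_category_rho >= 1) 0
           else if (rho_p <= 0) Inf
           else sqrt(1 / rho_p - 1)

    latent_member <- function(z, u_cat, e_mem) {
      c_k <- (z + config$noise_sd * u_cat) / sqrt(1 + config$noise_sd^2)
      if (is.infinite(tau)) return(e_mem)
      (c_k + tau * e_mem) / sqrt(1 + tau^2)
    }

    # Draw all noise first so the noiseless truth table can reuse the
    # same structural randomness (delta_p signs, metadata draws).
    cols <- list(); cols0 <- list()
    for (nm in names(cat_config$categories)) {
      cat <- cat_config$categories[[nm]]
      z <- z_of[[cat$index]]
      u_cat <- rnorm(n)
      base_cat <- if (nm == "cc") "cc" else nm
      for (j in seq_along(cat$members)) {
        member <- names(cat$members)[j]
        e_mem <- rnorm(n)
        y <- latent_member(z, u_cat, e_mem)
        sgn <- if (cat$members[[member]] == "lower") -1 else 1
        if (nm == "cc") {
          # Three fixed climate inputs, magnitudes monotone in the latent.
          if (member == "delta_t") {
            cols[[member]] <- 0.8 + 2.2 * pnorm(y)
            cols0[[member]] <- 0.8 + 2.2 * pnorm(z)
          } else if (member == "delta_p") {
            p_sign <- sample(c(-1, 1), n, replace = TRUE)
            cols[[member]] <- p_sign * (5 + 145 * pnorm(y))
            cols0[[member]] <- p_sign * (5 + 145 * pnorm(z))
          } else {
            cols[[member]] <- 45 * pnorm(y)^2
            cols0[[member]] <- 45 * pnorm(z)^2
          }
        } else {
          cols[[member]] <- synth_marginal(base_cat, j, sgn * y)
          cols0[[member]] <- synth_marginal(base_cat, j, sgn * z)
        }
      }
    }

    meta <- tibble::tibble(
      nation_id = synth_nation_ids(n),
      name = paste("Nation", synth_nation_ids(n)),
      region = sample(WB_REGIONS, n, replace = TRUE,
                      prob = config$region_probs),
      income_group = grade_by_latent(z_ac, INCOME_GROUPS,
                                     config$income_probs),
      developed_status = grade_by_latent(z_ac, DEVELOPED_STATUS,
                                         config$status_probs),
      food_deficit = runif(n) < plogis(qlogis(config$food_deficit_prob) -
                                         1.0 * z_ac),
      population = round(rlnorm(n, config$population_meanlog,
                                config$population_sdlog)))

    table <- dplyr::bind_cols(meta, tibble::as_tibble(cols))
    table0 <- dplyr::bind_cols(meta, tibble::as_tibble(cols0))

    # Truth: the additive-model ordering under the noiseless forward
    # model (suppress reduction-tie chatter from perfectly correlated
    # noiseless members).
    scores0 <- suppressMessages(score_indicators(table0, cat_config))
    idx0 <- compose_indices(scores0, cat_config)
    v0 <- suppressMessages(vulnerability_additive(idx0))
    truth <- tibble::tibble(
      nation_id = meta$nation_id,
      s_true = pnorm(z_s), e_true = pnorm(z_e), ac_true = pnorm(z_ac)) |>
      dplyr::left_join(
        dplyr::select(v0, "nation_id", v_raw_true = "v_raw",
                      v_rank_true = "rank"),
        by = "nation_id")

    list(table = table, truth = truth, config = cat_config)
  })
}

# Noisy ordinal grading: cut a jittered latent into levels with the given
# marginal probabilities, so group labels correlate with (but are not
# determined by) latent adaptive capacity.
grade_by_latent <- function(z, levels, probs) {
  score <- (z + 0.8 * rnorm(length(z))) / sqrt(1 + 0.64)
  breaks <- c(-Inf, qnorm(cumsum(probs / sum(probs)))[-length(probs)], Inf)
  levels[cut(score, breaks = breaks, labels = FALSE)]
}

synth_nation_ids <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1
  paste0(LETTERS[i %/% 676 + 1], LETTERS[(i %/% 26) %% 26 + 1],
         LETTERS[i %% 26 + 1])
}
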