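# Small in-code fixtures shared across test files.

# A 5-nation indicator table with one indicator per category (plus the
# three climate inputs), in the read_indicator_csv() schema.
tiny_config <- function() default_category_config(indicators_per_category = 1)

tiny_table <- function() {
  tibble::tibble(
    nation_id = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    name = paste("Nation", nation_id),
    region = c("Sub-Saharan Africa", "South Asia", "Europe and Central Asia",
               "North America", "East Asia and Pacific"),
    income_group = c("low", "lower middle", "high", "high", "upper middle"),
    developed_status = c("least developed", "developing", "developed",
                         "developed", "developing"),
    food_deficit = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    population = c(1e7, 8e7, 5e7, 3e8, 6e7),
    ss_1 = c(0.9, 0.7, 0.3, 0.2, 0.5),
    fs_1 = c(45, 30, 5, 4, 18),
    nc_1 = c(25, 30, 12, 15, 20),
    delta_t = c(2.5, 2.8, 1.2, 1.5, 2.0),
    delta_p = c(-60, 80, 20, -30, 50),
    extreme_weather_w = c(12, 20, 1, 3, 8),
    pg_1 = c(80, 60, -5, 20, 10),
    he_1 = c(50, 62, 81, 79, 74),
    ec_1 = c(2e9, 5e11, 3e12, 1.5e13, 1e12),
    gv_1 = c(-1.5, -0.6, 1.8, 1.4, 0.2))
}

# A small index-score table (already rescaled S/E/AC plus the cc and pg
# category scores scenario variants need).
tiny_scores <- function() {
  tibble::tibble(
    nation_id = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    ss = c(1, 0.7, 0.1, 0, 0.4), fs = c(1, 0.6, 0, 0.05, 0.3),
    nc = c(0.7, 1, 0, 0.2, 0.5),
    cc = c(0.8, 1, 0, 0.1, 0.4), pg = c(1, 0.75, 0, 0.3, 0.2),
    he = c(0, 0.4, 1, 0.9, 0.75), ec = c(0, 0.03, 0.2, 1, 0.07),
    gv = c(0, 0.3, 1, 0.85, 0.5))
}

# Independent Spearman oracle: 1 - 6*sum(d^2)/(n(n^2-1)), valid without ties.
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive signed-rank oracle: statistic (sum of ranks of positive
# differences) and two-sided exact p over all 2^n sign assignments.
signed_rank_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  all_w <- signs %*% r
  p <- min(1, 2 * min(mean(all_w <= w), mean(all_w >= w)))
  list(statistic = w, p_value = p, n = n)
}

quiet <- function(expr) suppressMessages(expr)
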