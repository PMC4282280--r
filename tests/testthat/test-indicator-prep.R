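test_that("min-max scaling matches the elementwise formula and handles polarity", {
  expect_equal(scale_minmax(c(2, 4, 10)), c(0, 0.25, 1))
  expect_equal(scale_minmax(c(2, 4, 10), "lower"), c(1, 0.75, 0))

  set.seed(42)
  x <- rnorm(50, 10, 4)
  oracle <- vapply(x, function(xi) (xi - min(x)) / (max(x) - min(x)),
                   numeric(1))
  s <- scale_minmax(x)
  expect_equal(s, oracle)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s[which.min(x)], 0)
  expect_equal(s[which.max(x)], 1)
  expect_identical(order(s), order(x))  # strictly order-preserving

  expect_error(scale_minmax(c(5, 5, 5)), class = "livevuln_zero_range_error")
  expect_error(scale_minmax(c(NA, NA, 3)), class = "livevuln_scaling_error")
  expect_equal(scale_minmax(c(2, NA, 10)), c(0, NA, 1))  # NA propagates
})

test_that("livestock-unit conversion is the coefficient-weighted sum and linear", {
  expect_equal(to_livestock_units(c(cattle = 10, sheep = 100)), 25)
  expect_equal(to_livestock_units(numeric(0)), 0)

  coeffs <- livestock_unit_coefficients()
  set.seed(7)
  counts <- setNames(round(runif(7, 0, 5000)), sample(names(coeffs), 7))
  oracle <- 0
  for (sp in names(counts)) oracle <- oracle + counts[[sp]] * coeffs[[sp]]
  expect_equal(to_livestock_units(counts, coeffs), oracle)
  # linearity in counts
  expect_equal(to_livestock_units(3 * counts, coeffs),
               3 * to_livestock_units(counts, coeffs))

  expect_error(to_livestock_units(c(dragon = 2), coeffs),
               class = "livevuln_coefficient_error", regexp = "dragon")
})

test_that("self-sufficiency ratio follows the trade formula with clamping", {
  expect_equal(self_sufficiency_ratio(100, 20, 80), 0.5)
  expect_equal(self_sufficiency_ratio(50, 0, 0), 1)
  expect_warning(r <- self_sufficiency_ratio(10, 20, 5), "clamped")
  expect_equal(r, 0)
  expect_error(self_sufficiency_ratio(10, 10, 0),
               class = "livevuln_undefined_ratio_error")
})

test_that("climate composite is |dt|*|dp|*w, sign-symmetric, annihilated by w=0", {
  expect_equal(climate_impact(2, -0.5, 10, scale = FALSE), 10)
  expect_equal(quiet(climate_impact(c(3, 5), c(100, -40), c(0, 2),
                                    scale = FALSE))[1], 0)

  set.seed(11)
  dt <- rnorm(5, 0, 2); dp <- rnorm(5, 0, 50); w <- runif(5, 1, 30)
  raw_oracle <- vapply(1:5, function(i) abs(dt[i]) * abs(dp[i]) * w[i],
                       numeric(1))
  oracle_scaled <- (raw_oracle - min(raw_oracle)) /
    (max(raw_oracle) - min(raw_oracle))
  expect_equal(climate_impact(dt, dp, w), oracle_scaled)
  # negating either delta leaves the composite unchanged
  expect_equal(climate_impact(-dt, dp, w), climate_impact(dt, dp, w))
  expect_equal(climate_impact(dt, -dp, w), climate_impact(dt, dp, w))
})

test_that("category reduction keeps the member with highest mean |rho|", {
  set.seed(3)
  tbl <- tibble::tibble(x1 = rnorm(30))
  tbl$x2 <- tbl$x1 + rnorm(30, sd = 0.05)   # near-monotone copy of x1
  tbl$x3 <- sample(tbl$x1)                   # shuffled: uncorrelated

  keep <- reduce_category(tbl, c("x1", "x2", "x3"))
  expect_true(keep %in% c("x1", "x2"))

  # brute-force oracle via the rank-difference Spearman formula
  rho <- function(a, b) spearman_oracle(a, b)
  mean_abs <- c(
    x1 = mean(abs(c(rho(tbl$x1, tbl$x2), rho(tbl$x1, tbl$x3)))),
    x2 = mean(abs(c(rho(tbl$x2, tbl$x1), rho(tbl$x2, tbl$x3)))),
    x3 = mean(abs(c(rho(tbl$x3, tbl$x1), rho(tbl$x3, tbl$x2)))))
  expect_identical(as.character(keep), names(which.max(mean_abs)))
  expect_equal(attr(keep, "mean_rho")[[keep]], max(mean_abs),
               tolerance = 1e-12)

  # single member: returned as-is; two members: symmetric tie, first wins
  expect_identical(as.character(reduce_category(tbl, "x3")), "x3")
  expect_message(two <- reduce_category(tbl, c("x2", "x1")), "tie")
  expect_identical(as.character(two), "x2")
})

test_that("reduction is invariant to strictly monotone member transforms", {
  set.seed(8)
  tbl <- tibble::tibble(a = runif(25), b = runif(25)^2, c = runif(25))
  tbl$b <- tbl$a + rnorm(25, sd = 0.2)
  keep1 <- quiet(reduce_category(tbl, c("a", "b", "c")))
  warped <- tbl
  warped$a <- exp(3 * warped$a)
  warped$b <- qlogis(plogis(warped$b) * 0.8 + 0.1)
  keep2 <- quiet(reduce_category(warped, c("a", "b", "c")))
  expect_identical(as.character(keep1), as.character(keep2))
  expect_equal(attr(keep1, "mean_rho"), attr(keep2, "mean_rho"))
})

test_that("score_indicators produces one 0-1 score per category", {
  cfg <- tiny_config()
  sc <- quiet(score_indicators(tiny_table(), cfg))
  for (nm in names(cfg$categories)) {
    expect_true(all(sc[[nm]] >= 0 & sc[[nm]] <= 1), info = nm)
    expect_equal(range(sc[[nm]]), c(0, 1), info = nm)
  }
  # polarity: a lower-is-more indicator scores highest for the lowest raw value
  cfg2 <- default_category_config(1, lower_polarity = "he_1")
  sc2 <- quiet(score_indicators(tiny_table(), cfg2))
  expect_equal(sc2$he[which.min(tiny_table()$he_1)], 1)
})
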