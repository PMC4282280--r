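test_that("percentile extremes use the ceiling rule and stay disjoint", {
  make_results <- function(n) {
    idx <- tibble::tibble(nation_id = sprintf("N%03d", 1:n),
                          S = seq(0, 1, length.out = n),
                          E = seq(0, 1, length.out = n)^2,
                          AC = rev(seq(0, 1, length.out = n)))
    quiet(vulnerability_additive(idx))
  }
  for (case in list(c(148, 15), c(100, 10), c(7, 1))) {
    ex <- percentile_extremes(make_results(case[1]), 0.1)
    expect_equal(ex$k, case[2])
    expect_equal(nrow(ex$top), case[2])
    expect_equal(nrow(ex$bottom), case[2])
    expect_length(intersect(ex$top$nation_id, ex$bottom$nation_id), 0)
    expect_identical(ex$top$rank, sort(ex$top$rank))
  }
  expect_error(percentile_extremes(make_results(10), 0.6),
               class = "livevuln_value_error")
})

test_that("population-weighted group means match the weighted-sum oracle", {
  df <- tibble::tibble(g = c("x", "x"), population = c(1e6, 3e6),
                       v = c(0.2, 0.6), S = c(0.1, 0.5),
                       E = c(0.3, 0.7), AC = c(0.9, 0.1))
  out <- weighted_group_mean(df, "g")
  expect_equal(out$v, 0.5)  # (1*0.2 + 3*0.6)/4

  # equal weights reduce to the plain mean
  eq <- df
  eq$population <- c(5, 5)
  expect_equal(weighted_group_mean(eq, "g")$v, mean(df$v))

  # 7-group synthetic cohort against a brute-force loop
  set.seed(21)
  n <- 70
  coh <- tibble::tibble(
    g = sample(paste0("R", 1:7), n, replace = TRUE),
    population = round(runif(n, 1e5, 1e8)),
    v = runif(n), S = runif(n), E = runif(n), AC = runif(n))
  out <- weighted_group_mean(coh, "g")
  oracle <- sapply(sort(unique(coh$g)), function(gr) {
    rows <- coh[coh$g == gr, ]
    sum(rows$population * rows$v) / sum(rows$population)
  })
  got <- setNames(out$v, out$group)[names(oracle)]
  expect_equal(got, oracle)
  expect_identical(sort(out$rank), seq_len(7))
  expect_identical(out$rank,
                   as.integer(rank(-out$v, ties.method = "min")))
  # weighted mean lies within member range; single-member group is itself
  for (gr in unique(coh$g)) {
    rows <- coh[coh$g == gr, ]
    m <- out$v[out$group == gr]
    expect_gte(m, min(rows$v)); expect_lte(m, max(rows$v))
  }
  single <- weighted_group_mean(coh[1, ], "g")
  expect_equal(single$v, coh$v[1])

  bad <- df
  bad$population <- c(0, 0)
  expect_error(weighted_group_mean(bad, "g"),
               class = "livevuln_value_error", regexp = "x")
})

test_that("Spearman influence matches the rank-difference formula and flags constants", {
  x <- c(3, 8, 1, 9, 5, 12, 7, 2, 10, 6)
  y <- c(2, 9, 3, 8, 4, 11, 10, 1, 12, 5)
  rep <- spearman_influence(tibble::tibble(x = x),
                            tibble::tibble(target = y))
  expect_equal(rep$rho, spearman_oracle(x, y), tolerance = 1e-12)
  expect_equal(rep$n, 10)

  ident <- spearman_influence(tibble::tibble(x = 1:10),
                              tibble::tibble(y = (1:10)^3))
  expect_equal(ident$rho, 1)
  rev <- spearman_influence(tibble::tibble(x = 1:10),
                            tibble::tibble(y = rev(1:10)))
  expect_equal(rev$rho, -1)

  const <- spearman_influence(tibble::tibble(x = rep(1, 10)),
                              tibble::tibble(y = 1:10))
  expect_true(is.na(const$rho))
  expect_match(const$note, "constant")
})

test_that("Spearman influence is invariant under monotone transforms", {
  set.seed(17)
  x <- rnorm(30); y <- x + rnorm(30)
  r1 <- spearman_influence(tibble::tibble(x = x), tibble::tibble(y = y))
  r2 <- spearman_influence(tibble::tibble(x = exp(2 * x)),
                           tibble::tibble(y = atan(y)))
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("Wilcoxon comparison matches exhaustive sign enumeration on a toy", {
  a <- c(10.2, 8.1, 12.5, 9.0, 11.3, 7.7)
  b <- c(9.0, 8.9, 10.1, 9.6, 10.0, 7.5)   # untied |differences|
  oracle <- signed_rank_oracle(a, b)
  got <- wilcoxon_model_compare(a, b)
  expect_equal(got$statistic, oracle$statistic)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  expect_equal(got$n_used, 6)
  expect_identical(got$method, "exact")
})

test_that("Wilcoxon statistic at cohort scale matches a rank-and-sum loop", {
  g <- generate_nations(synth_config(n_nations = 148, seed = 4))
  idx <- quiet(compose_indices(
    quiet(score_indicators(g$table, g$config)), g$config))
  va <- quiet(vulnerability_additive(idx))
  vm <- quiet(vulnerability_multiplicative(idx))
  got <- wilcoxon_model_compare(va$v, vm$v)

  d <- va$v - vm$v
  d <- d[d != 0]
  oracle_w <- sum(rank(abs(d))[d > 0])
  expect_equal(got$statistic, oracle_w)
  expect_equal(got$n_used, length(d))

  # invariant to adding a constant to both paired vectors
  shifted <- wilcoxon_model_compare(va$v + 5, vm$v + 5)
  expect_equal(shifted$statistic, got$statistic)
  expect_equal(shifted$p_value, got$p_value)
})

test_that("identical models give a degenerate comparison", {
  out <- wilcoxon_model_compare(c(1, 2, 3), c(1, 2, 3))
  expect_identical(out$method, "degenerate")
  expect_true(is.na(out$p_value))
  expect_equal(out$n_zero, 3)
})
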