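test_that("index composition is the stated component average", {
  expect_equal(compose_sensitivity(0.3, 0.6, 0.9), 0.6)
  expect_equal(compose_sensitivity(0, 0, 0), 0)
  expect_equal(compose_sensitivity(1, 1, 1), 1)
  expect_equal(compose_exposure(0.4, 0.8), 0.6)
  expect_equal(compose_exposure(1, 0), 0.5)
  expect_equal(compose_adaptive_capacity(0.9, 0.6, 0.3), 0.6)

  expect_equal(rescale_index(c(0.2, 0.5, 0.8)), c(0, 0.5, 1))
  set.seed(5)
  x <- runif(50)
  expect_equal(rescale_index(x), (x - min(x)) / (max(x) - min(x)))
})

test_that("rescaled additive vulnerability is affine-invariant", {
  idx <- quiet(compose_indices(tiny_scores(), default_category_config(1)))
  v1 <- quiet(vulnerability_additive(idx))

  # any a*(S+E-AC)+b, a>0, gives identical rescaled V and ranks;
  # in particular (S + E + (1 - AC))/3 is the same model
  for (ab in list(c(1 / 3, 1 / 3), c(2.7, -1.1), c(0.01, 5))) {
    raw <- ab[1] * (idx$S + idx$E - idx$AC) + ab[2]
    expect_equal(rescale_index(raw), v1$v, tolerance = 1e-12)
  }
  expect_identical(order(v1$v), order(v1$v_raw))  # rescale preserves order
})

test_that("additive V is monotone in S and E and antitone in AC", {
  idx <- quiet(compose_indices(tiny_scores(), default_category_config(1)))
  base <- quiet(vulnerability_additive(idx))
  set.seed(9)
  for (i in seq_len(20)) {
    j <- sample(nrow(idx), 1)
    bump <- runif(1, 0.01, 0.2)
    up <- idx
    up$S[j] <- min(1, up$S[j] + bump)
    up$AC[j] <- max(0, up$AC[j] - bump)
    v_up <- quiet(vulnerability_additive(up))
    expect_gte(v_up$v_raw[j], base$v_raw[j])
  }
})

test_that("multiplicative model annihilators and ratio form behave", {
  idx <- tibble::tibble(nation_id = c("a", "b", "c", "d"),
                        S = c(0, 0.5, 1, 0.8), E = c(0.9, 0.4, 0.7, 0.2),
                        AC = c(0.2, 1, 0.1, 0.6))
  v <- quiet(vulnerability_multiplicative(idx))
  expect_equal(v$v_raw[idx$S == 0], 0)   # S = 0 annihilates
  expect_equal(v$v_raw[idx$AC == 1], 0)  # AC = 1 annihilates default form

  r <- quiet(vulnerability_multiplicative(idx, form = "ratio", epsilon = 0.05))
  expect_equal(r$v_raw, idx$S * idx$E / (idx$AC + 0.05), tolerance = 1e-12)
  expect_error(vulnerability_multiplicative(idx, form = "ratio", epsilon = 0),
               class = "livevuln_config_error")
})

test_that("ranks are a min-tie permutation aligned between v and v_raw", {
  idx <- tibble::tibble(nation_id = letters[1:5],
                        S = c(0.2, 0.2, 0.8, 0.5, 1),
                        E = c(0.1, 0.1, 0.6, 0.3, 0.9),
                        AC = c(0.9, 0.9, 0.2, 0.5, 0))
  v <- quiet(vulnerability_additive(idx))
  expect_setequal(unique(v$rank), c(1, 2, 3, 4))  # a/b tie on rank 4
  expect_equal(sort(v$rank), c(1, 2, 3, 4, 4))
  expect_identical(v$rank, as.integer(rank(-v$v_raw, ties.method = "min")))
})

test_that("scenario variants isolate one exposure component", {
  cfg <- default_category_config(1)
  sc <- tiny_scores()

  # population-only: permuting cc across nations leaves ranks unchanged
  base <- quiet(scenario_variant(sc, vary = "population", config = cfg))
  set.seed(13)
  for (i in 1:5) {
    perm <- sc
    perm$cc <- sample(perm$cc)
    v <- quiet(scenario_variant(perm, vary = "population", config = cfg))
    expect_identical(v$rank, base$rank)
    expect_equal(v$v, base$v)
  }

  # pg constant in the cohort: climate-only ranks equal combined ranks
  const <- sc
  const$pg <- rep(0.5, nrow(const))
  combined <- quiet(vulnerability_additive(compose_indices(const, cfg)))
  climate <- quiet(scenario_variant(const, vary = "climate", config = cfg))
  expect_identical(climate$rank, combined$rank)

  # drop-term policy: E becomes the varying component alone
  dropped <- quiet(scenario_variant(sc, vary = "climate", config = cfg,
                                    hold = "drop"))
  expect_equal(dropped$E, rescale_index(sc$cc))
})

test_that("vulnerability_models stacks every requested combination", {
  res <- quiet(vulnerability_models(tiny_scores(),
                                    config = default_category_config(1)))
  expect_equal(nrow(res), 5 * 2 * 3)
  expect_setequal(unique(res$model), c("additive", "multiplicative"))
  expect_setequal(unique(res$variant),
                  c("combined", "climate_only", "population_only"))
})
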