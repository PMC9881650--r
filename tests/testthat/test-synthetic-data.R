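test_that("condition counts collapse to the three-state classification", {
  expect_equal(
    classify_health_state(c(0, 1, 2, 5, 9)),
    c("HEALTHY", "ONE_CC", "MULTI", "MULTI", "MULTI")
  )
  expect_error(classify_health_state(-1))
})

test_that("identity dynamics keep every individual in the entry state", {
  tp <- truth_params(
    n_individuals = 300, n_waves = 3, coefficients = identity_coefs()
  )
  panel <- generate_panel(tp, seed = 1)
  per <- dplyr::summarise(panel,
    n_states = dplyr::n_distinct(state), .by = individual_id
  )
  expect_true(all(per$n_states == 1))
  expect_false(any(panel$state == "DEAD"))
})

test_that("certain death sends every healthy wave-1 member to DEAD at wave 2", {
  co <- identity_coefs()
  co$HEALTHY["DEAD", "(Intercept)"] <- Inf
  tp <- truth_params(
    n_individuals = 200, n_waves = 2, attrition = 0, coefficients = co,
    entry_state_distribution = c(HEALTHY = 1, ONE_CC = 0, MULTI = 0)
  )
  panel <- generate_panel(tp, seed = 2)
  w <- sort(unique(panel$wave_year))
  expect_length(w, 2)
  w1 <- panel[panel$wave_year == w[1], ]
  w2 <- panel[panel$wave_year == w[2], ]
  expect_true(all(w1$state == "HEALTHY"))
  expect_true(all(w2$state == "DEAD"))
  expect_setequal(w2$individual_id, w1$individual_id)
})

test_that("biennial observation of the annual chain matches the matrix-squaring oracle", {
  # constant, covariate-free truth so the 2-step distribution is exact
  p <- list(
    HEALTHY = c(ONE_CC = 0.10, MULTI = 0.03, DEAD = 0.02),
    ONE_CC = c(MULTI = 0.10, DEAD = 0.05),
    MULTI = c(ONE_CC = 0.05, DEAD = 0.05)
  )
  co <- constant_coefs(p)
  P <- constant_matrix(co)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_equal(P["HEALTHY", "ONE_CC"], 0.10, tolerance = 1e-12)
  P2 <- P %*% P # independent oracle: explicit matrix squaring

  n <- 50000
  tp <- truth_params(
    n_individuals = n, n_waves = 2, wave_spacing_years = 2, attrition = 0,
    coefficients = co,
    entry_state_distribution = c(HEALTHY = 1, ONE_CC = 0, MULTI = 0)
  )
  panel <- generate_panel(tp, seed = 31)
  w2 <- panel[panel$wave_year == max(panel$wave_year), ]
  expect_equal(nrow(w2), n)
  emp <- table(factor(w2$state, health_states())) / n
  for (s in health_states()) {
    expected <- P2["HEALTHY", s]
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(emp[[s]] - expected), 3 * se + 1e-12)
  }
})

test_that("empirical annual transition frequencies converge to the truth matrix", {
  p <- list(
    HEALTHY = c(ONE_CC = 0.12, MULTI = 0.04, DEAD = 0.03),
    ONE_CC = c(MULTI = 0.09, DEAD = 0.06),
    MULTI = c(ONE_CC = 0.04, DEAD = 0.08)
  )
  co <- constant_coefs(p)
  P <- constant_matrix(co)
  tp <- truth_params(
    n_individuals = 25000, n_waves = 3, wave_spacing_years = 1,
    attrition = 0, coefficients = co,
    entry_state_distribution = c(HEALTHY = 0.4, ONE_CC = 0.35, MULTI = 0.25)
  )
  panel <- generate_panel(tp, seed = 5)
  rec <- expand_panel(panel, seed = 6) # annual spacing: expansion is exact
  for (o in living_states()) {
    sub <- rec[rec$origin_state == o, ]
    n_o <- nrow(sub)
    emp <- table(factor(sub$destination_state, health_states())) / n_o
    for (s in health_states()) {
      expected <- P[o, s]
      se <- sqrt(expected * (1 - expected) / n_o)
      expect_lt(abs(emp[[s]] - expected), 3 * se + 1e-12)
    }
  }
})

test_that("the same seed regenerates the panel exactly and no one outlives DEAD", {
  tp <- truth_params(n_individuals = 400, n_waves = 5)
  p1 <- generate_panel(tp, seed = 99)
  p2 <- generate_panel(tp, seed = 99)
  expect_identical(p1$state, p2$state)
  expect_identical(p1, p2)
  p3 <- generate_panel(tp, seed = 100)
  expect_false(identical(p1$state, p3$state))

  dead_pos <- p1 |>
    dplyr::mutate(i = dplyr::row_number(), .by = individual_id) |>
    dplyr::mutate(n = dplyr::n(), .by = individual_id) |>
    dplyr::filter(state == "DEAD")
  expect_true(all(dead_pos$i == dead_pos$n)) # DEAD only ever last

  # first observation constraints
  firsts <- p1 |> dplyr::slice_min(wave_year, by = individual_id)
  expect_true(all(firsts$age >= 50))
  expect_false(any(firsts$state == "DEAD"))
})

test_that("panel invariants: strictly increasing waves and age consistency", {
  tp <- truth_params(n_individuals = 300, n_waves = 4)
  panel <- generate_panel(tp, seed = 8)
  chk <- panel |>
    dplyr::arrange(individual_id, wave_year) |>
    dplyr::mutate(
      dy = wave_year - dplyr::lag(wave_year),
      da = age - dplyr::lag(age),
      .by = individual_id
    ) |>
    dplyr::filter(!is.na(dy))
  expect_true(all(chk$dy > 0))
  expect_true(all(chk$dy == chk$da))
})

test_that("degenerate generator parameters are rejected", {
  expect_error(truth_params(n_individuals = 0), "positive")
  expect_error(truth_params(wave_spacing_years = 0), "wave_spacing")
  expect_error(truth_params(attrition = 1.2), "probability")
  expect_error(
    truth_params(entry_state_distribution = c(0.6, 0.6, 0.2)),
    "summing to 1"
  )
})

test_that("conserved demographics: no births, deaths or migration keeps totals flat", {
  tp <- truth_params(n_individuals = 100, coefficients = identity_coefs())
  dem <- generate_demographics(
    tp,
    true_migration = 0, horizon = 5, total_population = 1e5,
    fertility_rate = c(nh_white = 0, nh_black = 0, hispanic = 0, other = 0),
    under50_mortality_scale = 0
  )
  expect_equal(
    dem$observed_totals$total,
    rep(dem$observed_totals$total[1], nrow(dem$observed_totals)),
    tolerance = 1e-12
  )
})

test_that("demographics generation is reproducible and stores the true migration", {
  tp <- truth_params(n_individuals = 100)
  d1 <- generate_demographics(tp, true_migration = 0.004, horizon = 3,
    total_population = 1e5, seed = 3)
  d2 <- generate_demographics(tp, true_migration = 0.004, horizon = 3,
    total_population = 1e5, seed = 3)
  expect_identical(d1$baseline$count, d2$baseline$count)
  expect_equal(d1$true_migration, 0.004)
  expect_error(
    generate_demographics(tp, horizon = 0, total_population = 1e5),
    "horizon"
  )
})
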