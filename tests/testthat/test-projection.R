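test_that("identity dynamics reduce the step to pure aging", {
  rates <- rates_from_coefficients(identity_coefs())
  dem <- zero_dem()
  pop <- empty_pop()
  pop$count[pop$state == "UNDER50"] <- 10
  pop$count[pop$age >= 50 & pop$state == "HEALTHY"] <- 5
  nxt <- project_step(pop, rates, dem, net_migration = 0)
  expect_equal(sum(nxt$count), sum(pop$count), tolerance = 1e-12)

  # each under-50 cohort moved up one age; newborns absent
  expect_true(all(nxt$count[nxt$age == 0] == 0))
  expect_true(all(nxt$count[nxt$age %in% 1:49 & nxt$state == "UNDER50"] == 10))
  # age-49 survivors entered at 50 as HEALTHY (entry distribution)
  expect_true(all(nxt$count[nxt$age == 50 & nxt$state == "HEALTHY"] == 10))
  # terminal bin accumulates 99 + 100
  expect_true(all(nxt$count[nxt$age == 100 & nxt$state == "HEALTHY"] == 10))
  expect_true(all(nxt$count[nxt$age %in% 51:99 & nxt$state == "HEALTHY"] == 5))
  flows <- attr(nxt, "flows")
  expect_equal(flows$deaths, 0)
  expect_equal(flows$births, 0)
  expect_equal(flows$entrants_50, sum(pop$count[pop$age == 49]))
})

test_that("a cohort facing certain death vanishes into the deaths ledger", {
  co <- identity_coefs()
  co$HEALTHY["DEAD", "(Intercept)"] <- Inf
  rates <- rates_from_coefficients(co)
  pop <- set_cell(empty_pop(), 60, "male", "nh_white", "HEALTHY", 1000)
  nxt <- project_step(pop, rates, zero_dem(), net_migration = 0)
  expect_equal(sum(nxt$count), 0)
  expect_equal(attr(nxt, "flows")$deaths, 1000)
})

test_that("a closed cohort follows the matrix-power solution", {
  p <- list(
    HEALTHY = c(ONE_CC = 0.10, MULTI = 0.03, DEAD = 0.02),
    ONE_CC = c(MULTI = 0.10, DEAD = 0.05),
    MULTI = c(ONE_CC = 0.05, DEAD = 0.05)
  )
  co <- constant_coefs(p)
  P <- constant_matrix(co)
  rates <- rates_from_coefficients(co)
  pop <- empty_pop() |>
    set_cell(50, "female", "nh_white", "HEALTHY", 600) |>
    set_cell(50, "female", "nh_white", "ONE_CC", 300) |>
    set_cell(50, "female", "nh_white", "MULTI", 100)
  horizon <- 10
  proj <- project_population(pop, rates, zero_dem(), 0, horizon)
  d0 <- c(600, 300, 100, 0)
  for (t in c(1, 5, horizon)) {
    expected <- (d0 %*% matpow(P, t))[1, 1:3]
    got <- proj$trajectory |>
      dplyr::filter(year == 2000 + t, age == 50 + t, sex == "female",
        race == "nh_white", state != "UNDER50") |>
      dplyr::arrange(state)
    expect_equal(got$count, unname(expected), tolerance = 1e-9)
  }
  # cumulative deaths ledger matches the absorbing mass
  expect_equal(
    sum(proj$flows$deaths),
    unname((d0 %*% matpow(P, horizon))[1, 4]),
    tolerance = 1e-9
  )
})

test_that("the accounting identity holds every year under varied regimes", {
  tp <- truth_params(n_individuals = 100)
  rates <- truth_rates(tp)
  dem <- generate_demographics(tp, true_migration = 0, horizon = 1,
    total_population = 2e5, seed = 17)
  for (m in c(-0.01, 0, 0.02)) {
    for (mode in c("rate", "count")) {
      mm <- if (mode == "count") m * 2e5 else m
      proj <- project_population(dem, rates, dem, mm, horizon = 8, mode = mode)
      expect_lt(max(abs(identity_residuals(proj))), 1e-9)
      expect_true(all(proj$trajectory$count >= 0))
    }
  }
})

test_that("without fertility and migration the total never grows", {
  tp <- truth_params(n_individuals = 100)
  rates <- truth_rates(tp)
  dem <- generate_demographics(tp, true_migration = 0, horizon = 1,
    total_population = 1e5, seed = 23,
    fertility_rate = c(nh_white = 0, nh_black = 0, hispanic = 0, other = 0))
  proj <- project_population(dem, rates, dem, 0, horizon = 10)
  expect_true(all(diff(proj$totals$total) <= 1e-9))
})

test_that("births equal fertility times fecund females", {
  rates <- rates_from_coefficients(identity_coefs())
  dem <- zero_dem(fertility = 0.05, srb = 0.512)
  pop <- set_cell(empty_pop(), 20, "female", "hispanic", "UNDER50", 1000)
  nxt <- project_step(pop, rates, dem, net_migration = 0)
  flows <- attr(nxt, "flows")
  expect_equal(flows$births, 50, tolerance = 1e-12)
  expect_equal(sum(nxt$count[nxt$age == 0]), 50, tolerance = 1e-12)
  expect_equal(
    nxt$count[nxt$age == 0 & nxt$sex == "male" & nxt$race == "hispanic"],
    50 * 0.512,
    tolerance = 1e-12
  )
})

test_that("count-mode migration adds the requested absolute flow", {
  rates <- rates_from_coefficients(identity_coefs())
  pop <- set_cell(empty_pop(), 60, "male", "other", "HEALTHY", 1000)
  nxt <- project_step(pop, rates, zero_dem(), 37, mode = "count")
  expect_equal(sum(nxt$count), 1037, tolerance = 1e-9)
  expect_equal(attr(nxt, "flows")$net_migrants, 37)
})

test_that("degenerate dynamics make the microsimulation exact", {
  rates <- rates_from_coefficients(identity_coefs())
  dem <- zero_dem()
  pop <- empty_pop()
  pop$count[pop$state == "UNDER50"] <- 5
  pop$count[pop$age >= 50 & pop$state == "ONE_CC"] <- 5
  n_agents <- as.integer(sum(pop$count))
  pr <- project_population(pop, rates, dem, 0, horizon = 4)
  ms <- microsim_oracle(pop, rates, dem, 0, horizon = 4,
    n_agents = n_agents, seed = 3)
  expect_equal(ms$trajectory$count, pr$trajectory$count, tolerance = 1e-12)
  ms2 <- microsim_oracle(pop, rates, dem, 0, horizon = 4,
    n_agents = n_agents, seed = 3)
  expect_identical(ms$trajectory, ms2$trajectory)
})

test_that("missing rate cells and bad inputs are rejected", {
  rates <- rates_from_coefficients(identity_coefs())
  pop <- empty_pop()
  expect_error(
    project_population(pop, rates[-1, ], zero_dem(), 0, horizon = 2),
    "missing cells"
  )
  expect_error(
    project_population(pop, rates, zero_dem(), 0, horizon = 0),
    "horizon"
  )
  bad <- pop
  bad$age[1] <- 120
  expect_error(project_step(bad, rates, zero_dem()), "0..100")
})
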