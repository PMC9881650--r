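obs <- function(id, year, age, sex = "male", race = "nh_white", state) {
  tibble::tibble(
    individual_id = id, wave_year = year, age = age,
    sex = sex, race = race, state = state
  )
}

test_that("an unchanged interval fills in the shared state year by year", {
  out <- expand_interval(
    obs(1, 2000, 70, state = "HEALTHY"),
    obs(1, 2002, 72, state = "HEALTHY")
  )
  expect_equal(nrow(out), 2)
  expect_equal(out$age, c(70, 71))
  expect_equal(out$year, c(2000, 2001))
  expect_true(all(out$origin_state == "HEALTHY"))
  expect_true(all(out$destination_state == "HEALTHY"))
  expect_true(all(out$pseudo))
})

test_that("a one-year interval with a state change needs no random placement", {
  out <- expand_interval(
    obs(1, 2001, 80, state = "ONE_CC"),
    obs(1, 2002, 81, state = "MULTI")
  )
  expect_equal(nrow(out), 1)
  expect_equal(as.character(out$origin_state), "ONE_CC")
  expect_equal(as.character(out$destination_state), "MULTI")
  expect_false(out$pseudo)
})

test_that("death placement is uniform over the interval's years", {
  n <- 10000
  panel <- dplyr::bind_rows(
    obs(seq_len(n), 2000, 80, state = "ONE_CC"),
    obs(seq_len(n), 2002, 82, state = "DEAD")
  )
  rec <- expand_panel(panel, seed = 7)
  per <- dplyr::summarise(rec, n_rec = dplyr::n(), .by = individual_id)
  expect_setequal(unique(per$n_rec), c(1L, 2L))
  # year-1 death -> single record; year-2 death -> two records
  frac1 <- mean(per$n_rec == 1)
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac1 - 0.5), 3 * se)
  one_rec <- rec |> dplyr::filter(individual_id %in% per$individual_id[per$n_rec == 1])
  expect_true(all(one_rec$destination_state == "DEAD"))
  two_rec <- rec |>
    dplyr::filter(individual_id %in% per$individual_id[per$n_rec == 2]) |>
    dplyr::arrange(individual_id, year)
  expect_true(all(two_rec$destination_state[c(TRUE, FALSE)] == "ONE_CC"))
  expect_true(all(two_rec$destination_state[c(FALSE, TRUE)] == "DEAD"))
})

test_that("record count equals summed interval lengths when nobody dies", {
  co <- constant_coefs(list(
    HEALTHY = c(ONE_CC = 0.15, MULTI = 0.05, DEAD = 1e-9),
    ONE_CC = c(MULTI = 0.12, DEAD = 1e-9),
    MULTI = c(ONE_CC = 0.05, DEAD = 1e-9)
  ))
  co$HEALTHY["DEAD", "(Intercept)"] <- -Inf
  co$ONE_CC["DEAD", "(Intercept)"] <- -Inf
  co$MULTI["DEAD", "(Intercept)"] <- -Inf
  tp <- truth_params(n_individuals = 200, n_waves = 4, coefficients = co)
  panel <- generate_panel(tp, seed = 21)
  expect_false(any(panel$state == "DEAD"))
  rec <- expand_panel(panel, seed = 22)
  spans <- panel |>
    dplyr::summarise(
      span = max(wave_year) - min(wave_year), .by = individual_id
    )
  expect_equal(nrow(rec), sum(spans$span)) # brute-force count identity
})

test_that("annualised paths chain consecutively and pass through observed states", {
  tp <- truth_params(n_individuals = 400, n_waves = 4)
  panel <- generate_panel(tp, seed = 13)
  rec <- expand_panel(panel, seed = 14)

  chain <- rec |>
    dplyr::arrange(individual_id, year) |>
    dplyr::mutate(
      nxt = dplyr::lead(as.character(origin_state)),
      .by = individual_id
    ) |>
    dplyr::filter(!is.na(nxt))
  expect_true(all(as.character(chain$destination_state) == chain$nxt))

  # the record starting at a wave year carries the observed wave state
  at_waves <- dplyr::inner_join(
    rec, panel,
    by = c("individual_id", "year" = "wave_year"), suffix = c("", "_obs")
  )
  expect_gt(nrow(at_waves), 0)
  expect_true(
    all(as.character(at_waves$origin_state) == as.character(at_waves$state))
  )
  expect_true(all(rec$age >= 50))
})

test_that("a two-step worsening is filled as one direct transition", {
  withr::with_seed(1, {
    for (i in 1:20) {
      out <- expand_interval(
        obs(1, 2000, 60, state = "HEALTHY"),
        obs(1, 2002, 62, state = "MULTI")
      )
      expect_equal(nrow(out), 2)
      expect_false(any(out$origin_state == "ONE_CC"))
      jump <- out$origin_state != out$destination_state
      expect_equal(sum(jump), 1)
      expect_equal(as.character(out$destination_state[jump]), "MULTI")
    }
  })
})

test_that("recovery to HEALTHY is rejected unless explicitly allowed", {
  s <- obs(1, 2000, 70, state = "ONE_CC")
  e <- obs(1, 2002, 72, state = "HEALTHY")
  expect_error(expand_interval(s, e), "recovery")
  ok <- withr::with_seed(3, expand_interval(s, e, allow_recovery = TRUE))
  expect_equal(nrow(ok), 2)
  # MULTI -> ONE_CC is a legal backward move by default
  back <- withr::with_seed(4, expand_interval(
    obs(1, 2000, 70, state = "MULTI"),
    obs(1, 2002, 72, state = "ONE_CC")
  ))
  expect_equal(sum(back$origin_state != back$destination_state), 1)
})

test_that("expansion handles empty panels and rejects malformed ones", {
  tp <- truth_params(n_individuals = 10, n_waves = 3)
  empty <- generate_panel(tp, seed = 1)[0, ]
  out <- expand_panel(empty, seed = 1)
  expect_equal(nrow(out), 0)
  expect_named(
    out,
    c("individual_id", "year", "age", "sex", "race", "origin_state",
      "destination_state", "pseudo")
  )
  dup <- dplyr::bind_rows(
    obs(1, 2000, 70, state = "HEALTHY"),
    obs(1, 2000, 70, state = "HEALTHY")
  )
  expect_error(expand_panel(dup, seed = 1), "duplicate")
  expect_error(
    expand_interval(obs(1, 2000, 70, state = "HEALTHY"),
      obs(1, 2000, 70, state = "HEALTHY")),
    "positive"
  )
  expect_error(
    expand_interval(obs(1, 2000, 70, state = "DEAD"),
      obs(1, 2002, 72, state = "DEAD")),
    "DEAD"
  )
})

test_that("expansion is reproducible under a fixed seed", {
  tp <- truth_params(n_individuals = 200, n_waves = 4)
  panel <- generate_panel(tp, seed = 50)
  r1 <- expand_panel(panel, seed = 60)
  r2 <- expand_panel(panel, seed = 60)
  r3 <- expand_panel(panel, seed = 61)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})
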