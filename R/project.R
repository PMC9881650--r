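# Discrete-time cohort-component engine. Internally the population lives in
# two dense arrays:
#   under50 [age 0..49, sex, race]
#   adults  [age 50..100+, sex, race, living state]
# The user-facing surface is a long tibble (year, age, sex, race, state,
# count) with state == "UNDER50" below age 50.

msp_pop_levels <- function() c("UNDER50", living_states())

# population tibble -> internal arrays
msp_pop_to_arrays <- function(pop) {
  u <- array(0, c(50, 2, 4), dimnames = list(
    age = as.character(0:49), sex = msp_sexes(), race = msp_races()
  ))
  a <- array(0, c(51, 2, 4, 3), dimnames = list(
    age = as.character(msp_adult_ages()), sex = msp_sexes(),
    race = msp_races(), state = living_states()
  ))
  if (any(pop$age < 0 | pop$age > 100)) {
    stop("population ages must lie in 0..100 (100 is the open bin)", call. = FALSE)
  }
  under <- pop[pop$age < 50, ]
  adult <- pop[pop$age >= 50, ]
  if (nrow(under)) {
    iu <- cbind(
      under$age + 1L, match(as.character(under$sex), msp_sexes()),
      match(as.character(under$race), msp_races())
    )
    u[iu] <- u[iu] + under$count
  }
  if (nrow(adult)) {
    st <- match(as.character(adult$state), living_states())
    if (anyNA(st)) stop("adult rows must carry a living health state", call. = FALSE)
    ia <- cbind(
      adult$age - 49L, match(as.character(adult$sex), msp_sexes()),
      match(as.character(adult$race), msp_races()), st
    )
    a[ia] <- a[ia] + adult$count
  }
  list(under50 = u, adults = a)
}

msp_arrays_to_pop <- function(year, u, a) {
  ug <- tidyr::expand_grid(age = 0:49, sex = msp_sexes(), race = msp_races())
  ug$state <- "UNDER50"
  ug$count <- u[cbind(ug$age + 1L, match(ug$sex, msp_sexes()), match(ug$race, msp_races()))]
  ag <- tidyr::expand_grid(
    age = msp_adult_ages(), sex = msp_sexes(), race = msp_races(),
    state = living_states()
  )
  ag$count <- a[cbind(
    ag$age - 49L, match(ag$sex, msp_sexes()), match(ag$race, msp_races()),
    match(ag$state, living_states())
  )]
  dplyr::bind_rows(ug, ag) |>
    dplyr::mutate(
      year = as.integer(year),
      sex = factor(.data$sex, msp_sexes()),
      race = factor(.data$race, msp_races()),
      state = factor(.data$state, msp_pop_levels()),
      .before = 1
    )
}

msp_q_array <- function(under50_mortality) {
  q <- array(NA_real_, c(50, 2, 4))
  q[cbind(
    under50_mortality$age + 1L,
    match(as.character(under50_mortality$sex), msp_sexes()),
    match(as.character(under50_mortality$race), msp_races())
  )] <- under50_mortality$q
  if (anyNA(q)) stop("under50_mortality must cover every age-sex-race cell", call. = FALSE)
  q
}

# one annual step on arrays; returns new arrays plus the flow ledger.
# Order: adult health transitions (incl. death) -> under-50 deaths ->
# aging (age-49 survivors enter the adult block via the entry state
# distribution; the 100+ bin absorbs) -> births -> net migration applied
# proportionally to the whole population.
msp_step_arrays <- function(u, a, R, q, fert, srb, entry, net_migration,
                            mode = c("rate", "count")) {
  mode <- match.arg(mode)
  trans <- array(0, c(51, 2, 4, 4))
  for (d in 1:4) trans[, , , d] <- rowSums(a * R[, , , , d], dims = 3)
  adult_deaths <- sum(trans[, , , 4])

  u_deaths <- sum(u * q)
  u_surv <- u * (1 - q)

  newa <- array(0, c(51, 2, 4, 3), dimnames = dimnames(a))
  newa[2:51, , , ] <- trans[1:50, , , 1:3]
  newa[51, , , ] <- newa[51, , , ] + trans[51, , , 1:3]
  entrants <- u_surv[50, , ] # age-49 survivors, [sex, race]
  for (s in 1:3) newa[1, , , s] <- entrants * entry[s]

  newu <- array(0, c(50, 2, 4), dimnames = dimnames(u))
  newu[2:50, , ] <- u_surv[1:49, , ]

  fecund_f <- colSums(newu[16:50, 1, ]) # females 15-49 by race
  births_r <- fert * fecund_f
  newu[1, 2, ] <- births_r * srb
  newu[1, 1, ] <- births_r * (1 - srb)
  births <- sum(births_r)

  total_pre <- sum(newu) + sum(newa)
  if (mode == "rate") {
    net_migrants <- net_migration * total_pre
    factor <- 1 + net_migration
  } else {
    net_migrants <- net_migration
    factor <- 1 + net_migration / total_pre
  }
  newu <- newu * factor
  newa <- newa * factor
  if (min(newu) < 0 || min(newa) < 0) {
    stop("negative population stock produced; check rates and migration", call. = FALSE)
  }

  list(
    under50 = newu, adults = newa,
    flows = tibble::tibble(
      births = births,
      deaths = adult_deaths + u_deaths,
      net_migrants = net_migrants,
      entrants_50 = sum(entrants)
    )
  )
}

#' Advance a population by one year
#'
#' Applies, in order: health-state transitions (including death) to the 50+
#' stocks at origin-age rates, life-table deaths below 50, aging of every
#' surviving cohort (age-49 survivors enter the adult block distributed over
#' living states, the 100+ bin absorbs), births from race-specific fertility
#' applied to females 15-49, and constant net migration spread
#' proportionally over the whole population.
#'
#' @param pop Population tibble (`year`, `age`, `sex`, `race`, `state`,
#'   `count`; `state == "UNDER50"` below age 50).
#' @param rates Transition rate table covering ages 50-100.
#' @param dem Demographic inputs ([generate_demographics()] or a compatible
#'   list).
#' @param net_migration Scalar migration parameter.
#' @param mode `"rate"` (net migrants = rate x total population, default) or
#'   `"count"` (absolute annual net migrants).
#' @return The year-(t+1) population tibble, with the flow ledger (births,
#'   deaths, net migrants, entrants at 50) in attribute `flows`.
#' @export
project_step <- function(pop, rates, dem, net_migration = 0,
                         mode = c("rate", "count")) {
  arr <- msp_pop_to_arrays(pop)
  R <- msp_rates_array(rates)
  q <- msp_q_array(dem$under50_mortality)
  fert <- dem$fertility$rate[match(msp_races(), dem$fertility$race)]
  st <- msp_step_arrays(
    arr$under50, arr$adults, R, q, fert, dem$sex_ratio_at_birth,
    dem$entry_state_distribution, net_migration, mode
  )
  out <- msp_arrays_to_pop(max(pop$year) + 1L, st$under50, st$adults)
  attr(out, "flows") <- st$flows
  out
}

#' Project a population forward
#'
#' Runs [project_step()] for `horizon` years and collects the yearly
#' population vectors and flow ledger. The projection is a deterministic
#' expected-value propagation of stocks; see [microsim_oracle()] for the
#' agent-level Monte-Carlo counterpart used to validate it.
#'
#' @inheritParams project_step
#' @param initial Base-year population tibble, or an `msp_demographics`
#'   object (its `baseline` is used).
#' @param horizon Number of years to project (>= 1).
#' @return An object of class `msp_projection`: `trajectory` (long tibble of
#'   yearly stocks), `flows` (one row per projected year), `totals` (year,
#'   total), `base_year`, `horizon`.
#' @examples
#' tp <- truth_params(n_individuals = 100)
#' dem <- generate_demographics(tp, horizon = 3, total_population = 1e5)
#' proj <- project_population(dem, truth_rates(tp), dem,
#'   net_migration = 0.002, horizon = 3
#' )
#' glance(proj)
#' @export
project_population <- function(initial, rates, dem, net_migration = 0,
                               horizon, mode = c("rate", "count")) {
  mode <- match.arg(mode)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (inherits(initial, "msp_demographics")) initial <- initial$baseline
  arr <- msp_pop_to_arrays(initial)
  R <- msp_rates_array(rates)
  q <- msp_q_array(dem$under50_mortality)
  fert <- dem$fertility$rate[match(msp_races(), dem$fertility$race)]
  base_year <- max(initial$year)

  traj <- vector("list", horizon + 1L)
  traj[[1L]] <- msp_arrays_to_pop(base_year, arr$under50, arr$adults)
  flows <- vector("list", horizon)
  u <- arr$under50
  a <- arr$adults
  for (t in seq_len(horizon)) {
    st <- msp_step_arrays(
      u, a, R, q, fert, dem$sex_ratio_at_birth,
      dem$entry_state_distribution, net_migration, mode
    )
    u <- st$under50
    a <- st$adults
    traj[[t + 1L]] <- msp_arrays_to_pop(base_year + t, u, a)
    flows[[t]] <- dplyr::mutate(st$flows, year = base_year + t, .before = 1)
  }
  trajectory <- dplyr::bind_rows(traj)
  totals <- trajectory |>
    dplyr::summarise(total = sum(.data$count), .by = "year")
  structure(
    list(
      trajectory = trajectory,
      flows = dplyr::bind_rows(flows),
      totals = totals,
      base_year = as.integer(base_year),
      horizon = as.integer(horizon)
    ),
    class = "msp_projection"
  )
}

#' @export
print.msp_projection <- function(x, ...) {
  cat(sprintf(
    "<msp_projection> %d -> %d, total %.4g -> %.4g\n",
    x$base_year, x$base_year + x$horizon,
    x$totals$total[1], x$totals$total[nrow(x$totals)]
  ))
  invisible(x)
}

#' Tidy a projection
#'
#' @param x An `msp_projection`.
#' @param ... Unused.
#' @return The long trajectory tibble (year, age, sex, race, state, count).
#' @method tidy msp_projection
#' @export
tidy.msp_projection <- function(x, ...) x$trajectory

#' Glance at a projection
#'
#' @param x An `msp_projection`.
#' @param ... Unused.
#' @return One-row tibble with base/end years and totals.
#' @method glance msp_projection
#' @export
glance.msp_projection <- function(x, ...) {
  tibble::tibble(
    base_year = x$base_year,
    end_year = x$base_year + x$horizon,
    horizon = x$horizon,
    total_base = x$totals$total[1],
    total_end = x$totals$total[nrow(x$totals)],
    births = sum(x$flows$births),
    deaths = sum(x$flows$deaths),
    net_migrants = sum(x$flows$net_migrants)
  )
}
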