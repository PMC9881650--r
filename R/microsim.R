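#' Agent-level Monte-Carlo oracle for the projection engine
#'
#' Simulates the same annual dynamics as [project_population()] at the level
#' of individual agents: multinomial health-state draws for adults,
#' Bernoulli deaths below 50, cohort aging with entry into the adult block
#' at 50, Bernoulli births to fecund females, and constant-rate net
#' migration applied as a deterministic per-year weight multiplier `(1 + m)`
#' shared by all agents (migration has no stochastic component, so the mean
#' trajectory stays comparable cell by cell). Its mean trajectory converges
#' to the expected-value engine as `n_agents` grows; it exists to validate
#' the engine and plays no role in production projections.
#'
#' Agents are allocated to the initial cells deterministically by largest
#' remainder, so with divisible counts and degenerate (0/1) dynamics the
#' oracle reproduces [project_population()] exactly.
#'
#' @inheritParams project_population
#' @param n_agents Number of simulated agents (>= 1).
#' @param seed Integer seed; fixes the whole simulation.
#' @return An object of class `msp_projection` (trajectory, flows, totals)
#'   whose counts are agent tallies scaled back to population units.
#' @export
microsim_oracle <- function(initial, rates, dem, net_migration = 0,
                            horizon, n_agents, seed) {
  if (n_agents < 1) stop("n_agents must be >= 1", call. = FALSE)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (inherits(initial, "msp_demographics")) initial <- initial$baseline
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  arr <- msp_pop_to_arrays(initial)
  R <- msp_rates_array(rates)
  q <- msp_q_array(dem$under50_mortality)
  fert <- dem$fertility$rate[match(msp_races(), dem$fertility$race)]
  srb <- dem$sex_ratio_at_birth
  entry <- dem$entry_state_distribution
  base_year <- max(initial$year)

  # largest-remainder allocation of agents over all occupied cells
  cells <- dplyr::filter(
    msp_arrays_to_pop(base_year, arr$under50, arr$adults), .data$count > 0
  )
  total0 <- sum(cells$count)
  quota <- n_agents * cells$count / total0
  n_cell <- floor(quota)
  shortfall <- n_agents - sum(n_cell)
  if (shortfall > 0) {
    extra <- order(quota - n_cell, decreasing = TRUE)[seq_len(shortfall)]
    n_cell[extra] <- n_cell[extra] + 1L
  }
  keep <- n_cell > 0
  idx <- rep(which(keep), n_cell[keep])
  age <- cells$age[idx]
  sex <- match(as.character(cells$sex), msp_sexes())[idx]
  race <- match(as.character(cells$race), msp_races())[idx]
  state <- match(as.character(cells$state), living_states())[idx] # NA under 50
  w <- total0 / n_agents # common agent weight, scaled by migration yearly

  snapshot <- function(year) {
    is_ad <- age >= 50
    lin_u <- age[!is_ad] + 1L + 50L * ((sex[!is_ad] - 1L) + 2L * (race[!is_ad] - 1L))
    u <- array(tabulate(lin_u, nbins = 50L * 2L * 4L) * w, c(50, 2, 4))
    lin_a <- (age[is_ad] - 49L) +
      51L * ((sex[is_ad] - 1L) + 2L * ((race[is_ad] - 1L) + 4L * (state[is_ad] - 1L)))
    a <- array(tabulate(lin_a, nbins = 51L * 2L * 4L * 3L) * w, c(51, 2, 4, 3))
    msp_arrays_to_pop(year, u, a)
  }

  traj <- vector("list", horizon + 1L)
  traj[[1L]] <- snapshot(base_year)
  flows <- vector("list", horizon)

  for (t in seq_len(horizon)) {
    n_deaths <- 0
    # adult transitions
    is_ad <- which(age >= 50)
    if (length(is_ad)) {
      ai <- pmin(age[is_ad], 100L) - 49L
      p <- sapply(1:4, function(d) R[cbind(ai, sex[is_ad], race[is_ad], state[is_ad], d)])
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      dest <- msp_sample_rows(p)
      died <- dest == 4L
      n_deaths <- n_deaths + sum(died)
      state[is_ad] <- ifelse(died, NA_integer_, dest)
      drop <- is_ad[died]
    } else {
      drop <- integer()
    }
    # under-50 deaths
    is_un <- which(age < 50)
    if (length(is_un)) {
      qd <- q[cbind(age[is_un] + 1L, sex[is_un], race[is_un])]
      died_u <- stats::runif(length(is_un)) < qd
      n_deaths <- n_deaths + sum(died_u)
      drop <- c(drop, is_un[died_u])
    }
    if (length(drop)) {
      age <- age[-drop]; sex <- sex[-drop]; race <- race[-drop]; state <- state[-drop]
    }
    # aging; entrants at 50 draw an entry state
    age <- pmin(age + 1L, 100L)
    entrants <- which(age == 50L & is.na(state))
    if (length(entrants)) {
      state[entrants] <- msp_sample_rows(
        matrix(entry, nrow = length(entrants), ncol = 3, byrow = TRUE)
      )
    }
    # births
    fec <- which(sex == 1L & age >= 15L & age <= 49L)
    born <- fec[stats::runif(length(fec)) < fert[race[fec]]]
    if (length(born)) {
      age <- c(age, rep(0L, length(born)))
      sex <- c(sex, 1L + (stats::runif(length(born)) < srb))
      race <- c(race, race[born])
      state <- c(state, rep(NA_integer_, length(born)))
    }
    # migration as a deterministic weight factor
    w_old <- w
    w <- w * (1 + net_migration)
    flows[[t]] <- tibble::tibble(
      year = base_year + t,
      births = length(born) * w_old,
      deaths = n_deaths * w_old,
      net_migrants = (w - w_old) * length(age),
      entrants_50 = length(entrants) * w_old
    )
    traj[[t + 1L]] <- snapshot(base_year + t)
  }
  trajectory <- dplyr::bind_rows(traj)
  totals <- trajectory |>
    dplyr::summarise(total = sum(.data$count), .by = "year")
  structure(
    list(
      trajectory = trajectory, flows = dplyr::bind_rows(flows),
      totals = totals, base_year = as.integer(base_year),
      horizon = as.integer(horizon), n_agents = as.integer(n_agents),
      seed = as.integer(seed)
    ),
    class = "msp_projection"
  )
}
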