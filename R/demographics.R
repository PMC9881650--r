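#' Generate synthetic demographic inputs consistent with truth dynamics
#'
#' Builds everything the cohort-component engine needs besides the
#' transition rates: a base-year population (ages 0 to the open 100+ bin by
#' sex and race, with health states for adults 50+), race-specific fertility
#' rates applied to females 15-49, under-50 mortality probabilities, the sex
#' ratio at birth, and an observed total-population series. The adult
#' health-state mix at each age is derived from the truth chain itself (the
#' entry distribution at 50 evolved age by age, conditioned on survival), so
#' the base year is internally consistent with the dynamics that generated
#' the panel. The observed series is produced by running the projection
#' engine forward under the truth rates with net migration fixed at
#' `true_migration`, which makes closed-loop calibration recovery testable.
#'
#' @param truth Ground-truth parameters from [truth_params()].
#' @param true_migration Constant annual net migration rate used to produce
#'   the observed total-population series (stored in the result).
#' @param seed Integer seed for the small multiplicative jitter applied to
#'   baseline cell counts.
#' @param base_year First calendar year of the series.
#' @param horizon Number of years of observed totals after the base year
#'   (must be >= 1).
#' @param total_population Base-year total across all ages.
#' @param under50_share Fraction of the base-year total aged below 50.
#' @param p_male Population share male.
#' @param fertility_rate Named births-per-fecund-female-per-year by race.
#' @param sex_ratio_at_birth Fraction of births that are male.
#' @param jitter_sd Log-normal sd of the baseline cell jitter (0 disables).
#' @param under50_mortality_scale Multiplier on the under-50 mortality
#'   schedule (0 gives a deathless under-50 block, useful for conservation
#'   checks).
#' @return Object of class `msp_demographics` with elements `base_year`,
#'   `baseline` (population tibble), `fertility`, `under50_mortality`,
#'   `sex_ratio_at_birth`, `entry_state_distribution`, `observed_totals`,
#'   and `true_migration`.
#' @export
generate_demographics <- function(truth,
                                  true_migration = 0.003,
                                  seed = 1L,
                                  base_year = 2018L,
                                  horizon = 42L,
                                  total_population = 330e6,
                                  under50_share = 0.62,
                                  p_male = 0.492,
                                  fertility_rate = c(
                                    nh_white = 0.052, nh_black = 0.058,
                                    hispanic = 0.063, other = 0.056
                                  ),
                                  sex_ratio_at_birth = 0.512,
                                  jitter_sd = 0.02,
                                  under50_mortality_scale = 1) {
  validate_truth_params(truth)
  if (horizon < 1) stop("horizon must be at least 1 year", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  races <- msp_races()
  sexes <- msp_sexes()
  race_p <- truth$race_distribution[races]
  sex_p <- c(female = 1 - p_male, male = p_male)

  # age shapes: mildly declining below 50, steeper decline above 85
  u_ages <- 0:49
  u_shape <- exp(-0.003 * u_ages)
  a_ages <- msp_adult_ages()
  a_shape <- exp(-0.05 * (a_ages - 50)) * ifelse(
    a_ages > 85, exp(-0.08 * (a_ages - 85)), 1
  )
  u_counts <- u_shape / sum(u_shape) * total_population * under50_share
  a_counts <- a_shape / sum(a_shape) * total_population * (1 - under50_share)

  under50 <- tidyr::expand_grid(age = u_ages, sex = sexes, race = races) |>
    dplyr::mutate(
      state = "UNDER50",
      count = u_counts[.data$age + 1L] * sex_p[.data$sex] * race_p[.data$race]
    )

  # adult state mix by age from the truth chain, conditioned on survival
  rates <- truth_rates(truth)
  R <- msp_rates_array(rates)
  mix <- array(NA_real_, c(51, 2, 4, 3))
  for (s in 1:2) {
    for (r in 1:4) {
      d <- truth$entry_state_distribution
      mix[1, s, r, ] <- d
      for (i in 1:50) {
        P <- R[i, s, r, , 1:3] # living -> living
        d <- as.vector(d %*% P)
        d <- d / sum(d)
        mix[i + 1, s, r, ] <- d
      }
    }
  }
  adults <- tidyr::expand_grid(
    age = a_ages, sex = sexes, race = races, state = living_states()
  ) |>
    dplyr::mutate(
      count = a_counts[.data$age - 49L] * sex_p[.data$sex] *
        race_p[.data$race] *
        mix[cbind(
          .data$age - 49L, match(.data$sex, sexes),
          match(.data$race, races), match(.data$state, living_states())
        )]
    )

  baseline <- dplyr::bind_rows(under50, adults) |>
    dplyr::mutate(
      year = as.integer(base_year),
      sex = factor(.data$sex, sexes),
      race = factor(.data$race, races),
      state = factor(.data$state, c("UNDER50", living_states())),
      .before = 1
    )
  if (jitter_sd > 0) {
    baseline$count <- baseline$count *
      exp(stats::rnorm(nrow(baseline), 0, jitter_sd))
  }

  q_base <- under50_mortality_scale *
    (0.005 * exp(-0.35 * u_ages) + 2e-5 * exp(0.09 * u_ages))
  under50_mortality <- tidyr::expand_grid(age = u_ages, sex = sexes, race = races) |>
    dplyr::mutate(
      q = q_base[.data$age + 1L] *
        ifelse(.data$sex == "male", 1.3, 1) *
        c(nh_white = 1, nh_black = 1.25, hispanic = 0.9, other = 0.95)[.data$race]
    )

  dem <- structure(
    list(
      base_year = as.integer(base_year),
      baseline = baseline,
      fertility = tibble::tibble(race = races, rate = unname(fertility_rate[races])),
      under50_mortality = under50_mortality,
      sex_ratio_at_birth = sex_ratio_at_birth,
      entry_state_distribution = truth$entry_state_distribution,
      observed_totals = NULL,
      true_migration = true_migration
    ),
    class = "msp_demographics"
  )
  validate_demographics(dem)

  proj <- project_population(
    baseline, rates, dem,
    net_migration = true_migration, horizon = as.integer(horizon)
  )
  dem$observed_totals <- proj$totals
  dem
}

#' Validate demographic inputs
#'
#' @param dem An `msp_demographics` object.
#' @return Invisibly `TRUE`; errors on negative counts or probabilities
#'   outside \[0, 1\].
#' @export
validate_demographics <- function(dem) {
  stopifnot(inherits(dem, "msp_demographics"))
  if (any(dem$baseline$count < 0)) stop("negative baseline count", call. = FALSE)
  if (any(dem$fertility$rate < 0 | dem$fertility$rate > 1)) {
    stop("fertility rates must lie in [0, 1]", call. = FALSE)
  }
  q <- dem$under50_mortality$q
  if (any(q < 0 | q > 1)) stop("under-50 mortality must lie in [0, 1]", call. = FALSE)
  if (dem$sex_ratio_at_birth < 0 || dem$sex_ratio_at_birth > 1) {
    stop("sex_ratio_at_birth must lie in [0, 1]", call. = FALSE)
  }
  d <- dem$entry_state_distribution
  if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
    stop("entry_state_distribution must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.msp_demographics <- function(x, ...) {
  cat("<msp_demographics>\n")
  cat(sprintf(
    "  base year %d, total population %.4g\n",
    x$base_year, sum(x$baseline$count)
  ))
  if (!is.null(x$observed_totals)) {
    cat(sprintf(
      "  observed totals %d..%d (true net migration rate %.4g)\n",
      min(x$observed_totals$year), max(x$observed_totals$year),
      x$true_migration
    ))
  }
  invisible(x)
}
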