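#' Annualise one interval-censored wave pair
#'
#' Converts the gap between two consecutive wave observations of the same
#' individual into one person-year record per year. If the two states agree,
#' every year keeps that state. If they differ, exactly one origin-to-end
#' transition is placed in a year drawn uniformly from the interval; years
#' before it stay in the starting state, years after it stay in the ending
#' state. When the ending state is `DEAD` the chain stops at the death year,
#' so a death interval contributes as many records as the drawn year index.
#'
#' Draws come from the session RNG stream; [expand_panel()] seeds it once for
#' the whole panel.
#'
#' @param start,end Single-row data frames (or lists) with the wave
#'   observation fields `individual_id`, `wave_year`, `age`, `sex`, `race`,
#'   `state`; `end.wave_year` must exceed `start.wave_year` and the start
#'   state must be living.
#' @param allow_recovery Permit transitions back to `HEALTHY` (and any other
#'   backward move). By default only `MULTI -> ONE_CC` is accepted among
#'   backward moves, since condition histories are lifetime histories.
#' @return Tibble of person-year records with columns `individual_id`,
#'   `year`, `age`, `sex`, `race`, `origin_state`, `destination_state`,
#'   `pseudo`.
#' @export
expand_interval <- function(start, end, allow_recovery = FALSE) {
  s0 <- as.character(start$state)
  s1 <- as.character(end$state)
  gap <- as.integer(end$wave_year - start$wave_year)
  if (gap < 1) stop("interval length must be positive", call. = FALSE)
  if (s0 == "DEAD") stop("interval cannot start in DEAD", call. = FALSE)
  msp_check_transition_legal(s0, s1, allow_recovery)
  k <- if (s0 == s1) 0L else sample.int(gap, 1L)
  msp_interval_records(
    id = start$individual_id, year0 = as.integer(start$wave_year),
    age0 = as.integer(start$age), sex = as.character(start$sex),
    race = as.character(start$race), s0 = s0, s1 = s1, gap = gap, k = k
  )
}

msp_check_transition_legal <- function(s0, s1, allow_recovery) {
  if (allow_recovery) return(invisible(TRUE))
  illegal <- (s0 %in% c("ONE_CC", "MULTI") & s1 == "HEALTHY")
  if (any(illegal)) {
    stop(
      "interval implies recovery to HEALTHY, impossible for lifetime condition histories; set allow_recovery = TRUE to accept",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# build the records of one interval given the drawn transition year k
# (k = 0 means no transition; states equal)
msp_interval_records <- function(id, year0, age0, sex, race, s0, s1, gap, k) {
  n_rec <- if (s1 == "DEAD") k else gap
  if (k == 0L) n_rec <- gap
  j <- seq_len(n_rec)
  origin <- ifelse(k != 0L & j > k, s1, s0)
  dest <- ifelse(k != 0L & j >= k, s1, s0)
  tibble::tibble(
    individual_id = rep(id, n_rec),
    year = year0 + j - 1L,
    age = age0 + j - 1L,
    sex = rep(sex, n_rec),
    race = rep(race, n_rec),
    origin_state = origin,
    destination_state = dest,
    pseudo = rep(gap > 1L, n_rec)
  )
}

#' Expand a whole panel into annual person-year records
#'
#' Applies [expand_interval()] to every consecutive wave pair of every
#' individual. The output is ordered by individual then year and is fully
#' reproducible given `seed` (one uniform draw per state-changing interval).
#'
#' @param panel Wave-observation tibble as produced by [generate_panel()] or
#'   [read_panel_csv()].
#' @param seed Integer seed for the transition-time draws.
#' @param allow_recovery See [expand_interval()].
#' @return Tibble of person-year records (`individual_id`, `year`, `age`,
#'   `sex`, `race`, `origin_state`, `destination_state`, `pseudo`) with
#'   factor-typed covariates and states.
#' @examples
#' p <- truth_params(n_individuals = 50, n_waves = 3)
#' panel <- generate_panel(p, seed = 1)
#' expand_panel(panel, seed = 2)
#' @export
expand_panel <- function(panel, seed, allow_recovery = FALSE) {
  if (nrow(panel) == 0) {
    return(tibble::tibble(
      individual_id = integer(), year = integer(), age = integer(),
      sex = factor(character(), msp_sexes()),
      race = factor(character(), msp_races()),
      origin_state = factor(character(), living_states()),
      destination_state = factor(character(), health_states()),
      pseudo = logical()
    ))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  panel <- dplyr::arrange(panel, .data$individual_id, .data$wave_year)
  if (anyDuplicated(panel[c("individual_id", "wave_year")]) > 0) {
    stop("duplicate wave_year for an individual", call. = FALSE)
  }

  # consecutive wave pairs per individual
  iv <- panel |>
    dplyr::mutate(
      end_year = dplyr::lead(.data$wave_year),
      end_state = dplyr::lead(as.character(.data$state)),
      .by = "individual_id"
    ) |>
    dplyr::filter(!is.na(.data$end_year)) |>
    dplyr::mutate(
      s0 = as.character(.data$state),
      gap = as.integer(.data$end_year - .data$wave_year)
    )
  if (any(iv$s0 == "DEAD")) {
    stop("observations follow a DEAD record for some individual", call. = FALSE)
  }
  msp_check_transition_legal(iv$s0, iv$end_state, allow_recovery)

  if (nrow(iv) == 0) {
    return(expand_panel(panel[0, ], seed))
  }

  changed <- iv$s0 != iv$end_state
  k <- integer(nrow(iv))
  # uniform transition year within each changing interval; one draw each
  k[changed] <- 1L + floor(stats::runif(sum(changed)) * iv$gap[changed])

  n_rec <- ifelse(changed & iv$end_state == "DEAD", k, iv$gap)
  row_iv <- rep(seq_len(nrow(iv)), n_rec)
  j <- sequence(n_rec)
  kk <- k[row_iv]
  s0 <- iv$s0[row_iv]
  s1 <- iv$end_state[row_iv]
  out <- tibble::tibble(
    individual_id = iv$individual_id[row_iv],
    year = as.integer(iv$wave_year[row_iv] + j - 1L),
    age = as.integer(iv$age[row_iv] + j - 1L),
    sex = factor(as.character(iv$sex)[row_iv], msp_sexes()),
    race = factor(as.character(iv$race)[row_iv], msp_races()),
    origin_state = factor(
      ifelse(kk != 0L & j > kk, s1, s0), living_states()
    ),
    destination_state = factor(
      ifelse(kk != 0L & j >= kk, s1, s0), health_states()
    ),
    pseudo = iv$gap[row_iv] > 1L
  )
  dplyr::arrange(out, .data$individual_id, .data$year)
}
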