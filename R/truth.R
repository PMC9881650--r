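#' Ground-truth dynamics for the synthetic panel generator
#'
#' Bundles the latent annual Markov-chain coefficients, the health-state mix
#' of 50-year-old entrants, and the survey-design parameters of the emulated
#' biennial panel. The defaults encode the qualitative patterns seen in
#' HRS-style data: progression to worse health and mortality rise with age
#' (healthy-to-one-condition onset tails off around age 90), males progress
#' and die faster, recovery from multimorbidity declines with age, and the
#' four race groups are separated in the directions reported for US adults.
#'
#' @param coefficients Named list of per-origin coefficient matrices on the
#'   log-odds scale (see [rates_from_coefficients()]); defaults to
#'   [default_truth_coefficients()].
#' @param entry_state_distribution Probability vector over
#'   `living_states()` for the state of a 50-year-old entrant.
#' @param n_individuals Number of panel members.
#' @param n_waves Number of survey waves.
#' @param wave_spacing_years Years between waves (2 emulates a biennial
#'   survey).
#' @param base_year Calendar year of wave 1.
#' @param entry_age_range,entry_age_decay Ages at first interview are drawn
#'   from `entry_age_range` with weights proportional to
#'   `exp(-entry_age_decay * (age - 50))`.
#' @param p_male Probability that a panel member is male.
#' @param race_distribution Named probability vector over `msp_races()`.
#' @param attrition Per-wave probability (after wave 1) that a member drops
#'   out completely at random.
#' @return An object of class `msp_truth_params`.
#' @export
truth_params <- function(coefficients = default_truth_coefficients(),
                         entry_state_distribution = c(
                           HEALTHY = 0.72, ONE_CC = 0.23, MULTI = 0.05
                         ),
                         n_individuals = 20000L,
                         n_waves = 11L,
                         wave_spacing_years = 2L,
                         base_year = 1998L,
                         entry_age_range = 50:85,
                         entry_age_decay = 0.06,
                         p_male = 0.45,
                         race_distribution = c(
                           nh_white = 0.65, nh_black = 0.12,
                           hispanic = 0.13, other = 0.10
                         ),
                         attrition = 0.03) {
  params <- structure(
    list(
      coefficients = coefficients,
      entry_state_distribution = entry_state_distribution,
      n_individuals = as.integer(n_individuals),
      n_waves = as.integer(n_waves),
      wave_spacing_years = as.integer(wave_spacing_years),
      base_year = as.integer(base_year),
      entry_age_range = as.integer(entry_age_range),
      entry_age_decay = entry_age_decay,
      p_male = p_male,
      race_distribution = race_distribution,
      attrition = attrition
    ),
    class = "msp_truth_params"
  )
  validate_truth_params(params)
  params
}

#' @rdname truth_params
#' @param params Object to validate.
#' @export
validate_truth_params <- function(params) {
  stopifnot(inherits(params, "msp_truth_params"))
  d <- params$entry_state_distribution
  if (length(d) != 3 || any(d < 0) || abs(sum(d) - 1) > 1e-9) {
    stop("entry_state_distribution must be a non-negative vector over the three living states summing to 1", call. = FALSE)
  }
  if (params$n_individuals < 1) stop("n_individuals must be positive", call. = FALSE)
  if (params$wave_spacing_years < 1) stop("wave_spacing_years must be >= 1", call. = FALSE)
  if (params$attrition < 0 || params$attrition > 1) {
    stop("attrition must be a probability", call. = FALSE)
  }
  r <- params$race_distribution
  if (any(r < 0) || abs(sum(r) - 1) > 1e-9) {
    stop("race_distribution must be a probability vector", call. = FALSE)
  }
  if (params$p_male < 0 || params$p_male > 1) stop("p_male must be a probability", call. = FALSE)
  stopifnot(is.list(params$coefficients))
  for (origin in names(params$coefficients)) {
    B <- params$coefficients[[origin]]
    if (is.null(rownames(B)) || is.null(colnames(B))) {
      stop("coefficient matrices need destination rownames and term colnames", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Default ground-truth coefficient blocks
#'
#' Log-odds (relative to staying in the origin state) linear in scaled age
#' `age_s = (age - 50)/10`, its square, a male indicator, and race contrasts
#' against non-Hispanic White.
#'
#' @return Named list of matrices usable as the `coefficients` field of
#'   [truth_params()].
#' @export
default_truth_coefficients <- function() {
  terms <- msp_default_terms()
  blk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- terms
    m
  }
  list(
    HEALTHY = blk(list(
      ONE_CC = c(-2.2, 0.55, -0.07, 0.15, -0.15, -0.05, -0.05),
      MULTI  = c(-4.2, 0.45, 0.00, 0.25, 0.15, 0.30, 0.10),
      DEAD   = c(-5.2, 0.95, 0.00, 0.35, 0.25, -0.20, -0.05)
    )),
    ONE_CC = blk(list(
      MULTI = c(-2.8, 0.40, -0.02, 0.20, 0.10, 0.25, -0.10),
      DEAD  = c(-4.8, 0.90, 0.00, 0.35, 0.20, -0.15, -0.05)
    )),
    MULTI = blk(list(
      ONE_CC = c(-2.0, -0.30, 0.00, -0.15, -0.20, 0.15, 0.05),
      DEAD   = c(-4.3, 0.85, 0.00, 0.30, 0.25, 0.05, 0.10)
    ))
  )
}

#' One-year transition probabilities implied by truth parameters
#'
#' @param params An `msp_truth_params` object.
#' @param ages Ages to evaluate.
#' @return Rate table tibble (see [rates_from_coefficients()]).
#' @export
truth_rates <- function(params, ages = msp_adult_ages()) {
  rates_from_coefficients(params$coefficients, ages)
}

#' @export
print.msp_truth_params <- function(x, ...) {
  cat("<msp_truth_params>\n")
  cat(sprintf(
    "  panel: %d individuals, %d waves every %d year(s) from %d\n",
    x$n_individuals, x$n_waves, x$wave_spacing_years, x$base_year
  ))
  cat(sprintf(
    "  entry states: %s\n",
    paste(sprintf("%s %.2f", names(x$entry_state_distribution),
      x$entry_state_distribution), collapse = ", ")
  ))
  cat(sprintf("  attrition/wave: %.3f\n", x$attrition))
  invisible(x)
}
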