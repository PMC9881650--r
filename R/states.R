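#' Health-state vocabulary
#'
#' The model tracks adults 50 and older across three living health states plus
#' death: `HEALTHY` (no chronic condition), `ONE_CC` (exactly one chronic
#' condition), `MULTI` (multimorbidity, i.e. two or more chronic conditions),
#' and the absorbing state `DEAD`.
#'
#' @return `health_states()` returns the four state labels in canonical
#'   order; `living_states()` the three non-absorbing ones.
#' @export
health_states <- function() c("HEALTHY", "ONE_CC", "MULTI", "DEAD")

#' @rdname health_states
#' @export
living_states <- function() c("HEALTHY", "ONE_CC", "MULTI")

# canonical factor level orders used throughout
msp_sexes <- function() c("female", "male")
msp_races <- function() c("nh_white", "nh_black", "hispanic", "other")

# adult age range; 100 is the open-ended "100 and older" bin
msp_adult_ages <- function() 50:100

#' Collapse a chronic-condition count into a health state
#'
#' Applies the three-state classification used for self-reported condition
#' histories: zero conditions is healthy, exactly one is a single chronic
#' condition, two or more is multimorbidity.
#'
#' @param n_conditions Integer vector of reported chronic-condition counts.
#' @return Character vector of health-state labels.
#' @examples
#' classify_health_state(c(0, 1, 2, 7))
#' @export
classify_health_state <- function(n_conditions) {
  stopifnot(is.numeric(n_conditions), all(n_conditions >= 0, na.rm = TRUE))
  dplyr::case_when(
    n_conditions == 0 ~ "HEALTHY",
    n_conditions == 1 ~ "ONE_CC",
    n_conditions >= 2 ~ "MULTI"
  )
}

#' Permitted destination states by origin
#'
#' Condition histories are lifetime histories, so recovery to `HEALTHY` is
#' structurally impossible; a one-step back-transition `MULTI -> ONE_CC` is
#' allowed. The first destination listed for each origin is the "stay"
#' reference category of the multinomial models.
#'
#' @param allow_recovery If `TRUE`, every living origin may reach every
#'   living destination (plus death).
#' @return Named list mapping each living origin state to its destinations.
#' @export
default_destinations <- function(allow_recovery = FALSE) {
  if (allow_recovery) {
    list(
      HEALTHY = c("HEALTHY", "ONE_CC", "MULTI", "DEAD"),
      ONE_CC  = c("ONE_CC", "HEALTHY", "MULTI", "DEAD"),
      MULTI   = c("MULTI", "HEALTHY", "ONE_CC", "DEAD")
    )
  } else {
    list(
      HEALTHY = c("HEALTHY", "ONE_CC", "MULTI", "DEAD"),
      ONE_CC  = c("ONE_CC", "MULTI", "DEAD"),
      MULTI   = c("MULTI", "ONE_CC", "DEAD")
    )
  }
}
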