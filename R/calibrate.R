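#' Calibrate the constant net migration rate
#'
#' Finds the scalar net migration rate that minimises the sum of squared
#' relative errors between projected and observed total population over a
#' series of calendar years. The loss is evaluated with the production
#' projection engine itself ([project_population()]), and minimised by
#' Brent's bracketing method ([stats::optimize()]), so the result is
#' deterministic.
#'
#' @inheritParams project_population
#' @param target Tibble with columns `year`, `total`: the observed
#'   total-population series (all counts > 0, years after the base year).
#'   An `msp_demographics` object may be passed; its `observed_totals` are
#'   used.
#' @param bounds Length-2 numeric interval bracketing the rate.
#' @param tol Convergence tolerance on the rate.
#' @return A tibble with one row: `net_migration` (the argmin), `loss`
#'   (achieved objective), `at_boundary` (`TRUE`, with a warning, when the
#'   optimum sits on a bound — the true minimum may lie outside `bounds`).
#' @examples
#' tp <- truth_params()
#' dem <- generate_demographics(tp, true_migration = 0.004, horizon = 6,
#'   total_population = 1e5)
#' calibrate_net_migration(dem, truth_rates(tp), dem, dem$observed_totals)
#' @export
calibrate_net_migration <- function(initial, rates, dem, target,
                                    bounds = c(-0.05, 0.05),
                                    mode = c("rate", "count"),
                                    tol = 1e-9) {
  mode <- match.arg(mode)
  if (inherits(target, "msp_demographics")) target <- target$observed_totals
  stopifnot(all(c("year", "total") %in% names(target)), nrow(target) > 0)
  if (any(target$total <= 0)) stop("observed totals must be positive", call. = FALSE)
  if (inherits(initial, "msp_demographics")) initial <- initial$baseline
  base_year <- max(initial$year)
  yrs <- target$year[target$year > base_year]
  if (!length(yrs)) stop("target series has no years after the base year", call. = FALSE)
  horizon <- max(yrs) - base_year
  obs <- target[target$year > base_year, ]

  loss <- function(m) {
    proj <- project_population(initial, rates, dem,
      net_migration = m, horizon = horizon, mode = mode
    )
    hit <- dplyr::inner_join(proj$totals, obs, by = "year",
      suffix = c("_proj", "_obs")
    )
    sum(((hit$total_proj - hit$total_obs) / hit$total_obs)^2)
  }

  opt <- stats::optimize(loss, interval = sort(bounds), tol = tol)
  span <- diff(range(bounds))
  at_boundary <- min(abs(opt$minimum - bounds)) < 1e-4 * span
  if (at_boundary) {
    warning("calibrated net migration lies on the search boundary; widen `bounds`",
      call. = FALSE
    )
  }
  tibble::tibble(
    net_migration = opt$minimum,
    loss = opt$objective,
    at_boundary = at_boundary
  )
}
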