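#' Plot transition rates against age
#'
#' One panel per origin-destination pair, probability against age, coloured
#' by sex with one line per race.
#'
#' @param rates Rate table tibble.
#' @param origins Origin states to include.
#' @return A ggplot object.
#' @export
plot_transition_rates <- function(rates, origins = living_states()) {
  df <- rates |>
    dplyr::filter(
      as.character(.data$origin) %in% origins,
      as.character(.data$origin) != as.character(.data$destination),
      .data$probability > 0 | as.character(.data$destination) == "DEAD"
    ) |>
    dplyr::mutate(
      transition = paste(.data$origin, "→", .data$destination)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$age, .data$probability,
    colour = .data$sex, linetype = .data$race,
    group = interaction(.data$sex, .data$race)
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~transition, scales = "free_y") +
    ggplot2::labs(
      x = "age", y = "1-year transition probability",
      colour = NULL, linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot msp_transition_model
#' @export
autoplot.msp_transition_model <- function(object, ...) {
  plot_transition_rates(predict_rates(object), ...)
}

#' @method autoplot msp_projection
#' @export
autoplot.msp_projection <- function(object, ...) {
  df <- object$trajectory |>
    dplyr::filter(as.character(.data$state) %in% living_states()) |>
    dplyr::summarise(count = sum(.data$count), .by = c("year", "state"))
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$count / 1e6,
    colour = .data$state
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "year", y = "adults 50+ (millions)", colour = "health state"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot msp_bootstrap_ensemble
#' @export
autoplot.msp_bootstrap_ensemble <- function(object, origin = "HEALTHY",
                                            destination = "DEAD", ...) {
  df <- object$rates |>
    dplyr::filter(
      as.character(.data$origin) == origin,
      as.character(.data$destination) == destination
    )
  band <- df |>
    dplyr::summarise(
      lower = min(.data$probability), upper = max(.data$probability),
      .by = c("age", "sex", "race")
    )
  ggplot2::ggplot(band, ggplot2::aes(.data$age)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper, fill = .data$sex),
      alpha = 0.3
    ) +
    ggplot2::facet_wrap(~race) +
    ggplot2::labs(
      x = "age", y = sprintf("P(%s → %s)", origin, destination),
      fill = NULL,
      title = "bootstrap min-max band"
    ) +
    ggplot2::theme_minimal()
}
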