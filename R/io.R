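# Plain-text artifact formats: panels, person-year records, rate tables and
# populations as CSV; coefficient blocks as JSON; configs and truth
# parameters as YAML. Readers restore the canonical factor levels so a
# round-trip is lossless.

#' Read and write pipeline artifacts
#'
#' CSV readers/writers for the tabular artifacts and JSON/YAML serialisers
#' for models and parameters. States are stored as their uppercase tokens;
#' sex and race as their lowercase codes.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the restored
#'   object.
#' @name msp_io
NULL

#' @rdname msp_io
#' @export
write_panel_csv <- function(x, path) {
  readr::write_csv(
    dplyr::mutate(x, dplyr::across(c("sex", "race", "state"), as.character)),
    path
  )
  invisible(path)
}

#' @rdname msp_io
#' @export
read_panel_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      sex = factor(.data$sex, msp_sexes()),
      race = factor(.data$race, msp_races()),
      state = factor(.data$state, health_states())
    )
}

#' @rdname msp_io
#' @export
write_person_years_csv <- function(x, path) {
  readr::write_csv(
    dplyr::mutate(x, dplyr::across(
      c("sex", "race", "origin_state", "destination_state"), as.character
    )),
    path
  )
  invisible(path)
}

#' @rdname msp_io
#' @export
read_person_years_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      sex = factor(.data$sex, msp_sexes()),
      race = factor(.data$race, msp_races()),
      origin_state = factor(.data$origin_state, living_states()),
      destination_state = factor(.data$destination_state, health_states())
    )
}

#' @rdname msp_io
#' @export
write_rates_csv <- function(x, path) {
  readr::write_csv(
    dplyr::mutate(x, dplyr::across(
      c("origin", "destination", "sex", "race"), as.character
    )),
    path
  )
  invisible(path)
}

#' @rdname msp_io
#' @export
read_rates_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      origin = factor(.data$origin, living_states()),
      destination = factor(.data$destination, health_states()),
      sex = factor(.data$sex, msp_sexes()),
      race = factor(.data$race, msp_races())
    )
}

#' @rdname msp_io
#' @export
write_population_csv <- function(x, path) {
  readr::write_csv(
    dplyr::mutate(x, dplyr::across(c("sex", "race", "state"), as.character)),
    path
  )
  invisible(path)
}

#' @rdname msp_io
#' @export
read_population_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      sex = factor(.data$sex, msp_sexes()),
      race = factor(.data$race, msp_races()),
      state = factor(.data$state, msp_pop_levels())
    )
}

#' @rdname msp_io
#' @export
write_model_json <- function(x, path) {
  stopifnot(inherits(x, "msp_transition_model"))
  ser_block <- function(B) {
    out <- lapply(rownames(B), function(d) as.list(stats::setNames(B[d, ], colnames(B))))
    stats::setNames(out, rownames(B))
  }
  payload <- list(
    formula = paste(deparse(x$formula), collapse = " "),
    destinations = x$destinations,
    coefficients = lapply(x$coefficients, ser_block),
    std_errors = lapply(x$std_errors, ser_block),
    diagnostics = x$diagnostics
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname msp_io
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_block <- function(blk) {
    terms <- names(blk[[1]])
    m <- do.call(rbind, lapply(blk, function(r) unlist(r[terms])))
    dimnames(m) <- list(names(blk), terms)
    m
  }
  structure(
    list(
      coefficients = lapply(payload$coefficients, de_block),
      std_errors = lapply(payload$std_errors, de_block),
      formula = stats::as.formula(payload$formula),
      destinations = lapply(payload$destinations, unlist),
      diagnostics = dplyr::bind_rows(lapply(payload$diagnostics, tibble::as_tibble))
    ),
    class = "msp_transition_model"
  )
}

#' @rdname msp_io
#' @export
write_truth_params_yaml <- function(x, path) {
  stopifnot(inherits(x, "msp_truth_params"))
  payload <- unclass(x)
  payload$coefficients <- lapply(payload$coefficients, function(B) {
    lapply(stats::setNames(rownames(B), rownames(B)), function(d) {
      as.list(stats::setNames(B[d, ], colnames(B)))
    })
  })
  payload$entry_state_distribution <- as.list(payload$entry_state_distribution)
  payload$race_distribution <- as.list(payload$race_distribution)
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname msp_io
#' @export
read_truth_params_yaml <- function(path) {
  payload <- yaml::read_yaml(path)
  coefs <- lapply(payload$coefficients, function(blk) {
    terms <- names(blk[[1]])
    m <- do.call(rbind, lapply(blk, function(r) unlist(r[terms])))
    dimnames(m) <- list(names(blk), terms)
    m
  })
  truth_params(
    coefficients = coefs,
    entry_state_distribution = unlist(payload$entry_state_distribution),
    n_individuals = payload$n_individuals,
    n_waves = payload$n_waves,
    wave_spacing_years = payload$wave_spacing_years,
    base_year = payload$base_year,
    entry_age_range = payload$entry_age_range,
    entry_age_decay = payload$entry_age_decay,
    p_male = payload$p_male,
    race_distribution = unlist(payload$race_distribution),
    attrition = payload$attrition
  )
}

#' Read a pipeline run configuration
#'
#' Loads a YAML run configuration and fills in defaults for any missing
#' field; see [default_run_config()] for the full structure.
#'
#' @param path YAML file path.
#' @return A nested configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  modify_defaults(default_run_config(), user)
}

modify_defaults <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
      !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}
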