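# Shared machinery turning per-origin multinomial coefficient blocks into
# one-year transition probabilities. Both the synthetic truth dynamics and
# fitted models are stored in the same structure, so generator, estimator
# and projection engine all run through one code path.
#
# A coefficient set is a named list (one element per living origin state) of
# numeric matrices: rows = non-reference destinations, columns = model terms.
# The reference destination is "stay in the origin state". Age enters the
# linear predictor as age_s = (age - 50) / 10 and age_s2 = age_s^2.

msp_default_terms <- function() {
  c(
    "(Intercept)", "age_s", "age_s2", "sexmale",
    "racenh_black", "racehispanic", "raceother"
  )
}

# model matrix for the default covariate specification
msp_model_matrix <- function(df, formula = msp_default_formula()) {
  df <- dplyr::mutate(
    df,
    # 100 is the open-ended bin: older ages share its covariate value
    age_s = (pmin(.data$age, 100) - 50) / 10,
    age_s2 = ((pmin(.data$age, 100) - 50) / 10)^2,
    sex = factor(.data$sex, levels = msp_sexes()),
    race = factor(.data$race, levels = msp_races())
  )
  stats::model.matrix(formula, df)
}

msp_default_formula <- function() {
  stats::as.formula(~ age_s + age_s2 + sex + race)
}

# numerically stable row softmax with an implicit leading reference column
# of eta = 0; non-finite linear predictors are clamped so that degenerate
# (0/1) dynamics can be expressed with +/-Inf coefficients.
msp_softmax <- function(eta) {
  eta <- cbind(0, eta)
  eta[eta > 1e6] <- 1e6
  eta[eta < -1e6] <- -1e6
  eta <- eta - apply(eta, 1L, max)
  w <- exp(eta)
  w / rowSums(w)
}

# probabilities over destinations (reference first) for covariate rows X
# given one origin's coefficient matrix B (rows = non-ref destinations)
msp_origin_probs <- function(X, B) {
  Bc <- B
  Bc[!is.finite(Bc)] <- sign(Bc[!is.finite(Bc)]) * 1e6
  eta <- X %*% t(Bc)
  msp_softmax(eta)
}

#' Expand coefficient blocks into a transition rate table
#'
#' Evaluates the per-origin multinomial linear predictors over a covariate
#' grid and returns one-year transition probabilities
#' `P(destination | origin, age, sex, race)`. Structurally impossible
#' destinations are reported with probability exactly 0 so every origin row
#' covers all four states.
#'
#' @param coefs Named list of coefficient matrices, one per living origin
#'   state; rows are non-reference destinations, columns model terms.
#' @param ages Integer vector of ages (50 to 100; 100 is the open bin).
#' @param formula Right-hand-side covariate formula matching the coefficient
#'   columns.
#' @return A tibble with columns `origin`, `destination`, `age`, `sex`,
#'   `race`, `probability`; rows within each (origin, age, sex, race) cell
#'   sum to 1.
#' @export
rates_from_coefficients <- function(coefs, ages = msp_adult_ages(),
                                    formula = msp_default_formula()) {
  stopifnot(is.list(coefs), length(coefs) >= 1)
  if (any(ages < 50 | ages > 100)) {
    stop("ages must lie in 50..100 (100 is the open-ended bin)", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    age = as.integer(ages),
    sex = msp_sexes(),
    race = msp_races()
  )
  X <- msp_model_matrix(grid, formula)
  out <- purrr::imap(coefs, function(B, origin) {
    p <- msp_origin_probs(X, B)
    dests <- c(origin, rownames(B))
    colnames(p) <- dests
    res <- dplyr::bind_cols(grid, tibble::as_tibble(p)) |>
      tidyr::pivot_longer(dplyr::all_of(dests),
        names_to = "destination", values_to = "probability"
      )
    # structural zeros: destinations absent from this origin's block
    missing <- setdiff(health_states(), dests)
    if (length(missing)) {
      zero <- tidyr::expand_grid(grid, destination = missing) |>
        dplyr::mutate(probability = 0)
      res <- dplyr::bind_rows(res, zero)
    }
    dplyr::mutate(res, origin = origin, .before = 1)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      origin = factor(.data$origin, levels = living_states()),
      destination = factor(.data$destination, levels = health_states()),
      sex = factor(.data$sex, levels = msp_sexes()),
      race = factor(.data$race, levels = msp_races())
    ) |>
    dplyr::arrange(.data$origin, .data$age, .data$sex, .data$race, .data$destination) |>
    dplyr::select(
      "origin", "destination", "age", "sex", "race", "probability"
    )
}

#' Validate a transition rate table
#'
#' Checks non-negativity and that every (origin, age, sex, race) row sums to
#' one within `tol`.
#'
#' @param rates Rate table as returned by [rates_from_coefficients()] or
#'   [predict_rates()].
#' @param tol Row-sum tolerance.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_rate_table <- function(rates, tol = 1e-12) {
  stopifnot(all(c("origin", "destination", "age", "sex", "race", "probability")
  %in% names(rates)))
  if (any(rates$probability < 0)) stop("negative transition probability", call. = FALSE)
  sums <- rates |>
    dplyr::summarise(
      s = sum(.data$probability),
      .by = c("origin", "age", "sex", "race")
    )
  bad <- abs(sums$s - 1) > tol
  if (any(bad)) {
    stop(
      sprintf("%d transition rows do not sum to 1 (max dev %.3g)",
        sum(bad), max(abs(sums$s - 1))),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# rate table -> dense array [age 50:100, sex, race, origin, destination]
msp_rates_array <- function(rates) {
  ages <- msp_adult_ages()
  arr <- array(
    NA_real_,
    dim = c(length(ages), 2L, 4L, 3L, 4L),
    dimnames = list(
      age = as.character(ages), sex = msp_sexes(), race = msp_races(),
      origin = living_states(), destination = health_states()
    )
  )
  idx <- cbind(
    match(rates$age, ages),
    match(as.character(rates$sex), msp_sexes()),
    match(as.character(rates$race), msp_races()),
    match(as.character(rates$origin), living_states()),
    match(as.character(rates$destination), health_states())
  )
  if (anyNA(idx)) stop("rate table contains cells outside the model grid", call. = FALSE)
  arr[idx] <- rates$probability
  if (anyNA(arr)) stop("rate table is missing cells for some (origin, age, sex, race)", call. = FALSE)
  arr
}
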