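#' Generate a synthetic biennial health-state panel
#'
#' Simulates an HRS-like longitudinal survey: each individual evolves on a
#' latent *annual* Markov chain over \{healthy, one chronic condition,
#' multimorbidity, dead\} driven by the ground-truth coefficients, but is
#' only observed every `wave_spacing_years` years. A death inside an
#' observation interval surfaces as a `DEAD` record at the next wave, after
#' which the individual contributes nothing. Attrition censors individuals
#' completely at random from a wave onward.
#'
#' Probabilities are always evaluated at the effective age `min(age, 100)`;
#' 100 is the open-ended age bin of the model.
#'
#' @param params Ground truth and survey design, from [truth_params()].
#' @param seed Integer seed; fixes all randomness, so identical
#'   `(params, seed)` reproduce the panel exactly.
#' @return A tibble of wave observations with columns `individual_id`,
#'   `wave_year`, `age`, `sex`, `race`, `state`, carrying the generating
#'   `params` in attribute `truth_params` and the seed in attribute `seed`.
#' @examples
#' p <- truth_params(n_individuals = 200, n_waves = 3)
#' panel <- generate_panel(p, seed = 1)
#' dplyr::count(panel, state)
#' @export
generate_panel <- function(params, seed) {
  validate_truth_params(params)
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- params$n_individuals
  spacing <- params$wave_spacing_years
  wave_years <- params$base_year + (seq_len(params$n_waves) - 1L) * spacing

  age_w <- exp(-params$entry_age_decay * (params$entry_age_range - 50))
  ind <- tibble::tibble(
    individual_id = seq_len(n),
    sex = msp_sexes()[1L + (stats::runif(n) < params$p_male)],
    race = sample(msp_races(), n, replace = TRUE, prob = params$race_distribution),
    entry_age = sample(params$entry_age_range, n, replace = TRUE, prob = age_w)
  )
  state <- sample.int(3L, n, replace = TRUE, prob = params$entry_state_distribution)

  # wave index from which an individual is lost to follow-up (Inf = never)
  dropout_wave <- rep(Inf, n)
  if (params$attrition > 0 && params$n_waves > 1) {
    dropout_wave <- 2 + stats::rgeom(n, params$attrition)
  }

  sex_i <- match(ind$sex, msp_sexes())
  race_i <- match(ind$race, msp_races())
  dead_emitted <- rep(FALSE, n)

  emit <- function(w) {
    year <- wave_years[w]
    sel <- which(dropout_wave > w & !dead_emitted)
    if (!length(sel)) return(NULL)
    dead_emitted[sel[state[sel] == 4L]] <<- TRUE
    tibble::tibble(
      individual_id = ind$individual_id[sel],
      wave_year = year,
      age = ind$entry_age[sel] + (year - params$base_year),
      sex = ind$sex[sel],
      race = ind$race[sel],
      state = health_states()[state[sel]]
    )
  }

  obs <- vector("list", params$n_waves)
  obs[[1L]] <- emit(1L)
  if (params$n_waves > 1) {
    for (w in 2:params$n_waves) {
      for (step_year in (wave_years[w - 1]):(wave_years[w] - 1L)) {
        age_now <- pmin(ind$entry_age + (step_year - params$base_year), 100L)
        state <- msp_advance_states(
          state, age_now, sex_i, race_i, params$coefficients
        )
      }
      obs[[w]] <- emit(w)
    }
  }

  panel <- dplyr::bind_rows(obs) |>
    dplyr::arrange(.data$individual_id, .data$wave_year) |>
    dplyr::mutate(
      sex = factor(.data$sex, levels = msp_sexes()),
      race = factor(.data$race, levels = msp_races()),
      state = factor(.data$state, levels = health_states())
    )
  attr(panel, "truth_params") <- params
  attr(panel, "seed") <- as.integer(seed)
  class(panel) <- c("msp_panel", class(panel))
  panel
}

# advance a vector of latent states by one annual step
msp_advance_states <- function(state, age, sex_i, race_i, coefs) {
  new_state <- state
  for (o in 1:3) {
    idx <- which(state == o)
    if (!length(idx)) next
    origin <- living_states()[o]
    df <- tibble::tibble(
      age = age[idx],
      sex = msp_sexes()[sex_i[idx]],
      race = msp_races()[race_i[idx]]
    )
    X <- msp_model_matrix(df)
    B <- coefs[[origin]]
    p <- msp_origin_probs(X, B)
    dest_states <- match(c(origin, rownames(B)), health_states())
    new_state[idx] <- dest_states[msp_sample_rows(p)]
  }
  new_state
}

# one categorical draw per row of a probability matrix
msp_sample_rows <- function(p) {
  k <- ncol(p)
  if (k == 1L) return(rep(1L, nrow(p)))
  L <- matrix(0, k, k - 1L)
  L[upper.tri(L, diag = TRUE)] <- 1
  cp <- p %*% L # cumulative probs over first k-1 categories
  u <- stats::runif(nrow(p))
  1L + as.integer(rowSums(u > cp))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
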