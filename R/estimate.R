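#' Fit per-origin multinomial transition models
#'
#' Fits one multinomial logistic regression per living origin state on
#' annual person-year records, with "stay in the origin state" as the
#' reference destination. The default covariate specification is scaled age
#' `(age - 50)/10`, its square, sex, and race main effects; pass
#' `formula = ~ 1` for intercept-only fits or any other right-hand side in
#' terms of `age_s`, `age_s2`, `sex`, `race`.
#'
#' Optimisation is deterministic (BFGS inside [nnet::multinom()] with fixed
#' tolerance and iteration cap), so refitting identical records reproduces
#' the model exactly.
#'
#' @param records Person-year tibble from [expand_panel()].
#' @param formula Right-hand-side covariate formula.
#' @param destinations Allowed destinations per origin (structural zeros are
#'   the states not listed); see [default_destinations()].
#' @param maxit,reltol Optimiser settings passed to [nnet::multinom()].
#' @param se Compute a Hessian-based standard error for every coefficient
#'   (skipped inside bootstrap replicates, where the ensemble itself carries
#'   the uncertainty).
#' @return An object of class `msp_transition_model` with per-origin
#'   coefficient and standard-error matrices, fit diagnostics, and the
#'   covariate specification.
#' @export
fit_transition_model <- function(records,
                                 formula = msp_default_formula(),
                                 destinations = default_destinations(),
                                 maxit = 500L, reltol = 1e-10, se = TRUE) {
  stopifnot(nrow(records) > 0)
  coefs <- list()
  ses <- list()
  diag <- list()
  for (origin in living_states()) {
    sub <- dplyr::filter(records, as.character(.data$origin_state) == origin)
    if (nrow(sub) == 0) {
      stop(sprintf("no person-year records with origin state %s", origin),
        call. = FALSE
      )
    }
    dests <- destinations[[origin]]
    obs_dest <- unique(as.character(sub$destination_state))
    extra <- setdiff(obs_dest, dests)
    if (length(extra)) {
      stop(sprintf(
        "origin %s has observed destination(s) %s outside the permitted set",
        origin, paste(extra, collapse = ", ")
      ), call. = FALSE)
    }
    df <- dplyr::transmute(
      sub,
      y = factor(as.character(.data$destination_state), levels = dests),
      age_s = (pmin(.data$age, 100) - 50) / 10,
      age_s2 = ((pmin(.data$age, 100) - 50) / 10)^2,
      sex = factor(as.character(.data$sex), levels = msp_sexes()),
      race = factor(as.character(.data$race), levels = msp_races())
    )
    rhs <- attr(stats::terms(formula), "term.labels")
    full <- stats::reformulate(if (length(rhs)) rhs else "1", response = "y")
    fit <- nnet::multinom(full,
      data = df, trace = FALSE, maxit = maxit,
      reltol = reltol, Hess = se
    )
    if (!is.null(fit$convergence) && fit$convergence != 0) {
      stop(sprintf(
        "multinomial fit for origin %s did not converge in %d iterations (deviance %.4f)",
        origin, maxit, fit$deviance
      ), call. = FALSE)
    }
    B <- stats::coef(fit)
    if (is.null(dim(B))) { # two-destination case returns a vector
      B <- matrix(B, nrow = 1, dimnames = list(dests[2], names(stats::coef(fit))))
    }
    S <- if (se) {
      sm <- summary(fit)
      semat <- sm$standard.errors
      if (is.null(dim(semat))) {
        semat <- matrix(semat, nrow = 1, dimnames = dimnames(B))
      }
      semat
    } else {
      array(NA_real_, dim(B), dimnames = dimnames(B))
    }
    if (any(!is.finite(B))) {
      stop(sprintf(
        "non-finite coefficients for origin %s: likely separation in the data",
        origin
      ), call. = FALSE)
    }
    coefs[[origin]] <- B
    ses[[origin]] <- S
    diag[[origin]] <- tibble::tibble(
      origin = origin, n = nrow(df),
      deviance = fit$deviance, edf = fit$edf, converged = TRUE
    )
  }
  structure(
    list(
      coefficients = coefs,
      std_errors = ses,
      formula = formula,
      destinations = destinations,
      diagnostics = dplyr::bind_rows(diag)
    ),
    class = "msp_transition_model"
  )
}

#' Predict one-year transition probabilities from a fitted model
#'
#' Evaluates the fitted multinomial models over the full age-sex-race grid.
#' Rows within each (origin, age, sex, race) cell sum to one; structurally
#' impossible destinations have probability exactly zero.
#'
#' @param model An `msp_transition_model`.
#' @param ages Ages to evaluate (50..100).
#' @return Rate table tibble; see [rates_from_coefficients()].
#' @export
predict_rates <- function(model, ages = msp_adult_ages()) {
  stopifnot(inherits(model, "msp_transition_model"))
  rates_from_coefficients(model$coefficients, ages, model$formula)
}

#' @export
print.msp_transition_model <- function(x, ...) {
  cat("<msp_transition_model>\n")
  print(x$diagnostics)
  invisible(x)
}

#' Tidy a fitted transition model
#'
#' @param x An `msp_transition_model`.
#' @param ... Unused.
#' @return Tibble with columns `origin`, `destination`, `term`, `estimate`,
#'   `std.error` (log-odds scale, reference = stay in origin state).
#' @method tidy msp_transition_model
#' @export
tidy.msp_transition_model <- function(x, ...) {
  purrr::imap(x$coefficients, function(B, origin) {
    S <- x$std_errors[[origin]]
    tibble::tibble(
      origin = origin,
      destination = rep(rownames(B), each = ncol(B)),
      term = rep(colnames(B), times = nrow(B)),
      estimate = as.vector(t(B)),
      std.error = as.vector(t(S))
    )
  }) |> dplyr::bind_rows()
}

#' Glance at a fitted transition model
#'
#' @param x An `msp_transition_model`.
#' @param ... Unused.
#' @return One-row tibble with pooled fit summaries.
#' @method glance msp_transition_model
#' @export
glance.msp_transition_model <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    nobs = sum(d$n),
    deviance = sum(d$deviance),
    edf = sum(d$edf),
    n_origins = nrow(d),
    converged = all(d$converged)
  )
}

#' Cluster-bootstrap transition rate tables
#'
#' Resamples whole individuals with replacement from the wave panel,
#' re-expands the intervals with a fresh sub-seed (so the single-draw
#' imputation variance is propagated), refits the transition models, and
#' predicts a full rate table per replicate. Replicates whose fit fails are
#' flagged and excluded.
#'
#' @param panel Wave-observation tibble.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed controlling resampling and all sub-seeds.
#' @param ages Ages at which replicate tables are predicted.
#' @param resample Set `FALSE` to refit on the original panel (identity
#'   resample); the b-th replicate then expands with seed `seed + b - 1`, so
#'   `B = 1` reproduces the point estimate obtained with expansion seed
#'   `seed`.
#' @inheritParams fit_transition_model
#' @param allow_recovery Passed to [expand_panel()].
#' @return An object of class `msp_bootstrap_ensemble`: replicate rate
#'   tables in `$rates` (with a `replicate` column), failed replicate ids in
#'   `$failed`, and the generating seed.
#' @export
bootstrap_rates <- function(panel, B, seed,
                            ages = msp_adult_ages(),
                            formula = msp_default_formula(),
                            destinations = default_destinations(),
                            resample = TRUE,
                            allow_recovery = FALSE) {
  stopifnot(B >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # identity mode keeps the expansion seed deterministic and equal to `seed`
  # for the first replicate, so B = 1 reproduces a point run exactly
  expansion_seeds <- if (resample) {
    sample.int(.Machine$integer.max - 1L, B)
  } else {
    as.integer(seed) + seq_len(B) - 1L
  }

  ids <- unique(panel$individual_id)
  rows_by_id <- split(seq_len(nrow(panel)), panel$individual_id)

  reps <- vector("list", B)
  failed <- integer()
  for (b in seq_len(B)) {
    if (resample) {
      take <- sample(length(ids), replace = TRUE)
      rows <- rows_by_id[take]
      rep_panel <- panel[unlist(rows), ]
      rep_panel$individual_id <- rep(seq_along(take), lengths(rows))
    } else {
      rep_panel <- panel
    }
    tab <- tryCatch(
      {
        rec <- expand_panel(rep_panel, expansion_seeds[b], allow_recovery)
        m <- fit_transition_model(rec, formula, destinations, se = FALSE)
        predict_rates(m, ages)
      },
      error = function(e) e
    )
    if (inherits(tab, "error")) {
      failed <- c(failed, b)
    } else {
      tab$replicate <- b
      reps[[b]] <- tab
    }
  }
  if (length(failed) == B) {
    stop("all bootstrap replicates failed to fit", call. = FALSE)
  }
  structure(
    list(
      rates = dplyr::bind_rows(reps),
      B = B,
      failed = failed,
      seed = as.integer(seed)
    ),
    class = "msp_bootstrap_ensemble"
  )
}

#' @export
print.msp_bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(
    "<msp_bootstrap_ensemble> %d replicates (%d failed), seed %d\n",
    x$B, length(x$failed), x$seed
  ))
  invisible(x)
}
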