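# Shared fixtures. Heavy objects (the 50k person-year recovery fit, the
# 200-replicate bootstrap ensemble) are computed lazily and cached for the
# whole test session.

.msp_cache <- new.env(parent = emptyenv())

# coefficient blocks with the default structure but supplied values
coef_blocks <- function(values) {
  terms <- c(
    "(Intercept)", "age_s", "age_s2", "sexmale",
    "racenh_black", "racehispanic", "raceother"
  )
  lapply(values, function(rows) {
    m <- do.call(rbind, lapply(rows, function(v) {
      out <- numeric(length(terms))
      out[seq_along(v)] <- v
      out
    }))
    dimnames(m) <- list(names(rows), terms)
    m
  })
}

# no transitions at all: every off-diagonal log-odds is -Inf
identity_coefs <- function() {
  coef_blocks(list(
    HEALTHY = list(ONE_CC = -Inf, MULTI = -Inf, DEAD = -Inf),
    ONE_CC = list(MULTI = -Inf, DEAD = -Inf),
    MULTI = list(ONE_CC = -Inf, DEAD = -Inf)
  ))
}

# age/sex/race-constant transition probabilities via intercepts
# p: named list origin -> named vector of destination probabilities
# (the complement goes to "stay")
constant_coefs <- function(p) {
  coef_blocks(lapply(p, function(probs) {
    stay <- 1 - sum(probs)
    lapply(as.list(log(probs / stay)), function(x) x)
  }))
}

# full 4x4 annual transition matrix (rows/cols in health_states() order)
# for covariate-constant coefficients
constant_matrix <- function(coefs) {
  rt <- rates_from_coefficients(coefs, ages = 60)
  P <- matrix(0, 4, 4, dimnames = list(health_states(), health_states()))
  one <- rt[rt$sex == "female" & rt$race == "nh_white", ]
  P[cbind(as.character(one$origin), as.character(one$destination))] <- one$probability
  P["DEAD", "DEAD"] <- 1
  P
}

matpow <- function(P, t) {
  Q <- diag(nrow(P))
  for (i in seq_len(t)) Q <- Q %*% P
  Q
}

# truth parameters for the balanced recovery design: flat entry ages, equal
# race shares, balanced entry states, annual waves, no attrition
balanced_truth <- function(n_individuals = 11000, n_waves = 8) {
  truth_params(
    n_individuals = n_individuals, n_waves = n_waves,
    wave_spacing_years = 1, attrition = 0,
    entry_age_range = 50:99, entry_age_decay = 0,
    race_distribution = c(
      nh_white = 0.25, nh_black = 0.25, hispanic = 0.25, other = 0.25
    ),
    entry_state_distribution = c(HEALTHY = 0.34, ONE_CC = 0.33, MULTI = 0.33)
  )
}

# ~50k person-year parameter-recovery experiment (cached)
recovery_fit <- function() {
  if (is.null(.msp_cache$recovery)) {
    tp <- balanced_truth()
    panel <- generate_panel(tp, seed = 42)
    records <- expand_panel(panel, seed = 43)
    fit <- fit_transition_model(records)
    .msp_cache$recovery <- list(
      truth = tp, records = records, fit = fit,
      rates = predict_rates(fit), truth_table = truth_rates(tp)
    )
  }
  .msp_cache$recovery
}

# 200-replicate cluster bootstrap on a demo-scale biennial panel (cached)
coverage_ensemble <- function() {
  if (is.null(.msp_cache$coverage)) {
    tp <- truth_params(n_individuals = 1500, n_waves = 6)
    panel <- generate_panel(tp, seed = 11)
    ens <- bootstrap_rates(panel, B = 200, seed = 12)
    .msp_cache$coverage <- list(truth = tp, panel = panel, ensemble = ens)
  }
  .msp_cache$coverage
}

# minimal demographic inputs for engine unit tests: no births, no under-50
# deaths, everyone enters the adult block healthy
zero_dem <- function(entry = c(HEALTHY = 1, ONE_CC = 0, MULTI = 0),
                     fertility = 0, srb = 0.5) {
  structure(
    list(
      base_year = 2000L,
      baseline = NULL,
      fertility = tibble::tibble(race = msp_races(), rate = fertility),
      under50_mortality = tidyr::expand_grid(
        age = 0:49, sex = msp_sexes(), race = msp_races()
      ) |> dplyr::mutate(q = 0),
      sex_ratio_at_birth = srb,
      entry_state_distribution = entry,
      observed_totals = NULL,
      true_migration = 0
    ),
    class = "msp_demographics"
  )
}

# an all-zero population tibble to fill cell by cell
empty_pop <- function(year = 2000L) {
  dplyr::bind_rows(
    tidyr::expand_grid(
      age = 0:49, sex = msp_sexes(), race = msp_races(), state = "UNDER50"
    ),
    tidyr::expand_grid(
      age = 50:100, sex = msp_sexes(), race = msp_races(),
      state = living_states()
    )
  ) |>
    dplyr::mutate(
      year = as.integer(year), count = 0,
      sex = factor(sex, msp_sexes()),
      race = factor(race, msp_races()),
      state = factor(state, c("UNDER50", living_states())),
      .before = 1
    )
}

set_cell <- function(pop, age, sex, race, state, count) {
  i <- pop$age == age & pop$sex == sex & pop$race == race & pop$state == state
  stopifnot(sum(i) == 1)
  pop$count[i] <- count
  pop
}

# per-year accounting-identity residuals of a projection, relative scale
identity_residuals <- function(proj) {
  tot <- proj$totals$total
  f <- proj$flows
  (tot[-1] - (tot[-length(tot)] + f$births - f$deaths + f$net_migrants)) /
    tot[-1]
}

# trajectory with counts placed into specific (age, sex, race, state) cells
traj_cells_acc <- function(cells, year = 2020L) {
  pop <- empty_pop(year)
  for (c in cells) {
    pop <- set_cell(
      pop, c$age,
      if (is.null(c$sex)) "female" else c$sex,
      if (is.null(c$race)) "nh_white" else c$race,
      c$state, c$count
    )
  }
  pop
}
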