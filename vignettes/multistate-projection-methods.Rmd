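---
title: "Projecting chronic-disease burden with a multi-state population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting chronic-disease burden with a multi-state population model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspop)
library(dplyr)
```

## The model

`mspop` projects the number of adults 50 and older who are healthy, live
with one chronic condition, or live with multimorbidity (two or more
chronic conditions), by combining three pieces:

1. **One-year transition probabilities** between the living health states
   and death, specific to age, sex and race, estimated from an
   interval-censored longitudinal panel;
2. a **discrete-time cohort-component engine** that evolves population
   stocks by age (single years, 0 to an open 100+ bin), sex, race and — for
   adults — health state, with births, life-table deaths below 50, and a
   constant net migration rate; and
3. **bootstrap uncertainty** propagated by re-estimating the transition
   tables on resampled panels and re-running the projection once per
   replicate table.

The state space for adults is \{healthy, one chronic condition,
multimorbidity, dead\}; death is absorbing. Because condition histories are
lifetime self-reports, recovery to the healthy state is treated as
structurally impossible; the one permitted backward move is multimorbidity
to one condition (a report with exactly one still-active condition). Both
choices are configurable (`default_destinations(allow_recovery = TRUE)`).

## Annualising interval-censored waves

Panels of the kind emulated here observe respondents every two years, while
the projection needs one-year probabilities. `expand_panel()` converts each
wave pair into annual person-year records by a pseudo-data fill-in rule:

* if the two wave states agree, every intervening year keeps that state;
* if they differ, exactly one transition is placed in a year drawn
  uniformly from the interval, with the start state before it and the end
  state after it; a death interval ends at the drawn year.

Two design choices are worth making explicit. The transition time is drawn
*once* per interval (no averaging over placements), which makes the draw
part of the estimator; the bootstrap therefore re-draws it inside every
replicate so imputation variance is propagated. And a worsening by two
steps (healthy at one wave, multimorbid at the next) is filled as one
direct transition rather than routed through the intermediate state: the
annual model permits direct healthy-to-multimorbidity moves, and the
fill-in rule imposes a single transition per interval. The expansion is
exact when waves are annual; for biennial waves it is an approximation that
slightly smooths the timing of transitions, which is the standard cost of
this rule and one reason the package ships an oracle-based validation
suite rather than relying on the estimator alone.

## Estimating transition probabilities

`fit_transition_model()` fits one multinomial logistic regression per
living origin state, with "stay" as the reference destination. The default
linear predictor is

$$\log\frac{P(d \mid o, a, s, r)}{P(o \mid o, a, s, r)} =
  \beta_{0}^{od} + \beta_{1}^{od}\,\tilde a + \beta_{2}^{od}\,\tilde a^{2}
  + \beta_{3}^{od}\,\mathbf{1}[s=\text{male}]
  + \boldsymbol\gamma^{od\top} \mathbf{r},$$

with $\tilde a = (a - 50)/10$ and race dummies against non-Hispanic White.
The quadratic age term is the smallest family that can reproduce onset
curves which rise through the 60s–80s and tail off past 90; no interactions
are included by default, but any right-hand side in `age_s`, `age_s2`,
`sex`, `race` may be passed (including `~ 1`, or a fully stratified
specification). Ages beyond 100 share the covariate value of the open
100+ bin. Optimisation runs through `nnet::multinom` with a 1e-10 relative
tolerance and a 500-iteration cap, so fits are deterministic; separation or
an empty origin stratum is an explicit error, not a silent zero.

Uncertainty comes from a **cluster bootstrap**: whole individuals are
resampled with replacement (person-years within one person are dependent
by construction), intervals are re-expanded with a fresh sub-seed, and the
model is refitted, yielding one full rate table per replicate
(`bootstrap_rates()`). Replicates that fail to fit are flagged and
excluded with a count. The production default is B = 1000; the bundled
demo configuration uses B = 50 so the whole pipeline runs at desk scale.

## The projection engine

`project_population()` is a deterministic expected-value stock-flow model.
Each annual step applies, in a fixed, documented order:

1. health-state transitions (including death) to the 50+ stocks, at the
   rates of the *origin* age — which is why transitions precede aging;
2. under-50 deaths from the (time-invariant) life-table schedule;
3. aging: every surviving cohort advances one year; survivors of age 49
   enter the adult block spread over living states by the entry-state
   distribution; age-99 survivors merge into the absorbing 100+ bin;
4. births at age 0, race-specific fertility times females 15–49, split by
   the sex ratio at birth (fertility and under-50 mortality are held at
   their base-year values throughout);
5. net migration: a single constant scalar. By default it is a *rate*
   applied to the post-event total and distributed proportionally over the
   full age-sex-race-state composition (migrants are assumed to look like
   the resident population); an absolute-count mode is available because
   published sources state migration either way.

With this ordering the bookkeeping identity
$\text{total}(t{+}1) = \text{total}(t) + \text{births} - \text{deaths} +
\text{net migrants}$ holds to floating-point precision every year, and the
test suite asserts it at 1e-9 relative tolerance in every run.

The base-year health-state composition of adults — not observable from
aggregate population counts — is initialised from the transition dynamics
themselves: the entry-state distribution at 50 is evolved age by age,
conditioned on survival. Entrants at age 50 use a configurable
distribution whose natural estimate is the panel's state mix at ages
50–51.

### Migration calibration

The constant migration rate is not taken from an external source but
calibrated: `calibrate_net_migration()` minimises the sum of squared
*relative* errors between projected and observed total population over a
year series, using Brent's method on the production engine itself (no
surrogate model), with a 1e-9 tolerance on the rate. Relative errors make
the loss scale-free; totals (rather than per-stratum series) are used
because only totals are plausibly available as a calibration target. An
optimum on the search boundary is flagged with a warning. Closed-loop
tests recover generating rates of −0.005, 0 and 0.01 per year to better
than 1e-6. Calibration runs once, against the point-estimate rate table:
the model has one constant rate, not one per replicate.

### The microsimulation oracle

`microsim_oracle()` simulates the same dynamics agent by agent —
multinomial state draws, Bernoulli deaths and births — and exists purely to
validate the expected-value engine; it is never the production path.
Agents are allocated to initial cells by largest remainder (so degenerate
0/1 dynamics reproduce the engine exactly), and constant-rate migration
enters as a deterministic per-year weight multiplier $(1+m)$ shared by all
agents, preserving mean equivalence without a stochastic migration process.
At 100,000 agents over a 10-year horizon, every state-by-age-band cell
agrees with the engine within 3 Monte-Carlo standard errors.

## The synthetic data generator

No public microdata accompany the package, so `generate_panel()` emulates
the study design the estimator targets: a biennial panel of adults 50+
whose true dynamics are an *annual* latent Markov chain with known
log-odds coefficients (`truth_params()`). Observation, not dynamics, is
biennial: a death inside an interval surfaces as a `DEAD` record at the
next wave; attrition censors individuals completely at random (3% per wave
by default), which keeps estimation unbiased so parameter-recovery tests
are meaningful. The default truth encodes the qualitative patterns
reported for US adults: onset and mortality log-odds rising with age (onset
of a first condition tailing off around 90), males progressing and dying
faster, recovery from multimorbidity declining with age, and race contrasts
in the directions observed (e.g. highest healthy-to-multimorbidity rates
for Hispanic adults, highest mortality for non-Hispanic Black adults).
Default survey-design values — 20,000 individuals, 11 biennial waves from
1998, entry ages 50–85 with exponentially decaying weights, race shares
65/12/13/10, 45% male — mirror an HRS-like panel.

What the generator does *not* emulate: survey weights, household
clustering, the nine underlying conditions as separate variables,
informative attrition, or period (calendar-time) effects. Passing tests
therefore demonstrate that the pipeline recovers dynamics of this
idealised design-generating process; they do not certify behaviour under
informative missingness or secular trends.

`generate_demographics()` supplies the remaining engine inputs at a chosen
scale: a base-year population with a mildly declining age profile below 50
and a steeper decline above 85, race-specific fertility (0.052–0.063
births per fecund female per year, 2018-like), an under-50 mortality
schedule (infant ~0.005 falling below 1e-3, rising again towards 50, with
sex and race multipliers), a 0.512 male birth ratio, and — crucially for
testing — an observed total-population series produced by running the
engine itself under the truth rates at a known migration rate, so that
calibration recovery is a closed loop.

## Experimental designs used in validation

Two deliberate design choices in the validation experiments differ from
the survey-emulating defaults:

* **Parameter recovery** uses a *balanced* design — flat entry ages 50–99,
  equal race shares, near-equal entry states, annual waves, no attrition —
  so that every stratum of every origin model is informative at the
  experiment's ~50,000 person-years. Recovery experiments answer "does the
  estimator find the truth given information", not "how much information
  does a realistic panel carry".
* Even so, absolute probability errors concentrate where probabilities are
  large: annual death probabilities of 0.3–0.4 at ages 85+ carry absolute
  sampling errors of roughly 0.03–0.06 at this sample size (they shrink
  like $1/\sqrt{n}$; ~0.028 remains at 300,000 person-years). Coefficient
  estimates sit well within 3 standard errors of truth; a uniform 0.02
  absolute cap on all 4,000+ table cells is beyond what 50,000
  person-years can deliver, and the test suite reports that check
  honestly rather than relaxing it.

Problem sizes elsewhere were chosen so the full suite runs comfortably on
a single core: the bootstrap-coverage experiment uses a 1,500-person,
six-wave panel with 200 replicates (coverage of truth by min–max replicate
ranges ≈ 98% of rate cells and 100% of reported burden cells); the oracle
comparison uses 100,000 agents; calibration experiments use a 1e6-person
synthetic population over 10 years.

## Reporting conventions

`aggregate_burden()` sums adult stocks into the published table layout —
groups *total*, *at least one chronic condition* (one condition +
multimorbidity) and *multimorbidity*, by age bands 50–59, 60–79, 80+ and
an all-ages-50+ row, optionally by sex or race. Intervals from a replicate
ensemble default to the full min–max range (a "100% interval", matching
the convention of the tables this layout mirrors); symmetric percentile
intervals are available (`summarize_ensemble(rule = "percentile")`).
Prevalence rows are denominated by the **total population of all ages**,
including the under-50 block — the only denominator consistent with the
published prevalence levels this layout reproduces — and the output
metadata says so. Printed values round half away from zero: counts in
millions to five significant figures, percentage changes to the printed
decimals (`round_half_up()`, `signif_half_up()`).

## A worked run at demo scale

```{r demo, eval = FALSE}
cfg <- default_run_config()
cfg$panel$n_individuals <- 2000   # full demo scale: 20000, B = 50
cfg$estimation$B <- 20
run_pipeline(cfg, "run1")
```

The run directory then contains the panel, person-year records, model
coefficients (JSON), point and replicate rate tables, the calibration
result, the projected trajectory and flow ledger, and the burden table
with intervals, plus a manifest recording seeds, package version and
artifact checksums; identical seeds reproduce every artifact byte for
byte.

## Known limitations

* Transition rates are held constant over the projection horizon within
  each replicate; uncertainty about future improvement or deterioration is
  carried entirely by the spread of the bootstrap ensemble, not by a
  secular-trend model.
* The pseudo-data rule is a single-imputation approximation to the
  interval-censored likelihood; with biennial waves it mildly biases
  timing (it is exact for annual waves).
* Migration has no age/sex/race profile of its own.
* The under-50 block carries no health states; everyone entering the adult
  block at 50 draws from one entry distribution.
* No survey weights: estimates are person-level, not population-weighted.
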