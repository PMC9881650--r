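#' Default pipeline configuration
#'
#' The demo-scale configuration: a panel of 20,000 individuals observed over
#' 11 biennial waves (emulating a 1998-2018 survey), 50 bootstrap
#' replicates, a 2018 base year and projections to 2050 reported for 2020,
#' 2035 and 2050. Every stage's seed is explicit so a run is reproducible
#' end to end.
#'
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    seeds = list(
      panel = 101L, demographics = 102L, expansion = 103L, bootstrap = 104L
    ),
    panel = list(
      n_individuals = 20000L, n_waves = 11L, wave_spacing_years = 2L,
      base_year = 1998L, attrition = 0.03
    ),
    estimation = list(B = 50L, allow_recovery = FALSE),
    demographics = list(
      base_year = 2018L, horizon = 42L, total_population = 330e6,
      true_migration = 0.003
    ),
    projection = list(horizon = 32L, migration_mode = "rate"),
    calibration = list(bounds = c(-0.05, 0.05)),
    report = list(years = c(2020L, 2035L, 2050L), interval = "range")
  )
}

msp_stage_deps <- c(
  expand = "simulate-data", estimate = "expand", bootstrap = "estimate",
  calibrate = "estimate", project = "calibrate", report = "project"
)

msp_require_artifact <- function(out_dir, file, stage, upstream) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop(sprintf(
      "stage '%s' needs artifact '%s'; run stage '%s' first",
      stage, file, upstream
    ), call. = FALSE)
  }
  path
}

#' Run the projection pipeline
#'
#' Orchestrates the stages `simulate-data`, `expand`, `estimate`,
#' `bootstrap`, `calibrate`, `project` and `report` (or `all`), reading and
#' writing plain-text artifacts under `out_dir` and recording seeds,
#' package version and artifact hashes in `manifest.json`. Each stage only
#' needs the artifacts of its upstream stage, so a run can be resumed or
#' re-entered stage by stage.
#'
#' @param config Configuration list ([default_run_config()] or
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = "all") {
  all_stages <- c(
    "simulate-data", "expand", "estimate", "bootstrap", "calibrate",
    "project", "report"
  )
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  if ("simulate-data" %in% stages) {
    tp <- truth_params(
      n_individuals = config$panel$n_individuals,
      n_waves = config$panel$n_waves,
      wave_spacing_years = config$panel$wave_spacing_years,
      base_year = config$panel$base_year,
      attrition = config$panel$attrition
    )
    panel <- generate_panel(tp, config$seeds$panel)
    dem <- generate_demographics(
      tp,
      true_migration = config$demographics$true_migration,
      seed = config$seeds$demographics,
      base_year = config$demographics$base_year,
      horizon = config$demographics$horizon,
      total_population = config$demographics$total_population
    )
    write_truth_params_yaml(tp, pth("truth_params.yaml"))
    write_panel_csv(panel, pth("panel.csv"))
    write_population_csv(dem$baseline, pth("baseline_population.csv"))
    readr::write_csv(dem$fertility, pth("fertility.csv"))
    readr::write_csv(dem$under50_mortality, pth("under50_mortality.csv"))
    readr::write_csv(dem$observed_totals, pth("observed_totals.csv"))
    yaml::write_yaml(
      list(
        base_year = dem$base_year,
        sex_ratio_at_birth = dem$sex_ratio_at_birth,
        entry_state_distribution = as.list(dem$entry_state_distribution),
        true_migration = dem$true_migration
      ),
      pth("demographics.yaml")
    )
  }

  read_dem <- function(stage) {
    msp_require_artifact(out_dir, "demographics.yaml", stage, "simulate-data")
    meta <- yaml::read_yaml(pth("demographics.yaml"))
    structure(
      list(
        base_year = meta$base_year,
        baseline = read_population_csv(msp_require_artifact(
          out_dir, "baseline_population.csv", stage, "simulate-data"
        )),
        fertility = readr::read_csv(pth("fertility.csv"), show_col_types = FALSE),
        under50_mortality = readr::read_csv(
          pth("under50_mortality.csv"), show_col_types = FALSE
        ),
        sex_ratio_at_birth = meta$sex_ratio_at_birth,
        entry_state_distribution = unlist(meta$entry_state_distribution),
        observed_totals = readr::read_csv(
          pth("observed_totals.csv"), show_col_types = FALSE
        ),
        true_migration = meta$true_migration
      ),
      class = "msp_demographics"
    )
  }

  if ("expand" %in% stages) {
    panel <- read_panel_csv(
      msp_require_artifact(out_dir, "panel.csv", "expand", "simulate-data")
    )
    rec <- expand_panel(panel, config$seeds$expansion,
      allow_recovery = config$estimation$allow_recovery
    )
    write_person_years_csv(rec, pth("person_years.csv"))
  }

  if ("estimate" %in% stages) {
    rec <- read_person_years_csv(
      msp_require_artifact(out_dir, "person_years.csv", "estimate", "expand")
    )
    model <- fit_transition_model(
      rec,
      destinations = default_destinations(config$estimation$allow_recovery)
    )
    write_model_json(model, pth("model.json"))
    write_rates_csv(predict_rates(model), pth("rates.csv"))
  }

  if ("bootstrap" %in% stages) {
    panel <- read_panel_csv(
      msp_require_artifact(out_dir, "panel.csv", "bootstrap", "simulate-data")
    )
    ens <- bootstrap_rates(
      panel, config$estimation$B, config$seeds$bootstrap,
      destinations = default_destinations(config$estimation$allow_recovery),
      allow_recovery = config$estimation$allow_recovery
    )
    write_rates_csv(ens$rates, pth("bootstrap_rates.csv"))
  }

  if ("calibrate" %in% stages) {
    rates <- read_rates_csv(
      msp_require_artifact(out_dir, "rates.csv", "calibrate", "estimate")
    )
    dem <- read_dem("calibrate")
    cal <- calibrate_net_migration(
      dem$baseline, rates, dem, dem$observed_totals,
      bounds = unlist(config$calibration$bounds),
      mode = config$projection$migration_mode
    )
    jsonlite::write_json(as.list(cal), pth("calibration.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  if ("project" %in% stages) {
    rates <- read_rates_csv(
      msp_require_artifact(out_dir, "rates.csv", "project", "estimate")
    )
    dem <- read_dem("project")
    cal <- jsonlite::read_json(msp_require_artifact(
      out_dir, "calibration.json", "project", "calibrate"
    ))
    proj <- project_population(
      dem$baseline, rates, dem,
      net_migration = cal$net_migration,
      horizon = config$projection$horizon,
      mode = config$projection$migration_mode
    )
    write_population_csv(proj$trajectory, pth("trajectory.csv"))
    readr::write_csv(proj$flows, pth("flows.csv"))
  }

  if ("report" %in% stages) {
    traj <- read_population_csv(
      msp_require_artifact(out_dir, "trajectory.csv", "report", "project")
    )
    years <- config$report$years
    point <- aggregate_burden(traj, years)
    boot_path <- pth("bootstrap_rates.csv")
    if (file.exists(boot_path)) {
      dem <- read_dem("report")
      cal <- jsonlite::read_json(msp_require_artifact(
        out_dir, "calibration.json", "report", "calibrate"
      ))
      reps <- read_rates_csv(boot_path)
      rep_burden <- reps |>
        dplyr::group_by(.data$replicate) |>
        dplyr::group_map(function(rt, key) {
          pr <- project_population(
            dem$baseline, rt, dem,
            net_migration = cal$net_migration,
            horizon = config$projection$horizon,
            mode = config$projection$migration_mode
          )
          dplyr::mutate(aggregate_burden(pr, years), replicate = key$replicate)
        }) |>
        dplyr::bind_rows()
      burden <- summarize_ensemble(point, rep_burden,
        rule = config$report$interval
      )
      readr::write_csv(
        dplyr::mutate(rep_burden, dplyr::across(c("group", "band"), as.character)),
        pth("burden_replicates.csv")
      )
    } else {
      burden <- point
    }
    readr::write_csv(
      dplyr::mutate(burden, dplyr::across(c("group", "band"), as.character)),
      pth("burden.csv")
    )
    writeLines(
      utils::capture.output(render_burden_table(burden)),
      pth("burden.txt")
    )
  }

  artifacts <- list.files(out_dir, full.names = TRUE)
  artifacts <- artifacts[!grepl("manifest\\.json$", artifacts)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mspop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    seeds = config$seeds,
    config = config,
    artifact_md5 = as.list(setNames(
      unname(tools::md5sum(artifacts)), basename(artifacts)
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
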