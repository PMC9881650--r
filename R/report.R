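#' Default reporting age bands
#'
#' The bands used throughout the burden tables: 50-59, 60-79, and the open
#' 80-and-older band.
#' @return Named list of `c(low, high)` integer pairs (high = 100 means the
#'   open 100+ bin inclusive).
#' @export
default_bands <- function() {
  list("50-59" = c(50L, 59L), "60-79" = c(60L, 79L), "80+" = c(80L, 100L))
}

#' Aggregate a projection into an age-band burden table
#'
#' Sums adult stocks into the reporting layout: one row per population group
#' (`total` = all adults 50+, `ge1cc` = at least one chronic condition, i.e.
#' one-condition plus multimorbidity, `multimorbidity`) and age band,
#' including an `all` band covering 50-100+, for each report year and
#' optional stratifier.
#'
#' @param x An `msp_projection` or a long trajectory tibble.
#' @param report_years Calendar years to report.
#' @param bands Named list of inclusive age bands, as [default_bands()].
#' @param by Optional extra grouping columns, e.g. `"race"`, `"sex"`.
#' @return Tibble with columns `group`, `band`, any `by` columns, `year`,
#'   `value` (persons).
#' @export
aggregate_burden <- function(x, report_years = c(2020L, 2035L, 2050L),
                             bands = default_bands(), by = NULL) {
  traj <- if (inherits(x, "msp_projection")) x$trajectory else x
  missing_years <- setdiff(report_years, unique(traj$year))
  if (length(missing_years)) {
    stop(sprintf(
      "report year(s) %s outside the trajectory",
      paste(missing_years, collapse = ", ")
    ), call. = FALSE)
  }
  for (b in bands) {
    if (b[1] < 50 || b[2] > 100) stop("bands must lie within 50..100+", call. = FALSE)
  }
  adult <- traj |>
    dplyr::filter(
      .data$year %in% report_years,
      as.character(.data$state) %in% living_states()
    )
  bands <- c(bands, list(all = c(50L, 100L)))
  per_band <- purrr::imap(bands, function(rng, label) {
    adult |>
      dplyr::filter(.data$age >= rng[1], .data$age <= rng[2]) |>
      dplyr::mutate(band = label)
  }) |> dplyr::bind_rows()
  groups <- list(
    total = living_states(),
    ge1cc = c("ONE_CC", "MULTI"),
    multimorbidity = "MULTI"
  )
  out <- purrr::imap(groups, function(states, g) {
    per_band |>
      dplyr::filter(as.character(.data$state) %in% states) |>
      dplyr::summarise(
        value = sum(.data$count),
        .by = dplyr::all_of(c("band", by, "year"))
      ) |>
      dplyr::mutate(group = g, .before = 1)
  }) |> dplyr::bind_rows()
  out |>
    dplyr::mutate(
      group = factor(.data$group, names(groups)),
      band = factor(.data$band, names(bands))
    ) |>
    dplyr::arrange(.data$group, .data$band, .data$year)
}

#' Relative change between two reported values
#'
#' @param v0,v1 Baseline and comparison values; `v0` must be positive.
#' @return Percent change `100 * (v1 - v0) / v0` (vectorised).
#' @examples
#' relative_change(137.25, 221.13)
#' @export
relative_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("baseline value must be positive", call. = FALSE)
  100 * (v1 - v0) / v0
}

#' Prevalence of chronic-disease groups in the total population
#'
#' Denominates the adult burden groups by the *total* population of all
#' ages (including the under-50 block), which is the convention used for
#' the prevalence rows of the burden tables.
#'
#' @inheritParams aggregate_burden
#' @param groups Burden groups to report.
#' @return Tibble `group`, `year`, `prevalence_pct`.
#' @export
prevalence <- function(x, report_years = c(2020L, 2035L, 2050L),
                       groups = c("ge1cc", "multimorbidity")) {
  traj <- if (inherits(x, "msp_projection")) x$trajectory else x
  burden <- aggregate_burden(traj, report_years)
  denom <- traj |>
    dplyr::filter(.data$year %in% report_years) |>
    dplyr::summarise(total = sum(.data$count), .by = "year")
  burden |>
    dplyr::filter(.data$group %in% groups, .data$band == "all") |>
    dplyr::left_join(denom, by = "year") |>
    dplyr::transmute(
      group = .data$group, year = .data$year,
      prevalence_pct = 100 * .data$value / .data$total
    )
}

#' Sex composition of the burden groups
#'
#' @inheritParams aggregate_burden
#' @param groups Burden groups to report.
#' @return Tibble `group`, `year`, `sex`, `pct`; female and male shares sum
#'   to 100 for each group-year.
#' @export
sex_fractions <- function(x, report_years = c(2020L, 2035L, 2050L),
                          groups = c("ge1cc", "multimorbidity")) {
  burden <- aggregate_burden(x, report_years, by = "sex")
  tot <- burden |>
    dplyr::filter(.data$band == "all", .data$group %in% groups) |>
    dplyr::summarise(denom = sum(.data$value), .by = c("group", "year"))
  if (any(tot$denom <= 0)) stop("zero group total; fractions undefined", call. = FALSE)
  burden |>
    dplyr::filter(.data$band == "all", .data$group %in% groups) |>
    dplyr::left_join(tot, by = c("group", "year")) |>
    dplyr::transmute(
      group = .data$group, year = .data$year, sex = .data$sex,
      pct = 100 * .data$value / .data$denom
    ) |>
    dplyr::arrange(.data$group, .data$year, .data$sex)
}

#' Summarise a replicate ensemble into interval cells
#'
#' Attaches uncertainty intervals to every cell of a point burden table.
#' The default rule is the full ensemble range (min-max over replicates, a
#' "100% interval"); `rule = "percentile"` uses symmetric percentile bounds
#' at `level`.
#'
#' @param point Burden tibble from [aggregate_burden()] run under the
#'   point-estimate rates.
#' @param replicates Burden tibble carrying a `replicate` column (or a list
#'   of burden tibbles, one per replicate).
#' @param rule `"range"` or `"percentile"`.
#' @param level Coverage for the percentile rule.
#' @return `point` with `lower` and `upper` columns; `lower <= upper` always
#'   holds, and the point value is reported as produced by the point run
#'   (it is not forced inside the replicate range).
#' @export
summarize_ensemble <- function(point, replicates, rule = c("range", "percentile"),
                               level = 0.95) {
  rule <- match.arg(rule)
  if (is.list(replicates) && !is.data.frame(replicates)) {
    replicates <- dplyr::bind_rows(replicates, .id = "replicate")
  }
  if (nrow(replicates) == 0) stop("empty replicate ensemble", call. = FALSE)
  keys <- setdiff(
    intersect(names(point), names(replicates)), c("value", "replicate")
  )
  bounds <- replicates |>
    dplyr::summarise(
      lower = if (rule == "range") min(.data$value) else
        unname(stats::quantile(.data$value, (1 - level) / 2, type = 7)),
      upper = if (rule == "range") max(.data$value) else
        unname(stats::quantile(.data$value, 1 - (1 - level) / 2, type = 7)),
      .by = dplyr::all_of(keys)
    )
  dplyr::left_join(point, bounds, by = keys)
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero (the convention
#' used when printing burden tables), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round half away from zero to significant figures
#'
#' @param x Numeric vector (non-zero entries).
#' @param digits Significant figures (burden tables print 5).
#' @return Rounded vector.
#' @export
signif_half_up <- function(x, digits = 5) {
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(out[nz])))
  out[nz] <- round_half_up(out[nz], digits - 1 - mag)
  out
}

#' Render a burden table as text
#'
#' Prints values in millions to five significant figures with min-max
#' intervals in brackets, one block per group, mirroring the layout of a
#' published projection table.
#'
#' @param burden Burden tibble with optional `lower`/`upper` columns.
#' @param scale Divisor applied before printing (1e6 = persons to millions).
#' @return Character vector of lines, invisibly also printed.
#' @export
render_burden_table <- function(burden, scale = 1e6) {
  fmt <- function(v) format(signif_half_up(v / scale, 5), trim = TRUE)
  has_int <- all(c("lower", "upper") %in% names(burden))
  lines <- character()
  for (g in levels(factor(burden$group))) {
    lines <- c(lines, sprintf("== %s ==", g))
    sub <- burden[burden$group == g, ]
    for (b in unique(as.character(sub$band))) {
      row <- sub[as.character(sub$band) == b, ]
      cells <- vapply(seq_len(nrow(row)), function(i) {
        if (has_int) {
          sprintf(
            "%d: %s [%s-%s]", row$year[i], fmt(row$value[i]),
            fmt(row$lower[i]), fmt(row$upper[i])
          )
        } else {
          sprintf("%d: %s", row$year[i], fmt(row$value[i]))
        }
      }, character(1))
      lines <- c(lines, sprintf("  %-6s %s", b, paste(cells, collapse = "  ")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
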