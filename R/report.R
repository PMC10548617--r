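write_table <- function(df, stem, out_dir, formats) {
  paths <- character(0)
  if ("csv" %in% formats) {
    p <- file.path(out_dir, paste0(stem, ".csv"))
    readr::write_csv(df, p)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, paste0(stem, ".json"))
    jsonlite::write_json(df, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("md" %in% formats) {
    p <- file.path(out_dir, paste0(stem, ".md"))
    writeLines(render_md_table(df), p)
    paths <- c(paths, p)
  }
  paths
}

grid_to_wide <- function(grid) {
  row_axis <- attr(grid, "row_axis")
  col_axis <- attr(grid, "col_axis")
  value_col <- attr(grid, "value_col")
  grid |>
    dplyr::select(dplyr::all_of(c(row_axis, col_axis, value_col))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(col_axis),
                       values_from = dplyr::all_of(value_col))
}

profile_echo <- function(profile) {
  cost <- profile$cost
  life <- profile$life
  tibble(
    parameter = c("ems_fee", "ems_fee_low", "ems_fee_high", "ed_visit_cost",
                  "physician_fee_base", "physician_fee", "naloxone_cost",
                  "hospitalization_cost", "hospitalization_cost_low",
                  "hospitalization_cost_high", "hospitalization_prob",
                  "community_response_cost",
                  paste0("operating_cost[", names(cost$operating_cost_by_period), "]"),
                  "annual_income", "employment_rate", "median_age_at_death",
                  "retirement_age", "value_of_one_life",
                  "pn", "pi", "pn_low", "pn_high"),
    value = c(cost$ems_fee, cost$ems_fee_range, cost$ed_visit_cost,
              cost$physician_fee_base, cost$physician_fee, cost$naloxone_cost,
              cost$hospitalization_cost, cost$hospitalization_cost_range,
              cost$hospitalization_prob, cost$community_response_cost,
              unname(cost$operating_cost_by_period),
              life$annual_income, life$employment_rate,
              life$median_age_at_death, life$retirement_age,
              value_of_one_life(life),
              profile$mortality$pn, profile$mortality$pi,
              profile$mortality$pn_range)
  )
}

#' Run the full cost-benefit pipeline and write the report bundle
#'
#' Executes every stage of the analysis on a call log and writes the six
#' report tables plus a JSON summary to `out_dir`: the parameter echo, the
#' per-period service tally, the life-years table (deaths prevented, value,
#' life-years, cost per life-year), the main cost-benefit table with ranges,
#' the deaths-averted scaling grid, and the two-way operating-cost x
#' mortality sensitivity grid. Re-running with the same inputs and seed
#' produces byte-identical files.
#'
#' @param log A call-log data frame, a path to a call-log CSV, `"fixture"`
#'   for the bundled reference log ([nors_fixture()]), or `"synthetic"` for
#'   a freshly generated log ([generate_call_log()] seeded with `seed`).
#' @param profile Profile name or path, or a `cba_profile` object.
#' @param out_dir Output directory (created if absent).
#' @param formats Output formats, a subset of `c("csv", "json", "md")`.
#' @param mc A [monte_carlo_spec()] for the mortality simulation; its seed
#'   is replaced by `seed` when `seed` is given.
#' @param deaths_prevented Optional per-period prevented-death counts for
#'   the life-years table (named by period, or in tally order). Defaults to
#'   the model's rounded deaths-averted estimates.
#' @param include_unknown Passed to [cost_benefit_analysis()].
#' @param seed Optional integer seed overriding the Monte Carlo spec's and
#'   the synthetic generator's seed.
#' @param periods Optional period labels passed to [tally_calls()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every computed table (`tally`, `cba`,
#'   `life_years`, `scaling_grid`, `two_way_grid`, `monte_carlo`,
#'   `summary`) and the written file paths.
#' @examples
#' \donttest{
#' out <- run_full_cba("fixture", out_dir = tempfile(), quiet = TRUE)
#' out$summary$bc_ratio
#' }
#' @export
run_full_cba <- function(log = "fixture",
                         profile = "nors2022",
                         out_dir = "cba-report",
                         formats = c("csv", "json"),
                         mc = monte_carlo_spec("uniform"),
                         deaths_prevented = NULL,
                         include_unknown = FALSE,
                         seed = NULL,
                         periods = NULL,
                         quiet = FALSE) {
  formats <- match.arg(formats, c("csv", "json", "md"), several.ok = TRUE)
  say <- function(...) if (!quiet) message(...)
  if (!inherits(profile, "cba_profile")) profile <- cba_profile(profile)
  if (!is.null(seed)) mc$seed <- as.integer(seed)

  calls <- if (is.data.frame(log)) {
    validate_call_log(log)
  } else if (identical(log, "fixture")) {
    nors_fixture()
  } else if (identical(log, "synthetic")) {
    cfg <- generator_config()
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    generate_call_log(cfg)
  } else {
    read_call_log(log)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("stage tally: ", nrow(calls), " call records")
  tally <- tally_calls(calls, periods = periods)

  say("stage benefits: cost-benefit analysis")
  cba <- cost_benefit_analysis(tally, profile, include_unknown = include_unknown)
  cba_table <- tidy(cba)

  say("stage life-years")
  vol <- cba$value_of_one_life
  py <- cba$productive_years
  dp <- deaths_prevented %||% round_half_up(cba$periods$deaths_averted, 0)
  if (!is.null(names(dp))) dp <- unname(dp[cba$periods$period])
  safe_ly <- function(d) {
    if (length(d) && all(d > 0)) life_year_summary(d, vol, py)
    else tibble(deaths_prevented = d, value_of_deaths = round_cents(d * vol),
                life_years = d * py, cost_per_life_year = NA_real_)
  }
  ly <- dplyr::bind_rows(
    safe_ly(dp) |> dplyr::mutate(period = cba$periods$period, .before = 1),
    safe_ly(sum(dp)) |> dplyr::mutate(period = "Total", .before = 1)
  )

  say("stage grids")
  scaling <- deaths_averted_grid(pn = profile$mortality$pn)
  tw <- two_way_sensitivity(
    n = cba$total$n_unique_overdoses,
    operating_cost = cba$total$operating_cost,
    medical_cost = cba$total$medical_cost,
    value_of_life = vol)

  say("stage simulate: ", mc$n_draws, " draws (seed ", mc$seed, ")")
  sim <- monte_carlo_mortality(mc, n = cba$total$n_unique_overdoses,
                               value_of_life = vol)

  summary <- list(
    profile = profile$name,
    seed = mc$seed,
    pn = profile$mortality$pn,
    pn_range = profile$mortality$pn_range,
    n_unique_overdoses = cba$total$n_unique_overdoses,
    value_of_one_life = vol,
    value_of_deaths_averted = cba$total$value_of_deaths_averted,
    operating_cost = cba$total$operating_cost,
    medical_cost = cba$total$medical_cost,
    net_benefit = cba$total$net_benefit,
    bc_ratio = round_half_up(cba$total$bc_ratio, 2),
    bc_ratio_range = round_half_up(c(cba$total$bc_low, cba$total$bc_high), 2),
    break_even_pn = cba$break_even_pn,
    mc_mean_pn = sim$summary$mean_pn,
    mc_mean_deaths_averted = sim$summary$mean_deaths_averted
  )

  paths <- c(
    write_table(profile_echo(profile), "parameters", out_dir, formats),
    write_table(tally, "tally", out_dir, formats),
    write_table(ly, "life_years", out_dir, formats),
    write_table(cba_table, "cost_benefit", out_dir, formats),
    write_table(grid_to_wide(scaling), "scaling_grid", out_dir, formats),
    write_table(grid_to_wide(tw), "two_way_grid", out_dir, formats)
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("report written to ", out_dir)

  invisible(list(tally = tally, cba = cba, cba_table = cba_table,
                 life_years = ly, scaling_grid = scaling, two_way_grid = tw,
                 monte_carlo = sim, summary = summary,
                 paths = c(paths, summary_path)))
}
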