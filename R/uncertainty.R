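#' Exact Poisson confidence interval for a mortality rate
#'
#' Garwood exact interval for a Poisson-distributed death count, divided by
#' the number of exposed individuals, giving a confidence interval for the
#' per-person death probability while using the service. The lower bound is
#' 0 when no deaths are observed; the upper bound for zero deaths is
#' `-log(alpha/2) / n_exposed`.
#'
#' @param observed_deaths Observed death count (non-negative integer).
#' @param n_exposed Number of exposed individuals (> 0).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A one-row tibble: `observed_deaths`, `n_exposed`, `level`,
#'   `low`, `high` (probabilities).
#' @examples
#' poisson_exact_ci(0, 23) # upper bound ~ 0.1604
#' @export
poisson_exact_ci <- function(observed_deaths, n_exposed, level = 0.95) {
  check_nonneg(observed_deaths, "observed_deaths")
  if (!is.numeric(n_exposed) || n_exposed <= 0) {
    stop_invalid("n_exposed", "must be positive")
  }
  if (level <= 0 || level >= 1) stop_invalid("level", "must be in (0, 1)")
  alpha <- 1 - level
  k <- observed_deaths
  low_mu <- ifelse(k == 0, 0, stats::qchisq(alpha / 2, 2 * k) / 2)
  high_mu <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  tibble(observed_deaths = k, n_exposed = n_exposed, level = level,
         low = low_mu / n_exposed, high = high_mu / n_exposed)
}

new_sensitivity_grid <- function(cells, row_axis, col_axis, value_col) {
  structure(cells,
            row_axis = row_axis, col_axis = col_axis, value_col = value_col,
            class = c("sensitivity_grid", class(cells)))
}

#' Deaths-averted scaling grid
#'
#' Projects deaths averted if the service were scaled to larger populations
#' of overdosing users, across a grid of on-service mortality rates Pi:
#' `cell(N, Pi) = round(N * (pn - Pi))` (nearest integer). The defaults
#' span 1,000-10,000 users and Pi from 0 to 0.7% in 0.1% steps.
#'
#' @param populations Population sizes N (row axis; sorted increasing).
#' @param pi_values On-service death probabilities Pi (column axis; sorted).
#' @param pn Counterfactual unwitnessed-overdose death probability.
#' @return A long tibble of class `sensitivity_grid` with columns
#'   `population`, `pi`, `deaths_averted`.
#' @examples
#' deaths_averted_grid(populations = 1000, pi_values = c(0, 0.001))
#' @export
deaths_averted_grid <- function(populations = seq(1000, 10000, by = 1000),
                                pi_values = seq(0, 0.007, by = 0.001),
                                pn = 0.45) {
  check_nonneg(populations, "populations")
  check_prob(pi_values, "pi_values")
  check_prob(pn, "pn")
  populations <- sort(unique(populations))
  pi_values <- sort(unique(pi_values))
  cells <- tidyr::expand_grid(population = populations, pi = pi_values) |>
    dplyr::mutate(deaths_averted = round_half_up(
      .data$population * (pn - .data$pi), 0))
  new_sensitivity_grid(cells, "population", "pi", "deaths_averted")
}

#' Two-way cost-by-mortality sensitivity grid
#'
#' Varies the program operating budget (as a multiplier of the current
#' budget, medical-systems cost held fixed) against the counterfactual
#' mortality rate Pn, reporting the net benefit and benefit-to-cost ratio
#' in every cell:
#' `value = n x pn x value_of_life`,
#' `net = value - (m x operating + medical)`,
#' `ratio = value / (m x operating + medical)`.
#'
#' @param n Unique overdosing service users.
#' @param operating_cost Current total operating cost, CAD.
#' @param medical_cost Total medical-systems cost, CAD (held fixed).
#' @param value_of_life Value of one life, CAD.
#' @param cost_multipliers Operating-budget multipliers (row axis); the
#'   default spans 40%-200% of the current budget.
#' @param pn_values Mortality-rate grid (column axis); the default spans
#'   the literature range 8%-80% including the 45% point estimate.
#' @param pi On-service death probability (default 0).
#' @return A long tibble of class `sensitivity_grid` with columns
#'   `cost_multiplier`, `pn`, `value`, `total_cost`, `net_benefit`,
#'   `bc_ratio`.
#' @examples
#' two_way_sensitivity(23, 1368375, 221726.18, 1320304.68,
#'                     cost_multipliers = 1, pn_values = 0.45)
#' @export
two_way_sensitivity <- function(n, operating_cost, medical_cost, value_of_life,
                                cost_multipliers = seq(0.4, 2, by = 0.2),
                                pn_values = c(0.08, seq(0.1, 0.4, by = 0.1),
                                              0.45, seq(0.5, 0.8, by = 0.1)),
                                pi = 0) {
  check_nonneg(n, "n")
  check_nonneg(operating_cost, "operating_cost")
  check_nonneg(medical_cost, "medical_cost")
  check_nonneg(value_of_life, "value_of_life")
  check_prob(pn_values, "pn_values")
  check_prob(pi, "pi")
  if (any(cost_multipliers <= 0)) {
    stop_invalid("cost_multipliers", "must be positive")
  }
  cost_multipliers <- sort(unique(cost_multipliers))
  pn_values <- sort(unique(pn_values))
  cells <- tidyr::expand_grid(cost_multiplier = cost_multipliers,
                              pn = pn_values) |>
    dplyr::mutate(
      value = round_cents(n * (.data$pn - pi) * value_of_life),
      total_cost = round_cents(.data$cost_multiplier * operating_cost) +
        medical_cost,
      net_benefit = round_cents(.data$value - .data$total_cost),
      bc_ratio = .data$value / .data$total_cost
    )
  new_sensitivity_grid(cells, "cost_multiplier", "pn", "net_benefit")
}

#' Heat-map of a sensitivity grid
#'
#' @param object A `sensitivity_grid` tibble.
#' @param ... Unused.
#' @return A ggplot tile plot of the grid's primary value.
#' @method autoplot sensitivity_grid
#' @export
autoplot.sensitivity_grid <- function(object, ...) {
  row_axis <- attr(object, "row_axis")
  col_axis <- attr(object, "col_axis")
  value_col <- attr(object, "value_col")
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data[[col_axis]]), y = factor(.data[[row_axis]]),
    fill = .data[[value_col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = col_axis, y = row_axis, fill = value_col) +
    ggplot2::theme_minimal()
}

#' Monte Carlo simulation specification
#'
#' Describes the sampling distribution of Pn (the unwitnessed-overdose
#' death probability) for [monte_carlo_mortality()]: `"uniform"` or
#' `"triangular"` over `(low, high)` (the default spans the literature
#' range 0.08-0.80), or `"fixed"` at `low`. The seed makes every summary
#' reproducible.
#'
#' @param distribution One of `"uniform"`, `"triangular"`, `"fixed"`.
#' @param low,high Distribution support within `[0, 1]`; for `"fixed"`,
#'   `high` defaults to `low`.
#' @param mode Mode for the triangular distribution (defaults to the
#'   midpoint).
#' @param n_draws Number of Monte Carlo draws (default 100,000).
#' @param seed Integer RNG seed.
#' @return A list of class `mc_spec`.
#' @export
monte_carlo_spec <- function(distribution = c("uniform", "triangular", "fixed"),
                             low = 0.08, high = NULL, mode = NULL,
                             n_draws = 100000L, seed = 1L) {
  distribution <- match.arg(distribution)
  high <- high %||% if (distribution == "fixed") low else 0.80
  check_prob(low, "low")
  check_prob(high, "high")
  if (low > high) stop_invalid("low", "must not exceed high")
  if (distribution == "triangular") {
    mode <- mode %||% ((low + high) / 2)
    if (mode < low || mode > high) {
      stop_invalid("mode", "must lie within [low, high]")
    }
  }
  if (n_draws < 1) stop_invalid("n_draws", "must be at least 1")
  structure(list(distribution = distribution, low = low, high = high,
                 mode = mode, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "mc_spec")
}

# inverse-CDF triangular sampler
rtriangular <- function(n, low, high, mode) {
  u <- stats::runif(n)
  fc <- if (high > low) (mode - low) / (high - low) else 0
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Monte Carlo over the unwitnessed-overdose mortality rate
#'
#' Draws Pn from the specified distribution and summarises the induced
#' distribution of deaths averted (`n x Pn`) and, if a value of life is
#' supplied, of the value of deaths averted. Deterministic given the
#' specification's seed and number of draws.
#'
#' @param spec A [monte_carlo_spec()].
#' @param n Number of overdosing service users exposed to the
#'   counterfactual.
#' @param value_of_life Optional value of one life, CAD.
#' @return An object of class `mc_mortality` holding the draws, the
#'   simulation specification
#'   and a one-row `summary` tibble (means and central 95% intervals of Pn
#'   and deaths averted, plus value columns when `value_of_life` is given).
#'   `tidy()` returns the summary.
#' @examples
#' monte_carlo_mortality(monte_carlo_spec("fixed", low = 0.45), n = 66)
#' @export
monte_carlo_mortality <- function(spec, n, value_of_life = NULL) {
  stopifnot(inherits(spec, "mc_spec"))
  check_nonneg(n, "n")
  draws <- withr::with_seed(spec$seed, switch(
    spec$distribution,
    uniform = stats::runif(spec$n_draws, spec$low, spec$high),
    triangular = rtriangular(spec$n_draws, spec$low, spec$high, spec$mode),
    fixed = rep(spec$low, spec$n_draws)
  ))
  deaths <- n * draws
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  summary <- tibble(
    n = n,
    mean_pn = mean(draws),
    pn_low = q(draws, 0.025), pn_high = q(draws, 0.975),
    mean_deaths_averted = mean(deaths),
    deaths_low = q(deaths, 0.025), deaths_high = q(deaths, 0.975)
  )
  if (!is.null(value_of_life)) {
    summary$mean_value <- round_cents(mean(deaths) * value_of_life)
    summary$value_low <- round_cents(q(deaths, 0.025) * value_of_life)
    summary$value_high <- round_cents(q(deaths, 0.975) * value_of_life)
  }
  structure(list(draws = draws, summary = summary, spec = spec, n = n,
                 value_of_life = value_of_life),
            class = "mc_mortality")
}

#' @export
print.mc_mortality <- function(x, ...) {
  s <- x$summary
  cat("Monte Carlo mortality simulation (", x$spec$distribution,
      ", ", x$spec$n_draws, " draws, seed ", x$spec$seed, ")\n", sep = "")
  cat(sprintf("  Pn: mean %.4f (95%% interval %.4f-%.4f)\n",
              s$mean_pn, s$pn_low, s$pn_high))
  cat(sprintf("  Deaths averted among N = %s: mean %.1f (%.1f-%.1f)\n",
              format(x$n), s$mean_deaths_averted, s$deaths_low, s$deaths_high))
  if (!is.null(x$value_of_life)) {
    cat("  Value of deaths averted: ", fmt_cad(s$mean_value), " (",
        fmt_cad(s$value_low), " - ", fmt_cad(s$value_high), ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname monte_carlo_mortality
#' @param x An `mc_mortality` object.
#' @param ... Unused.
#' @method tidy mc_mortality
#' @export
tidy.mc_mortality <- function(x, ...) x$summary

#' @rdname monte_carlo_mortality
#' @param object An `mc_mortality` object.
#' @method autoplot mc_mortality
#' @export
autoplot.mc_mortality <- function(object, ...) {
  ggplot2::ggplot(tibble(pn = object$draws), ggplot2::aes(x = .data$pn)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$mean_pn,
                        linetype = "dashed") +
    ggplot2::labs(x = "Pn (death probability, unwitnessed overdose)",
                  y = "draws") +
    ggplot2::theme_minimal()
}

#' Break-even mortality rate
#'
#' The unwitnessed-overdose death probability at which the value of deaths
#' averted exactly offsets total program cost (benefit-to-cost ratio 1):
#' `total_cost / (n x value_of_life)`.
#'
#' @param total_cost Total program cost (operating + medical), CAD.
#' @param n Unique overdosing service users.
#' @param value_of_life Value of one life, CAD.
#' @return The break-even Pn.
#' @examples
#' break_even_mortality(1590101.18, 23, 1320304.68) # ~0.0524
#' @export
break_even_mortality <- function(total_cost, n, value_of_life) {
  check_nonneg(total_cost, "total_cost")
  if (n * value_of_life <= 0) {
    stop_invalid("n", "n x value_of_life must be positive")
  }
  total_cost / (n * value_of_life)
}
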