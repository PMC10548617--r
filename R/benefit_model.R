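#' Remaining productive years of life
#'
#' Years of productive life lost when death occurs at the median age of
#' drug-toxicity death: retirement age minus median age at death.
#'
#' @param life A [life_value_parameters()] object.
#' @return Productive years (e.g. 64.8 - 38 = 26.8 under the default profile).
#' @export
productive_years <- function(life) {
  stopifnot(inherits(life, "life_value_params"))
  py <- life$retirement_age - life$median_age_at_death
  if (py <= 0) stop_invalid("retirement_age", "must exceed median_age_at_death")
  py
}

#' Human-capital value of one prevented death
#'
#' Values one life lost to overdose as the lost productivity to society:
#' annual income x employment rate x remaining productive years, rounded
#' half-up to cents. No discounting of future earnings is applied.
#'
#' @param life A [life_value_parameters()] object.
#' @return Value of one life, CAD.
#' @examples
#' value_of_one_life(life_value_parameters()) # 1320304.68
#' @export
value_of_one_life <- function(life) {
  stopifnot(inherits(life, "life_value_params"))
  round_cents(life$annual_income * life$employment_rate * productive_years(life))
}

#' Deaths averted by the service
#'
#' The counterfactual number of deaths averted among `n` unique overdosing
#' service users: `Np = n * (Pn - Pi)`, where Pn is the probability of death
#' following an unwitnessed overdose and Pi the probability of death while
#' using the service. Returned unrounded; a negative value (Pi > Pn) is
#' permitted but flagged with a warning, since it describes a harmful
#' scenario.
#'
#' @param n Number of unique individuals who overdosed while using the
#'   service.
#' @param mortality A [mortality_assumption()] object, or a numeric Pn.
#' @param pi Probability of death while using the service; only used when
#'   `mortality` is numeric.
#' @return Expected deaths averted (real, unrounded).
#' @examples
#' deaths_averted(23, 0.45) # 10.35
#' @export
deaths_averted <- function(n, mortality, pi = 0) {
  check_nonneg(n, "n")
  if (is.numeric(mortality)) {
    check_prob(mortality, "pn")
    check_prob(pi, "pi")
    pn <- mortality
  } else {
    stopifnot(inherits(mortality, "mortality_assumption"))
    pn <- mortality$pn
    pi <- mortality$pi
  }
  np <- n * (pn - pi)
  if (any(np < 0)) {
    warn("Negative deaths averted: Pi exceeds Pn (harmful-scenario flag)")
  }
  np
}

#' Economic value of deaths averted
#'
#' `n x pn x value_of_life`, rounded half-up to cents. In the base case the
#' on-service death probability is zero, so the full counterfactual
#' mortality converts to averted deaths.
#'
#' @param n Unique overdosing service users.
#' @param pn Probability of death from an unwitnessed overdose (net of any
#'   on-service mortality already subtracted by the caller).
#' @param value_of_life Value of one life, CAD (see [value_of_one_life()]).
#' @return Value of deaths averted, CAD.
#' @examples
#' value_of_deaths_averted(13, 0.45, 1320304.68) # 7723782.38
#' @export
value_of_deaths_averted <- function(n, pn, value_of_life) {
  check_nonneg(n, "n")
  check_prob(pn, "pn")
  check_nonneg(value_of_life, "value_of_life")
  round_cents(n * pn * value_of_life)
}

#' Net benefit of the program
#'
#' Total cost-benefit: value of deaths averted minus operating cost minus
#' medical-systems cost.
#'
#' @param value Value of deaths averted, CAD.
#' @param operating Program operating cost, CAD.
#' @param medical Medical-systems cost (TMSc), CAD.
#' @return Net benefit, CAD.
#' @export
net_benefit <- function(value, operating, medical) {
  check_nonneg(operating, "operating")
  check_nonneg(medical, "medical")
  round_cents(value - operating - medical)
}

#' Benefit-to-cost ratio
#'
#' Value of deaths averted per dollar of total program cost; the
#' denominator is operating plus medical cost. Returned unrounded (tables
#' display it to 2 decimals).
#'
#' @inheritParams net_benefit
#' @return Dimensionless ratio.
#' @export
benefit_cost_ratio <- function(value, operating, medical) {
  check_nonneg(operating, "operating")
  check_nonneg(medical, "medical")
  total <- operating + medical
  if (any(total <= 0)) {
    abort("Benefit-to-cost ratio is undefined: total cost is zero",
          class = "vomscba_undefined_ratio")
  }
  value / total
}

# pipeline-internal ratio: NA (not an error) when total cost is zero, so
# degenerate inputs (empty logs) flow through with the ratio flagged
ratio_or_na <- function(value, operating, medical) {
  total <- operating + medical
  out <- ifelse(total > 0, value / total, NA_real_)
  if (anyNA(out)) {
    warn("Benefit-to-cost ratio undefined (zero total cost); reported as NA")
  }
  out
}

#' Life-years saved and cost per life-year
#'
#' Converts a count of prevented deaths to life-years saved
#' (`deaths x productive_years`) and the cost per life-year implied by the
#' human-capital valuation (`deaths x value_of_life / life_years`, which
#' reduces to `value_of_life / productive_years` and is therefore
#' independent of the death count).
#'
#' @param deaths_prevented Number of prevented deaths (> 0).
#' @param value_of_life Value of one life, CAD.
#' @param py Remaining productive years per death.
#' @return A one-row tibble: `deaths_prevented`, `value_of_deaths`
#'   (CAD), `life_years`, `cost_per_life_year` (CAD).
#' @examples
#' life_year_summary(7, 1320304.68, 26.8)
#' @export
life_year_summary <- function(deaths_prevented, value_of_life, py) {
  check_nonneg(deaths_prevented, "deaths_prevented")
  check_nonneg(value_of_life, "value_of_life")
  if (py <= 0) stop_invalid("py", "must be positive")
  if (any(deaths_prevented == 0)) {
    abort("Cost per life-year is undefined for zero prevented deaths",
          class = "vomscba_undefined_ratio")
  }
  life_years <- deaths_prevented * py
  tibble(
    deaths_prevented = deaths_prevented,
    value_of_deaths = round_cents(deaths_prevented * value_of_life),
    life_years = life_years,
    cost_per_life_year = round_cents(deaths_prevented * value_of_life / life_years)
  )
}

#' Full cost-benefit analysis of a service tally
#'
#' Runs the complete per-period cost-benefit analysis: values deaths
#' averted among unique overdosing callers at the human-capital value of
#' one life, subtracts operating and medical-systems costs, and reports net
#' benefit and benefit-to-cost ratios at the point mortality estimate and
#' across the reporting range of Pn. A `Total` row aggregates the periods
#' (value and costs sum; the ratio is recomputed from the sums).
#'
#' @param tally A per-period tally from [tally_calls()]; every period must
#'   have an operating cost in the profile.
#' @param profile A [cba_profile()] parameter profile.
#' @param include_unknown Count overdoses from unidentified callers in N
#'   (default `FALSE`: only callers with a recorded identifier are counted,
#'   the conservative choice since unknown callers cannot be deduplicated).
#' @return An object of class `vomscba`: a list with `periods` (per-period
#'   tibble), `total` (one-row tibble), `break_even_pn`, and the inputs.
#'   Use [tidy()][generics::tidy] for the period-level table,
#'   [glance()][generics::glance] for the one-row headline summary, and
#'   `autoplot()` for a picture.
#' @examples
#' cba <- nors_fixture() |> tally_calls() |> cost_benefit_analysis()
#' glance(cba)
#' @export
cost_benefit_analysis <- function(tally, profile = cba_profile("nors2022"),
                                  include_unknown = FALSE) {
  stopifnot(inherits(profile, "cba_profile"))
  vol <- value_of_one_life(profile$life)
  py <- productive_years(profile$life)
  m <- profile$mortality
  op <- profile$cost$operating_cost_by_period
  missing_op <- setdiff(tally$period, names(op))
  if (length(missing_op)) {
    stop_invalid("operating_cost_by_period",
                 paste0("no operating cost for period(s): ",
                        paste(missing_op, collapse = ", ")))
  }

  costs <- medical_services_cost(tally, profile$cost)
  n <- tally$n_overdoses_unique +
    if (include_unknown) tally$n_overdoses_unknown else 0L

  value_at <- function(pn) round_cents(n * (pn - m$pi) * vol)
  periods <- tibble(
    period = tally$period,
    n_unique_overdoses = n,
    deaths_averted = n * (m$pn - m$pi),
    value_of_deaths_averted = value_at(m$pn),
    value_low = value_at(m$pn_range[1]),
    value_high = value_at(m$pn_range[2]),
    operating_cost = costs$operating_cost,
    medical_cost = costs$medical_cost
  ) |>
    dplyr::mutate(
      net_benefit = net_benefit(.data$value_of_deaths_averted,
                                .data$operating_cost, .data$medical_cost),
      net_low = net_benefit(.data$value_low, .data$operating_cost,
                            .data$medical_cost),
      net_high = net_benefit(.data$value_high, .data$operating_cost,
                             .data$medical_cost),
      bc_ratio = ratio_or_na(.data$value_of_deaths_averted,
                             .data$operating_cost, .data$medical_cost),
      bc_low = ratio_or_na(.data$value_low, .data$operating_cost,
                           .data$medical_cost),
      bc_high = ratio_or_na(.data$value_high, .data$operating_cost,
                            .data$medical_cost),
      life_years = .data$deaths_averted * py,
      cost_per_life_year = round_cents(vol / py)
    )

  sum_cols <- c("n_unique_overdoses", "deaths_averted",
                "value_of_deaths_averted", "value_low", "value_high",
                "operating_cost", "medical_cost", "net_benefit",
                "net_low", "net_high", "life_years")
  total <- periods |>
    dplyr::summarise(period = "Total",
                     dplyr::across(dplyr::all_of(sum_cols), sum)) |>
    dplyr::mutate(
      bc_ratio = ratio_or_na(.data$value_of_deaths_averted,
                             .data$operating_cost, .data$medical_cost),
      bc_low = ratio_or_na(.data$value_low, .data$operating_cost,
                           .data$medical_cost),
      bc_high = ratio_or_na(.data$value_high, .data$operating_cost,
                            .data$medical_cost),
      cost_per_life_year = round_cents(vol / py)
    )

  structure(
    list(periods = periods, total = total,
         break_even_pn = if (total$n_unique_overdoses > 0) {
           break_even_mortality(total$operating_cost + total$medical_cost,
                                total$n_unique_overdoses, vol)
         } else NA_real_,
         value_of_one_life = vol, productive_years = py,
         profile = profile, include_unknown = include_unknown),
    class = "vomscba"
  )
}

#' @export
print.vomscba <- function(x, ...) {
  cat("Cost-benefit analysis (", x$profile$name, " profile, Pn = ",
      x$profile$mortality$pn, ", range ", x$profile$mortality$pn_range[1],
      "-", x$profile$mortality$pn_range[2], ")\n\n", sep = "")
  rows <- dplyr::bind_rows(x$periods, x$total)
  disp <- tibble(
    Period = rows$period,
    N = rows$n_unique_overdoses,
    `Value of deaths averted` = fmt_cad(rows$value_of_deaths_averted),
    `Operating` = fmt_cad(rows$operating_cost),
    `Medical` = fmt_cad(rows$medical_cost),
    `Net benefit` = fmt_cad(rows$net_benefit),
    `B:C` = sprintf("%.2f (%.2f-%.2f)", round_half_up(rows$bc_ratio, 2),
                    round_half_up(rows$bc_low, 2), round_half_up(rows$bc_high, 2))
  )
  print(as.data.frame(disp), row.names = FALSE, right = FALSE)
  cat(sprintf("\nValue of one life: %s | break-even Pn: %.4f\n",
              fmt_cad(x$value_of_one_life), x$break_even_pn))
  invisible(x)
}

#' Tidy a cost-benefit analysis
#'
#' `tidy()` returns one row per period plus the `Total` row, with all value,
#' cost, net-benefit and ratio columns; `glance()` returns the one-row
#' headline summary (totals, ratio with range, break-even Pn).
#'
#' @param x A `vomscba` object from [cost_benefit_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy vomscba
#' @export
tidy.vomscba <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$periods, is_total = FALSE),
    dplyr::mutate(x$total, is_total = TRUE)
  )
}

#' @rdname tidy.vomscba
#' @method glance vomscba
#' @export
glance.vomscba <- function(x, ...) {
  t <- x$total
  tibble(
    n_unique_overdoses = t$n_unique_overdoses,
    deaths_averted = t$deaths_averted,
    value_of_deaths_averted = t$value_of_deaths_averted,
    operating_cost = t$operating_cost,
    medical_cost = t$medical_cost,
    net_benefit = t$net_benefit,
    bc_ratio = t$bc_ratio,
    bc_ratio_low = t$bc_low,
    bc_ratio_high = t$bc_high,
    value_of_one_life = x$value_of_one_life,
    break_even_pn = x$break_even_pn
  )
}

#' Plot a cost-benefit analysis
#'
#' Bar chart of the value of deaths averted against total program cost
#' (operating + medical) per period, with the net benefit annotated.
#'
#' @param object A `vomscba` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vomscba
#' @export
autoplot.vomscba <- function(object, ...) {
  rows <- dplyr::bind_rows(object$periods, object$total)
  long <- rows |>
    dplyr::transmute(period = factor(.data$period, levels = .data$period),
                     Benefit = .data$value_of_deaths_averted,
                     Cost = .data$operating_cost + .data$medical_cost) |>
    tidyr::pivot_longer(c("Benefit", "Cost"), names_to = "side",
                        values_to = "cad")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$cad,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) fmt_cad(v)) +
    ggplot2::labs(x = NULL, y = "2022 CAD", fill = NULL,
                  title = "Value of deaths averted vs. program cost") +
    ggplot2::theme_minimal()
}
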