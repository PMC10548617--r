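#' Medical-systems cost parameters
#'
#' Constructs the validated set of unit costs driving the medical-systems
#' cost of an overdose response: ambulance (EMS) call-out fee, emergency
#' department visit, physician assessment (stored both in source-year and
#' analysis-year dollars; the model always consumes the inflated value),
#' nasal naloxone kit, and hospitalization cost entering as an expected
#' value through the probability of admission after a non-fatal overdose.
#' Defaults are the 2022 CAD national-average reference costs for the
#' Canadian National Overdose Response Service (NORS) evaluation; see
#' [cba_profile()] for the bundled profile.
#'
#' @param ems_fee EMS call-out fee, CAD.
#' @param ems_fee_range `(low, high)` range for the EMS fee.
#' @param ed_visit_cost Emergency-department visit cost, CAD.
#' @param physician_fee_base Physician assessment fee in source-year dollars.
#' @param physician_fee Physician assessment fee in analysis-year dollars
#'   (the value the cost model uses).
#' @param naloxone_cost Cost of one intranasal naloxone kit, CAD.
#' @param hospitalization_cost Cost of one hospital admission, CAD.
#' @param hospitalization_cost_range `(low, high)` range for admission cost.
#' @param hospitalization_prob Probability of admission given a non-fatal
#'   overdose attended by EMS, in `[0, 1]`.
#' @param community_response_cost Cost of a community-based (lay responder)
#'   overdose response; defaults to one naloxone kit.
#' @param operating_cost_by_period Named numeric vector mapping period label
#'   to the program operating cost for that period, CAD.
#' @param currency_year Calendar year of the currency units.
#' @return A list of class `cost_params`.
#' @seealso [life_value_parameters()], [mortality_assumption()], [cba_profile()]
#' @export
cost_parameters <- function(ems_fee = 518,
                            ems_fee_range = c(240, 848),
                            ed_visit_cost = 1061,
                            physician_fee_base = 176,
                            physician_fee = 196.83,
                            naloxone_cost = 125,
                            hospitalization_cost = 7803,
                            hospitalization_cost_range = c(6620, 13647),
                            hospitalization_prob = 0.33,
                            community_response_cost = naloxone_cost,
                            operating_cost_by_period = c("Funded 1" = 787500,
                                                         "Funded 2" = 580875),
                            currency_year = 2022) {
  check_nonneg(ems_fee, "ems_fee")
  check_nonneg(ed_visit_cost, "ed_visit_cost")
  check_nonneg(physician_fee_base, "physician_fee_base")
  check_nonneg(physician_fee, "physician_fee")
  check_nonneg(naloxone_cost, "naloxone_cost")
  check_nonneg(hospitalization_cost, "hospitalization_cost")
  check_nonneg(community_response_cost, "community_response_cost")
  check_prob(hospitalization_prob, "hospitalization_prob")
  check_range(ems_fee_range, ems_fee, "ems_fee_range")
  check_range(hospitalization_cost_range, hospitalization_cost,
              "hospitalization_cost_range")
  check_nonneg(operating_cost_by_period, "operating_cost_by_period")
  if (length(operating_cost_by_period) > 0 &&
      is.null(names(operating_cost_by_period))) {
    stop_invalid("operating_cost_by_period", "must be named by period label")
  }
  structure(
    list(ems_fee = ems_fee,
         ems_fee_range = as.numeric(ems_fee_range),
         ed_visit_cost = ed_visit_cost,
         physician_fee_base = physician_fee_base,
         physician_fee = physician_fee,
         naloxone_cost = naloxone_cost,
         hospitalization_cost = hospitalization_cost,
         hospitalization_cost_range = as.numeric(hospitalization_cost_range),
         hospitalization_prob = hospitalization_prob,
         community_response_cost = community_response_cost,
         operating_cost_by_period = operating_cost_by_period,
         currency_year = as.integer(currency_year)),
    class = "cost_params"
  )
}

#' @export
print.cost_params <- function(x, ...) {
  cat("<cost_params> (", x$currency_year, " CAD)\n", sep = "")
  cat("  EMS call-out fee:       ", fmt_cad(x$ems_fee),
      sprintf("  (%s - %s)\n", fmt_cad(x$ems_fee_range[1]), fmt_cad(x$ems_fee_range[2])))
  cat("  ED visit:               ", fmt_cad(x$ed_visit_cost), "\n")
  cat("  Physician assessment:   ", fmt_cad(x$physician_fee),
      sprintf("  (base %s)\n", fmt_cad(x$physician_fee_base)))
  cat("  Nasal naloxone kit:     ", fmt_cad(x$naloxone_cost), "\n")
  cat("  Hospitalization:        ", fmt_cad(x$hospitalization_cost),
      sprintf("  x prob %.2f\n", x$hospitalization_prob))
  cat("  Community response:     ", fmt_cad(x$community_response_cost), "\n")
  if (length(x$operating_cost_by_period)) {
    cat("  Operating cost by period:\n")
    for (p in names(x$operating_cost_by_period)) {
      cat("    ", p, ": ", fmt_cad(x$operating_cost_by_period[[p]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Human-capital value-of-life parameters
#'
#' Parameters for valuing one prevented overdose death by lost productivity:
#' average annual income in the relevant age band, the employment rate among
#' people who use substances, the median age at death from drug toxicity,
#' and the average retirement age. The value of one life is
#' income x employment rate x (retirement age - median age at death);
#' see [value_of_one_life()].
#'
#' @param annual_income Average annual income, CAD/year.
#' @param employment_rate Proportion gainfully employed, in `[0, 1]`.
#' @param median_age_at_death Median age at death from drug poisoning, years.
#' @param retirement_age Average retirement age, years; must exceed
#'   `median_age_at_death`.
#' @return A list of class `life_value_params`.
#' @export
life_value_parameters <- function(annual_income = 73530,
                                  employment_rate = 0.67,
                                  median_age_at_death = 38,
                                  retirement_age = 64.8) {
  check_nonneg(annual_income, "annual_income")
  check_prob(employment_rate, "employment_rate")
  check_nonneg(median_age_at_death, "median_age_at_death")
  check_nonneg(retirement_age, "retirement_age")
  if (retirement_age <= median_age_at_death) {
    stop_invalid("retirement_age", "must exceed median_age_at_death")
  }
  structure(
    list(annual_income = annual_income,
         employment_rate = employment_rate,
         median_age_at_death = median_age_at_death,
         retirement_age = retirement_age),
    class = "life_value_params"
  )
}

#' @export
print.life_value_params <- function(x, ...) {
  cat("<life_value_params>\n")
  cat("  Annual income:      ", fmt_cad(x$annual_income), "/year\n", sep = "")
  cat("  Employment rate:    ", x$employment_rate, "\n", sep = "")
  cat("  Median age at death:", x$median_age_at_death, "y\n")
  cat("  Retirement age:     ", x$retirement_age, "y\n")
  cat("  Value of one life:  ", fmt_cad(value_of_one_life(x)), "\n", sep = "")
  invisible(x)
}

#' Mortality assumptions for the counterfactual
#'
#' Holds Pn, the probability of death following an unwitnessed or unattended
#' overdose (the counterfactual had the monitoring service not intervened),
#' Pi, the probability of death during an overdose while using the service,
#' and the reporting range for Pn. Deaths averted among N unique overdosing
#' service users are `N * (Pn - Pi)`.
#'
#' @param pn Probability of death from an unwitnessed overdose.
#' @param pi Probability of death while using the service (0 in the base
#'   case: no deaths occurred on the line).
#' @param pn_range `(low, high)` range of Pn used for reporting ranges.
#' @return A list of class `mortality_assumption`.
#' @export
mortality_assumption <- function(pn = 0.45, pi = 0, pn_range = c(0.08, 0.80)) {
  check_prob(pn, "pn")
  check_prob(pi, "pi")
  check_prob(pn_range, "pn_range")
  if (pn_range[1] > pn_range[2]) {
    stop_invalid("pn_range", "must be ordered (low, high)")
  }
  if (pi > pn) {
    warn("pi > pn: the service is assumed more lethal than the counterfactual; deaths averted will be negative")
  }
  structure(list(pn = pn, pi = pi, pn_range = as.numeric(pn_range)),
            class = "mortality_assumption")
}

#' Adjust a cost for inflation
#'
#' Multiplies an amount by a supplied inflation factor and rounds half-up to
#' cents. The factor is supplied by the analyst (e.g. a CPI ratio between the
#' source year and the analysis year); no price index is looked up.
#'
#' @param amount Non-negative cost, CAD.
#' @param factor Positive inflation ratio (new-year dollars per old-year dollar).
#' @return The inflated amount, rounded to cents.
#' @examples
#' adjust_for_inflation(176, 196.83 / 176) # 196.83
#' @export
adjust_for_inflation <- function(amount, factor) {
  check_nonneg(amount, "amount")
  if (!is.numeric(factor) || any(!is.finite(factor)) || any(factor <= 0)) {
    stop_invalid("factor", "must be a positive finite number")
  }
  round_cents(amount * factor)
}

#' Bundled analysis profiles
#'
#' Loads a complete, validated parameter profile (cost, value-of-life and
#' mortality parameters). The bundled `"nors2022"` profile carries the 2022
#' CAD reference costs and mortality assumptions of the NORS evaluation:
#' EMS $518, ED visit $1,061, physician $196.83 (inflated from $176),
#' naloxone $125, hospitalization $7,803 at probability 0.33, operating
#' costs $787,500 / $580,875 for the two funded periods, income $73,530,
#' employment 0.67, ages 38 and 64.8, Pn 0.45 with range 0.08-0.80, Pi 0.
#'
#' The program's reported operating total ($1,366,749) differs by $1,626
#' from the sum of the per-period budget lines ($1,368,375); all published
#' ratios derive from the per-period lines, which are therefore the default.
#' `use_reported_operating_total = TRUE` rescales the per-period costs
#' proportionally so they sum to the reported total instead.
#'
#' @param name Profile name (currently `"nors2022"`) or a path to a YAML
#'   parameter file in the same layout (see [read_parameters()]).
#' @param use_reported_operating_total Use the reported operating total
#'   rather than the per-period budget lines (default `FALSE`).
#' @return A list of class `cba_profile` with elements `cost`, `life`,
#'   `mortality`, `name`, and `reported_operating_total`.
#' @examples
#' p <- cba_profile("nors2022")
#' p$cost$ems_fee
#' @export
cba_profile <- function(name = "nors2022", use_reported_operating_total = FALSE) {
  path <- if (file.exists(name)) {
    name
  } else {
    f <- system.file("extdata", paste0(name, ".yaml"), package = "vomscba")
    if (!nzchar(f)) {
      abort(paste0("Unknown profile '", name, "' (not a bundled profile or an existing file)"),
            class = "vomscba_invalid_parameter")
    }
    f
  }
  profile <- read_parameters(path)
  if (use_reported_operating_total &&
      !is.null(profile$reported_operating_total)) {
    op <- profile$cost$operating_cost_by_period
    scale <- profile$reported_operating_total / sum(op)
    profile$cost$operating_cost_by_period <- round_cents(op * scale)
  }
  profile
}

required_keys <- function(x, keys, where) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    abort(paste0("Parameter file is missing key(s) in `", where, "`: ",
                 paste(missing, collapse = ", ")),
          class = "vomscba_invalid_parameter")
  }
}

#' Read and write parameter profiles
#'
#' Parameter profiles are YAML files with top-level maps `cost`, `life` and
#' `mortality` whose keys match the arguments of [cost_parameters()],
#' [life_value_parameters()] and [mortality_assumption()]. Every value is
#' validated on read; a missing key, a negative cost or an out-of-range
#' probability raises an error naming the offending field.
#'
#' @param path Path to a YAML parameter file.
#' @return `read_parameters()` returns a validated `cba_profile` list;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Parameter file not found: ", path), class = "vomscba_io_error")
  }
  raw <- yaml::read_yaml(path)
  required_keys(raw, c("cost", "life", "mortality"), "profile")
  required_keys(raw$cost, c("ems_fee", "ed_visit_cost", "physician_fee",
                            "naloxone_cost", "hospitalization_cost",
                            "hospitalization_prob", "operating_cost_by_period"),
                "cost")
  required_keys(raw$life, c("annual_income", "employment_rate",
                            "median_age_at_death", "retirement_age"), "life")
  required_keys(raw$mortality, c("pn", "pi"), "mortality")

  op <- unlist(raw$cost$operating_cost_by_period)
  cost_args <- raw$cost
  cost_args$operating_cost_by_period <- op
  cost <- do.call(cost_parameters, cost_args)
  life <- do.call(life_value_parameters, raw$life)
  mortality <- do.call(mortality_assumption, raw$mortality)
  structure(
    list(name = raw$name %||% basename(path),
         cost = cost, life = life, mortality = mortality,
         reported_operating_total = raw$reported_operating_total),
    class = "cba_profile"
  )
}

#' @param profile A `cba_profile` list as returned by [read_parameters()] or
#'   [cba_profile()].
#' @rdname read_parameters
#' @export
write_parameters <- function(profile, path) {
  stopifnot(inherits(profile, "cba_profile"))
  out <- list(
    name = profile$name,
    reported_operating_total = profile$reported_operating_total,
    cost = unclass(profile$cost),
    life = unclass(profile$life),
    mortality = unclass(profile$mortality)
  )
  out$cost$operating_cost_by_period <- as.list(profile$cost$operating_cost_by_period)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.cba_profile <- function(x, ...) {
  cat("<cba_profile> ", x$name, "\n\n", sep = "")
  print(x$cost)
  cat("\n")
  print(x$life)
  cat("\nMortality: Pn = ", x$mortality$pn, " (range ",
      x$mortality$pn_range[1], "-", x$mortality$pn_range[2],
      "), Pi = ", x$mortality$pi, "\n", sep = "")
  invisible(x)
}
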