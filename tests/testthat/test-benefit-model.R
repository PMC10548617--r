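test_that("productive years and value of one life follow the human-capital formula", {
  expect_equal(productive_years(nors_profile$life), 26.8)
  expect_equal(productive_years(life_value_parameters(
    median_age_at_death = 59.5, retirement_age = 60)), 0.5)
  expect_equal(value_of_one_life(nors_profile$life), 1320304.68)
  expect_equal(value_of_one_life(life_value_parameters(
    annual_income = 100000, employment_rate = 1,
    median_age_at_death = 40, retirement_age = 65)), 2500000.00)
  expect_equal(value_of_one_life(life_value_parameters(employment_rate = 0)), 0)
})

test_that("deaths averted is N * (Pn - Pi), unrounded, with harm flagged", {
  expect_equal(deaths_averted(23, 0.45), 10.35)
  expect_equal(deaths_averted(8000, 0.45, pi = 0.001), 3592, tolerance = 1e-9)
  expect_equal(round_half_up(deaths_averted(8000, 0.45, pi = 0.001), 0), 3592)
  expect_equal(deaths_averted(17, 0.3, pi = 0.3), 0)
  expect_equal(deaths_averted(23, mortality_assumption(pn = 0.45, pi = 0)), 10.35)
  expect_warning(da <- deaths_averted(10, 0.1, pi = 0.2), "harmful")
  expect_equal(da, -1)
})

test_that("value of deaths averted reproduces the published period values", {
  vol <- value_of_one_life(nors_profile$life)
  expect_equal(value_of_deaths_averted(13, 0.45, vol), 7723782.38)
  expect_equal(value_of_deaths_averted(10, 0.45, vol), 5941371.06)
  expect_equal(value_of_deaths_averted(23, 0.08, vol), 2429360.61)
  expect_equal(value_of_deaths_averted(23, 0.80, vol), 24293606.11)
  expect_equal(value_of_deaths_averted(0, 0.5, vol), 0)
})

test_that("value of deaths averted is monotone in each argument", {
  vol <- 1320304.68
  for (n in c(5, 23)) for (pn in c(0.1, 0.45)) {
    expect_lte(value_of_deaths_averted(n, pn, vol),
               value_of_deaths_averted(n + 1, pn, vol))
    expect_lte(value_of_deaths_averted(n, pn, vol),
               value_of_deaths_averted(n, pn + 0.05, vol))
    expect_lte(value_of_deaths_averted(n, pn, vol),
               value_of_deaths_averted(n, pn, vol + 100))
  }
})

test_that("net benefit and ratio reproduce the published totals", {
  expect_equal(net_benefit(7723782.38, 787500.00, 163290.52), 6772991.86)
  expect_equal(net_benefit(23 * 0.45 * 1320304.68, 1368375.00, 221726.18),
               12075052.26)
  expect_equal(net_benefit(0, 100, 25), -125)
  expect_equal(round_half_up(benefit_cost_ratio(13665153.44, 1368375.00,
                                                221726.18), 2), 8.59)
  expect_equal(round_half_up(benefit_cost_ratio(5941371.06, 580875.00,
                                                58435.66), 2), 9.29)
  expect_equal(benefit_cost_ratio(1000, 600, 400), 1.00)
  expect_error(benefit_cost_ratio(10, 0, 0), class = "vomscba_undefined_ratio")
})

test_that("ratio above one exactly when net benefit is positive", {
  cases <- expand.grid(value = c(0, 500000, 1590101.18, 2e7),
                       operating = c(100, 1368375), medical = c(0, 221726.18))
  for (i in seq_len(nrow(cases))) {
    v <- cases$value[i]; o <- cases$operating[i]; m <- cases$medical[i]
    expect_equal(benefit_cost_ratio(v, o, m) > 1, net_benefit(v, o, m) > 0)
  }
})

test_that("life-years scale with deaths but cost per life-year does not", {
  ly <- life_year_summary(7, 1320304.68, 26.8)
  expect_equal(ly$life_years, 187.6)
  expect_equal(ly$cost_per_life_year, 49265.10)
  expect_equal(ly$value_of_deaths, 9242132.76)
  # cancellation: the ratio is independent of the death count
  for (d in c(1, 7, 21, 28, 100)) {
    expect_equal(life_year_summary(d, 1320304.68, 26.8)$cost_per_life_year,
                 49265.10)
  }
  expect_equal(life_year_summary(10, 268.0, 26.8)$cost_per_life_year, 10.00)
  expect_error(life_year_summary(0, 1320304.68, 26.8),
               class = "vomscba_undefined_ratio")
})

test_that("the full analysis reproduces the published cost-benefit table", {
  cba <- nors_fixture() |> tally_calls() |> cost_benefit_analysis(nors_profile)
  p <- cba$periods
  expect_equal(p$n_unique_overdoses, c(13, 10))
  expect_equal(p$value_of_deaths_averted, c(7723782.38, 5941371.06))
  expect_equal(p$value_low, c(1373116.87, 1056243.74))
  expect_equal(p$value_high, c(13731168.67, 10562437.44))
  expect_equal(p$net_benefit, c(6772991.86, 5302060.40))
  expect_equal(p$net_low, c(422326.35, 416933.08))
  expect_equal(p$net_high, c(12780378.15, 9923126.78))
  expect_equal(round_half_up(p$bc_ratio, 2), c(8.12, 9.29))
  expect_equal(round_half_up(p$bc_low, 2), c(1.44, 1.65))
  expect_equal(round_half_up(p$bc_high, 2), c(14.44, 16.52))
  t <- cba$total
  expect_equal(t$value_of_deaths_averted, 13665153.44)
  expect_equal(t$net_benefit, 12075052.26)
  expect_equal(round_half_up(t$bc_ratio, 2), 8.59)
  expect_equal(round_half_up(c(t$bc_low, t$bc_high), 2), c(1.53, 15.28))
  # shared-denominator identity at the summary level
  g <- glance(cba)
  expect_equal(g$bc_ratio > 1, g$net_benefit > 0)
  expect_equal(g$break_even_pn, 0.05236279, tolerance = 1e-6)
  # totals are the sums of the periods (base case, shared parameters)
  expect_equal(t$value_of_deaths_averted, sum(p$value_of_deaths_averted))
  expect_equal(t$net_benefit, sum(p$net_benefit))
})

test_that("unknown overdose callers can be included in N on request", {
  tally <- tally_calls(nors_fixture())
  cba <- cost_benefit_analysis(tally, nors_profile, include_unknown = TRUE)
  expect_equal(cba$total$n_unique_overdoses, 27)
  expect_equal(cba$total$value_of_deaths_averted,
               value_of_deaths_averted(27, 0.45, 1320304.68))
})

test_that("tidy and glance expose the period table and headline summary", {
  cba <- cost_benefit_analysis(tally_calls(nors_fixture()), nors_profile)
  td <- tidy(cba)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$period, c("Funded 1", "Funded 2", "Total"))
  expect_equal(td$is_total, c(FALSE, FALSE, TRUE))
  g <- glance(cba)
  expect_equal(nrow(g), 1)
  expect_equal(g$value_of_one_life, 1320304.68)
  pl <- autoplot(cba)
  expect_s3_class(pl, "ggplot")
})
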