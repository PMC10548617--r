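# Table of published scaling-grid cells: deaths averted for N service users
# at on-service mortality Pi (columns 0-0.7%), counterfactual mortality 45%.
published_scaling_grid <- function() {
  rows <- list(
    `10000` = c(4500, 4490, 4480, 4470, 4460, 4450, 4440, 4430),
    `9000` = c(4050, 4041, 4032, 4023, 4014, 4005, 3996, 3987),
    `8000` = c(3600, 3592, 3584, 3576, 3568, 3560, 3552, 3544),
    `7000` = c(3150, 3143, 3136, 3129, 3122, 3115, 3108, 3101),
    `6000` = c(2700, 2694, 2688, 2682, 2676, 2670, 2664, 2658),
    `5000` = c(2250, 2245, 2240, 2235, 2230, 2225, 2220, 2215),
    `4000` = c(1800, 1796, 1792, 1788, 1784, 1780, 1776, 1772),
    `3000` = c(1350, 1347, 1344, 1341, 1338, 1335, 1332, 1329),
    `2000` = c(900, 898, 896, 894, 892, 890, 888, 886),
    `1000` = c(450, 449, 448, 447, 446, 445, 444, 443)
  )
  tidyr::expand_grid(population = as.numeric(rev(names(rows))),
                     pi = seq(0, 0.007, by = 0.001)) |>
    dplyr::mutate(expected = unlist(rev(unname(rows))))
}

test_that("exact Poisson interval matches a tail-sum inversion oracle", {
  for (k in 0:10) {
    got <- poisson_exact_ci(k, 100, 0.95)
    want <- poisson_ci_tail_oracle(k, 100, 0.95)
    expect_equal(got$low, unname(want["low"]), tolerance = 1e-6)
    expect_equal(got$high, unname(want["high"]), tolerance = 1e-6)
  }
})

test_that("zero observed deaths give a zero lower bound and -log(a/2)/n upper", {
  ci <- poisson_exact_ci(0, 23, 0.95)
  expect_equal(ci$low, 0)
  expect_equal(ci$high, -log(0.025) / 23, tolerance = 1e-12)
  expect_equal(ci$high, 0.1604, tolerance = 1e-4)
  expect_error(poisson_exact_ci(1, 0), class = "vomscba_invalid_parameter")
})

test_that("the exact interval covers the observed rate", {
  for (k in 1:5) {
    ci <- poisson_exact_ci(k, 100, 0.95)
    expect_lt(ci$low, k / 100)
    expect_gt(ci$high, k / 100)
  }
})

test_that("the scaling grid reproduces every published cell", {
  grid <- deaths_averted_grid()
  expect_equal(nrow(grid), 80)
  merged <- dplyr::inner_join(grid, published_scaling_grid(),
                              by = c("population", "pi"))
  expect_equal(nrow(merged), 80)
  expect_equal(merged$deaths_averted, merged$expected)
  # brute-force: every printed cell is the exact product N * (0.45 - Pi)
  expect_equal(merged$deaths_averted, merged$population * (0.45 - merged$pi),
               tolerance = 1e-9)
  # Pi equal to Pn kills every cell
  flat <- deaths_averted_grid(pi_values = 0.45, pn = 0.45)
  expect_true(all(flat$deaths_averted == 0))
})

test_that("two-way grid reproduces published cells and is monotone", {
  tw <- two_way_sensitivity(23, 1368375.00, 221726.18, 1320304.68)
  cell <- function(m, pn) dplyr::filter(tw, .data$cost_multiplier == m,
                                        .data$pn == !!pn)
  c1 <- cell(1, 0.45)
  expect_equal(c1$net_benefit, 12075052.26)
  expect_equal(round_half_up(c1$bc_ratio, 2), 8.59)
  c2 <- cell(2, 0.08)
  expect_equal(c2$net_benefit, -529115.57)
  expect_equal(round_half_up(c2$bc_ratio, 2), 0.82)
  # current-budget row matches the published summary ratios at the range ends
  expect_equal(round_half_up(cell(1, 0.08)$bc_ratio, 2), 1.53)
  expect_equal(round_half_up(cell(1, 0.80)$bc_ratio, 2), 15.28)
  # net benefit strictly increases with mortality and decreases with cost
  by_pn <- tw |> dplyr::arrange(.data$cost_multiplier, .data$pn) |>
    dplyr::group_by(.data$cost_multiplier) |>
    dplyr::summarise(mono = all(diff(.data$net_benefit) > 0))
  expect_true(all(by_pn$mono))
  by_cost <- tw |> dplyr::arrange(.data$pn, .data$cost_multiplier) |>
    dplyr::group_by(.data$pn) |>
    dplyr::summarise(mono = all(diff(.data$net_benefit) < 0))
  expect_true(all(by_cost$mono))
  # break-even: value equal to total cost gives ratio exactly 1, net 0
  be <- break_even_mortality(1590101.18, 23, 1320304.68)
  expect_equal(be, 1590101.18 / (23 * 1320304.68))
  at_be <- two_way_sensitivity(23, 1368375.00, 221726.18, 1320304.68,
                               cost_multipliers = 1, pn_values = be)
  expect_equal(at_be$bc_ratio, 1, tolerance = 1e-8)
  expect_equal(at_be$net_benefit, 0, tolerance = 0.01)
})

test_that("Monte Carlo mortality is seed-reproducible and distribution-faithful", {
  spec <- monte_carlo_spec("uniform", 0.08, 0.80, n_draws = 100000L, seed = 99L)
  a <- monte_carlo_mortality(spec, n = 23)
  b <- monte_carlo_mortality(spec, n = 23)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  # analytic mean of uniform(0.08, 0.80) is 0.44; MC error ~ sd/sqrt(n)
  se <- (0.80 - 0.08) / sqrt(12) / sqrt(spec$n_draws)
  expect_lt(abs(a$summary$mean_pn - 0.44), 4 * se)
  # across seeds the mean moves but stays within Monte Carlo error
  c_ <- monte_carlo_mortality(monte_carlo_spec("uniform", 0.08, 0.80,
                                               n_draws = 100000L, seed = 100L),
                              n = 23)
  expect_false(identical(a$draws, c_$draws))
  expect_lt(abs(c_$summary$mean_pn - 0.44), 4 * se)
  # degenerate uniform collapses to its endpoint
  d <- monte_carlo_mortality(monte_carlo_spec("uniform", 0.3, 0.3,
                                              n_draws = 100L), n = 10)
  expect_true(all(d$draws == 0.3))
  expect_error(monte_carlo_spec("uniform", 0.8, 0.08),
               class = "vomscba_invalid_parameter")
})

test_that("the fixed-rate scenario reports the published deaths-averted estimate", {
  sim <- monte_carlo_mortality(monte_carlo_spec("fixed", low = 0.45), n = 66)
  expect_equal(sim$summary$mean_deaths_averted, 29.7)
  expect_equal(round_half_up(sim$summary$mean_deaths_averted, 0), 30)
  expect_equal(sim$summary$mean_pn, 0.45)
})

test_that("triangular draws stay in support with the right mean", {
  spec <- monte_carlo_spec("triangular", 0.08, 0.80, mode = 0.45,
                           n_draws = 50000L, seed = 5L)
  sim <- monte_carlo_mortality(spec, n = 23)
  expect_true(all(sim$draws >= 0.08 & sim$draws <= 0.80))
  # mean of triangular = (low + mode + high) / 3
  se <- stats::sd(sim$draws) / sqrt(spec$n_draws)
  expect_lt(abs(sim$summary$mean_pn - (0.08 + 0.45 + 0.80) / 3), 4 * se)
})
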