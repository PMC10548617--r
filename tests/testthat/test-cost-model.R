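test_that("per-overdose EMS pathway cost sums the fee schedule", {
  expect_equal(round_half_up(per_ems_overdose_cost(nors_profile$cost)), 4475.82)
  p0 <- cost_parameters(hospitalization_prob = 0)
  expect_equal(round_half_up(per_ems_overdose_cost(p0)), 1900.83)
  zero <- cost_parameters(ems_fee = 0, ems_fee_range = c(0, 0),
                          ed_visit_cost = 0, physician_fee_base = 0,
                          physician_fee = 0, naloxone_cost = 0,
                          hospitalization_cost = 0,
                          hospitalization_cost_range = c(0, 0))
  expect_equal(per_ems_overdose_cost(zero), 0)
})

test_that("medical-systems cost reproduces the published period totals", {
  t <- tally_calls(nors_fixture())
  mc <- medical_services_cost(t, nors_profile$cost)
  expect_equal(mc$medical_cost, c(163290.52, 58435.66))
  expect_equal(mc$operating_cost, c(787500.00, 580875.00))
  # total = sum of the five components, to the cent
  comp_sum <- mc$ambulance_component + mc$ed_component +
    mc$hospitalization_component + mc$false_positive_component +
    mc$community_component
  expect_equal(mc$medical_cost, comp_sum)
  expect_true(all(as.matrix(mc[-1]) >= 0))

  # all-zero tally prices to zero
  t0 <- tally_calls(tiny_log()[0, ], periods = "Funded 1")
  expect_equal(medical_services_cost(t0, nors_profile$cost)$medical_cost, 0)
})

test_that("medical cost is linear in each response count", {
  base <- tally_calls(tiny_log()[0, ], periods = "P")
  params <- cost_parameters(operating_cost_by_period = c(P = 0))
  cost_of <- function(t_ems, t_fc, t_cr) {
    t <- base
    t$t_ems <- t_ems; t$t_od <- t_ems; t$t_fc <- t_fc; t$t_cr <- t_cr
    medical_services_cost(t, params)
  }
  for (counts in list(c(5, 3, 2), c(36, 2, 9), c(1, 0, 7))) {
    one <- cost_of(counts[1], counts[2], counts[3])
    dbl_ems <- cost_of(2 * counts[1], counts[2], counts[3])
    # doubling t_ems doubles the EMS-pathway components only
    expect_equal(dbl_ems$ambulance_component, 2 * one$ambulance_component)
    expect_equal(dbl_ems$ed_component, 2 * one$ed_component)
    expect_equal(dbl_ems$hospitalization_component,
                 2 * one$hospitalization_component)
    expect_equal(dbl_ems$false_positive_component, one$false_positive_component)
    expect_equal(dbl_ems$community_component, one$community_component)
    dbl_fc <- cost_of(counts[1], 2 * counts[2], counts[3])
    expect_equal(dbl_fc$false_positive_component,
                 2 * one$false_positive_component)
    expect_equal(dbl_fc$ambulance_component, one$ambulance_component)
    dbl_cr <- cost_of(counts[1], counts[2], 2 * counts[3])
    expect_equal(dbl_cr$community_component, 2 * one$community_component)
  }
})

test_that("medical cost equals a record-by-record pricing oracle", {
  for (seed in c(3L, 17L)) {
    log <- generate_call_log(generator_config(seed = seed))
    t <- tally_calls(log)
    mc <- medical_services_cost(t, nors_profile$cost)
    expect_equal(sum(mc$medical_cost),
                 price_log_by_record(log, nors_profile$cost),
                 tolerance = 0.02)
  }
  # degenerate schedule: only the ambulance fee is non-zero, so the total
  # collapses to ems_fee * (t_ems + t_fc) + community cost
  p <- cost_parameters(ed_visit_cost = 0, physician_fee = 0,
                       physician_fee_base = 0, naloxone_cost = 0,
                       hospitalization_prob = 0, community_response_cost = 10)
  t <- tally_calls(nors_fixture())
  mc <- medical_services_cost(t, p)
  expect_equal(mc$medical_cost, p$ems_fee * (t$t_ems + t$t_fc) + 10 * t$t_cr)
})

test_that("false-positive call-outs cost one ambulance fee each", {
  t <- tally_calls(nors_fixture())
  expect_equal(false_positive_cost(t, nors_profile$cost), 1036.00)
  t$t_fc <- c(0, 0)
  expect_equal(false_positive_cost(t, nors_profile$cost), 0)
  t$t_fc <- c(3, 0)
  expect_equal(false_positive_cost(t, cost_parameters(ems_fee = 240)), 720.00)
})

test_that("community responses save the EMS pathway cost less a naloxone kit", {
  cs <- community_savings(11, nors_profile$cost)
  expect_equal(cs$per_response, 4350.82)
  expect_equal(cs$total, 47859.02)
  expect_equal(community_savings(0, nors_profile$cost)$total, 0)
  # equal costs -> no savings
  p <- cost_parameters(community_response_cost =
                         per_ems_overdose_cost(nors_profile$cost))
  expect_equal(community_savings(1, p)$total, 0)
})
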