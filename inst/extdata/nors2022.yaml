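name: nors2022
reported_operating_total: 1366749.00
cost:
  ems_fee: 518.00
  ems_fee_range: [240.00, 848.00]
  ed_visit_cost: 1061.00
  physician_fee_base: 176.00
  physician_fee: 196.83
  naloxone_cost: 125.00
  hospitalization_cost: 7803.00
  hospitalization_cost_range: [6620.00, 13647.00]
  hospitalization_prob: 0.33
  community_response_cost: 125.00
  operating_cost_by_period:
    "Funded 1": 787500.00
    "Funded 2": 580875.00
  currency_year: 2022
life:
  annual_income: 73530.00
  employment_rate: 0.67
  median_age_at_death: 38
  retirement_age: 64.8
mortality:
  pn: 0.45
  pi: 0.0
  pn_range: [0.08, 0.80]
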