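# shared fixtures: the bundled profile and small hand-built call logs

nors_profile <- cba_profile("nors2022")

# a minimal well-formed log: one overdose (EMS), one community overdose by
# the same caller, one plain substance call, one false positive
tiny_log <- function(period = "Funded 1") {
  tibble::tibble(
    timestamp = as.POSIXct("2021-05-01 12:00:00", tz = "UTC") + 3600 * 0:3,
    period = period,
    category = c("substance_use", "substance_use", "substance_use", "other"),
    overdose = c(TRUE, TRUE, FALSE, FALSE),
    caller_id = c("A", "A", "B", NA),
    response = c("ems", "community", "none", "ems"),
    false_positive_ems = c(FALSE, FALSE, FALSE, TRUE),
    non_overdose_emergency = FALSE
  )
}

# brute-force oracle: price a call log record by record
price_log_by_record <- function(calls, params) {
  per_ems <- per_ems_overdose_cost(params)
  sum(ifelse(calls$overdose & calls$response == "ems", per_ems,
      ifelse(calls$overdose & calls$response == "community",
             params$community_response_cost,
      ifelse(calls$false_positive_ems, params$ems_fee, 0))))
}

# brute-force oracle: exact Poisson interval by tail-sum inversion
poisson_ci_tail_oracle <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  upper <- stats::uniroot(function(mu) stats::ppois(k, mu) - alpha / 2,
                          c(1e-12, 1000), tol = 1e-12)$root
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(mu) stats::ppois(k - 1, mu) - (1 - alpha / 2),
                   c(1e-12, 1000), tol = 1e-12)$root
  }
  c(low = lower / n, high = upper / n)
}
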