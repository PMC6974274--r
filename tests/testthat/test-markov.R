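# Cohort engine: rate conversions, cycle mechanics, conservation.

test_that("rate-to-probability conversion follows the constant-hazard form", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(log(2), 1), 0.5)
  expect_equal(rate_to_probability(0.0154, 1), 0.015282, tolerance = 1e-4)
  expect_error(rate_to_probability(-0.1, 1), "non-negative")
  expect_error(rate_to_probability(0.1, -1), "non-negative")

  # small-rate limit: |p - rt| <= (rt)^2 / 2
  for (rt in c(1e-4, 5e-5, 1e-6)) {
    expect_lte(abs(rate_to_probability(rt, 1) - rt), rt^2 / 2 + 1e-16)
  }
  # monotone in both arguments
  r <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(rate_to_probability(r, 1)) > 0))
  expect_true(all(diff(rate_to_probability(0.3, r)) > 0))
})

test_that("albuminuric probabilities scale the hazard before conversion", {
  expect_equal(albuminuric_probability(0.0006, 3.432, 1), 0.0020571,
               tolerance = 1e-4)
  expect_equal(albuminuric_probability(0.0095, 1.480, 1), 0.013962,
               tolerance = 1e-4)
  r <- c(0, 0.001, 0.02, 0.3)
  expect_equal(albuminuric_probability(r, 1, 2), rate_to_probability(r, 2))
  expect_error(albuminuric_probability(0.01, 0), "positive")
})

test_that("a single cycle reproduces the closed-form decision tree", {
  cfg <- model_config(horizon = 1)
  s <- cfg$screening
  p <- 1 - exp(-cfg$outcomes$rate_normo)
  q <- 1 - exp(-cfg$outcomes$rate_normo * cfg$outcomes$hr)

  tr_q <- run_strategy("quantitative", cfg)
  expect_equal(tr_q$cycles$screens, 1)
  expect_equal(tr_q$cycles$exits, 1 - s$q_negative)
  expect_equal(as.vector(tr_q$events[1, , "q_negative"]), s$q_negative * p)

  tr_s <- run_strategy("semi-quantitative", cfg)
  expect_equal(tr_s$cycles$screens, 1)
  expect_equal(tr_s$cycles$confirmatory, 1 - s$semiq_negative)
  expect_equal(tr_s$cycles$exits,
               (1 - s$semiq_negative) * s$tp_given_semiq_positive)
  tn <- s$semiq_negative * (1 - s$fn_given_semiq_negative)
  fn <- s$semiq_negative * s$fn_given_semiq_negative
  fp <- (1 - s$semiq_negative) * (1 - s$tp_given_semiq_positive)
  expect_equal(as.vector(tr_s$events[1, , "true_negative"]), tn * p)
  expect_equal(as.vector(tr_s$events[1, , "false_negative"]), fn * q)
  expect_equal(as.vector(tr_s$events[1, , "false_positive"]), fp * p)
})

test_that("an event-free never-positive cohort persists unchanged", {
  cfg <- model_config(
    screening = screening_params(q_negative = c(1, 0),
                                 semiq_negative = c(1, 0),
                                 fn_given_semiq_negative = c(0, 1),
                                 tp_given_semiq_positive = c(0, 1)),
    outcomes = outcome_params(
      esrd = list(rate = 0, hr = 1, unit_cost = 0),
      cvd = list(rate = 0, hr = 1, unit_cost = 0),
      death = list(rate = 0, hr = 1, unit_cost = 0)))
  tr <- run_strategy("quantitative", cfg)
  expect_equal(tr$cycles$occupancy, rep(1, 10))
  expect_equal(sum(tr$events), 0)
  expect_equal(sum(tr$cycles$screens), 10)
})

test_that("mass is conserved and occupancy decays geometrically", {
  for (cfg in list(development_config(), validation_config())) {
    for (strat in c("quantitative", "semi-quantitative")) {
      tr <- run_strategy(strat, cfg)
      cy <- tr$cycles
      # exits + events + survivors = occupancy, every cycle
      expect_equal(cy$exits + cy$events + cy$survivors, cy$occupancy,
                   tolerance = 1e-12)
      # survivors feed the next cycle
      expect_equal(cy$occupancy[-1], cy$survivors[-nrow(cy)])
      # strict geometric decay: constant occupancy ratio
      ratio <- cy$occupancy[-1] / cy$occupancy[-nrow(cy)]
      expect_true(all(abs(diff(ratio)) < 1e-12))
      expect_true(all(ratio > 0 & ratio < 1))
    }
  }
})

test_that("horizon totals match the closed-form geometric oracle", {
  cfg <- development_config()
  for (strat in c("quantitative", "semi-quantitative")) {
    tr <- run_strategy(strat, cfg)
    o <- oracle_totals(cfg, strat)
    expect_equal(sum(tr$cycles$screens), o$screens, tolerance = 1e-12)
    expect_equal(sum(tr$cycles$confirmatory), o$confirms, tolerance = 1e-12)
    costed <- setdiff(dimnames(tr$events)$stratum, "false_positive")
    expect_equal(apply(tr$events[, , costed, drop = FALSE], 2, sum),
                 o$events, tolerance = 1e-12)
  }
  # development screening volume: 10-year expected screens per person
  expect_equal(sum(run_strategy("quantitative", cfg)$cycles$screens),
               4.545, tolerance = 1e-3)
  expect_equal(sum(run_strategy("semi-quantitative", cfg)$cycles$confirmatory),
               2.270, tolerance = 1e-3)
})

test_that("unit hazard ratios equalize per-occupant event rates across strata", {
  oc <- outcome_params()
  oc$hr[] <- 1
  cfg <- model_config(outcomes = oc)
  tr <- run_strategy("semi-quantitative", cfg)
  s <- cfg$screening
  tn_occ <- s$semiq_negative * (1 - s$fn_given_semiq_negative)
  fn_occ <- s$semiq_negative * s$fn_given_semiq_negative
  per_tn <- apply(tr$events[, , "true_negative"], 2, sum) / tn_occ
  per_fn <- apply(tr$events[, , "false_negative"], 2, sum) / fn_occ
  expect_equal(per_tn, per_fn, tolerance = 1e-12)
})

test_that("parameter updates are validated and applied", {
  cfg <- development_config()
  cfg2 <- set_parameter(cfg, "hr_esrd", 2.757)
  expect_equal(cfg2$outcomes["ESRD", "hr"], 2.757)
  cfg3 <- set_parameter(cfg, "cost_transport", 10)
  expect_equal(cfg3$cost_transport, 10)
  cfg4 <- set_parameter(cfg, "rate_cvd", 0.02)
  expect_equal(cfg4$outcomes["CVD", "rate_normo"], 0.02)
  expect_error(set_parameter(cfg, "cost_of_tea", 1), "valid names")
  expect_error(set_parameter(cfg, "cost_death", NA_real_), "finite")
  expect_error(model_config(horizon = 0), "horizon")
  expect_error(model_config(discount_rate = -0.1), "discount_rate")
  expect_error(model_config(cost_quant_test = -1), "non-negative")
})
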