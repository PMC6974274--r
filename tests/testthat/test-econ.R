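# Cost accounting and sensitivity analysis, checked against the
# closed-form geometric oracle and structural invariants.

test_that("cost components match the closed-form oracle exactly", {
  for (cfg in list(development_config(), validation_config())) {
    cmp <- compare_strategies(cfg)
    for (strat in c("quantitative", "semi-quantitative")) {
      bd <- if (strat == "quantitative") cmp$quantitative else cmp$semi_quantitative
      o <- oracle_totals(cfg, strat)
      expect_equal(bd$total_crude, o$total_crude, tolerance = 1e-9)
      expect_equal(bd$total_discounted, o$total_discounted, tolerance = 1e-9)
      # component-level: screening rows from the same closed form
      screen_cost <- if (strat == "quantitative") cfg$cost_quant_test else cfg$cost_semiq_test
      expect_equal(bd$components["screening_test", "crude"],
                   o$screens * screen_cost, tolerance = 1e-9)
      expect_equal(bd$components["confirmatory_test", "crude"],
                   o$confirms * cfg$cost_quant_test, tolerance = 1e-9)
      expect_equal(unname(bd$components[paste0("outcome_", names(o$events)), "crude"]),
                   unname(o$events * cfg$outcomes[names(o$events), "unit_cost"]),
                   tolerance = 1e-9)
    }
  }
})

test_that("totals decompose into their components", {
  for (cfg in list(development_config(), validation_config(),
                   model_config(discount_rate = 0.07, horizon = 25))) {
    for (strat in c("quantitative", "semi-quantitative")) {
      bd <- cost_breakdown(run_strategy(strat, cfg))
      expect_equal(sum(bd$components$crude), bd$total_crude, tolerance = 1e-9)
      expect_equal(sum(bd$components$discounted), bd$total_discounted,
                   tolerance = 1e-9)
      expect_true(all(bd$components$discounted <= bd$components$crude + 1e-12))
    }
  }
})

test_that("zero discounting reproduces crude totals exactly", {
  cfg <- model_config(discount_rate = 0)
  for (strat in c("quantitative", "semi-quantitative")) {
    bd <- cost_breakdown(run_strategy(strat, cfg))
    expect_equal(bd$components$discounted, bd$components$crude)
    expect_equal(bd$total_discounted, bd$total_crude)
  }
})

test_that("cash flows are linear in unit costs", {
  cfg <- development_config()
  oc2 <- cfg$outcomes; oc2$unit_cost <- oc2$unit_cost * 2
  doubled <- model_config(outcomes = oc2,
                          cost_quant_test = cfg$cost_quant_test * 2,
                          cost_semiq_test = cfg$cost_semiq_test * 2,
                          cost_transport = cfg$cost_transport * 2)
  for (strat in c("quantitative", "semi-quantitative")) {
    b1 <- cost_breakdown(run_strategy(strat, cfg))
    b2 <- cost_breakdown(run_strategy(strat, doubled))
    expect_equal(b2$components$crude, 2 * b1$components$crude, tolerance = 1e-12)
    expect_equal(b2$total_discounted, 2 * b1$total_discounted, tolerance = 1e-12)
  }
  # all unit costs zero: every component vanishes
  oc0 <- cfg$outcomes; oc0$unit_cost <- 0
  zero <- model_config(outcomes = oc0, cost_quant_test = 0,
                       cost_semiq_test = 0, cost_transport = 0)
  expect_equal(cost_breakdown(run_strategy("quantitative", zero))$total_crude, 0)
  expect_equal(cost_breakdown(run_strategy("semi-quantitative", zero))$total_crude, 0)
})

test_that("savings respond monotonically to the two test prices", {
  cfg <- development_config()
  base <- compare_strategies(cfg)$saving$crude_saving
  up_q <- compare_strategies(set_parameter(cfg, "cost_quant_test", 25))$saving$crude_saving
  dn_q <- compare_strategies(set_parameter(cfg, "cost_quant_test", 10))$saving$crude_saving
  expect_gt(up_q, base)
  expect_lt(dn_q, base)
  up_s <- compare_strategies(set_parameter(cfg, "cost_semiq_test", 5))$saving$crude_saving
  expect_lt(up_s, base)
})

# relabel a quantitative breakdown as semi-quantitative to build the
# "identical breakdowns" degenerate case
relabel_semiq <- function(bd) { bd$strategy <- "semi-quantitative"; bd }

test_that("saved cost compares the two strategies in order", {
  cmp <- compare_strategies(development_config())
  sv <- cmp$saving
  expect_equal(sv$crude_saving,
               cmp$quantitative$total_crude - cmp$semi_quantitative$total_crude)
  expect_equal(sv$crude_fraction, sv$crude_saving / cmp$quantitative$total_crude)
  expect_error(saved_cost(cmp$semi_quantitative, cmp$quantitative), "order")
  # identical breakdowns: zero saving
  expect_equal(saved_cost(cmp$quantitative, relabel_semiq(cmp$quantitative)),
               list(crude_saving = 0, crude_fraction = 0,
                    discounted_saving = 0, discounted_fraction = 0),
               tolerance = 1e-12)
})

test_that("one-way sensitivity is exact at degenerate ranges and linear in costs", {
  cfg <- development_config()
  base_disc <- compare_strategies(cfg)$saving$discounted_saving
  flat <- one_way_sensitivity(cfg, "cost_transport", cfg$cost_transport,
                              cfg$cost_transport)
  expect_equal(flat$saving_at_low, base_disc, tolerance = 1e-12)
  expect_equal(flat$span, 0)

  # linearity: the two-point line through +/-20% passes through baseline
  ow <- one_way_sensitivity(cfg, "cost_transport",
                            cfg$cost_transport * 0.8, cfg$cost_transport * 1.2)
  expect_equal((ow$saving_at_low + ow$saving_at_high) / 2, base_disc,
               tolerance = 1e-9)
})

test_that("tornado entries are complete, ordered, and led by the cost of death", {
  cfg <- development_config()
  tor <- tornado(cfg)
  expect_equal(nrow(tor), 12)  # 6 costs + 3 rates + 3 HRs
  expect_true(all(diff(tor$span) <= 1e-12))
  expect_equal(tor$parameter[1], "cost_death")
  expect_equal(attr(tor, "baseline_saving"),
               compare_strategies(cfg)$saving$discounted_saving)
  # single-entry list comes back trivially ordered
  single <- tornado(cfg, ranges = data.frame(parameter = "cost_cvd",
                                             low = 10000, high = 16000))
  expect_equal(nrow(single), 1)
  expect_error(tornado(cfg, ranges = data.frame()), "non-empty")
})

test_that("costing false-positive events is available as an explicit switch", {
  tr <- run_strategy("semi-quantitative", development_config())
  default <- cost_breakdown(tr)
  with_fp <- cost_breakdown(tr, cost_false_positive_events = TRUE)
  expect_gt(with_fp$total_crude, default$total_crude)
  # the difference is exactly the false-positive events' cost
  fp_cost <- sum(apply(tr$events[, , "false_positive"], 2, sum) *
                   tr$config$outcomes[colnames(tr$events), "unit_cost"])
  expect_equal(with_fp$total_crude - default$total_crude, fp_cost,
               tolerance = 1e-9)
})
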