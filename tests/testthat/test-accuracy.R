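# Diagnostic accuracy: concordance tables, dichotomized metrics, NNS,
# and the screening proportions handed to the cost model.

test_that("record tabulation reproduces known cell counts and validates input", {
  # reconstruct per-patient records from the development-subgroup cells
  cnt <- development_subgroup_table()$counts
  mids <- c(10, 100, 500)  # representative values inside each bin
  quant <- rep(rep(mids, each = 3), times = as.vector(t(cnt)))
  semiq <- rep(rep(uacr_categories(), times = 3), times = as.vector(t(cnt)))
  tab <- build_concordance(quant, semiq, label = "rebuilt")
  expect_equal(unname(tab$counts), unname(cnt))
  expect_equal(tab$n, 1110)

  # boundary values 30 and 300 belong to the upper bin
  expect_equal(as.character(bin_uacr(c(0, 29.999, 30, 299.9, 300, 2000))),
               c("<30", "<30", "30-300", "30-300", ">=300", ">=300"))

  expect_error(build_concordance(numeric(0), character(0)), "at least one")
  expect_error(build_concordance(c(10, 20), c("<30", "micro")),
               "unknown semi-quantitative category.*record 2")
  one_cell <- build_concordance(rep(10, 3), rep("<30", 3))
  expect_equal(sum(one_cell$counts), 3)
  expect_equal(one_cell$counts["<30", "<30"], 3)
})

test_that("accuracy metrics match the printed cohort summaries", {
  cases <- list(
    list(tab = development_all_table(),
         sens = 748 / 800, spec = 664 / 1081,
         over = 417 / 1881, under = 52 / 1881),
    list(tab = development_subgroup_table(),
         sens = 157 / 193, spec = 579 / 917,
         over = 338 / 1110, under = 36 / 1110),
    list(tab = validation_overall_table(),
         sens = 93 / 111, spec = 214 / 320,
         over = 106 / 431, under = 18 / 431),
    list(tab = validation_subgroup_table(),
         sens = 38 / 46, spec = 187 / 255,
         over = 68 / 301, under = 8 / 301))
  for (cs in cases) {
    m <- accuracy_metrics(cs$tab)
    expect_equal(m$sensitivity, cs$sens)
    expect_equal(m$specificity, cs$spec)
    expect_equal(m$over_detected, cs$over)
    expect_equal(m$under_detected, cs$under)
    expect_equal(m$nns, 1 / cs$sens)
  }
  # one-decimal display values as published
  m <- accuracy_metrics(development_all_table())
  expect_equal(round(100 * c(m$sensitivity, m$specificity,
                             m$over_detected, m$under_detected), 1),
               c(93.5, 61.4, 22.2, 2.8))
})

test_that("degenerate tables are flagged, not silently summarized", {
  all_neg <- concordance_table(matrix(c(5, 2, 0, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE))
  expect_error(accuracy_metrics(all_neg), "sensitivity is undefined")
  all_pos <- concordance_table(matrix(c(0, 0, 0, 1, 5, 0, 0, 0, 2), 3, byrow = TRUE))
  expect_error(accuracy_metrics(all_pos), "specificity is undefined")
  expect_error(concordance_table(matrix(0, 3, 3)), "n >= 1")
  expect_error(concordance_table(matrix(c(-1, rep(1, 8)), 3, 3)), "non-negative")
})

test_that("a perfectly concordant table gives ideal metrics", {
  diag_tab <- concordance_table(diag(c(50, 30, 5)))
  m <- accuracy_metrics(diag_tab)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$over_detected, 0)
  expect_equal(m$under_detected, 0)
  expect_equal(m$nns, 1)
  expect_equal(unname(m$row_concordance), c(1, 1, 1))
  sp <- strategy_probabilities(diag_tab)
  expect_equal(sp$fn_given_semiq_negative, 0)
  expect_equal(sp$tp_given_semiq_positive, 1)
})

test_that("number needed to screen is the reciprocal of sensitivity", {
  # all six published cohort rows at one-decimal rounding
  sens <- c(0.935, 0.833, 0.902, 0.813, 0.656, 0.527)
  expect_equal(round(number_needed_to_screen(sens), 1),
               c(1.1, 1.2, 1.1, 1.2, 1.5, 1.9))
  expect_equal(number_needed_to_screen(1), 1)
  expect_error(number_needed_to_screen(0), "undefined")
  expect_error(number_needed_to_screen(1.2), "\\(0, 1\\]")
  # exact reciprocal identity on a grid
  s <- seq(0.05, 1, by = 0.05)
  expect_equal(number_needed_to_screen(s) * s, rep(1, length(s)))
})

test_that("strategy proportions carry the published beta counts", {
  sp <- strategy_probabilities(development_subgroup_table())
  expect_equal(unname(sp$beta$q_negative), c(917, 193))
  expect_equal(unname(sp$beta$semiq_negative), c(615, 495))
  expect_equal(unname(sp$beta$fn_given_semiq_negative), c(36, 579))
  expect_equal(unname(sp$beta$tp_given_semiq_positive), c(157, 338))
  expect_equal(sp$q_negative, 917 / 1110)

  spv <- strategy_probabilities(validation_subgroup_table())
  expect_equal(spv$q_negative, 255 / 301)
  expect_equal(spv$semiq_negative, 195 / 301)
  expect_equal(spv$fn_given_semiq_negative, 8 / 195)
  expect_equal(spv$tp_given_semiq_positive, 38 / 106)
})

test_that("dichotomized cells are conserved and proportions round-trip", {
  set.seed(42)
  for (i in 1:20) {
    tab <- random_table()
    m <- accuracy_metrics(tab)
    d <- uacrscreen:::.dichotomize(tab)
    # over + under + concordant-dichotomized = everyone
    expect_equal(m$over_detected * tab$n + m$under_detected * tab$n +
                   d$tp + d$tn, tab$n)
    # beta counts regenerate the dichotomized margins
    sp <- strategy_probabilities(tab)
    expect_equal(sum(sp$beta$q_negative), tab$n)
    expect_equal(sum(sp$beta$semiq_negative), tab$n)
    expect_equal(sum(sp$beta$fn_given_semiq_negative), d$s_neg)
    expect_equal(sum(sp$beta$tp_given_semiq_positive), d$s_pos)
    expect_equal(sp$beta$fn_given_semiq_negative[1] +
                   sp$beta$tp_given_semiq_positive[2], d$q_pos - d$tp + d$fp)
  }
})
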