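test_that("discount factors follow the annual convention with cycle 0 undiscounted", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(round(discount_factor(1, 0.03), 6), 0.970874)
  expect_equal(discount_factor(0:49, 0), rep(1, 50))
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("state costs compose the printed components", {
  # PD H-Y3: medical + home care + productivity loss
  expect_equal(state_cost("PD_HY3", paper_ps, conv),
               71969.3 + 22220 + 95538.9)
  expect_equal(state_cost("PD_HY3", paper_ps, conv), 189728.2)
  expect_equal(state_cost("Normal", paper_ps, conv, cycle = 5), 0)
  # covered DM at age 45: medical + productivity + drug
  expect_equal(state_cost("DM", paper_ps, exe, cycle = 5),
               43903.6 + 635049 + 33926.8)
  expect_equal(state_cost("DM", paper_ps, exe, cycle = 5), 712879.4)
  # uncovered DM omits the drug
  expect_equal(state_cost("DM", paper_ps, conv, cycle = 5), 43903.6 + 635049)
  # PD+DM adds the DM productivity loss but not DM medical by default
  expect_equal(state_cost("PDDM_HY2", paper_ps, conv, cycle = 5),
               90217.1 + 0 + 52185.1 + 635049)
  ps <- cea_parameters(economics = list(pddm_includes_dm_medical = TRUE))
  expect_equal(state_cost("PDDM_HY2", ps, conv, cycle = 5),
               90217.1 + 0 + 52185.1 + 635049 + 43903.6)
  expect_error(state_cost("Death_DM", paper_ps, conv), "death")
})

test_that("state utilities compose the printed components and clamp to [0, 1]", {
  expect_equal(state_utility("PD_HY1", paper_ps, conv), 0.708)
  expect_equal(state_utility("Normal", paper_ps, conv, cycle = 30), 0.84)
  expect_equal(state_utility("Normal", paper_ps, conv, cycle = 24), 0.92)
  expect_equal(state_utility("Normal", paper_ps, conv, cycle = 25), 0.84)
  # DM at cycle 0 covered: 0.92 - 0.04 + 0.08
  expect_equal(state_utility("DM", paper_ps, exe, cycle = 0), 0.96)
  # model-time decline: cycle 10 subtracts 0.03 more
  expect_equal(state_utility("DM", paper_ps, conv, cycle = 10),
               0.92 - 0.04 - 0.003 * 10)
  expect_equal(state_utility("PDDM_HY4", paper_ps, conv, cycle = 10),
               0.499 - 0.04 - 0.03)
  # clamping
  ps <- paper_ps
  ps$utilities$dm_decrement <- 1
  ps$utilities$dm_decrement_low <- NA_real_
  ps$utilities$dm_decrement_high <- NA_real_
  expect_equal(state_utility("DM", ps, conv, cycle = 0), 0)
  expect_error(state_utility("Death_PD", paper_ps, conv), "death")
})

test_that("accrual matches the geometric-series closed form on the toy model", {
  grid <- expand.grid(p = c(0, 0.1, 0.35, 1), r = c(0, 0.03, 0.05),
                      u = c(0.8, 1), cost = c(0, 1234.5), T = c(3, 50))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    spec <- toy_model_spec(g$p, cost = g$cost, utility = g$u,
                           discount = g$r, horizon = g$T)
    cf <- closed_form_outcomes(spec)
    ps <- toy_parameters(spec)
    out <- accrue(run_cohort(ps, conv), ps, conv)
    expect_equal(out$ly, cf$ly, tolerance = 1e-10)
    expect_equal(out$qaly, cf$qaly, tolerance = 1e-10)
    expect_equal(out$cost, cf$cost, tolerance = 1e-10)
    expect_equal(out$qaly_undiscounted, cf$qaly_undiscounted, tolerance = 1e-10)
  }
  # spot value evaluated directly from the series
  spec <- toy_model_spec(0.1, utility = 0.8, discount = 0.03, horizon = 3)
  expect_equal(closed_form_outcomes(spec)$qaly,
               sum(0.8 * (0.9 / 1.03)^(0:2)), tolerance = 1e-12)

  # half-cycle timing: rewards on the average of adjacent boundaries
  spec <- toy_model_spec(0.2, utility = 0.7, discount = 0.03, horizon = 8)
  ps <- toy_parameters(spec)
  ps$economics$reward_timing <- "half_cycle"
  out <- accrue(run_cohort(ps, conv), ps, conv)
  s <- 0.8
  expect_equal(out$qaly, 0.7 * (1 + s) / 2 * sum((s / 1.03)^(0:7)),
               tolerance = 1e-10)
})

test_that("zero discounting makes discounted and undiscounted outcomes identical", {
  ps <- param_set(paper_ps, "economics.discount_rate", 0)
  res <- run_cea(ps)
  for (arm in list(res$conventional, res$exenatide)) {
    expect_equal(arm$ly, arm$ly_undiscounted)
    expect_equal(arm$qaly, arm$qaly_undiscounted)
    expect_equal(arm$cost, arm$cost_undiscounted)
  }
})

test_that("scaling all cost inputs scales costs and ICERs linearly, leaving QALYs fixed", {
  base <- run_cea(short_ps)
  k <- 2.5
  scaled <- run_cea(scale_costs(short_ps, k))
  expect_equal(scaled$incremental$delta_cost, k * base$incremental$delta_cost)
  expect_equal(scaled$incremental$icer_per_qaly,
               k * base$incremental$icer_per_qaly)
  expect_equal(scaled$incremental$icer_per_ly, k * base$incremental$icer_per_ly)
  expect_equal(scaled$incremental$delta_qaly, base$incremental$delta_qaly)
  expect_equal(scaled$conventional$qaly, base$conventional$qaly)
})

test_that("QALYs never exceed life years", {
  for (seed in 0:3) {
    ps <- if (seed == 0) paper_ps else perturb_parameters(paper_ps, seed)
    res <- run_cea(ps)
    expect_lte(res$conventional$qaly, res$conventional$ly)
    expect_lte(res$exenatide$qaly, res$exenatide$ly)
    expect_lte(res$conventional$qaly_undiscounted,
               res$conventional$ly_undiscounted)
  }
})

test_that("the add-on arm gains QALYs at extra cost under the base-case inputs", {
  res <- run_cea(paper_ps)
  expect_gt(res$incremental$delta_qaly, 0)
  expect_gt(res$incremental$delta_cost, 0)
  expect_gt(res$incremental$delta_ly, 0)
  # discounted totals never exceed undiscounted ones at a positive rate
  expect_lt(res$conventional$cost, res$conventional$cost_undiscounted)
  expect_lt(res$conventional$qaly, res$conventional$qaly_undiscounted)
})

test_that("incremental results divide, classify and label dominance correctly", {
  mk <- function(cost, qaly, ly = qaly) {
    structure(list(strategy = "x", ly = ly, qaly = qaly, cost = cost,
                   ly_undiscounted = ly, qaly_undiscounted = qaly,
                   cost_undiscounted = cost),
              class = "outcome_summary")
  }
  inc <- incremental(mk(1000, 10), mk(1200, 14), wtp = 100)
  expect_equal(inc$icer_per_qaly, 50)
  expect_equal(inc$nmb, 100 * 4 - 200)

  gdp <- 839558
  expect_equal(incremental(mk(0, 1), mk(268333, 2), wtp = gdp)$classification,
               "very cost-effective")
  expect_equal(incremental(mk(0, 1), mk(2 * gdp, 2), wtp = gdp)$classification,
               "cost-effective")
  expect_equal(incremental(mk(0, 1), mk(4 * gdp, 2), wtp = gdp)$classification,
               "not cost-effective")

  dom <- incremental(mk(1000, 10), mk(900, 11), wtp = 100)
  expect_equal(dom$classification, "dominant")
  expect_gt(dom$nmb, 0)
  expect_equal(incremental(mk(900, 11), mk(1000, 10), wtp = 100)$classification,
               "dominated")
  undef <- incremental(mk(1000, 10), mk(1100, 10), wtp = 100)
  expect_match(undef$classification, "undefined")
  expect_true(is.na(undef$icer_per_qaly))
})
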