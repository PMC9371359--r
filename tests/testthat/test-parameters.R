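test_that("default parameter inventory reproduces every published input value", {
  ps <- paper_ps
  # incidences
  expect_identical(ps$incidence$pd$value,
                   c(0, 0.000211, 0.000995, 0.003005, 0.003699))
  expect_identical(ps$incidence$dm$value,
                   c(0.00964, 0.00964, 0.01906, 0.01906, 0.01637))
  expect_identical(ps$incidence$pd_dm$value,
                   c(0, 0.000464, 0.001542, 0.004658, 0.005733))
  expect_identical(ps$incidence$pd$low[-1],
                   c(0.000193, 0.000773, 0.002577, 0.003280))
  expect_identical(ps$incidence$pd$high[-1],
                   c(0.000229, 0.001218, 0.003435, 0.004118))
  # mortality
  expect_identical(ps$mortality$dm$value,
                   c(0.01510, 0.02195, 0.03931, 0.05288, 0.08150))
  expect_identical(ps$mortality$dm$lower, c(40, 50, 60, 70, 75))
  expect_identical(ps$mortality$dm_exenatide_printed$value,
                   c(0.01329, 0.01932, 0.03459, 0.04653, 0.07172))
  expect_identical(ps$mortality$other$value,
                   c(0.00266, 0.00507, 0.01028, 0.02677, 0.05722))
  expect_identical(ps$mortality$pd_stage$value, c(0.01, 0.048, 0.080, 0.199))
  # transition rates and effects
  expect_identical(unname(ps$rates$pd), c(0.3237, 0.068, 0.3192))
  expect_identical(unname(ps$rates$pd_dm), c(0.4369, 0.1462, 0.3192))
  expect_identical(unname(ps$effects$multipliers), c(0.947, 0.239, 0.206))
  expect_identical(ps$effects$multipliers_printed$value, c(0.981, 0.245, 0.214))
  expect_identical(ps$effects$multipliers_printed$low, c(0.95, 0.20, 0.17))
  expect_identical(ps$effects$multipliers_printed$high, c(0.99, 0.32, 0.28))
  expect_identical(ps$effects$dm_mortality_factor, 0.88)
  expect_identical(ps$effects$dm_utility_increment, 0.08)
  # costs
  expect_identical(ps$costs$pd_medical$value,
                   c(21821.9, 69074.2, 71969.3, 133558.1))
  expect_identical(ps$costs$pddm_medical$value,
                   c(21821.9, 90217.1, 77079.1, 148740.9))
  expect_identical(ps$costs$home_care$value, c(0, 0, 22220, 22220))
  expect_identical(ps$costs$pd_productivity$value,
                   c(17261.2, 52185.1, 95538.9, 54593.7))
  expect_identical(ps$costs$dm_medical$value,
                   c(43903.6, 58903.6, 73903.6, 88903.6, 103903.6))
  expect_identical(ps$costs$dm_productivity$value,
                   c(635049, 605055.6, 481893, 0))
  expect_identical(ps$costs$exenatide_annual, 33926.8)
  # utilities
  expect_identical(ps$utilities$normal$value, c(0.92, 0.84))
  expect_identical(ps$utilities$pd$value, c(0.708, 0.678, 0.622, 0.499))
  expect_identical(ps$utilities$dm_decrement, 0.04)
  expect_identical(ps$utilities$dm_annual_decline, 0.003)
  # economic settings
  expect_identical(ps$economics$discount_rate, 0.03)
  expect_identical(ps$economics$horizon_cycles, 50L)
  expect_identical(ps$economics$cohort_size, 1000)
  expect_identical(ps$economics$entry_age, 40)
  expect_identical(ps$economics$dm_prevalence_at_entry, 0.0605)
  expect_identical(ps$economics$wtp_gdp, 839558)
})

test_that("defaults pass validation with zero violations", {
  expect_identical(validate_parameters(paper_ps), character(0))
})

test_that("age-band lookup uses inclusive-lower exclusive-upper boundaries", {
  ps <- paper_ps
  expect_equal(lookup_band(ps$mortality$dm, 45), 0.01510)
  expect_equal(lookup_band(ps$mortality$dm, 50), 0.02195)  # 50 is in 50-59
  expect_equal(lookup_band(ps$incidence$pd, 40), 0)
  expect_equal(lookup_band(ps$mortality$other, 80), 0.05722)
  expect_equal(lookup_band(ps$mortality$other, 95), 0.05722)  # open-ended top
  expect_equal(lookup_band(ps$mortality$dm, 74), 0.05288)
  expect_equal(lookup_band(ps$mortality$dm, 75), 0.08150)
  expect_error(lookup_band(ps$mortality$dm, 39), "below the first band")
  # vectorised and piecewise-constant over the whole modelled age range
  ages <- 40:95
  vals <- lookup_band(ps$costs$dm_medical, ages)
  expect_length(vals, length(ages))
  expect_true(all(vals %in% ps$costs$dm_medical$value))
})

test_that("treated-rate arithmetic reproduces the published treated rows", {
  m <- c(0.947, 0.239, 0.206)
  expect_identical(
    derive_treated_rates(c(0.3237, 0.068, 0.3192), m, rounded = TRUE),
    c(lambda1 = 0.3065, lambda2 = 0.0163, lambda3 = 0.0658))
  expect_identical(
    derive_treated_rates(c(0.4369, 0.1462, 0.3192), m, rounded = TRUE),
    c(lambda1 = 0.4137, lambda2 = 0.0349, lambda3 = 0.0658))
  # identity multipliers leave the rates unchanged
  lam <- c(0.3237, 0.068, 0.3192)
  expect_equal(unname(derive_treated_rates(lam, c(1, 1, 1))), lam)
  expect_error(derive_treated_rates(c(-0.1, 0, 0), c(1, 1, 1)), "non-negative")
  # the printed add-on DM mortality column is conventional x 0.88 to 5 decimals
  expect_identical(round(paper_ps$mortality$dm$value * 0.88, 5),
                   paper_ps$mortality$dm_exenatide_printed$value)
})

test_that("PD+DM stage-3 treated rate follows the documented default with a printed override", {
  # default: the product of the stated factors, not the printed 0.0210
  expect_equal(round(treated_rates(paper_ps, "pd_dm")[["lambda3"]], 4), 0.0658)
  ps <- cea_parameters(economics = list(pddm_lambda3 = "printed"))
  expect_equal(treated_rates(ps, "pd_dm")[["lambda3"]], 0.0210)
  # untreated rates are returned as stored
  expect_identical(treated_rates(paper_ps, "pd", treated = FALSE),
                   paper_ps$rates$pd)
})

test_that("validation names the offending field", {
  ps <- paper_ps
  ps$mortality$pd_stage$value[2] <- -0.1
  v <- validate_parameters(ps)
  expect_true(any(grepl("mortality.pd_stage", v)))

  ps <- paper_ps
  ps$incidence$dm$low[1] <- 0.5  # low above base
  v <- validate_parameters(ps)
  expect_true(any(grepl("sa_range.incidence.dm.1", v, fixed = TRUE)))

  ps <- paper_ps
  ps$incidence$pd_dm$value[3] <- 1e-5  # below plain PD incidence
  expect_true(any(grepl("incidence.pd_dm", validate_parameters(ps))))

  ps <- paper_ps
  ps$utilities$pd$value <- c(0.7, 0.7, 0.6, 0.5)  # not strictly decreasing
  expect_true(any(grepl("utilities.pd", validate_parameters(ps))))
})

test_that("sensitivity registry brackets every base value and has unique ids", {
  sa <- sa_parameters(paper_ps)
  expect_gt(nrow(sa), 40)
  expect_false(any(duplicated(sa$id)))
  expect_true(all(sa$low <= sa$base & sa$base <= sa$high))
  # parameters without printed ranges are not registered
  expect_false(any(grepl("home_care|exenatide_annual|dm_productivity", sa$id)))
  expect_false("incidence.pd.1" %in% sa$id)
})

test_that("param_set/param_get round-trip and keep derived rates consistent", {
  ps <- paper_ps
  ps2 <- param_set(ps, "mortality.dm.1", 0.02)
  expect_equal(param_get(ps2, "mortality.dm.1"), 0.02)
  expect_equal(param_get(ps, "mortality.dm.1"), 0.01510)  # copy-on-write
  expect_error(param_set(ps, "no.such.id.here", 1), "unknown parameter")

  # setting a rate multiplier re-derives the treated rates and stays valid
  ps3 <- param_set(ps, "effects.m1", 0.97)
  expect_equal(unname(ps3$effects$multipliers["m1"]), 0.97)
  expect_identical(validate_parameters(ps3), character(0))
  expect_equal(treated_rates(ps3, "pd")[["lambda1"]], 0.3237 * 0.97)

  ps4 <- param_set(ps, "economics.discount_rate", 0)
  expect_equal(ps4$economics$discount_rate, 0)
})
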