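test_that("the analytic sample size matches its closed form", {
  expect_equal(analytic_sample_size(0.6, 0.6, 0.1, 0.025, 0.8), 377L)
  expect_equal(analytic_sample_size(0.6, 0.6, 0.1, 0.025, 0.5), 185L)
  expect_error(analytic_sample_size(0.6, 0.6, 0, 0.025, 0.8), "margin")
  expect_error(analytic_sample_size(0.4, 0.6, 0.1, 0.025, 0.8),
               "not attainable")
  # boundary design (difference exactly at the margin) is unwinnable too,
  # including when floating point makes margin + delta a hair above zero
  expect_error(analytic_sample_size(0.5, 0.6, 0.1, 0.025, 0.8),
               "not attainable")
  expect_error(analytic_sample_size(0.6, 0.6, 0.1, 0.025, 1), "power")
})

test_that("analytic and simulated power agree under full adherence", {
  full <- scenario_spec()
  grid <- expand.grid(n = c(200, 400, 800), eff_E = c(0.6, 0.55))
  for (i in seq_len(nrow(grid))) {
    d <- trial_design(grid$n[i], grid$eff_E[i], 0.6, margin = 0.1)
    pr <- simulated_power(d, full, R = 4000, seed = 50 + i)
    oracle <- claim_probability_oracle(d$eff_experimental, d$eff_control,
                                      d$n_per_arm, d$margin)
    expect_lt(abs(pr$power - oracle), 3 * pr$mc_std_error + 0.003)
  }
})

test_that("simulated power increases with the sample size", {
  full <- scenario_spec()
  small <- simulated_power(trial_design(50, 0.6, 0.6, 0.1), full,
                           R = 2000, seed = 1)
  large <- simulated_power(trial_design(400, 0.6, 0.6, 0.1), full,
                           R = 2000, seed = 2)
  expect_lt(small$power, large$power)
  expect_error(simulated_power(trial_design(50, 0.6, 0.6, 0.1), full, R = 50),
               "at least 100")
})

test_that("required_n returns the analytic value under full adherence", {
  d <- trial_design(100, 0.6, 0.6, margin = 0.1)
  expect_equal(required_n(d, scenario_spec(), power_target = 0.8), 377L)
  expect_error(required_n(d, scenario_spec(), power_target = 1), "unreachable")
})

test_that("required_n is non-increasing in the margin", {
  d10 <- trial_design(100, 0.6, 0.6, margin = 0.1)
  d15 <- trial_design(100, 0.6, 0.6, margin = 0.15)
  expect_gte(required_n(d10, scenario_spec(), 0.8),
             required_n(d15, scenario_spec(), 0.8))
})

test_that("crossover dilution lowers the apparent sample-size requirement", {
  # the paper's central hazard: dilution moves the observed difference
  # towards zero, so the trial seems to need fewer participants
  d <- trial_design(100, 0.55, 0.60, margin = 0.1)
  sc <- scenario_spec(c("experimental", "control"), "crossover",
                      adherence = c(experimental = 0.75, control = 0.75))
  n_full <- required_n(d, scenario_spec(), power_target = 0.8)
  n_diluted <- required_n(d, sc, power_target = 0.8, R = 1500, seed = 5)
  expect_equal(n_full, 1531L)
  expect_lt(n_diluted, n_full)
})
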