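test_that("outcome model without confounders is the constant efficacy", {
  d <- trial_design(100, 0.6, 0.6, margin = 0.1)
  om <- calibrate_outcome_model(d, list())
  expect_equal(om$prob("experimental", data.frame(row = 1:5)), rep(0.6, 5))
  expect_equal(om$prob("control", data.frame(row = 1:5)), rep(0.6, 5))
})

test_that("mean-centring keeps the marginal efficacy exact", {
  d <- trial_design(100, 0.5, 0.6, margin = 0.1)
  sev <- confounder_spec("severity", "uniform01", outcome_coefficient = 0.2)
  om <- calibrate_outcome_model(d, list(sev))
  expect_equal(om$prob("experimental", data.frame(severity = 0.25)), 0.45)
  # marginal over the uniform distribution equals the design efficacy
  marg <- integrate(function(x) om$prob("experimental", data.frame(severity = x)),
                    0, 1)$value
  expect_equal(marg, 0.5, tolerance = 1e-9)
})

test_that("coefficients pushing probabilities outside [0,1] are rejected", {
  d <- trial_design(100, 0.6, 0.6, margin = 0.1)
  sev <- confounder_spec("severity", "uniform01", outcome_coefficient = 1.5)
  expect_error(calibrate_outcome_model(d, list(sev)),
               "outcome model invalid.*'experimental'")
  # one-sided violation names the crossed bound
  hi <- confounder_spec("severity", "uniform01", outcome_coefficient = 0.6)
  expect_error(
    calibrate_outcome_model(trial_design(100, 0.8, 0.5, 0.1), list(hi)),
    "'experimental' exceeds 1"
  )
})

test_that("adherence intercept is the exact logit when no confounder acts", {
  sc <- scenario_spec("experimental", "crossover",
                      adherence = c(experimental = 0.75, control = 1))
  am <- calibrate_adherence_model(sc, "experimental")
  expect_equal(am$intercept, qlogis(0.75), tolerance = 1e-9)
  expect_equal(am$intercept, 1.098612, tolerance = 1e-6)
})

test_that("full adherence bypasses the logistic model", {
  sc <- scenario_spec()
  am <- calibrate_adherence_model(sc, "control")
  expect_equal(am$prob(data.frame(severity = c(0, 0.5, 1))), rep(1, 3))
})

test_that("calibrated marginal adherence matches numeric integration", {
  sev <- confounder_spec("severity", "uniform01",
                         adherence_coefficients = c(experimental = 1, control = 0))
  sc <- scenario_spec("experimental", "crossover",
                      adherence = c(experimental = 0.75, control = 1),
                      confounders = list(sev))
  am <- calibrate_adherence_model(sc, "experimental")
  marg <- integrate(function(x) plogis(am$intercept + 1 * (x - 0.5)), 0, 1,
                    rel.tol = 1e-10)$value
  expect_equal(marg, 0.75, tolerance = 1e-6)
})

test_that("every catalogued preset is calibrated on both margins", {
  d <- catalogue_design()
  grid01 <- seq(0.0005, 0.9995, by = 0.001)   # midpoint rule, 1000 cells
  for (row in table1_rows()) {
    sc <- table1_scenario(row, d)
    om <- calibrate_outcome_model(d, sc$confounders, sc$alternative_efficacy)
    if (length(sc$confounders)) {
      # marginal efficacy under each treatment
      for (tr in names(om$efficacies)) {
        marg <- mean(om$prob(tr, data.frame(severity = grid01)))
        expect_equal(marg, unname(om$efficacies[tr]), tolerance = 1e-3)
      }
    }
    for (arm in sc$nonadherent_arms) {
      am <- calibrate_adherence_model(sc, arm)
      marg <- mean(am$prob(data.frame(severity = grid01)))
      expect_equal(marg, 0.75, tolerance = 1e-4)
    }
  }
  # worked example: two confounders, enumerate doctor x severity grid
  sc <- worked_example_scenario()
  dwe <- worked_example_design()
  om <- calibrate_outcome_model(dwe, sc$confounders)
  X <- expand.grid(severity = grid01, doctor = c(0, 1))
  for (tr in c("experimental", "control")) {
    expect_equal(mean(om$prob(tr, X)), unname(om$efficacies[tr]),
                 tolerance = 1e-3)
  }
  for (arm in c("experimental", "control")) {
    am <- calibrate_adherence_model(sc, arm)
    expect_equal(mean(am$prob(X)), 0.75, tolerance = 1e-4)
  }
})
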