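test_that("the claim-probability oracle matches its closed form", {
  # at the boundary (true difference = -margin) the probability is alpha
  expect_equal(claim_probability_oracle(0.5, 0.6, 400, 0.1), 0.025,
               tolerance = 1e-7)
  # 10% symmetric crossover mixture
  expect_equal(claim_probability_oracle(0.51, 0.59, 400, 0.1), 0.0823279,
               tolerance = 1e-6)
  # consistency: a truly non-inferior difference is detected almost surely
  expect_gt(claim_probability_oracle(0.55, 0.6, 1e7, 0.1), 0.999)
  expect_error(claim_probability_oracle(0, 0.6, 400, 0.1), "inside")
})

test_that("run_oc validates its inputs", {
  d <- catalogue_design()
  expect_error(run_oc(d, scenario_spec(), R = 0), "at least 1")
  # an IV request on an alternative-destination scenario fails in every
  # replicate and is reported rather than silently dropped
  sc <- table1_scenario("both/inferior/nonconfounded", catalogue_design(50))
  expect_error(run_oc(catalogue_design(50), sc, methods = "IV", R = 20, seed = 1),
               "failed")
})

test_that("run_oc is deterministic given the master seed", {
  d <- catalogue_design(100)
  sc <- table1_scenario("both/crossover/nonconfounded", d)
  expect_identical(run_oc(d, sc, methods = c("ITT", "PP"), R = 500, seed = 8),
                   run_oc(d, sc, methods = c("ITT", "PP"), R = 500, seed = 8))
  scc <- table1_scenario("both/crossover/confounded-increase", d)
  expect_identical(run_oc(d, scc, methods = "PP", R = 50, seed = 8),
                   run_oc(d, scc, methods = "PP", R = 50, seed = 8))
})

test_that("binomial shortcut and participant-level paths agree", {
  d <- catalogue_design(200)
  sc <- scenario_spec(c("experimental", "control"), "crossover",
                      adherence = c(experimental = 0.9, control = 0.9),
                      id = "x10")
  fast <- run_oc(d, sc, methods = c("ITT", "PP"), R = 4000, seed = 21)
  slow <- run_oc(d, sc, methods = c("ITT", "PP"), R = 2000, seed = 22,
                 use_shortcut = FALSE)
  for (m in c("ITT", "PP")) {
    f <- fast[fast$method == m, ]; s <- slow[slow$method == m, ]
    tol_p <- 3 * sqrt(f$mc_std_error^2 + s$mc_std_error^2)
    expect_lt(abs(f$prob_claim_ni - s$prob_claim_ni), tol_p)
    tol_m <- 3 * sqrt(f$sd_estimate^2 / f$replicates +
                      s$sd_estimate^2 / s$replicates)
    expect_lt(abs(f$mean_estimate - s$mean_estimate), tol_m)
  }
})

test_that("claim probability rises monotonically as adherence falls", {
  # truly inferior by exactly the margin; symmetric crossover dilutes the
  # difference towards zero, inflating the false non-inferiority claims
  d <- catalogue_design()
  grid <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
  probs <- ses <- numeric(length(grid))
  for (i in seq_along(grid)) {
    a <- grid[i]
    sc <- if (a == 1) scenario_spec() else
      scenario_spec(c("experimental", "control"), "crossover",
                    adherence = c(experimental = a, control = a))
    oc <- run_oc(d, sc, methods = "ITT", R = 4000, seed = 100 + i)
    probs[i] <- oc$prob_claim_ni; ses[i] <- oc$mc_std_error
  }
  for (i in seq_len(length(grid) - 1)) {
    expect_gt(probs[i + 1] - probs[i],
              -3 * sqrt(ses[i]^2 + ses[i + 1]^2))
  }
  # and the trend is genuinely increasing overall
  expect_gt(probs[length(grid)], probs[1])
})

test_that("direction labelling is 'same' within the Monte-Carlo tolerance", {
  expect_equal(niadhere:::label_prob(0.025, 0.002, 0.026, 0.002), "same")
  expect_equal(niadhere:::label_prob(0.1, 0.002, 0.025, 0.002), "higher")
  expect_equal(niadhere:::label_prob(0.004, 0.002, 0.025, 0.002), "lower")
  expect_equal(niadhere:::label_estimate(-0.05, 0.03, -0.1, 0.03, 5000),
               "towards_0")
  expect_equal(niadhere:::label_estimate(-0.15, 0.03, -0.1, 0.03, 5000),
               "higher")
})

test_that("direction_matrix recovers a known row at small R", {
  d <- catalogue_design()
  dm <- direction_matrix(d, row_ids = "both/crossover/nonconfounded",
                         R = 2000, seed = 6)
  expect_equal(dm$prob_label[dm$method == "ITT"], "higher")
  expect_equal(dm$estimate_label[dm$method == "ITT"], "towards_0")
  expect_equal(dm$prob_label[dm$method == "PP"], "same")
  expect_error(direction_matrix(d, row_ids = "nope", R = 10), "valid")
})
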