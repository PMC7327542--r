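test_that("the non-inferiority decision rule is strict on both scales", {
  # the worked example's published-style interval on the harm scale
  expect_false(ni_decision(0.114, 0.032, 0.195, margin = 0.10, polarity = "harm"))
  # boundary: CI bound exactly at the margin is not enough
  expect_false(ni_decision(0, -0.10, 0.05, margin = 0.10, polarity = "success"))
  expect_true(ni_decision(0, -0.01, 0.01, margin = 0.10, polarity = "success"))
  expect_error(ni_decision(0, -0.01, 0.01, margin = 0), "positive")
  # equivalence of the two scales by negation
  expect_equal(ni_decision(0.05, 0.01, 0.09, 0.1, "harm"),
               ni_decision(-0.05, -0.09, -0.01, 0.1, "success"))
})

test_that("ITT is the plain difference of assigned-arm proportions", {
  res <- itt_estimate(toy_adherent_table(), toy_design())
  expect_equal(res$estimate, -0.25)
  expect_equal(res$n_analyzed, 8L)
  empty <- make_table("experimental", "experimental", 1)
  expect_error(itt_estimate(empty, toy_design()), "non-empty")
})

test_that("PP restricts to adherent rows", {
  tab <- make_table(
    assigned = rep(c("experimental", "control"), each = 4),
    received = c("experimental", "experimental", "experimental", "control",
                 "control", "control", "control", "experimental"),
    outcome = c(1, 1, 0, 0, 1, 1, 1, 0)
  )
  res <- pp_estimate(tab, toy_design())
  expect_equal(res$n_analyzed, 6L)
  expect_equal(res$estimate, 2 / 3 - 1)
  # an arm with fewer than 2 adherent participants errors
  tab$received[1:3] <- "control"
  expect_error(pp_estimate(tab, toy_design()), "at least 2")
})

test_that("all methods coincide at full adherence and IV equals ITT exactly", {
  d <- trial_design(300, 0.5, 0.6, margin = 0.1)
  tab <- simulate_cohort(d, scenario_spec(), seed = 17)
  itt <- itt_estimate(tab, d)
  pp <- pp_estimate(tab, d)
  ipw <- ipw_estimate(tab, d, bootstrap_reps = 0)
  std <- standardisation_estimate(tab, d, strata_definition = character(0),
                                  bootstrap_reps = 0)
  iv <- iv_estimate(tab, d)
  expect_identical(pp$estimate, itt$estimate)
  expect_identical(ipw$estimate, itt$estimate)
  expect_equal(std$estimate, itt$estimate)
  expect_identical(iv$estimate, itt$estimate)
  expect_equal(iv$std_error, itt$std_error)
})

test_that("constant adherence probabilities leave the Hajek estimate at PP", {
  # non-adherence with no recorded confounders: intercept-only weight model
  d <- trial_design(200, 0.5, 0.6, margin = 0.1)
  sc <- scenario_spec(c("experimental", "control"), "crossover",
                      adherence = c(experimental = 0.7, control = 0.7))
  tab <- simulate_cohort(d, sc, seed = 29)
  ipw <- ipw_estimate(tab, d, bootstrap_reps = 0)
  pp <- pp_estimate(tab, d)
  expect_equal(ipw$estimate, pp$estimate, tolerance = 1e-12)
})

test_that("IPW removes confounding that biases the naive PP analysis", {
  d <- trial_design(4000, 0.5, 0.4, margin = 0.1, outcome_polarity = "harm")
  tab <- simulate_cohort(d, worked_example_scenario(), seed = 41)
  ipw <- ipw_estimate(tab, d, bootstrap_reps = 0)
  pp <- pp_estimate(tab, d)
  expect_lt(abs(ipw$estimate - (-0.1)), abs(pp$estimate - (-0.1)))
})

test_that("standardisation averages stratum risks by cohort shares", {
  # two strata, 50% of the cohort each:
  # stratum 0: E 8/10 vs C 6/10; stratum 1: E 2/10 vs C 4/10 -> difference 0
  tab <- make_table(
    assigned = rep(rep(c("experimental", "control"), each = 10), 2),
    received = rep(rep(c("experimental", "control"), each = 10), 2),
    outcome = c(rep(1, 8), 0, 0, rep(1, 6), rep(0, 4),
                1, 1, rep(0, 8), rep(1, 4), rep(0, 6)),
    g = rep(c(0, 1), each = 20)
  )
  d <- trial_design(20, 0.5, 0.5, margin = 0.2)
  res <- standardisation_estimate(tab, d, strata_definition = "g",
                                  bootstrap_reps = 0)
  expect_equal(res$estimate, 0)
})

test_that("a single stratum reproduces the PP estimate", {
  tab <- toy_adherent_table()
  tab$g <- 0
  d <- toy_design()
  res <- standardisation_estimate(tab, d, strata_definition = "g",
                                  bootstrap_reps = 0)
  expect_equal(res$estimate, pp_estimate(tab, d)$estimate)
})

test_that("an empty stratum-arm cell is reported by name", {
  tab <- make_table(
    assigned = rep(c("experimental", "control"), each = 4),
    received = rep(c("experimental", "control"), each = 4),
    outcome = rep(c(1, 0), 4),
    g = c(0, 0, 1, 1, 0, 0, 0, 0)   # stratum 1 has no control participants
  )
  d <- toy_design()
  expect_error(standardisation_estimate(tab, d, "g", bootstrap_reps = 0),
               "no adherent participants in the control arm")
})

test_that("the IV estimate is the Wald ratio of ITT over the first stage", {
  # ITT difference 0.10, first stage 0.60 -> 0.166667
  tab <- make_table(
    assigned = rep(c("experimental", "control"), each = 10),
    received = c(rep("experimental", 8), rep("control", 2),
                 rep("experimental", 2), rep("control", 8)),
    outcome = c(rep(1, 6), rep(0, 4), rep(1, 5), rep(0, 5))
  )
  d <- trial_design(10, 0.5, 0.5, margin = 0.2)
  res <- iv_estimate(tab, d)
  expect_equal(res$estimate, 0.1666667, tolerance = 1e-6)
  expect_equal(res$diagnostics$first_stage, 0.6)
})

test_that("IV rejects non-trial treatments and weak instruments", {
  d <- catalogue_design(100)
  sc <- table1_scenario("both/inferior/nonconfounded", d)
  tab <- simulate_cohort(d, sc, seed = 2)
  expect_error(iv_estimate(tab, d), "alternative")

  weak <- make_table(
    assigned = rep(c("experimental", "control"), each = 4),
    received = rep(c("experimental", "control"), 4),
    outcome = rep(c(1, 0), 4)
  )
  expect_error(iv_estimate(weak, trial_design(4, 0.5, 0.5, 0.2)),
               "weak instrument")
})

test_that("IV is less precise than ITT whenever the first stage is below 1", {
  d <- worked_example_design()
  tab <- worked_example_cohort(seed = 13)
  expect_gt(iv_estimate(tab, d)$std_error, itt_estimate(tab, d)$std_error)
})

test_that("bootstrap intervals are reproducible and contain the estimate", {
  d <- worked_example_design()
  tab <- worked_example_cohort(seed = 19)
  a <- ipw_estimate(tab, d, bootstrap_reps = 200, seed = 99)
  b <- ipw_estimate(tab, d, bootstrap_reps = 200, seed = 99)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  for (r in list(a, itt_estimate(tab, d), pp_estimate(tab, d),
                 iv_estimate(tab, d))) {
    expect_lte(r$ci_low, r$estimate)
    expect_gte(r$ci_high, r$estimate)
    expect_gte(r$estimate, -1)
    expect_lte(r$estimate, 1)
  }
  # weight diagnostics are coherent
  expect_lte(a$diagnostics$effective_sample_size, a$n_analyzed)
  expect_gte(a$diagnostics$min_weight, 1)
})

test_that("confidence intervals shrink as the cohort grows", {
  sc <- worked_example_scenario()
  widths <- vapply(c(400, 800, 1600), function(n) {
    d <- trial_design(n, 0.5, 0.4, margin = 0.1, outcome_polarity = "harm")
    r <- itt_estimate(simulate_cohort(d, sc, seed = 7), d)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("complete separation in the adherence model is reported", {
  set.seed(4)
  x <- c(runif(50, 0, 0.45), runif(50, 0.55, 1))
  tab <- make_table(
    assigned = rep(c("experimental", "control"), 50),
    received = ifelse(x < 0.5, rep(c("experimental", "control"), 50),
                      rep(c("control", "experimental"), 50)),
    outcome = rbinom(100, 1, 0.5),
    severity = x
  )
  d <- trial_design(50, 0.5, 0.5, margin = 0.2)
  expect_error(ipw_estimate(tab, d, bootstrap_reps = 0),
               "separation|converge")
})
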