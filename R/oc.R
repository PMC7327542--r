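# Monte-Carlo operating characteristics: probability of claiming
# non-inferiority, mean and spread of the estimate, per scenario and method.

# vectorised arm-level shortcut for non-confounded scenarios: draws the arm
# success counts directly from the mixture probability instead of simulating
# participants (valid because, without confounders, outcomes within an
# assigned arm are iid Bernoulli with the mixture probability)
oc_shortcut <- function(design, scenario, method, R) {
  n <- design$n_per_arm
  z <- z_quantile(design$alpha_one_sided)
  if (method == "ITT") {
    e <- expected_arm_efficacy(design, scenario)
    m_e <- rep(n, R); m_c <- rep(n, R)
    y_e <- stats::rbinom(R, n, e[["experimental"]])
    y_c <- stats::rbinom(R, n, e[["control"]])
  } else { # PP: adherent counts are binomial, adherent outcomes keep the
           # assigned treatment's efficacy when non-adherence is unconfounded
    a <- scenario$adherence
    m_e <- stats::rbinom(R, n, a[["experimental"]])
    m_c <- stats::rbinom(R, n, a[["control"]])
    m_e <- pmax(m_e, 2L); m_c <- pmax(m_c, 2L)
    y_e <- stats::rbinom(R, m_e, design$eff_experimental)
    y_c <- stats::rbinom(R, m_c, design$eff_control)
  }
  p_e <- y_e / m_e; p_c <- y_c / m_c
  v_e <- ifelse(p_e %in% c(0, 1),
                ((y_e + 0.5) / (m_e + 1)) * (1 - (y_e + 0.5) / (m_e + 1)) / m_e,
                p_e * (1 - p_e) / m_e)
  v_c <- ifelse(p_c %in% c(0, 1),
                ((y_c + 0.5) / (m_c + 1)) * (1 - (y_c + 0.5) / (m_c + 1)) / m_c,
                p_c * (1 - p_c) / m_c)
  est <- p_e - p_c
  claim <- est - z * sqrt(v_e + v_c) > -design$margin
  list(estimates = est, claims = claim, n_failed = 0L)
}

# one shared cohort stream, every requested method applied to each cohort
oc_participant <- function(design, scenario, methods, R, seed, bootstrap_reps) {
  gen <- make_cohort_generator(design, scenario)
  funs <- lapply(methods, function(method) switch(method,
    ITT = function(t, i) itt_estimate(t, design),
    PP  = function(t, i) pp_estimate(t, design),
    IPW = function(t, i) ipw_estimate(t, design, bootstrap_reps,
                                      seed = derive_seed(seed, 500000L + i)),
    STD = function(t, i) standardisation_estimate(t, design,
                                                  bootstrap_reps = bootstrap_reps,
                                                  seed = derive_seed(seed, 600000L + i)),
    IV  = function(t, i) iv_estimate(t, design),
    stop("unknown method '", method, "'", call. = FALSE)))
  names(funs) <- methods
  est <- matrix(NA_real_, nrow = R, ncol = length(methods),
                dimnames = list(NULL, methods))
  claim <- matrix(NA, nrow = R, ncol = length(methods),
                  dimnames = list(NULL, methods))
  for (i in seq_len(R)) {
    tab <- gen(seed = derive_seed(seed, i))
    for (m in methods) {
      res <- tryCatch(funs[[m]](tab, i), error = function(e) NULL)
      if (!is.null(res)) {
        est[i, m] <- res$estimate
        claim[i, m] <- res$ni_claimed
      }
    }
  }
  lapply(stats::setNames(methods, methods), function(m) {
    ok <- !is.na(est[, m])
    list(estimates = est[ok, m], claims = claim[ok, m], n_failed = sum(!ok))
  })
}

#' Monte-Carlo operating characteristics of a scenario
#'
#' Simulates \code{R} independent trial cohorts under the scenario, applies
#' each analysis method, and returns the probability of claiming
#' non-inferiority, its Monte-Carlo standard error, and the mean and
#' standard deviation of the estimate.  For non-confounded scenarios the
#' intention-to-treat and per-protocol analyses use a fast arm-level
#' binomial shortcut (success counts drawn directly from the mixture
#' probability), which is cross-validated against the participant-level path
#' in the test suite.  Replicate seeds are derived from \code{seed} by a
#' counter scheme, so every scenario is reproducible independently of
#' execution order.
#'
#' @param design a \code{\link{trial_design}}.
#' @param scenario a \code{\link{scenario_spec}}.
#' @param methods subset of \code{c("ITT", "PP", "IPW", "STD", "IV")}.
#' @param R number of simulation replicates (>= 1).
#' @param seed master seed.
#' @param bootstrap_reps bootstrap replicates used by IPW/STD inside each
#'   simulation replicate (kept small by default; the claim probability of
#'   the weighted methods is bootstrap-based).
#' @param use_shortcut set \code{FALSE} to force the participant-level path.
#' @return A data frame with one row per method: \code{scenario_id},
#'   \code{method}, \code{replicates}, \code{prob_claim_ni},
#'   \code{mc_std_error}, \code{mean_estimate}, \code{sd_estimate},
#'   \code{n_failed}.
#' @examples
#' d <- trial_design(400, 0.5, 0.6, margin = 0.1)
#' full <- scenario_spec()
#' run_oc(d, full, methods = "ITT", R = 2000, seed = 1)
#' @export
run_oc <- function(design, scenario, methods = c("ITT", "PP"), R, seed = 1L,
                   bootstrap_reps = 200, use_shortcut = TRUE) {
  if (R < 1) stop("`R` must be at least 1", call. = FALSE)
  methods <- match.arg(methods, c("ITT", "PP", "IPW", "STD", "IV"),
                       several.ok = TRUE)
  validate_scenario(design, scenario)
  nonconf <- length(scenario$confounders) == 0
  sc_methods <- if (nonconf && use_shortcut) intersect(methods, c("ITT", "PP"))
                else character(0)
  pl_methods <- setdiff(methods, sc_methods)

  results <- list()
  for (method in sc_methods) {
    k <- match(method, methods)
    results[[method]] <- with_seed(derive_seed(seed, 100000L * k),
                                   oc_shortcut(design, scenario, method, R))
  }
  if (length(pl_methods)) {
    results <- c(results, oc_participant(design, scenario, pl_methods, R,
                                         derive_seed(seed, 900000L),
                                         bootstrap_reps))
  }

  rows <- lapply(methods, function(method) {
    res <- results[[method]]
    if (res$n_failed >= 0.01 * R) {
      stop(sprintf("method %s failed in %d of %d replicates (>= 1%%)",
                   method, res$n_failed, R), call. = FALSE)
    }
    p <- mean(res$claims)
    data.frame(
      scenario_id = scenario$id %||% NA_character_,
      method = method,
      replicates = R,
      prob_claim_ni = p,
      mc_std_error = sqrt(p * (1 - p) / length(res$claims)),
      mean_estimate = mean(res$estimates),
      sd_estimate = stats::sd(res$estimates),
      n_failed = res$n_failed,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Closed-form oracle for the probability of claiming non-inferiority
#'
#' Normal-approximation twin of the Wald decision rule for the arm-level
#' binomial model: returns
#' \eqn{\Phi\left((\Delta + m)/se - z_{1-\alpha}\right)} where
#' \eqn{\Delta} is the expected efficacy difference, \eqn{m} the margin and
#' \eqn{se = \sqrt{e_E(1-e_E)/n + e_C(1-e_C)/n}}.  Exact for the arm-level
#' binomial model up to the normal approximation.
#'
#' @param expected_eff_E,expected_eff_C expected marginal efficacy of each
#'   assigned arm (mixture probabilities under non-adherence), in (0, 1).
#' @param n_per_arm per-arm sample size.
#' @param margin non-inferiority margin.
#' @param alpha one-sided type-I error level.
#' @return Probability of claiming non-inferiority.
#' @examples
#' claim_probability_oracle(0.5, 0.6, 400, 0.1)    # boundary: 0.025
#' claim_probability_oracle(0.51, 0.59, 400, 0.1)  # 10% crossover: ~0.082
#' @export
claim_probability_oracle <- function(expected_eff_E, expected_eff_C,
                                     n_per_arm, margin, alpha = 0.025) {
  for (e in c(expected_eff_E, expected_eff_C)) {
    if (e <= 0 || e >= 1) {
      stop("expected efficacies must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  se <- sqrt(expected_eff_E * (1 - expected_eff_E) / n_per_arm +
             expected_eff_C * (1 - expected_eff_C) / n_per_arm)
  delta <- expected_eff_E - expected_eff_C
  stats::pnorm((delta + margin) / se - z_quantile(alpha))
}

label_prob <- function(p_row, se_row, p_base, se_base) {
  tol <- 3 * sqrt(se_row^2 + se_base^2)
  d <- p_row - p_base
  if (abs(d) <= tol) "same" else if (d > 0) "higher" else "lower"
}

label_estimate <- function(m_row, sd_row, m_base, sd_base, R) {
  tol <- 3 * sqrt(sd_row^2 / R + sd_base^2 / R)
  d <- m_row - m_base
  if (abs(d) <= tol) return("same")
  if (abs(m_row) < abs(m_base)) "towards_0"
  else if (m_row < m_base) "higher"   # larger efficacy deficit
  else "lower"
}

#' Direction labels of the catalogued scenarios against full adherence
#'
#' Runs the operating characteristics of each catalogued scenario (see
#' \code{\link{table1_rows}}) and labels the shift of the mean estimate and
#' the probability of claiming non-inferiority against a 100\%-adherence
#' baseline: \code{"same"} within a tolerance of 3 pooled Monte-Carlo
#' standard errors, otherwise \code{"higher"}, \code{"lower"} or (estimates
#' only) \code{"towards_0"}.  The probability labels are the primary
#' operating characteristic; the estimate labels are informational, since a
#' mean shift may be both "towards 0" and "higher than the true deficit"
#' depending on the reference point.
#'
#' @param design a \code{\link{trial_design}} (the catalogued rows presume a
#'   true efficacy difference of -margin, e.g. efficacies 0.5 vs 0.6 with a
#'   10\% margin).
#' @param row_ids identifiers from \code{\link{table1_rows}}.
#' @param R simulation replicates per scenario and for the baseline.
#' @param seed master seed.
#' @param methods analysis methods to label.
#' @return A data frame with one row per scenario and method, holding the
#'   mean estimate, claim probability, their baseline values and the two
#'   labels.
#' @export
direction_matrix <- function(design, row_ids = table1_rows(), R = 5000,
                             seed = 1L, methods = c("ITT", "PP")) {
  base_sc <- scenario_spec(id = "baseline-full-adherence")
  base <- run_oc(design, base_sc, methods = methods, R = R,
                 seed = derive_seed(seed, 0L))
  out <- list()
  for (j in seq_along(row_ids)) {
    row <- row_ids[j]
    sc <- table1_scenario(row, design)
    oc <- run_oc(design, sc, methods = methods, R = R,
                 seed = derive_seed(seed, j * 1000L))
    for (m in methods) {
      b <- base[base$method == m, ]
      r <- oc[oc$method == m, ]
      out[[length(out) + 1L]] <- data.frame(
        row = row, method = m,
        mean_estimate = r$mean_estimate,
        baseline_estimate = b$mean_estimate,
        estimate_label = label_estimate(r$mean_estimate, r$sd_estimate,
                                        b$mean_estimate, b$sd_estimate, R),
        prob_claim_ni = r$prob_claim_ni,
        baseline_prob = b$prob_claim_ni,
        prob_label = label_prob(r$prob_claim_ni, r$mc_std_error,
                                b$prob_claim_ni, b$mc_std_error),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
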