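# Analytic and simulation-based power / sample-size calculation for
# non-inferiority designs with binary outcomes.

#' Analytic per-arm sample size for a non-inferiority trial
#'
#' Normal-approximation sample size for the Wald risk-difference test:
#' \deqn{n = \lceil (z_{1-\alpha} + z_{\mathrm{power}})^2
#'   \{p_E(1-p_E) + p_C(1-p_C)\} / (m + p_E - p_C)^2 \rceil}
#' per arm, without continuity correction (matching the Wald test used by
#' the estimators).
#'
#' @param eff_E,eff_C true success probabilities of the experimental and
#'   control treatment.
#' @param margin non-inferiority margin (absolute difference).
#' @param alpha one-sided type-I error level.
#' @param power target power.
#' @return Required participants per arm (integer).
#' @examples
#' analytic_sample_size(0.6, 0.6, 0.1, 0.025, 0.8)  # 377 per arm, 754 total
#' @export
analytic_sample_size <- function(eff_E, eff_C, margin, alpha = 0.025,
                                 power = 0.8) {
  if (margin + (eff_E - eff_C) <= 1e-12) {
    stop("margin not attainable: margin + (eff_E - eff_C) must be positive",
         call. = FALSE)
  }
  if (power <= 0 || power >= 1) {
    stop("`power` must lie strictly inside (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha) + stats::qnorm(power)
  v <- eff_E * (1 - eff_E) + eff_C * (1 - eff_C)
  as.integer(ceiling(z^2 * v / (margin + eff_E - eff_C)^2))
}

#' Simulated power under a non-adherence scenario
#'
#' Monte-Carlo power of the chosen analysis method under the design and
#' scenario: the probability of claiming non-inferiority, which is the power
#' when the true difference lies inside the margin (and the type-I error
#' when it lies on or beyond it).
#'
#' @param design a \code{\link{trial_design}}.
#' @param scenario a \code{\link{scenario_spec}}.
#' @param method analysis method (default intention-to-treat).
#' @param R simulation replicates (>= 100).
#' @param seed master seed.
#' @param ... passed to \code{\link{run_oc}}.
#' @return An object of class \code{power_result}: mode, n_per_arm, power,
#'   Monte-Carlo standard error and the settings used.
#' @export
simulated_power <- function(design, scenario, method = "ITT", R = 2000,
                            seed = 1L, ...) {
  if (R < 100) stop("`R` must be at least 100", call. = FALSE)
  oc <- run_oc(design, scenario, methods = method, R = R, seed = seed, ...)
  structure(
    list(mode = "simulated", n_per_arm = design$n_per_arm,
         power = oc$prob_claim_ni, mc_std_error = oc$mc_std_error,
         method = method, replicates = R, seed = seed,
         design = design, scenario = scenario),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s power: %.3f%s at n = %d per arm%s\n",
              x$mode, x$power,
              if (!is.null(x$mc_std_error) && is.finite(x$mc_std_error))
                sprintf(" (MC se %.4f)", x$mc_std_error) else "",
              x$n_per_arm,
              if (x$mode == "simulated") sprintf(" [%s, R = %d]", x$method, x$replicates)
              else ""))
  invisible(x)
}

power_at_n <- function(design, scenario, n, method, R, seed, ...) {
  d <- design
  d$n_per_arm <- as.integer(n)
  simulated_power(d, scenario, method = method, R = R, seed = seed, ...)
}

#' Smallest per-arm sample size reaching a target power
#'
#' Under full adherence the analytic formula is returned directly.
#' Otherwise the simulated power of the chosen method is bracketed by
#' doubling and the smallest \code{n_per_arm} whose simulated power reaches
#' \code{power_target} minus one Monte-Carlo standard error is found by
#' bisection (power is monotone in n for all supported scenarios).
#'
#' @inheritParams simulated_power
#' @param power_target target power in (0, 1).
#' @return An integer per-arm sample size.
#' @export
required_n <- function(design, scenario, power_target = 0.8, R = 2000,
                       seed = 1L, method = "ITT", ...) {
  if (power_target <= 0 || power_target >= 1) {
    stop("`power_target` must lie strictly inside (0, 1) ",
         "(a target of exactly 1 is unreachable)", call. = FALSE)
  }
  if (is_full_adherence(scenario)) {
    return(analytic_sample_size(design$eff_experimental, design$eff_control,
                                design$margin, design$alpha_one_sided,
                                power_target))
  }
  reaches <- function(n) {
    pr <- power_at_n(design, scenario, n, method, R, derive_seed(seed, n), ...)
    pr$power >= power_target - pr$mc_std_error
  }
  # bracket by doubling from the analytic size at the diluted efficacies
  e <- expected_arm_efficacy(design, scenario)
  lo <- 2L
  hi <- tryCatch(
    analytic_sample_size(e[["experimental"]], e[["control"]], design$margin,
                         design$alpha_one_sided, power_target),
    error = function(e) 64L
  )
  while (!reaches(hi)) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e6) stop("bracket exhausted: no n <= 1e6 reaches the target power",
                       call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (reaches(mid)) hi <- mid else lo <- mid
  }
  hi
}
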