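# Calibration of the outcome and adherence models.
#
# Outcome model: linear on the risk scale with mean-centred confounders,
#   pi_t(X) = eff_t + sum_j gamma_j (X_j - E[X_j]),
# so the marginal success probability under every treatment equals the
# design efficacy exactly.  Adherence model: logistic in the mean-centred
# confounders with the intercept chosen by root-finding so the marginal
# adherence hits the scenario target.

# deterministic quadrature grid over the joint confounder distribution:
# Gauss-Legendre nodes for uniform01 components, exact enumeration for
# bernoulli components (confounders are independent)
confounder_grid <- function(confounders, n_nodes = 64) {
  if (length(confounders) == 0) {
    return(list(nodes = matrix(numeric(0), nrow = 1), weights = 1))
  }
  parts <- lapply(confounders, function(cf) {
    if (cf$distribution == "uniform01") {
      gl <- pracma::gaussLegendre(n_nodes, 0, 1)
      list(x = gl$x, w = gl$w)
    } else {
      list(x = c(0, 1), w = c(1 - cf$prob, cf$prob))
    }
  })
  grids <- expand.grid(lapply(parts, `[[`, "x"))
  wgrid <- expand.grid(lapply(parts, `[[`, "w"))
  nodes <- as.matrix(grids)
  colnames(nodes) <- vapply(confounders, `[[`, character(1), "name")
  list(nodes = nodes, weights = apply(as.matrix(wgrid), 1, prod))
}

#' Calibrate the outcome model for a design and confounder set
#'
#' Builds per-treatment success-probability functions
#' \eqn{\pi_t(X) = \mathrm{eff}_t + \sum_j \gamma_j (X_j - E[X_j])} and
#' validates that every attainable confounder value keeps every treatment's
#' probability inside [0, 1].  Because the confounders are mean-centred, the
#' marginal success probability under each treatment equals the design
#' efficacy exactly, with no recalibration.
#'
#' @param design a \code{\link{trial_design}}.
#' @param confounders list of \code{\link{confounder_spec}} objects.
#' @param alternative_efficacy optional efficacy of a non-trial alternative
#'   treatment, validated and included as treatment \code{"alternative"}.
#' @return An object of class \code{outcome_model} with a
#'   \code{$prob(treatment, X)} function (X a data frame or matrix with the
#'   confounder columns).
#' @export
calibrate_outcome_model <- function(design, confounders = list(),
                                    alternative_efficacy = NULL) {
  stopifnot(inherits(design, "trial_design"))
  effs <- c(experimental = design$eff_experimental,
            control = design$eff_control)
  if (!is.null(alternative_efficacy)) {
    effs <- c(effs, alternative = alternative_efficacy)
  }
  gammas <- vapply(confounders, `[[`, numeric(1), "outcome_coefficient")
  mus <- vapply(confounders, confounder_mean, numeric(1))
  nms <- vapply(confounders, `[[`, character(1), "name")
  names(gammas) <- names(mus) <- nms

  # linear model: extremes occur at the corners of the confounder box
  if (length(confounders) > 0) {
    lo_shift <- sum(pmin(gammas * (0 - mus), gammas * (1 - mus)))
    hi_shift <- sum(pmax(gammas * (0 - mus), gammas * (1 - mus)))
  } else {
    lo_shift <- hi_shift <- 0
  }
  for (tr in names(effs)) {
    if (effs[[tr]] + lo_shift < 0) {
      stop(sprintf(
        "outcome model invalid: success probability for treatment '%s' falls below 0 (minimum %.3f)",
        tr, effs[[tr]] + lo_shift), call. = FALSE)
    }
    if (effs[[tr]] + hi_shift > 1) {
      stop(sprintf(
        "outcome model invalid: success probability for treatment '%s' exceeds 1 (maximum %.3f)",
        tr, effs[[tr]] + hi_shift), call. = FALSE)
    }
  }

  prob <- function(treatment, X) {
    base <- unname(effs[treatment])
    if (length(gammas) == 0) return(rep(base, length.out = max(1, NROW(X))))
    X <- as.matrix(as.data.frame(X)[, names(gammas), drop = FALSE])
    base + as.vector(sweep(X, 2, mus) %*% gammas)
  }

  structure(
    list(efficacies = effs, coefficients = gammas, means = mus, prob = prob),
    class = "outcome_model"
  )
}

#' Calibrate the adherence model for one arm of a scenario
#'
#' Returns the arm's probability of adhering given the confounders,
#' \eqn{P(\mathrm{adhere} \mid \mathrm{arm}, X) =
#' \mathrm{logit}^{-1}(\alpha + \sum_j \delta_j (X_j - E[X_j]))}, with the
#' intercept \eqn{\alpha} chosen by one-dimensional root-finding so that the
#' marginal adherence (averaged over the confounder distribution by
#' quadrature) equals the scenario target to within 1e-6.  With all
#' \eqn{\delta = 0} the intercept is the exact logit of the target; a target
#' of 1 returns a constant model with probability 1 for every participant.
#'
#' @param scenario a \code{\link{scenario_spec}}.
#' @param arm \code{"experimental"} or \code{"control"}.
#' @return An object of class \code{adherence_model} with a
#'   \code{$prob(X)} function.
#' @export
calibrate_adherence_model <- function(scenario,
                                      arm = c("experimental", "control")) {
  arm <- match.arg(arm)
  stopifnot(inherits(scenario, "scenario_spec"))
  target <- unname(scenario$adherence[arm])
  if (target <= 0) stop("marginal adherence target 0 is degenerate", call. = FALSE)

  if (target == 1) {
    return(structure(
      list(arm = arm, target = 1, intercept = Inf, coefficients = numeric(0),
           prob = function(X) rep(1, max(1, NROW(X)))),
      class = "adherence_model"
    ))
  }

  cfs <- scenario$confounders
  deltas <- vapply(cfs, function(cf) cf$adherence_coefficients[[arm]], numeric(1))
  mus <- vapply(cfs, confounder_mean, numeric(1))
  nms <- vapply(cfs, `[[`, character(1), "name")
  names(deltas) <- names(mus) <- nms

  if (length(deltas) == 0 || all(deltas == 0)) {
    alpha <- stats::qlogis(target)
  } else {
    grid <- confounder_grid(cfs)
    eta <- as.vector(sweep(grid$nodes[, names(deltas), drop = FALSE], 2, mus) %*% deltas)
    marg <- function(a) sum(grid$weights * stats::plogis(a + eta)) - target
    root <- tryCatch(
      stats::uniroot(marg, c(-35, 35), tol = 1e-12),
      error = function(e) stop(sprintf(
        "adherence intercept root-finding failed for arm '%s' (target %.3f): %s",
        arm, target, conditionMessage(e)), call. = FALSE)
    )
    alpha <- root$root
    achieved <- marg(alpha) + target
    if (abs(achieved - target) > 1e-6) {
      stop(sprintf(
        "adherence calibration for arm '%s' off target: achieved %.8f, wanted %.8f",
        arm, achieved, target), call. = FALSE)
    }
  }

  prob <- function(X) {
    if (length(deltas) == 0) return(rep(stats::plogis(alpha), max(1, NROW(X))))
    X <- as.matrix(as.data.frame(X)[, names(deltas), drop = FALSE])
    stats::plogis(alpha + as.vector(sweep(X, 2, mus) %*% deltas))
  }

  structure(
    list(arm = arm, target = target, intercept = alpha,
         coefficients = deltas, prob = prob),
    class = "adherence_model"
  )
}
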