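#' Specify a two-arm non-inferiority trial design
#'
#' A trial design holds the per-arm sample size, the true marginal efficacy
#' (success probability) of each treatment, the non-inferiority margin on the
#' absolute risk-difference scale, and the one-sided type-I error level.
#'
#' All internal computations are carried out on the efficacy-difference scale
#' \eqn{\Delta = p_E - p_C}, where \eqn{p_E} and \eqn{p_C} are the success
#' probabilities under the experimental and control treatment.  For harm
#' endpoints (e.g. death by day 30) supply the event risks and set
#' \code{outcome_polarity = "harm"}: risks are converted internally via
#' \eqn{p = 1 - \mathrm{risk}}, and reporting functions convert back.
#'
#' @param n_per_arm participants randomised to each arm (>= 2).
#' @param eff_experimental,eff_control marginal success probability of each
#'   treatment (or event risk when \code{outcome_polarity = "harm"}).
#' @param margin non-inferiority margin, an absolute difference in (0, 1).
#' @param alpha_one_sided one-sided type-I error level in (0, 0.5).
#' @param outcome_polarity \code{"success"} if larger outcome probabilities
#'   are better, \code{"harm"} if the outcome is an adverse event.
#' @return An object of class \code{trial_design}.
#' @examples
#' trial_design(400, 0.6, 0.6, margin = 0.1)
#' # mortality endpoint: risks 0.5 vs 0.4 become efficacies 0.5 vs 0.6
#' trial_design(400, 0.5, 0.4, margin = 0.1, outcome_polarity = "harm")
#' @export
trial_design <- function(n_per_arm, eff_experimental, eff_control, margin,
                         alpha_one_sided = 0.025,
                         outcome_polarity = c("success", "harm")) {
  outcome_polarity <- match.arg(outcome_polarity)
  stopifnot(is.numeric(n_per_arm), length(n_per_arm) == 1L)
  if (n_per_arm < 2 || n_per_arm != round(n_per_arm)) {
    stop("`n_per_arm` must be an integer >= 2", call. = FALSE)
  }
  for (nm in c("eff_experimental", "eff_control")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  if (!is.numeric(margin) || margin <= 0 || margin >= 1) {
    stop("`margin` must lie in (0, 1)", call. = FALSE)
  }
  if (alpha_one_sided <= 0 || alpha_one_sided >= 0.5) {
    stop("`alpha_one_sided` must lie in (0, 0.5)", call. = FALSE)
  }
  if (outcome_polarity == "harm") {
    eff_experimental <- 1 - eff_experimental
    eff_control <- 1 - eff_control
  }
  structure(
    list(
      n_per_arm = as.integer(n_per_arm),
      eff_experimental = eff_experimental,
      eff_control = eff_control,
      margin = margin,
      alpha_one_sided = alpha_one_sided,
      outcome_polarity = outcome_polarity
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Non-inferiority trial design\n")
  cat(sprintf("  n per arm        : %d\n", x$n_per_arm))
  cat(sprintf("  efficacy (E, C)  : %.3f, %.3f  (true difference %+.3f)\n",
              x$eff_experimental, x$eff_control,
              x$eff_experimental - x$eff_control))
  cat(sprintf("  margin           : %.3f\n", x$margin))
  cat(sprintf("  one-sided alpha  : %.4f\n", x$alpha_one_sided))
  cat(sprintf("  outcome polarity : %s\n", x$outcome_polarity))
  invisible(x)
}

#' Specify a confounder of adherence and outcome
#'
#' A confounder has a marginal distribution, an additive effect on the
#' success probability (per unit of the mean-centred confounder, on the
#' efficacy scale), and arm-specific log-odds effects on the probability of
#' adhering to the assigned treatment.  A negative
#' \code{outcome_coefficient} describes a severity-type variable that raises
#' the risk of a harm endpoint.
#'
#' @param name column name used in simulated participant tables.
#' @param distribution \code{"uniform01"} (continuous on [0, 1]) or
#'   \code{"bernoulli"}.
#' @param prob success probability for a Bernoulli confounder (ignored for
#'   \code{"uniform01"}).
#' @param outcome_coefficient additive risk-scale effect on the success
#'   probability per unit of the mean-centred confounder (identical under
#'   every treatment, which keeps marginal efficacies exactly calibrated).
#' @param adherence_coefficients named numeric vector
#'   \code{c(experimental = , control = )}: log-odds effect of the
#'   mean-centred confounder on adhering in each arm.
#' @return An object of class \code{confounder_spec}.
#' @examples
#' confounder_spec("severity", "uniform01", outcome_coefficient = -0.3,
#'                 adherence_coefficients = c(experimental = -3, control = 3))
#' @export
confounder_spec <- function(name,
                            distribution = c("uniform01", "bernoulli"),
                            prob = 0.5,
                            outcome_coefficient = 0,
                            adherence_coefficients = c(experimental = 0,
                                                       control = 0)) {
  distribution <- match.arg(distribution)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (distribution == "bernoulli" &&
      (!is.numeric(prob) || prob <= 0 || prob >= 1)) {
    stop("`prob` of a bernoulli confounder must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(outcome_coefficient) || length(outcome_coefficient) != 1L) {
    stop("`outcome_coefficient` must be a single number", call. = FALSE)
  }
  if (!all(c("experimental", "control") %in% names(adherence_coefficients))) {
    stop("`adherence_coefficients` needs elements named 'experimental' and 'control'",
         call. = FALSE)
  }
  structure(
    list(
      name = name,
      distribution = distribution,
      prob = if (distribution == "bernoulli") prob else NA_real_,
      outcome_coefficient = outcome_coefficient,
      adherence_coefficients =
        adherence_coefficients[c("experimental", "control")]
    ),
    class = "confounder_spec"
  )
}

confounder_mean <- function(cf) {
  if (cf$distribution == "uniform01") 0.5 else cf$prob
}

# attainable range of the confounder (both supported distributions live on
# [0,1]; linearity means box corners give the outcome-probability extremes)
confounder_range <- function(cf) c(0, 1)

#' Specify a non-adherence scenario
#'
#' A scenario states which arm(s) contain non-adherent participants, what
#' treatment those participants actually receive (the opposite arm's
#' treatment under \code{"crossover"}, or an inferior non-trial treatment
#' under \code{"alternative"}), the target marginal adherence in each arm,
#' and the confounders driving adherence and outcome.  Arms not listed in
#' \code{nonadherent_arms} have marginal adherence fixed at 1.
#'
#' @param nonadherent_arms character subset of
#'   \code{c("experimental", "control")} (empty for full adherence).
#' @param destination \code{"crossover"} or \code{"alternative"}.
#' @param alternative_efficacy success probability of the alternative
#'   treatment; required when \code{destination = "alternative"} and must be
#'   below both arm efficacies (checked against the design at simulation
#'   time).
#' @param adherence named numeric vector \code{c(experimental =, control =)}
#'   of target marginal adherence probabilities in (0, 1].
#' @param confounders list of \code{\link{confounder_spec}} objects (empty
#'   list = non-confounded non-adherence).
#' @param id optional scenario label carried through results.
#' @return An object of class \code{scenario_spec}.
#' @examples
#' # 10% symmetric crossover, non-confounded
#' scenario_spec(c("experimental", "control"), "crossover",
#'               adherence = c(experimental = 0.9, control = 0.9))
#' @export
scenario_spec <- function(nonadherent_arms = character(0),
                          destination = c("crossover", "alternative"),
                          alternative_efficacy = NULL,
                          adherence = c(experimental = 1, control = 1),
                          confounders = list(),
                          id = NULL) {
  destination <- match.arg(destination)
  arms <- c("experimental", "control")
  if (!all(nonadherent_arms %in% arms)) {
    stop("`nonadherent_arms` must be a subset of c('experimental', 'control')",
         call. = FALSE)
  }
  if (!all(arms %in% names(adherence))) {
    stop("`adherence` needs elements named 'experimental' and 'control'",
         call. = FALSE)
  }
  adherence <- adherence[arms]
  if (any(adherence <= 0) || any(adherence > 1)) {
    stop("marginal adherence must lie in (0, 1]; an arm with target 0 is degenerate",
         call. = FALSE)
  }
  full <- setdiff(arms, nonadherent_arms)
  if (any(adherence[full] != 1)) {
    stop("arms not listed in `nonadherent_arms` must have marginal adherence 1",
         call. = FALSE)
  }
  if (length(nonadherent_arms) > 0 && destination == "alternative" &&
      is.null(alternative_efficacy)) {
    stop("`alternative_efficacy` is required when destination = 'alternative'",
         call. = FALSE)
  }
  if (!is.null(alternative_efficacy) &&
      (alternative_efficacy < 0 || alternative_efficacy > 1)) {
    stop("`alternative_efficacy` must be a probability", call. = FALSE)
  }
  if (!all(vapply(confounders, inherits, logical(1), "confounder_spec"))) {
    stop("`confounders` must be a list of confounder_spec objects", call. = FALSE)
  }
  nms <- vapply(confounders, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("confounder names must be unique", call. = FALSE)
  structure(
    list(
      nonadherent_arms = nonadherent_arms,
      destination = destination,
      alternative_efficacy = alternative_efficacy,
      adherence = adherence,
      confounders = confounders,
      id = id
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Non-adherence scenario",
      if (!is.null(x$id)) sprintf("'%s'", x$id) else "", "\n")
  if (length(x$nonadherent_arms) == 0) {
    cat("  full adherence in both arms\n")
  } else {
    cat(sprintf("  non-adherent arm(s): %s -> %s\n",
                paste(x$nonadherent_arms, collapse = ", "),
                if (x$destination == "crossover") "opposite arm's treatment"
                else sprintf("alternative treatment (efficacy %.2f)",
                             x$alternative_efficacy)))
    cat(sprintf("  marginal adherence : E %.2f, C %.2f\n",
                x$adherence["experimental"], x$adherence["control"]))
  }
  if (length(x$confounders) > 0) {
    for (cf in x$confounders) {
      cat(sprintf("  confounder %s (%s): outcome %+.2f, adherence log-odds E %+.2f / C %+.2f\n",
                  cf$name, cf$distribution, cf$outcome_coefficient,
                  cf$adherence_coefficients["experimental"],
                  cf$adherence_coefficients["control"]))
    }
  } else {
    cat("  no confounders\n")
  }
  invisible(x)
}

is_full_adherence <- function(scenario) {
  length(scenario$nonadherent_arms) == 0 || all(scenario$adherence == 1)
}

# cross-checks that need both the design and the scenario
validate_scenario <- function(design, scenario) {
  stopifnot(inherits(design, "trial_design"), inherits(scenario, "scenario_spec"))
  if (scenario$destination == "alternative" &&
      length(scenario$nonadherent_arms) > 0) {
    lo <- min(design$eff_experimental, design$eff_control)
    if (scenario$alternative_efficacy >= lo) {
      stop(sprintf(
        "alternative treatment efficacy (%.3f) must be below both arm efficacies (min %.3f)",
        scenario$alternative_efficacy, lo), call. = FALSE)
    }
  }
  invisible(TRUE)
}
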