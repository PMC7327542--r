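# Participant-level cohort simulation.

draw_confounders <- function(n, confounders) {
  out <- lapply(confounders, function(cf) {
    if (cf$distribution == "uniform01") stats::runif(n)
    else stats::rbinom(n, 1L, cf$prob)
  })
  names(out) <- vapply(confounders, `[[`, character(1), "name")
  out
}

#' Simulate one trial cohort
#'
#' Generates a participant-level cohort under a design and non-adherence
#' scenario.  Exactly \code{n_per_arm} participants are assigned to each arm;
#' confounders are drawn from their marginal distributions; adherence is
#' drawn from the arm's calibrated logistic model; non-adherent participants
#' receive the opposite arm's treatment (\code{"crossover"}) or the inferior
#' alternative treatment; the binary outcome is drawn from the calibrated
#' linear-risk outcome model of the treatment actually received.  The result
#' is deterministic given \code{seed}.
#'
#' @param design a \code{\link{trial_design}}.
#' @param scenario a \code{\link{scenario_spec}}.
#' @param seed integer seed (the caller's RNG state is left untouched).
#' @return A \code{data.frame} of class \code{participant_table} with columns
#'   \code{id}, \code{assigned}, \code{received}, one column per confounder,
#'   and binary \code{outcome}.
#' @examples
#' d <- trial_design(100, 0.6, 0.6, margin = 0.1)
#' s <- scenario_spec(c("experimental", "control"), "crossover",
#'                    adherence = c(experimental = 0.9, control = 0.9))
#' head(simulate_cohort(d, s, seed = 1))
#' @export
simulate_cohort <- function(design, scenario, seed = NULL) {
  gen <- make_cohort_generator(design, scenario)
  gen(seed)
}

# pre-calibrates all models once and returns a fast function(seed) -> cohort;
# used internally by the operating-characteristics engine to avoid
# re-running the calibration root-finding in every replicate
make_cohort_generator <- function(design, scenario) {
  validate_scenario(design, scenario)
  om <- calibrate_outcome_model(design, scenario$confounders,
                                scenario$alternative_efficacy)
  am_e <- calibrate_adherence_model(scenario, "experimental")
  am_c <- calibrate_adherence_model(scenario, "control")

  n <- 2L * design$n_per_arm
  assigned <- rep(c("experimental", "control"), each = design$n_per_arm)
  idx_e <- assigned == "experimental"
  crossover <- scenario$destination == "crossover"
  opposite <- ifelse(idx_e, "control", "experimental")
  ids <- seq_len(n)

  function(seed = NULL) {
    with_seed(seed, {
      X <- draw_confounders(n, scenario$confounders)
      Xdf <- if (length(X)) as.data.frame(X, optional = TRUE) else
        as.data.frame(matrix(numeric(0), nrow = n))
      p_adh <- numeric(n)
      p_adh[idx_e] <- am_e$prob(Xdf[idx_e, , drop = FALSE])
      p_adh[!idx_e] <- am_c$prob(Xdf[!idx_e, , drop = FALSE])
      adhere <- stats::rbinom(n, 1L, p_adh) == 1L

      received <- assigned
      received[!adhere] <- if (crossover) opposite[!adhere] else "alternative"

      p_out <- numeric(n)
      for (tr in unique(received)) {
        sel <- received == tr
        p_out[sel] <- om$prob(tr, Xdf[sel, , drop = FALSE])
      }
      outcome <- stats::rbinom(n, 1L, p_out)

      tab <- data.frame(id = ids, assigned = assigned,
                        received = received, stringsAsFactors = FALSE)
      for (nm in names(X)) tab[[nm]] <- X[[nm]]
      tab$outcome <- outcome
      class(tab) <- c("participant_table", "data.frame")
      tab
    })
  }
}

confounder_columns <- function(table) {
  setdiff(names(table), c("id", "assigned", "received", "outcome"))
}

# expected marginal efficacy of each assigned arm under a scenario (exact
# under the linear shared-coefficient outcome model, since the treatment
# difference is constant in the confounders)
expected_arm_efficacy <- function(design, scenario) {
  a <- scenario$adherence
  other <- c(experimental = design$eff_control,
             control = design$eff_experimental)
  own <- c(experimental = design$eff_experimental,
           control = design$eff_control)
  dest <- if (scenario$destination == "crossover") other
          else c(experimental = scenario$alternative_efficacy %||% NA_real_,
                 control = scenario$alternative_efficacy %||% NA_real_)
  res <- a * own + (1 - a) * dest
  res[a == 1] <- own[a == 1]
  res
}

## ---- worked example preset -------------------------------------------------

#' Design of the worked-example trial
#'
#' A hypothetical open-label non-inferiority trial comparing a short-duration
#' (experimental) with a long-duration (control) antibiotic treatment for
#' ventilator-associated pneumonia.  The primary outcome is death by day 30
#' (a harm endpoint): 30-day mortality risks are 0.50 under the short and
#' 0.40 under the long treatment, so the true efficacy difference is -0.10.
#' 400 participants per arm, 10\% margin, one-sided 2.5\% alpha.
#'
#' @return A \code{\link{trial_design}}.
#' @export
worked_example_design <- function() {
  trial_design(n_per_arm = 400, eff_experimental = 0.50, eff_control = 0.40,
               margin = 0.10, alpha_one_sided = 0.025,
               outcome_polarity = "harm")
}

#' Non-adherence scenario of the worked-example trial
#'
#' Crossover non-adherence in both arms with marginal adherence calibrated to
#' 75\% in each arm, driven by two confounders:
#' \itemize{
#'   \item \code{severity}: disease severity, uniform on [0, 1]; raises the
#'     death risk (+0.3 per unit) and pushes severe patients off the
#'     short-duration arm (log-odds -3) while keeping them on the
#'     long-duration arm (log-odds +3) - doctors prescribe long courses for
#'     severe disease;
#'   \item \code{doctor}: treating physician (Bernoulli(0.5); 1 = doctor B);
#'     doctor B achieves slightly better outcomes (death risk lower by 0.1
#'     per unit) and preferentially keeps
#'     patients on (or moves them to) the short-duration treatment
#'     (log-odds +2 in the experimental arm, -2 in the control arm).
#' }
#'
#' @return A \code{\link{scenario_spec}}.
#' @export
worked_example_scenario <- function() {
  scenario_spec(
    nonadherent_arms = c("experimental", "control"),
    destination = "crossover",
    adherence = c(experimental = 0.75, control = 0.75),
    confounders = list(
      confounder_spec("severity", "uniform01",
                      outcome_coefficient = -0.3,
                      adherence_coefficients = c(experimental = -3, control = 3)),
      confounder_spec("doctor", "bernoulli", prob = 0.5,
                      outcome_coefficient = 0.1,
                      adherence_coefficients = c(experimental = 2, control = -2))
    ),
    id = "worked-example"
  )
}

#' Simulate the worked-example cohort
#'
#' Generates the 800-participant cohort (400 per arm) of the
#' ventilator-associated-pneumonia trial preset: see
#' \code{\link{worked_example_design}} and
#' \code{\link{worked_example_scenario}} for the data-generating model.
#'
#' @param seed integer seed.
#' @return A \code{participant_table} with 800 rows.
#' @export
worked_example_cohort <- function(seed = NULL) {
  simulate_cohort(worked_example_design(), worked_example_scenario(), seed)
}
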