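# Catalogue of canonical non-adherence scenarios: every combination of
# non-adherent population (both / experiment / control), destination of the
# non-adherent participants (crossover / inferior non-trial alternative) and
# confounding (none, or a severity-type confounder that raises the risk of
# the harm endpoint and either increases or decreases the stated switching
# probability).  18 rows in total: 6 non-confounded, 12 confounded.
#
# Frozen catalogue constants (documented in the methods vignette):
#  - marginal adherence 0.75 in each non-adherent arm;
#  - alternative treatment efficacy 0.30 (inferior to both arms);
#  - confounder "severity" ~ uniform01 with outcome coefficient -0.3 on the
#    success scale (severity raises the probability of the harm outcome);
#  - adherence log-odds coefficients of magnitude 3 (moderately strong
#    confounded selection); for the both-arm inferior-destination rows the
#    effect is stronger in the control arm (-0.5 vs -5), reflecting severe
#    patients abandoning the longer control regimen more readily.

.table1_adherence <- 0.75
.table1_alternative_eff <- 0.30
.table1_gamma <- -0.3

table1_catalogue <- function() {
  pops <- c("both", "experiment", "control")
  dests <- c("crossover", "inferior")
  confs <- c("nonconfounded", "confounded-increase", "confounded-decrease")
  ids <- as.vector(outer(pops, dests, FUN = function(p, d) paste(p, d, sep = "/")))
  sort(as.vector(outer(ids, confs, FUN = function(x, c) paste(x, c, sep = "/"))))
}

#' List the identifiers of the catalogued non-adherence scenarios
#'
#' @return Character vector of the 18 scenario identifiers of the form
#'   \code{"<population>/<destination>/<confounding>"} with population in
#'   \code{both}, \code{experiment}, \code{control}; destination in
#'   \code{crossover}, \code{inferior}; confounding in
#'   \code{nonconfounded}, \code{confounded-increase},
#'   \code{confounded-decrease} (the confounder increases, respectively
#'   decreases, the stated switching probability while always increasing the
#'   probability of the harm outcome).
#' @export
table1_rows <- function() table1_catalogue()

# adherence log-odds coefficients per (population, destination) for the
# "confounded-increase" variant; the "-decrease" variant negates them.
# Crossover rows: the confounder increases the probability of receiving the
# experimental treatment (adhere in E, switch in C).  Inferior rows: the
# confounder increases take-up of the alternative treatment (reduces
# adherence) in each non-adherent arm.
table1_deltas <- function(population, destination) {
  if (destination == "crossover") {
    switch(population,
      both       = c(experimental = 3, control = -3),
      experiment = c(experimental = 3, control = 0),
      control    = c(experimental = 0, control = -3))
  } else {
    switch(population,
      both       = c(experimental = -0.5, control = -5),
      experiment = c(experimental = -3, control = 0),
      control    = c(experimental = 0, control = -3))
  }
}

#' Build a catalogued non-adherence scenario
#'
#' Returns the \code{\link{scenario_spec}} for one of the 18 catalogued
#' combinations of non-adherent population, destination and confounding (see
#' \code{\link{table1_rows}}).  Confounded rows use a single uniform [0, 1]
#' severity confounder that increases the probability of the harm outcome
#' (outcome coefficient -0.3 on the success scale) with adherence
#' coefficients signed so that the confounder increases
#' (\code{confounded-increase}) or decreases (\code{confounded-decrease})
#' the row's stated switching probability.
#'
#' @param row scenario identifier, e.g. \code{"both/crossover/nonconfounded"}.
#' @param design a \code{\link{trial_design}}; used to validate that the
#'   alternative treatment is inferior to both arms.
#' @return A \code{\link{scenario_spec}}.
#' @examples
#' d <- trial_design(400, 0.5, 0.6, margin = 0.1)
#' table1_scenario("experiment/inferior/nonconfounded", d)
#' @export
table1_scenario <- function(row, design) {
  rows <- table1_catalogue()
  if (!is.character(row) || length(row) != 1L || !(row %in% rows)) {
    stop("unknown scenario row '", row, "'; valid identifiers are:\n  ",
         paste(rows, collapse = "\n  "), call. = FALSE)
  }
  parts <- strsplit(row, "/", fixed = TRUE)[[1]]
  population <- parts[1]; destination <- parts[2]; confounding <- parts[3]

  arms <- switch(population,
                 both = c("experimental", "control"),
                 experiment = "experimental",
                 control = "control")
  adherence <- c(experimental = 1, control = 1)
  adherence[arms] <- .table1_adherence

  confounders <- list()
  if (confounding != "nonconfounded") {
    deltas <- table1_deltas(population, destination)
    if (confounding == "confounded-decrease") deltas <- -deltas
    confounders <- list(confounder_spec(
      "severity", "uniform01",
      outcome_coefficient = .table1_gamma,
      adherence_coefficients = deltas
    ))
  }

  sc <- scenario_spec(
    nonadherent_arms = arms,
    destination = if (destination == "crossover") "crossover" else "alternative",
    alternative_efficacy = if (destination == "inferior") .table1_alternative_eff,
    adherence = adherence,
    confounders = confounders,
    id = row
  )
  validate_scenario(design, sc)
  sc
}
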