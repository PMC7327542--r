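# Biocreep: consecutive non-inferiority trials, each comparing the next
# (truly inferior) treatment against the previous one, at a fixed adherence
# level with symmetric crossover.

#' Configuration of a chain of consecutive non-inferiority trials
#'
#' The chain starts from a standard of care and tests, in fixed comparator
#' pairs, treatments whose true efficacy drops by \code{per_step_drop} at
#' every step (standard-of-care vs A, A vs B, B vs C, C vs D by default).
#' Each trial applies the intention-to-treat analysis at the given
#' symmetric-crossover adherence.  A treatment becomes the accepted standard
#' only if its own trial and all preceding trials claimed non-inferiority.
#'
#' @param initial_soc_efficacy efficacy of the initial standard of care.
#' @param per_step_drop absolute efficacy decrement of each new treatment.
#' @param n_treatments number of consecutive new treatments (default 4,
#'   labelled A, B, C, ...).
#' @param margin,alpha non-inferiority margin and one-sided alpha per trial.
#' @param n_per_arm per-arm sample size per trial; the default sizes each
#'   trial the way sponsors size a non-inferiority trial - assuming the new
#'   treatment is truly equivalent to its comparator -
#'   (\code{\link{analytic_sample_size}} at 80\% power with both efficacies
#'   equal to the standard of care's).
#' @param adherence symmetric marginal adherence in every trial (1 = full).
#' @param replicates Monte-Carlo replicates.
#' @return An object of class \code{chain_config}.
#' @export
chain_config <- function(initial_soc_efficacy = 0.6, per_step_drop = 0.1,
                         n_treatments = 4, margin = 0.1, alpha = 0.025,
                         n_per_arm = NULL, adherence = 1,
                         replicates = 10000) {
  if (per_step_drop <= 0) stop("`per_step_drop` must be positive", call. = FALSE)
  effs <- initial_soc_efficacy - per_step_drop * (0:n_treatments)
  if (any(effs <= 0) || any(effs >= 1)) {
    stop(sprintf(
      "chain efficacies must stay inside (0, 1); got %s",
      paste(sprintf("%.2f", effs), collapse = ", ")), call. = FALSE)
  }
  if (adherence <= 0 || adherence > 1) {
    stop("`adherence` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(n_per_arm)) {
    n_per_arm <- analytic_sample_size(effs[1], effs[1], margin, alpha, 0.8)
  }
  structure(
    list(initial_soc_efficacy = initial_soc_efficacy,
         per_step_drop = per_step_drop, n_treatments = as.integer(n_treatments),
         margin = margin, alpha = alpha, n_per_arm = as.integer(n_per_arm),
         adherence = adherence, replicates = as.integer(replicates),
         efficacies = effs,
         labels = c("SOC", LETTERS[seq_len(n_treatments)])),
    class = "chain_config"
  )
}

chain_mixture <- function(config, k) {
  a <- config$adherence
  e_new <- config$efficacies[k + 1]   # experimental arm of trial k
  e_old <- config$efficacies[k]       # control arm (previous standard)
  c(experimental = a * e_new + (1 - a) * e_old,
    control = a * e_old + (1 - a) * e_new)
}

#' Independence-product oracle for the biocreep chain
#'
#' Per-trial claim probabilities from
#' \code{\link{claim_probability_oracle}} evaluated at each pair's
#' crossover-mixture efficacies; the cumulative acceptance probability of
#' treatment k is the running product (the trials are independent).
#'
#' @param config a \code{\link{chain_config}}.
#' @return A data frame with per-trial claim probabilities and cumulative
#'   acceptance probabilities.
#' @export
chain_oracle <- function(config) {
  per_trial <- vapply(seq_len(config$n_treatments), function(k) {
    e <- chain_mixture(config, k)
    claim_probability_oracle(e[["experimental"]], e[["control"]],
                             config$n_per_arm, config$margin, config$alpha)
  }, numeric(1))
  data.frame(
    treatment = config$labels[-1],
    true_efficacy = config$efficacies[-1],
    claim_probability = per_trial,
    cumulative_acceptance = cumprod(per_trial),
    stringsAsFactors = FALSE
  )
}

#' Simulate a chain of consecutive non-inferiority trials
#'
#' Each replicate simulates the fixed comparator pairs independently (the
#' arm-level binomial shortcut applies: the chain is non-confounded).  A
#' treatment is accepted as the new standard only if its trial and all
#' preceding trials claimed non-inferiority, so cumulative acceptance
#' probabilities are non-increasing along the chain.
#'
#' @param config a \code{\link{chain_config}}.
#' @param seed master seed.
#' @return An object of class \code{biocreep_result}: a data frame of
#'   per-trial claim probabilities and cumulative acceptance probabilities
#'   with Monte-Carlo standard errors, plus the configuration.
#' @examples
#' run_chain(chain_config(adherence = 0.7, replicates = 2000), seed = 1)
#' @export
run_chain <- function(config, seed = 1L) {
  stopifnot(inherits(config, "chain_config"))
  R <- config$replicates
  n <- config$n_per_arm
  z <- stats::qnorm(1 - config$alpha)
  claims <- matrix(NA, nrow = R, ncol = config$n_treatments)
  for (k in seq_len(config$n_treatments)) {
    e <- chain_mixture(config, k)
    with_seed(derive_seed(seed, k), {
      y_e <- stats::rbinom(R, n, e[["experimental"]])
      y_c <- stats::rbinom(R, n, e[["control"]])
    })
    p_e <- y_e / n; p_c <- y_c / n
    se <- sqrt(p_e * (1 - p_e) / n + p_c * (1 - p_c) / n)
    claims[, k] <- (p_e - p_c) - z * se > -config$margin
  }
  accepted <- t(apply(claims, 1, cumprod)) == 1
  if (config$n_treatments == 1L) accepted <- matrix(claims[, 1], ncol = 1)
  cum <- colMeans(accepted)
  per <- colMeans(claims)
  res <- data.frame(
    treatment = config$labels[-1],
    true_efficacy = config$efficacies[-1],
    claim_probability = per,
    cumulative_acceptance = cum,
    mc_std_error = sqrt(cum * (1 - cum) / R),
    stringsAsFactors = FALSE
  )
  structure(list(result = res, config = config, replicates = R, seed = seed),
            class = "biocreep_result")
}

#' @export
print.biocreep_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Biocreep chain: %d consecutive trials, adherence %.0f%%, n = %d/arm, margin %.2f\n",
    cfg$n_treatments, 100 * cfg$adherence, cfg$n_per_arm, cfg$margin))
  df <- x$result
  df$claim_probability <- sprintf("%.3f", df$claim_probability)
  df$cumulative_acceptance <- sprintf("%.3f", df$cumulative_acceptance)
  df$mc_std_error <- sprintf("%.4f", df$mc_std_error)
  print(df, row.names = FALSE)
  invisible(x)
}
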