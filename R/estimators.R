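# Analysis strategies for a simulated or imported participant table.
# All estimates are on the efficacy-difference scale (eff_E - eff_C); the
# print method converts to the harm scale when the design says so.

#' Non-inferiority decision rule
#'
#' On the efficacy-difference scale, non-inferiority is claimed when the
#' lower confidence bound lies strictly above \code{-margin}; on the harm
#' scale, when the upper bound lies strictly below \code{margin}.  The two
#' forms are equivalent by negation of the interval.
#'
#' @param estimate point estimate (unused by the rule itself, kept for a
#'   consistency check that the interval contains it).
#' @param ci_low,ci_high confidence interval bounds.
#' @param margin positive non-inferiority margin.
#' @param polarity \code{"success"} (efficacy-difference scale) or
#'   \code{"harm"}.
#' @return \code{TRUE} if non-inferiority is claimed.
#' @examples
#' # harm-scale interval (0.032, 0.195) against a 10% margin: not non-inferior
#' ni_decision(0.114, 0.032, 0.195, margin = 0.10, polarity = "harm")
#' @export
ni_decision <- function(estimate, ci_low, ci_high, margin,
                        polarity = c("success", "harm")) {
  polarity <- match.arg(polarity)
  if (margin <= 0) stop("`margin` must be positive", call. = FALSE)
  if (ci_low > estimate || ci_high < estimate) {
    stop("confidence interval does not contain the point estimate", call. = FALSE)
  }
  if (polarity == "success") ci_low > -margin else ci_high < margin
}

new_analysis_result <- function(method, estimate, std_error, ci_low, ci_high,
                                design, n_analyzed, diagnostics = NULL) {
  structure(
    list(
      method = method,
      estimate = estimate,
      std_error = std_error,
      ci_low = ci_low,
      ci_high = ci_high,
      ci_level = 1 - 2 * design$alpha_one_sided,
      n_analyzed = as.integer(n_analyzed),
      ni_claimed = ni_decision(estimate, ci_low, ci_high, design$margin,
                               "success"),
      margin = design$margin,
      outcome_polarity = design$outcome_polarity,
      diagnostics = diagnostics
    ),
    class = "ni_analysis"
  )
}

#' @export
print.ni_analysis <- function(x, ...) {
  harm <- x$outcome_polarity == "harm"
  est <- if (harm) -x$estimate else x$estimate
  lo <- if (harm) -x$ci_high else x$ci_low
  hi <- if (harm) -x$ci_low else x$ci_high
  cat(sprintf("%s: %s difference %+.3f (%.0f%% CI %+.3f to %+.3f), n = %d\n",
              x$method, if (harm) "risk" else "efficacy",
              est, 100 * x$ci_level, lo, hi, x$n_analyzed))
  cat(sprintf("  non-inferiority (margin %.2f): %s\n", x$margin,
              if (x$ni_claimed) "claimed" else "NOT claimed"))
  invisible(x)
}

#' @export
as.data.frame.ni_analysis <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate,
             std_error = x$std_error, ci_low = x$ci_low, ci_high = x$ci_high,
             ci_level = x$ci_level, n_analyzed = x$n_analyzed,
             ni_claimed = x$ni_claimed, stringsAsFactors = FALSE)
}

# Wald risk difference between two outcome vectors; when an arm proportion is
# exactly 0 or 1, that arm's variance uses 0.5 added successes and failures
# (variance only) to avoid zero-width intervals on small cohorts.
wald_risk_difference <- function(y_e, y_c, design, method, n_analyzed = NULL) {
  n_e <- length(y_e); n_c <- length(y_c)
  p_e <- mean(y_e); p_c <- mean(y_c)
  v_arm <- function(p, n, successes) {
    if (p == 0 || p == 1) {
      p_adj <- (successes + 0.5) / (n + 1)
      p_adj * (1 - p_adj) / n
    } else p * (1 - p) / n
  }
  se <- sqrt(v_arm(p_e, n_e, sum(y_e)) + v_arm(p_c, n_c, sum(y_c)))
  z <- z_quantile(design$alpha_one_sided)
  est <- p_e - p_c
  new_analysis_result(method, est, se, est - z * se, est + z * se,
                      design, n_analyzed %||% (n_e + n_c))
}

#' Intention-to-treat estimate
#'
#' Compares all randomised participants according to their assigned arm:
#' estimate \eqn{\hat\Delta = \bar Y_E - \bar Y_C} with Wald standard error
#' and normal confidence interval at level \eqn{1 - 2\alpha}.
#'
#' @param table a \code{participant_table}.
#' @param design the \code{\link{trial_design}}.
#' @return An object of class \code{ni_analysis}.
#' @export
itt_estimate <- function(table, design) {
  y_e <- table$outcome[table$assigned == "experimental"]
  y_c <- table$outcome[table$assigned == "control"]
  if (length(y_e) == 0 || length(y_c) == 0) {
    stop("both assigned arms must be non-empty", call. = FALSE)
  }
  wald_risk_difference(y_e, y_c, design, "ITT")
}

#' Naive per-protocol estimate
#'
#' The intention-to-treat comparison restricted to participants who received
#' their assigned treatment.  Vulnerable to confounding by determinants of
#' adherence.
#'
#' @inheritParams itt_estimate
#' @return An object of class \code{ni_analysis}.
#' @export
pp_estimate <- function(table, design) {
  adh <- table[table$received == table$assigned, , drop = FALSE]
  y_e <- adh$outcome[adh$assigned == "experimental"]
  y_c <- adh$outcome[adh$assigned == "control"]
  if (length(y_e) < 2 || length(y_c) < 2) {
    stop("per-protocol analysis needs at least 2 adherent participants per arm",
         call. = FALSE)
  }
  wald_risk_difference(y_e, y_c, design, "PP", n_analyzed = nrow(adh))
}

# fit the arm-specific logistic adherence model and return 1/p weights for
# the adherent rows of that arm (all rows of the arm used for fitting)
fit_arm_weights <- function(arm_tab, conf_cols) {
  adhere <- as.integer(arm_tab$received == arm_tab$assigned)
  if (all(adhere == 1L)) {
    # fully adherent arm: weights 1 (documented fall-back to per-protocol)
    return(list(weights = rep(1, nrow(arm_tab)), converged = TRUE,
                all_adherent = TRUE))
  }
  dat <- if (length(conf_cols)) {
    cbind(data.frame(.adhere = adhere), arm_tab[, conf_cols, drop = FALSE])
  } else data.frame(.adhere = adhere)
  fit <- suppressWarnings(stats::glm(
    .adhere ~ ., data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged) {
    stop("adherence model did not converge (", nrow(arm_tab), " rows, ",
         length(conf_cols), " confounders)", call. = FALSE)
  }
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("adherence model shows complete or quasi-complete separation ",
         "(diverging coefficients: ",
         paste(sprintf("%s=%.1f", names(stats::coef(fit)), stats::coef(fit)),
               collapse = ", "), ")", call. = FALSE)
  }
  list(weights = 1 / stats::fitted(fit), converged = TRUE,
       all_adherent = FALSE)
}

ipw_point <- function(table, design, weight_cap_quantile = NULL) {
  conf_cols <- confounder_columns(table)
  props <- numeric(2); names(props) <- c("experimental", "control")
  w_all <- numeric(0)
  for (arm in names(props)) {
    arm_tab <- table[table$assigned == arm, , drop = FALSE]
    fw <- fit_arm_weights(arm_tab, conf_cols)
    sel <- arm_tab$received == arm_tab$assigned
    w <- fw$weights[sel]
    if (!is.null(weight_cap_quantile)) {
      w <- pmin(w, stats::quantile(w, weight_cap_quantile))
    }
    y <- arm_tab$outcome[sel]
    props[arm] <- sum(w * y) / sum(w)   # Hajek (normalised) estimator
    w_all <- c(w_all, w)
  }
  list(estimate = unname(props["experimental"] - props["control"]),
       weights = w_all)
}

# percentile bootstrap of a point estimator, resampling rows within each
# assigned arm and re-fitting every nuisance model in each replicate
bootstrap_ci <- function(table, design, point_fun, reps, seed) {
  idx_e <- which(table$assigned == "experimental")
  idx_c <- which(table$assigned == "control")
  with_seed(seed, {
    ests <- rep(NA_real_, reps)
    for (b in seq_len(reps)) {
      take <- c(sample(idx_e, replace = TRUE), sample(idx_c, replace = TRUE))
      ests[b] <- tryCatch(point_fun(table[take, , drop = FALSE]),
                          error = function(e) NA_real_)
    }
    ok <- ests[!is.na(ests)]
    if (length(ok) < 0.5 * reps) {
      stop("bootstrap failed in more than half of the replicates", call. = FALSE)
    }
    alpha2 <- design$alpha_one_sided
    list(ci = unname(stats::quantile(ok, c(alpha2, 1 - alpha2))),
         se = stats::sd(ok), n_failed = reps - length(ok))
  })
}

#' Inverse-probability-weighted per-protocol estimate
#'
#' Fits, separately in each assigned arm, a logistic model of adherence on
#' the observed confounders; restricts to adherent participants and weights
#' each by the reciprocal of their fitted adherence probability.  Arm risks
#' are Hajek (weight-normalised) proportions, and the confidence interval is
#' a nonparametric percentile bootstrap (resampling within arm, re-fitting
#' the weight model in every replicate).  A fully adherent input reduces to
#' the per-protocol estimate with unit weights.
#'
#' @inheritParams itt_estimate
#' @param bootstrap_reps bootstrap replicates for the CI (0 skips the
#'   bootstrap; the interval and standard error are then \code{NA}).
#' @param seed seed for the bootstrap resampling.
#' @param weight_cap_quantile optional quantile (e.g. 0.99) at which weights
#'   are truncated; \code{NULL} (default) leaves weights untouched.
#' @return An object of class \code{ni_analysis}; the \code{diagnostics}
#'   element holds the weight summary (min/max/mean weight, effective sample
#'   size) and the convergence flag.
#' @export
ipw_estimate <- function(table, design, bootstrap_reps = 1000, seed = 1L,
                         weight_cap_quantile = NULL) {
  pt <- ipw_point(table, design, weight_cap_quantile)
  n_adh <- sum(table$received == table$assigned)
  w <- pt$weights
  diag <- list(min_weight = min(w), max_weight = max(w), mean_weight = mean(w),
               effective_sample_size = sum(w)^2 / sum(w^2),
               converged = TRUE)
  if (bootstrap_reps > 0) {
    bs <- bootstrap_ci(table, design,
                       function(t) ipw_point(t, design, weight_cap_quantile)$estimate,
                       bootstrap_reps, seed)
    diag$bootstrap_failures <- bs$n_failed
    res <- new_analysis_result("IPW", pt$estimate, bs$se, bs$ci[1], bs$ci[2],
                               design, n_adh, diag)
  } else {
    res <- structure(list(
      method = "IPW", estimate = pt$estimate, std_error = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      ci_level = 1 - 2 * design$alpha_one_sided, n_analyzed = as.integer(n_adh),
      ni_claimed = NA, margin = design$margin,
      outcome_polarity = design$outcome_polarity, diagnostics = diag
    ), class = "ni_analysis")
  }
  res
}

std_strata_factor <- function(table, strata_definition) {
  if (length(strata_definition) == 0) {
    # no stratification variables: a single stratum (reduces to per-protocol)
    return(factor(rep("all", nrow(table))))
  }
  if (is.character(strata_definition)) {
    strata_definition <- stats::setNames(
      vector("list", length(strata_definition)), strata_definition)
  }
  facs <- lapply(names(strata_definition), function(nm) {
    if (!nm %in% names(table)) {
      stop("stratification variable '", nm, "' not found in the table",
           call. = FALSE)
    }
    x <- table[[nm]]
    if (all(x %in% c(0, 1))) return(factor(x, levels = c(0, 1)))
    probs <- strata_definition[[nm]] %||% c(0.25, 0.5, 0.75)
    cuts <- unique(stats::quantile(x, probs))
    cut(x, breaks = c(-Inf, cuts, Inf), labels = FALSE)
  })
  interaction(facs, drop = FALSE, sep = ":")
}

std_point <- function(table, design, strata_definition) {
  stratum <- std_strata_factor(table, strata_definition)
  shares <- table(stratum) / nrow(table)   # share of the full randomised cohort
  adh <- table$received == table$assigned
  est <- 0
  for (s in names(shares)) {
    if (shares[[s]] == 0) next
    sel <- stratum == s & adh
    for (arm in c("experimental", "control")) {
      if (!any(sel & table$assigned == arm)) {
        stop("standardisation failed: stratum '", s,
             "' has no adherent participants in the ", arm, " arm",
             call. = FALSE)
      }
    }
    r_e <- mean(table$outcome[sel & table$assigned == "experimental"])
    r_c <- mean(table$outcome[sel & table$assigned == "control"])
    est <- est + shares[[s]] * (r_e - r_c)
  }
  est
}

#' Standardised (stratified) per-protocol estimate
#'
#' Stratifies on discrete confounders (continuous ones are discretised at
#' quantile cut points, quartiles by default), computes adherent-only arm
#' risks per stratum and averages them with weights equal to each stratum's
#' share of the full randomised cohort.  The confidence interval uses the
#' same within-arm percentile bootstrap as \code{\link{ipw_estimate}}.
#'
#' @inheritParams ipw_estimate
#' @param strata_definition either a character vector of confounder column
#'   names (continuous ones cut at quartiles) or a named list mapping column
#'   names to quantile probabilities for the cut points.
#' @return An object of class \code{ni_analysis}.
#' @export
standardisation_estimate <- function(table, design,
                                     strata_definition = confounder_columns(table),
                                     bootstrap_reps = 1000, seed = 1L) {
  est <- std_point(table, design, strata_definition)
  n_adh <- sum(table$received == table$assigned)
  if (bootstrap_reps > 0) {
    bs <- bootstrap_ci(table, design,
                       function(t) std_point(t, design, strata_definition),
                       bootstrap_reps, seed)
    new_analysis_result("STD", est, bs$se, bs$ci[1], bs$ci[2], design, n_adh,
                        list(bootstrap_failures = bs$n_failed))
  } else {
    structure(list(
      method = "STD", estimate = est, std_error = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, ci_level = 1 - 2 * design$alpha_one_sided,
      n_analyzed = as.integer(n_adh), ni_claimed = NA, margin = design$margin,
      outcome_polarity = design$outcome_polarity, diagnostics = NULL
    ), class = "ni_analysis")
  }
}

#' Instrumental-variable (Wald) estimate
#'
#' Randomisation is the instrument: the estimate is the intention-to-treat
#' outcome difference divided by the first-stage difference
#' \eqn{P(\mathrm{received} = E \mid Z = E) - P(\mathrm{received} = E \mid Z = C)},
#' with a delta-method standard error that accounts for the within-arm
#' covariance of outcome and received treatment.  Only valid under
#' crossover-type non-adherence: rows that received a non-trial alternative
#' treatment are rejected, as is a weak instrument (first stage <= 0.01).
#' At full adherence the first stage is 1 and the estimate (and its standard
#' error) equal the intention-to-treat analysis exactly.
#'
#' @inheritParams itt_estimate
#' @return An object of class \code{ni_analysis}; \code{diagnostics} holds
#'   the first-stage difference.
#' @export
iv_estimate <- function(table, design) {
  if (any(table$received == "alternative")) {
    stop("instrumental-variable estimation requires crossover-only ",
         "non-adherence; the table contains participants on a non-trial ",
         "alternative treatment", call. = FALSE)
  }
  z <- z_quantile(design$alpha_one_sided)
  arm_stats <- lapply(c("experimental", "control"), function(arm) {
    t <- table[table$assigned == arm, , drop = FALSE]
    n <- nrow(t)
    y <- t$outcome
    a <- as.integer(t$received == "experimental")
    list(n = n, py = mean(y), pa = mean(a),
         vy = mean(y) * (1 - mean(y)) / n,
         va = mean(a) * (1 - mean(a)) / n,
         cya = (mean(y * a) - mean(y) * mean(a)) / n)
  })
  names(arm_stats) <- c("experimental", "control")
  b <- arm_stats$experimental$py - arm_stats$control$py   # ITT difference
  d <- arm_stats$experimental$pa - arm_stats$control$pa   # first stage
  if (d <= 0.01) {
    stop(sprintf(
      "weak instrument: first-stage difference %.4f <= 0.01; randomisation barely predicts treatment received",
      d), call. = FALSE)
  }
  est <- b / d
  var_b <- arm_stats$experimental$vy + arm_stats$control$vy
  var_d <- arm_stats$experimental$va + arm_stats$control$va
  cov_bd <- arm_stats$experimental$cya + arm_stats$control$cya
  se <- sqrt((var_b + est^2 * var_d - 2 * est * cov_bd) / d^2)
  new_analysis_result("IV", est, se, est - z * se, est + z * se, design,
                      nrow(table), list(first_stage = d))
}
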