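---
title: "Simulating non-inferiority trials under non-adherence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating non-inferiority trials under non-adherence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A two-arm non-inferiority trial asks whether an experimental treatment is no
worse than an active control by more than a pre-specified margin $m$.  With a
binary outcome and efficacies (success probabilities) $p_E$ and $p_C$, the
hypotheses on the absolute scale are

$$H_0: p_E - p_C \le -m \qquad \text{vs} \qquad H_1: p_E - p_C > -m,$$

and non-inferiority is claimed when the lower bound of the two-sided
$(1-2\alpha)$ confidence interval for $\hat\Delta = \hat p_E - \hat p_C$ lies
strictly above $-m$ (equivalently, on a harm scale such as 30-day mortality,
when the upper bound lies strictly below $m$).

Non-adherence is uniquely dangerous in this setting.  When participants cross
over to the opposite arm or take an alternative treatment, the observed arm
difference is usually *diluted towards zero* — which in a superiority trial
costs power, but in a non-inferiority trial *inflates the probability of a
false non-inferiority claim*.  When the determinants of adherence also affect
the outcome (confounded non-adherence), the naive per-protocol analysis is
biased in a direction controlled by that confounding.  `niadhere` simulates
these mechanisms with exact marginal calibration, applies the standard and
causal analysis strategies, and measures the resulting operating
characteristics.

## Data-generating model

**Outcome model.**  Given confounders $X_j$ with means $\mu_j$, the success
probability under treatment $t \in \{E, C, \text{alternative}\}$ is linear on
the risk scale in the mean-centred confounders:

$$\pi_t(X) = \mathrm{eff}_t + \sum_j \gamma_j (X_j - \mu_j).$$

The model is deliberately linear rather than logistic: mean-centring makes
the *marginal* success probability under every treatment equal to
$\mathrm{eff}_t$ exactly, with no recalibration, so closed-form oracles for
intention-to-treat mixtures hold exactly and every simulated scenario has a
known truth.  Validity is enforced at construction: since the model is
linear and both supported confounder distributions (uniform on $[0,1]$,
Bernoulli) live on $[0,1]$, the extremes of $\pi_t$ occur at the corners of
the confounder box, and any coefficient/efficacy combination that pushes a
probability outside $[0,1]$ is rejected with the offending treatment and
bound named.  A shared $\gamma_j$ across treatments means the treatment
difference $\pi_E(X)-\pi_C(X)$ is constant in $X$; this is what makes
intention-to-treat arm marginals *exact* mixture probabilities even under
confounded adherence.

**Adherence model.**  Each arm's probability of adhering is logistic in the
mean-centred confounders,

$$P(\text{adhere} \mid \text{arm } a, X) = \operatorname{logit}^{-1}\!\Big(
\alpha_a + \sum_j \delta_{ja} (X_j - \mu_j)\Big),$$

with the intercept $\alpha_a$ found by one-dimensional root-finding
(`stats::uniroot`, tolerance $10^{-12}$ on the root) so that the marginal
adherence — averaged over the joint confounder distribution by 64-node
Gauss–Legendre quadrature per continuous component and exact enumeration per
Bernoulli component — hits the scenario's target within $10^{-6}$.  With all
$\delta = 0$ the intercept is the exact logit; a target of 1 bypasses the
logistic entirely.

**Cohort generation.**  Exactly `n_per_arm` participants are assigned to
each arm (balanced allocation, as in practice; it also simplifies the
variance oracles).  Non-adherent participants deterministically receive the
opposite arm's treatment (crossover) or a single inferior alternative
treatment; richer destination mixtures are out of scope.  Outcomes are
Bernoulli draws from $\pi_{\text{received}}(X)$.  All randomness is governed
by one integer seed; sub-stream seeds are derived by a counter scheme so any
replicate is reproducible independently of execution order, and the caller's
RNG state is never disturbed.

## Analysis strategies

* **ITT** — difference of assigned-arm proportions, Wald standard error,
  normal CI.  When an arm proportion is exactly 0 or 1, that arm's variance
  (only) uses 0.5 added successes and failures, avoiding zero-width
  intervals on small cohorts.
* **PP** — the same estimator restricted to participants with
  `received == assigned`.
* **IPW** — per-arm logistic regression of adherence on the confounders
  (`stats::glm`, IRLS with convergence tolerance $10^{-8}$ and a
  100-iteration cap; separation is detected as any coefficient exceeding 15
  in absolute value and reported as an error).  Adherent participants are
  weighted by $1/\hat p_i$ and arm risks are Hájek (weight-normalised)
  proportions.  The CI is a within-arm nonparametric percentile bootstrap
  (default 1,000 replicates) re-fitting the weight model in every replicate;
  a sandwich variance would also be defensible, but the bootstrap is simpler
  to specify and robust to the two-stage estimation.  Weight truncation is
  off by default (an optional quantile cap is exposed).  A fully adherent
  arm falls back to unit weights.
* **Standardisation** — adherent-only risks within strata of discrete
  confounders (continuous ones cut at quantiles, quartiles by default),
  averaged with weights equal to each stratum's share of the *full
  randomised* cohort; bootstrap CI as for IPW.  An empty stratum-arm cell is
  an error naming the stratum.
* **IV (Wald)** — intention-to-treat outcome difference divided by the
  first-stage difference $P(A{=}E \mid Z{=}E) - P(A{=}E \mid Z{=}C)$, with a
  delta-method standard error including the within-arm outcome/treatment
  covariance.  Valid only for crossover-type non-adherence, so rows on a
  non-trial alternative are rejected, as are first stages $\le 0.01$ (weak
  instrument); a Fieller interval is unnecessary away from weak instruments,
  which the precondition excludes.  At full adherence IV reduces to ITT
  exactly, estimate and standard error alike.

All internal estimates live on the efficacy-difference scale
$\Delta = p_E - p_C$; harm-scale designs are negated at the boundary (one
decision rule, no sign bugs), and reporting converts back.

## Operating characteristics and oracles

`run_oc()` simulates `R` cohorts and applies each method.  For
non-confounded scenarios ITT and PP use an arm-level binomial shortcut —
success counts drawn directly from the mixture probabilities
$e_E = a_E\,\mathrm{eff}_E + (1-a_E)\,e_{\text{dest}}$ and likewise for the
control arm — which is orders of magnitude faster and is cross-validated
against the participant-level path in the test suite.

The closed-form oracle for the claim probability is

$$\Phi\!\left(\frac{\Delta_{\exp} + m}{se} - z_{1-\alpha}\right), \qquad
se = \sqrt{\tfrac{e_E(1-e_E)}{n} + \tfrac{e_C(1-e_C)}{n}},$$

exact for the arm-level binomial model *up to the normal approximation*.  By
exact binomial convolution the approximation error at $n$ per arm around
377–400 is up to about 0.004 in absolute probability; oracle-versus-Monte-
Carlo tests therefore allow 3 Monte-Carlo standard errors plus an explicit
0.005 approximation allowance.  At the boundary $\Delta_{\exp} = -m$ the
claim probability is $\alpha$ for *any* $n$, which is why the per-protocol
probability under non-confounded non-adherence stays at the nominal level.

`direction_matrix()` compares each catalogued scenario against a
100%-adherence baseline and labels the mean estimate and the claim
probability as `same` within 3 pooled Monte-Carlo standard errors, otherwise
`higher`/`lower`/(estimates only) `towards_0`.  The probability labels are
the primary characteristic; an estimate shift can be simultaneously
"towards zero" and "above the true deficit" depending on the reference
point, so estimate labels are informational.

## The scenario catalogue

Eighteen canonical scenarios combine the non-adherent population (both /
experiment / control), the destination (crossover / inferior alternative)
and confounding (none, or a severity-type confounder that *increases* or
*decreases* the stated switching probability).  Frozen constants, chosen
once as realistic study conditions:

| quantity | value | rationale |
|---|---|---|
| true difference | $-0.10$ (eff 0.5 vs 0.6) | inferior by exactly the 10% margin |
| margin, $\alpha$ | 0.10, 0.025 | standard NI frame |
| n per arm, replicates | 400, 5000–10000 | detectable shifts at practical runtime |
| marginal adherence | 0.75 per non-adherent arm | typical of pragmatic trials |
| alternative efficacy | 0.30 | clearly inferior to both arms (placebo-like) |
| severity outcome coefficient | $-0.3$ (success scale) | severity raises the harm outcome |
| adherence log-odds | magnitude 3 | moderately strong confounded selection |

For crossover rows, "switching towards the experimental treatment" is read
as the confounder raising $P(\text{receive } E)$ in both arms (log-odds $+3$
in the experimental arm, $-3$ in the control arm).  For the both-arm
inferior-alternative rows, a shared outcome coefficient with *symmetric*
adherence effects would make the per-protocol selection cancel exactly (the
treatment difference is constant in the confounder), so the catalogue makes
severity's effect on abandoning the assigned regimen stronger in the control
arm ($-5$ versus $-0.5$) — severe patients abandon the longer control
regimen more readily — which preserves the stated direction in each arm
while producing a genuinely asymmetric selection.

## The worked-example preset

An open-label trial of short- versus long-duration antibiotic treatment for
ventilator-associated pneumonia: 800 participants (400 per arm), 30-day
mortality risks 0.50 (short) versus 0.40 (long) — a true efficacy difference
of $-0.10$ against a 10% margin — and marginal adherence calibrated to 75%
in each arm (symmetric, the simplest reading of an overall 75%).  Two
confounders drive crossover: disease severity (uniform on $[0,1]$; $+0.3$ on
the death risk; log-odds $-3$ for adhering to the short arm, $+3$ for the
long arm — clinicians move severe patients to, and keep them on, long
treatment) and the treating physician (Bernoulli(0.5); doctor B lowers the
death risk by 0.1 and prefers short duration, log-odds $+2$/$-2$).  The
effect sizes are the package's own choices of plausible magnitudes; only the
design frame (sizes, efficacies, margin, adherence level) is fixed by the
scenario being emulated.

The preset produces the canonical qualitative picture at scale: the naive
per-protocol estimate understates the short arm's excess mortality by about
0.055 (adherent short-arm patients are milder and more often doctor B's),
intention-to-treat dilutes the difference to about half, inverse probability
weighting recovers the truth (the weight model is correctly specified by
construction), and the instrumental-variable interval is honest but wide.
Note the dilution floor: with 75% adherence in both arms the ITT difference
cannot shrink below $(a_E + a_C - 1)\Delta = -0.05$, so in a cohort of 800
the ITT analysis claims non-inferiority in only a minority of realisations —
single simulated datasets can show a starker contrast between the naive and
adjusted analyses than the repeated-sampling average does.

## Power and sample size

The analytic per-arm size is the normal-approximation formula
$n = \lceil (z_{1-\alpha} + z_{1-\beta})^2 \{p_E(1-p_E) + p_C(1-p_C)\} /
(m + \Delta)^2 \rceil$, without continuity correction — internal consistency
with the Wald test beats matching any particular textbook.  Rounding is per
arm.  `simulated_power()` wraps the operating-characteristics engine;
`required_n()` returns the analytic value under full adherence and
otherwise brackets by doubling and bisects on the simulated power, accepting
$n$ when power reaches the target minus one Monte-Carlo standard error.
Under symmetric crossover with a truly inferior experimental arm the
*required* $n$ falls as adherence falls — dilution moves the apparent
difference towards zero — which is precisely the hazard this package exists
to quantify, not a benefit.

## Biocreep

`run_chain()` simulates consecutive non-inferiority trials with fixed
comparator pairs (standard-of-care vs A, A vs B, B vs C, C vs D), each new
treatment truly 10% less effective than its comparator, all trials at a
common symmetric-crossover adherence.  A treatment becomes the accepted
standard only if its own and all preceding trials claimed non-inferiority;
the trials are independent, so the cumulative acceptance probability is the
product of per-trial claim probabilities (`chain_oracle()`).  A
"winner-carries-forward" semantics, where later comparators depend on
earlier outcomes, is deliberately not implemented.  Each trial's default
size (377 per arm) is computed the way sponsors size such trials — assuming
the new treatment truly equals its comparator — because sizing at the true
(boundary) difference would require an infinite trial.  Falling adherence
raises every treatment's acceptance probability; with the defaults here the
fourth treatment, 40% less effective than the original standard of care,
still becomes the standard about 3% of the time at 70% adherence.

## Numerical choices and degenerate inputs

* Quadrature: 64 Gauss–Legendre nodes per continuous confounder (exact to
  machine precision for the logistic integrands used here); Bernoulli
  components enumerated exactly.
* Root-finding bracket $[-35, 35]$ on the adherence intercept; achieved
  marginal verified to $10^{-6}$ or an error is raised.
* Bootstrap: percentile intervals at level $1-2\alpha$; replicates that fail
  to refit are dropped, and more than half failing is an error.
* Degenerate inputs error early and by name: empty arms, fewer than two
  adherent participants per arm, adherence target 0, alternative efficacy
  not below both arms, weak instruments, empty stratum-arm cells, unknown
  scenario identifiers.
* Problem sizes used by the test suite and acceptance script — 5,000
  replicates for the 18-scenario direction matrix, 10,000 for single-scenario
  claim probabilities and chains, 10 cohorts of 20,000 for large-sample
  recovery — were chosen so every targeted shift exceeds its 3-standard-error
  tolerance by at least a factor of two.

## Limitations

The simulator covers a time-fixed binary treatment and a binary endpoint:
no time-varying adherence, censoring, immortal-time structure, dropout,
clustering, or non-binary outcomes.  The generator's confounders are
independent with known parametric forms, and the IPW adherence model is
therefore correctly specified by construction — passing recovery tests show
the estimators work *when the weight model is right*, not that confounding
in real trials is as measurable or as well-behaved.  Non-adherence
destinations are a deterministic crossover or a single alternative
treatment, not a mixture.  G-estimation, matching and doubly-robust
estimators are out of scope, as are exact (Farrington–Manning) power
methods and group-sequential designs.
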