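---
title: "Serial latent mediation in competing-risk joint models: methods and design"
author: "serialjm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial latent mediation in competing-risk joint models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`serialjm` fits a joint model for two longitudinal outcomes and two
competing time-to-event outcomes in which the longitudinal outcomes form a
*serial chain* rather than a merely correlated pair. For subject $i$, the
first outcome follows a linear mixed model

$$y_{i1}(t) = m_{i1}(t) + \varepsilon_{i1}(t), \qquad
  m_{i1}(t) = x_{i1}^\top(t)\beta_1 + z_{i1}^\top(t) b_{i1},$$

with independent Gaussian measurement error of SD $\sigma_1$ and bivariate
normal random intercepts and slopes $b_{i1} \sim N(0, \Sigma_{b1})$. The
second outcome includes the *latent trajectory* of the first as a
time-varying covariate,

$$m_{i2}(t) = x_{i2}^\top(t)\beta_2 + z_{i2}^\top(t) b_{i2} + \xi\, m_{i1}(t),$$

so $\xi$ is directly interpretable: the change in the predicted value of
outcome 2 per unit increase in the predicted value of outcome 1, holding
the rest fixed. Using the latent value rather than the noisy observation
separates the process of interest from its measurement error. The random
effects of the two outcomes are a priori independent; their marginal
dependence is carried entirely by $\xi$.

Both latent processes drive two cause-specific hazards
($k = 1, 2$; in the motivating dementia-trial setting these are start of
open-label medication and dropout):

$$h_{ik}(t) = h_{0k}(t)\exp\{\gamma_k^\top w_i
  + \alpha_{k1} m_{i1}(t) + \alpha_{k2} m_{i2}(t)\}.$$

The log baseline hazards $\log h_{0k}$ are B-splines — cubic by default,
five interior knots at equally spaced quantiles of the observed event
times, boundary knots at 0 and the largest observed time. Modelling on the
log scale keeps the hazard positive for any coefficient value; evaluation
outside the boundary knots is an error rather than an extrapolation,
because silently extrapolated hazards are unsafe.

Cumulative hazards use 15-point Gauss–Legendre quadrature on $[0, T_i]$,
the standard choice in joint-model software. With the constant or smoothly
varying baselines used throughout the simulation designs the integrand is
analytic and the quadrature is accurate to well below $10^{-6}$ relative
error (the tests verify this against adaptive integration); for very rough
spline coefficients the integrand is only $C^2$ across knots and the
fixed-order rule is accurate to roughly $10^{-5}$, which is far below the
Monte Carlo noise of any posterior summary.

## The mediation decomposition

Let $\mathcal{B}_j(t)$ denote the intervention profile of outcome $j$: the
intervention main effect plus the intervention-by-time interaction times
$t$ (either term may be absent; at least one must be present). On the
log-hazard scale the intervention effect on risk 1 splits into four paths:

* **direct**: $\gamma_{11}$,
* **through outcome 1**: $\alpha_{11}\mathcal{B}_1(t)$,
* **through outcome 2**: $\alpha_{12}\mathcal{B}_2(t)$,
* **serially through both**: $\xi\alpha_{12}\mathcal{B}_1(t)$,

and the total time-varying hazard ratio is
$\mathcal{T}(t) = \exp\{\gamma_{11} + \alpha_{11}\mathcal{B}_1(t)
+ \alpha_{12}\mathcal{B}_2(t) + \xi\alpha_{12}\mathcal{B}_1(t)\}$.
This is the product-of-coefficients construction: every path coefficient is
estimated inside one model, simultaneously and mutually adjusted. A
difference-in-coefficients construction would need a second, differently
specified model for the unadjusted effect and cannot produce a
time-varying mediated effect, so it is deliberately not implemented.
`mediation_decompose()` evaluates all paths per posterior draw, so the
additivity identity holds to machine precision draw by draw, and the
symmetric decomposition for risk 2 is available via `risk = 2`.

All hazard ratios are conditional on the random effects
(subject-specific); no marginalization over random effects is attempted.
Credible bands are pointwise central 95% posterior intervals of each
exp-transformed component. Whether the plotted centre is the posterior
mean of $\exp(\cdot)$ or $\exp(\text{posterior mean})$ is a presentation
choice; the default is the former (`band_type = "mean_of_exp"`), the
latter is available. Note the decomposition quantifies paths under the
fitted model; it does not by itself establish causal mediation, which
would need sequential-ignorability-type assumptions that repeated,
serially dependent mediators violate.

## Priors

Weakly informative defaults, all overridable via `jm_priors()`:
$N(0, 10^2)$ on fixed effects, hazard coefficients, associations and
$\xi$; $N(0, 5^2)$ ridge on spline coefficients; half-$t(3, 2.5)$ on the
error and random-effect SDs; LKJ(2) on each within-outcome random-effect
correlation. These are the conventional choices for joint models of this
class and are effectively flat at the scale of standardized outcomes.

## Posterior computation

Sampling uses an adaptive block Metropolis-within-Gibbs written in C++:

* **Blocks**: $\beta_1$; $(\beta_2, \xi)$; $\log\sigma_j$; per risk the
  joint $(\gamma_k, \alpha_{k\cdot}, \phi_k)$ block, because the
  association parameters and the baseline spline ride a posterior ridge;
  the random-effect hyperparameters; and one all-parameter block whose
  covariance is adapted during warm-up to cross the remaining ridges.
  Scalar/low-dimensional blocks target acceptance 0.44/0.35, larger blocks
  0.234, with Robbins–Monro scale adaptation and Haario-style covariance
  adaptation, both frozen after warm-up.
* **Random effects** are updated subject by subject with proposals
  preconditioned by the analytic conditional precision (longitudinal
  information plus the random-effect prior).
* **Interweaving moves** exploit exact invariances of the likelihood:
  shifting any fixed effect while counter-shifting the random intercepts
  or slopes; shifting $\xi$ while absorbing $\delta\, m_{i1}(t)$ — exactly
  linear in $t$ per subject — into the outcome-2 random effects; jointly
  rescaling a random-effect SD with its effects; and rotating the random
  slopes with the correlation parameter in non-centred coordinates. These
  moves cost only the prior terms (or one likelihood pass) and remove the
  strong coupling between fixed effects and random-effect means that makes
  centred parameterizations mix slowly.

A gradient-based sampler (HMC/NUTS) would be a reasonable alternative;
only the posterior is the contract, and the Metropolis-within-Gibbs
scheme with interweaving was chosen because it admits exact, cheap
conditional updates for this model family and keeps the whole sampler
dependency-free. Initialization is per-outcome least squares for the
longitudinal fixed effects, crude event rates for the baselines, and zero
for all associations; a non-finite initial posterior is an error, not a
silent restart.

Convergence is monitored by split R-hat and an initial-positive-sequence
effective sample size, computed in-package. In the replication harness a
replicate is dropped (and counted) when any regression, association,
error-SD or random-effect parameter has split R-hat above 1.1. The gate
deliberately excludes the spline coefficients: the basis functions near
the right boundary are supported by very few subjects at risk, are
prior-dominated, and their slow drift says nothing about the scientific
parameters. The 1.1 threshold is matched to the chain lengths of the desk
preset: at a few thousand retained draws the sampling noise of split
R-hat itself is of order a few hundredths, and a 1.05 gate at these
lengths would discard replicates mostly by diagnostic noise rather than by
genuine non-convergence.

## The simulator and the study presets

`simulate_dataset()` draws from the full generative model: Bernoulli(0.5)
randomization; independent bivariate-normal random effects per outcome;
event times by inverting the all-cause survival function
$\exp\{-\sum_k \Lambda_{ik}(t)\} = U$ with bisection to $10^{-8}$ (exact
because the latent trajectories are linear in time per subject, which the
implementation exploits); exponential censoring with mean 5 years; an
administrative horizon of 3.2 years (ties between event and censoring go
to the event — a measure-zero case); and 10 equally spaced visits on the
horizon, kept while the subject is under observation, with Gaussian
measurement noise.

The named scenarios fix the generating coefficients of the simulation
design — $\beta_1 = (0.07, -0.25, 0.12)$, $\beta_2 = (0.15, 0.45, -0.10)$
(intercept, time, intervention-by-time; no intervention main effect),
$\gamma_{11} = -0.2$, $\gamma_{21} = 0.1$,
$\alpha = \begin{pmatrix} -0.6 & 0.4 \\ -0.1 & 0.1\end{pmatrix}$, and
$\xi = -0.5$ for the recovery study or $\xi \in \{-0.01, -1, -2, -3\}$
for the misspecification scenarios I–IV. Quantities the design leaves
unstated are package defaults, chosen once as realistic for standardized
outcomes and documented here: $\sigma_1 = \sigma_2 = 0.5$; random-effect
SDs 0.5 (intercept) and 0.25 (slope) with within-outcome correlation 0.2;
constant true baseline hazards of 0.25/year per risk, encoded as a cubic
spline with all coefficients $\log 0.25$ and shared by both risks. Under
these defaults roughly 45% of subjects experience event 1, 15% event 2,
and the rest are censored by 3.2 years — a realistic event/censoring mix.

Two presets size the replication harness. The **desk** preset — 50
replicates of 500 subjects, one chain of 2,000 retained draws (thinned by
2) after 1,250 warm-up per fit — runs on one CPU core in well under an
hour and is the scale at which the package's own tests and acceptance
script exercise parameter recovery: absolute bias of every regression,
association and serial parameter at or below 0.05 and coverage within
binomial noise of the mid-90% range. The per-dataset sample size is kept
at 500 deliberately: the treatment log-hazard-ratio coefficients
$\gamma_{k1}$ carry an inherent finite-sample bias that scales roughly
with $1/n$ (about $-0.03$ at $n = 500$ under this design, and about twice
that at $n = 250$), so shrinking the datasets rather than the replicate
count or chain length would move the harness outside the tolerance it is
meant to check for reasons that have nothing to do with implementation
correctness. A single chain per replicate follows common practice for
replication studies; split R-hat is still computed from the chain halves.
The **full** preset (200 replicates of 500 subjects with long chains)
reproduces the complete design and is intended for a cluster. Bias and
coverage are properties of estimator calibration, so the desk-scale check
is informative even though the full design's exact baseline-spline
coefficients and variance components are not recoverable from their
published description.

What the simulator deliberately does not emulate about real trial data:
irregular and outcome-dependent visit schedules, intermittently missing
measurements at attended visits, site and baseline-severity covariate
effects (supported by the model configuration but not part of the
generating scenarios), nonlinear latent trajectories, and any violation of
the model's own assumptions. Passing tests therefore demonstrate correct
self-recovery and calibrated uncertainty under the stated design — not
robustness to misspecification beyond the univariate-versus-multivariate
comparison that the second study targets.

## Numerical and degenerate-input conventions

* Measurement at $t = 0$ is legal; measurement after $T_i$ is a hard error
  naming the subject.
* Subjects without longitudinal measurements contribute survival
  information only.
* A univariate configuration (`long2 = NULL`) removes outcome 2, $\xi$,
  $\sigma_2$, $\Sigma_{b2}$ and $\alpha_{k2}$; on data whose outcome-2
  series are absent it is identical to the generic entry point.
* The event-time inverter reports administrative censoring (`NULL`) when
  the horizon's cumulative hazard cannot reach $-\log U$.
* Cause attribution at the solved event time uses
  $h_1(t^*)/\{h_1(t^*) + h_2(t^*)\}$.
* Equal-tailed (2.5%/97.5%) intervals are used everywhere, including for
  coverage; highest-density intervals are not.

## Known limitations

The hazard ratios are subject-specific; population-averaged (marginal)
effects would need integration over the random effects and are out of
scope. The serial direction (outcome 1 drives outcome 2) is an input, not
something the model can test; with no clear a-priori ordering a parallel
multivariate joint model is the better tool. Association structures other
than current-value (slope or cumulative loadings between the outcomes),
more than two longitudinal outcomes and more than two competing risks are
not supported.
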