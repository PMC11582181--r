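---
title: "Graded response state-space models: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded response state-space models: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordssm)
library(dplyr)
```

## The model

Intensive longitudinal designs — ecological momentary assessment (EMA),
experience sampling, daily diaries — produce ordinal time series: Likert-type
items answered many times a day. `ordssm` models such data with a
discrete-time, time-invariant state-space model whose latent states follow a
VAR(1),

$$x_{t+1} = A x_t + \varepsilon_t, \qquad \varepsilon_t \sim N_p(0, \Sigma),$$

and whose measurements are ordinal items under a graded response (GR) model.
Item $i$ measures exactly one state (simple structure, selector
$\delta_i$), and the probability of exceeding category $j$ is a cumulative
logistic curve with discrimination $\alpha_i$ and ordered thresholds
$\beta_{ij}$:

$$P(y_{it} > j \mid x_t) = \mathrm{logit}^{-1}\!\big(\alpha_i(\delta_i(x_t) - \beta_{ij})\big),
\qquad
P(y_{it} = j \mid x_t) = P(y_{it} > j-1 \mid x_t) - P(y_{it} > j \mid x_t),$$

with $P(y > 0) = 1$. The comparator throughout is the *linear
approximation*: treating the integer category codes as continuous and fitting
the normal-measurement model $y_t = C x_t + \varsigma_t$,
$\varsigma_t \sim N_q(0, \Psi)$ — the standard practice whose biases this
model class is designed to avoid.

### Identification: unit marginal state variances

A latent scale must be pinned down. Because the marginal covariance of the
states, $\Gamma$, is a function of both $A$ and $\Sigma$
($\mathrm{vec}(\Gamma) = (I - A \otimes A)^{-1}\mathrm{vec}(\Sigma)$),
fixing single entries of either matrix does not fix the state scale. Instead
the package solves, for every candidate $A$, for the unique pair
$(\Gamma, \Sigma)$ with $\mathrm{diag}(\Gamma) = 1$ and $\Sigma$ diagonal.
`identify_innovations()` implements this with the selection-matrix linear
solve for the off-diagonal of $\Gamma$ and back-substitution for
$\mathrm{diag}(\Sigma)$; `selection_structure()` exposes the selection
matrices themselves. The payoff is that estimates of $A$ are on the same
scale no matter which measurement model produced the likelihood, so GR and
linear-approximation dynamics can be compared directly.

Two numerical points. First, the solve uses the exact $p^2$-dimensional
linear system, not an iterative Lyapunov solver: state dimensions here are
small (typically $p \le 4$) and exactness matters because the solve sits
inside the estimator's innermost loop. Second, not every stationary $A$ is
compatible with unit marginal variances — the implied innovation variance
can be non-positive (rotation-heavy dynamics with complex eigenvalues are
the typical case). Such matrices raise a distinct infeasibility condition,
and the estimator treats them as zero-weight proposals rather than
reparameterizing; `vec()` stacking is column-major everywhere, verified by
round-trip tests.

## Filtering

For the linear measurement model the filtering distribution is Gaussian and
`kalman_filter()` gives exact filtered means and the exact log-likelihood by
prediction-error decomposition (it doubles as the oracle in the test suite).
Ordinal measurements make the filtering distribution intractable, so
`particle_filter()` implements the bootstrap filter: $K$ particles start
from $f_0 = N(0, I)$, propagate through the state equation with the
identification-implied $\Sigma$, are weighted by the measurement likelihood,
and are resampled every timepoint. Choices worth stating:

* **$f_0 = N(0, I)$, not $N(0, \Gamma)$.** The filter's initial law follows
  the estimation convention for this model class even though the stationary
  law is $N(0, \Gamma)$; the mismatch affects only the first few timepoints
  and keeps the filter's initialization parameter-free. The synthetic-data
  generator, by contrast, *does* draw $x_1 \sim N(0, \Gamma)$ so simulated
  trajectories are exactly stationary with no burn-in.
* **Systematic resampling** by default (one uniform per timepoint, lower
  Monte Carlo variance); multinomial resampling is kept for oracle tests.
  Resampling happens at every timepoint; ESS-triggered adaptive resampling
  is deliberately not used.
* **Log-weights throughout**, normalized per timepoint by log-sum-exp; the
  per-timepoint log-mean-weight accumulates into the log-likelihood
  estimate. Filtered means use the pre-resampling normalized weights.
* A proposal for which every particle has zero likelihood raises a
  degeneracy error carrying the timepoint — the signal that a parameter
  proposal is impossible, not a numerical accident.

## Parameter estimation: iterated filtering (MIF2)

`mif2_fit()` estimates $A$ (all $p^2$ entries, unconstrained) and optionally
the measurement parameters by iterated filtering: parameters ride along with
the state particles, get Gaussian perturbations whose scale cools
geometrically over iterations, and are resampled jointly with the states by
the same index vector. Over iterations the swarm freezes near the maximum
likelihood estimate, simulated-annealing style. Implementation contracts:

* **Estimation scale.** Thresholds are stored as (first threshold,
  log-intervals), so any Gaussian perturbation decodes to strictly ordered
  thresholds; linear error variances live on the log scale; $A$ entries are
  perturbed on the natural scale, and proposals that decode to
  non-stationary or infeasible dynamics simply receive zero weight. This
  keeps the sampler unbiased near the feasibility boundary instead of
  projecting onto it.
* **Cooling.** `cooling_sd(m, sd0, f)` returns
  $sd_0 \, f^{(m-1)/100}$: the perturbation *variance* halves-to-$f$ over 50
  iterations. The alternative convention (fraction applied to the SD over
  50 iterations, as in some other iterated-filtering implementations) is
  available as `cooling_on_sd = TRUE`.
* **Perturbation granularity.** By default each particle's parameters get
  one cooled Gaussian kick per MIF2 iteration (`perturb_every =
  "iteration"`). The classic continuous-random-walk kernel that re-perturbs
  at every observation is available (`"timepoint"`), but with the
  conventional starting SD of .3 it injects $0.3\sqrt{T}$ of
  within-iteration diffusion — about 6.7 SD units at $T = 500$ — and we
  found it reliably collapses the linear comparator's loadings into the
  flat large-$\Psi$ region of the likelihood (measurement signal lost,
  state recovery near zero), while the per-iteration kernel converges to
  the dominant basin for both measurement kinds. The per-iteration kernel
  also makes the effective annealing schedule independent of the series
  length.
* **Multi-run protocol.** `n_runs` independent runs from the same initial
  values (default $A = \mathrm{diag}(.1)$; thresholds starting at $-2$ with
  intervals .36; linear loadings 1 and error variances 1) are averaged
  elementwise on the estimation scale; a run's own estimate is the mean of
  its final parameter swarm. The data are then re-filtered at the averaged
  estimate to produce the reported filtered states. Runs that die of
  degeneracy are dropped with a warning as long as one survives.
* **Sign identification of the linear comparator.** The linear measurement
  likelihood is invariant to jointly negating a state and the loadings of
  its items, so independent runs can converge to opposite-sign copies of
  the same maximum — and averaging across modes would destroy the estimate.
  Each run is therefore aligned to the conventional mode in which every
  state's loadings sum positive ($A \to DAD$, loadings $\to D\,$loadings,
  $D$ diagonal $\pm 1$) before averaging, the standard resolution of sign
  indeterminacy in factor models. The graded response kind has no such
  aliasing: $\alpha_i > 0$ is fixed and thresholds are ordered.
* **Discriminations $\alpha_i$ are never estimated** (fixed, default 1):
  the likelihood is nearly flat in $\alpha$ away from zero, which defeats
  a stochastic hill-climber; calibrated values can be supplied instead.
* **Centering of the linear comparator.** The linear measurement equation
  has no intercept, but integer-coded categories have nonzero means while
  states are mean-zero. `mif2_fit()` therefore centers each item at its
  sample mean before fitting (recorded in the returned model; `center =
  "keep"` overrides). Without this the linear model cannot fit coded
  categories at all.

Three tuning presets are shipped: `mif2_preset("simulation")` (1000
particles, 250 iterations, cooling .05, SD .3 — the setting for synthetic
studies with estimated measurement parameters), `"empirical"` (500
iterations, cooling .75, SD .05, measurement fixed — the gentler schedule
that converges on real EMA series with externally calibrated items), and
`"desk"` (500 particles, 100 iterations, 2 runs) for reduced-scale work.
Empirical under-identification — sparsely used response categories — makes
simultaneous estimation of thresholds and dynamics fragile on real data; the
recommended workflow is to fix the measurement model from a calibration
(e.g. the table shipped in `inst/extdata/ema_measurement.csv`) and estimate
only the dynamics.

## Standard errors

MIF2 provides no curvature information, so `slice_se()` approximates
standard errors from *slice likelihoods*: fix all parameters at the
estimate, move one along a grid, evaluate replicated particle-filter
log-likelihoods with common random numbers across grid points, and fit a
quadratic; local asymptotic normality turns the curvature into a
per-parameter SE, $se = (-2c)^{-1/2}$. Defaults: 11 grid points, half-width
5 times the final cooled perturbation SD, 3 replicates per point. A flat or
convex slice raises an error — that is what empirical under-identification
looks like, and a fabricated SE would be worse than none.

These SEs ignore cross-parameter information and are liberal by
construction. The simulation harness measures the consequence: 95% Wald
intervals cover the autoregressive truth roughly three quarters of the
time, and the stricter 99.8% interval ($\pm 3.09\,se$, `wald_ci(level =
0.998)`) restores approximately nominal 95% coverage. Report slice SEs as
such, and prefer the wide intervals for decisions.

## The synthetic-data generator

`make_condition_dataset()` reproduces the two-state generating design used
throughout the package's own validation: $A = [[AR, CR], [0, AR]]$, both
states carrying identical GR item sets with $\alpha = 1$, and thresholds
built by either rule:

* `equal_thresholds(J)`: the integer sequence $1..J{-}1$ centered on zero —
  every item identical, e.g. $[-2.5, \ldots, 2.5]$ for $J = 7$;
* `offset_thresholds(n, J)`: items shifted symmetrically about zero by
  $\min(n/(J{-}1), 1.25)$ per step — items covering different regions of
  the latent continuum, as designed psychometric scales do. The centering
  of the whole collection at zero generalizes the printed three-item
  example symmetrically.

The full factorial grid (`condition_grid()`: T ∈ {100, 500}, 3 or 6 items
per state, 3 or 7 categories, AR ∈ {.3, .7}, CR ∈ {0, .25}, equal/offset —
64 conditions) and a pure seed manifest (`condition_seed()`) make any slice
of the study re-runnable bit-identically. What the generator does *not*
emulate about real EMA data: missingness patterns, unequal sampling
intervals, day/phase structure, response styles, and cross-loading items.
Passing synthetic benchmarks therefore says the estimator works when the
model is true, not that the model is right for a given dataset —
`posterior_predictive_item_mse()` exists for the latter question.

## Problem sizes used in the shipped validation

The package's own test suite and acceptance script run scaled-down versions
of the full design, chosen to exercise every pathway at interactive cost:
identification checks on thousands of random matrices plus one
$T = 100{,}000$ trajectory; particle-vs-Kalman likelihood agreement at
$K = 5000$ over 20 seeds; parameter recovery and the worst-condition
recovery medians with ~20 replicates per condition at the desk or published
preset; coverage at a reduced replicate count. The corresponding
full-scale quantities in the source study used 300 replicates per condition
across all 64 conditions. Medians of Spearman recovery are insensitive to
this reduction at the tolerance we test (a few hundredths), which is why
the scaled bands are meaningful.

## Known limitations

* Idiographic ($N = 1$): no pooling across participants; dynamics are
  comparable across fits, state values only when the measurement model is
  fixed and shared.
* No smoothing pass; filtering only.
* Slice SEs are liberal; profile likelihoods and Hessian approximations are
  out of scope.
* The estimator is simulation-based: a fit is minutes, not seconds, and
  tuning (particles, cooling, perturbation scale) can matter on difficult
  data; the presets encode the two settings known to work well. Starting
  values matter too: threshold starts far from their maximum-likelihood
  region (several latent-scale units) can strand a short run in a poor
  basin — compare multi-run log-likelihood traces (`autoplot(fit)`) and
  restart from better values when runs disagree.
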