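---
title: "Joint modelling of multivariate longitudinal and time-to-event data in multijm"
author: "multijm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of multivariate longitudinal and time-to-event data in multijm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`multijm` fits a joint model for K continuous longitudinal outcomes and one
right-censored event time. Each outcome follows a linear mixed sub-model

$$y_{ik}(t) = \mathbf{x}_{ik}^\top(t)\,\boldsymbol\beta_k +
  \mathbf{z}_{ik}^\top(t)\,\mathbf{b}_{ik} + \varepsilon_{ik}(t), \qquad
  \varepsilon_{ik}(t) \sim N(0, \sigma_k^2),$$

with subject-and-outcome random effects stacked as
$\mathbf{b}_i = (\mathbf{b}_{i1}^\top,\dots,\mathbf{b}_{iK}^\top)^\top \sim
N(0, \mathbf{D})$ for an unstructured covariance $\mathbf{D}$ whose
off-diagonal blocks carry the between-outcome correlation. The hazard of the
event is

$$\lambda_i(t) = \lambda_0(t)\,\exp\{\mathbf{v}_i^\top\boldsymbol\gamma_v +
  W_{2i}(t)\}, \qquad
  W_{2i}(t) = \sum_{k=1}^K \gamma_{yk}\, \mathbf{z}_{ik}^\top(t)\,\mathbf{b}_{ik},$$

so the same latent trajectories that generate the longitudinal data shift
the hazard, with one association coefficient $\gamma_{yk}$ per outcome. The
baseline hazard $\lambda_0$ is left unspecified and estimated
nonparametrically with an atom at every distinct observed failure time.
Conditional on $\mathbf{b}_i$ (and covariates) the two processes are
independent; censoring and visit times are assumed non-informative. More
elaborate latent structures (stationary Gaussian process components,
frailties in the hazard) and time-varying survival covariates are out of
scope; survival covariates are taken at baseline.

### Assumptions worth stating plainly

* Residuals are homoscedastic and serially uncorrelated within outcome.
* The association is through the *current value* of the latent trajectory
  (a weighted sum of the $W_{1i}^{(k)}$); no slope-only or cumulative forms.
* Measurements recorded after the observed event/censoring time are retained
  with a warning: the likelihood conditions on all recorded measurements and
  nothing in the estimation requires truncating them.

## Estimation: Monte Carlo EM

The observed-data likelihood integrates the random effects out of
$f(\mathbf{y}_i\mid\mathbf{b}_i)\,f(T_i,\delta_i\mid\mathbf{b}_i)\,
f(\mathbf{b}_i)$. Treating $\mathbf{b}_i$ as missing data gives an EM
algorithm whose E-step requires conditional expectations
$E[h(\mathbf{b}_i)\mid T_i,\delta_i,\mathbf{y}_i]$. These are intractable,
but $\mathbf{b}_i \mid \mathbf{y}_i$ is Gaussian with covariance
$\mathbf{A}_i = (\mathbf{Z}_i^\top\boldsymbol\Sigma_i^{-1}\mathbf{Z}_i +
\mathbf{D}^{-1})^{-1}$, so the E-step samples from that Gaussian and
reweights by the survival density
$f(T_i,\delta_i\mid \mathbf{b})$ (a self-normalised importance-sampling
ratio). Draws are **antithetic pairs** $\mu_i \pm \mathbf{C}_i\Omega$ with
$\mathbf{C}_i\mathbf{C}_i^\top=\mathbf{A}_i$: pair averages equal the
posterior mean exactly and negative within-pair correlation reduces the
Monte Carlo variance. Log-weights are shifted by their maximum before
exponentiation to avoid underflow. The weight of a draw is

$$\log f(T_i,\delta_i \mid \mathbf{b}) =
  \delta_i\{\log\lambda_0(T_i) + \mathbf{v}_i^\top\boldsymbol\gamma_v +
  W_{2i}(T_i)\} - \sum_{j:\ t_j \le T_i} \lambda_{0j}
  \exp\{\mathbf{v}_i^\top\boldsymbol\gamma_v + W_{2i}(t_j)\},$$

the cumulative hazard being a step-sum over the hazard atoms (the
nonparametric maximum-likelihood convention; it also makes the Breslow
M-step self-consistent).

The M-step is closed-form for everything except the hazard coefficients:
generalized least squares for $\boldsymbol\beta$ (block-diagonal designs
decouple it per outcome), expected residual sums of squares for each
$\sigma_k^2$, $\mathbf{D} = n^{-1}\sum_i E[\mathbf{b}_i\mathbf{b}_i^\top]$,
and the Breslow update
$\lambda_{0j} = d_j / \sum_{i \in R(t_j)} E[\exp\{\mathbf{v}_i^\top
\boldsymbol\gamma_v + W_{2i}(t_j)\}]$. The coefficients
$\boldsymbol\gamma = (\boldsymbol\gamma_v, \boldsymbol\gamma_y)$ take **one**
Newton-Raphson step per iteration (step size 1) using the observed
information at fixed $\lambda_0$, or optionally a Gauss-Newton-like step
(size 0.5) using the empirical information
$\sum_i s_i s_i^\top - n^{-1}SS^\top$, which is cheaper. In practice the two
give nearly indistinguishable estimates; both are exercised in the tests.

### Stopping rules and dynamic Monte Carlo size

Convergence is monitored on $\theta_{-\lambda}$ = (beta, vech(D), sigma^2,
gamma); the high-dimensional profiled baseline hazard is excluded. Two
classical rules are available: the relative difference
$\Delta_{rel} = \max |\theta' - \theta| / (|\theta| + \epsilon_1)$ with
tolerance $\epsilon_0$, and the absolute difference with tolerance
$\epsilon_2$. Because several covariance entries in realistic designs are
essentially zero, the pure relative rule can never pass for them under
Monte Carlo noise; the default is therefore a **hybrid** rule: parameters
with magnitude below 0.01 are checked by absolute difference, the rest by
relative difference. Defaults are $\epsilon_0 = \epsilon_2 = 0.005$,
$\epsilon_1 = 0.001$, and the rule must pass on **three consecutive
iterations** to guard against premature stochastic convergence.

The MC size starts at $N_0 = 100K$ and is held there for a burn-in of
$100K$ iterations ($K$ = number of outcomes). Afterwards, a coefficient of
variation of the last three $\Delta_{rel}$ values is compared with the
previous (overlapping) window; if it has increased — parameter changes are
being swamped by MC error — $N$ grows to $N + \lfloor N/\delta\rfloor$
(default $\delta = 3$), rounded up to an even number to keep antithetic
pairing. `N_max` (default unbounded) optionally caps $N$: the growth rule
occasionally compounds into the $10^5$ range on slowly-converging fits, and
a cap bounds compute without changing the model being fitted. Study scripts
in this package set `N_max = 5000`.

### Initial values

Separate univariate linear mixed models (ML, via `lme4`) seed a dedicated
EM algorithm for the **multivariate** LMM, whose E- and M-steps are closed
form; because that EM is exact, it uses a stricter absolute tolerance
(1e-6; the paper trail for this choice is that a deterministic EM can
afford it, while the MCEM cannot). For the hazard: when visit schedules are
balanced across outcomes, BLUP-estimated latent trajectories from the
separate fits enter a Cox model (Breslow ties, via `survival`) as
left-continuous step time-varying covariates evaluated at the distinct
failure times, yielding starting values for $(\boldsymbol\gamma_v,
\boldsymbol\gamma_y)$; with unbalanced schedules a baseline-covariate-only
Cox model is used and $\boldsymbol\gamma_y$ starts at zero. The baseline
hazard starts from Breslow increments computed with the random effects fixed
at their posterior means.

### Standard errors

The default is the **empirical profile information**: per-subject
conditional expected complete-data scores for $\theta_{-\lambda}$ at the
maximiser (with $\lambda_0$ replaced by its Breslow estimator), combined as
$I_e = \sum_i s_i s_i^\top - n^{-1} S S^\top$. The subtracted term would
vanish at an exact maximiser and is kept because MC error leaves it slightly
nonzero. Score expectations are recomputed with a fresh MC sample four times
the final fit size to reduce MC contamination. These SEs inherit the known
tendency of implicit-profile estimators to understate uncertainty. The
alternative is a subject-level **bootstrap** (resample subjects with
replacement, re-label, refit from the fitted estimates; percentile
intervals; non-converged replicates dropped and counted). No SEs are
produced for $\lambda_0$, and the profiled baseline does not count towards
the parameter dimension in AIC/BIC.

## The simulator

`sim_scenario()` encodes the bivariate reference design used throughout the
package: n = 200 subjects, visits at 0..5, random intercepts and slopes per
outcome, intercept variances 0.25, slope variances 0.04, intercept–intercept
covariance −0.125 (correlation −0.5), residual variances 0.25, fixed effects
(0, 1, 1, 1) and (0, −1, 0, 0.5) on (intercept, time, x1, x2) with
x1 ~ N(0,1) and x2 ~ Bin(1, 0.5) shared by both sub-models, Gompertz
baseline hazard $\exp(\theta_0 + \theta_1 t)$ with $\theta_0 = 0.25$,
$\theta_1 = -3.5$, hazard coefficients $\gamma_v = (0, 1)$ and associations
$\gamma_y = (-0.5, 1)$, independent exponential censoring at rate 0.05, and
administrative censoring: any subject whose event and censoring times both
exceed 5 is recorded as censored at 5.1. Event times invert the subject's
log-linear cumulative hazard in closed form
(`invert_loglinear_hazard`); with a negative slope the cumulative hazard is
bounded and the event may never occur, which is why some censoring must be
active. Longitudinal visits are kept up to the observed time, the standard
practice for joint-model simulations (the paper trail is silent on it). A
multivariate-$t_5$ variant draws the random effects from a heavier-tailed
distribution scaled so the *covariance* (not the scale matrix) equals
$\mathbf{D}$, keeping true values comparable.

What the simulator does **not** emulate: irregular or informative visit
schedules, missing visits before dropout, measurement-error structure beyond
i.i.d. Gaussian noise, and covariate-dependent censoring. Passing tests on
simulated data therefore demonstrate correctness of the estimation machinery
under the stated model, not robustness to real-data violations of it.

## Evaluation convention for the hazard design

The hazard needs $\mathbf{z}_{ik}(t)$ at arbitrary event times, but the
package deliberately avoids a formula language (inputs are plain numeric
columns). The convention: a random covariate column equal to the outcome's
time column evaluates to $t$; any other random covariate must be constant
within subject (intercepts, baseline covariates). This makes every
$\mathbf{z}_{ik}(t)$ affine in $t$, which the implementation exploits
heavily (the per-subject design maps are two constant matrices), and covers
random-intercept / random-slope models — the forms used in practice with
this class of joint model. Columns that vary within subject and are not the
time column are rejected at hazard-evaluation time with a clear error.

## Numerical choices

* Posterior precision matrices are factorised by Cholesky; failures raise an
  error carrying the condition number.
* $\mathbf{D}$ iterates are symmetrised and eigenvalue-floored at 1e-10
  (warning on activation) to survive MC rounding noise.
* Log-weights use the max-shift; a subject whose weights are all zero
  (all log-weights $-\infty$) raises a "degenerate survival weights" error
  naming the subject.
* Duplicate (id, time) rows within an outcome are an error, not averaged:
  silent aggregation would change $\boldsymbol\Sigma_i$.
* Missing responses or covariates drop the row with a warning; no
  imputation.
* Ties in event times are handled by Breslow's convention throughout,
  matching the Breslow baseline estimator.
* The E-step refreshes all draws every iteration (no reuse across
  iterations), avoiding dependence bias; given a seed, fits are bit
  reproducible (the C++ sampler consumes the R RNG stream in the same order
  as the R-level constructor).

## Known limitations, and one honest finding

On flat datasets the association parameters are weakly identified: with
n = 200 and roughly half the subjects experiencing events, the observed
log-likelihood can be nearly constant (a couple of log-likelihood units)
along a ridge that trades $\boldsymbol\gamma_y$ against the random-effect
variances. On such datasets any faithful maximiser — this package's MCEM, an
independently coded dense-quadrature profile likelihood, and a Bayesian fit
of the same model — lands far from the generating values, with commensurately
large standard errors. Consequences: single-dataset estimates of
$\gamma_{y}$ can be several reference-SEs from truth while remaining inside
their own (wide) confidence intervals, and simulation-study empirical SEs
for $\gamma_y$ are larger than the tightest published figures for this
design. Confidence-interval coverage is not materially harmed because the
SEs widen along with the spread. Users fitting small studies should inspect
the convergence trace and treat point estimates of weakly identified
association parameters with caution.

## Problem sizes used by the packaged studies

The packaged acceptance study (`scripts/acceptance.R`, 8 replicates) and the
heaviest test (10 replicates) use a reduced design as the package's own
study condition: replicates of the default scenario fitted with
$N_0 = 100$, burn-in 100, $\epsilon_0 = 0.01$, `N_max = 5000`, and
empirical-information SEs; plus one single end-to-end fit. Oracle comparisons (dense-grid quadrature, finite
differences, hand-computed Breslow increments, closed-form inversions) run
on instances with $r \le 2$ and up to $2\times10^5$ Monte Carlo draws.
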