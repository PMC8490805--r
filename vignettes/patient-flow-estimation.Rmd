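---
title: "Two-stage state and rate estimation for patient-flow networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage state and rate estimation for patient-flow networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porterflow)
```

## The model

A patient-flow process is described by transfer rules over labelled nodes
(species): each rule consumes unit counts of its input species and produces
unit counts of its outputs. We restrict the flow law to first-order mass
action with a single unit-coefficient driver species, $v_j = k_j\,
\eta_{d(j)}$, because that is the only reading under which the compiled
dynamics

$$\frac{d\eta}{dt} = A(k)\,\eta + B(k)\,u(t)$$

are linear; rules with several input species are rejected in linear mode
rather than silently linearized. Source rules (empty input side) are driven
by an exogenous arrival channel through $B(k)$ with entries $k_j b_{ij}$;
sink rules remove items at rate $k_j \eta_{d(j)}$. Stoichiometric
coefficients are nonnegative integers, rates are nonnegative reals, and the
time unit is minutes throughout. Rates are treated as constant in time; what
varies is our *estimate* of them.

$A$ and $B$ are linear and homogeneous in $k$, so the derivative pair
$(\partial A/\partial k_j, \partial B/\partial k_j)$ is constant and equals
rule $j$'s contribution at $k_j = 1$; `rate_jacobians()` exploits this, and
$\sum_j k_j\,\partial A/\partial k_j = A(k)$ is asserted in the tests.

## Two-stage estimation

The scheme alternates two estimators over each observation epoch.

**Stage 1.** The sensitivity functions $\psi_j(t) = \partial\eta/\partial
k_j$ obey $\dot\psi_j = A\psi_j + (\partial A/\partial k_j)\eta + (\partial
B/\partial k_j)u$ with $\psi_j(0) = 0$. We integrate the nominal state and
all $r$ sensitivities as one joint linear system, stepped exactly by matrix
exponentials, so model and sensitivities are mutually consistent to machine
precision. In parallel a continuous–discrete Kalman filter produces the
state estimate $\hat\eta$: between observations the mean follows
$\dot{\hat x} = F\hat x + Bu$ and the covariance $\dot\Sigma = F\Sigma +
\Sigma F^\top + GQG^\top$; at each observation instant the standard update
with gain $K = \Sigma H^\top (H\Sigma H^\top + R_{obs})^{-1}$ applies. We
take $F$ to be the system matrix of whatever `linear_dynamics` is supplied —
the plain $A(k)$ in state-only use, or the $2N$ sensitivity-augmented block
matrix $[[A, \partial A/\partial k_j],[0, A]]$ from
`build_augmented_system()` when state and sensitivity are filtered jointly.
The augmentation is per parameter ($r$ separate $2N$ systems) rather than
one $(r+1)N$ system: the $\psi_j$ do not couple to each other, and the
covariance bookkeeping stays simple.

**Stage 2.** The residual $y(t) = \hat\eta(t) - \eta_{model}(t)$ is, to
first order, $\Psi(t)\,\Delta k$ with $\Psi = [\psi_1 \cdots \psi_r]$. The
perturbation estimate minimizes the exponentially forgotten least-squares
criterion $\int_0^t e^{-a(t-\tau)}\,\lVert y(\tau) - \Psi(\tau)^{\!\top\!}
\Delta k\rVert^2 d\tau$ (we read the criterion's integrand as a *squared*
residual norm — only that reading makes the stated gradient-flow equations
its minimizer), whose flow is

$$\frac{d\Delta\hat k}{dt} = P\,\Psi^\top (y - \Psi\,\Delta\hat k), \qquad
  \frac{dP}{dt} = aP - P\,\Psi^\top\Psi\,P, \qquad
  \frac{dR}{dt} = -aR + \Psi^\top\Psi,$$

with $R = P^{-1}$ the exponentially weighted Fisher information. Estimate
and model are compared at the same time stamp, which absorbs the drift term
that would otherwise appear when aligning a perturbed estimate with a
nominal trajectory; no extra regressor is introduced.

With the refresh option (on by default) the accumulated perturbation is
folded into the nominal rates every `cadence` epochs after a burn-in, the
rates are projected onto $k \ge 0$, the model state is rebased onto the
filtered estimate, and the sensitivities restart from zero. Each refresh
re-linearizes the regression about the improved rates, in the spirit of a
recursive Gauss–Newton iteration; a no-refresh mode retains the pure linear
theory and is used in the linear-theory tests.

### Identifiability needs excitation

Under a constant arrival input the network settles into a steady state
$\eta^* = -A^{-1}Bu$ that is *invariant* under proportional scaling of all
rates: $\Psi^\top\Delta k \to 0$ for $\Delta k \propto k$. With forgetting
($a > 0$) the transient information that distinguishes that direction decays
away and the estimate can drift along it. The estimator therefore needs a
time-varying input — which hospital arrivals naturally provide — and the
reference scenarios in the test suite use a step-profile arrival intensity.
The Fisher matrix makes the diagnosis operational: directions the data do
not excite stay at their $\varepsilon$-level initialization, and
`two_stage_estimate()` reports a configuration as non-identifiable when the
Fisher spectrum remains rank-deficient (relative eigenvalue threshold
$10^{-8}$) after burn-in.

## Numerical choices

* **Exact linear stepping.** State and displacement per step come from
  $\exp([[A, Bu],[0,0]]\,\Delta t)$; the covariance propagation and the
  discrete process noise from Van Loan's block-exponential construction.
  Inputs are held piecewise-constant between grid points (matching the CSV
  observation cadence); other interpolations are out of scope. Steps with
  repeated $(\Delta t, Bu)$ reuse cached exponentials, so regular grids cost
  one decomposition.
* **Joseph-form update.** Covariances are updated as $(I-KH)\Sigma(I-KH)^\top
  + KR_{obs}K^\top$, algebraically equal to $(I-KH)\Sigma$ but PSD-safe; the
  equality is asserted as a test, not relied on numerically. Innovation
  covariances with reciprocal condition below $10^{-14}$ are rejected.
* **Shared quadrature for $P$ and $R$.** The discrete recursion decays the
  information by $e^{-a\Delta t}$ exactly and adds the regressor outer
  product by the trapezoidal rule, split into two rank updates (previous
  regressor before the decay, current one after). The gain matrix is updated
  through the Woodbury identity on the same increment, and the estimate is
  maintained in information form ($\Delta\hat k = P b$, with $b$ the
  matching information vector), so the discrete estimate is the exact
  criterion minimizer at every step and $P(t)R(t) = I$ holds to roundoff
  under matched initialization — the checkable version of the claimed
  correspondence between the forgetting-factor estimator and standard
  filtering. Roundoff-level indefiniteness in $P$ is repaired by eigenvalue
  flooring; a genuinely indefinite update (degenerate regressors) is an
  error.
* **Initialization.** The defining integral gives $R(0) = 0$, leaving
  $P(0)$ undefined; we default to $P(0) = p_0 I$ with $p_0 = 10^4$ (an
  almost-uninformative prior on $\Delta k$) and $R(0) = p_0^{-1} I$ so the
  duality holds from the start. The filter start is likewise unspecified in
  principle: when no initial state is supplied, $\hat x(0)$ is lifted from
  the first observation by the Moore–Penrose pseudo-inverse of $H$ with
  $\Sigma(0) = \sigma_0^2 I$ ($\sigma_0 = 10$ counts by default). Both are
  config knobs, flagged as choices the underlying theory does not make.
* **Process noise.** All process noise is modelled at the filter level as
  $G\,dw$ with intensity $Q$; the sensitivity integrator itself is
  deterministic. $G$ defaults to the identity on the state rows (zero on
  sensitivity rows in augmented use) and $Q$ to a diagonal supplied in
  config — the uncertainty-on-rates interpretation of the noise is exposed
  only through this matrix, since no concrete value is available to encode
  more.

## The synthetic generator

`simulate_linear_sde()` draws from the exact Gaussian transition law of the
linear SDE (mean by matrix exponential, covariance by the Van Loan
integral), so estimator tests run against data whose model is *exactly* the
one being fitted; that isolates estimator defects from model error.

`simulate_porter_day()` is a discrete-event simulation of the dispatch
process: inhomogeneous Poisson arrivals over a piecewise-constant daily
profile, a pool of identical porters, non-preemptive priority queueing
(higher class first, FCFS within class), and per-order stage durations drawn
from moment-matched distributions. The stage family defaults to lognormal
because the measured searching-time SD (10.66 min) far exceeds its mean
(5.37 min), ruling out symmetric families; gamma and deterministic are
offered as alternatives. Clear-call (reporting) time is treated as zero.
Priority weights default to 0.7 / 0.2 / 0.1 for normal / urgent / very
urgent — the class structure is standard, the weights are our choice. The
hourly shape of the arrival profile is likewise our choice (quiet nights at
25% of the daytime base, elevated 10:00–12:00 and 14:00–17:00 windows) and
is isolated in `arrival_profile()`.

### Stage composition and the peak preset

The three stage definitions overlap in the source process: the migrating
interval is clocked from the moment the porter *starts moving toward the
patient* to the completion report, so it contains the walking leg. The
simulator supports both compositions. The default is `"sequential"` (total
service = searching + walking + migrating = 18.395 min at the means), the
simplest pipeline reading and the one the stage-occupancy counts assume. The
frozen peak-congestion preset (`porter_peak_preset()`) uses
`"overlapping"` (total = searching + max(walking, migrating)), because the
20-minute service target is only consistent with that reading: under
sequential lognormal stages, more than 30% of orders would exceed 20 minutes
*even with zero queueing*, whereas the overlapping composition puts the
uncongested miss probability near one fifth — matching the operating figure
the defaults encode. The preset's one free parameter, the peak intensity
multiplier, was fixed once at 3.0 and is thereafter frozen; with ~1,000
orders/day across 80 porters the pool utilization is low (~0.2 at peak), so
the peak miss fraction is a property of the service-time distribution, not
an emergent congestion prediction, and the preset is a calibration
verification target rather than a forecast.

### What the generator does not emulate

No geography (elevator queues, the ~195 m walks are only absorbed into the
walking/migrating distributions), no porter shifts, breaks or decentralized
dispatch policies, no order cancellations, and no state-dependent arrival
suppression. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated stochastic model, not fidelity of that
model to any particular hospital.

## Reference problem sizes

The test suite and the acceptance script use: 200,000 draws per service
stage for the moment checks; 100 simulated days (≈55,000 peak-window orders)
for the service-level check; 480 one-minute observation epochs for the
filter and recovery scenarios (an 8-hour shift at the natural observation
cadence); and a 10% proportional rate perturbation at observation noise
SD 0.01 counts with process-noise intensity $10^{-4}$ for the headline
recovery test. These sizes were chosen as representative of one hospital
working day and keep every scenario comfortably reproducible on a laptop.

## Known limitations

Nonlinear (bilinear or saturating) flow laws, time-varying rate constants,
capacity constraints inside the ODE, smoothing, adaptive noise estimation,
constrained estimation beyond the $k \ge 0$ projection, and model selection
among candidate networks are all out of scope. The linear model is a fluid
approximation of the underlying queueing process: when the DES counts are
filtered, the compartmental rates play the role of effective service rates,
and discrepancies between the two are expected at low occupancy.
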