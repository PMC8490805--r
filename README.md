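# porterflow

Hospitals move patients and materials between wards through porter services:
an order is placed, a dispatcher finds a free porter (*searching*), the porter
walks to the pickup ward (*walking*), and transports the patient to its
destination (*migrating*). Planners need short-horizon forecasts of how many
orders sit in each stage of this pipeline, and the transfer rates that drive
those forecasts drift and are never known exactly.

`porterflow` implements a two-stage estimation engine for such patient-flow
networks, for hospital operations analysts and researchers in health-care
queueing:

1. **Network compiler.** A flow process is written as transfer rules in a
   small text DSL, e.g. `WAIT -> TRANSIT @ k1`, with source rules driven by
   exogenous arrival channels (`0 -> WAIT @ k0 [u_arrivals]`). Rules compile
   to the linear compartmental model
   *dη/dt = A(k)η + B(k)u(t)*, where η is the vector of node counts and
   *k* the per-minute rate constants; *A* and *B* are linear in *k*, and the
   per-parameter derivatives ∂A/∂k_j, ∂B/∂k_j come for free.
2. **Stage 1 — state estimation.** A continuous–discrete Kalman filter
   propagates mean and covariance exactly between (possibly irregular)
   observation instants (matrix-exponential / Van Loan discretization) and
   assimilates node-count observations *z(tₙ) = H x(tₙ) + v(tₙ)* with a
   Joseph-form update. Alongside, the sensitivity functions
   ψ_j(t) = ∂η/∂k_j are integrated jointly with the nominal model.
3. **Stage 2 — rate estimation.** The residual *y(t) = η̂(t) − η_model(t)*
   is regressed on the sensitivity matrix Ψ(t) by recursive least squares
   with exponential forgetting (rate *a* per minute),
   *dΔk̂/dt = P Ψ (y − Ψᵀ Δk̂)*, *dP/dt = aP − P Ψ Ψᵀ P*, together with the
   Fisher information *dR/dt = −aR + Ψ Ψᵀ*, which is propagated with the
   same quadrature so that *P·R = I* holds along the trajectory. Estimated
   perturbations are folded back into the nominal rates, re-linearizing the
   scheme as it runs.

A seeded synthetic-data module provides (a) exact simulation of the linear
stochastic model and (b) a discrete-event simulation of a porter dispatch
service — inhomogeneous Poisson arrivals, priority queueing over a porter
pool, and lognormal stage durations calibrated by moment matching to the
motivating hospital's measured statistics (searching 5.37 ± 10.66, walking
4.00 ± 3.56, migrating 9.025 ± 7.13 minutes; ~1,000 orders/day, ~80 porters,
20-minute completion target, congestion peaks 10:00–12:00 and 14:00–17:00).

## Worked example

Estimate all three rates of a two-node tandem network from 8 hours of
1-minute node counts, when the true rates sit 10% above the nominal values:

```r
library(porterflow)

net <- parse_rule_file("
0 -> WAIT @ k0 [u_arrivals]
WAIT -> TRANSIT @ k1
TRANSIT -> 0 @ k2")
kbar  <- c(k0 = 1, k1 = 0.2, k2 = 0.1)   # nominal rates (per minute)
ktrue <- 1.1 * kbar                       # ground truth: +10% everywhere
u <- function(t) 2 + 2 * (t %% 240 >= 60 & t %% 240 < 180)  # arrivals/min

dyn <- build_system_matrices(net, ktrue, Q = diag(1e-4, 2))
om  <- observation_model(diag(1, 2), diag(0.01^2, 2))
sim <- simulate_linear_sde(dyn, c(5, 10), u, 0:480, om, seed = 7)

fit <- two_stage_estimate(net, rate_parameters(kbar, net), sim$series, om,
                          estimator_config(u = u, eta0 = c(5, 10),
                                           q_process = 1e-4, sigma0 = 1))
fit
#> two-stage fit: 481 epochs, 3 rate parameters
#> final rate estimates:
#>        k0        k1        k2
#> 1.1033862 0.2205821 0.1103434
```

Every rate is recovered within 0.4% of the truth (1.1, 0.22, 0.11); starting
from the nominal values would have left a 10% error. The arrival intensity
must vary over time (as hospital arrivals do): under a constant input the
steady state is invariant to proportional rate changes and that direction of
*k* becomes unidentifiable.

The porter simulator reproduces the operating profile its defaults encode:

```r
log <- simulate_porter_day(porter_peak_preset(n_days = 10, seed = 42))
s <- sla_statistics(log, 20)
sprintf("SLA misses: %.1f%% overall, %.1f%% in peak windows",
        100 * s$exceed_fraction, 100 * s$peak_exceed_fraction)
#> "SLA misses: 21.0% overall, 20.7% in peak windows"
```

about a fifth of peak-window orders exceed the 20-minute target.
`orders_to_counts()` bins such a log into per-stage occupancy series that
feed straight into the filter, and `flow_cli()` (or the
`inst/cli/porterflow` script) exposes `simulate` / `calibrate` / `filter` /
`estimate` / `forecast` subcommands over YAML configs — see
`inst/extdata/tandem.yaml`.

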