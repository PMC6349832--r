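---
title: "Adaptive Fisher-information stimulus design for E-I rate networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Fisher-information stimulus design for E-I rate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eidesign)
```

## The model

`eidesign` studies system identification for the smallest recurrent
firing-rate circuit: one excitatory and one inhibitory unit with
membrane-potential-like states $V_e, V_i$,

$$\dot V_e = \beta_e\bigl(-V_e + w_{ee}\,g_e(V_e) - w_{ei}\,g_i(V_i) + w_e I(t)\bigr),$$
$$\dot V_i = \beta_i\bigl(-V_i + w_{ie}\,g_e(V_e) - w_{ii}\,g_i(V_i) + w_i I(t)\bigr),$$

with logistic gains $g_j(V) = \Gamma_j / (1 + e^{-a_j(V - h_j)})$. The eight
estimated parameters, in the canonical order used throughout, are
$\theta = (\beta_e, \beta_i, w_e, w_i, w_{ee}, w_{ei}, w_{ie}, w_{ii})$:
inverse time constants in 1/s and nonnegative dimensionless weights (the
signs of inhibition are written into the equations). The gain constants
($\Gamma_e = 100$ spikes/s, $a_e = 0.04$, $h_e = 70$; $\Gamma_i = 50$,
$a_i = 0.04$, $h_i = 35$) describe the input-output property of each unit
and are treated as known, so the estimation problem is purely about the
network.

Only the excitatory unit is observed, and only through spikes: recordings
are inhomogeneous-Poisson spike trains with intensity
$r_e(t) = g_e(V_e(t))$. The log-likelihood of $M$ independent
stimulus-response pairs is

$$\ell(\theta) = \sum_{m=1}^{M}\Bigl[-\int_0^T r_e^{(m)}(t)\,dt +
  \sum_k \ln r_e^{(m)}(t_k^{(m)})\Bigr].$$

## Stimuli and the design criterion

Stimuli are bounded Fourier series on a harmonic grid,
$I(t) = \sum_{n=1}^{N} A_n \cos(2\pi n f_{base} t + \phi_n)$, with defaults
$N = 5$, $f_{base} = 10/3$ Hz, duration $T = 3$ s and amplitude bound
$A_{max} = 120$ (so one stimulus covers exactly ten base periods). Phases
are unconstrained during optimization and wrapped to $[-\pi, \pi)$ only for
reporting, which leaves the waveform unchanged.

A stimulus is scored by the trace-based (A-optimal) utility of the
time-integrated Fisher information of the Poisson observation,

$$U_k(x, \theta) = \int_0^T \frac{1}{r_e}\Bigl(\frac{\partial r_e}{\partial \theta_k}\Bigr)^2 dt,
\qquad U = \sum_{k=1}^{8} U_k ,$$

maximized over the $2N$ stimulus parameters $x = (A_1..A_N, \phi_1..\phi_N)$.
Because the eight parameters live on very different scales (a rate
sensitivity to $w_e$ can exceed the one to $\beta_e$ a hundredfold), the
loop optimizes the $U_k$ one parameter at a time, cycling $k = 1..8$, rather
than the raw trace, which a high-sensitivity term would otherwise dominate.
Determinant- and eigenvalue-based criteria are deliberately out of scope:
the trace needs no numerical derivatives of eigenstructure and its gradient
is available in closed form below.

## Forward sensitivities

All gradients are obtained by augmenting the ODE system, never by
differencing simulations. Differentiating the dynamics gives linear
variational equations for $\partial v/\partial x$ (forced by
$\partial I/\partial x$), $\partial v/\partial \theta_k$ (forced by a
per-parameter term: the brace of the vector field for the $\beta$'s, the
stimulus for the input weights, the partner unit's rate for the recurrent
weights), and the second-order cross blocks
$\partial^2 v/\partial x\,\partial\theta_k$ needed for the utility
gradient. The chain rule through the gain then yields
$\partial r_e/\partial\theta_k = g_e'(V_e)\,\partial V_e/\partial\theta_k$
and its stimulus analogues, and

$$\frac{\partial U_k}{\partial x_l} = \int_0^T\Bigl[
  -\frac{1}{r_e^2}\frac{\partial r_e}{\partial x_l}
   \Bigl(\frac{\partial r_e}{\partial\theta_k}\Bigr)^2
  + \frac{2}{r_e}\frac{\partial r_e}{\partial\theta_k}
    \frac{\partial^2 r_e}{\partial x_l\,\partial\theta_k}\Bigr]dt .$$

The whole augmented system (2 state + 16 + $4N$ + $32N$ sensitivity
components at $N = 5$) is integrated jointly with one fixed-step classical
RK4 scheme on one shared grid, so state, sensitivities and all quadratures
see exactly the same time points and no interpolation error enters between
blocks. The correctness contract for this module is the finite-difference
oracle in the test suite: every analytic block must match central
differences of plain simulations (initial state held fixed) to better than
$10^{-3}$ relative error.

## Numerical choices

* **Integrator.** Fixed-step classical RK4, default $dt = 0.001$ s. The
  fixed step guarantees the shared grid; RK4 makes step-halving errors
  ($\sim 10^{-7}$ relative at the default step) negligible against the
  Poisson noise. The scaled-down studies in the tests and the acceptance
  script use $dt = 0.01$ s, a coarsening under which spike trains are
  generated and fitted on the same grid, so estimation stays consistent.
* **Initial condition.** Every presentation starts at the network's
  autonomous equilibrium at $I = 0$, the pre-stimulus baseline, found by
  damped fixed-point iteration with a Newton polish (residual $< 10^{-8}$);
  `experiment_config(init_at_onset = TRUE)` is reserved for starting at the
  stimulus-onset equilibrium instead. The reference parameter regime has a
  unique equilibrium for every stationary input, so non-convergence is
  treated as a pathological parameter draw and raised as an error.
* **Equilibrium sensitivity.** Because a candidate model is simulated from
  its *own* equilibrium, that initial state moves with the recurrent
  weights. The likelihood gradient therefore seeds the
  $\partial v/\partial\theta$ block with the implicit-function-theorem
  sensitivity $(I - WG)^{-1} S_k\, g(\bar v)$ of the equilibrium
  (`equilibrium_dtheta()`); with zero initial derivatives instead, the
  analytic gradient would disagree with the likelihood's finite differences
  by several percent on the recurrent weights. The design-utility path keeps
  zero initial sensitivities: there the stimulus parameters do not move the
  baseline at all.
* **Quadrature and rate floor.** All time integrals use the trapezoid rule
  on the simulation grid; rates inside $\ln(\cdot)$ and $1/(\cdot)$ are
  floored at $10^{-9}$ spikes/s. The logistic gain is strictly positive, so
  the floor only guards round-off, never shapes results.
* **Spike sampling.** Exact thinning against the bound $\max r$ with linear
  interpolation of the rate between grid points. Thinning is exact for a
  bounded intensity and trivially seedable; its correctness is checked by
  constant-rate moment tests and a time-rescaling Kolmogorov-Smirnov suite.
* **Optimization.** Both maximizations (utility over stimuli, likelihood
  over parameters) use bounded quasi-Newton local search (`optim`,
  L-BFGS-B) with the analytic gradients, projected-gradient tolerance
  $10^{-6}$, from multiple uniform random starts; the best endpoint wins,
  ties breaking to the lowest start index for determinism. Defaults:
  8 starts for design (the hardest utilities have many local optima; the
  budget is configurable), 10 for estimation. In the closed loop the
  previous estimate is added as a warm start for the next estimation — it
  can only raise the achieved likelihood and keeps the multistart contract.
* **Seeds.** Every random draw (initial estimate, design starts, spike
  trains, estimation starts, trial replication) uses a child seed derived by
  hashing the master seed with a role label, so whole experiments are
  reproducible and replicate batches are order-independent.

## The closed loop and the control arm

`run_experiment()` alternates design and estimation: initialize
$\hat\theta$ uniformly in the bounds ($\beta$'s in $[0, 100]$, input weights
in $[0, 2]$, recurrent weights in $[0, 3]$); for each iteration and each
$k = 1..8$, design a stimulus maximizing $U_k(\cdot, \hat\theta)$, present
it to the true network, record a Poisson spike train, and re-estimate
$\hat\theta$ from *all* data collected so far. An experiment of
$N_{itr}$ iterations therefore presents exactly $8 N_{itr}$ stimuli. The
control arm replaces every designed stimulus with a random one (amplitudes
uniform on $[0, A_{max}]$, phases uniform on $[-\pi, \pi)$) and, by
default, estimates once at the end; per-stimulus cadence is available for
parity studies. If a design or estimation step fails, the loop substitutes
a random stimulus (or keeps the previous estimate), flags the slot, and
continues, so long runs never die midway.

## What the synthetic generator does and does not emulate

All data are generated by the package itself: the reference ("true")
network above driven by random or designed Fourier stimuli, with
independent Poisson spiking. This captures the features the method is
about — transient-plus-sustained rate responses, spike-count noise,
information-poor versus information-rich stimuli — and deliberately omits
features of real recordings: refractoriness and spike-history effects,
adaptation and plasticity across presentations, non-Poisson dispersion,
unmodelled cell types, and model mismatch in the gain functions (the fitted
model class always contains the generator). Passing tests therefore
demonstrate correct inference *within* the model class, not robustness to
misspecification.

## Problem sizes in the tests and acceptance script

The full-scale study (100 trials of 120 stimuli per arm) is a
cluster-computing workload. The package's own validation uses reduced sizes,
chosen once: 10 nonadaptive trials of $M = 24$ stimuli with 5-start
estimation for the random-arm recovery statistics (also what
`scripts/acceptance.R` reruns); 3 adaptive trials of $N_{itr} = 3$ with
4-start design for the adaptive-arm check; likelihood-versus-$M$ medians at
$M \in \{8, 16, 24\}$ from those same runs for the efficiency-ratio
regression; and a 40-stimulus fixed dataset with $8 \times 5$ multistart
estimations for the local-optima probability. At these sizes the random-arm
trial means sit well inside three reference standard deviations of the
published full-scale columns, while per-trial spreads are naturally wider
than at $M = 120$. One quantity is size-sensitive: the per-start success
probability of estimation (pass under the 10% per-coordinate rule against
the best endpoint) comes out near 0.65 at $M = 40$, with essentially all
near-misses on the $w_{ii}$ coordinate alone — at 40 stimuli the likelihood
is still flat in the self-inhibition weight, whose deviations shrink like
$1/\sqrt{M}$ toward the full-scale behaviour.

## Confounding diagnostics

Estimation errors of different parameters correlate in structured ways, and
three pairs dominate: $(\beta_e, w_e)$, whose product is the effective
stimulus drive, so $\hat w_e \approx \beta_e w_e / \hat\beta_e$;
$(\beta_i, w_{ei})$, coupled through the ratio $w_{ei}/\beta_i$ that scales
how the inhibitory unit's motion feeds back on the excitatory equation, so
$\hat w_{ei} \approx w_{ei}\hat\beta_i/\beta_i$; and $(w_{ee}, w_{ei})$,
tied by the near-equilibrium recurrent balance
$w_{ee} g_e(\bar V_e) - w_{ei} g_i(\bar V_i)$. `confounding_curves()`
returns these three relations as functions (each passes exactly through the
true parameter point), `error_correlations()` computes the Pearson matrix
of estimation errors per arm, and `plot_confounding()` overlays both. The
relations are heuristic: they predict the sign and shape of the error
clouds, not their exact slopes.

## Known limitations

* Two units only; the generic $K$-unit rate network is out of scope here,
  though every derivation extends mechanically.
* Gain constants are fixed, not estimated.
* The utility is evaluated at the current point estimate; a badly wrong
  early estimate can steer design down a poor path (multistart estimation
  mitigates, a posterior over $\theta$ would address it properly and is
  future work).
* Stimulus optimization has many local optima — per-start success
  probabilities below 0.2 occur for the hardest $U_k$ — so designed stimuli
  are "good", not certified global optima; they still dominate random
  stimuli, which is what the closed loop needs.
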