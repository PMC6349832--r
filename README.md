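# eidesign

Adaptive optimal stimulus design for estimating the parameters of a
two-unit excitatory–inhibitory (E–I) firing-rate network from Poisson spike
trains.

## The problem

Fitting a recurrent circuit model to extracellular recordings means
recovering its time constants and connection weights from spike timing
alone — and the answer depends heavily on which stimuli were played.
`eidesign` implements the closed-loop alternative to presenting random
stimuli: after every presentation, re-estimate the model by maximum
likelihood, then *design* the next stimulus to be maximally informative
about the parameters under the current estimate. It is aimed at
computational/systems neuroscientists studying system identification and
optimal experimental design for dynamic network models.

## The model and criterion

The network is the standard rate model with one excitatory and one
inhibitory unit,

    dV_e/dt = beta_e ( -V_e + w_ee g_e(V_e) - w_ei g_i(V_i) + w_e I(t) )
    dV_i/dt = beta_i ( -V_i + w_ie g_e(V_e) - w_ii g_i(V_i) + w_i I(t) )

with logistic gains `g_j(V) = Gamma_j / (1 + exp(-a_j (V - h_j)))` (fixed)
and eight estimated parameters
`theta = (beta_e, beta_i, w_e, w_i, w_ee, w_ei, w_ie, w_ii)`. Spikes from
the excitatory unit follow an inhomogeneous Poisson process with intensity
`r_e = g_e(V_e)`, giving the log-likelihood
`l = sum_m [ -∫ r_e dt + sum_k ln r_e(t_k) ]`.

Stimuli are bounded Fourier series
`I(t) = sum_n A_n cos(2 pi n f_base t + phi_n)` (defaults N = 5,
f_base = 10/3 Hz, T = 3 s, 0 ≤ A_n ≤ 120). Each designed stimulus maximizes
a per-parameter A-optimal utility — a diagonal entry of the time-integrated
Fisher information of the Poisson observation,

    U_k(x, theta) = ∫ (1 / r_e) (∂r_e/∂theta_k)^2 dt,

cycling k = 1..8 so that low-sensitivity parameters (the time constants)
are not drowned out by high-sensitivity ones. All gradients — of `U_k` with
respect to the 2N stimulus parameters and of the likelihood with respect to
theta — come from forward sensitivity ODEs integrated jointly with the
state by a compiled fixed-step RK4 scheme, never from numerical
differencing. Estimation and design both use bounded multistart
quasi-Newton optimization with these analytic gradients.

## Worked example

Generate a small nonadaptive dataset from the reference network, fit it,
and design an informative stimulus against the fit:

```r
library(eidesign)
p <- true_params()                       # beta_e = 50, ..., w_ii = 0.4

set.seed(42)
stimuli <- replicate(8, random_stimulus(), simplify = FALSE)
spikes  <- lapply(stimuli, function(st)
  sample_spikes(simulate_network(p, st, dt = 0.01)$r_e, st$T))
data <- ei_dataset(stimuli, spikes)

set.seed(43)
fit <- estimate_network(data, n_starts = 4, dt = 0.01)
tidy(fit, truth = p)
#> # A tibble: 8 × 4
#>   parameter estimate true_value rel_error_pct
#> 1 beta_e      48.1         50            3.75
#> 2 beta_i      26.0         25            4.06
#> 3 w_e          0.979        1            2.08
#> 4 w_i          0.662        0.7          5.44
#> 5 w_ee         1.78         1.2         48.5
#> 6 w_ei         3            2           50
#> 7 w_ie         1.76         0.7        151.
#> 8 w_ii         2.00         0.4        401.

set.seed(44)
des <- design_stimulus(theta_to_params(fit$theta_hat), k = 3,
                       n_starts = 4, dt = 0.01)
des$U_k
#> [1] 9124.51
```

After only 8 random stimuli the directly driven parameters (`beta_e`,
`w_e`, `w_i`) are already recovered to a few percent, while the weights of
the unobserved inhibitory pathway (`w_ie`, `w_ii`) are still badly wrong —
exactly the parameters the adaptive loop targets. The designed stimulus
achieves `U_3 ≈ 9125` versus `≈ 247` for an average random stimulus, a
~37-fold information gain for `w_e`. The full closed loop is one call:

```r
cfg <- experiment_config(mode = "optimal", N_itr = 3, seed = 1)
rec <- run_experiment(cfg)     # 24 designed stimuli, re-fitting after each
tidy(rec)                      # per-update estimates and log-likelihoods
```

Analysis helpers (`summarize_recovery()`, `likelihood_regression()`,
`best_solution_probability()`, `error_correlations()`,
`confounding_curves()`, `compare_modes()`) turn replicate runs into
recovery tables, efficiency ratios, local-optima probabilities and
parameter-confounding diagnostics; `autoplot()`/`plot_*()` provide the
standard figures. See the vignette `vignettes/adaptive-design.Rmd` for the
method and all numerical choices.

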