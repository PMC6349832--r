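# Small in-code fixtures shared across test files. Everything is generated
# at test time; dt is coarsened to keep the suite fast (step-halving accuracy
# is itself under test in test-model_core.R).

fast_dt <- 0.01

# A reproducible random dataset of M stimulus-response pairs from the
# reference network.
make_dataset <- function(M, seed = 1, dt = fast_dt, p = true_params()) {
  set.seed(seed)
  stimuli <- replicate(M, random_stimulus(), simplify = FALSE)
  spikes <- lapply(stimuli, function(st) {
    traj <- simulate_network(p, st, dt = dt)
    sample_spikes(traj$r_e, st$T)
  })
  ei_dataset(stimuli, spikes)
}

# A random parameter draw inside the default estimation box, kept away from
# the zero lower bound so dynamics stay non-degenerate.
random_params <- function() {
  b <- default_bounds()
  th <- runif(8, b$lower + 0.05 * (b$upper - b$lower), b$upper)
  theta_to_params(th)
}

# Central finite difference of f over coordinate k of x0.
central_fd <- function(f, x0, k, delta) {
  xp <- x0; xp[k] <- x0[k] + delta
  xm <- x0; xm[k] <- x0[k] - delta
  (f(xp) - f(xm)) / (2 * delta)
}
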