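#' Spike train container
#' @param times Strictly increasing spike instants in `[0, T]` (s).
#' @param T Observation window (s).
#' @return A `spike_train` object.
#' @export
spike_train <- function(times, T) {
  times <- as.numeric(times)
  stopifnot(T > 0, all(times >= 0), all(times <= T),
            !is.unsorted(times, strictly = TRUE) || length(times) <= 1)
  structure(list(times = times, T = T), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in [0, %g] s\n", length(x$times), x$T))
  invisible(x)
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Exact Ogata thinning against the bound `max(r)`: homogeneous candidates at
#' the bounding rate are accepted with probability `r(t)/max(r)`, with `r`
#' linearly interpolated between grid points. Uses the current RNG state.
#'
#' @param r Nonnegative rate values (spikes/s) on the uniform grid
#'   `seq(0, T, length.out = length(r))`.
#' @param T Window (s).
#' @return A [spike_train()].
#' @export
sample_spikes <- function(r, T) {
  stopifnot(all(r >= 0), T > 0, length(r) >= 2)
  rmax <- max(r)
  if (rmax == 0) return(spike_train(numeric(0), T))
  tt <- seq(0, T, length.out = length(r))
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, rmax)
    if (t > T) break
    rt <- stats::approx(tt, r, xout = t)$y
    if (stats::runif(1) < rt / rmax) times <- c(times, t)
  }
  spike_train(times, T)
}

#' Assemble a stimulus-response dataset
#'
#' A tibble with one row per presented stimulus and list-columns holding the
#' [fourier_stimulus()] and elicited [spike_train()]. Responses to different
#' stimuli are treated as independent by the likelihood.
#'
#' @param stimuli List of [fourier_stimulus()] objects.
#' @param spikes List of [spike_train()] objects, same length.
#' @param ... Further per-pair columns (e.g. `seed`, `k`, `m`).
#' @return A tibble of class `ei_dataset`.
#' @export
ei_dataset <- function(stimuli, spikes, ...) {
  stopifnot(length(stimuli) == length(spikes))
  out <- tibble::tibble(m = seq_along(stimuli), stimulus = stimuli,
                        spikes = spikes, ...)
  class(out) <- c("ei_dataset", class(out))
  out
}

trapz <- function(y, dt) dt * (sum(y) - 0.5 * (y[1] + y[length(y)]))

# rate floor inside ln() and 1/(): the logistic gain is strictly positive, so
# this only guards round-off
RATE_FLOOR <- 1e-9

# Per-pair log-likelihood terms (and optional gradient) from one solved pair.
pair_loglik <- function(p, stim, spk, dt, gradient = FALSE) {
  v0 <- find_equilibrium(p, 0)
  # the initial state is the candidate model's own equilibrium, so the
  # dv/dtheta block starts at the equilibrium's parameter-sensitivity
  sens <- solve_sensitivities(p, stim, T = spk$T, dt = dt,
                              which = if (gradient) "dtheta" else "state",
                              v0 = v0,
                              dtheta0 = if (gradient)
                                equilibrium_dtheta(p, 0, v0) else NULL)
  r <- pmax(sens$trajectory$r_e, RATE_FLOOR)
  tt <- sens$times
  ll <- -trapz(r, dt)
  if (length(spk$times) > 0) {
    rk <- pmax(stats::approx(tt, r, xout = spk$times)$y, RATE_FLOOR)
    ll <- ll + sum(log(rk))
  }
  if (!gradient) return(list(ll = ll))
  dr <- sens$dre_dtheta
  grad <- -apply(dr, 2, trapz, dt = dt)
  if (length(spk$times) > 0) {
    rk <- pmax(stats::approx(tt, r, xout = spk$times)$y, RATE_FLOOR)
    drk <- apply(dr, 2, function(col) stats::approx(tt, col, xout = spk$times)$y)
    drk <- matrix(drk, nrow = length(spk$times))
    grad <- grad + colSums(drk / rk)
  }
  list(ll = ll, grad = grad)
}

# Pack a homogeneous dataset (shared N, f_base, T) into the matrices the
# compiled likelihood consumes; NULL when the pairs are heterogeneous.
pack_dataset <- function(data) {
  st <- data$stimulus
  N <- st[[1]]$N; fb <- st[[1]]$f_base; T <- st[[1]]$T
  same <- all(vapply(st, function(s)
    s$N == N && isTRUE(all.equal(s$f_base, fb)) && isTRUE(all.equal(s$T, T)),
    TRUE)) &&
    all(vapply(data$spikes, function(s) isTRUE(all.equal(s$T, T)), TRUE))
  if (!same) return(NULL)
  list(A = do.call(rbind, lapply(st, `[[`, "A")),
       phi = do.call(rbind, lapply(st, `[[`, "phi")),
       f_base = fb, T = T,
       spikes = lapply(data$spikes, `[[`, "times"))
}

#' Spike-train log-likelihood of the network parameters
#'
#' For each stimulus-response pair the inhomogeneous-Poisson log-likelihood is
#' `-integral(r_e) + sum_k ln r_e(t_k)`, with the integral by trapezoid on the
#' simulation grid and the rate at spike times by linear interpolation; pairs
#' are summed (independence across stimuli). Each pair's simulation starts at
#' the candidate model's baseline equilibrium. When all pairs share the
#' stimulus configuration, the whole sum is accumulated inside the compiled
#' integrator.
#'
#' @param data An [ei_dataset()].
#' @param p A [network_params()] object.
#' @param dt Simulation step (s).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, p, dt = 1e-3) {
  stopifnot(inherits(data, "ei_dataset"), nrow(data) >= 1)
  packed <- pack_dataset(data)
  if (!is.null(packed)) {
    v0 <- find_equilibrium(p, 0)
    return(ei_dataset_loglik(as_theta(p), gain_vec(p), packed$A, packed$phi,
                             packed$f_base, packed$T, dt, packed$spikes, v0,
                             matrix(0, 0, 0), FALSE)$ll)
  }
  sum(vapply(seq_len(nrow(data)), function(i)
    pair_loglik(p, data$stimulus[[i]], data$spikes[[i]], dt)$ll, 0))
}

#' Analytic gradient of the spike-train log-likelihood
#'
#' Uses the rate sensitivities `dre/dtheta_k` from the forward sensitivity
#' system: `dl/dtheta_k = sum_m [-integral(dre/dtheta_k) +
#' sum_spikes (1/r_e) dre/dtheta_k]`.
#'
#' @inheritParams log_likelihood
#' @return Named numeric 8-vector.
#' @export
log_likelihood_gradient <- function(data, p, dt = 1e-3) {
  stats::setNames(loglik_with_gradient(data, p, dt)$grad, theta_names())
}

# Value and gradient in one pass (shared ODE solves), for the optimizer.
loglik_with_gradient <- function(data, p, dt) {
  stopifnot(inherits(data, "ei_dataset"), nrow(data) >= 1)
  packed <- pack_dataset(data)
  if (!is.null(packed)) {
    v0 <- find_equilibrium(p, 0)
    res <- ei_dataset_loglik(as_theta(p), gain_vec(p), packed$A, packed$phi,
                             packed$f_base, packed$T, dt, packed$spikes, v0,
                             equilibrium_dtheta(p, 0, v0), TRUE)
    return(list(ll = res$ll, grad = res$grad))
  }
  res <- lapply(seq_len(nrow(data)), function(i)
    pair_loglik(p, data$stimulus[[i]], data$spikes[[i]], dt, gradient = TRUE))
  list(ll = sum(vapply(res, `[[`, 0, "ll")),
       grad = rowSums(vapply(res, `[[`, numeric(8), "grad")))
}

#' Write a dataset as JSON-lines
#'
#' One record per line: `{m, stimulus: {A, phi, f_base, T}, spikes, seed}`.
#' @param data An [ei_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset_jsonl <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(data))) {
    st <- data$stimulus[[i]]
    rec <- list(m = data$m[i],
                stimulus = list(A = st$A, phi = st$phi,
                                f_base = st$f_base, T = st$T),
                spikes = data$spikes[[i]]$times)
    if ("seed" %in% names(data)) rec$seed <- data$seed[i]
    if ("k" %in% names(data)) rec$k <- data$k[i]
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset_jsonl()]
#' @param path JSON-lines file.
#' @return An [ei_dataset()].
#' @export
read_dataset_jsonl <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  stimuli <- lapply(recs, function(r)
    fourier_stimulus(r$stimulus$A, r$stimulus$phi,
                     f_base = r$stimulus$f_base, T = r$stimulus$T))
  spikes <- lapply(recs, function(r)
    spike_train(as.numeric(unlist(r$spikes)), r$stimulus$T))
  ei_dataset(stimuli, spikes)
}
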