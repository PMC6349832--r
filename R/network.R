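#' Excitatory-inhibitory network parameters
#'
#' Bundles the eight estimated parameters of the two-unit recurrent rate
#' network -- the inverse time constants `beta_e = 1/tau_e`, `beta_i = 1/tau_i`
#' and six nonnegative connection weights -- together with the fixed gain
#' constants of the two units. The canonical flattened ordering used everywhere
#' (sensitivities, gradients, bounds) is
#' `theta = c(beta_e, beta_i, w_e, w_i, w_ee, w_ei, w_ie, w_ii)`.
#'
#' Signs of inhibition are carried by the dynamical equations themselves, so
#' all weights are nonnegative numbers. The dynamics of the state
#' `v = c(V_e, V_i)` are
#' \deqn{dV_e/dt = \beta_e(-V_e + w_{ee} g_e(V_e) - w_{ei} g_i(V_i) + w_e I)}
#' \deqn{dV_i/dt = \beta_i(-V_i + w_{ie} g_e(V_e) - w_{ii} g_i(V_i) + w_i I)}
#' and the observable rate is `r_e = g_e(V_e)`.
#'
#' @param beta_e,beta_i Inverse time constants (1/s), `>= 0`.
#' @param w_e,w_i Stimulus input weights, `>= 0`.
#' @param w_ee,w_ei,w_ie,w_ii Recurrent connection weights, `>= 0`.
#' @param gain_e,gain_i [gain_params()] of the two units (fixed, not estimated).
#' @return A `network_params` object.
#' @seealso [true_params()] for the reference parameter set.
#' @export
network_params <- function(beta_e, beta_i, w_e, w_i, w_ee, w_ei, w_ie, w_ii,
                           gain_e = gain_params(100, 0.04, 70),
                           gain_i = gain_params(50, 0.04, 35)) {
  th <- c(beta_e, beta_i, w_e, w_i, w_ee, w_ei, w_ie, w_ii)
  stopifnot(length(th) == 8, all(is.finite(th)), all(th >= 0))
  structure(list(beta_e = beta_e, beta_i = beta_i, w_e = w_e, w_i = w_i,
                 w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
                 gain_e = gain_e, gain_i = gain_i),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  th <- as_theta(x)
  cat(paste(sprintf("  %-6s = %g", names(th), th), collapse = "\n"), "\n")
  invisible(x)
}

#' Names of the eight estimated parameters, in canonical order
#' @return Character vector of length 8.
#' @export
theta_names <- function() {
  c("beta_e", "beta_i", "w_e", "w_i", "w_ee", "w_ei", "w_ie", "w_ii")
}

#' Flatten network parameters to the canonical 8-vector
#' @param p A [network_params()] object.
#' @return Named numeric vector in the order given by [theta_names()].
#' @export
as_theta <- function(p) {
  stopifnot(inherits(p, "network_params"))
  stats::setNames(vapply(theta_names(), function(nm) p[[nm]], 0), theta_names())
}

#' Build network parameters from a theta vector
#' @param theta Numeric 8-vector in canonical order.
#' @param gain_e,gain_i Gain constants to attach.
#' @return A [network_params()] object.
#' @export
theta_to_params <- function(theta,
                            gain_e = gain_params(100, 0.04, 70),
                            gain_i = gain_params(50, 0.04, 35)) {
  stopifnot(length(theta) == 8)
  network_params(theta[1], theta[2], theta[3], theta[4],
                 theta[5], theta[6], theta[7], theta[8],
                 gain_e = gain_e, gain_i = gain_i)
}

#' Reference ("generating") parameter set
#'
#' The parameter values used to generate all synthetic recordings:
#' `beta_e = 50`, `beta_i = 25` (time constants 20 ms and 40 ms), input weights
#' `w_e = 1`, `w_i = 0.7`, recurrent weights `w_ee = 1.2`, `w_ei = 2`,
#' `w_ie = 0.7`, `w_ii = 0.4`, with gain constants
#' `Gamma_e = 100, a_e = 0.04, h_e = 70` and `Gamma_i = 50, a_i = 0.04, h_i = 35`.
#' @return A [network_params()] object.
#' @export
true_params <- function() {
  network_params(50, 25, 1, 0.7, 1.2, 2, 0.7, 0.4)
}

#' Default estimation box bounds for the eight parameters
#'
#' Lower bounds are all 0; upper bounds are 100 for the two inverse time
#' constants, 2 for the two input weights, and 3 for the four recurrent
#' weights.
#' @return List with numeric 8-vectors `lower` and `upper`.
#' @export
default_bounds <- function() {
  list(lower = stats::setNames(rep(0, 8), theta_names()),
       upper = stats::setNames(c(100, 100, 2, 2, 3, 3, 3, 3), theta_names()))
}

gain_vec <- function(p) {
  c(p$gain_e$Gamma, p$gain_e$a, p$gain_e$h,
    p$gain_i$Gamma, p$gain_i$a, p$gain_i$h)
}

#' Time derivative of the network state
#'
#' @param state Numeric 2-vector `c(V_e, V_i)`.
#' @param I Scalar stimulus value.
#' @param p A [network_params()] object.
#' @return Numeric 2-vector `c(dV_e/dt, dV_i/dt)`.
#' @export
vector_field <- function(state, I, p) {
  stopifnot(length(state) == 2, is.finite(I))
  ge <- gain(state[1], p$gain_e)
  gi <- gain(state[2], p$gain_i)
  c(p$beta_e * (-state[1] + p$w_ee * ge - p$w_ei * gi + p$w_e * I),
    p$beta_i * (-state[2] + p$w_ie * ge - p$w_ii * gi + p$w_i * I))
}

#' Equilibrium state under a constant stimulus
#'
#' Solves `0 = -v + W g(v) + w I` by damped fixed-point iteration followed by a
#' Newton polish on the 2-D root system. The reference parameter regime has a
#' unique equilibrium for every stationary input; failure to converge signals a
#' pathological parameter draw and raises an error.
#'
#' @param p A [network_params()] object.
#' @param I_const Constant stimulus value (default 0, the pre-stimulus
#'   baseline).
#' @param tol Tolerance on the norm of the vector field at the returned point.
#' @param max_iter Fixed-point iteration budget.
#' @return Numeric 2-vector `c(V_e, V_i)`.
#' @export
find_equilibrium <- function(p, I_const = 0, tol = 1e-8, max_iter = 500) {
  W <- matrix(c(p$w_ee, p$w_ie, -p$w_ei, -p$w_ii), 2, 2)
  wI <- c(p$w_e, p$w_i) * I_const
  gfun <- function(v) c(gain(v[1], p$gain_e), gain(v[2], p$gain_i))
  v <- c(0, 0)
  for (it in seq_len(max_iter)) {
    vn <- 0.5 * v + 0.5 * (drop(W %*% gfun(v)) + wI)
    if (max(abs(vn - v)) < 1e-6) { v <- vn; break }
    v <- vn
  }
  # Newton polish on F(v) = -v + W g(v) + w I
  newton <- function(v) {
    for (it in seq_len(50)) {
      Fv <- -v + drop(W %*% gfun(v)) + wI
      if (max(abs(Fv)) < 1e-13) break
      G <- diag(c(gain(v[1], p$gain_e, 1), gain(v[2], p$gain_i, 1)))
      J <- -diag(2) + W %*% G
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      v <- v - drop(step)
      if (any(!is.finite(v))) return(c(NA_real_, NA_real_))
    }
    v
  }
  resid <- function(v) if (any(!is.finite(v))) Inf else
    sqrt(sum(vector_field(v, I_const, p)^2))
  anchor <- v
  v <- newton(v)
  if (resid(v) >= tol) {
    # strong recurrence can defeat the fixed-point/Newton pair; fall back to
    # Newton from a deterministic grid and keep the root nearest the damped
    # fixed-point iterate
    grid <- as.matrix(expand.grid(Ve = c(-100, -50, -20, 0, 20, 50, 100, 200),
                                  Vi = c(-50, -20, 0, 20, 50, 100)))
    best <- v
    best_d <- Inf
    for (i in seq_len(nrow(grid))) {
      cand <- newton(grid[i, ])
      if (resid(cand) < tol) {
        d <- sum((cand - anchor)^2)
        if (d < best_d) { best <- cand; best_d <- d }
      }
    }
    v <- best
  }
  if (resid(v) >= tol)
    stop("find_equilibrium did not converge; pathological parameter set?")
  v
}

#' Parameter-sensitivity of an equilibrium state
#'
#' The baseline equilibrium `v_bar(theta)` solves
#' `0 = -v + W g(v) + w I`, so by the implicit function theorem its
#' derivative with respect to each network parameter is
#' `(I2 - W G)^{-1}` applied to the direct parameter-derivative of the
#' right-hand side at `v_bar`. Used to seed the `dv/dtheta` sensitivity block
#' when a simulation starts from the candidate model's own equilibrium, which
#' makes the analytic likelihood gradient consistent with the likelihood
#' itself.
#'
#' @param p A [network_params()] object.
#' @param I_const Constant input defining the equilibrium (default 0).
#' @param v_bar Optional precomputed equilibrium.
#' @return A 2 x 8 matrix, columns in [theta_names()] order.
#' @export
equilibrium_dtheta <- function(p, I_const = 0, v_bar = NULL) {
  if (is.null(v_bar)) v_bar <- find_equilibrium(p, I_const)
  W <- matrix(c(p$w_ee, p$w_ie, -p$w_ei, -p$w_ii), 2, 2)
  G <- diag(c(gain(v_bar[1], p$gain_e, 1), gain(v_bar[2], p$gain_i, 1)))
  ge <- gain(v_bar[1], p$gain_e)
  gi <- gain(v_bar[2], p$gain_i)
  # direct derivative of W g(v) + w I in each parameter (betas drop out)
  rhs <- cbind(beta_e = c(0, 0), beta_i = c(0, 0),
               w_e = c(I_const, 0), w_i = c(0, I_const),
               w_ee = c(ge, 0), w_ei = c(-gi, 0),
               w_ie = c(0, ge), w_ii = c(0, -gi))
  solve(diag(2) - W %*% G, rhs)
}

#' Simulate the network under a stimulus
#'
#' Deterministic fixed-step RK4 integration of the two-unit dynamics on the
#' grid `seq(0, T, by = dt)`. The stimulus can be a [fourier_stimulus()] (in
#' which case duration defaults to the stimulus' own and the compiled
#' integrator is used) or an arbitrary function of time.
#'
#' @param p A [network_params()] object.
#' @param stimulus A [fourier_stimulus()] or a function `I(t)`.
#' @param T Duration (s). Defaults to the stimulus duration when available.
#' @param dt Step (s), default 0.001.
#' @param v0 Initial state; defaults to the equilibrium at `I = 0`.
#' @return A tibble of class `ei_trajectory` with columns `time`, `V_e`,
#'   `V_i`, `r_e`.
#' @examples
#' traj <- simulate_network(true_params(), square_wave_stimulus(), T = 1, dt = 0.01)
#' head(traj)
#' @export
simulate_network <- function(p, stimulus, T = NULL, dt = 1e-3, v0 = NULL) {
  stopifnot(inherits(p, "network_params"))
  if (is.null(T)) {
    T <- if (inherits(stimulus, "fourier_stimulus")) stimulus$T else
      stop("T must be given for a function stimulus")
  }
  stopifnot(T > 0, dt > 0, dt <= T)
  if (is.null(v0)) v0 <- find_equilibrium(p, 0)
  th <- as_theta(p)
  if (inherits(stimulus, "fourier_stimulus")) {
    sol <- ei_integrate(th, gain_vec(p), stimulus$A, stimulus$phi,
                        stimulus$f_base, T, dt, v0, FALSE, FALSE, FALSE,
                        matrix(0, 0, 0))
  } else {
    stopifnot(is.function(stimulus))
    n <- round(T / dt)
    Iv <- stimulus(seq(0, T, by = dt / 2))
    stopifnot(length(Iv) == 2 * n + 1)
    sol <- ei_integrate_tabular(th, gain_vec(p), Iv, T, dt, v0)
  }
  new_trajectory(sol$times, sol$V[, 1], sol$V[, 2], p)
}

new_trajectory <- function(times, Ve, Vi, p) {
  out <- tibble::tibble(time = times, V_e = Ve, V_i = Vi,
                        r_e = gain(Ve, p$gain_e))
  class(out) <- c("ei_trajectory", class(out))
  out
}

#' Write a trajectory to CSV
#' @param traj An `ei_trajectory`.
#' @param path Output file; columns `time,V_e,V_i,r_e`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time", "V_e", "V_i", "r_e")],
                   path, row.names = FALSE)
  invisible(path)
}
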