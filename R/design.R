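#' A-optimal Fisher-information utilities of a stimulus
#'
#' The per-parameter utility is the time-integrated diagonal entry of the
#' pointwise Fisher information of the Poisson rate,
#' `U_k = integral_0^T (1/r_e) (dre/dtheta_k)^2 dt`, by trapezoid on the
#' simulation grid; the total A-optimal utility is the trace, `U = sum_k U_k`.
#'
#' @param x A [fourier_stimulus()].
#' @param p A [network_params()] object (typically the current estimate).
#' @param dt Simulation step (s).
#' @return A list of class `ei_utility` with `U_k` (named 8-vector) and `U`
#'   (their sum).
#' @export
utility <- function(x, p, dt = 1e-3) {
  sens <- solve_sensitivities(p, x, dt = dt, which = "dtheta")
  r <- pmax(sens$trajectory$r_e, RATE_FLOOR)
  Uk <- apply(sens$dre_dtheta^2 / r, 2, trapz, dt = dt)
  structure(list(U_k = stats::setNames(Uk, theta_names()), U = sum(Uk)),
            class = "ei_utility")
}

#' @export
print.ei_utility <- function(x, ...) {
  cat(sprintf("<ei_utility> U = %g\n", x$U))
  print(signif(x$U_k, 4))
  invisible(x)
}

# Per-parameter utility and its stimulus-gradient from one cross-sensitivity
# solve; k = 1..8 or 0 for the total.
utility_eval <- function(x, p, k, dt) {
  sens <- solve_sensitivities(p, x, dt = dt, which = "cross")
  r <- pmax(sens$trajectory$r_e, RATE_FLOOR)
  dth <- sens$dre_dtheta
  dx <- sens$dre_dx
  cross <- sens$d2re_dxdtheta
  ks <- if (k == 0) 1:8 else k
  Uk <- vapply(ks, function(kk) trapz(dth[, kk]^2 / r, dt), 0)
  nx <- ncol(dx)
  grad <- numeric(nx)
  for (kk in ks) {
    integ <- -(dx * dth[, kk]^2) / r^2 + 2 * (dth[, kk] * cross[, , kk]) / r
    grad <- grad + apply(integ, 2, trapz, dt = dt)
  }
  list(value = sum(Uk), grad = grad)
}

#' Stimulus-gradient of a Fisher-information utility
#'
#' Analytic gradient of `U_k` (or of the total `U` for `k = 0`) with respect
#' to the 2N stimulus parameters, using the second-order cross sensitivities:
#' `dU_k/dx_l = integral [-(1/r_e^2)(dre/dx_l)(dre/dtheta_k)^2 +
#' (2/r_e)(dre/dtheta_k)(d2re/dx_l dtheta_k)] dt`.
#'
#' @param x A [fourier_stimulus()].
#' @param p A [network_params()] object.
#' @param k Parameter index 1..8, or 0 for the total utility.
#' @param dt Simulation step (s).
#' @return Numeric 2N-vector.
#' @export
utility_gradient <- function(x, p, k = 0, dt = 1e-3) {
  stopifnot(k %in% 0:8)
  utility_eval(x, p, k, dt)$grad
}

#' Design a stimulus by maximizing a per-parameter utility
#'
#' Multistart bounded local optimization of `U_k` over the 2N stimulus
#' parameters with the analytic gradient. Starts draw amplitudes from
#' `Uniform[0, A_max]` and phases from `Uniform[-pi, pi)`; amplitudes are box
#' constrained to `[0, A_max]` while phases vary freely (wrapped only for
#' reporting). The best endpoint across starts is returned; exact ties break
#' to the lowest start index.
#'
#' @param p_hat Current parameter estimate ([network_params()]).
#' @param k Parameter index 1..8 whose utility `U_k` is maximized (0 for the
#'   total).
#' @param N,f_base,T,A_max Stimulus configuration.
#' @param n_starts Number of random starts (default 8).
#' @param dt Simulation step (s).
#' @param maxit Iteration cap per start.
#' @param pgtol Projected-gradient tolerance.
#' @return A list of class `ei_design` with `stimulus` (the designed
#'   [fourier_stimulus()]), `U_k` (achieved utility), `k`, `n_starts`,
#'   `improved` (FALSE with a warning if no start improved on its start
#'   point), and `starts` (per-start achieved values).
#' @export
design_stimulus <- function(p_hat, k, N = 5, f_base = 10 / 3, T = 3,
                            A_max = 120, n_starts = 8, dt = 1e-3,
                            maxit = 200, pgtol = 1e-6) {
  stopifnot(k %in% 0:8, n_starts >= 1)
  template <- fourier_stimulus(rep(0, N), rep(0, N), f_base = f_base, T = T)
  lower <- c(rep(0, N), rep(-Inf, N))
  upper <- c(rep(A_max, N), rep(Inf, N))

  cache <- new.env(parent = emptyenv())
  eval_at <- function(xv) {
    key <- paste(xv, collapse = ",")
    if (!identical(cache$key, key)) {
      xc <- c(pmin(pmax(xv[1:N], 0), A_max), xv[N + 1:N])
      cache$val <- utility_eval(x_to_stimulus(xc, template), p_hat, k, dt)
      cache$key <- key
    }
    cache$val
  }
  fn <- function(xv) -eval_at(xv)$value
  gr <- function(xv) -eval_at(xv)$grad

  results <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    x0 <- c(stats::runif(N, 0, A_max), stats::runif(N, -pi, pi))
    U0 <- utility_eval(x_to_stimulus(x0, template), p_hat, k, dt)$value
    opt <- tryCatch(
      stats::optim(x0, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = maxit, pgtol = pgtol)),
      error = function(e) NULL)
    if (is.null(opt)) {
      results[[s]] <- list(x = x0, U = U0, U0 = U0, converged = FALSE)
    } else {
      results[[s]] <- list(x = opt$par, U = -opt$value, U0 = U0,
                           converged = opt$convergence == 0)
    }
  }
  Us <- vapply(results, `[[`, 0, "U")
  best <- which.max(Us)          # ties break to lowest index
  improved <- any(Us > vapply(results, `[[`, 0, "U0"))
  if (!improved)
    warning("design_stimulus: no start improved on its start point")
  xbest <- results[[best]]$x
  xbest[1:N] <- pmin(pmax(xbest[1:N], 0), A_max)
  structure(list(stimulus = x_to_stimulus(xbest, template),
                 U_k = Us[best], k = k, n_starts = n_starts,
                 improved = improved, starts = Us),
            class = "ei_design")
}

#' @export
print.ei_design <- function(x, ...) {
  cat(sprintf("<ei_design> k = %d, achieved U_k = %g over %d starts\n",
              x$k, x$U_k, x$n_starts))
  print(x$stimulus)
  invisible(x)
}
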