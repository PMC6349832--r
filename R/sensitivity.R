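#' Solve the forward sensitivity equations alongside the state
#'
#' Integrates the network state jointly with the requested first- and
#' second-order sensitivity blocks on one shared fixed-step RK4 grid. The
#' blocks are the solutions of the variational systems obtained by
#' differentiating the network dynamics with respect to the eight network
#' parameters (`dv/dtheta`), the 2N stimulus parameters (`dv/dx`), and both
#' (`d2v/dx dtheta`). All sensitivities start at zero; the state starts at the
#' pre-stimulus equilibrium (`I = 0`) unless `v0` is given.
#'
#' @param p A [network_params()] object.
#' @param x A [fourier_stimulus()].
#' @param T Duration (s); defaults to the stimulus duration.
#' @param dt Step (s), default 0.001.
#' @param which One of `"state"`, `"dtheta"`, `"dx"`, `"cross"` -- each level
#'   includes the previous ones (`"cross"` integrates everything).
#' @param v0 Optional initial state.
#' @param dtheta0 Optional 2 x 8 initial value for the `dv/dtheta` block
#'   (default zero). Pass [equilibrium_dtheta()] when the initial state is
#'   the candidate model's own equilibrium and the derivatives must account
#'   for its parameter dependence, as the likelihood gradient does.
#' @return A list of class `ei_sensitivities` with elements `trajectory` (an
#'   `ei_trajectory` tibble), `times`, and matrices `dVe_dtheta`
#'   (`n_t x 8`), `dVi_dtheta`, `dVe_dx` (`n_t x 2N`), `dVi_dx`,
#'   `d2Ve_dxdtheta` (`n_t x 2N x 8` array) as requested, plus the
#'   rate-derivative blocks from [rate_derivatives()] (`dre_dtheta`, `dre_dx`,
#'   `d2re_dxdtheta`).
#' @export
solve_sensitivities <- function(p, x, T = NULL, dt = 1e-3,
                                which = c("dtheta", "state", "dx", "cross"),
                                v0 = NULL, dtheta0 = NULL) {
  stopifnot(inherits(p, "network_params"), inherits(x, "fourier_stimulus"))
  which <- match.arg(which)
  if (is.null(T)) T <- x$T
  if (is.null(v0)) v0 <- find_equilibrium(p, 0)
  wth <- which %in% c("dtheta", "cross")
  wx <- which %in% c("dx", "cross")
  wcross <- which == "cross"
  if (is.null(dtheta0)) dtheta0 <- matrix(0, 0, 0)
  sol <- ei_integrate(as_theta(p), gain_vec(p), x$A, x$phi, x$f_base,
                      T, dt, v0, wth, wx, wcross, dtheta0)
  out <- list(trajectory = new_trajectory(sol$times, sol$V[, 1], sol$V[, 2], p),
              times = sol$times, N = x$N, dt = dt, params = p, stimulus = x)
  if (wth) {
    out$dVe_dtheta <- sol$dVe_dtheta
    out$dVi_dtheta <- sol$dVi_dtheta
    colnames(out$dVe_dtheta) <- colnames(out$dVi_dtheta) <- theta_names()
  }
  if (wx) {
    out$dVe_dx <- sol$dVe_dx
    out$dVi_dx <- sol$dVi_dx
  }
  if (wcross) {
    nt <- length(sol$times)
    out$d2Ve_dxdtheta <- array(sol$d2Ve_dxdtheta, dim = c(nt, 2 * x$N, 8))
    out$d2Vi_dxdtheta <- array(sol$d2Vi_dxdtheta, dim = c(nt, 2 * x$N, 8))
  }
  class(out) <- "ei_sensitivities"
  rate_derivatives(out)
}

#' Map state sensitivities to rate sensitivities
#'
#' The observable rate is `r_e = g_e(V_e)`, so by the chain rule
#' `dre/dtheta_k = g_e'(V_e) dVe/dtheta_k`, `dre/dx_l = g_e'(V_e) dVe/dx_l`,
#' and
#' `d2re/dx_l dtheta_k = g_e''(V_e) dVe/dx_l dVe/dtheta_k + g_e'(V_e) d2Ve/dx_l dtheta_k`,
#' pointwise in time. Called automatically by [solve_sensitivities()]; exposed
#' for re-deriving rate blocks from stored state sensitivities.
#'
#' @param bundle An `ei_sensitivities` object holding the needed V-blocks.
#' @return The bundle with `dre_dtheta`, `dre_dx`, `d2re_dxdtheta` filled in
#'   (those whose V-blocks are present).
#' @export
rate_derivatives <- function(bundle) {
  stopifnot(inherits(bundle, "ei_sensitivities"))
  p <- bundle$params
  Ve <- bundle$trajectory$V_e
  g1 <- gain(Ve, p$gain_e, 1)
  if (!is.null(bundle$dVe_dtheta))
    bundle$dre_dtheta <- bundle$dVe_dtheta * g1
  if (!is.null(bundle$dVe_dx))
    bundle$dre_dx <- bundle$dVe_dx * g1
  if (!is.null(bundle$d2Ve_dxdtheta)) {
    if (is.null(bundle$dVe_dtheta) || is.null(bundle$dVe_dx))
      stop("cross rate derivatives need both first-order V-blocks")
    g2 <- gain(Ve, p$gain_e, 2)
    cr <- bundle$d2Ve_dxdtheta
    for (k in 1:8) {
      cr[, , k] <- g2 * bundle$dVe_dx * bundle$dVe_dtheta[, k] +
        g1 * bundle$d2Ve_dxdtheta[, , k]
    }
    bundle$d2re_dxdtheta <- cr
  }
  bundle
}

#' @export
print.ei_sensitivities <- function(x, ...) {
  cat(sprintf("<ei_sensitivities> %d time points, dt = %g s, N = %d harmonics\n",
              length(x$times), x$dt, x$N))
  cat("  blocks:", paste(intersect(
    c("dVe_dtheta", "dVe_dx", "d2Ve_dxdtheta"), names(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Write the eight rate-sensitivity time courses to CSV
#' @param bundle An `ei_sensitivities` with the `dre_dtheta` block.
#' @param path Output file; columns `time` plus one per parameter.
#' @return `path`, invisibly.
#' @export
write_rate_sensitivities_csv <- function(bundle, path) {
  stopifnot(!is.null(bundle$dre_dtheta))
  df <- data.frame(time = bundle$times, bundle$dre_dtheta)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
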