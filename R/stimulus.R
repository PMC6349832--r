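#' Fourier-series stimulus
#'
#' A time-varying stimulus written as a sum of phased cosines on a harmonic
#' grid, `I(t) = sum_n A_n cos(omega_n t + phi_n)` with
#' `omega_n = 2 * pi * n * f_base`. The flattened stimulus-parameter vector
#' used by the design machinery is `x = c(A_1..A_N, phi_1..phi_N)`.
#'
#' Amplitudes are bounded in `[0, A_max]`; phases are unconstrained during
#' optimization and only wrapped to `[-pi, pi)` for storage and reporting
#' (wrapping leaves the waveform unchanged).
#'
#' @param A Numeric vector of N amplitudes (`>= 0`).
#' @param phi Numeric vector of N phases (radians).
#' @param f_base Base frequency (Hz), default `10/3`.
#' @param T Duration (s), default 3.
#' @return A `fourier_stimulus` object.
#' @export
fourier_stimulus <- function(A, phi, f_base = 10 / 3, T = 3) {
  stopifnot(length(A) == length(phi), all(is.finite(A)), all(A >= 0),
            all(is.finite(phi)), f_base > 0, T > 0)
  structure(list(A = as.numeric(A), phi = wrap_phase(as.numeric(phi)),
                 f_base = f_base, T = T, N = length(A)),
            class = "fourier_stimulus")
}

#' @export
print.fourier_stimulus <- function(x, ...) {
  cat(sprintf("<fourier_stimulus> N = %d, f_base = %.4g Hz, T = %g s\n",
              x$N, x$f_base, x$T))
  cat("  A  :", paste(signif(x$A, 4), collapse = " "), "\n")
  cat("  phi:", paste(signif(x$phi, 4), collapse = " "), "\n")
  invisible(x)
}

#' Wrap phases to [-pi, pi)
#' @param phi Numeric vector of phases (radians).
#' @return Wrapped phases.
#' @export
wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

#' Flatten a stimulus to the parameter vector x = c(A, phi)
#' @param x A [fourier_stimulus()].
#' @return Numeric 2N-vector.
#' @export
as_x <- function(x) {
  stopifnot(inherits(x, "fourier_stimulus"))
  c(x$A, x$phi)
}

x_to_stimulus <- function(xv, template) {
  N <- template$N
  fourier_stimulus(pmax(xv[seq_len(N)], 0), xv[N + seq_len(N)],
                   f_base = template$f_base, T = template$T)
}

#' Evaluate a Fourier stimulus
#' @param x A [fourier_stimulus()].
#' @param t Time(s) in seconds; vectorized.
#' @return Stimulus value(s).
#' @export
eval_stimulus <- function(x, t) {
  stopifnot(inherits(x, "fourier_stimulus"))
  omega <- 2 * pi * seq_len(x$N) * x$f_base
  vapply(t, function(tt) sum(x$A * cos(omega * tt + x$phi)), 0)
}

#' Derivatives of the stimulus with respect to its 2N parameters
#'
#' Entry `n` is `cos(omega_n t + phi_n)` (amplitude) and entry `N + n` is
#' `-A_n sin(omega_n t + phi_n)` (phase).
#' @param x A [fourier_stimulus()].
#' @param t Scalar time (s).
#' @return Numeric 2N-vector.
#' @export
stimulus_derivs <- function(x, t) {
  stopifnot(inherits(x, "fourier_stimulus"), length(t) == 1)
  omega <- 2 * pi * seq_len(x$N) * x$f_base
  arg <- omega * t + x$phi
  c(cos(arg), -x$A * sin(arg))
}

#' Draw a random stimulus (the nonadaptive control)
#'
#' Amplitudes are i.i.d. `Uniform[0, A_max]`, phases i.i.d. `Uniform[-pi, pi)`.
#' Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param N Number of harmonics (default 5).
#' @param f_base Base frequency (Hz).
#' @param T Duration (s).
#' @param A_max Amplitude upper bound (default 120).
#' @return A [fourier_stimulus()].
#' @export
random_stimulus <- function(N = 5, f_base = 10 / 3, T = 3, A_max = 120) {
  fourier_stimulus(stats::runif(N, 0, A_max), stats::runif(N, -pi, pi),
                   f_base = f_base, T = T)
}

#' Square-wave demonstration stimulus
#'
#' A constant-on pulse used to illustrate the network's transient-then-plateau
#' response: `I(t) = height` for `t_on <= t < t_off`, 0 elsewhere. Returns a
#' function of time suitable for [simulate_network()].
#'
#' @param height Pulse height (stimulus units).
#' @param t_on,t_off Pulse onset/offset (s).
#' @return Function `I(t)`, vectorized over `t`.
#' @export
square_wave_stimulus <- function(height = 50, t_on = 0.1, t_off = 2) {
  force(height); force(t_on); force(t_off)
  function(t) ifelse(t >= t_on & t < t_off, height, 0)
}

#' Serialize a stimulus to JSON
#' @param x A [fourier_stimulus()].
#' @return A JSON string `{A, phi, f_base, T}`.
#' @export
stimulus_to_json <- function(x) {
  stopifnot(inherits(x, "fourier_stimulus"))
  jsonlite::toJSON(list(A = x$A, phi = x$phi, f_base = x$f_base, T = x$T),
                   digits = NA, auto_unbox = TRUE)
}

#' Deserialize a stimulus from JSON
#' @param json A JSON string produced by [stimulus_to_json()].
#' @return A [fourier_stimulus()].
#' @export
stimulus_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  fourier_stimulus(o$A, o$phi, f_base = o$f_base, T = o$T)
}

#' Write a rendered stimulus waveform to CSV
#' @param x A [fourier_stimulus()].
#' @param path Output file; columns `time,I`.
#' @param dt Rendering step (s).
#' @return `path`, invisibly.
#' @export
write_stimulus_csv <- function(x, path, dt = 1e-3) {
  tt <- seq(0, x$T, by = dt)
  utils::write.csv(data.frame(time = tt, I = eval_stimulus(x, tt)),
                   path, row.names = FALSE)
  invisible(path)
}
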