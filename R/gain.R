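#' Sigmoidal gain-function constants
#'
#' The gain function maps a unit's membrane-potential-like state to its firing
#' rate: `g(V) = Gamma / (1 + exp(-a * (V - h)))`. The three constants are
#' treated as known and fixed throughout; only the network time constants and
#' connection weights are estimated.
#'
#' @param Gamma Maximum firing rate (spikes/s), `> 0`.
#' @param a Slope of the sigmoid (1/voltage-unit), `> 0`.
#' @param h Soft threshold (voltage-units); `g(h) = Gamma/2`.
#' @return A `gain_params` object.
#' @examples
#' gp <- gain_params(100, 0.04, 70)
#' gain(70, gp)        # Gamma/2 at threshold
#' gain(70, gp, 1)     # slope Gamma*a/4 at threshold
#' @export
gain_params <- function(Gamma, a, h) {
  stopifnot(is.numeric(Gamma), Gamma > 0, is.numeric(a), a > 0, is.numeric(h))
  structure(list(Gamma = Gamma, a = a, h = h), class = "gain_params")
}

#' @export
print.gain_params <- function(x, ...) {
  cat(sprintf("<gain_params> Gamma = %g spikes/s, a = %g, h = %g\n",
              x$Gamma, x$a, x$h))
  invisible(x)
}

#' Evaluate a gain function or its derivatives
#'
#' @param V State value(s) (voltage-units); vectorized.
#' @param gp A [gain_params()] object.
#' @param order 0 for the rate, 1 or 2 for the first or second V-derivative.
#' @return Numeric vector the length of `V`.
#' @export
gain <- function(V, gp, order = 0) {
  stopifnot(inherits(gp, "gain_params"), order %in% 0:2)
  s <- stats::plogis(gp$a * (V - gp$h))
  switch(as.character(order),
    "0" = gp$Gamma * s,
    "1" = gp$Gamma * gp$a * s * (1 - s),
    "2" = gp$Gamma * gp$a^2 * s * (1 - s) * (1 - 2 * s))
}
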