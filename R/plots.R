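#' Plot a simulated trajectory
#'
#' Panels for the two membrane-potential-like states and the excitatory
#' firing rate, against time.
#' @param object An `ei_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ei_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("V_e", "V_i", "r_e"),
                              names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = c("V_e", "V_i", "r_e"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot the eight rate-sensitivity time courses
#' @param object An `ei_sensitivities` with the `dre_dtheta` block.
#' @param ... Unused.
#' @return A ggplot object, one facet per network parameter.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ei_sensitivities <- function(object, ...) {
  stopifnot(!is.null(object$dre_dtheta))
  df <- tibble::as_tibble(as.data.frame(object$dre_dtheta))
  df$time <- object$times
  long <- tidyr::pivot_longer(df, -"time", names_to = "parameter",
                              values_to = "sensitivity")
  long$parameter <- factor(long$parameter, levels = theta_names())
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$sensitivity)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~parameter, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "d r_e / d theta_k")
}

#' Plot a rendered stimulus waveform
#' @param object A [fourier_stimulus()].
#' @param dt Rendering step (s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fourier_stimulus <- function(object, dt = 1e-3, ...) {
  tt <- seq(0, object$T, by = dt)
  ggplot2::ggplot(tibble::tibble(time = tt, I = eval_stimulus(object, tt)),
                  ggplot2::aes(.data$time, .data$I)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "stimulus")
}

#' Recovery summary bar plot
#'
#' Mean absolute relative error per parameter and mode.
#' @param recovery Output of [summarize_recovery()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery) {
  ggplot2::ggplot(recovery,
                  ggplot2::aes(.data$parameter, .data$mean_rel_error_pct,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean |relative error| (%)")
}

#' Scatter plots of the three confounded parameter pairs with their
#' predicted compensation curves
#' @param estimates Tibble of final estimates (see [final_estimates()]).
#' @param truth Generating [network_params()].
#' @return A ggplot object with one facet per pair.
#' @export
plot_confounding <- function(estimates, truth) {
  curves <- confounding_curves(truth)
  mk <- function(xn, yn, f) {
    xs <- seq(min(estimates[[xn]]), max(estimates[[xn]]), length.out = 100)
    list(pts = tibble::tibble(pair = paste(xn, "vs", yn),
                              x = estimates[[xn]], y = estimates[[yn]],
                              mode = estimates$mode),
         cv = tibble::tibble(pair = paste(xn, "vs", yn), x = xs, y = f(xs)))
  }
  parts <- list(mk("beta_e", "w_e", curves$w_e_of_beta_e),
                mk("beta_i", "w_ei", curves$w_ei_of_beta_i),
                mk("w_ee", "w_ei", curves$w_ei_of_w_ee))
  pts <- dplyr::bind_rows(lapply(parts, `[[`, "pts"))
  cv <- dplyr::bind_rows(lapply(parts, `[[`, "cv"))
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mode), alpha = 0.7) +
    ggplot2::geom_line(data = cv) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
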