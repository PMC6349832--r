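#' Summarize parameter recovery across replicate trials
#'
#' Per-parameter (and per-mode) mean and sample standard deviation of the
#' final estimates, plus the mean absolute relative error in percent
#' (`100 * |estimate - truth| / truth`, averaged over trials).
#'
#' @param estimates Tibble of final estimates, one row per trial, with a
#'   `mode` column and the eight parameter columns (see [final_estimates()]).
#' @param truth Generating [network_params()].
#' @return Tibble with columns `parameter`, `mode`, `true_value`, `mean`,
#'   `sd`, `mean_rel_error_pct`.
#' @export
summarize_recovery <- function(estimates, truth) {
  stopifnot(nrow(estimates) >= 2)
  tv <- as_theta(truth)
  estimates |>
    tidyr::pivot_longer(dplyr::all_of(theta_names()),
                        names_to = "parameter", values_to = "estimate") |>
    dplyr::group_by(.data$parameter, .data$mode) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean = mean(.data$estimate),
      sd = stats::sd(.data$estimate),
      mean_rel_error_pct = mean(100 * abs(.data$estimate -
        tv[[.data$parameter[1]]]) / tv[[.data$parameter[1]]]),
      .groups = "drop") |>
    dplyr::mutate(true_value = unname(tv[.data$parameter]),
                  parameter = factor(.data$parameter, levels = theta_names())) |>
    dplyr::arrange(.data$parameter) |>
    dplyr::select("parameter", "mode", "true_value", "n_trials", "mean",
                  "sd", "mean_rel_error_pct")
}

#' Likelihood-versus-sample-size regression and efficiency ratio
#'
#' Ordinary least squares of the per-`M` median achieved log-likelihood on
#' `M`, per mode. With both an `"optimal"` and a `"random"` mode present,
#' also returns the slope ratio `slope_opt / slope_rand` (the per-stimulus
#' information gain of the adaptive design) and the stimulus-savings fraction
#' `1 - slope_rand / slope_opt`.
#'
#' @param medians Tibble with columns `mode`, `M`, `loglik` (median achieved
#'   log-likelihood at that sample size); at least 3 distinct `M` per mode.
#' @return List of class `ei_regression`: `fits` (tibble: mode, slope,
#'   intercept), `ratio`, `savings`, `degenerate` (TRUE when the random slope
#'   is zero/non-finite, in which case `ratio`/`savings` are `NA`).
#' @export
likelihood_regression <- function(medians) {
  stopifnot(all(c("mode", "M", "loglik") %in% names(medians)))
  fits <- medians |>
    dplyr::group_by(.data$mode) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$M)) < 3)
        stop("likelihood_regression needs >= 3 distinct M values per mode")
      co <- stats::coef(stats::lm(loglik ~ M, data = df))
      tibble::tibble(slope = unname(co[["M"]]),
                     intercept = unname(co[["(Intercept)"]]))
    }) |>
    dplyr::ungroup()
  ratio <- savings <- NA_real_
  degenerate <- FALSE
  if (all(c("optimal", "random") %in% fits$mode)) {
    s_opt <- fits$slope[fits$mode == "optimal"]
    s_rand <- fits$slope[fits$mode == "random"]
    scale <- max(abs(medians$loglik), 1)
    if (!is.finite(s_rand) || !is.finite(s_opt) ||
        abs(s_rand) < 1e-10 * scale) {
      degenerate <- TRUE
    } else {
      ratio <- s_opt / s_rand
      savings <- 1 - s_rand / s_opt
    }
  }
  structure(list(fits = fits, ratio = ratio, savings = savings,
                 degenerate = degenerate),
            class = "ei_regression")
}

#' @export
print.ei_regression <- function(x, ...) {
  print(x$fits)
  if (x$degenerate) cat("degenerate: slope ratio undefined\n")
  else if (is.finite(x$ratio))
    cat(sprintf("slope ratio %.4f, savings fraction %.4f\n",
                x$ratio, x$savings))
  invisible(x)
}

#' Probability of reaching the best solution in multistart optimization
#'
#' Each run passes when every coordinate of its endpoint lies within a
#' relative tolerance `eta` of the best endpoint (the one with the highest
#' objective). On the parameter side the denominator is the true parameter
#' value; on the stimulus side (`truth = NULL`) it is the best endpoint's own
#' amplitudes. The per-start success probability `p` is recovered from the
#' pass fraction via `Prob("best") = 1 - (1 - p)^n`.
#'
#' @param endpoints Tibble with one row per run: an `objective` column plus
#'   coordinate columns (the eight parameter names, or amplitude columns).
#' @param truth Optional [network_params()]; when given, coordinates are the
#'   eight parameters and relative errors use the true values as denominators.
#' @param eta Relative tolerance (default 0.1).
#' @param n Number of starts each run represents (default 1).
#' @param abs_tol Absolute fallback tolerance for zero-denominator
#'   coordinates (flagged in the result).
#' @return List of class `ei_probbest`: `prob_best` (pass fraction), `p`
#'   (inverted per-start probability), `pass` (logical per run), `best_run`,
#'   `zero_denominators` (flag).
#' @export
best_solution_probability <- function(endpoints, truth = NULL, eta = 0.1,
                                      n = 1, abs_tol = 1e-6) {
  stopifnot(nrow(endpoints) >= 2, "objective" %in% names(endpoints),
            eta > 0, n >= 1)
  coord_cols <- if (!is.null(truth)) theta_names() else
    setdiff(names(endpoints), c("objective", "run", "trial", "mode"))
  X <- as.matrix(endpoints[, coord_cols, drop = FALSE])
  best <- which.max(endpoints$objective)
  xb <- X[best, ]
  denom <- if (!is.null(truth)) unname(as_theta(truth))[
    match(coord_cols, theta_names())] else abs(xb)
  zero <- denom == 0
  pass <- vapply(seq_len(nrow(X)), function(i) {
    d <- abs(X[i, ] - xb)
    ok <- ifelse(zero, d <= abs_tol, d / ifelse(zero, 1, denom) <= eta)
    all(ok)
  }, TRUE)
  prob <- mean(pass)
  p <- 1 - (1 - prob)^(1 / n)
  structure(list(prob_best = prob, p = p, pass = pass, best_run = best,
                 zero_denominators = any(zero), eta = eta, n = n),
            class = "ei_probbest")
}

#' Forward map of the multistart success probability
#'
#' `Prob("best") = 1 - (1 - p)^n`: the probability that at least one of `n`
#' independent starts finds the best solution when a single start succeeds
#' with probability `p`. Inverse of the inversion done by
#' [best_solution_probability()].
#' @param p Per-start success probability in `[0, 1]`.
#' @param n Number of starts.
#' @return Probability in `[0, 1]`.
#' @export
prob_best_forward <- function(p, n) 1 - (1 - p)^n

#' Heuristic parameter-confounding curves
#'
#' Three approximate compensation relations between parameter pairs whose
#' estimation errors correlate most strongly, derived from the network
#' equations: the stimulus drive `beta_e * w_e` (so
#' `w_e_hat = beta_e w_e / beta_e_hat`), the inhibitory coupling ratio
#' `w_ei / beta_i` (so `w_ei_hat = w_ei beta_i_hat / beta_i`), and the
#' near-equilibrium recurrent balance
#' `w_ee g_e(Ve_bar) - w_ei g_i(Vi_bar)` (solving for `w_ei_hat` given
#' `w_ee_hat`). Each curve passes exactly through the true parameter point.
#'
#' @param truth Generating [network_params()].
#' @param I_baseline Constant input at which the equilibrium is evaluated
#'   (default 0).
#' @return Named list of three functions:
#'   `w_e_of_beta_e(beta_e_hat)`, `w_ei_of_beta_i(beta_i_hat)`,
#'   `w_ei_of_w_ee(w_ee_hat)`.
#' @export
confounding_curves <- function(truth, I_baseline = 0) {
  stopifnot(inherits(truth, "network_params"))
  veq <- find_equilibrium(truth, I_baseline)
  ge_bar <- gain(veq[1], truth$gain_e)
  gi_bar <- gain(veq[2], truth$gain_i)
  if (gi_bar == 0) stop("inhibitory equilibrium rate is zero")
  balance <- truth$w_ee * ge_bar - truth$w_ei * gi_bar
  list(
    w_e_of_beta_e = function(beta_e_hat) {
      if (any(beta_e_hat == 0)) stop("beta_e_hat must be nonzero")
      truth$beta_e * truth$w_e / beta_e_hat
    },
    w_ei_of_beta_i = function(beta_i_hat) {
      truth$w_ei * beta_i_hat / truth$beta_i
    },
    w_ei_of_w_ee = function(w_ee_hat) {
      (w_ee_hat * ge_bar - balance) / gi_bar
    })
}

#' Correlation matrix of parameter-estimation errors
#'
#' Pearson correlations of the estimation errors `theta_hat - theta_true`
#' across replicate trials, per mode. Constant estimate columns yield `NA`
#' entries (reported as missing rather than failing). The three parameter
#' pairs expected to confound -- (`beta_e`, `w_e`), (`beta_i`, `w_ei`),
#' (`w_ee`, `w_ei`) -- are listed in `highlight`.
#'
#' @param estimates Tibble as for [summarize_recovery()].
#' @param truth Generating [network_params()].
#' @return List of class `ei_confounding`: `matrices` (named list of 8x8
#'   correlation matrices, one per mode) and `highlight` (tibble of the three
#'   pairs with their correlations per mode).
#' @export
error_correlations <- function(estimates, truth) {
  stopifnot(nrow(estimates) >= 3)
  tv <- as_theta(truth)
  pairs <- tibble::tibble(p1 = c("beta_e", "beta_i", "w_ee"),
                          p2 = c("w_e", "w_ei", "w_ei"))
  mats <- lapply(split(estimates, estimates$mode), function(df) {
    err <- sweep(as.matrix(df[, theta_names()]), 2, tv)
    suppressWarnings(stats::cor(err))
  })
  hl <- dplyr::bind_rows(lapply(names(mats), function(md) {
    tibble::tibble(mode = md, p1 = pairs$p1, p2 = pairs$p2,
                   correlation = mapply(function(a, b) mats[[md]][a, b],
                                        pairs$p1, pairs$p2))
  }))
  structure(list(matrices = mats, highlight = hl), class = "ei_confounding")
}

#' @export
print.ei_confounding <- function(x, ...) {
  for (md in names(x$matrices)) {
    cat("mode:", md, "\n")
    print(round(x$matrices[[md]], 2))
  }
  invisible(x)
}

#' Rank-sum comparison of per-parameter errors between modes
#'
#' Two-sided Wilcoxon rank-sum test of the absolute relative errors of each
#' parameter, optimal versus random mode. Identical samples give `p = 1`.
#'
#' @param estimates Tibble as for [summarize_recovery()], containing both
#'   modes with at least 3 trials each.
#' @param truth Generating [network_params()].
#' @return Tibble with `parameter`, `p_value`, `n_optimal`, `n_random`.
#' @export
compare_modes <- function(estimates, truth) {
  tv <- as_theta(truth)
  stopifnot(all(c("optimal", "random") %in% estimates$mode))
  dplyr::bind_rows(lapply(theta_names(), function(pn) {
    eo <- abs(estimates[[pn]][estimates$mode == "optimal"] - tv[[pn]]) / tv[[pn]]
    er <- abs(estimates[[pn]][estimates$mode == "random"] - tv[[pn]]) / tv[[pn]]
    stopifnot(length(eo) >= 3, length(er) >= 3)
    pv <- if (length(unique(c(eo, er))) == 1) 1 else
      suppressWarnings(stats::wilcox.test(eo, er)$p.value)
    tibble::tibble(parameter = pn, p_value = pv,
                   n_optimal = length(eo), n_random = length(er))
  }))
}

#' Write a recovery summary, correlation matrices and regression to files
#'
#' Convenience output shaped like the package's standard analysis products:
#' a recovery CSV, one correlation-matrix CSV per mode, and a regression /
#' probability JSON.
#'
#' @param recovery Output of [summarize_recovery()].
#' @param confounding Optional [error_correlations()] result.
#' @param regression Optional [likelihood_regression()] result.
#' @param probability Optional [best_solution_probability()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(recovery, confounding = NULL, regression = NULL,
                           probability = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(recovery, file.path(dir, "recovery.csv"), row.names = FALSE)
  if (!is.null(confounding)) {
    for (md in names(confounding$matrices))
      utils::write.csv(confounding$matrices[[md]],
                       file.path(dir, paste0("correlations_", md, ".csv")))
  }
  if (!is.null(regression)) {
    jsonlite::write_json(
      list(fits = regression$fits, ratio = regression$ratio,
           savings = regression$savings, degenerate = regression$degenerate),
      file.path(dir, "regression.json"), digits = NA, auto_unbox = TRUE,
      dataframe = "rows")
  }
  if (!is.null(probability)) {
    jsonlite::write_json(
      list(prob_best = probability$prob_best, p = probability$p,
           eta = probability$eta, n = probability$n),
      file.path(dir, "probability.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
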