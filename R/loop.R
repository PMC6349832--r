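#' Derive a reproducible child seed from a master seed and a role label
#'
#' Every source of randomness in an experiment draws its seed as a
#' deterministic hash of the master seed plus a role label (and indices), so
#' runs are byte-reproducible and replicate batches are order-independent.
#'
#' @param seed Master seed (integer).
#' @param ... Role labels / indices (coerced to character).
#' @return An integer in `[1, 2^31 - 20]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h) + 1L
}

#' Closed-loop experiment configuration
#'
#' @param truth Generating [network_params()].
#' @param bounds Estimation bounds (default [default_bounds()]).
#' @param N_itr Number of loop iterations; optimal mode presents
#'   `8 * N_itr` stimuli (one per parameter per iteration).
#' @param mode `"optimal"` (adaptive design) or `"random"` (nonadaptive
#'   control).
#' @param N,f_base,T,A_max Stimulus configuration.
#' @param dt Simulation step (s).
#' @param n_starts_design,n_starts_mle Multistart budgets.
#' @param design_maxit,mle_maxit Per-start iteration caps.
#' @param estimate_each In random mode, re-estimate after every stimulus
#'   (`TRUE`, mirroring optimal mode) or once at the end (`FALSE`, default).
#' @param init_at_onset Use the equilibrium at the stimulus onset value as the
#'   initial condition instead of the `I = 0` baseline equilibrium (default
#'   `FALSE`).
#' @param seed Master seed.
#' @return An `ei_config` list.
#' @export
experiment_config <- function(truth = true_params(), bounds = default_bounds(),
                              N_itr = 15, mode = c("optimal", "random"),
                              N = 5, f_base = 10 / 3, T = 3, A_max = 120,
                              dt = 1e-3, n_starts_design = 8,
                              n_starts_mle = 10, design_maxit = 200,
                              mle_maxit = 500, estimate_each = FALSE,
                              init_at_onset = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(N_itr >= 1)
  structure(list(truth = truth, bounds = bounds, N_itr = N_itr, mode = mode,
                 N = N, f_base = f_base, T = T, A_max = A_max, dt = dt,
                 n_starts_design = n_starts_design,
                 n_starts_mle = n_starts_mle, design_maxit = design_maxit,
                 mle_maxit = mle_maxit, estimate_each = estimate_each,
                 init_at_onset = init_at_onset, seed = as.integer(seed)),
            class = "ei_config")
}

# Simulate the truth's response to one stimulus and draw one spike train.
elicit_response <- function(cfg, stim, seed_spike) {
  traj <- simulate_network(cfg$truth, stim, T = cfg$T, dt = cfg$dt)
  set.seed(seed_spike)
  sample_spikes(traj$r_e, cfg$T)
}

#' Run one closed-loop (or random-control) experiment
#'
#' Optimal mode follows the adaptive loop: initialize the estimate uniformly
#' in the bounds, then for each iteration and each parameter `k = 1..8` design
#' a stimulus maximizing `U_k` at the current estimate, present it to the true
#' network, record the Poisson spike train, and re-estimate from all data so
#' far (the previous estimate is included as a warm start). Random mode
#' presents `8 * N_itr` random stimuli and estimates either after every
#' stimulus or once at the end. If a design or estimation step fails, a random
#' stimulus is substituted (or the previous estimate kept) and the failure is
#' flagged -- long runs never die midway.
#'
#' @param cfg An [experiment_config()].
#' @return An `ei_experiment` list: `config`, `data` (the accumulated
#'   [ei_dataset()] with per-stimulus `k`, `seed`, `designed` flag),
#'   `estimates` (tibble of per-update estimates: `m`, `loglik`, one column
#'   per parameter), `theta_hat` (final estimate), `loglik`, `failures`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ei_config"))
  M_total <- 8L * cfg$N_itr
  set.seed(derive_seed(cfg$seed, "init"))
  theta_hat <- stats::runif(8, cfg$bounds$lower, cfg$bounds$upper)
  stimuli <- list(); spikes <- list()
  kvec <- integer(0); seeds <- integer(0); designed <- logical(0)
  est_rows <- list()
  failures <- character(0)
  fit <- NULL

  for (m in seq_len(M_total)) {
    k <- ((m - 1L) %% 8L) + 1L
    if (cfg$mode == "optimal") {
      set.seed(derive_seed(cfg$seed, "design", m))
      des <- tryCatch(
        design_stimulus(theta_to_params(theta_hat), k, N = cfg$N,
                        f_base = cfg$f_base, T = cfg$T, A_max = cfg$A_max,
                        n_starts = cfg$n_starts_design, dt = cfg$dt,
                        maxit = cfg$design_maxit),
        error = function(e) NULL)
      if (is.null(des)) {
        failures <- c(failures, sprintf("design failed at m=%d; random substitute", m))
        set.seed(derive_seed(cfg$seed, "design-fallback", m))
        stim <- random_stimulus(cfg$N, cfg$f_base, cfg$T, cfg$A_max)
        was_designed <- FALSE
      } else {
        stim <- des$stimulus
        was_designed <- TRUE
      }
    } else {
      set.seed(derive_seed(cfg$seed, "stimulus", m))
      stim <- random_stimulus(cfg$N, cfg$f_base, cfg$T, cfg$A_max)
      was_designed <- FALSE
    }
    sseed <- derive_seed(cfg$seed, "spikes", m)
    spk <- elicit_response(cfg, stim, sseed)
    stimuli[[m]] <- stim; spikes[[m]] <- spk
    kvec[m] <- k; seeds[m] <- sseed; designed[m] <- was_designed

    do_estimate <- cfg$mode == "optimal" || cfg$estimate_each || m == M_total
    if (do_estimate) {
      data_m <- ei_dataset(stimuli, spikes)
      set.seed(derive_seed(cfg$seed, "mle", m))
      new_fit <- tryCatch(
        estimate_network(data_m, bounds = cfg$bounds,
                         n_starts = cfg$n_starts_mle,
                         extra_starts = if (cfg$mode == "optimal")
                           list(theta_hat) else NULL,
                         dt = cfg$dt, maxit = cfg$mle_maxit,
                         gain_e = cfg$truth$gain_e, gain_i = cfg$truth$gain_i),
        error = function(e) NULL)
      if (is.null(new_fit)) {
        failures <- c(failures, sprintf("estimation failed at m=%d; kept previous estimate", m))
      } else {
        fit <- new_fit
        theta_hat <- unname(fit$theta_hat)
        est_rows[[length(est_rows) + 1L]] <- tibble::tibble(
          m = m, loglik = fit$loglik,
          !!!stats::setNames(as.list(theta_hat), theta_names()))
      }
    }
  }
  data <- ei_dataset(stimuli, spikes, k = kvec, seed = seeds,
                     designed = designed)
  structure(list(config = cfg, data = data,
                 estimates = dplyr::bind_rows(est_rows),
                 theta_hat = stats::setNames(theta_hat, theta_names()),
                 loglik = if (is.null(fit)) NA_real_ else fit$loglik,
                 failures = failures),
            class = "ei_experiment")
}

#' @export
print.ei_experiment <- function(x, ...) {
  cat(sprintf("<ei_experiment> mode = %s, M = %d stimuli, final loglik = %.2f\n",
              x$config$mode, nrow(x$data), x$loglik))
  print(signif(x$theta_hat, 4))
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' Per-update estimates of an experiment, one row per update
#' @param x An `ei_experiment`.
#' @param ... Unused.
#' @return Tibble with `m`, `loglik`, and the eight parameter columns.
#' @export
#' @exportS3Method generics::tidy
tidy.ei_experiment <- function(x, ...) x$estimates

#' One-row summary of an experiment
#' @param x An `ei_experiment`.
#' @param ... Unused.
#' @return Tibble with mode, M, final loglik, failure count.
#' @export
#' @exportS3Method generics::glance
glance.ei_experiment <- function(x, ...) {
  tibble::tibble(mode = x$config$mode, M = nrow(x$data), loglik = x$loglik,
                 n_failures = length(x$failures))
}

#' Run independent replicate experiments
#'
#' Each trial derives its own seed from the master seed and the trial index,
#' so batches with disjoint index ranges concatenate to the same results as
#' one larger batch.
#'
#' @param cfg An [experiment_config()] (its `seed` is the master seed).
#' @param n_trials Number of replicates.
#' @param trial_offset Index of the first trial (default 1); lets batches be
#'   split across calls.
#' @return List of `ei_experiment` records; failed trials are recorded as
#'   `NULL` with a warning, leaving the others unaffected.
#' @export
run_replicates <- function(cfg, n_trials, trial_offset = 1L) {
  stopifnot(n_trials >= 1)
  lapply(seq_len(n_trials) + trial_offset - 1L, function(tr) {
    cfg_t <- cfg
    cfg_t$seed <- derive_seed(cfg$seed, "trial", tr)
    tryCatch(run_experiment(cfg_t), error = function(e) {
      warning(sprintf("trial %d failed: %s", tr, conditionMessage(e)))
      NULL
    })
  })
}

#' Final estimates of a list of replicate experiments
#' @param records List of `ei_experiment` (as from [run_replicates()]);
#'   `NULL` entries are dropped.
#' @return Tibble with `trial`, `mode`, `loglik`, and parameter columns.
#' @export
final_estimates <- function(records) {
  records <- Filter(Negate(is.null), records)
  dplyr::bind_rows(lapply(seq_along(records), function(i) {
    r <- records[[i]]
    tibble::tibble(trial = i, mode = r$config$mode, loglik = r$loglik,
                   !!!stats::setNames(as.list(unname(r$theta_hat)),
                                      theta_names()))
  }))
}
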