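mk_est <- function(mat, mode = "random") {
  colnames(mat) <- theta_names()
  out <- tibble::as_tibble(mat)
  out$mode <- mode
  out$trial <- seq_len(nrow(mat))
  out
}

test_that("recovery summary reproduces hand-computed statistics", {
  truth <- true_params()
  tv <- unname(as_theta(truth))
  # all trials exactly at truth: zero errors and zero spread
  exact <- mk_est(matrix(rep(tv, 3), nrow = 3, byrow = TRUE))
  s <- summarize_recovery(exact, truth)
  expect_equal(s$mean, tv[match(s$parameter, theta_names())])
  expect_true(all(s$sd == 0))
  expect_true(all(s$mean_rel_error_pct == 0))
  # two trials straddling beta_e = 50 by 1
  two <- mk_est(matrix(rep(tv, 2), nrow = 2, byrow = TRUE))
  two$beta_e <- c(49, 51)
  s2 <- summarize_recovery(two, truth)
  row <- s2[s2$parameter == "beta_e", ]
  expect_equal(row$mean, 50)
  expect_equal(row$sd, sd(c(49, 51)))   # sample sd = sqrt(2)
  expect_equal(row$mean_rel_error_pct, 2)
})

test_that("likelihood regression recovers planted lines and their ratio", {
  M <- c(8, 16, 24, 40)
  med <- dplyr::bind_rows(
    tibble::tibble(mode = "optimal", M = M, loglik = 257.1 * M + 76.2),
    tibble::tibble(mode = "random", M = M, loglik = 174.5 * M + 31.1))
  reg <- likelihood_regression(med)
  opt <- reg$fits[reg$fits$mode == "optimal", ]
  rnd <- reg$fits[reg$fits$mode == "random", ]
  expect_equal(opt$slope, 257.1, tolerance = 1e-9)
  expect_equal(opt$intercept, 76.2, tolerance = 1e-9)
  expect_equal(rnd$slope, 174.5, tolerance = 1e-9)
  expect_equal(reg$ratio, 257.1 / 174.5, tolerance = 1e-12)
  expect_equal(reg$savings, 1 - 174.5 / 257.1, tolerance = 1e-12)
  expect_false(reg$degenerate)
})

test_that("degenerate horizontal data are flagged, not NaN-crashed", {
  med <- dplyr::bind_rows(
    tibble::tibble(mode = "optimal", M = c(8, 16, 24), loglik = c(1, 2, 3)),
    tibble::tibble(mode = "random", M = c(8, 16, 24), loglik = c(5, 5, 5)))
  reg <- likelihood_regression(med)
  expect_true(reg$degenerate)
  expect_true(is.na(reg$ratio))
  expect_error(likelihood_regression(
    tibble::tibble(mode = "optimal", M = c(8, 16), loglik = c(1, 2))),
    "3 distinct M")
})

test_that("best-solution probability and its inversion behave as stated", {
  truth <- true_params()
  tv <- unname(as_theta(truth))
  # identical runs: probability one regardless of n
  same <- mk_est(matrix(rep(tv, 4), nrow = 4, byrow = TRUE))
  same$objective <- c(5, 5, 5, 5)
  r <- best_solution_probability(same, truth = truth, n = 7)
  expect_equal(r$prob_best, 1)
  expect_equal(r$p, 1)
  # 3 of 4 pass at n = 1: p equals the pass fraction
  off <- mk_est(matrix(rep(tv, 4), nrow = 4, byrow = TRUE))
  off$beta_e[4] <- 30   # 40% off the best run
  off$objective <- c(9, 5, 5, 5)
  r2 <- best_solution_probability(off, truth = truth, n = 1)
  expect_equal(r2$prob_best, 0.75)
  expect_equal(r2$p, 0.75)
  expect_equal(r2$best_run, 1)
  # forward and inverse compose to the identity
  expect_equal(prob_best_forward(0.3, 5), 1 - 0.7^5)
  r3 <- list(prob = 1 - 0.7^5)
  expect_equal(1 - (1 - r3$prob)^(1 / 5), 0.3, tolerance = 1e-12)
})

test_that("confounding curves pass through the truth and match worked values", {
  truth <- true_params()
  cv <- confounding_curves(truth)
  expect_equal(cv$w_e_of_beta_e(50), 1)
  expect_equal(cv$w_ei_of_beta_i(25), 2)
  expect_equal(cv$w_ei_of_w_ee(1.2), 2)
  # drive compensation: beta_e 62.5 maps to w_e 0.8
  expect_equal(cv$w_e_of_beta_e(62.5), 0.8)
  # inhibitory ratio: beta_i 30 maps to w_ei 2.4
  expect_equal(cv$w_ei_of_beta_i(30), 2.4)
  expect_error(cv$w_e_of_beta_e(0), "nonzero")
})

test_that("error correlations detect planted structure and a null", {
  truth <- true_params()
  # estimates drawn exactly on the drive-compensation curve: negative corr
  cv <- confounding_curves(truth)
  be <- seq(40, 60, length.out = 12)
  m <- matrix(rep(unname(as_theta(truth)), 12), nrow = 12, byrow = TRUE)
  m[, 1] <- be
  m[, 3] <- cv$w_e_of_beta_e(be)
  est <- mk_est(m, mode = "optimal")
  cc <- error_correlations(est, truth)
  expect_lt(cc$matrices$optimal["beta_e", "w_e"], 0)
  expect_equal(diag(cc$matrices$optimal), rep(1, 8), ignore_attr = TRUE)
  expect_equal(cc$matrices$optimal, t(cc$matrices$optimal))
  # independent Gaussian errors: off-diagonals near zero
  set.seed(91)
  n <- 400
  g <- mk_est(matrix(rep(unname(as_theta(truth)), n), nrow = n, byrow = TRUE) +
                matrix(rnorm(8 * n, sd = 0.05), n, 8))
  ccg <- error_correlations(g, truth)$matrices$random
  offdiag <- ccg[upper.tri(ccg)]
  expect_true(all(abs(offdiag) < 3 / sqrt(n)))
  # constant column: reported missing, not an error
  k <- mk_est(matrix(rep(unname(as_theta(truth)), 5), nrow = 5, byrow = TRUE) +
                cbind(rnorm(5), matrix(rnorm(7 * 5, sd = 0.1), 5, 7)))
  k$w_ii <- 0.4
  cck <- error_correlations(k, truth)$matrices$random
  expect_true(all(is.na(cck["w_ii", setdiff(theta_names(), "w_ii")])))
})

test_that("mode comparison via rank-sum handles ties, separation, and power", {
  truth <- true_params()
  tv <- unname(as_theta(truth))
  # identical samples in both modes: p = 1 everywhere
  m <- matrix(rep(tv, 6), nrow = 6, byrow = TRUE) * 1.05
  est <- dplyr::bind_rows(mk_est(m[1:3, ], "optimal"), mk_est(m[4:6, ], "random"))
  cmp <- compare_modes(est, truth)
  expect_true(all(cmp$p_value == 1))
  # completely separated 5 vs 5: the exact minimal two-sided p = 2/choose(10,5)
  sep_o <- mk_est(matrix(rep(tv, 5), 5, byrow = TRUE) * (1 + 0.001 * (1:5)),
                  "optimal")
  sep_r <- mk_est(matrix(rep(tv, 5), 5, byrow = TRUE) * (1 + 0.2 + 0.01 * (1:5)),
                  "random")
  cmp2 <- compare_modes(dplyr::bind_rows(sep_o, sep_r), truth)
  expect_equal(cmp2$p_value, rep(2 / choose(10, 5), 8), tolerance = 1e-10)
  # stochastically smaller optimal errors are detected most of the time
  wins <- vapply(1:10, function(sd) {
    set.seed(920 + sd)
    eo <- mk_est(matrix(rep(tv, 30), 30, byrow = TRUE) *
                   (1 + matrix(rnorm(240, sd = 0.05), 30, 8)), "optimal")
    er <- mk_est(matrix(rep(tv, 30), 30, byrow = TRUE) *
                   (1 + matrix(rnorm(240, sd = 0.15), 30, 8)), "random")
    cm <- compare_modes(dplyr::bind_rows(eo, er), truth)
    mean(cm$p_value < 0.05) >= 0.5
  }, TRUE)
  expect_gte(sum(wins), 9)
})

test_that("analysis artifacts are written in their standard shapes", {
  truth <- true_params()
  set.seed(93)
  m <- matrix(rep(unname(as_theta(truth)), 6), nrow = 6, byrow = TRUE) +
    matrix(rnorm(48, sd = 0.05), 6, 8)
  est <- dplyr::bind_rows(mk_est(m[1:3, ], "optimal"), mk_est(m[4:6, ], "random"))
  dir <- tempfile()
  reg <- likelihood_regression(dplyr::bind_rows(
    tibble::tibble(mode = "optimal", M = c(8, 16, 24), loglik = c(100, 200, 300)),
    tibble::tibble(mode = "random", M = c(8, 16, 24), loglik = c(80, 150, 230))))
  prob <- best_solution_probability(
    dplyr::mutate(est[est$mode == "optimal", ], objective = c(3, 2, 1)),
    truth = truth)
  write_analysis(summarize_recovery(est, truth),
                 confounding = error_correlations(est, truth),
                 regression = reg, probability = prob, dir = dir)
  expect_true(file.exists(file.path(dir, "recovery.csv")))
  expect_true(file.exists(file.path(dir, "correlations_optimal.csv")))
  expect_true(file.exists(file.path(dir, "regression.json")))
  expect_true(file.exists(file.path(dir, "probability.json")))
  rj <- jsonlite::fromJSON(file.path(dir, "regression.json"))
  expect_equal(rj$ratio, reg$ratio)
})
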