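# The decisive correctness checks for the sensitivity module are the
# finite-difference oracles: analytic blocks against central differences of
# plain simulations (with the initial state held fixed, so the differencing
# isolates the dynamical dependence). The full multi-instance sweep runs in
# the acceptance suite; here two instances guard each block.

test_that("sensitivities vanish identically in the forced-silence cases", {
  p <- true_params()
  silent <- fourier_stimulus(rep(0, 5), rep(0, 5))
  s <- solve_sensitivities(p, silent, dt = fast_dt, which = "dtheta")
  # input-weight sensitivities are forced by I, which is zero
  expect_equal(max(abs(s$dVe_dtheta[, "w_e"])), 0)
  expect_equal(max(abs(s$dVe_dtheta[, "w_i"])), 0)
  expect_equal(max(abs(s$dVi_dtheta[, "w_e"])), 0)
  # fully uncoupled network at its equilibrium: no beta sensitivity
  p0 <- network_params(50, 25, 0, 0, 0, 0, 0, 0)
  s0 <- solve_sensitivities(p0, silent, dt = fast_dt, which = "dtheta",
                            v0 = c(0, 0))
  expect_equal(max(abs(s0$dVe_dtheta[, "beta_e"])), 0)
  # every block is exactly zero at t = 0 by construction
  sc <- solve_sensitivities(p, silent, dt = fast_dt, which = "cross")
  expect_equal(max(abs(sc$dVe_dtheta[1, ])), 0)
  expect_equal(max(abs(sc$dVe_dx[1, ])), 0)
  expect_equal(max(abs(sc$d2Ve_dxdtheta[1, , ])), 0)
})

test_that("parameter and stimulus sensitivities match finite differences", {
  set.seed(71)
  for (i in 1:2) {
    p <- random_params()
    st <- random_stimulus()
    v0 <- find_equilibrium(p, 0)
    s <- solve_sensitivities(p, st, dt = fast_dt, which = "cross", v0 = v0)
    th <- as_theta(p)
    for (k in c(1, 4, 6)) {
      d <- 1e-4 * max(th[k], 1)
      fd <- central_fd(function(t2)
        simulate_network(theta_to_params(t2), st, dt = fast_dt, v0 = v0)$V_e,
        th, k, d)
      scale <- max(abs(s$dVe_dtheta[, k]))
      expect_lt(max(abs(fd - s$dVe_dtheta[, k])) / scale, 1e-3)
    }
    xv <- as_x(st)
    for (l in c(2, 8)) {
      d <- 1e-4 * max(abs(xv[l]), 1)
      fd <- central_fd(function(x2) {
        s2 <- fourier_stimulus(pmax(x2[1:5], 0), x2[6:10],
                               f_base = st$f_base, T = st$T)
        simulate_network(p, s2, dt = fast_dt, v0 = v0)$V_e
      }, xv, l, d)
      scale <- max(abs(s$dVe_dx[, l]))
      expect_lt(max(abs(fd - s$dVe_dx[, l])) / scale, 1e-3)
    }
    # cross block: difference the first-order stimulus sensitivities over theta
    for (k in c(2, 5)) {
      d <- 1e-4 * max(th[k], 1)
      fd <- central_fd(function(t2)
        solve_sensitivities(theta_to_params(t2), st, dt = fast_dt,
                            which = "dx", v0 = v0)$dVe_dx,
        th, k, d)
      an <- s$d2Ve_dxdtheta[, , k]
      expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-3)
    }
  }
})

test_that("rate derivatives follow the chain rule through the gain", {
  p <- true_params()
  set.seed(73)
  st <- random_stimulus()
  s <- solve_sensitivities(p, st, dt = fast_dt, which = "dtheta")
  g1 <- gain(s$trajectory$V_e, p$gain_e, 1)
  expect_equal(s$dre_dtheta, s$dVe_dtheta * g1)
  # where the V-sensitivity is zero the rate sensitivity is zero
  silent <- fourier_stimulus(rep(0, 5), rep(0, 5))
  s0 <- solve_sensitivities(p, silent, dt = fast_dt, which = "dtheta")
  expect_equal(max(abs(s0$dre_dtheta[, "w_e"])), 0)
  # finite difference of the rate itself
  v0 <- find_equilibrium(p, 0)
  s <- solve_sensitivities(p, st, dt = fast_dt, which = "dtheta", v0 = v0)
  th <- as_theta(p)
  fd <- central_fd(function(t2)
    simulate_network(theta_to_params(t2), st, dt = fast_dt, v0 = v0)$r_e,
    th, 3, 1e-4)
  expect_lt(max(abs(fd - s$dre_dtheta[, 3])) / max(abs(s$dre_dtheta[, 3])),
            1e-3)
})

test_that("input-weight sensitivity dwarfs the excitatory time-constant one", {
  # on strong stimuli the rate is far more sensitive to w_e than to beta_e
  p <- true_params()
  set.seed(77)
  for (i in 1:3) {
    st <- random_stimulus()
    s <- solve_sensitivities(p, st, dt = fast_dt, which = "dtheta")
    expect_gt(max(abs(s$dre_dtheta[, "w_e"])),
              max(abs(s$dre_dtheta[, "beta_e"])))
  }
})

test_that("equilibrium parameter-sensitivity matches differencing the root", {
  p <- true_params()
  dth <- equilibrium_dtheta(p, 0)
  th <- as_theta(p)
  for (k in c(5, 6, 8)) {
    d <- 1e-5 * max(th[k], 1)
    fd <- central_fd(function(t2) find_equilibrium(theta_to_params(t2), 0),
                     th, k, d)
    expect_equal(dth[, k], fd, tolerance = 1e-5, ignore_attr = TRUE)
  }
  # betas do not move the equilibrium
  expect_equal(dth[, 1], c(0, 0), ignore_attr = TRUE)
  expect_equal(dth[, 2], c(0, 0), ignore_attr = TRUE)
})
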