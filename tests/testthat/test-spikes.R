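test_that("zero rate yields no spikes and constant-rate counts are Poisson", {
  set.seed(1)
  expect_length(sample_spikes(rep(0, 100), 3)$times, 0)
  # constant 20 spikes/s over 3 s: mean and variance both 60
  set.seed(2)
  counts <- vapply(1:2000, function(i)
    length(sample_spikes(rep(20, 50), 3)$times), 0L)
  se_mean <- sqrt(60 / 2000)
  expect_lt(abs(mean(counts) - 60), 3 * se_mean)
  se_var <- sqrt(2 * 60^2 / 1999)   # approximate SE of a Poisson variance
  expect_lt(abs(var(counts) - 60), 3 * se_var)
})

test_that("time-rescaled intervals of a modulated rate are unit exponential", {
  T <- 3
  tt <- seq(0, T, length.out = 1501)
  r <- 30 + 25 * sin(2 * pi * 2 * tt)
  Lambda <- function(t) 30 * t + 25 * (1 - cos(2 * pi * 2 * t)) / (2 * pi * 2)
  ok <- vapply(1:20, function(sd) {
    # rescale each train separately and pool the intervals
    iv <- unlist(lapply(1:8, function(i) {
      set.seed(4000 + 20 * sd + i)
      s <- sample_spikes(r, T)$times
      if (length(s) < 2) return(numeric(0))
      diff(Lambda(s))
    }))
    suppressWarnings(stats::ks.test(iv, "pexp", 1)$p.value) > 0.01
  }, TRUE)
  expect_gte(sum(ok), 18)
})

test_that("likelihood of a weightless network matches the closed form", {
  # all weights zero: the state stays at its equilibrium (0,0) and the rate
  # is the constant g_e(0), so l = -rT + K ln r exactly
  p0 <- network_params(50, 25, 0, 0, 0, 0, 0, 0)
  r0 <- gain(0, p0$gain_e)
  st <- fourier_stimulus(rep(0, 5), rep(0, 5))
  spk <- spike_train(c(0.3, 1.1, 2.2, 2.9), 3)
  d <- ei_dataset(list(st), list(spk))
  expect_equal(log_likelihood(d, p0, dt = fast_dt),
               -r0 * 3 + 4 * log(r0), tolerance = 1e-10)
  # empty train: just the negative rate integral
  d0 <- ei_dataset(list(st), list(spike_train(numeric(0), 3)))
  expect_equal(log_likelihood(d0, p0, dt = fast_dt), -r0 * 3,
               tolerance = 1e-10)
})

test_that("likelihood is additive over partitions and doubles when doubled", {
  d <- make_dataset(4, seed = 41)
  p <- true_params()
  ll <- log_likelihood(d, p, dt = fast_dt)
  ll1 <- log_likelihood(d[1:2, ], p, dt = fast_dt)
  ll2 <- log_likelihood(d[3:4, ], p, dt = fast_dt)
  expect_equal(ll, ll1 + ll2, tolerance = 1e-12)
  doubled <- ei_dataset(c(d$stimulus, d$stimulus), c(d$spikes, d$spikes))
  expect_equal(log_likelihood(doubled, p, dt = fast_dt), 2 * ll,
               tolerance = 1e-12)
})

test_that("compiled whole-dataset likelihood equals the per-pair reference", {
  d <- make_dataset(3, seed = 43)
  p <- random_params()
  ref <- sum(vapply(1:3, function(i)
    eidesign:::pair_loglik(p, d$stimulus[[i]], d$spikes[[i]], fast_dt)$ll, 0))
  expect_equal(log_likelihood(d, p, dt = fast_dt), ref, tolerance = 1e-10)
  gref <- rowSums(vapply(1:3, function(i)
    eidesign:::pair_loglik(p, d$stimulus[[i]], d$spikes[[i]], fast_dt,
                           gradient = TRUE)$grad, numeric(8)))
  expect_equal(unname(log_likelihood_gradient(d, p, dt = fast_dt)),
               unname(gref), tolerance = 1e-9)
})

test_that("analytic likelihood gradient matches finite differences", {
  d <- make_dataset(3, seed = 47)
  set.seed(48)
  p <- random_params()
  th <- as_theta(p)
  g <- log_likelihood_gradient(d, p, dt = fast_dt)
  for (k in 1:8) {
    dd <- 1e-5 * max(th[k], 1)
    fd <- central_fd(function(t2)
      log_likelihood(d, theta_to_params(t2), dt = fast_dt), th, k, dd)
    expect_lt(abs(g[k] - fd) / max(abs(fd), 1e-8), 1e-3)
  }
  # silent stimuli: input-weight gradient components vanish exactly
  silent <- fourier_stimulus(rep(0, 5), rep(0, 5))
  spk <- lapply(1:2, function(i) spike_train(c(0.5, 1.5), 3))
  dsil <- ei_dataset(list(silent, silent), spk)
  gs <- log_likelihood_gradient(dsil, true_params(), dt = fast_dt)
  expect_equal(unname(gs["w_e"]), 0)
  expect_equal(unname(gs["w_i"]), 0)
})

test_that("likelihood peaks near the generating beta_e in a 1-D sweep", {
  hits <- vapply(1:10, function(sd) {
    d <- make_dataset(40, seed = 600 + sd)
    lls <- vapply(c(40, 45, 50, 55, 60), function(b) {
      p <- network_params(b, 25, 1, 0.7, 1.2, 2, 0.7, 0.4)
      log_likelihood(d, p, dt = fast_dt)
    }, 0)
    which.max(lls) == 3
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("datasets round-trip through JSON-lines", {
  d <- make_dataset(3, seed = 51)
  path <- tempfile(fileext = ".jsonl")
  write_dataset_jsonl(d, path)
  back <- read_dataset_jsonl(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$stimulus[[2]]$A, d$stimulus[[2]]$A)
  expect_equal(back$spikes[[3]]$times, d$spikes[[3]]$times)
  p <- true_params()
  expect_equal(log_likelihood(back, p, dt = fast_dt),
               log_likelihood(d, p, dt = fast_dt))
})
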