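test_that("no input and no adaptation leaves the membrane at rest", {
  p <- neuron_params(a = 0, b = 0, Delta_T = 0)
  inp <- uncorrelated_input(J_e = 0, J_i = 0)
  cfg <- sim_config(duration = 500, burn_in = 100, n_repeats = 1, seed = 1,
                    record_traces = TRUE)
  sim <- simulate_uncorrelated(p, inp, cfg)
  expect_identical(length(sim$spike_times[[1]]), 0L)
  expect_equal(sim$rate_estimate, 0)
  expect_true(all(abs(sim$traces[[1]]$V - p$E_L) < 1e-12))
})

test_that("a fixed seed gives bit-identical results; spike times increase", {
  p <- default_neuron()
  inp <- default_input()
  cfg <- sim_config(duration = 12000, burn_in = 2000, n_repeats = 2, seed = 7)
  s1 <- simulate_uncorrelated(p, inp, cfg)
  s2 <- simulate_uncorrelated(p, inp, cfg)
  expect_identical(s1$spike_times, s2$spike_times)
  expect_identical(s1$rate_estimate, s2$rate_estimate)
  for (st in s1$spike_times) expect_true(all(diff(st) > 0))
  cfg$seed <- 8
  s3 <- simulate_uncorrelated(p, inp, cfg)
  expect_false(identical(s1$spike_times, s3$spike_times))
})

test_that("spike-based adaptation lengthens interspike intervals", {
  # deterministic drive: constant current, no synaptic input, strong b
  p <- neuron_params(a = 0, b = 0.3, tau_w = 200)
  inp <- uncorrelated_input(J_e = 0, J_i = 0, r_e = 0, r_i = 0)
  cfg <- sim_config(duration = 2000, burn_in = 0, n_repeats = 1, seed = 1)
  sim <- simulate_uncorrelated(p, inp, cfg, I_const = 3)
  isi <- diff(sim$spike_times[[1]])
  expect_gt(length(isi), 3)
  # monotone non-decreasing up to the time-bin quantization of spike times
  expect_true(all(diff(isi) >= -cfg$dt - 1e-9))
  expect_gt(isi[length(isi)], 1.5 * isi[1])
})

test_that("arrival aliasing is rejected", {
  p <- default_neuron()
  expect_error(simulate_uncorrelated(p, uncorrelated_input(r_e = 200),
                                     sim_config(dt = 0.1, duration = 100,
                                                burn_in = 10, n_repeats = 1)),
               "aliasing|dt")
})

test_that("Welch estimator: white-noise PSD level, Parseval, filter identity", {
  set.seed(5)
  dt <- 0.1
  D <- 0.25
  n <- 2^18
  x <- rnorm(n, sd = sqrt(2 * D / dt))
  ps <- estimate_csd(x, x, dt, segment_len = 2^12)
  expect_true(all(abs(Im(ps$csd)) < 1e-12))
  expect_equal(mean(Re(ps$csd)), 2 * D, tolerance = 0.02)
  # Parseval: two-sided integral of the PSD recovers the variance
  df <- ps$f[2] - ps$f[1]
  L <- 2 * (nrow(ps) - 1)
  two_sided <- (2 * sum(Re(ps$csd)) - Re(ps$csd[1]) - Re(ps$csd[nrow(ps)])) * df
  expect_equal(two_sided, var(x), tolerance = 0.03)
  # convolution with an exponential kernel: C_xy = K~ C_xx
  tau <- 2
  a1 <- exp(-dt / tau)
  y <- stats::filter(x * dt / tau, a1, method = "recursive")
  cxy <- estimate_csd(x, as.numeric(y), dt, segment_len = 2^12)
  keep <- cxy$f > 0.02 & cxy$f < 1
  Ktheory <- 1 / (1 + 2i * pi * cxy$f[keep] * tau)
  ratio <- cxy$csd[keep] / ps$csd[keep]
  expect_lt(max(Mod(ratio - Ktheory)), 0.05)
  expect_error(estimate_csd(x, x, dt, segment_len = 2^20), "segment")
})

test_that("spike-triggered average of an unrelated input vanishes", {
  set.seed(9)
  u <- rnorm(50000)
  spikes <- sort(runif(300, 60, 4940))
  sta <- estimate_sta(u, spikes, dt = 0.1, window = 20)
  expect_equal(nrow(sta), 401L)
  expect_lt(max(abs(sta$sta)), 5 * 1 / sqrt(300))
  expect_error(estimate_sta(u, numeric(0), dt = 0.1, window = 5), "spikes")
})

test_that("free membrane-adaptation variance matches the matched-variance form", {
  p <- default_neuron()
  inp <- default_input()
  cfg <- sim_config(duration = 35000, n_repeats = 6, seed = 3,
                    record_traces = TRUE)
  sim <- simulate_uncorrelated(p, inp, cfg, free = TRUE)
  v <- vapply(sim$traces, function(tr) var(tr$V[tr$t > cfg$burn_in]),
              numeric(1))
  sem <- sd(v) / sqrt(length(v))
  target <- free_variance_uncorrelated(p, diffusion_uncorrelated(inp))
  expect_lt(abs(mean(v) - target), 3 * sem + 0.01 * target)
  # and clearly distinguishes the quasi-static (adaptation-blind) value
  expect_gt(abs(mean(v) - 20.4375), 10 * sem)
})

test_that("OU-modulated rates have the right stationary moments", {
  p <- default_neuron()
  ci <- correlated_input()
  # free correlated membrane variance agrees with the spectral quadrature
  cfg <- sim_config(dt = 0.025, duration = 25000, n_repeats = 6, seed = 5,
                    record_traces = TRUE)
  sim <- simulate_correlated(p, ci, cfg, free = TRUE)
  v <- vapply(sim$traces, function(tr) var(tr$V[tr$t > cfg$burn_in]),
              numeric(1))
  sem <- sd(v) / sqrt(length(v))
  target <- d_eff_correlated(p, ci) * p$tau_m
  expect_lt(abs(mean(v) - target), 3 * sem + 0.01 * target)
})

test_that("correlated model converges to the uncorrelated one for fast kernels", {
  p <- default_neuron()
  ci <- correlated_input(tau_e = 0.02, tau_ri = 0.01, tau_di = 0.03,
                         tau_nu = 0.05, sigma_nu = 0)
  cfg <- sim_config(dt = 0.005, duration = 30000, n_repeats = 4, seed = 12)
  sc <- simulate_correlated(p, ci, cfg)
  su <- simulate_uncorrelated(p, default_input(),
                              sim_config(dt = 0.005, duration = 30000,
                                         n_repeats = 4, seed = 13))
  pooled <- sqrt(sc$rate_sem^2 + su$rate_sem^2)
  expect_lt(abs(sc$rate_estimate - su$rate_estimate), 4 * pooled)
})

test_that("halving the time step changes the rate by little at the defaults", {
  p <- default_neuron()
  inp <- default_input()
  s1 <- simulate_uncorrelated(p, inp, sim_config(dt = 0.1, n_repeats = 6,
                                                 seed = 30))
  s2 <- simulate_uncorrelated(p, inp, sim_config(dt = 0.05, n_repeats = 6,
                                                 seed = 31))
  pooled <- sqrt(s1$rate_sem^2 + s2$rate_sem^2)
  expect_lt(abs(s1$rate_estimate - s2$rate_estimate), 3 * pooled)
})

test_that("shared-input pair: independence at c = 0, identity at c = 1", {
  p <- default_neuron()
  # no inhibition so that c = 1 makes the two neurons' inputs identical
  inp <- uncorrelated_input(r_i = 0)
  cfg <- sim_config(duration = 20000, burn_in = 2000, n_repeats = 1, seed = 4)
  s_ident <- simulate_shared_pair(p, inp, c = 1, cfg)
  expect_identical(s_ident$spike_times1, s_ident$spike_times2)
  cfg0 <- sim_config(duration = 65000, n_repeats = 6, seed = 5)
  s_indep <- simulate_shared_pair(p, default_input(), c = 0, cfg0)
  xc <- estimate_spike_xcov(s_indep, dt_bin = 2, max_lag = 30)
  # statistically zero: the average |cross-covariance| is at the level
  # expected from pure sampling noise (E|N(0, sem)| ~ 0.8 sem)
  expect_lt(mean(abs(xc$xcov)), 1.6 * mean(xc$sem))
})

test_that("binned spike trains recover the firing rate", {
  s <- c(10.05, 12.4, 13.1, 999.95)
  b <- bin_spike_train(s, dt_bin = 1, burn_in = 0, duration = 1000)
  expect_identical(length(b), 1000L)
  expect_equal(sum(b) * 1, length(s))
  expect_equal(mean(b), length(s) / 1000)
})
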