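test_that("input moments match their closed forms at the defaults", {
  inp <- default_input()
  expect_equal(input_mean(inp), 0.4 * 10 + (-0.75) * 2)   # 2.5 mV*kHz
  expect_equal(input_mean(uncorrelated_input(r_e = 0, r_i = 0)), 0)
  # balanced excitation/inhibition
  expect_equal(input_mean(uncorrelated_input(J_e = 0.3, r_e = 5,
                                             J_i = -0.5, r_i = 3)), 0)
  expect_equal(diffusion_uncorrelated(inp), (0.16 * 10 + 0.5625 * 2) / 2)
  expect_equal(diffusion_uncorrelated(uncorrelated_input(J_e = 0, J_i = 0)), 0)
})

test_that("weight scaling at fixed mean input scales the diffusion linearly", {
  base <- default_input()
  for (cc in c(0.5, 2, 4)) {
    inp <- uncorrelated_input(J_e = cc * base$J_e, J_i = cc * base$J_i,
                              r_e = base$r_e / cc, r_i = base$r_i / cc)
    expect_equal(input_mean(inp), input_mean(base), tolerance = 1e-12)
    expect_equal(diffusion_uncorrelated(inp), cc * diffusion_uncorrelated(base),
                 tolerance = 1e-12)
  }
})

test_that("matched-variance factor has the right limits, value and monotonicity", {
  expect_equal(matched_variance_factor(neuron_params(a = 0)), 1)
  expect_equal(matched_variance_factor(neuron_params(tau_w = 1e12)), 1,
               tolerance = 1e-9)
  # defaults: 1 - (0.15/(0.15 + 1/15)) * (15/65)
  expect_equal(matched_variance_factor(default_neuron()),
               1 - (0.15 / (0.15 + 1 / 15)) * (15 / 65), tolerance = 1e-12)
  expect_equal(matched_variance_factor(default_neuron()), 0.8402367,
               tolerance = 1e-6)
  # strictly decreasing in a, strictly increasing in tau_w
  a_grid <- seq(0, 0.5, by = 0.05)
  f_a <- vapply(a_grid, function(a) matched_variance_factor(neuron_params(a = a)),
                numeric(1))
  expect_true(all(diff(f_a) < 0))
  tw_grid <- c(5, 10, 25, 50, 100, 400)
  f_tw <- vapply(tw_grid, function(tw)
    matched_variance_factor(neuron_params(tau_w = tw)), numeric(1))
  expect_true(all(diff(f_tw) > 0))
  expect_true(all(f_a > 0 & f_a <= 1))
})

test_that("free membrane potential variance with and without adaptation", {
  p <- default_neuron()
  D_I <- diffusion_uncorrelated(default_input())
  expect_equal(free_variance_uncorrelated(p, D_I, with_adaptation = FALSE),
               1.3625 * 15)                                     # 20.4375 mV^2
  expect_equal(free_variance_uncorrelated(p, D_I, with_adaptation = TRUE),
               20.4375 * matched_variance_factor(p))            # ~17.17 mV^2
  p0 <- neuron_params(a = 0)
  expect_equal(free_variance_uncorrelated(p0, D_I, TRUE),
               free_variance_uncorrelated(p0, D_I, FALSE))
})

test_that("correlated-input power spectral density has the printed form", {
  inp <- correlated_input()
  f <- seq(-3, 3, by = 0.05)
  S <- input_psd_correlated(f, inp)
  expect_true(all(S >= 0))
  expect_equal(S, rev(S))                              # even in f
  expect_lt(input_psd_correlated(500, inp),
            1e-6 * input_psd_correlated(0, inp))       # low-pass rolloff
  # zero-frequency value by direct substitution
  Cnn0 <- 2 * inp$sigma_nu^2 * inp$tau_nu
  expect_equal(input_psd_correlated(0, inp),
               inp$J_e^2 * (inp$r_e + Cnn0) + inp$J_i^2 * (inp$r_i + Cnn0),
               tolerance = 1e-12)
  # white-noise limit: no rate fluctuations, vanishing kernels -> 2 D_I
  wn <- correlated_input(tau_e = 1e-6, tau_ri = 1e-6, tau_di = 2e-6,
                         tau_nu = 1e-6, sigma_nu = 0)
  expect_equal(input_psd_correlated(0.5, wn),
               2 * diffusion_uncorrelated(default_input()), tolerance = 1e-4)
})

test_that("effective diffusion for correlated input has the uncorrelated limits", {
  p <- default_neuron()
  D_I <- diffusion_uncorrelated(default_input())
  tiny <- correlated_input(tau_e = 4e-3, tau_ri = 1e-3, tau_di = 6e-3,
                           tau_nu = 1e-2)
  # vanishing timescales, no voltage adaptation -> D_I
  p0 <- neuron_params(a = 0)
  expect_equal(d_eff_correlated(p0, tiny), D_I, tolerance = 0.01)
  # vanishing timescales with adaptation -> D_I * matched-variance factor
  expect_equal(d_eff_correlated(p, tiny), D_I * matched_variance_factor(p),
               tolerance = 0.01)
  # temporal correlations can only reduce the variance transferred: D_eff <= D_I
  expect_lt(d_eff_correlated(p, correlated_input()), D_I)
  expect_gt(d_eff_correlated(p, correlated_input()), 0)
})

test_that("diffusion specs pick the advertised coefficient", {
  p <- default_neuron()
  inp <- default_input()
  qs <- diffusion_spec(p, inp, "quasi_static")
  mv <- diffusion_spec(p, inp, "matched_variance")
  expect_equal(qs$D, diffusion_uncorrelated(inp))
  expect_equal(mv$D, diffusion_uncorrelated(inp) * matched_variance_factor(p))
  expect_equal(qs$mu_I, 2.5)
  # white-noise probe adds to the coefficient
  expect_equal(diffusion_spec(p, inp, "quasi_static", D_extra = 0.1)$D,
               qs$D + 0.1)
})

test_that("self-consistent solve satisfies the adaptation fixed-point relation", {
  p <- default_neuron()
  inp <- default_input()
  fp <- solve_self_consistent(p, diffusion_spec(p, inp), mesh = test_mesh(p))
  expect_true(fp$converged)
  # mu_w = a (mu_V - E_L) + tau_w b r0 at the fixed point
  expect_lt(abs(fp$mu_w - (p$a * (fp$mu_V - p$E_L) + p$tau_w * p$b * fp$r0)),
            1e-4)
  expect_gt(fp$r0, 0)
  # no adaptation: fixed point reached immediately with mu_w = 0
  p0 <- neuron_params(a = 0, b = 0)
  fp0 <- solve_self_consistent(p0, diffusion_spec(p0, inp),
                               mesh = test_mesh(p0))
  expect_identical(fp0$iterations, 1L)
  expect_identical(fp0$mu_w, 0)
  # and equals the plain (non-adaptive) steady-state rate
  ss <- steady_state(p0, 0, 2.5, diffusion_uncorrelated(inp), test_mesh(p0))
  expect_equal(fp0$r0, ss$r0, tolerance = 1e-12)
})

test_that("strong voltage adaptation still converges (damped iteration)", {
  p <- neuron_params(a = 0.3, tau_w = 25)
  fp <- solve_self_consistent(p, diffusion_spec(p, default_input()),
                              mesh = test_mesh(p))
  expect_true(fp$converged)
  expect_lt(abs(fp$mu_w - (p$a * (fp$mu_V - p$E_L) + p$tau_w * p$b * fp$r0)),
            1e-4)
})
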