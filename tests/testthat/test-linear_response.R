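# A converged matched-variance base state at the defaults, shared by the
# susceptibility tests (solver work dominates, so compute it once).
lr_base <- local({
  p <- default_neuron()
  inp <- default_input()
  base <- solve_self_consistent(p, diffusion_spec(p, inp))
  list(p = p, inp = inp, base = base)
})

test_that("zero-frequency susceptibility equals the rate-vs-input derivative", {
  p <- lr_base$p
  S0 <- susceptibility_zero(lr_base$base, p)
  Slow <- susceptibility_at(1e-5, lr_base$base, p)
  expect_lt(abs(Re(Slow) - S0) / abs(S0), 0.01)
  expect_lt(abs(Im(Slow)) / abs(S0), 0.01)
  # without adaptation the agreement is essentially exact
  p0 <- neuron_params(a = 0, b = 0)
  b0 <- solve_self_consistent(p0, diffusion_spec(p0, lr_base$inp),
                              mesh = test_mesh(p0))
  expect_lt(abs(Re(susceptibility_at(1e-5, b0, p0)) -
                susceptibility_zero(b0, p0)) / susceptibility_zero(b0, p0),
            1e-3)
})

test_that("adaptation produces a low-frequency resonance; none without it", {
  p <- lr_base$p
  f <- c(1e-4, 0.003, 0.008, 0.013, 0.02, 0.05, 0.2, 0.5, 1, 2)
  S <- susceptibility_at(f, lr_base$base, p)
  i_peak <- which.max(Mod(S))
  expect_gt(f[i_peak], 1e-4)     # peak strictly above zero frequency
  expect_lt(f[i_peak], 0.05)     # and in the low-frequency range
  # a pronounced peak relative to the zero-frequency response
  expect_gt(max(Mod(S)) / Mod(S[1]), 1.2)
  # monotone rolloff beyond the resonance
  expect_true(all(diff(Mod(S)[i_peak:length(S)]) < 0))
  # no adaptation: the low-frequency band is flat (any resonance sits near
  # the firing rate, far above the adaptation band probed here)
  p0 <- neuron_params(a = 0, b = 0)
  b0 <- solve_self_consistent(p0, diffusion_spec(p0, lr_base$inp),
                              mesh = test_mesh(p0))
  flow <- f[f <= 0.02]
  S0 <- susceptibility_at(flow, b0, p0)
  expect_lt(max(Mod(S0)) / Mod(S0[1]), 1.1)
})

test_that("30-point coarse curve reproduces direct evaluation within 1%", {
  curve <- susceptibility_curve(lr_base$base, lr_base$p)
  expect_identical(length(curve$f_coarse), 31L)   # 30 log points + f = 0
  expect_identical(length(curve$f), 20001L)
  expect_equal(curve$f[2] - curve$f[1], 1e-4)
  idx <- seq(2, length(curve$f), by = 400)
  Sdir <- susceptibility_at(curve$f[idx], lr_base$base, lr_base$p)
  expect_lt(max(Mod(curve$S[idx] - Sdir) / Mod(Sdir)), 0.01)
})

test_that("susceptibility at coarse nodes is reproduced exactly by the curve", {
  curve <- susceptibility_curve(lr_base$base, lr_base$p)
  i <- c(5, 15, 25)
  expect_equal(curve$S_coarse[i + 1],
               susceptibility_at(curve$f_coarse[i + 1], lr_base$base, lr_base$p),
               tolerance = 1e-10)
})

test_that("spike-triggered average: scaling, reality and route identity", {
  curve <- susceptibility_curve(lr_base$base, lr_base$p)
  sta0 <- sta_from_susceptibility(curve, D_n = 0)
  expect_true(all(sta0$sta == 0))
  sta <- sta_from_susceptibility(curve, D_n = 0.1, max_lag = 80)
  expect_true(all(abs(sta$lag) <= 80))
  expect_true(is.numeric(sta$sta))
  # doubling D_n doubles the STA
  sta2 <- sta_from_susceptibility(curve, D_n = 0.2, max_lag = 80)
  expect_equal(sta2$sta, 2 * sta$sta, tolerance = 1e-12)
  # vanishes at the window edges
  edge <- abs(sta$lag) > 70
  expect_lt(max(abs(sta$sta[edge])), 0.02 * max(abs(sta$sta)))
  # identity: STA(tau) = C_us(-tau) / r0 with C_us = 2 D_n S_r
  ht <- adexfp:::hermitian_ifft(Conj(2 * 0.1 * curve$S), curve$df)
  sta_alt <- ht$value / lr_base$base$r0
  keep <- abs(ht$lag) <= 80
  expect_equal(sta$sta, sta_alt[keep], tolerance = 1e-12)
  # the input precedes its effect: mass of the STA sits at negative lags
  expect_gt(sum(sta$sta[sta$lag < 0]), 10 * abs(sum(sta$sta[sta$lag > 1])))
})

test_that("pair cross-spectrum: linearity in c, symmetry, positivity", {
  curve <- susceptibility_curve(lr_base$base, lr_base$p)
  inp <- lr_base$inp
  pc0 <- pair_cross_spectrum(curve, 0, inp)
  expect_true(all(pc0$csd == 0))
  expect_true(all(abs(pc0$xcov) < 1e-300))
  pc1 <- pair_cross_spectrum(curve, 0.1, inp, max_lag = 60)
  pc2 <- pair_cross_spectrum(curve, 0.2, inp, max_lag = 60)
  expect_equal(pc2$csd, 2 * pc1$csd, tolerance = 1e-12)
  expect_true(all(pc1$csd >= 0))
  # identical neurons: cross-covariance is even in the lag
  expect_equal(pc1$xcov, rev(pc1$xcov), tolerance = 1e-10 * max(abs(pc1$xcov)))
  expect_gt(pc1$xcov[pc1$lag == 0], 0)
})

test_that("modulation solve rejects a non-positive frequency", {
  expect_error(susceptibility_at(0, lr_base$base, lr_base$p), "omega")
})
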