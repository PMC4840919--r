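#' Mean synaptic input current
#'
#' `mu_I = J_e*r_e + J_i*r_i`, the mean input bias per capacitance.
#'
#' @param inp an input model object ([uncorrelated_input()] or
#'   [correlated_input()]; both have the same mean).
#' @return Mean input, mV*kHz.
#' @export
input_mean <- function(inp) inp$J_e * inp$r_e + inp$J_i * inp$r_i

#' Diffusion coefficient of the temporally uncorrelated input model
#'
#' `D_I = (J_e^2*r_e + J_i^2*r_i)/2`, matching the first two infinitesimal
#' moments of the shot-noise input.
#'
#' @inheritParams input_mean
#' @return Diffusion coefficient, mV^2*kHz.
#' @export
diffusion_uncorrelated <- function(inp) (inp$J_e^2 * inp$r_e + inp$J_i^2 * inp$r_i) / 2

#' Matched-variance correction factor for sub-threshold adaptation
#'
#' The dimensionless factor
#' `1 - (a/(a + g_L)) * (tau_m/(tau_m + tau_w))` (with `g_L = 1/tau_m`) by
#' which the diffusion coefficient is rescaled so that the reduced
#' one-dimensional model reproduces the free membrane potential variance of
#' the coupled membrane-adaptation system.  Equals 1 when `a = 0` (no
#' voltage-based adaptation) or `tau_w -> Inf`.
#'
#' @param p an [neuron_params()] object.
#' @return Factor in (0, 1].
#' @export
matched_variance_factor <- function(p) {
  gL <- 1 / p$tau_m
  1 - (p$a / (p$a + gL)) * (p$tau_m / (p$tau_m + p$tau_w))
}

#' Free membrane potential variance, uncorrelated input
#'
#' Steady-state variance of the free (non-spiking) membrane potential:
#' `D_I * tau_m` for the quasi-static reduction (an Ornstein-Uhlenbeck
#' process, independent of adaptation), or `D_I * tau_m *
#' matched_variance_factor(p)` when the coupling to the sub-threshold
#' adaptation current is accounted for.
#'
#' @inheritParams matched_variance_factor
#' @param D_I diffusion coefficient, mV^2*kHz.
#' @param with_adaptation if `TRUE`, include the sub-threshold adaptation
#'   correction.
#' @return Variance, mV^2.
#' @export
free_variance_uncorrelated <- function(p, D_I, with_adaptation = TRUE) {
  stopifnot(D_I >= 0)
  D_I * p$tau_m * if (with_adaptation) matched_variance_factor(p) else 1
}

#' Power spectral density of the temporally correlated synaptic input
#'
#' `C_II(f) = J_e^2*[r_e + C_nn(f)]*ae(f) + J_i^2*[r_i + C_nn(f)]*ai(f)`
#' where `ae(f) = 1/(1 + 4 pi^2 tau_e^2 f^2)` and
#' `ai(f) = 1/((1 + 4 pi^2 tau_ri^2 f^2)(1 + 4 pi^2 tau_di^2 f^2))` are the
#' squared magnitudes of the unit-area synaptic kernels' Fourier transforms
#' and `C_nn(f) = 2 sigma_nu^2 tau_nu / (1 + 4 pi^2 tau_nu^2 f^2)` is the
#' power spectral density of the Ornstein-Uhlenbeck rate fluctuations.
#'
#' @param f frequency (kHz); vectorized.
#' @param inp a [correlated_input()] object.
#' @return Two-sided power spectral density, mV^2*kHz / kHz (i.e. mV^2*ms);
#'   real, nonnegative and even in `f`.
#' @export
input_psd_correlated <- function(f, inp) {
  w2 <- 4 * pi^2 * f^2
  Cnn <- 2 * inp$sigma_nu^2 * inp$tau_nu / (1 + inp$tau_nu^2 * w2)
  ae <- 1 / (1 + inp$tau_e^2 * w2)
  ai <- 1 / ((1 + inp$tau_ri^2 * w2) * (1 + inp$tau_di^2 * w2))
  inp$J_e^2 * (inp$r_e + Cnn) * ae + inp$J_i^2 * (inp$r_i + Cnn) * ai
}

# squared magnitude of the effective free-membrane filter
# K_eff = K_v / (1 + a K_v K_w), K_v = tau_m/(1 + 2 pi i f tau_m),
# K_w = 1/(1 + 2 pi i f tau_w)  (C_m = 1 units)
keff_sq <- function(f, p) {
  Kv <- p$tau_m / (1 + 2i * pi * f * p$tau_m)
  Kw <- 1 / (1 + 2i * pi * f * p$tau_w)
  Mod(Kv / (1 + p$a * Kv * Kw))^2
}

#' Matched-variance diffusion coefficient for temporally correlated input
#'
#' `D_eff = (1/tau_m) * Integral C_II(f) |K_eff(f)|^2 df` over all
#' frequencies, where `K_eff` is the transfer function from input current to
#' free membrane potential with the sub-threshold adaptation loop closed.
#' Computed by adaptive quadrature on `[0, Inf)` doubled by evenness.  In
#' the limit of vanishing input timescales this converges to
#' `diffusion_uncorrelated(inp) * matched_variance_factor(p)`.
#'
#' @inheritParams matched_variance_factor
#' @param inp a [correlated_input()] object.
#' @param rel.tol quadrature relative tolerance.
#' @return Effective diffusion coefficient, mV^2*kHz.
#' @export
d_eff_correlated <- function(p, inp, rel.tol = 1e-9) {
  q <- integrate(function(f) input_psd_correlated(f, inp) * keff_sq(f, p),
                 0, Inf, rel.tol = rel.tol, abs.tol = 0, stop.on.error = FALSE)
  if (!q$message %in% "OK")
    stop(sprintf("quadrature for D_eff did not converge (achieved abs error %g): %s",
                 q$abs.error, q$message))
  2 * q$value / p$tau_m
}

#' Diffusion specification for the reduced one-dimensional model
#'
#' Packages the mean input `mu_I` and the diffusion coefficient used by the
#' Fokker-Planck solver: `D_I` for the quasi-static approximation or the
#' matched-variance `D_eff` (sub-threshold-adaptation correction for the
#' uncorrelated model; full spectral quadrature for the correlated model).
#'
#' @inheritParams matched_variance_factor
#' @param inp an input model object.
#' @param method `"matched_variance"` or `"quasi_static"`.
#' @param D_extra intensity of an additional independent white-noise current
#'   (mV^2*kHz), added to the diffusion coefficient.  Use this when the
#'   neuron is probed with a weak noise current (e.g. for spike-triggered
#'   averages): even a weak probe shifts the operating point, and the base
#'   state must include it.
#' @return An object of class `adex_diffusion_spec` with fields `mu_I`, `D`,
#'   `method`, `input_model`.
#' @export
diffusion_spec <- function(p, inp, method = c("matched_variance", "quasi_static"),
                           D_extra = 0) {
  method <- match.arg(method)
  stopifnot(D_extra >= 0)
  correlated <- inherits(inp, "adex_input_correlated")
  D_I <- diffusion_uncorrelated(inp)
  D <- if (method == "quasi_static") {
    D_I
  } else if (correlated) {
    d_eff_correlated(p, inp)
  } else {
    D_I * matched_variance_factor(p)
  }
  D <- D + D_extra
  structure(list(mu_I = input_mean(inp), D = D, method = method,
                 input_model = if (correlated) "correlated" else "uncorrelated",
                 input = inp),
            class = c("adex_diffusion_spec", "list"))
}

#' Self-consistent steady state of the adaptive neuron
#'
#' Couples the one-dimensional Fokker-Planck steady state to the mean
#' adaptation current by damped fixed-point iteration: given `mu_w`, solve
#' for `(r0, mu_V)` with [steady_state()], then relax
#' `mu_w <- (1 - lambda)*mu_w + lambda*(a*(mu_V - E_L) + tau_w*b*r0)` until
#' the rate changes by less than `tol` between iterations.  With
#' `a = b = 0` the fixed point is reached in one iteration (`mu_w = 0`).
#'
#' @inheritParams matched_variance_factor
#' @param spec a [diffusion_spec()] object (choice of `mu_I` and `D`).
#' @param mesh an [build_mesh()] object; built with defaults if `NULL`.
#' @param scheme integration scheme passed to [steady_state()].
#' @param lambda relaxation factor in (0, 1], or `NULL` (default) for the
#'   automatic choice `min(0.5, 1/(1 + a*tau_m))`.  The fixed-point map has
#'   loop gain close to `a*tau_m` (the voltage-adaptation feedback through
#'   the mean membrane potential), so undamped or half-damped iteration
#'   diverges when `a*tau_m` exceeds 1; the automatic damping keeps the
#'   damped map contractive for all adaptation strengths.
#' @param tol convergence tolerance on `|delta r0|`, kHz.
#' @param max_iter maximum number of iterations; if exceeded, the best
#'   iterate is returned with `converged = FALSE`.
#' @param mu_w0 initial mean adaptation current, mV*kHz.
#' @return An object of class `adex_fixed_point`: `r0` (kHz), `mu_V` (mV),
#'   `mu_w` (mV*kHz), `iterations`, `converged`, `density` (the final
#'   [steady_state()] object), `spec`, and the residual of the adaptation
#'   fixed-point relation.
#' @examples
#' p <- neuron_params()
#' spec <- diffusion_spec(p, uncorrelated_input())
#' fp <- solve_self_consistent(p, spec, mesh = build_mesh(p, dv = 0.05))
#' fp$r0 * 1000  # Hz
#' @export
solve_self_consistent <- function(p, spec, mesh = NULL,
                                  scheme = "simpson", lambda = NULL,
                                  tol = 1e-6, max_iter = 100, mu_w0 = 0) {
  if (is.null(mesh)) mesh <- build_mesh(p)
  if (is.null(lambda)) lambda <- min(0.5, 1 / (1 + p$a * p$tau_m))
  mu_w <- mu_w0
  r0_prev <- Inf
  ss <- NULL
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    ss <- steady_state(p, mu_w, spec$mu_I, spec$D, mesh, scheme)
    target <- p$a * (ss$mu_V - p$E_L) + p$tau_w * p$b * ss$r0
    if (abs(ss$r0 - r0_prev) < tol && abs(mu_w - target) < 1e-5) {
      converged <- TRUE
      break
    }
    r0_prev <- ss$r0
    if (p$a == 0 && p$b == 0) {  # no adaptation: fixed point is immediate
      mu_w <- 0
      converged <- TRUE
      break
    }
    mu_w <- (1 - lambda) * mu_w + lambda * target
  }
  residual <- abs(mu_w - (p$a * (ss$mu_V - p$E_L) + p$tau_w * p$b * ss$r0))
  if (!converged)
    warning("fixed-point iteration did not converge within max_iter; ",
            "returning the best iterate")
  structure(list(r0 = ss$r0, mu_V = ss$mu_V, mu_w = mu_w,
                 iterations = iter, converged = converged, residual = residual,
                 density = ss, spec = spec, mesh = mesh, scheme = scheme),
            class = c("adex_fixed_point", "list"))
}

#' @export
print.adex_fixed_point <- function(x, ...) {
  cat(sprintf("Self-consistent steady state (%s, %s input):\n",
              x$spec$method, x$spec$input_model))
  cat(sprintf("  r0 = %.4f Hz, mu_V = %.3f mV, mu_w = %.5f mV*kHz\n",
              1000 * x$r0, x$mu_V, x$mu_w))
  cat(sprintf("  %d iterations, converged = %s, residual = %.2e\n",
              x$iterations, x$converged, x$residual))
  invisible(x)
}
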