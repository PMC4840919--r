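#' adexfp: diffusion approximations and Fokker-Planck methods for AdEx neurons
#'
#' Steady-state and linear-response statistics of the adaptive exponential
#' integrate-and-fire (AdEx) neuron driven by stochastic synaptic input.
#' The package couples matched-variance and quasi-static diffusion
#' approximations to a threshold-integration Fokker-Planck solver, and
#' validates every approximation against a compiled forward-Euler Monte Carlo
#' simulator of the exact two-dimensional model.
#'
#' Unit convention: all currents are expressed per membrane capacitance, so
#' C_m = 1 and g_L = 1/tau_m.  Voltages are in mV, times in ms, rates in kHz,
#' currents in mV*kHz and diffusion coefficients in mV^2*kHz.
#'
#' @useDynLib adexfp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft integrate pnorm approx rnorm rpois runif sd splinefun var
#' @importFrom utils modifyList read.csv write.csv
#' @keywords internal
"_PACKAGE"

#' Membrane and adaptation parameters of the AdEx neuron
#'
#' Bundles the constants of the adaptive exponential integrate-and-fire
#' model: a leaky membrane with an exponential spike-initiation term, a
#' linear adaptation current with time constant `tau_w`, voltage coupling
#' `a` and spike increment `b`, and a threshold/reset rule.  All currents
#' are per capacitance (C_m = 1), so `a` is in kHz and `b` in mV*kHz, as in
#' the default parameter table.
#'
#' @param tau_m membrane time constant, ms.
#' @param E_L leak reversal potential, mV.
#' @param Delta_T spike slope factor, mV; `Delta_T = 0` gives the leaky
#'   integrate-and-fire limit.
#' @param V_T soft spike-initiation threshold, mV.
#' @param V_th hard threshold at which a spike is registered, mV.
#' @param V_re reset potential, mV.
#' @param a voltage-based adaptation strength per capacitance, kHz.
#' @param b spike-based adaptation increment per capacitance, mV*kHz.
#' @param tau_w adaptation time constant, ms.
#'
#' @return An object of class `adex_neuron` (named list of the parameters).
#' @examples
#' p <- neuron_params()
#' psi(p$V_T, p)  # = Delta_T / tau_m
#' @export
neuron_params <- function(tau_m = 15, E_L = -72, Delta_T = 1, V_T = -55,
                          V_th = -45, V_re = -72, a = 0.15, b = 0.025,
                          tau_w = 50) {
  p <- list(tau_m = tau_m, E_L = E_L, Delta_T = Delta_T, V_T = V_T,
            V_th = V_th, V_re = V_re, a = a, b = b, tau_w = tau_w)
  stopifnot(tau_m > 0, tau_w > 0, Delta_T >= 0, V_re < V_th, a >= 0, b >= 0)
  class(p) <- c("adex_neuron", "list")
  p
}

#' Temporally uncorrelated synaptic input model
#'
#' Excitatory and inhibitory presynaptic spikes arrive as homogeneous
#' Poisson processes with rates `r_e`, `r_i` and delta-function synaptic
#' currents of weight `J_e` > 0 and `J_i` < 0 (mV per event, per
#' capacitance).
#'
#' @param J_e excitatory synaptic weight, mV (> 0, or 0 degenerate).
#' @param J_i inhibitory synaptic weight, mV (< 0, or 0 degenerate).
#' @param r_e,r_i presynaptic rates, kHz.
#' @return An object of class `adex_input_uncorrelated`.
#' @examples
#' inp <- uncorrelated_input()
#' input_mean(inp)             # 2.5 mV*kHz
#' diffusion_uncorrelated(inp) # 1.3625 mV^2*kHz
#' @export
uncorrelated_input <- function(J_e = 0.4, J_i = -0.75, r_e = 10, r_i = 2) {
  stopifnot(r_e >= 0, r_i >= 0, J_e >= 0, J_i <= 0)
  inp <- list(J_e = J_e, J_i = J_i, r_e = r_e, r_i = r_i)
  class(inp) <- c("adex_input_uncorrelated", "adex_input", "list")
  inp
}

#' Temporally correlated synaptic input model
#'
#' Presynaptic spikes arrive as inhomogeneous Poisson processes whose rates
#' follow Ornstein-Uhlenbeck dynamics (mean `r_x`, standard deviation
#' `sigma_nu`, timescale `tau_nu`), and synaptic currents have unit-area
#' kernels: a single-exponential EPSC with decay `tau_e`, and a
#' difference-of-exponentials IPSC with rise `tau_ri` and decay `tau_di`
#' (AMPA- and GABA_B-like kinetics).
#'
#' @inheritParams uncorrelated_input
#' @param tau_e EPSC decay timescale, ms.
#' @param tau_ri,tau_di IPSC rise and decay timescales, ms (`tau_ri < tau_di`).
#' @param tau_nu timescale of presynaptic rate fluctuations, ms.
#' @param sigma_nu standard deviation of rate fluctuations, kHz.  Should be
#'   small compared to the rates so that negative excursions are rare; a
#'   warning is issued otherwise.
#' @return An object of class `adex_input_correlated`.
#' @export
correlated_input <- function(J_e = 0.4, J_i = -0.75, r_e = 10, r_i = 2,
                             tau_e = 4, tau_ri = 1, tau_di = 6, tau_nu = 10,
                             sigma_nu = 0.1) {
  stopifnot(r_e >= 0, r_i >= 0, J_e >= 0, J_i <= 0,
            tau_e > 0, tau_ri > 0, tau_di > 0, tau_nu > 0,
            tau_ri < tau_di, sigma_nu >= 0)
  rmin <- min(r_e[r_e > 0], r_i[r_i > 0])
  if (length(rmin) && sigma_nu > 0.5 * rmin)
    warning("sigma_nu is not small compared to the presynaptic rates; ",
            "rate excursions below zero will be clipped frequently")
  inp <- list(J_e = J_e, J_i = J_i, r_e = r_e, r_i = r_i, tau_e = tau_e,
              tau_ri = tau_ri, tau_di = tau_di, tau_nu = tau_nu,
              sigma_nu = sigma_nu)
  class(inp) <- c("adex_input_correlated", "adex_input", "list")
  inp
}

#' Default parameter set
#'
#' The default neuron and input parameters used throughout the package:
#' tau_m = 15 ms, E_L = V_re = -72 mV, Delta_T = 1 mV, V_T = -55 mV,
#' V_th = -45 mV, a = 0.15 kHz, b = 0.025 mV*kHz, tau_w = 50 ms,
#' J_e = 0.4 mV, J_i = -0.75 mV, r_e = 10 kHz, r_i = 2 kHz, and synaptic /
#' rate-fluctuation timescales tau_e = 4, tau_ri = 1, tau_di = 6,
#' tau_nu = 10 ms with sigma_nu = 0.1 kHz.
#'
#' @return A list with elements `neuron`, `uncorrelated` and `correlated`.
#' @export
adex_defaults <- function() {
  list(neuron = neuron_params(),
       uncorrelated = uncorrelated_input(),
       correlated = correlated_input())
}

#' Exponential spike-initiation current
#'
#' The spike-generating nonlinearity of the AdEx model, per capacitance:
#' `psi(V) = (Delta_T / tau_m) * exp((V - V_T) / Delta_T)`, or 0 in the LIF
#' limit `Delta_T = 0`.  The exponent is clamped at +50 to guard against
#' overflow when evaluated above threshold during Monte Carlo simulation.
#'
#' @param V membrane potential(s), mV.
#' @param p an [neuron_params()] object.
#' @return Drift contribution, mV/ms (vectorized over `V`).
#' @export
psi <- function(V, p) {
  if (p$Delta_T <= 0) return(rep(0, length(V)))
  z <- pmin((V - p$V_T) / p$Delta_T, 50)
  (p$Delta_T / p$tau_m) * exp(z)
}

#' Total drift of the one-dimensional reduced model
#'
#' `drift(V) = (E_L - V)/tau_m + psi(V) - mu_w + mu_I` -- the deterministic
#' part of the reduced membrane equation in which the adaptation current is
#' replaced by its mean `mu_w` and the synaptic input by its mean `mu_I`.
#'
#' @inheritParams psi
#' @param mu_w mean adaptation current per capacitance, mV*kHz.
#' @param mu_I mean synaptic input per capacitance, mV*kHz.
#' @return Drift, mV/ms (vectorized over `V`).
#' @export
drift <- function(V, p, mu_w = 0, mu_I = 0) {
  (p$E_L - V) / p$tau_m + psi(V, p) - mu_w + mu_I
}

#' Write / read a parameter bundle as flat JSON
#'
#' Parameters are serialized as a flat key-value JSON object with full
#' double precision, so that a round trip reproduces the values bit-exactly.
#'
#' @param params a named list (e.g. from [neuron_params()] or an input
#'   constructor); classes are preserved via a `"_class"` key.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   the restored object.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x[["_class"]] <- class(params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x[["_class"]]
  x[["_class"]] <- NULL
  # JSON has no integer/double distinction; parameters are doubles
  x <- lapply(x, function(v) if (is.integer(v)) as.double(v) else v)
  if (!is.null(cls)) class(x) <- cls
  x
}

#' @export
print.adex_neuron <- function(x, ...) {
  cat("AdEx neuron parameters (C_m = 1 units):\n")
  cat(sprintf("  tau_m = %g ms, E_L = %g mV, Delta_T = %g mV, V_T = %g mV\n",
              x$tau_m, x$E_L, x$Delta_T, x$V_T))
  cat(sprintf("  V_th = %g mV, V_re = %g mV\n", x$V_th, x$V_re))
  cat(sprintf("  a = %g kHz, b = %g mV*kHz, tau_w = %g ms\n",
              x$a, x$b, x$tau_w))
  invisible(x)
}

#' @export
print.adex_input <- function(x, ...) {
  kind <- if (inherits(x, "adex_input_correlated")) "temporally correlated"
          else "temporally uncorrelated"
  cat(sprintf("Synaptic input model (%s):\n", kind))
  cat(sprintf("  J_e = %g mV, J_i = %g mV, r_e = %g kHz, r_i = %g kHz\n",
              x$J_e, x$J_i, x$r_e, x$r_i))
  if (inherits(x, "adex_input_correlated"))
    cat(sprintf("  tau_e = %g, tau_ri = %g, tau_di = %g, tau_nu = %g ms, sigma_nu = %g kHz\n",
                x$tau_e, x$tau_ri, x$tau_di, x$tau_nu, x$sigma_nu))
  invisible(x)
}
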