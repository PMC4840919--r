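mod_arrays <- function(base, p) {
  mesh <- base$mesh
  v <- mesh$v
  vm <- 0.5 * (v[-1] + v[-length(v)])
  vq <- v[-length(v)] + 0.25 * diff(v)
  list(v = v,
       Fn = drift(v, p, base$mu_w, base$spec$mu_I),
       Fm = drift(vm, p, base$mu_w, base$spec$mu_I),
       Fq = drift(vq, p, base$mu_w, base$spec$mu_I),
       P0 = base$density$P,
       i_re = mesh$i_re - 1L,
       D = base$spec$D)
}

#' Susceptibility of the firing rate at one frequency
#'
#' First-order transfer function `S_r(f)` from a weak uniform current
#' modulation to the modulation of the instantaneous firing rate, about a
#' converged self-consistent steady state.  The non-adaptive modulation
#' responses `A_r(f)` (rate) and `A_V(f)` (mean voltage) are computed by
#' threshold integration of the modulated Fokker-Planck system on the base
#' mesh, and the adaptation loop is closed through the linearized mean
#' adaptation dynamics:
#' `w_hat = (a V_hat + tau_w b r_hat) / (1 + 2 pi i f tau_w)`, giving
#' `S_r = A_r / (1 + L)` with
#' `L = (a A_V + tau_w b A_r) / (1 + 2 pi i f tau_w)`.
#'
#' @param f frequency, kHz (must be > 0; use [susceptibility_zero()] for
#'   the zero-frequency limit).
#' @param base a converged [solve_self_consistent()] object.
#' @param p the [neuron_params()] used for `base`.
#' @return Complex susceptibility, kHz per (mV*kHz), i.e. 1/mV.
#' @export
susceptibility_at <- function(f, base, p) {
  if (!base$converged) stop("base steady state is not converged")
  arr <- mod_arrays(base, p)
  out <- vapply(f, function(f1) {
    m <- fp_modulation_cpp(arr$v, arr$Fn, arr$Fm, arr$Fq, arr$P0, arr$D,
                           arr$i_re, 2 * pi * f1)
    A_r <- m$A_r
    A_V <- m$A_V
    L <- (p$a * A_V + p$tau_w * p$b * A_r) / (1 + 2i * pi * f1 * p$tau_w)
    if (Mod(1 + L) < 1e-12)
      stop("singular adaptation loop at f = ", f1, " kHz")
    A_r / (1 + L)
  }, complex(1))
  out
}

#' Zero-frequency susceptibility by finite differences
#'
#' `S_r(0) = d r0 / d mu_I` of the full self-consistent rate (adaptation
#' loop closed), computed by a centered finite difference with the
#' diffusion coefficient held fixed.
#'
#' @inheritParams susceptibility_at
#' @param delta finite-difference step in `mu_I`, mV*kHz.
#' @return Real susceptibility at `f = 0`, 1/mV.
#' @export
susceptibility_zero <- function(base, p, delta = 1e-3) {
  solve_at <- function(dmu) {
    spec <- base$spec
    spec$mu_I <- spec$mu_I + dmu
    # the fixed point must be converged far below the finite-difference
    # signal delta * S0, so the tolerance is much tighter than the default
    solve_self_consistent(p, spec, mesh = base$mesh, scheme = base$scheme,
                          mu_w0 = base$mu_w, tol = 1e-12, max_iter = 400)$r0
  }
  (solve_at(delta) - solve_at(-delta)) / (2 * delta)
}

#' Susceptibility curve on coarse and fine frequency grids
#'
#' Evaluates [susceptibility_at()] on `n_coarse` log-spaced frequencies in
#' `[f_min, f_max]`, prepends the finite-difference zero-frequency value,
#' and interpolates the real and imaginary parts separately by monotone
#' piecewise-cubic Hermite polynomials onto a uniform fine grid
#' (default 0 to 2 kHz in 0.1 Hz steps, 20001 points), suitable for inverse
#' FFT products.  Threshold integration is performed only at the coarse
#' frequencies.
#'
#' @inheritParams susceptibility_at
#' @param n_coarse number of coarse log-spaced frequencies.
#' @param f_min lowest coarse frequency, kHz.
#' @param f_max highest frequency, kHz (coarse grid reaches it, so the fine
#'   grid never extrapolates).
#' @param df fine grid step, kHz.
#' @return An object of class `adex_susceptibility`: `f_coarse`, `S_coarse`
#'   (with the `f = 0` value first), `f`, `S` (interpolated fine grid),
#'   `S0`, and the base solution.
#' @export
susceptibility_curve <- function(base, p, n_coarse = 30, f_min = 1e-5,
                                 f_max = 2, df = 1e-4) {
  stopifnot(f_min > 0, f_max > f_min, df > 0)
  if (df < f_min)
    stop("fine grid step df must not be below the lowest coarse frequency")
  fc <- exp(seq(log(f_min), log(f_max), length.out = n_coarse))
  Sc <- susceptibility_at(fc, base, p)
  S0 <- susceptibility_zero(base, p)
  # interpolate against log f after factoring out the known membrane
  # low-pass rolloff 1/(1 + 2 pi i f tau_m); the residual is flat at both
  # ends of the log grid, which keeps the piecewise-cubic error small on
  # the wide high-frequency intervals
  y <- Sc * (1 + 2i * pi * fc * p$tau_m)
  re <- splinefun(log(fc), Re(y), method = "monoH.FC")
  im <- splinefun(log(fc), Im(y), method = "monoH.FC")
  f <- seq(0, f_max, by = df)
  fp <- f[-1]
  Sp <- complex(real = re(log(fp)), imaginary = im(log(fp))) /
        (1 + 2i * pi * fp * p$tau_m)
  structure(list(f_coarse = c(0, fc), S_coarse = c(complex(real = S0), Sc),
                 f = f, S = c(complex(real = S0), Sp),
                 S0 = S0, df = df, base = base, p = p),
            class = c("adex_susceptibility", "list"))
}

#' @export
print.adex_susceptibility <- function(x, ...) {
  cat(sprintf("Susceptibility curve: %d coarse (log) points interpolated to %d uniform points on [0, %g] kHz\n",
              length(x$f_coarse) - 1L, length(x$f), max(x$f)))
  cat(sprintf("  S(0) = %.5f /mV, peak |S| = %.5f at f = %.4f kHz\n",
              x$S0, max(Mod(x$S)), x$f[which.max(Mod(x$S))]))
  invisible(x)
}

# Hermitian-extend a one-sided spectrum sampled on f = 0, df, ..., f_max and
# inverse-FFT it; returns lags (centred) and the real time-domain values.
hermitian_ifft <- function(S, df) {
  M <- length(S)
  N <- 2L * (M - 1L)
  X <- complex(N)
  X[1] <- complex(real = Re(S[1]))          # zero-frequency bin is real
  X[2:M] <- S[2:M]
  X[M] <- complex(real = Re(S[M]))          # Nyquist bin must be real
  X[(M + 1L):N] <- Conj(S[(M - 1L):2])
  xt <- fft(X, inverse = TRUE) * df
  resid <- max(abs(Im(xt)))
  if (resid > 1e-10 * max(abs(Re(xt)), .Machine$double.eps))
    warning("imaginary residue after Hermitian inverse FFT: ", resid)
  dlag <- 1 / (N * df)
  lag <- seq_len(N) - 1L
  lag[lag >= N / 2] <- lag[lag >= N / 2] - N
  ord <- order(lag)
  list(lag = lag[ord] * dlag, value = Re(xt)[ord])
}

#' Spike-triggered average from the susceptibility
#'
#' For a weak added white-noise current of intensity `D_n`, the
#' input-spike cross-spectral density is `C_us(f) = 2 D_n S_r(f)` and the
#' spike-triggered average is the inverse Fourier transform
#' `STA = (2 D_n / r0) F^{-1}[S_r^*]`, evaluated by Hermitian extension and
#' FFT on the curve's uniform fine grid.
#'
#' @param curve an [susceptibility_curve()] object.
#' @param D_n white-noise intensity, mV^2*kHz.
#' @param r0 base firing rate, kHz (defaults to the curve's base solution).
#' @param max_lag truncate the returned lags to `|lag| <= max_lag` ms
#'   (`Inf` keeps all).
#' @return An object of class `adex_sta`: data.frame fields `lag` (ms) and
#'   `sta` (mV*kHz), plus `D_n` and `r0` attributes.
#' @export
sta_from_susceptibility <- function(curve, D_n, r0 = curve$base$r0,
                                    max_lag = Inf) {
  ht <- hermitian_ifft(Conj(curve$S), curve$df)
  sta <- (2 * D_n / r0) * ht$value
  keep <- abs(ht$lag) <= max_lag
  structure(data.frame(lag = ht$lag[keep], sta = sta[keep]),
            D_n = D_n, r0 = r0, class = c("adex_sta", "data.frame"))
}

#' Shared-input spike-train cross-spectrum and cross-covariance
#'
#' To first order in the shared fraction `c`, two identical neurons whose
#' excitatory presynaptic pools overlap by a fraction `c` have spike-train
#' cross-spectral density `C_s1s2(f) = |S_r(f)|^2 * c * J_e^2 * r_e`
#' (the input cross-spectrum `c J_e^2 r_e` filtered by the squared
#' susceptibility).  The cross-covariance follows by Hermitian inverse FFT.
#'
#' @inheritParams sta_from_susceptibility
#' @param c shared excitatory fraction in `[0, 1]`.
#' @param inp the [uncorrelated_input()] model.
#' @return An object of class `adex_pair_correlation`: `f`, `csd` (kHz,
#'   real nonnegative), `lag` (ms), `xcov` (kHz^2), `shared_fraction`.
#' @export
pair_cross_spectrum <- function(curve, c, inp, max_lag = Inf) {
  stopifnot(c >= 0, c <= 1)
  csd <- Mod(curve$S)^2 * c * inp$J_e^2 * inp$r_e
  ht <- hermitian_ifft(complex(real = csd), curve$df)
  keep <- abs(ht$lag) <= max_lag
  structure(list(f = curve$f, csd = csd,
                 lag = ht$lag[keep], xcov = ht$value[keep],
                 shared_fraction = c),
            class = c("adex_pair_correlation", "list"))
}
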