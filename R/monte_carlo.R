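#' Monte Carlo simulation configuration
#'
#' Forward-Euler protocol settings.  Defaults follow the standard validation
#' protocol: time bin `dt = 0.1` ms, 65 s runs of which the first 5 s are
#' discarded as burn-in, 10 repeats.
#'
#' @param dt time bin, ms.
#' @param duration total simulated time per repeat, ms.
#' @param burn_in initial transient discarded from all statistics, ms.
#' @param n_repeats number of independent repeats; repeat `k` uses seed
#'   `seed + k - 1`.
#' @param seed base RNG seed (integer).
#' @param record_traces record (t, V, w) traces at `dt` resolution.
#' @return An object of class `adex_sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 65000, burn_in = 5000,
                       n_repeats = 10, seed = 1, record_traces = FALSE) {
  stopifnot(dt > 0, burn_in < duration, n_repeats >= 1)
  structure(list(dt = dt, duration = duration, burn_in = burn_in,
                 n_repeats = n_repeats, seed = seed,
                 record_traces = record_traces),
            class = c("adex_sim_config", "list"))
}

check_aliasing <- function(inp, dt) {
  if (dt * max(inp$r_e, inp$r_i) > 10)
    stop("dt * max(r_e, r_i) > 10: Poisson arrival counts per bin are too ",
         "large for a meaningful simulation; decrease dt")
}

run_repeats <- function(cfg, one_run) {
  reps <- vector("list", cfg$n_repeats)
  for (k in seq_len(cfg$n_repeats)) {
    set.seed(cfg$seed + k - 1L)
    reps[[k]] <- one_run()
  }
  reps
}

finish_sim <- function(reps, cfg, extra = list()) {
  rates <- vapply(reps, function(r) r$rate, numeric(1))
  out <- c(list(spike_times = lapply(reps, `[[`, "spike_times"),
                rates = rates,
                rate_estimate = mean(rates),
                rate_sem = if (length(rates) > 1) sd(rates) / sqrt(length(rates)) else NA_real_,
                config = cfg, seed_used = cfg$seed),
           extra)
  if (!is.null(reps[[1]]$V))
    out$traces <- lapply(reps, function(r) data.frame(t = r$t, V = r$V, w = r$w))
  if (!is.null(reps[[1]]$noise))
    out$noise <- lapply(reps, `[[`, "noise")
  class(out) <- c("adex_sim", "list")
  out
}

#' Monte Carlo simulation, temporally uncorrelated input
#'
#' Forward-Euler simulation of the full AdEx model with delta-synapse
#' Poisson input: per bin the number of excitatory (inhibitory) arrivals is
#' Poisson with mean `r_x * dt` and each arrival increments `V` by `J_x`;
#' threshold crossings reset `V` to `V_re` and increment `w` by `b`.
#' Optionally a weak white-noise current of intensity `D_n` is added (for
#' spike-triggered-average validation), a constant bias `I_const`, or the
#' spike/exponential machinery can be disabled (`free = TRUE`) to simulate
#' the free membrane-adaptation system.
#'
#' @param p an [neuron_params()] object.
#' @param inp an [uncorrelated_input()] object.
#' @param cfg a [sim_config()] object.
#' @param D_n intensity of an added white-noise current, mV^2*kHz (0 = none).
#' @param I_const constant bias current, mV*kHz.
#' @param free simulate the free (non-spiking, linear) membrane: the
#'   exponential term and the threshold/reset rule are removed.
#' @param record_noise record the white-noise sample path (needed for
#'   [estimate_sta()]).
#' @return An object of class `adex_sim`: per-repeat `spike_times` (ms,
#'   strictly increasing), per-repeat `rates` and the pooled
#'   `rate_estimate` (kHz, spikes after burn-in over post-burn-in time),
#'   `rate_sem`, optional `traces` / `noise`, and the configuration.
#' @export
simulate_uncorrelated <- function(p, inp, cfg = sim_config(), D_n = 0,
                                  I_const = 0, free = FALSE,
                                  record_noise = FALSE) {
  check_aliasing(inp, cfg$dt)
  reps <- run_repeats(cfg, function()
    sim_adex_cpp(p$tau_m, p$E_L, p$Delta_T, p$V_T, p$V_th, p$V_re, p$a, p$b,
                 p$tau_w, inp$J_e, inp$J_i, inp$r_e, inp$r_i,
                 FALSE, 1, 1, 2, 1, 0,
                 cfg$dt, cfg$duration, cfg$burn_in, I_const, D_n, free,
                 cfg$record_traces, 1L, record_noise))
  finish_sim(reps, cfg)
}

#' Monte Carlo simulation, temporally correlated input
#'
#' As [simulate_uncorrelated()], but presynaptic rates follow an exact
#' per-bin Ornstein-Uhlenbeck update (clipped at zero only when drawing
#' arrivals) and arrivals are filtered through the unit-area EPSC
#' (single-exponential) and IPSC (difference-of-exponentials) kernels.
#'
#' @inheritParams simulate_uncorrelated
#' @param inp a [correlated_input()] object.
#' @export
simulate_correlated <- function(p, inp, cfg = sim_config(), D_n = 0,
                                I_const = 0, free = FALSE,
                                record_noise = FALSE) {
  check_aliasing(inp, cfg$dt)
  reps <- run_repeats(cfg, function()
    sim_adex_cpp(p$tau_m, p$E_L, p$Delta_T, p$V_T, p$V_th, p$V_re, p$a, p$b,
                 p$tau_w, inp$J_e, inp$J_i, inp$r_e, inp$r_i,
                 TRUE, inp$tau_e, inp$tau_ri, inp$tau_di, inp$tau_nu,
                 inp$sigma_nu,
                 cfg$dt, cfg$duration, cfg$burn_in, I_const, D_n, free,
                 cfg$record_traces, 1L, record_noise))
  finish_sim(reps, cfg)
}

#' Monte Carlo simulation of a shared-input neuron pair
#'
#' Two identical AdEx neurons receive partially shared excitatory input: a
#' common Poisson stream of rate `c * r_e` plus independent streams of rate
#' `(1 - c) * r_e` each, and independent inhibitory streams.  Temporally
#' uncorrelated (delta synapse) model.
#'
#' @inheritParams simulate_uncorrelated
#' @param c fraction of shared excitatory presynaptic spikes, in `[0, 1]`.
#' @return An object of class `adex_sim_pair`: per-repeat `spike_times1`,
#'   `spike_times2`, rates for each neuron, and the configuration.
#' @export
simulate_shared_pair <- function(p, inp, c, cfg = sim_config()) {
  stopifnot(c >= 0, c <= 1)
  check_aliasing(inp, cfg$dt)
  reps <- run_repeats(cfg, function()
    sim_adex_pair_cpp(p$tau_m, p$E_L, p$Delta_T, p$V_T, p$V_th, p$V_re, p$a,
                      p$b, p$tau_w, inp$J_e, inp$J_i, inp$r_e, inp$r_i, c,
                      cfg$dt, cfg$duration, cfg$burn_in))
  r1 <- vapply(reps, `[[`, numeric(1), "rate1")
  r2 <- vapply(reps, `[[`, numeric(1), "rate2")
  structure(list(spike_times1 = lapply(reps, `[[`, "spike_times1"),
                 spike_times2 = lapply(reps, `[[`, "spike_times2"),
                 rates1 = r1, rates2 = r2,
                 rate_estimate = mean(c(r1, r2)),
                 shared_fraction = c, config = cfg, seed_used = cfg$seed),
            class = c("adex_sim_pair", "list"))
}

#' @export
print.adex_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo result: %d repeat(s) of %g s (dt = %g ms), rate = %.4f +/- %.4f Hz\n",
              length(x$spike_times), x$config$duration / 1000, x$config$dt,
              1000 * x$rate_estimate,
              if (is.na(x$rate_sem)) NA else 1000 * x$rate_sem))
  invisible(x)
}

#' Welch cross-spectral density estimator
#'
#' Averaged cross-periodogram of two equally long, uniformly sampled series
#' over Hann-windowed segments with 50% overlap, after subtracting the
#' series means.  Normalized so that for a white-noise series of variance
#' `2 D / dt` per sample the (two-sided) power spectral density is flat at
#' `2 D`, and the integral of the PSD over all frequencies recovers the
#' series variance (Parseval).
#'
#' @param x,y numeric series sampled at `dt` (use `y = x` for the PSD).
#' @param dt sampling interval, ms.
#' @param segment_len segment length in samples (default 2^14).
#' @param overlap fractional segment overlap.
#' @return A data.frame with `f` (kHz, from 0 to Nyquist) and complex `csd`
#'   (units of `x*y*ms`), plus the number of segments in attribute
#'   `"n_segments"`.
#' @export
estimate_csd <- function(x, y, dt, segment_len = 2^14, overlap = 0.5) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  L <- as.integer(segment_len)
  if (L > n) stop("segment longer than series")
  x <- x - mean(x)
  y <- y - mean(y)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)  # Hann
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  acc <- complex(L)
  for (s in starts) {
    X <- fft(x[s:(s + L - 1L)] * w)
    Y <- fft(y[s:(s + L - 1L)] * w)
    acc <- acc + Conj(X) * Y
  }
  csd <- acc / length(starts) * dt / (L * mean(w^2))
  k <- 0:(L %/% 2)
  data.frame(f = k / (L * dt),
             csd = csd[k + 1L]) |>
    structure(n_segments = length(starts))
}

#' Spike-triggered average of an input series
#'
#' Averages the recorded input `u` in a window around each spike:
#' `STA(tau) = mean_j u(t_j + tau)`, with lag 0 aligned to the spike bin.
#' Spikes whose window extends beyond the recorded series, or that fall in
#' the burn-in period, are discarded.
#'
#' @param u input series sampled at `dt` starting at time 0 (e.g. the
#'   `noise` component of a simulation run with `record_noise = TRUE`).
#' @param spikes spike times, ms.
#' @param dt sampling interval of `u`, ms.
#' @param window half-width of the lag window, ms.
#' @param burn_in discard spikes at or before this time, ms.
#' @return A data.frame with `lag` (ms) and `sta` (units of `u`);
#'   number of spikes used in attribute `"n_spikes"`.
#' @export
estimate_sta <- function(u, spikes, dt, window = 100, burn_in = 0) {
  nlag <- as.integer(round(window / dt))
  idx <- as.integer(round(spikes / dt))  # spike at bin end k*dt -> index k
  idx <- idx[spikes > burn_in & idx - nlag >= 1L & idx + nlag <= length(u)]
  if (length(idx) == 0L) stop("no usable spikes for the spike-triggered average")
  lags <- (-nlag):nlag
  sta <- vapply(lags, function(l) mean(u[idx + l]), numeric(1))
  structure(data.frame(lag = lags * dt, sta = sta), n_spikes = length(idx))
}

#' Bin spike times into an instantaneous-rate series
#'
#' Counts spikes in bins of width `dt_bin` over `(burn_in, duration]` and
#' divides by the bin width, giving a series in kHz whose mean is the
#' firing rate.
#'
#' @param spikes spike times, ms.
#' @param dt_bin bin width, ms.
#' @param burn_in,duration window bounds, ms.
#' @return Numeric vector of length `(duration - burn_in)/dt_bin`.
#' @export
bin_spike_train <- function(spikes, dt_bin, burn_in, duration) {
  nb <- as.integer(round((duration - burn_in) / dt_bin))
  s <- spikes[spikes > burn_in & spikes <= duration]
  idx <- pmin(nb, as.integer(ceiling((s - burn_in) / dt_bin)))
  tabulate(idx, nbins = nb) / dt_bin
}

#' Cross-covariance between the spike trains of a simulated pair
#'
#' Bins both spike trains at `dt_bin`, subtracts means, and estimates the
#' cross-covariance `cov(s1(t), s2(t + tau))` by circular FFT correlation,
#' averaged over repeats; the between-repeat standard error is returned per
#' lag.
#'
#' @param sim an [simulate_shared_pair()] result.
#' @param dt_bin lag resolution, ms.
#' @param max_lag maximum |lag|, ms.
#' @return A data.frame with `lag` (ms), `xcov` (kHz^2) and `sem`.
#' @export
estimate_spike_xcov <- function(sim, dt_bin = 1, max_lag = 50) {
  cfg <- sim$config
  nl <- as.integer(round(max_lag / dt_bin))
  per <- lapply(seq_along(sim$spike_times1), function(k) {
    s1 <- bin_spike_train(sim$spike_times1[[k]], dt_bin, cfg$burn_in, cfg$duration)
    s2 <- bin_spike_train(sim$spike_times2[[k]], dt_bin, cfg$burn_in, cfg$duration)
    n <- length(s1)
    cc <- Re(fft(Conj(fft(s1 - mean(s1))) * fft(s2 - mean(s2)),
                 inverse = TRUE)) / n^2
    # circular lags: index j+1 <-> lag j*dt_bin (wrapping for negative)
    c(cc[(n - nl + 1L):n], cc[1:(nl + 1L)])
  })
  m <- do.call(rbind, per)
  data.frame(lag = seq(-nl, nl) * dt_bin,
             xcov = colMeans(m),
             sem = apply(m, 2, sd) / sqrt(nrow(m)))
}
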