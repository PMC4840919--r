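#' Write / read a numeric table as typed CSV
#'
#' Lossless round-trip of double-precision tables: values are written in
#' full scientific notation (17 significant digits) with a header line, and
#' non-finite values are serialized as `nan` / `inf` / `-inf` tokens.
#'
#' @param table a data.frame of numeric (or character) columns.
#' @param path file path.
#' @return `write_table` returns `path` invisibly; `read_table` the
#'   restored data.frame.
#' @export
write_table <- function(table, path) {
  tab <- as.data.frame(table)
  for (j in seq_along(tab)) {
    if (is.numeric(tab[[j]])) {
      s <- sprintf("%.17g", tab[[j]])
      s[is.nan(tab[[j]])] <- "nan"
      s[tab[[j]] == Inf] <- "inf"
      s[tab[[j]] == -Inf] <- "-inf"
      s[is.na(tab[[j]]) & !is.nan(tab[[j]])] <- "na"
      tab[[j]] <- s
    }
  }
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (j in seq_along(tab)) {
    x <- tab[[j]]
    y <- suppressWarnings(as.numeric(ifelse(x == "nan", "NaN",
                            ifelse(x == "inf", "Inf",
                            ifelse(x == "-inf", "-Inf",
                            ifelse(x == "na", NA, x))))))
    ok <- !is.na(y) | x %in% c("na", "nan")
    if (all(ok)) tab[[j]] <- y
  }
  tab
}

scale_sweep <- function(x, scale) {
  # thin a sweep under reduced scale, always keeping both endpoints
  if (scale >= 1 || length(x) <= 3) return(x)
  keep <- unique(round(seq(1, length(x),
                           length.out = max(3, ceiling(length(x) * scale^(1/3))))))
  x[keep]
}

scaled_cfg <- function(scale, seed, dt = 0.1) {
  post <- max(2000, 60000 * scale)
  sim_config(dt = dt, duration = 5000 + post, burn_in = 5000,
             n_repeats = max(4, ceiling(10 * scale)), seed = seed)
}

#' Run a predefined comparison experiment
#'
#' Reproduces one of the package's standard validation protocols, running
#' the quasi-static and matched-variance approximations alongside the Monte
#' Carlo oracle and returning/writing per-curve tables plus an error
#' summary:
#' \describe{
#'   \item{`rate_sweep`}{firing rate vs presynaptic excitatory rate `r_e`
#'     (8-12 kHz), uncorrelated input.}
#'   \item{`adaptation_grid`}{absolute and percent rate errors over a grid
#'     of voltage-adaptation strengths `a` and timescales `tau_w`.}
#'   \item{`weight_scaling`}{rate error under `J -> c J`, `r -> r/c`
#'     scalings that hold the mean input fixed.}
#'   \item{`sta`}{spike-triggered average and input-spike cross-spectrum
#'     under a weak white-noise perturbation, for `r_e` = 8, 10, 12 kHz.}
#'   \item{`pair_xcov`}{spike-train cross-covariance of a shared-input pair
#'     (`c` = 0.1).}
#'   \item{`rate_sweep_correlated`}{as `rate_sweep` for the temporally
#'     correlated input model.}
#'   \item{`timescale_sweep`}{correlated-model rate error as all input
#'     timescales are scaled jointly (`r_e` = 11 kHz, dt = 0.05 ms).}
#' }
#' Figure-style aliases `fig1`, `fig3`, `fig5`, `fig8`, `fig10`, `fig11`,
#' `fig12` map onto these in that order.
#'
#' @param name experiment name (see above).
#' @param scale fraction in (0, 1] controlling Monte Carlo effort: the
#'   post-burn-in duration is `60 s * scale` per repeat (floor 2 s), the
#'   repeat count is `max(4, ceiling(10 * scale))`, and parameter sweeps
#'   are thinned (endpoints kept).
#' @param seed base RNG seed.
#' @param outdir if non-`NULL`, write each result table as CSV and the
#'   error summary as JSON into this directory.
#' @return A list of data.frames (tables) plus `summary` (max absolute and
#'   percent rate errors per method, where applicable), invisibly if
#'   `outdir` is given.
#' @export
run_experiment <- function(name, scale = 0.2, seed = 1, outdir = NULL) {
  stopifnot(scale > 0, scale <= 1)
  alias <- c(fig1 = "rate_sweep", fig3 = "adaptation_grid",
             fig5 = "weight_scaling", fig8 = "sta", fig10 = "pair_xcov",
             fig11 = "rate_sweep_correlated", fig12 = "timescale_sweep")
  if (name %in% names(alias)) name <- alias[[name]]
  res <- switch(name,
    rate_sweep = exp_rate_sweep(scale, seed, correlated = FALSE),
    adaptation_grid = exp_adaptation_grid(scale, seed),
    weight_scaling = exp_weight_scaling(scale, seed),
    sta = exp_sta(scale, seed),
    pair_xcov = exp_pair_xcov(scale, seed),
    rate_sweep_correlated = exp_rate_sweep(scale, seed, correlated = TRUE),
    timescale_sweep = exp_timescale_sweep(scale, seed),
    stop("unknown experiment name: ", name))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(res), "summary"))
      write_table(res[[nm]], file.path(outdir, paste0(name, "_", nm, ".csv")))
    jsonlite::write_json(res$summary,
                         file.path(outdir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

approx_rates <- function(p, inp, mesh = build_mesh(p)) {
  vapply(c("quasi_static", "matched_variance"), function(m) {
    solve_self_consistent(p, diffusion_spec(p, inp, m), mesh = mesh)$r0
  }, numeric(1))
}

rate_error_summary <- function(tab) {
  list(max_abs_error_Hz = list(
         quasi_static = max(abs(tab$r0_qs - tab$r0_mc)) * 1000,
         matched_variance = max(abs(tab$r0_mv - tab$r0_mc)) * 1000),
       max_pct_error = list(
         quasi_static = max(100 * abs(tab$r0_qs - tab$r0_mc) / tab$r0_mc),
         matched_variance = max(100 * abs(tab$r0_mv - tab$r0_mc) / tab$r0_mc)))
}

exp_rate_sweep <- function(scale, seed, correlated) {
  p <- neuron_params()
  re_vals <- scale_sweep(seq(8, 12, by = 0.5), scale)
  cfg <- scaled_cfg(scale, seed)
  mesh <- build_mesh(p)
  rows <- lapply(seq_along(re_vals), function(i) {
    inp <- if (correlated) correlated_input(r_e = re_vals[i])
           else uncorrelated_input(r_e = re_vals[i])
    ap <- approx_rates(p, inp, mesh)
    cfg$seed <- seed + 1000L * i
    mc <- if (correlated) simulate_correlated(p, inp, cfg)
          else simulate_uncorrelated(p, inp, cfg)
    data.frame(r_e = re_vals[i], r0_qs = ap[["quasi_static"]],
               r0_mv = ap[["matched_variance"]], r0_mc = mc$rate_estimate,
               mc_sem = mc$rate_sem)
  })
  tab <- do.call(rbind, rows)
  list(rates = tab, summary = rate_error_summary(tab))
}

exp_adaptation_grid <- function(scale, seed,
                                a_vals = c(0, 0.075, 0.15, 0.225, 0.3),
                                tw_vals = c(25, 50, 100, 200)) {
  inp <- uncorrelated_input()
  a_vals <- scale_sweep(a_vals, scale)
  tw_vals <- scale_sweep(tw_vals, scale)
  cfg <- scaled_cfg(scale, seed)
  grid <- expand.grid(a = a_vals, tau_w = tw_vals)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- neuron_params(a = grid$a[i], tau_w = grid$tau_w[i])
    ap <- approx_rates(p, inp)
    cfg$seed <- seed + 1000L * i
    mc <- simulate_uncorrelated(p, inp, cfg)
    data.frame(a = grid$a[i], tau_w = grid$tau_w[i],
               r0_qs = ap[["quasi_static"]], r0_mv = ap[["matched_variance"]],
               r0_mc = mc$rate_estimate, mc_sem = mc$rate_sem)
  })
  tab <- do.call(rbind, rows)
  list(rates = tab, summary = rate_error_summary(tab))
}

exp_weight_scaling <- function(scale, seed, c_vals = c(0.5, 1, 2, 4)) {
  p <- neuron_params()
  base <- uncorrelated_input()
  cfg <- scaled_cfg(scale, seed)
  # larger weights mean more diffusion: deepen the mesh lower bound
  mesh <- build_mesh(p, V_lb = p$E_L - 70)
  rows <- lapply(seq_along(c_vals), function(i) {
    cc <- c_vals[i]
    inp <- uncorrelated_input(J_e = cc * base$J_e, J_i = cc * base$J_i,
                              r_e = base$r_e / cc, r_i = base$r_i / cc)
    ap <- approx_rates(p, inp, mesh)
    cfg$seed <- seed + 1000L * i
    mc <- simulate_uncorrelated(p, inp, cfg)
    data.frame(c = cc, r0_qs = ap[["quasi_static"]],
               r0_mv = ap[["matched_variance"]], r0_mc = mc$rate_estimate,
               mc_sem = mc$rate_sem)
  })
  tab <- do.call(rbind, rows)
  list(rates = tab, summary = rate_error_summary(tab))
}

exp_sta <- function(scale, seed, re_vals = c(8, 10, 12), D_n = 0.1) {
  p <- neuron_params()
  cfg <- scaled_cfg(scale, seed)
  mesh <- build_mesh(p)
  tabs <- lapply(seq_along(re_vals), function(i) {
    inp <- uncorrelated_input(r_e = re_vals[i])
    base <- solve_self_consistent(p, diffusion_spec(p, inp, D_extra = D_n),
                                  mesh = mesh)
    curve <- susceptibility_curve(base, p)
    sta_th <- sta_from_susceptibility(curve, D_n, max_lag = 100)
    cfg$seed <- seed + 1000L * i
    mc <- simulate_uncorrelated(p, inp, cfg, D_n = D_n, record_noise = TRUE)
    stas <- lapply(seq_along(mc$noise), function(k) {
      has <- any(mc$spike_times[[k]] > cfg$burn_in + 100 &
                 mc$spike_times[[k]] < cfg$duration - 100)
      if (!has) return(NULL)   # short low-rate repeats can lack usable spikes
      estimate_sta(mc$noise[[k]], mc$spike_times[[k]], cfg$dt, window = 100,
                   burn_in = cfg$burn_in)$sta
    })
    stas <- Filter(Negate(is.null), stas)
    if (length(stas) == 0)
      stop("no spikes available for the spike-triggered average; increase scale")
    m <- do.call(cbind, stas)
    lag_mc <- seq(-100, 100, by = cfg$dt)
    data.frame(r_e = re_vals[i], lag = lag_mc, sta_mc = rowMeans(m),
               sta_sem = apply(m, 1, sd) / sqrt(ncol(m)),
               sta_theory = approx(sta_th$lag, sta_th$sta, xout = lag_mc)$y)
  })
  list(sta = do.call(rbind, tabs),
       summary = list(D_n = D_n, r_e = re_vals))
}

exp_pair_xcov <- function(scale, seed, cshare = 0.1) {
  p <- neuron_params()
  inp <- uncorrelated_input()
  mesh <- build_mesh(p)
  base <- solve_self_consistent(p, diffusion_spec(p, inp), mesh = mesh)
  curve <- susceptibility_curve(base, p)
  th <- pair_cross_spectrum(curve, cshare, inp, max_lag = 50)
  cfg <- scaled_cfg(scale, seed)
  mc <- simulate_shared_pair(p, inp, cshare, cfg)
  xc <- estimate_spike_xcov(mc, dt_bin = 1, max_lag = 50)
  xc$xcov_theory <- approx(th$lag, th$xcov, xout = xc$lag)$y
  list(xcov = xc,
       csd = data.frame(f = th$f, csd = th$csd),
       summary = list(shared_fraction = cshare,
                      rate_mc_Hz = 1000 * mc$rate_estimate,
                      rate_theory_Hz = 1000 * base$r0))
}

exp_timescale_sweep <- function(scale, seed,
                                factors = c(0.25, 0.5, 1, 2, 4)) {
  p <- neuron_params()
  factors <- scale_sweep(factors, scale)
  cfg <- scaled_cfg(scale, seed, dt = 0.05)
  mesh <- build_mesh(p)
  rows <- lapply(seq_along(factors), function(i) {
    s <- factors[i]
    inp <- correlated_input(r_e = 11, tau_e = 4 * s, tau_ri = 1 * s,
                            tau_di = 6 * s, tau_nu = 10 * s)
    ap <- approx_rates(p, inp, mesh)
    cfg$seed <- seed + 1000L * i
    mc <- simulate_correlated(p, inp, cfg)
    data.frame(factor = s, r0_qs = ap[["quasi_static"]],
               r0_mv = ap[["matched_variance"]], r0_mc = mc$rate_estimate,
               mc_sem = mc$rate_sem)
  })
  tab <- do.call(rbind, rows)
  list(rates = tab, summary = rate_error_summary(tab))
}
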