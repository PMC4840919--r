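// Forward-Euler Monte Carlo kernels for the AdEx neuron with shot-noise
// synaptic input (time bin dt, threshold handled at bin resolution: a spike
// is registered at the first bin where the Euler-updated V >= V_th, then
// V -> V_re and w -> w + b).  Arrival counts per bin are Poisson with mean
// rate*dt; for the temporally correlated model the rates follow an exact
// per-bin Ornstein-Uhlenbeck update (clipped at zero only when generating
// arrivals) and arrivals are passed through unit-area synaptic filters:
// single-exponential EPSC and difference-of-exponentials IPSC.
//
// Randomness comes from R's RNG (RNGScope via Rcpp attributes), so set.seed()
// on the R side makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double psi_exp(double V, double Delta_T, double V_T,
                             double tau_m) {
  if (Delta_T <= 0.0) return 0.0;
  double z = (V - V_T) / Delta_T;
  if (z > 50.0) z = 50.0;  // overflow guard between threshold crossings
  return (Delta_T / tau_m) * std::exp(z);
}

// [[Rcpp::export]]
List sim_adex_cpp(double tau_m, double E_L, double Delta_T, double V_T,
                  double V_th, double V_re, double a, double b, double tau_w,
                  double Je, double Ji, double re, double ri, bool correlated,
                  double tau_e, double tau_ri, double tau_di, double tau_nu,
                  double sigma_nu, double dt, double duration, double burn_in,
                  double I_const, double Dn, bool free_membrane,
                  bool record_traces, int trace_stride, bool record_noise) {
  const int nsteps = (int)std::lround(duration / dt);
  double V = E_L, w = 0.0;
  double nu_e = re, nu_i = ri;
  double x_e = re, y_d = ri * tau_di, y_r = ri * tau_ri;
  const double rho = correlated ? std::exp(-dt / tau_nu) : 0.0;
  const double sd_ou = correlated ? sigma_nu * std::sqrt(1.0 - rho * rho) : 0.0;
  const double noise_sd = (Dn > 0.0) ? std::sqrt(2.0 * Dn / dt) : 0.0;

  std::vector<double> spikes;
  NumericVector noise(record_noise ? nsteps : 0);
  const int ntr = record_traces ? nsteps / trace_stride + 1 : 0;
  NumericVector tr_t(ntr), tr_V(ntr), tr_w(ntr);
  int itr = 0;

  for (int k = 0; k < nsteps; ++k) {
    double dVin;
    if (correlated) {
      nu_e = re + (nu_e - re) * rho + sd_ou * norm_rand();
      nu_i = ri + (nu_i - ri) * rho + sd_ou * norm_rand();
      const double ne = R::rpois(std::max(nu_e, 0.0) * dt);
      const double ni = R::rpois(std::max(nu_i, 0.0) * dt);
      x_e += dt * (-x_e / tau_e);
      x_e += ne / tau_e;
      y_d += dt * (-y_d / tau_di);
      y_d += ni;
      y_r += dt * (-y_r / tau_ri);
      y_r += ni;
      const double x_i = (y_d - y_r) / (tau_di - tau_ri);
      dVin = dt * (Je * x_e + Ji * x_i);
    } else {
      const double ne = R::rpois(re * dt);
      const double ni = R::rpois(ri * dt);
      dVin = ne * Je + ni * Ji;
    }
    double un = 0.0;
    if (noise_sd > 0.0) un = noise_sd * norm_rand();
    const double Fv = (E_L - V) / tau_m - w + I_const +
                      (free_membrane ? 0.0 : psi_exp(V, Delta_T, V_T, tau_m));
    const double Vnew = V + dt * (Fv + un) + dVin;
    const double wnew = w + dt * (a * (V - E_L) - w) / tau_w;
    V = Vnew;
    w = wnew;
    if (!free_membrane && V >= V_th) {
      spikes.push_back((k + 1) * dt);
      V = V_re;
      w += b;
    }
    if (record_noise) noise[k] = un;
    if (record_traces && (k % trace_stride == 0)) {
      tr_t[itr] = (k + 1) * dt;
      tr_V[itr] = V;
      tr_w[itr] = w;
      ++itr;
    }
  }

  int npost = 0;
  for (size_t i = 0; i < spikes.size(); ++i)
    if (spikes[i] > burn_in) ++npost;
  const double rate = npost / (duration - burn_in);

  List out = List::create(_["spike_times"] = wrap(spikes), _["rate"] = rate,
                          _["n_spikes_post"] = npost);
  if (record_noise) out["noise"] = noise;
  if (record_traces) {
    out["t"] = tr_t[Range(0, itr - 1)];
    out["V"] = tr_V[Range(0, itr - 1)];
    out["w"] = tr_w[Range(0, itr - 1)];
  }
  return out;
}

// Two AdEx neurons driven by partially shared excitatory input: a common
// Poisson stream of rate c*re plus two independent streams of rate (1-c)*re
// each, and independent inhibitory streams of rate ri.  Temporally
// uncorrelated (delta synapse) model only.

// [[Rcpp::export]]
List sim_adex_pair_cpp(double tau_m, double E_L, double Delta_T, double V_T,
                       double V_th, double V_re, double a, double b,
                       double tau_w, double Je, double Ji, double re,
                       double ri, double cshare, double dt, double duration,
                       double burn_in) {
  const int nsteps = (int)std::lround(duration / dt);
  double V1 = E_L, V2 = E_L, w1 = 0.0, w2 = 0.0;
  std::vector<double> sp1, sp2;
  const double lam_sh = cshare * re * dt;
  const double lam_ind = (1.0 - cshare) * re * dt;
  const double lam_i = ri * dt;
  for (int k = 0; k < nsteps; ++k) {
    const double nsh = R::rpois(lam_sh);
    const double n1 = lam_ind > 0.0 ? R::rpois(lam_ind) : 0.0;
    const double n2 = lam_ind > 0.0 ? R::rpois(lam_ind) : 0.0;
    const double ni1 = lam_i > 0.0 ? R::rpois(lam_i) : 0.0;
    const double ni2 = lam_i > 0.0 ? R::rpois(lam_i) : 0.0;
    const double F1 = (E_L - V1) / tau_m - w1 + psi_exp(V1, Delta_T, V_T, tau_m);
    const double F2 = (E_L - V2) / tau_m - w2 + psi_exp(V2, Delta_T, V_T, tau_m);
    const double V1n = V1 + dt * F1 + (nsh + n1) * Je + ni1 * Ji;
    const double V2n = V2 + dt * F2 + (nsh + n2) * Je + ni2 * Ji;
    w1 += dt * (a * (V1 - E_L) - w1) / tau_w;
    w2 += dt * (a * (V2 - E_L) - w2) / tau_w;
    V1 = V1n;
    V2 = V2n;
    if (V1 >= V_th) {
      sp1.push_back((k + 1) * dt);
      V1 = V_re;
      w1 += b;
    }
    if (V2 >= V_th) {
      sp2.push_back((k + 1) * dt);
      V2 = V_re;
      w2 += b;
    }
  }
  int n1p = 0, n2p = 0;
  for (size_t i = 0; i < sp1.size(); ++i)
    if (sp1[i] > burn_in) ++n1p;
  for (size_t i = 0; i < sp2.size(); ++i)
    if (sp2[i] > burn_in) ++n2p;
  const double T = duration - burn_in;
  return List::create(_["spike_times1"] = wrap(sp1),
                      _["spike_times2"] = wrap(sp2),
                      _["rate1"] = n1p / T, _["rate2"] = n2p / T);
}
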