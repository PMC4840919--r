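// Threshold-integration solvers for the steady-state and weakly modulated
// one-dimensional Fokker-Planck equation of an exponential integrate-and-fire
// neuron with white-noise input of intensity D.
//
// The steady-state flux/density pair is integrated backward from the spike
// threshold V_th (last mesh node) with unit efflux: the unnormalized flux is
// j(V) = 1 on (V_re, V_th) and 0 below V_re (the reset re-injection enters as
// a flux step at the V_re node), and the unnormalized density obeys
//   D dp/dV = F(V) p - j(V),     p(V_th) = 0,
// where F is the drift.  The firing rate is r0 = 1 / integral(p) and
// P = r0 * p.  Three schemes are provided:
//   0 "euler":    first-order explicit step on the density ODE;
//   1 "midpoint": per-cell exact integrating factor with the drift frozen at
//                 the cell midpoint (modified Euler, midpoint rule);
//   2 "simpson":  per-cell integrating factor with the exponent and the
//                 inhomogeneous integral evaluated by 3-point Simpson rules.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double trapz(const NumericVector &x, const NumericVector &y) {
  double s = 0.0;
  for (int i = 1; i < x.size(); ++i)
    s += 0.5 * (x[i] - x[i - 1]) * (y[i] + y[i - 1]);
  return s;
}

static inline double safe_exp(double z) {
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return std::exp(z);
}

// The Simpson scheme also evaluates the density at cell midpoints (via a
// half-cell integrating-factor step, accurate enough not to limit the
// order) and uses per-cell Simpson quadrature for the normalization mass
// and the voltage moment; the lower-order schemes use the trapezoid rule,
// as in their original formulations.  Fq3 holds the drift at the 3/4
// points of each cell (the midpoint of the upper half-cell).

// [[Rcpp::export]]
List fp_steady_cpp(NumericVector v, NumericVector Fn, NumericVector Fm,
                   NumericVector Fq, NumericVector Fq3, double D, int ire,
                   int scheme) {
  const int n = v.size();
  NumericVector p(n), pmid(scheme == 2 ? n - 1 : 0);
  p[n - 1] = 0.0;
  for (int k = n - 1; k >= 1; --k) {
    const double dv = v[k] - v[k - 1];
    const double j = (k - 1 >= ire) ? 1.0 : 0.0;
    if (scheme == 0) {
      p[k - 1] = p[k] - dv * (Fn[k] * p[k] - j) / D;
    } else if (scheme == 1) {
      const double Fc = Fm[k - 1];
      const double G = Fc * dv / D;
      const double E = safe_exp(-G);
      double I;
      if (std::fabs(G) > 1e-10)
        I = (D / Fc) * (-std::expm1(-G));
      else
        I = dv * (1.0 - 0.5 * G);
      p[k - 1] = p[k] * E + (j / D) * I;
    } else {
      const double G  = dv * (Fn[k - 1] + 4.0 * Fm[k - 1] + Fn[k]) / (6.0 * D);
      const double Gh = 0.5 * dv * (Fn[k - 1] + 4.0 * Fq[k - 1] + Fm[k - 1]) /
                        (6.0 * D);
      const double E = safe_exp(-G);
      const double I = dv / 6.0 * (1.0 + 4.0 * safe_exp(-Gh) + E);
      p[k - 1] = p[k] * E + (j / D) * I;
      // density at the cell midpoint: half-cell step from the upper node
      const double Ft = Fq3[k - 1];
      const double Gt = 0.5 * dv * Ft / D;
      const double Et = safe_exp(-Gt);
      double It;
      if (std::fabs(Gt) > 1e-10)
        It = (D / Ft) * (-std::expm1(-Gt));
      else
        It = 0.5 * dv * (1.0 - 0.5 * Gt);
      pmid[k - 1] = p[k] * Et + (j / D) * It;
    }
    if (scheme != 0 && !std::isfinite(p[k - 1]))
      stop("non-finite density during threshold integration at node %d (V = %g mV)",
           k, v[k - 1]);
  }
  double mass, mom;
  if (scheme == 2) {
    mass = 0.0;
    mom = 0.0;
    for (int c = 0; c < n - 1; ++c) {
      const double dv = v[c + 1] - v[c];
      const double vm = 0.5 * (v[c] + v[c + 1]);
      mass += dv / 6.0 * (p[c] + 4.0 * pmid[c] + p[c + 1]);
      mom += dv / 6.0 * (v[c] * p[c] + 4.0 * vm * pmid[c] + v[c + 1] * p[c + 1]);
    }
  } else {
    mass = trapz(v, p);
    NumericVector vp(n);
    for (int i = 0; i < n; ++i) vp[i] = v[i] * p[i];
    mom = trapz(v, vp);
  }
  double r0;
  bool degenerate = false;
  if (!std::isfinite(mass) || mass <= 0.0) {
    r0 = 0.0;
    degenerate = true;
  } else {
    r0 = 1.0 / mass;
  }
  NumericVector P(n), flux(n);
  for (int i = 0; i < n; ++i) {
    P[i] = degenerate ? NA_REAL : r0 * p[i];
    flux[i] = (i >= ire) ? r0 : 0.0;
  }
  const double mu_V = degenerate ? NA_REAL : mom / mass;
  return List::create(_["P"] = P, _["flux"] = flux, _["r0"] = r0,
                      _["mu_V"] = mu_V, _["degenerate"] = degenerate);
}

// Linear-response (modulation) solver: first-order response of the density
// and flux to a weak uniform current modulation at angular frequency omega
// (omega = 2*pi*f, f in kHz).  The coupled system on the mesh is
//   D dphat/dV = F(V) phat + uhat P0(V) - Jhat,
//   dJhat/dV   = -i omega phat,
// with phat(V_th) = 0, reflecting lower boundary Jhat(V_lb) = 0, efflux
// rhat = Jhat(V_th) and a re-injection flux step -rhat just below V_re.
// Each cell contributes the same Simpson-rule integrating-factor relation
// used by the steady-state solver (with the flux entering the source term)
// plus a trapezoid continuity relation.  Backward (shooting) integration of
// this system is unstable at high frequency -- oscillatory homogeneous
// modes grow like exp(sqrt(omega/2D) |V|) and destroy the solution -- so
// the discrete relations are assembled into one block-tridiagonal linear
// system (2x2 blocks per node, unknowns (phat_i, Jhat_i)) and solved
// globally; the re-injection coupling to Jhat(V_th) is a rank-one border
// handled by the Sherman-Morrison identity.  Returns
//   A_r = rhat/uhat (rate modulation per unit current modulation) and
//   A_V = mean-voltage modulation per unit current modulation,
// for the non-adaptive model about the supplied steady state P0.

typedef std::complex<double> cplx;

struct Block {
  cplx a11, a12, a21, a22;
};

static inline Block binv(const Block &B, bool &ok) {
  const cplx det = B.a11 * B.a22 - B.a12 * B.a21;
  if (std::abs(det) < 1e-280) { ok = false; return Block{0, 0, 0, 0}; }
  ok = true;
  return Block{B.a22 / det, -B.a12 / det, -B.a21 / det, B.a11 / det};
}

static inline Block bmul(const Block &X, const Block &Y) {
  return Block{X.a11 * Y.a11 + X.a12 * Y.a21, X.a11 * Y.a12 + X.a12 * Y.a22,
               X.a21 * Y.a11 + X.a22 * Y.a21, X.a21 * Y.a12 + X.a22 * Y.a22};
}

// [[Rcpp::export]]
List fp_modulation_cpp(NumericVector v, NumericVector Fn, NumericVector Fm,
                       NumericVector Fq, NumericVector P0, double D, int ire,
                       double omega) {
  if (omega <= 0.0)
    stop("omega must be positive; the zero-frequency response is computed by finite differences");
  const int n = v.size();
  const int nc = n - 1;
  const cplx iw(0.0, omega);

  // per-cell coefficients
  std::vector<double> Ev(nc), Ehv(nc), w0v(nc), dvv(nc);
  for (int c = 0; c < nc; ++c) {
    const double dv = v[c + 1] - v[c];
    const double G = dv * (Fn[c] + 4.0 * Fm[c] + Fn[c + 1]) / (6.0 * D);
    const double Gh = 0.5 * dv * (Fn[c] + 4.0 * Fq[c] + Fm[c]) / (6.0 * D);
    Ev[c] = safe_exp(-G);
    Ehv[c] = safe_exp(-Gh);
    w0v[c] = dv / (6.0 * D);
    dvv[c] = dv;
  }

  // block-tridiagonal assembly: block-row i has equations
  //   i = 0:      { J_0 = 0,              E1(cell 0) }
  //   0 < i < n-1:{ E2(cell i-1),         E1(cell i) }
  //   i = n-1:    { E2(cell n-2),         p_{n-1} = 0 }
  // with, for cell c (nodes c, c+1):
  //   E1: p_c - E p_{c+1} - w0[(1+2Eh) J_c + (E+2Eh) J_{c+1}^eff] = rhs1
  //       rhs1 = -u w0[(1+2Eh) P0_c + (E+2Eh) P0_{c+1}]
  //   E2: J_{c+1}^eff - J_c + i omega (dv/2)(p_c + p_{c+1}) = 0
  // where J^eff subtracts J_{n-1} at the reset node (rank-one border).
  std::vector<Block> A(n), B(n), C(n);
  std::vector<cplx> d1(2 * n, cplx(0, 0)), d2(2 * n, cplx(0, 0));
  for (int i = 0; i < n; ++i) {
    A[i] = Block{0, 0, 0, 0};
    B[i] = Block{0, 0, 0, 0};
    C[i] = Block{0, 0, 0, 0};
  }
  // boundary rows
  B[0].a12 = 1.0;               // J_0 = 0
  B[n - 1].a21 = 1.0;           // p_{n-1} = 0  (second equation of last row)
  // E1 equations: row (block i, eq 1) for cell c = i, i = 0..n-2
  for (int c = 0; c < nc; ++c) {
    const double E = Ev[c], Eh = Ehv[c], w0 = w0v[c];
    B[c].a21 += 1.0;                      // p_c
    B[c].a22 += -w0 * (1.0 + 2.0 * Eh);   // J_c
    C[c].a21 += -E;                       // p_{c+1}
    C[c].a22 += -w0 * (E + 2.0 * Eh);     // J_{c+1}
    d1[2 * c + 1] = -w0 * ((1.0 + 2.0 * Eh) * P0[c] +
                           (E + 2.0 * Eh) * P0[c + 1]);  // uhat = 1
  }
  // E2 equations: row (block i, eq 0) for cell c = i-1, i = 1..n-1
  for (int c = 0; c < nc; ++c) {
    const int i = c + 1;
    const cplx hw = iw * 0.5 * dvv[c];
    A[i].a11 += hw;    // p_c
    A[i].a12 += -1.0;  // J_c
    B[i].a11 += hw;    // p_{c+1}
    B[i].a12 += 1.0;   // J_{c+1}
  }
  // the last-row E1 slot is the p boundary equation (already set): fix layout
  // note: E1 of cell n-2 sits in block-row n-2 (eq 1) and couples to block
  // n-1 through C[n-2]; block-row n-1's eq 1 is the p boundary.

  // rank-one border: cells just below V_re reference J^eff = J_ire - J_{n-1}
  // in their equations; column entries of J_{n-1}:
  //   E1 of cell c* = ire-1 (row 2*c*+1):  +w0 (E + 2 Eh)
  //   E2 of cell c* (row 2*(c*+1)):        -1
  const int cs = ire - 1;
  if (cs < 0 || ire >= n - 1)
    stop("reset node must lie strictly inside the mesh");
  std::vector<cplx> ucol(2 * n, cplx(0, 0));
  ucol[2 * cs + 1] = w0v[cs] * (Ev[cs] + 2.0 * Ehv[cs]);
  ucol[2 * (cs + 1)] = -1.0;
  d2 = ucol;

  // block Thomas factorization, two right-hand sides (d1 = source, d2 = u)
  std::vector<Block> Sinv(n);
  std::vector<Block> Cs(n);
  std::vector<cplx> y1(2 * n), y2(2 * n);
  bool ok = true;
  Block S = B[0];
  Sinv[0] = binv(S, ok);
  if (!ok) stop("singular block at node 0 in the modulation solve");
  Cs[0] = C[0];
  y1[0] = d1[0]; y1[1] = d1[1];
  y2[0] = d2[0]; y2[1] = d2[1];
  for (int i = 1; i < n; ++i) {
    const Block M = bmul(A[i], Sinv[i - 1]);
    const Block MC = bmul(M, Cs[i - 1]);
    S = Block{B[i].a11 - MC.a11, B[i].a12 - MC.a12, B[i].a21 - MC.a21,
              B[i].a22 - MC.a22};
    Sinv[i] = binv(S, ok);
    if (!ok) stop("singular block at node %d in the modulation solve", i);
    Cs[i] = C[i];
    y1[2 * i] = d1[2 * i] - (M.a11 * y1[2 * (i - 1)] + M.a12 * y1[2 * i - 1]);
    y1[2 * i + 1] =
        d1[2 * i + 1] - (M.a21 * y1[2 * (i - 1)] + M.a22 * y1[2 * i - 1]);
    y2[2 * i] = d2[2 * i] - (M.a11 * y2[2 * (i - 1)] + M.a12 * y2[2 * i - 1]);
    y2[2 * i + 1] =
        d2[2 * i + 1] - (M.a21 * y2[2 * (i - 1)] + M.a22 * y2[2 * i - 1]);
  }
  std::vector<cplx> x1(2 * n), x2(2 * n);
  // back substitution
  x1[2 * (n - 1)] = Sinv[n - 1].a11 * y1[2 * (n - 1)] +
                    Sinv[n - 1].a12 * y1[2 * (n - 1) + 1];
  x1[2 * (n - 1) + 1] = Sinv[n - 1].a21 * y1[2 * (n - 1)] +
                        Sinv[n - 1].a22 * y1[2 * (n - 1) + 1];
  x2[2 * (n - 1)] = Sinv[n - 1].a11 * y2[2 * (n - 1)] +
                    Sinv[n - 1].a12 * y2[2 * (n - 1) + 1];
  x2[2 * (n - 1) + 1] = Sinv[n - 1].a21 * y2[2 * (n - 1)] +
                        Sinv[n - 1].a22 * y2[2 * (n - 1) + 1];
  for (int i = n - 2; i >= 0; --i) {
    cplx r1p = y1[2 * i] - (Cs[i].a11 * x1[2 * (i + 1)] +
                            Cs[i].a12 * x1[2 * (i + 1) + 1]);
    cplx r1j = y1[2 * i + 1] - (Cs[i].a21 * x1[2 * (i + 1)] +
                                Cs[i].a22 * x1[2 * (i + 1) + 1]);
    x1[2 * i] = Sinv[i].a11 * r1p + Sinv[i].a12 * r1j;
    x1[2 * i + 1] = Sinv[i].a21 * r1p + Sinv[i].a22 * r1j;
    cplx r2p = y2[2 * i] - (Cs[i].a11 * x2[2 * (i + 1)] +
                            Cs[i].a12 * x2[2 * (i + 1) + 1]);
    cplx r2j = y2[2 * i + 1] - (Cs[i].a21 * x2[2 * (i + 1)] +
                                Cs[i].a22 * x2[2 * (i + 1) + 1]);
    x2[2 * i] = Sinv[i].a11 * r2p + Sinv[i].a12 * r2j;
    x2[2 * i + 1] = Sinv[i].a21 * r2p + Sinv[i].a22 * r2j;
  }
  // Sherman-Morrison: x = x1 - x2 * (e_k . x1) / (1 + e_k . x2),
  // k = index of J_{n-1}
  const int k = 2 * (n - 1) + 1;
  const cplx denom = 1.0 + x2[k];
  if (std::abs(denom) < 1e-280)
    stop("singular Sherman-Morrison denominator in the modulation solve");
  const cplx scale = x1[k] / denom;
  std::vector<cplx> p(n);
  for (int i = 0; i < n; ++i) p[i] = x1[2 * i] - scale * x2[2 * i];
  const cplx rhat = x1[k] - scale * x2[k];

  cplx AV(0, 0), mass(0, 0);
  for (int i = 1; i < n; ++i) {
    const double h = 0.5 * (v[i] - v[i - 1]);
    AV += h * (v[i - 1] * p[i - 1] + v[i] * p[i]);
    mass += h * (p[i - 1] + p[i]);
  }
  ComplexVector Ar(1), AVv(1), massv(1);
  Ar[0].r = rhat.real(); Ar[0].i = rhat.imag();
  AVv[0].r = AV.real(); AVv[0].i = AV.imag();
  massv[0].r = mass.real(); massv[0].i = mass.imag();
  return List::create(_["A_r"] = Ar, _["A_V"] = AVv, _["mass"] = massv);
}
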