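#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout shared by the kernels (see pack_kin_pars in R):
// 0-2 k_ads (tPA, PLG, PLS), 3-5 k_rev, 6 k2, 7 K_M, 8 k_cat, 9 gamma,
// 10 kappa, 11 k_loss, 12 eps0, 13 n0, 14 theta0_tPA, 15 theta0_PLG,
// 16 theta exponent q.
//
// Free-phase state G is the superficial concentration eps*C per cell (eps = 1
// outside the clot); bound state S exists only in clot cells. Lysis L is in
// uM of fibrin. Kinetics are advanced with explicit Euler substeps; the
// solubilization singularity at L -> n0 is handled by releasing all remaining
// bound mass once less than 1e-6*n0 fibrin remains.

static inline double eps_of_rem(double rem, double eps0) {
  return 1.0 - (1.0 - eps0) * rem;
}

// [[Rcpp::export]]
List cpp_kinetics_advance(NumericMatrix G_, NumericMatrix S_, NumericVector L_,
                          LogicalVector clot, double dt, int nsub,
                          NumericVector pars) {
  NumericMatrix G = clone(G_);
  NumericMatrix S = clone(S_);
  NumericVector L = clone(L_);
  const int n = G.ncol();
  const double *kads = &pars[0], *krev = &pars[3];
  const double k2 = pars[6], KM = pars[7], kcat = pars[8], gam = pars[9],
               kappa = pars[10], kloss = pars[11], eps0 = pars[12],
               n0 = pars[13], th0t = pars[14], th0p = pars[15], q = pars[16];
  const double hdt = dt / nsub;

  for (int c = 0; c < n; ++c) {
    if (!clot[c]) continue;
    double l = L[c];
    double g0 = G(0, c), g1 = G(1, c), g2 = G(2, c);
    double s0 = S(0, c), s1 = S(1, c), s2 = S(2, c);
    for (int it = 0; it < nsub; ++it) {
      double rem = 1.0 - l / n0;
      if (rem < 1e-6) {  // complete lysis: release every bound phase
        g0 += s0; g1 += s1; g2 += s2;
        s0 = s1 = s2 = 0.0; l = n0;
        break;
      }
      double eps = eps_of_rem(rem, eps0);
      double rq = (q == 2.0) ? rem : std::sqrt(rem);
      double tht = th0t * rq, thp = th0p * rq;
      double c0 = g0 / eps, c1 = g1 / eps, c2 = g2 / eps;
      double freet = tht - s0; if (freet < 0) freet = 0;
      double freep = thp - s1 - s2; if (freep < 0) freep = 0;
      double A0 = kads[0] * c0 * freet - krev[0] * s0;
      double A1 = kads[1] * c1 * freep - krev[1] * s1;
      double A2 = kads[2] * c2 * freep - krev[2] * s2;
      double Gp = k2 * s0 * s1 / (KM + s1);
      double dL = (kcat / gam) * (s2 > 0 ? s2 : 0);
      double fac = kappa * dL / (n0 - l);
      double r0 = fac * (s0 > 0 ? s0 : 0);
      double r1 = fac * (s1 > 0 ? s1 : 0);
      double r2 = fac * (s2 > 0 ? s2 : 0);

      g0 += hdt * (-A0 + r0);
      g1 += hdt * (-A1 + r1);
      g2 += hdt * (-A2 + r2 - kloss * g2);
      s0 += hdt * (A0 - r0);
      s1 += hdt * (A1 - Gp - r1);
      s2 += hdt * (A2 + Gp - r2 - kloss * s2);
      l += hdt * dL;
      if (g0 < 0) g0 = 0; if (g1 < 0) g1 = 0; if (g2 < 0) g2 = 0;
      if (s0 < 0) s0 = 0; if (s1 < 0) s1 = 0; if (s2 < 0) s2 = 0;
      if (l > n0) l = n0;
    }
    G(0, c) = g0; G(1, c) = g1; G(2, c) = g2;
    S(0, c) = s0; S(1, c) = s1; S(2, c) = s2;
    L[c] = l;
  }
  return List::create(_["G"] = G, _["S"] = S, _["L"] = L);
}

// Explicit conservative central-difference diffusion of C = G/eps on a 1D
// cell-centred grid. Left boundary: Dirichlet ghost at concentration
// inletC (if dirichlet_inlet), else zero flux. Right boundary: zero gradient
// (zero diffusive flux).
// [[Rcpp::export]]
NumericMatrix cpp_diffuse_1d(NumericMatrix G_, NumericVector eps,
                             NumericVector D, double dx, double dt,
                             NumericVector inletC, bool dirichlet_inlet) {
  NumericMatrix G = clone(G_);
  const int n = G.ncol();
  const double idx2 = 1.0 / (dx * dx);
  std::vector<double> C(n);
  for (int s = 0; s < 3; ++s) {
    for (int i = 0; i < n; ++i) C[i] = G(s, i) / eps[i];
    const double d = D[s] * dt * idx2;
    for (int i = 0; i < n; ++i) {
      double fl, fr;  // flux differences expressed as Laplacian terms
      if (i == 0)
        fl = dirichlet_inlet ? (inletC[s] - C[0]) : 0.0;
      else
        fl = C[i - 1] - C[i];
      fr = (i == n - 1) ? 0.0 : (C[i + 1] - C[i]);
      G(s, i) += d * (fl + fr);
    }
  }
  return G;
}

// Full 1D advance: n_steps of (diffusion, kinetics-with-substeps).
// [[Rcpp::export]]
List cpp_advance_1d(NumericMatrix G_, NumericMatrix S_, NumericVector L_,
                    LogicalVector clot, NumericVector eps0field_unused,
                    NumericVector D, double dx, double dt, int n_steps,
                    int nsub, NumericVector inletC, bool dirichlet_inlet,
                    NumericVector pars) {
  NumericMatrix G = clone(G_);
  NumericMatrix S = clone(S_);
  NumericVector L = clone(L_);
  const int n = G.ncol();
  const double eps0 = pars[12], n0 = pars[13];
  NumericVector eps(n);
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      eps[i] = clot[i] ? eps_of_rem(1.0 - L[i] / n0, eps0) : 1.0;
    G = cpp_diffuse_1d(G, eps, D, dx, dt, inletC, dirichlet_inlet);
    List out = cpp_kinetics_advance(G, S, L, clot, dt, nsub, pars);
    G = as<NumericMatrix>(out["G"]);
    S = as<NumericMatrix>(out["S"]);
    L = as<NumericVector>(out["L"]);
  }
  return List::create(_["G"] = G, _["S"] = S, _["L"] = L);
}
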