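// Mean-field equilibrium solver for end-grafted freely-jointed bead chains
// with grand-canonical hard-sphere colloids in an axisymmetric (r,z) cell.
//
// Chain connectivity is handled with the exact freely-jointed-chain
// propagator (spherical-shell bond kernel, passed in as precomputed
// interpolation triplets). Hard-core packing enters through a local
// Boublik-Mansoori (BMCSL) hard-sphere-mixture excess free energy, capped at
// a maximum packing fraction; attractive tails enter as mean-field
// convolutions (kernels precomputed on the R side, contact energies
// included). Self-consistency by adaptively damped Picard iteration on the
// species potentials.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI6 = M_PI / 6.0;

// BMCSL excess chemical potentials (kBT) for a binary hard-sphere mixture,
// with packing capped at `cap` and a linear penalty beyond it.
static inline void bmcsl_mu(double rho1, double rho2, double d1, double d2,
                            double cap, double slope,
                            double &mu1, double &mu2) {
  double x3_raw = PI6 * (rho1 * d1 * d1 * d1 + rho2 * d2 * d2 * d2);
  double pen = 0.0, scale = 1.0;
  if (x3_raw > cap) {
    pen = slope * (x3_raw - cap);
    scale = cap / x3_raw;
  }
  double r1 = rho1 * scale, r2 = rho2 * scale;
  double x0 = PI6 * (r1 + r2);
  double x1 = PI6 * (r1 * d1 + r2 * d2);
  double x2 = PI6 * (r1 * d1 * d1 + r2 * d2 * d2);
  double x3 = PI6 * (r1 * d1 * d1 * d1 + r2 * d2 * d2 * d2);
  if (x3 < 1e-14) { mu1 = pen; mu2 = pen; return; }
  double om = 1.0 - x3;
  double L = std::log(om);
  double A = x2 * x2 * x2;
  // partials of the excess free-energy density wrt the xi moments
  double g0 = -L;
  double g1 = 3.0 * x2 / om;
  double g2 = 3.0 * x2 * x2 / (x3 * x3) * L + 3.0 * x1 / om +
              3.0 * x2 * x2 / (x3 * om * om);
  double g3 = -2.0 * A / (x3 * x3 * x3) * L - (A / (x3 * x3) - x0) / om +
              3.0 * x1 * x2 / (om * om) +
              A * (-1.0 / (x3 * x3 * om * om) + 2.0 / (x3 * om * om * om));
  mu1 = g0 + g1 * d1 + g2 * d1 * d1 + g3 * d1 * d1 * d1 + pen;
  mu2 = g0 + g1 * d2 + g2 * d2 * d2 + g3 * d2 * d2 * d2 + pen;
}

// [[Rcpp::export(name = ".bmcsl_mu")]]
NumericMatrix bmcsl_mu_R(NumericVector rho1, NumericVector rho2,
                         double d1, double d2,
                         double cap = 0.65, double slope = 100.0) {
  int n = rho1.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double m1, m2;
    bmcsl_mu(rho1[i], rho2[i], d1, d2, cap, slope, m1, m2);
    out(i, 0) = m1; out(i, 1) = m2;
  }
  return out;
}

// apply the bond-shell kernel: out[re, z] = sum_e w_e * g[src_e, z + dz_e]
static void shell_apply(const double *g, double *out,
                        const IntegerVector &rec, const IntegerVector &src,
                        const IntegerVector &dzo, const NumericVector &w,
                        int nr, int nz) {
  std::fill(out, out + (size_t)nr * nz, 0.0);
  int ne = rec.size();
  for (int e = 0; e < ne; ++e) {
    int re = rec[e], rs = src[e], k = dzo[e];
    double we = w[e];
    int z0 = std::max(0, -k), z1 = std::min(nz, nz - k);
    for (int z = z0; z < z1; ++z)
      out[re + nr * z] += we * g[rs + nr * (z + k)];
  }
}

// mean-field attraction: U[re, z] += sum_{rs,k} K[re, rs, k] rho[rs, z+k-z0]
static void conv_apply(const NumericVector &K, int knz,
                       const std::vector<double> &rho, std::vector<double> &U,
                       int nr, int nz) {
  int z0 = (knz - 1) / 2;
  for (int k = 0; k < knz; ++k) {
    int off = k - z0;
    for (int rs = 0; rs < nr; ++rs) {
      for (int re = 0; re < nr; ++re) {
        double kv = K[re + nr * (rs + nr * k)];
        if (kv == 0.0) continue;
        int za = std::max(0, -off), zb = std::min(nz, nz - off);
        for (int z = za; z < zb; ++z)
          U[re + nr * z] += kv * rho[rs + nr * (z + off)];
      }
    }
  }
}

struct ChainResult {
  bool ok;
  double logQ;
};

// grafted freely-jointed-chain density from the propagator pair, normalized
// to n_chains * n_beads total beads
static ChainResult chain_density(const std::vector<double> &expw,
                                 std::vector<double> &rho,
                                 const IntegerVector &rec,
                                 const IntegerVector &src,
                                 const IntegerVector &dzo,
                                 const NumericVector &w,
                                 const NumericVector &vol, int nr, int nz,
                                 int n_beads, double n_chains,
                                 std::vector<double> &gf,
                                 std::vector<double> &gb,
                                 std::vector<double> &tmp) {
  ChainResult res = {false, 0.0};
  int nc = nr * nz;
  std::vector<double> lsf(n_beads, 0.0), lsb(n_beads, 0.0);
  // forward: bead 1 confined to the first z layer
  for (int i = 0; i < nc; ++i) gf[i] = 0.0;
  for (int r = 0; r < nr; ++r) gf[r] = expw[r];
  for (int s = 1; s < n_beads; ++s) {
    const double *gin = &gf[(size_t)(s - 1) * nc];
    shell_apply(gin, tmp.data(), rec, src, dzo, w, nr, nz);
    double m = 0.0;
    double *gout = &gf[(size_t)s * nc];
    for (int i = 0; i < nc; ++i) {
      gout[i] = expw[i] * tmp[i];
      if (gout[i] > m) m = gout[i];
    }
    if (m <= 0.0) return res;
    for (int i = 0; i < nc; ++i) gout[i] /= m;
    lsf[s] = lsf[s - 1] + std::log(m);
  }
  // backward: free end
  {
    double m = 0.0;
    for (int i = 0; i < nc; ++i) { gb[i] = expw[i]; if (gb[i] > m) m = gb[i]; }
    if (m <= 0.0) return res;
    for (int i = 0; i < nc; ++i) gb[i] /= m;
    lsb[0] = std::log(m);
  }
  for (int s = 1; s < n_beads; ++s) {
    const double *gin = &gb[(size_t)(s - 1) * nc];
    shell_apply(gin, tmp.data(), rec, src, dzo, w, nr, nz);
    double m = 0.0;
    double *gout = &gb[(size_t)s * nc];
    for (int i = 0; i < nc; ++i) {
      gout[i] = expw[i] * tmp[i];
      if (gout[i] > m) m = gout[i];
    }
    if (m <= 0.0) return res;
    for (int i = 0; i < nc; ++i) gout[i] /= m;
    lsb[s] = lsb[s - 1] + std::log(m);
  }
  // composition: rho ~ sum_s gf_s gb_{N+1-s} / expw, with log-scale shifts
  double M = -1e300;
  for (int s = 0; s < n_beads; ++s) {
    double t = lsf[s] + lsb[n_beads - 1 - s];
    if (t > M) M = t;
  }
  std::fill(rho.begin(), rho.end(), 0.0);
  for (int s = 0; s < n_beads; ++s) {
    double fac = std::exp(lsf[s] + lsb[n_beads - 1 - s] - M);
    if (fac < 1e-300) continue;
    const double *a = &gf[(size_t)s * nc];
    const double *b = &gb[(size_t)(n_beads - 1 - s) * nc];
    for (int i = 0; i < nc; ++i)
      if (expw[i] > 0.0) rho[i] += fac * a[i] * b[i] / expw[i];
  }
  double total = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int r = 0; r < nr; ++r) total += rho[r + nr * z] * vol[r];
  if (total <= 0.0) return res;
  double fac = n_chains * (double)n_beads / total;
  for (int i = 0; i < nc; ++i) rho[i] *= fac;
  res.ok = true;
  res.logQ = M;
  return res;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export(name = ".scf_solve")]]
List scf_solve(int nr, int nz,
               NumericVector vol, IntegerVector cmask,
               IntegerVector sk_rec, IntegerVector sk_src,
               IntegerVector sk_dz, NumericVector sk_w,
               NumericVector Kpp, int kpp_nz,
               NumericVector Kpc, int kpc_nz,
               int n_beads, double n_chains,
               bool has_colloid, double z_act,
               double d_p, double d_c, double phi_cap, double pen_slope,
               NumericMatrix wp_init, NumericMatrix wc_init,
               double tol, int max_iter,
               double mix_init, double mix_min, double mix_max) {
  int nc = nr * nz;
  std::vector<double> wp(wp_init.begin(), wp_init.end());
  std::vector<double> wc(wc_init.begin(), wc_init.end());
  std::vector<double> expwp(nc), rho_p(nc), rho_c(nc, 0.0);
  std::vector<double> mu_p(nc), mu_c(nc), up(nc), uc(nc);
  std::vector<double> gf((size_t)n_beads * nc), gb((size_t)n_beads * nc),
      tmp(nc);
  bool use_pp = false, use_pc = false;
  for (double v : Kpp) if (v != 0.0) { use_pp = true; break; }
  for (double v : Kpc) if (v != 0.0) { use_pc = true; break; }
  std::vector<double> res_hist;
  double mix = mix_init, prev_res = R_PosInf, res = R_PosInf;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    for (int i = 0; i < nc; ++i)
      expwp[i] = std::exp(-clampd(wp[i], -40.0, 40.0));
    ChainResult cr = chain_density(expwp, rho_p, sk_rec, sk_src, sk_dz, sk_w,
                                   vol, nr, nz, n_beads, n_chains, gf, gb,
                                   tmp);
    if (!cr.ok)
      stop("chain propagator vanished (fields too repulsive everywhere)");
    if (has_colloid) {
      for (int z = 0; z < nz; ++z)
        for (int r = 0; r < nr; ++r) {
          int i = r + nr * z;
          rho_c[i] = cmask[r] ?
            z_act * std::exp(-clampd(wc[i], -40.0, 40.0)) : 0.0;
        }
    }
    for (int i = 0; i < nc; ++i) {
      double m1, m2;
      bmcsl_mu(rho_p[i], rho_c[i], d_p, d_c, phi_cap, pen_slope, m1, m2);
      mu_p[i] = m1; mu_c[i] = m2;
    }
    std::fill(up.begin(), up.end(), 0.0);
    std::fill(uc.begin(), uc.end(), 0.0);
    if (use_pp) conv_apply(Kpp, kpp_nz, rho_p, up, nr, nz);
    if (use_pc && has_colloid) conv_apply(Kpc, kpc_nz, rho_c, up, nr, nz);
    if (use_pc && has_colloid) conv_apply(Kpc, kpc_nz, rho_p, uc, nr, nz);
    res = 0.0;
    for (int i = 0; i < nc; ++i) {
      double wn = clampd(mu_p[i] + up[i], -60.0, 120.0);
      double d = std::fabs(wn - wp[i]);
      if (d > res) res = d;
      wp[i] += mix * (wn - wp[i]);
    }
    if (has_colloid) {
      for (int z = 0; z < nz; ++z)
        for (int r = 0; r < nr; ++r) {
          if (!cmask[r]) continue;
          int i = r + nr * z;
          double wn = clampd(mu_c[i] + uc[i], -60.0, 120.0);
          double d = std::fabs(wn - wc[i]);
          if (d > res) res = d;
          wc[i] += mix * (wn - wc[i]);
        }
    }
    res_hist.push_back(res);
    if (res < tol) { converged = true; break; }
    if (res <= prev_res * 1.001) mix = std::min(mix * 1.04, mix_max);
    else mix = std::max(mix * 0.5, mix_min);
    prev_res = res;
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix rp(nr, nz), rc(nr, nz), wpo(nr, nz), wco(nr, nz);
  std::copy(rho_p.begin(), rho_p.end(), rp.begin());
  std::copy(rho_c.begin(), rho_c.end(), rc.begin());
  std::copy(wp.begin(), wp.end(), wpo.begin());
  std::copy(wc.begin(), wc.end(), wco.begin());
  return List::create(
      _["rho_p"] = rp, _["rho_c"] = rc, _["wp"] = wpo, _["wc"] = wco,
      _["converged"] = converged, _["iterations"] = std::min(it, max_iter),
      _["residual"] = res, _["res_hist"] = wrap(res_hist));
}
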