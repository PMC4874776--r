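// Metropolis Monte Carlo oracle: freely-jointed hard-sphere bead chains
// end-grafted in a cylinder, plus grand-canonical hard-sphere colloids with
// the same exponential-tail pair attractions as the mean-field solver.
// Brute-force O(n) energy evaluation per move; systems are small by design.
// Randomness comes from R's RNG so a set.seed() on the R side makes runs
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Vec3 { double x, y, z; };

struct McSystem {
  int n_chains, n_beads;
  double b, sig_p, sig_c, eps_pp, eps_pc, lambda, rcut_p, rcut_c;
  double R, H, Rc_col;          // R <= 0: no side wall
  bool z_periodic, bottom_wall, phantom, grafted;
  std::vector<Vec3> beads;      // chain-major
  std::vector<Vec3> cols;

  inline double dz_img(double dz) const {
    if (!z_periodic) return dz;
    if (dz > 0.5 * H) return dz - H;
    if (dz < -0.5 * H) return dz + H;
    return dz;
  }
  inline double dist2_bb(const Vec3 &a, const Vec3 &b2) const {
    double dx = a.x - b2.x, dy = a.y - b2.y, dz = a.z - b2.z;
    return dx * dx + dy * dy + dz * dz;
  }
  inline double dist2_bc(const Vec3 &a, const Vec3 &c) const {
    double dx = a.x - c.x, dy = a.y - c.y, dz = dz_img(a.z - c.z);
    return dx * dx + dy * dy + dz * dz;
  }
  inline double tail(double d, double sig, double eps) const {
    return -eps * std::exp(-(d - sig) / lambda);
  }
  // energy of bead (ci, bi) at position p against everything else;
  // returns +inf on hard overlap
  double bead_energy(int ci, int bi, const Vec3 &p) const {
    if (!phantom) {
      if (R > 0 && p.x * p.x + p.y * p.y >= R * R) return R_PosInf;
      if (bottom_wall && (p.z <= 0.0 || p.z >= H)) return R_PosInf;
    }
    if (phantom) return 0.0;
    double e = 0.0;
    double hc2 = sig_p * sig_p * (1.0 - 1e-9);
    double rc2 = rcut_p * rcut_p;
    int me = ci * n_beads + bi;
    for (int j = 0; j < (int)beads.size(); ++j) {
      if (j == me) continue;
      double d2 = dist2_bb(p, beads[j]);
      bool bonded = (j == me - 1 || j == me + 1) && j / n_beads == ci;
      if (!bonded && d2 < hc2) return R_PosInf;
      if (eps_pp != 0.0 && d2 < rc2)
        e += tail(std::sqrt(d2), sig_p, eps_pp);
    }
    double sig_bc = 0.5 * (sig_p + sig_c);
    double hcc2 = sig_bc * sig_bc * (1.0 - 1e-9);
    double rcc2 = (sig_bc + 8.0 * lambda) * (sig_bc + 8.0 * lambda);
    for (const Vec3 &c : cols) {
      double d2 = dist2_bc(p, c);
      if (d2 < hcc2) return R_PosInf;
      if (eps_pc != 0.0 && d2 < rcc2)
        e += tail(std::sqrt(d2), sig_bc, eps_pc);
    }
    return e;
  }
  // energy of a colloid at p against everything (excluding colloid `skip`)
  double colloid_energy(const Vec3 &p, int skip) const {
    if (Rc_col > 0 && p.x * p.x + p.y * p.y >= Rc_col * Rc_col)
      return R_PosInf;
    double e = 0.0;
    double sig_bc = 0.5 * (sig_p + sig_c);
    double hcb2 = sig_bc * sig_bc * (1.0 - 1e-9);
    double rcb2 = (sig_bc + 8.0 * lambda) * (sig_bc + 8.0 * lambda);
    for (const Vec3 &bd : beads) {
      double d2 = dist2_bc(bd, p);
      if (d2 < hcb2) return R_PosInf;
      if (eps_pc != 0.0 && d2 < rcb2)
        e += tail(std::sqrt(d2), sig_bc, eps_pc);
    }
    double hcc2 = sig_c * sig_c * (1.0 - 1e-9);
    for (int j = 0; j < (int)cols.size(); ++j) {
      if (j == skip) continue;
      double dx = p.x - cols[j].x, dy = p.y - cols[j].y;
      double dzv = dz_img(p.z - cols[j].z);
      if (dx * dx + dy * dy + dzv * dzv < hcc2) return R_PosInf;
      // no colloid-colloid attraction
    }
    return e;
  }
};

static inline Vec3 rand_sphere(double b) {
  double u = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - u * u));
  Vec3 v = {b * s * std::cos(phi), b * s * std::sin(phi), b * u};
  return v;
}

// rotate point p about the axis through a with direction u by angle th
static inline Vec3 rotate_about(const Vec3 &p, const Vec3 &a, const Vec3 &u,
                                double th) {
  double px = p.x - a.x, py = p.y - a.y, pz = p.z - a.z;
  double c = std::cos(th), s = std::sin(th);
  double dot = u.x * px + u.y * py + u.z * pz;
  Vec3 r;
  r.x = a.x + px * c + (u.y * pz - u.z * py) * s + u.x * dot * (1 - c);
  r.y = a.y + py * c + (u.z * px - u.x * pz) * s + u.y * dot * (1 - c);
  r.z = a.z + pz * c + (u.x * py - u.y * px) * s + u.z * dot * (1 - c);
  return r;
}

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(int n_chains, int n_beads, double b, double sig_c,
            double eps_pp, double eps_pc, double lambda,
            double R, double H, bool z_periodic, bool bottom_wall,
            bool phantom, NumericMatrix anchors,
            bool gc_colloids, double z_act,
            int n_equil, int n_sample, int sample_every,
            int nr, double dr, int nz, double dz) {
  RNGScope scope;
  McSystem S;
  S.n_chains = n_chains; S.n_beads = n_beads;
  S.b = b; S.sig_p = b; S.sig_c = sig_c;
  S.eps_pp = eps_pp; S.eps_pc = eps_pc; S.lambda = lambda;
  S.rcut_p = b + 8.0 * lambda;
  S.R = R; S.H = H;
  S.Rc_col = R > 0 ? R - 0.5 * sig_c : -1.0;
  S.z_periodic = z_periodic; S.bottom_wall = bottom_wall;
  S.phantom = phantom;
  S.beads.resize((size_t)n_chains * n_beads);

  // initial configuration: straight vertical rods from the anchors
  for (int ci = 0; ci < n_chains; ++ci) {
    double ax = anchors(ci, 0), ay = anchors(ci, 1);
    for (int bi = 0; bi < n_beads; ++bi) {
      Vec3 &p = S.beads[ci * n_beads + bi];
      p.x = ax; p.y = ay; p.z = 0.5 * b + bi * b;
    }
  }

  double acc_bead = 0, att_bead = 0, acc_col = 0, att_col = 0;
  double acc_exch = 0, att_exch = 0;
  std::vector<double> hist_p((size_t)std::max(1, nr * nz), 0.0);
  std::vector<double> hist_c((size_t)std::max(1, nr * nz), 0.0);
  std::vector<double> r2_samples, ncol_samples;
  int n_sampled = 0;
  double col_vol = R > 0 ?
    M_PI * S.Rc_col * S.Rc_col * H : 0.0;

  int total_sweeps = n_equil + n_sample;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    // chain moves: crankshaft for interior beads, sphere resample for ends
    for (int ci = 0; ci < n_chains; ++ci) {
      for (int bi = 1; bi < n_beads; ++bi) {
        int idx = ci * n_beads + bi;
        Vec3 old = S.beads[idx];
        Vec3 prop;
        if (bi == n_beads - 1) {
          Vec3 prev = S.beads[idx - 1];
          Vec3 d = rand_sphere(b);
          prop.x = prev.x + d.x; prop.y = prev.y + d.y; prop.z = prev.z + d.z;
        } else {
          Vec3 a = S.beads[idx - 1], c = S.beads[idx + 1];
          double ux = c.x - a.x, uy = c.y - a.y, uz = c.z - a.z;
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          if (nrm < 1e-9) {
            Vec3 d = rand_sphere(b);
            prop.x = a.x + d.x; prop.y = a.y + d.y; prop.z = a.z + d.z;
          } else {
            Vec3 u = {ux / nrm, uy / nrm, uz / nrm};
            prop = rotate_about(old, a, u, 2.0 * M_PI * unif_rand());
          }
        }
        att_bead += 1;
        double e_old = S.phantom ? 0.0 : S.bead_energy(ci, bi, old);
        double e_new = S.bead_energy(ci, bi, prop);
        if (S.phantom) {
          // walls may still apply in phantom mode when bottom_wall is set
          if (bottom_wall && (prop.z <= 0.0 || prop.z >= H)) continue;
          if (R > 0 && prop.x * prop.x + prop.y * prop.y >= R * R) continue;
          S.beads[idx] = prop; acc_bead += 1; continue;
        }
        if (std::isfinite(e_new) &&
            (e_new <= e_old || unif_rand() < std::exp(e_old - e_new))) {
          S.beads[idx] = prop; acc_bead += 1;
        }
      }
    }
    // colloid translation + grand-canonical exchange
    if (gc_colloids) {
      int n_try = std::max(6, (int)S.cols.size());
      for (int t = 0; t < n_try; ++t) {
        if (!S.cols.empty()) {
          att_col += 1;
          int j = (int)std::floor(unif_rand() * S.cols.size());
          Vec3 old = S.cols[j], prop = old;
          prop.x += (unif_rand() - 0.5) * 2.0;
          prop.y += (unif_rand() - 0.5) * 2.0;
          prop.z += (unif_rand() - 0.5) * 2.0;
          if (S.z_periodic) {
            prop.z -= H * std::floor(prop.z / H);
          } else if (prop.z <= 0.0 || prop.z >= H) {
            continue;
          }
          double e_old = S.colloid_energy(old, j);
          double e_new = S.colloid_energy(prop, j);
          if (std::isfinite(e_new) &&
              (e_new <= e_old || unif_rand() < std::exp(e_old - e_new))) {
            S.cols[j] = prop; acc_col += 1;
          }
        }
        att_exch += 1;
        if (unif_rand() < 0.5) {  // insertion
          Vec3 p;
          double rr = S.Rc_col * std::sqrt(unif_rand());
          double ph = 2.0 * M_PI * unif_rand();
          p.x = rr * std::cos(ph); p.y = rr * std::sin(ph);
          p.z = unif_rand() * H;
          double e = S.colloid_energy(p, -1);
          if (std::isfinite(e)) {
            double arg = z_act * col_vol / (S.cols.size() + 1.0) *
              std::exp(-e);
            if (unif_rand() < arg) { S.cols.push_back(p); acc_exch += 1; }
          }
        } else if (!S.cols.empty()) {  // deletion
          int j = (int)std::floor(unif_rand() * S.cols.size());
          double e = S.colloid_energy(S.cols[j], j);
          double arg = S.cols.size() / (z_act * col_vol) * std::exp(e);
          if (std::isfinite(arg) && unif_rand() < arg) {
            S.cols[j] = S.cols.back(); S.cols.pop_back(); acc_exch += 1;
          }
        }
      }
    }
    // sampling
    if (sweep >= n_equil && (sweep - n_equil) % sample_every == 0) {
      n_sampled += 1;
      if (nr > 0 && nz > 0) {
        for (const Vec3 &p : S.beads) {
          int ir = (int)(std::sqrt(p.x * p.x + p.y * p.y) / dr);
          int iz = (int)(p.z / dz);
          if (ir >= 0 && ir < nr && iz >= 0 && iz < nz)
            hist_p[ir + nr * iz] += 1;
        }
        for (const Vec3 &p : S.cols) {
          int ir = (int)(std::sqrt(p.x * p.x + p.y * p.y) / dr);
          int iz = (int)(p.z / dz);
          if (ir >= 0 && ir < nr && iz >= 0 && iz < nz)
            hist_c[ir + nr * iz] += 1;
        }
      }
      double r2 = 0.0;
      for (int ci = 0; ci < n_chains; ++ci) {
        const Vec3 &a = S.beads[ci * n_beads];
        const Vec3 &e = S.beads[ci * n_beads + n_beads - 1];
        double dx = e.x - a.x, dy = e.y - a.y, dzv = e.z - a.z;
        r2 += dx * dx + dy * dy + dzv * dzv;
      }
      r2_samples.push_back(r2 / n_chains);
      ncol_samples.push_back((double)S.cols.size());
    }
    if (sweep % 500 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix hp(nr > 0 ? nr : 1, nz > 0 ? nz : 1);
  NumericMatrix hc(nr > 0 ? nr : 1, nz > 0 ? nz : 1);
  if (n_sampled > 0 && nr > 0 && nz > 0) {
    for (int i = 0; i < nr * nz; ++i) {
      hp[i] = hist_p[i] / n_sampled;
      hc[i] = hist_c[i] / n_sampled;
    }
  }
  return List::create(
      _["count_p"] = hp, _["count_c"] = hc,
      _["r2_samples"] = wrap(r2_samples),
      _["ncol_samples"] = wrap(ncol_samples),
      _["acc_bead"] = att_bead > 0 ? acc_bead / att_bead : NA_REAL,
      _["acc_colloid"] = att_col > 0 ? acc_col / att_col : NA_REAL,
      _["acc_exchange"] = att_exch > 0 ? acc_exch / att_exch : NA_REAL,
      _["n_sampled"] = n_sampled, _["colloid_volume"] = col_vol);
}
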