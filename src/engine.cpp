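// Bead-spring MD engine: WCA + square-well + cosine-smoothed attraction,
// stiff harmonic bonds, periodic cubic box.  Ensembles: NVE, NVT (Nose-Hoover
// chains), NPT (MTK isotropic barostat), Langevin.  All quantities in reduced
// units (epsilon = sigma = m = 1).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct PairParams {
  double rmin2, rcut2, alpha, beta;
  double k_spring, l0;
  // lambda by species class pair: [0][0] matrix-matrix, [1][1] emb-emb, cross
  double lam[2][2];
};

// energy and f/r (force-over-r, force = fr * (ri - rj)) for one non-bonded pair
inline void pair_ef(double r2, double lam, const PairParams &p,
                    double &e, double &fr) {
  if (r2 >= p.rcut2) { e = 0.0; fr = 0.0; return; }
  if (r2 <= p.rmin2) {
    double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
    e  = 4.0 * (ir6 * ir6 - ir6) + 1.0 - lam;   // shifted WCA + square well
    fr = (48.0 * ir6 * ir6 - 24.0 * ir6) * ir2; // -dV/dr / r
  } else {
    double u = p.alpha * r2 + p.beta;
    e  = 0.5 * lam * (std::cos(u) - 1.0);
    fr = lam * p.alpha * std::sin(u);           // -dV/dr / r (negative: attraction)
  }
}

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against floor rounding
  return x;
}

// valid for |dx| < 1.5 L; positions are kept wrapped so dx is in (-L, L)
inline double min_image(double dx, double L) {
  if (dx > 0.5 * L) dx -= L;
  else if (dx < -0.5 * L) dx += L;
  return dx;
}

struct System {
  int N;
  std::vector<double> x, y, z;    // wrapped positions
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  double L;
  std::vector<int> cls;           // species class 0 = matrix, 1 = embedded
  std::vector<int> b1, b2;        // bond index pairs (0-based)
  std::vector<std::vector<int>> excl; // sorted bonded partners per particle
  PairParams pp;
  bool ideal;                     // no interactions at all (ideal gas)
  double U, W;                    // potential energy, virial sum r.f

  bool excluded(int i, int j) const {
    const std::vector<int> &e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }

  void accumulate_pair(int i, int j) {
    double dx = min_image(x[i] - x[j], L);
    double dy = min_image(y[i] - y[j], L);
    double dz = min_image(z[i] - z[j], L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pp.rcut2) return;
    if (excluded(i, j)) return;
    double lam = pp.lam[cls[i]][cls[j]];
    double e, fr;
    pair_ef(r2, lam, pp, e, fr);
    U += e;
    W += fr * r2;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }

  void compute_forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    U = 0.0; W = 0.0;
    if (ideal) return;

    double rcut = std::sqrt(pp.rcut2);
    int nc = (int)std::floor(L / rcut);
    // a very dilute system in a large box (e.g. an isolated chain) would
    // allocate a huge, mostly empty grid each step; fall back to the direct
    // sum when the grid dwarfs the particle count
    bool use_cells = nc >= 3 &&
      (double)nc * nc * nc <= std::max(10000.0, 30.0 * N);
    if (use_cells) {
      // linked-cell list, half neighbor stencil
      double cw = L / nc;
      int ncell = nc * nc * nc;
      std::vector<int> head(ncell, -1), nxt(N, -1);
      for (int i = 0; i < N; ++i) {
        int cx = (int)(x[i] / cw), cy = (int)(y[i] / cw), cz = (int)(z[i] / cw);
        if (cx >= nc) cx = nc - 1; if (cy >= nc) cy = nc - 1; if (cz >= nc) cz = nc - 1;
        int c = (cx * nc + cy) * nc + cz;
        nxt[i] = head[c]; head[c] = i;
      }
      static const int st[13][3] = {
        {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
        {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
      for (int cx = 0; cx < nc; ++cx)
        for (int cy = 0; cy < nc; ++cy)
          for (int cz = 0; cz < nc; ++cz) {
            int c = (cx * nc + cy) * nc + cz;
            // within-cell pairs
            for (int i = head[c]; i != -1; i = nxt[i])
              for (int j = nxt[i]; j != -1; j = nxt[j])
                accumulate_pair(i, j);
            // neighbor cells
            for (int s = 0; s < 13; ++s) {
              int ax = (cx + st[s][0] + nc) % nc;
              int ay = (cy + st[s][1] + nc) % nc;
              int az = (cz + st[s][2] + nc) % nc;
              int c2 = (ax * nc + ay) * nc + az;
              if (c2 == c) continue; // tiny boxes: stencil can wrap onto self
              for (int i = head[c]; i != -1; i = nxt[i])
                for (int j = head[c2]; j != -1; j = nxt[j])
                  accumulate_pair(i, j);
            }
          }
    } else {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j)
          accumulate_pair(i, j);
    }

    // bonds (minimum image: bonds through periodic boundaries are permitted)
    for (size_t b = 0; b < b1.size(); ++b) {
      int i = b1[b], j = b2[b];
      double dx = min_image(x[i] - x[j], L);
      double dy = min_image(y[i] - y[j], L);
      double dz = min_image(z[i] - z[j], L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - pp.l0;
      U += pp.k_spring * dr * dr;                 // k (r - l0)^2, no 1/2
      double fr = -2.0 * pp.k_spring * dr / r;    // -dV/dr / r
      W += fr * r * r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }

  double kinetic2() const { // 2 * kinetic energy (m = 1)
    double s = 0.0;
    for (int i = 0; i < N; ++i)
      s += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    return s;
  }

  void wrap_all() {
    for (int i = 0; i < N; ++i) {
      x[i] = wrap(x[i], L); y[i] = wrap(y[i], L); z[i] = wrap(z[i], L);
    }
  }
};

// Nose-Hoover chain (length 3), single Trotter sweep per half step
struct NHChain {
  double vxi[3] = {0, 0, 0};
  double Q[3];
  double Nf, kT;
  void init(double Nf_, double kT_, double tau) {
    Nf = Nf_; kT = kT_;
    Q[0] = Nf * kT * tau * tau;
    Q[1] = Q[2] = kT * tau * tau;
  }
  // K2 = 2*K of coupled degrees of freedom; returns velocity scale factor
  double half_step(double K2, double dt2) {
    double dt4 = dt2 / 2.0, dt8 = dt2 / 4.0;
    double G2 = (Q[1] * vxi[1] * vxi[1] - kT) / Q[2];
    vxi[2] += G2 * dt4;
    double G1 = (Q[0] * vxi[0] * vxi[0] - kT) / Q[1];
    vxi[1] *= std::exp(-vxi[2] * dt8);
    vxi[1] += G1 * dt4;
    vxi[1] *= std::exp(-vxi[2] * dt8);
    double G0 = (K2 - Nf * kT) / Q[0];
    vxi[0] *= std::exp(-vxi[1] * dt8);
    vxi[0] += G0 * dt4;
    vxi[0] *= std::exp(-vxi[1] * dt8);
    double scale = std::exp(-vxi[0] * dt2);
    K2 *= scale * scale;
    vxi[0] *= std::exp(-vxi[1] * dt8);
    G0 = (K2 - Nf * kT) / Q[0];
    vxi[0] += G0 * dt4;
    vxi[0] *= std::exp(-vxi[1] * dt8);
    vxi[1] *= std::exp(-vxi[2] * dt8);
    G1 = (Q[0] * vxi[0] * vxi[0] - kT) / Q[1];
    vxi[1] += G1 * dt4;
    vxi[1] *= std::exp(-vxi[2] * dt8);
    G2 = (Q[1] * vxi[1] * vxi[1] - kT) / Q[2];
    vxi[2] += G2 * dt4;
    return scale;
  }
};

inline double sinhc(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 + x * x / 6.0;
  return std::sinh(x) / x;
}

} // namespace

// Force/energy/virial evaluation on a fixed configuration.
// pos: N x 3; bonds: B x 2 (1-based); cls: 0/1 species class; lambdas: lam_mtx,
// lam_emb, lam_cr; direct = TRUE forces the O(N^2) path.
// [[Rcpp::export(name = ".forces_cpp")]]
List forces_cpp(NumericMatrix pos, double box, IntegerMatrix bonds,
                IntegerVector cls, List par, bool direct = false) {
  System s;
  s.N = pos.nrow();
  s.L = box;
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.assign(s.N, 0); s.vy.assign(s.N, 0); s.vz.assign(s.N, 0);
  s.fx.resize(s.N); s.fy.resize(s.N); s.fz.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = wrap(pos(i, 0), box);
    s.y[i] = wrap(pos(i, 1), box);
    s.z[i] = wrap(pos(i, 2), box);
  }
  s.cls.assign(cls.begin(), cls.end());
  s.excl.assign(s.N, {});
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    s.b1.push_back(i); s.b2.push_back(j);
    s.excl[i].push_back(j); s.excl[j].push_back(i);
  }
  for (auto &e : s.excl) std::sort(e.begin(), e.end());
  double rmin = par["r_min"], rcut = par["r_cut"];
  s.pp.rmin2 = rmin * rmin; s.pp.rcut2 = rcut * rcut;
  s.pp.alpha = par["alpha"]; s.pp.beta = par["beta"];
  s.pp.k_spring = par["spring_k"]; s.pp.l0 = par["bond_l0"];
  s.pp.lam[0][0] = par["lambda_mtx"];
  s.pp.lam[1][1] = par["lambda_emb"];
  s.pp.lam[0][1] = s.pp.lam[1][0] = par["lambda_cr"];
  s.ideal = false;

  if (direct) {
    std::fill(s.fx.begin(), s.fx.end(), 0.0);
    std::fill(s.fy.begin(), s.fy.end(), 0.0);
    std::fill(s.fz.begin(), s.fz.end(), 0.0);
    s.U = 0; s.W = 0;
    for (int i = 0; i < s.N; ++i)
      for (int j = i + 1; j < s.N; ++j)
        s.accumulate_pair(i, j);
    for (size_t b = 0; b < s.b1.size(); ++b) {
      int i = s.b1[b], j = s.b2[b];
      double dx = min_image(s.x[i] - s.x[j], s.L);
      double dy = min_image(s.y[i] - s.y[j], s.L);
      double dz = min_image(s.z[i] - s.z[j], s.L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - s.pp.l0;
      s.U += s.pp.k_spring * dr * dr;
      double fr = -2.0 * s.pp.k_spring * dr / r;
      s.W += fr * r * r;
      s.fx[i] += fr * dx; s.fy[i] += fr * dy; s.fz[i] += fr * dz;
      s.fx[j] -= fr * dx; s.fy[j] -= fr * dy; s.fz[j] -= fr * dz;
    }
  } else {
    s.compute_forces();
  }

  NumericMatrix F(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    F(i, 0) = s.fx[i]; F(i, 1) = s.fy[i]; F(i, 2) = s.fz[i];
  }
  return List::create(_["forces"] = F, _["energy"] = s.U, _["virial"] = s.W);
}

// Integrate the system.  ensemble: 0 = NVE, 1 = NVT (NHC), 2 = NPT (NHC+MTK),
// 3 = Langevin (BAOAB).  Returns per-sample scalars and the final state.
// [[Rcpp::export(name = ".md_run_cpp")]]
List md_run_cpp(NumericMatrix pos, NumericMatrix vel, double box,
                IntegerMatrix bonds, IntegerVector cls, List par,
                int ensemble, double target_pressure,
                int nsteps, int sample_every,
                double tau_T, double tau_P, double gamma,
                int seed, bool ideal, bool record_rg) {
  System s;
  s.N = pos.nrow();
  s.L = box;
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.resize(s.N); s.vy.resize(s.N); s.vz.resize(s.N);
  s.fx.resize(s.N); s.fy.resize(s.N); s.fz.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = wrap(pos(i, 0), box);
    s.y[i] = wrap(pos(i, 1), box);
    s.z[i] = wrap(pos(i, 2), box);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
  }
  s.cls.assign(cls.begin(), cls.end());
  s.excl.assign(s.N, {});
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    s.b1.push_back(i); s.b2.push_back(j);
    s.excl[i].push_back(j); s.excl[j].push_back(i);
  }
  for (auto &e : s.excl) std::sort(e.begin(), e.end());

  double rmin = par["r_min"], rcut = par["r_cut"];
  s.pp.rmin2 = rmin * rmin; s.pp.rcut2 = rcut * rcut;
  s.pp.alpha = par["alpha"]; s.pp.beta = par["beta"];
  s.pp.k_spring = par["spring_k"]; s.pp.l0 = par["bond_l0"];
  s.pp.lam[0][0] = par["lambda_mtx"];
  s.pp.lam[1][1] = par["lambda_emb"];
  s.pp.lam[0][1] = s.pp.lam[1][0] = par["lambda_cr"];
  s.ideal = ideal;

  double kT = par["kT"], dt = par["dt"];
  double dt2 = dt / 2.0, dt4 = dt / 4.0;

  // degrees of freedom: net momentum is conserved (and zeroed at init) for
  // NVE/NVT/NPT; Langevin does not conserve momentum
  double Nf = (ensemble == 3) ? 3.0 * s.N : 3.0 * s.N - 3.0;

  NHChain therm, baro_therm;
  therm.init(Nf, kT, tau_T);
  baro_therm.init(1.0, kT, tau_P);
  double Wb = (Nf + 3.0) * kT * tau_P * tau_P; // MTK barostat mass
  double veps = 0.0;                           // barostat velocity

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double lg_c1 = std::exp(-gamma * dt), lg_c2 = std::sqrt(kT * (1.0 - lg_c1 * lg_c1));

  s.compute_forces();

  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericVector o_step(nsamp), o_V(nsamp), o_T(nsamp), o_W(nsamp), o_P(nsamp),
      o_U(nsamp), o_Rg2(record_rg ? nsamp : 0);
  int isamp = 0;

  for (int step = 1; step <= nsteps; ++step) {
    if (ensemble == 0 || ensemble == 1) {
      if (ensemble == 1) {
        double sc = therm.half_step(s.kinetic2(), dt2);
        for (int i = 0; i < s.N; ++i) { s.vx[i] *= sc; s.vy[i] *= sc; s.vz[i] *= sc; }
      }
      for (int i = 0; i < s.N; ++i) {
        s.vx[i] += dt2 * s.fx[i]; s.vy[i] += dt2 * s.fy[i]; s.vz[i] += dt2 * s.fz[i];
        if (std::fabs(dt * s.vx[i]) > 0.5 * s.L ||
            std::fabs(dt * s.vy[i]) > 0.5 * s.L ||
            std::fabs(dt * s.vz[i]) > 0.5 * s.L)
          stop("integration failure (single-step displacement exceeds half the box) at step %d", step);
        s.x[i] += dt * s.vx[i]; s.y[i] += dt * s.vy[i]; s.z[i] += dt * s.vz[i];
      }
      s.wrap_all();
      s.compute_forces();
      for (int i = 0; i < s.N; ++i) {
        s.vx[i] += dt2 * s.fx[i]; s.vy[i] += dt2 * s.fy[i]; s.vz[i] += dt2 * s.fz[i];
      }
      if (ensemble == 1) {
        double sc = therm.half_step(s.kinetic2(), dt2);
        for (int i = 0; i < s.N; ++i) { s.vx[i] *= sc; s.vy[i] *= sc; s.vz[i] *= sc; }
      }
    } else if (ensemble == 3) { // Langevin BAOAB
      for (int i = 0; i < s.N; ++i) {
        s.vx[i] += dt2 * s.fx[i]; s.vy[i] += dt2 * s.fy[i]; s.vz[i] += dt2 * s.fz[i];
        s.x[i] += dt2 * s.vx[i]; s.y[i] += dt2 * s.vy[i]; s.z[i] += dt2 * s.vz[i];
        s.vx[i] = lg_c1 * s.vx[i] + lg_c2 * gauss(rng);
        s.vy[i] = lg_c1 * s.vy[i] + lg_c2 * gauss(rng);
        s.vz[i] = lg_c1 * s.vz[i] + lg_c2 * gauss(rng);
        s.x[i] += dt2 * s.vx[i]; s.y[i] += dt2 * s.vy[i]; s.z[i] += dt2 * s.vz[i];
      }
      s.wrap_all();
      s.compute_forces();
      for (int i = 0; i < s.N; ++i) {
        s.vx[i] += dt2 * s.fx[i]; s.vy[i] += dt2 * s.fy[i]; s.vz[i] += dt2 * s.fz[i];
      }
    } else { // NPT, MTK isotropic
      double V = s.L * s.L * s.L;
      double K2 = s.kinetic2();
      // thermostat barostat velocity, then particles
      {
        double sc = baro_therm.half_step(Wb * veps * veps, dt2);
        veps *= sc;
        sc = therm.half_step(K2, dt2);
        for (int i = 0; i < s.N; ++i) { s.vx[i] *= sc; s.vy[i] *= sc; s.vz[i] *= sc; }
        K2 *= sc * sc;
      }
      double Pint = (K2 + s.W) / (3.0 * V);
      double Geps = (3.0 * V * (Pint - target_pressure) + (3.0 / Nf) * K2) / Wb;
      veps += dt2 * Geps;
      {
        double a = veps * (1.0 + 3.0 / Nf);
        double e1 = std::exp(-a * dt2);
        double e2 = std::exp(-a * dt4) * sinhc(a * dt4) * dt2;
        for (int i = 0; i < s.N; ++i) {
          s.vx[i] = s.vx[i] * e1 + s.fx[i] * e2;
          s.vy[i] = s.vy[i] * e1 + s.fy[i] * e2;
          s.vz[i] = s.vz[i] * e1 + s.fz[i] * e2;
        }
      }
      {
        double b = veps;
        double e1 = std::exp(b * dt);
        double e2 = std::exp(b * dt2) * sinhc(b * dt2) * dt;
        for (int i = 0; i < s.N; ++i) {
          s.x[i] = s.x[i] * e1 + s.vx[i] * e2;
          s.y[i] = s.y[i] * e1 + s.vy[i] * e2;
          s.z[i] = s.z[i] * e1 + s.vz[i] * e2;
        }
        s.L *= e1;
      }
      s.wrap_all();
      s.compute_forces();
      {
        double a = veps * (1.0 + 3.0 / Nf);
        double e1 = std::exp(-a * dt2);
        double e2 = std::exp(-a * dt4) * sinhc(a * dt4) * dt2;
        for (int i = 0; i < s.N; ++i) {
          s.vx[i] = s.vx[i] * e1 + s.fx[i] * e2;
          s.vy[i] = s.vy[i] * e1 + s.fy[i] * e2;
          s.vz[i] = s.vz[i] * e1 + s.fz[i] * e2;
        }
      }
      V = s.L * s.L * s.L;
      K2 = s.kinetic2();
      Pint = (K2 + s.W) / (3.0 * V);
      Geps = (3.0 * V * (Pint - target_pressure) + (3.0 / Nf) * K2) / Wb;
      veps += dt2 * Geps;
      {
        double sc = therm.half_step(K2, dt2);
        for (int i = 0; i < s.N; ++i) { s.vx[i] *= sc; s.vy[i] *= sc; s.vz[i] *= sc; }
        sc = baro_therm.half_step(Wb * veps * veps, dt2);
        veps *= sc;
      }
    }

    if ((step & 0xFF) == 0) {
      // blow-up guard
      for (int i = 0; i < s.N; ++i)
        if (!std::isfinite(s.x[i]) || !std::isfinite(s.vx[i]))
          stop("integration failure (non-finite coordinate) at step %d", step);
      Rcpp::checkUserInterrupt();
    }

    if (sample_every > 0 && step % sample_every == 0 && isamp < nsamp) {
      double V = s.L * s.L * s.L;
      double K2 = s.kinetic2();
      o_step[isamp] = step;
      o_V[isamp] = V;
      o_T[isamp] = K2 / Nf;
      o_W[isamp] = s.W;
      o_U[isamp] = s.U;
      o_P[isamp] = (K2 + s.W) / (3.0 * V);
      if (record_rg) {
        // radius of gyration of the whole system, unwrapped via minimum-image
        // walk from particle 0 (valid for a single molecule smaller than L/2
        // per bond step; used for isolated-chain runs)
        double cx = 0, cy = 0, cz = 0;
        std::vector<double> ux(s.N), uy(s.N), uz(s.N);
        ux[0] = s.x[0]; uy[0] = s.y[0]; uz[0] = s.z[0];
        for (int i = 1; i < s.N; ++i) {
          ux[i] = ux[i - 1] + min_image(s.x[i] - s.x[i - 1], s.L);
          uy[i] = uy[i - 1] + min_image(s.y[i] - s.y[i - 1], s.L);
          uz[i] = uz[i - 1] + min_image(s.z[i] - s.z[i - 1], s.L);
        }
        for (int i = 0; i < s.N; ++i) { cx += ux[i]; cy += uy[i]; cz += uz[i]; }
        cx /= s.N; cy /= s.N; cz /= s.N;
        double rg2 = 0;
        for (int i = 0; i < s.N; ++i) {
          double dx = ux[i] - cx, dy = uy[i] - cy, dz = uz[i] - cz;
          rg2 += dx * dx + dy * dy + dz * dz;
        }
        o_Rg2[isamp] = rg2 / s.N;
      }
      ++isamp;
    }
  }

  NumericMatrix P(s.N, 3), Vl(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    P(i, 0) = s.x[i]; P(i, 1) = s.y[i]; P(i, 2) = s.z[i];
    Vl(i, 0) = s.vx[i]; Vl(i, 1) = s.vy[i]; Vl(i, 2) = s.vz[i];
  }
  DataFrame samples = record_rg
    ? DataFrame::create(_["step"] = o_step, _["V"] = o_V, _["T_inst"] = o_T,
                        _["W"] = o_W, _["U"] = o_U, _["P_inst"] = o_P,
                        _["Rg2"] = o_Rg2)
    : DataFrame::create(_["step"] = o_step, _["V"] = o_V, _["T_inst"] = o_T,
                        _["W"] = o_W, _["U"] = o_U, _["P_inst"] = o_P);
  return List::create(_["positions"] = P, _["velocities"] = Vl,
                      _["box_length"] = s.L, _["samples"] = samples);
}

// Single-chain Monte Carlo sampler: Metropolis single-bead displacements
// (sampling bond-length fluctuations) alternated with pivot rotations of the
// chain tail (decorrelating the global size in O(1) moves, where dynamics
// needs a Rouse time).  Exact canonical sampling of the same Hamiltonian as
// the MD engine; used for solvent-quality calibration where near-theta
// chains have prohibitive MD autocorrelation times.
// [[Rcpp::export(name = ".chain_rg_mc_cpp")]]
NumericVector chain_rg_mc_cpp(int N, double lambda, List par, int n_sweeps,
                              int burn_sweeps, int seed,
                              double bead_step = 0.03) {
  PairParams pp;
  double rmin = par["r_min"], rcut = par["r_cut"];
  pp.rmin2 = rmin * rmin; pp.rcut2 = rcut * rcut;
  pp.alpha = par["alpha"]; pp.beta = par["beta"];
  pp.k_spring = par["spring_k"]; pp.l0 = par["bond_l0"];
  double kT = par["kT"];

  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; ++i) { x[i] = i * pp.l0; y[i] = 0; z[i] = 0; }

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  auto nb_e = [&](double r2) {
    if (r2 >= pp.rcut2) return 0.0;
    double e, fr;
    pair_ef(r2, lambda, pp, e, fr);
    return e;
  };
  auto bond_e = [&](double r2) {
    double dr = std::sqrt(r2) - pp.l0;
    return pp.k_spring * dr * dr;
  };
  auto d2 = [&](double ax, double ay, double az, double bx, double by,
                double bz) {
    double dx = ax - bx, dy = ay - by, dz = az - bz;
    return dx * dx + dy * dy + dz * dz;
  };

  int total = burn_sweeps + n_sweeps;
  NumericVector rg2(n_sweeps);
  for (int s = 0; s < total; ++s) {
    // single-bead displacements
    for (int m = 0; m < N; ++m) {
      int i = (int)(unif(rng) * N);
      if (i >= N) i = N - 1;
      double nx = x[i] + bead_step * (2 * unif(rng) - 1);
      double ny = y[i] + bead_step * (2 * unif(rng) - 1);
      double nz = z[i] + bead_step * (2 * unif(rng) - 1);
      double dE = 0;
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double r2o = d2(x[i], y[i], z[i], x[j], y[j], z[j]);
        double r2n = d2(nx, ny, nz, x[j], y[j], z[j]);
        if (std::abs(j - i) == 1) dE += bond_e(r2n) - bond_e(r2o);
        else dE += nb_e(r2n) - nb_e(r2o);
      }
      if (dE < 0 || unif(rng) < std::exp(-dE / kT)) {
        x[i] = nx; y[i] = ny; z[i] = nz;
      }
    }
    // pivot rotations
    for (int m = 0; m < 2; ++m) {
      int k = 1 + (int)(unif(rng) * (N - 2));
      if (k > N - 2) k = N - 2;
      double ux = gauss(rng), uy = gauss(rng), uz = gauss(rng);
      double un = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= un; uy /= un; uz /= un;
      double th = 2 * M_PI * unif(rng), ct = std::cos(th), st = std::sin(th);
      std::vector<double> tx(N - 1 - k), ty(N - 1 - k), tz(N - 1 - k);
      for (int j = k + 1; j < N; ++j) {
        double px = x[j] - x[k], py = y[j] - y[k], pz = z[j] - z[k];
        double dot = px * ux + py * uy + pz * uz;
        // Rodrigues rotation about axis u through bead k
        double cx = uy * pz - uz * py, cy = uz * px - ux * pz,
               cz = ux * py - uy * px;
        tx[j - k - 1] = x[k] + px * ct + cx * st + ux * dot * (1 - ct);
        ty[j - k - 1] = y[k] + py * ct + cy * st + uy * dot * (1 - ct);
        tz[j - k - 1] = z[k] + pz * ct + cz * st + uz * dot * (1 - ct);
      }
      // only head-tail non-bonded cross terms change (the k,k+1 bond length
      // is preserved by the rotation)
      double dE = 0;
      for (int i2 = 0; i2 <= k; ++i2)
        for (int j = k + 1; j < N; ++j) {
          if (i2 == k && j == k + 1) continue;
          double r2o = d2(x[i2], y[i2], z[i2], x[j], y[j], z[j]);
          double r2n = d2(x[i2], y[i2], z[i2], tx[j - k - 1], ty[j - k - 1],
                          tz[j - k - 1]);
          dE += nb_e(r2n) - nb_e(r2o);
        }
      if (dE < 0 || unif(rng) < std::exp(-dE / kT)) {
        for (int j = k + 1; j < N; ++j) {
          x[j] = tx[j - k - 1]; y[j] = ty[j - k - 1]; z[j] = tz[j - k - 1];
        }
      }
    }
    if (s >= burn_sweeps) {
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < N; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
      cx /= N; cy /= N; cz /= N;
      double r = 0;
      for (int i = 0; i < N; ++i)
        r += d2(x[i], y[i], z[i], cx, cy, cz);
      rg2[s - burn_sweeps] = r / N;
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return rg2;
}
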