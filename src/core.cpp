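// Core kernels: pair/bond/angle/active forces with virial accumulation,
// overdamped Euler-Maruyama integration with a counter-based RNG, soft
// push-off repulsion, and double-bridging bond-swap Monte Carlo.
// Beads are assumed ordered by (chain, rank); bonds join consecutive rows
// of the same chain. All pair vectors use the minimum-image convention.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <sstream>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// splitmix64 finalizer; streams are keyed by (seed, step, bead) so that a
// trajectory is reproducible independent of evaluation order.
static inline uint64_t sm64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline void gauss3(uint64_t seed, uint64_t step, uint64_t bead,
                          double out[3]) {
  uint64_t base = sm64(seed ^ (step * 0xA24BAED4963EE407ULL) ^
                       (bead * 0x9FB21C651E98DF25ULL));
  double u1 = u01(sm64(base ^ 1ULL));
  double u2 = u01(sm64(base ^ 2ULL));
  double u3 = u01(sm64(base ^ 3ULL));
  double u4 = u01(sm64(base ^ 4ULL));
  double r1 = std::sqrt(-2.0 * std::log(u1));
  double r2 = std::sqrt(-2.0 * std::log(u3));
  out[0] = r1 * std::cos(2.0 * M_PI * u2);
  out[1] = r1 * std::sin(2.0 * M_PI * u2);
  out[2] = r2 * std::cos(2.0 * M_PI * u4);
}

static inline double mc_u01(uint64_t seed, uint64_t ctr, uint64_t tag) {
  return u01(sm64(seed ^ (ctr * 0xD6E8FEB86659FD93ULL) ^
                  (tag * 0xCA5A826395121157ULL)));
}

// ---------------------------------------------------------- geometry ----
static inline double mi(double d, double box) {
  return d - box * std::round(d / box);
}

// ------------------------------------------------------------ params ----
struct FFPar {
  double box;
  double eps_wca, sigma;
  double kf, R0;          // FENE spring constant (kBT/sigma^2) and max length
  double kappa;
  double Fp;
  bool wca_on;
  bool soft_on;           // capped soft-core repulsion replaces WCA
  double softA;           // soft-core amplitude
  bool active_virial;     // include tangential terms in the virial
  bool active_raw;        // unnormalized tangent sum (sensitivity variant)
};

static FFPar par_from_list(const List& par) {
  FFPar P;
  P.box = as<double>(par["box"]);
  P.eps_wca = as<double>(par["eps_wca"]);
  P.sigma = as<double>(par["sigma"]);
  P.kf = as<double>(par["k_fene"]);
  P.R0 = as<double>(par["R0"]);
  P.kappa = as<double>(par["kappa"]);
  P.Fp = as<double>(par["Fp"]);
  P.wca_on = as<bool>(par["wca_on"]);
  P.soft_on = as<bool>(par["soft_on"]);
  P.softA = as<double>(par["softA"]);
  P.active_virial = as<bool>(par["active_virial"]);
  P.active_raw = par.containsElementNamed("active_raw")
                     ? as<bool>(par["active_raw"])
                     : false;
  return P;
}

// ---------------------------------------------------------- cell list ----
struct CellList {
  int nc;                    // cells per dimension (1 => all-pairs fallback)
  double box;
  std::vector<int> head, nxt;

  void build(int n, const double* x, const double* y, const double* z,
             double box_, double rc) {
    box = box_;
    nc = (int)std::floor(box / rc);
    if (nc < 3) nc = 1;
    head.assign((size_t)nc * nc * nc, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = cell_of(x[i]), cy = cell_of(y[i]), cz = cell_of(z[i]);
      int c = (cx * nc + cy) * nc + cz;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int cell_of(double v) const {
    int c = (int)std::floor(v / (box / nc));
    if (c < 0) c = 0;
    if (c >= nc) c = nc - 1;
    return c;
  }
};

// ------------------------------------------------------- force worker ----
// Accumulates total forces, per-contribution virials (W[ab] += F_k^a r_kl^b
// over unordered pairs; stress = -W/V), potential energies, and bond/pair
// diagnostics. Component arrays may be NULL.
struct ForceOut {
  double E_pair, E_fene, E_ang;
  double Wpair[9], Wang[9], Wact[9];
  double bond_min, bond_max, pair_min;
  int overstretch;          // index of first overstretched bond, else -1
};

static void forces_core(int n, const double* x, const double* y,
                        const double* z, const double* uxp, const double* uyp,
                        const double* uzp, const int* chain, const FFPar& P,
                        double* fx, double* fy, double* fz, ForceOut& out,
                        double* cwx = 0, double* cwy = 0, double* cwz = 0,
                        double* cfx = 0, double* cfy = 0, double* cfz = 0,
                        double* cax = 0, double* cay = 0, double* caz = 0,
                        double* cpx = 0, double* cpy = 0, double* cpz = 0) {
  const double box = P.box;
  out.E_pair = out.E_fene = out.E_ang = 0.0;
  for (int k = 0; k < 9; ++k) out.Wpair[k] = out.Wang[k] = out.Wact[k] = 0.0;
  out.bond_min = R_PosInf;
  out.bond_max = 0.0;
  out.pair_min = R_PosInf;
  out.overstretch = -1;
  for (int i = 0; i < n; ++i) fx[i] = fy[i] = fz[i] = 0.0;

  const double rc = std::pow(2.0, 1.0 / 6.0) * P.sigma;
  const double rc2 = rc * rc;
  const double s2 = P.sigma * P.sigma;

  // --- nonbonded repulsion (WCA or capped soft core) ---
  if (P.wca_on || P.soft_on) {
    CellList cl;
    cl.build(n, x, y, z, box, rc);

    auto pair_term = [&](int i, int j, double sx, double sy, double sz) {
      double dx = x[i] - x[j] - sx;
      double dy = y[i] - y[j] - sy;
      double dz = z[i] - z[j] - sz;
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) return;
      double r = std::sqrt(r2);
      if (r < out.pair_min) out.pair_min = r;
      double fscal, u;
      if (P.soft_on) {
        double w = M_PI * r / rc;
        u = P.softA * (1.0 + std::cos(w));
        fscal = (r > 1e-14) ? P.softA * (M_PI / rc) * std::sin(w) / r
                            : P.softA * M_PI * M_PI / (rc * rc);
      } else {
        if (r2 < 1e-20) {
          out.overstretch = -2;  // singular overlap
          return;
        }
        double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        u = 4.0 * P.eps_wca * (sr12 - sr6) + P.eps_wca;
        fscal = 24.0 * P.eps_wca * (2.0 * sr12 - sr6) / r2;
      }
      out.E_pair += u;
      double fxi = fscal * dx, fyi = fscal * dy, fzi = fscal * dz;
      fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
      fx[j] -= fxi; fy[j] -= fyi; fz[j] -= fzi;
      if (cwx) {
        cwx[i] += fxi; cwy[i] += fyi; cwz[i] += fzi;
        cwx[j] -= fxi; cwy[j] -= fyi; cwz[j] -= fzi;
      }
      double F[3] = {fxi, fyi, fzi}, d[3] = {dx, dy, dz};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) out.Wpair[3 * a + b] += F[a] * d[b];
    };

    if (cl.nc == 1) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          // minimum image via explicit rounding in the dense fallback
          double sx = box * std::round((x[i] - x[j]) / box);
          double sy = box * std::round((y[i] - y[j]) / box);
          double sz = box * std::round((z[i] - z[j]) / box);
          pair_term(i, j, sx, sy, sz);
        }
    } else {
      const int nc = cl.nc;
      static const int off[13][3] = {
          {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
          {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
          {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
      for (int cx = 0; cx < nc; ++cx)
        for (int cy = 0; cy < nc; ++cy)
          for (int cz = 0; cz < nc; ++cz) {
            int c = (cx * nc + cy) * nc + cz;
            int h = cl.head[c];
            if (h < 0) continue;
            // same cell: no shift
            for (int i = h; i >= 0; i = cl.nxt[i])
              for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j])
                pair_term(i, j, 0.0, 0.0, 0.0);
            // half of the neighbour cells, with cell-level periodic shifts
            for (int k = 0; k < 13; ++k) {
              int rx = cx + off[k][0], ry = cy + off[k][1],
                  rz = cz + off[k][2];
              double sx = 0, sy = 0, sz = 0;
              if (rx < 0) { rx += nc; sx = -box; }
              else if (rx >= nc) { rx -= nc; sx = box; }
              if (ry < 0) { ry += nc; sy = -box; }
              else if (ry >= nc) { ry -= nc; sy = box; }
              if (rz < 0) { rz += nc; sz = -box; }
              else if (rz >= nc) { rz -= nc; sz = box; }
              int c2 = (rx * nc + ry) * nc + rz;
              int h2 = cl.head[c2];
              if (h2 < 0) continue;
              for (int i = h; i >= 0; i = cl.nxt[i])
                for (int j = h2; j >= 0; j = cl.nxt[j])
                  pair_term(i, j, sx, sy, sz);
            }
          }
    }
  }

  // --- FENE bonds ---
  const double R02 = P.R0 * P.R0;
  for (int i = 0; i + 1 < n; ++i) {
    if (chain[i] != chain[i + 1]) continue;
    double dx, dy, dz;
    if (uxp) {
      dx = uxp[i] - uxp[i + 1]; dy = uyp[i] - uyp[i + 1];
      dz = uzp[i] - uzp[i + 1];
    } else {
      dx = mi(x[i] - x[i + 1], box); dy = mi(y[i] - y[i + 1], box);
      dz = mi(z[i] - z[i + 1], box);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    if (r < out.bond_min) out.bond_min = r;
    if (r > out.bond_max) out.bond_max = r;
    if (r >= P.R0) {
      if (out.overstretch == -1) out.overstretch = i;
      continue;
    }
    double denom = 1.0 - r2 / R02;
    out.E_fene += -0.5 * P.kf * R02 * std::log(denom);
    double fscal = -P.kf / denom;
    double fxi = fscal * dx, fyi = fscal * dy, fzi = fscal * dz;
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
    fx[i + 1] -= fxi; fy[i + 1] -= fyi; fz[i + 1] -= fzi;
    if (cfx) {
      cfx[i] += fxi; cfy[i] += fyi; cfz[i] += fzi;
      cfx[i + 1] -= fxi; cfy[i + 1] -= fyi; cfz[i + 1] -= fzi;
    }
    double F[3] = {fxi, fyi, fzi}, d[3] = {dx, dy, dz};
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) out.Wpair[3 * a + b] += F[a] * d[b];
  }

  // --- bending: kappa * (1 - t_j . t_{j+1}) per unique tangent pair,
  //     decomposed into central pair forces along (a,b), (b,c), (a,c)
  //     so the virial is a sum of symmetric pairwise dyads ---
  if (P.kappa != 0.0) {
    for (int i = 1; i + 1 < n; ++i) {
      if (chain[i - 1] != chain[i] || chain[i] != chain[i + 1]) continue;
      // a = i-1, b = i, c = i+1
      double ux, uy, uz, vx, vy, vz;
      if (uxp) {
        ux = uxp[i] - uxp[i - 1]; uy = uyp[i] - uyp[i - 1];
        uz = uzp[i] - uzp[i - 1];
        vx = uxp[i + 1] - uxp[i]; vy = uyp[i + 1] - uyp[i];
        vz = uzp[i + 1] - uzp[i];
      } else {
        ux = mi(x[i] - x[i - 1], box); uy = mi(y[i] - y[i - 1], box);
        uz = mi(z[i] - z[i - 1], box);
        vx = mi(x[i + 1] - x[i], box); vy = mi(y[i + 1] - y[i], box);
        vz = mi(z[i + 1] - z[i], box);
      }
      double wx = ux + vx, wy = uy + vy, wz = uz + vz;  // a -> c
      double rab = std::sqrt(ux * ux + uy * uy + uz * uz);
      double rbc = std::sqrt(vx * vx + vy * vy + vz * vz);
      double rac2 = wx * wx + wy * wy + wz * wz;
      double rac = std::sqrt(rac2);
      if (rab < 1e-14 || rbc < 1e-14) {
        out.overstretch = (out.overstretch < 0) ? -3 : out.overstretch;
        continue;
      }
      double cost = (rac2 - rab * rab - rbc * rbc) / (2.0 * rab * rbc);
      out.E_ang += P.kappa * (1.0 - cost);
      // dU/dr_p = -kappa * dcos/dr_p
      double dc_dab =
          (rbc * rbc - rab * rab - rac2) / (2.0 * rab * rab * rbc);
      double dc_dbc =
          (rab * rab - rbc * rbc - rac2) / (2.0 * rbc * rbc * rab);
      double dc_dac = rac / (rab * rbc);
      double g_ab = P.kappa * dc_dab;  // -dU/dr_ab
      double g_bc = P.kappa * dc_dbc;
      double g_ac = P.kappa * dc_dac;
      // central force on first bead of each pair: g_p * d_p / r_p
      // pair (a,b): d = a - b = -u
      double f1x = -g_ab * ux / rab, f1y = -g_ab * uy / rab,
             f1z = -g_ab * uz / rab;
      // pair (b,c): d = b - c = -v
      double f2x = -g_bc * vx / rbc, f2y = -g_bc * vy / rbc,
             f2z = -g_bc * vz / rbc;
      // pair (a,c): d = a - c = -w
      double f3x = -g_ac * wx / rac, f3y = -g_ac * wy / rac,
             f3z = -g_ac * wz / rac;
      int a = i - 1, b = i, c = i + 1;
      double addx[3] = {f1x + f3x, -f1x + f2x, -f2x - f3x};
      double addy[3] = {f1y + f3y, -f1y + f2y, -f2y - f3y};
      double addz[3] = {f1z + f3z, -f1z + f2z, -f2z - f3z};
      int idx[3] = {a, b, c};
      for (int k = 0; k < 3; ++k) {
        fx[idx[k]] += addx[k]; fy[idx[k]] += addy[k]; fz[idx[k]] += addz[k];
        if (cax) {
          cax[idx[k]] += addx[k]; cay[idx[k]] += addy[k];
          caz[idx[k]] += addz[k];
        }
      }
      // symmetric pairwise virial: sum_p F_p^a d_p^b
      double Fs[3][3] = {{f1x, f1y, f1z}, {f2x, f2y, f2z}, {f3x, f3y, f3z}};
      double Ds[3][3] = {{-ux, -uy, -uz}, {-vx, -vy, -vz}, {-wx, -wy, -wz}};
      for (int p = 0; p < 3; ++p)
        for (int aa = 0; aa < 3; ++aa)
          for (int bb = 0; bb < 3; ++bb)
            out.Wang[3 * aa + bb] += Fs[p][aa] * Ds[p][bb];
    }
  }

  // --- tangential active force, constant magnitude Fp per bead ---
  if (P.Fp != 0.0) {
    for (int i = 0; i < n; ++i) {
      bool has_prev = (i > 0 && chain[i - 1] == chain[i]);
      bool has_next = (i + 1 < n && chain[i + 1] == chain[i]);
      if (!has_prev && !has_next) continue;
      double t1x = 0, t1y = 0, t1z = 0, t2x = 0, t2y = 0, t2z = 0;
      double r1 = 0, r2n = 0;
      if (has_prev) {
        if (uxp) {
          t1x = uxp[i] - uxp[i - 1]; t1y = uyp[i] - uyp[i - 1];
          t1z = uzp[i] - uzp[i - 1];
        } else {
          t1x = mi(x[i] - x[i - 1], box); t1y = mi(y[i] - y[i - 1], box);
          t1z = mi(z[i] - z[i - 1], box);
        }
        r1 = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
        if (r1 > 1e-14) { t1x /= r1; t1y /= r1; t1z /= r1; }
      }
      if (has_next) {
        if (uxp) {
          t2x = uxp[i + 1] - uxp[i]; t2y = uyp[i + 1] - uyp[i];
          t2z = uzp[i + 1] - uzp[i];
        } else {
          t2x = mi(x[i + 1] - x[i], box); t2y = mi(y[i + 1] - y[i], box);
          t2z = mi(z[i + 1] - z[i], box);
        }
        r2n = std::sqrt(t2x * t2x + t2y * t2y + t2z * t2z);
        if (r2n > 1e-14) { t2x /= r2n; t2y /= r2n; t2z /= r2n; }
      }
      double sx = t1x + t2x, sy = t1y + t2y, sz = t1z + t2z;
      double sn = std::sqrt(sx * sx + sy * sy + sz * sz);
      if (!has_prev || !has_next) {
        // end bead: magnitude Fp along its single tangent, head-ward
        double tx = has_next ? t2x : t1x, ty = has_next ? t2y : t1y,
               tz = has_next ? t2z : t1z;
        double ax = P.Fp * tx, ay = P.Fp * ty, az = P.Fp * tz;
        fx[i] += ax; fy[i] += ay; fz[i] += az;
        if (cpx) { cpx[i] += ax; cpy[i] += ay; cpz[i] += az; }
        if (P.active_virial) {
          int j = has_next ? i + 1 : i - 1;
          double rb = has_next ? r2n : r1;
          double dx, dy, dz;
          if (uxp) {
            dx = uxp[i] - uxp[j]; dy = uyp[i] - uyp[j]; dz = uzp[i] - uzp[j];
          } else {
            dx = mi(x[i] - x[j], box); dy = mi(y[i] - y[j], box);
            dz = mi(z[i] - z[j], box);
          }
          double F[3] = {ax, ay, az}, d[3] = {dx, dy, dz};
          (void)rb;
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) out.Wact[3 * a + b] += F[a] * d[b];
        }
        continue;
      }
      if (sn < 1e-8) continue;  // perfect hairpin: zero active force
      double c = P.active_raw ? P.Fp : P.Fp / sn;
      double ax = c * sx, ay = c * sy, az = c * sz;
      fx[i] += ax; fy[i] += ay; fz[i] += az;
      if (cpx) { cpx[i] += ax; cpy[i] += ay; cpz[i] += az; }
      if (P.active_virial) {
        // attribute each tangent part to its generating bond pair
        // part from t1: partner i-1, r_kl = r_i - r_{i-1} = r1 * t1
        double F1[3] = {c * t1x, c * t1y, c * t1z};
        double d1[3] = {r1 * t1x, r1 * t1y, r1 * t1z};
        double F2[3] = {c * t2x, c * t2y, c * t2z};
        double d2[3] = {-r2n * t2x, -r2n * t2y, -r2n * t2z};
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) {
            out.Wact[3 * a + b] += F1[a] * d1[b] + F2[a] * d2[b];
          }
      }
    }
  }
  if (out.bond_min == R_PosInf) {
    out.bond_min = NA_REAL;
    out.bond_max = NA_REAL;
  }
}

static NumericMatrix mat3(int n, const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = x[i]; m(i, 1) = y[i]; m(i, 2) = z[i];
  }
  return m;
}

static NumericMatrix w3(const double* W) {
  NumericMatrix m(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) m(a, b) = W[3 * a + b];
  return m;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix posU, IntegerVector chain,
                List par) {
  int n = pos.nrow();
  FFPar P = par_from_list(par);
  std::vector<double> x(n), y(n), z(n), ux(n), uy(n), uz(n), fx(n), fy(n),
      fz(n);
  std::vector<double> cwx(n, 0), cwy(n, 0), cwz(n, 0), cfx(n, 0), cfy(n, 0),
      cfz(n, 0), cax(n, 0), cay(n, 0), caz(n, 0), cpx(n, 0), cpy(n, 0),
      cpz(n, 0);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    ux[i] = posU(i, 0); uy[i] = posU(i, 1); uz[i] = posU(i, 2);
  }
  ForceOut out;
  forces_core(n, x.data(), y.data(), z.data(), ux.data(), uy.data(),
              uz.data(), chain.begin(), P, fx.data(),
              fy.data(), fz.data(), out, cwx.data(), cwy.data(), cwz.data(),
              cfx.data(), cfy.data(), cfz.data(), cax.data(), cay.data(),
              caz.data(), cpx.data(), cpy.data(), cpz.data());
  if (out.overstretch == -2) stop("singular overlap: two beads at zero separation");
  return List::create(
      _["f_total"] = mat3(n, fx, fy, fz), _["f_wca"] = mat3(n, cwx, cwy, cwz),
      _["f_fene"] = mat3(n, cfx, cfy, cfz), _["f_ang"] = mat3(n, cax, cay, caz),
      _["f_active"] = mat3(n, cpx, cpy, cpz), _["E_pair"] = out.E_pair,
      _["E_fene"] = out.E_fene, _["E_ang"] = out.E_ang,
      _["W_pair"] = w3(out.Wpair), _["W_ang"] = w3(out.Wang),
      _["W_active"] = w3(out.Wact), _["bond_min"] = out.bond_min,
      _["bond_max"] = out.bond_max, _["pair_min"] = out.pair_min,
      _["overstretch"] = out.overstretch);
}

// ------------------------------------------------------------ BD run ----
// Euler-Maruyama integration of the overdamped Langevin equation
//   zeta dr_i/dt = -grad_i U + F_p,i + F_r,i
// with <F_r F_r> = 2 kBT zeta delta(t-t'). Samples stress, configurations,
// bond lengths and an observable log at fixed strides; stress sampling
// starts only once t >= steady_start_time.
// [[Rcpp::export]]
List cpp_bd_run(NumericMatrix posW_, NumericMatrix posU_, IntegerVector chain_,
                List par, double kBT, double zeta, double dt, int n_steps,
                double seed, double step0, double time0, int stride_stress,
                double steady_start_time, int stride_config, int stride_log,
                int stride_bond) {
  int n = posW_.nrow();
  FFPar P = par_from_list(par);
  const double box = P.box;
  std::vector<double> x(n), y(n), z(n), ux(n), uy(n), uz(n), fx(n), fy(n),
      fz(n);
  std::vector<int> chain(chain_.begin(), chain_.end());
  for (int i = 0; i < n; ++i) {
    x[i] = posW_(i, 0); y[i] = posW_(i, 1); z[i] = posW_(i, 2);
    ux[i] = posU_(i, 0); uy[i] = posU_(i, 1); uz[i] = posU_(i, 2);
  }
  // chain end indices for Ree^2 logging
  std::vector<int> c_first, c_last;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || chain[i] != chain[i - 1]) c_first.push_back(i);
    if (i == n - 1 || chain[i + 1] != chain[i]) c_last.push_back(i);
  }

  const double mob = dt / zeta;
  const double noise = std::sqrt(2.0 * (kBT / zeta) * dt);
  const double vol = box * box * box;
  const uint64_t useed = (uint64_t)seed;

  std::vector<double> stress_rows;   // time, sxx..szz, sxy, sxz, syz
  std::vector<double> log_rows;      // time, Epair, Efene, Eang, Ree2, bmin, bmax
  std::vector<double> bond_rows;     // first-bond length samples
  List traj_frames;
  std::vector<double> traj_times;

  ForceOut out;
  for (int s = 0; s <= n_steps; ++s) {
    double gstep = step0 + s;
    long long gsi = (long long)step0 + s;
    double tnow = time0 + s * dt;
    forces_core(n, x.data(), y.data(), z.data(), ux.data(), uy.data(),
                uz.data(), chain.data(), P, fx.data(), fy.data(), fz.data(),
                out);
    if (out.overstretch >= 0) {
      std::ostringstream msg;
      msg << "FENE bond overstretched (bond after bead index "
          << out.overstretch + 1 << ", length >= R0) at step "
          << (long long)gstep << ", t = " << tnow;
      stop(msg.str());
    }
    if (out.overstretch == -2) {
      std::ostringstream msg;
      msg << "singular overlap between beads at step " << (long long)gstep;
      stop(msg.str());
    }

    bool do_stress = stride_stress > 0 &&
                     gsi % stride_stress == 0 &&
                     tnow >= steady_start_time - 1e-12;
    if (do_stress) {
      double W[9];
      for (int k = 0; k < 9; ++k)
        W[k] = out.Wpair[k] + out.Wang[k] + out.Wact[k];
      // symmetrize and convert: sigma_ab = -W_ab / V
      auto sig = [&](int a, int b) {
        return -0.5 * (W[3 * a + b] + W[3 * b + a]) / vol;
      };
      double row[8] = {tnow, sig(0, 0), sig(1, 1), sig(2, 2),
                       sig(0, 1), sig(0, 2), sig(1, 2), vol};
      stress_rows.insert(stress_rows.end(), row, row + 8);
    }
    if (stride_log > 0 && gsi % stride_log == 0) {
      double ree2 = 0.0;
      int ncn = (int)c_first.size();
      for (int c = 0; c < ncn; ++c) {
        double dx = ux[c_last[c]] - ux[c_first[c]];
        double dy = uy[c_last[c]] - uy[c_first[c]];
        double dz = uz[c_last[c]] - uz[c_first[c]];
        ree2 += dx * dx + dy * dy + dz * dz;
      }
      ree2 /= std::max(1, ncn);
      double row[7] = {tnow, out.E_pair, out.E_fene, out.E_ang,
                       ree2, out.bond_min, out.bond_max};
      log_rows.insert(log_rows.end(), row, row + 7);
      if (!std::isfinite(x[0]) || !std::isfinite(fx[0])) {
        std::ostringstream msg;
        msg << "numerical instability (non-finite positions) at step "
            << (long long)gstep;
        stop(msg.str());
      }
    }
    if (stride_bond > 0 && gsi % stride_bond == 0 &&
        n >= 2 && chain[0] == chain[1]) {
      double dx = mi(x[0] - x[1], box), dy = mi(y[0] - y[1], box),
             dz = mi(z[0] - z[1], box);
      bond_rows.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    if (stride_config > 0 && gsi % stride_config == 0) {
      traj_frames.push_back(mat3(n, ux, uy, uz));
      traj_times.push_back(tnow);
    }
    if (s == n_steps) break;

    for (int i = 0; i < n; ++i) {
      double g[3];
      gauss3(useed, (uint64_t)gstep, (uint64_t)i, g);
      double dxs = mob * fx[i] + noise * g[0];
      double dys = mob * fy[i] + noise * g[1];
      double dzs = mob * fz[i] + noise * g[2];
      x[i] += dxs; y[i] += dys; z[i] += dzs;
      ux[i] += dxs; uy[i] += dys; uz[i] += dzs;
      x[i] -= box * std::floor(x[i] / box);
      y[i] -= box * std::floor(y[i] / box);
      z[i] -= box * std::floor(z[i] / box);
    }
  }

  int nst = (int)stress_rows.size() / 8;
  NumericMatrix stress(nst, 8);
  for (int r = 0; r < nst; ++r)
    for (int cidx = 0; cidx < 8; ++cidx)
      stress(r, cidx) = stress_rows[8 * r + cidx];
  int nlg = (int)log_rows.size() / 7;
  NumericMatrix lg(nlg, 7);
  for (int r = 0; r < nlg; ++r)
    for (int cidx = 0; cidx < 7; ++cidx) lg(r, cidx) = log_rows[7 * r + cidx];

  return List::create(
      _["posW"] = mat3(n, x, y, z), _["posU"] = mat3(n, ux, uy, uz),
      _["stress"] = stress, _["log"] = lg,
      _["bond_samples"] = NumericVector(bond_rows.begin(), bond_rows.end()),
      _["traj"] = traj_frames,
      _["traj_times"] = NumericVector(traj_times.begin(), traj_times.end()),
      _["time_end"] = time0 + (double)n_steps * dt,
      _["step_end"] = step0 + (double)n_steps);
}

// ------------------------------------------------ bond-swap Monte Carlo ----
// Symmetric double-bridging on a monodisperse melt: pick a bond rank a on
// chain c1 and another chain c2, propose exchanging tails beyond rank a.
// The move is rejected outright unless all four involved bonds (two old,
// two new) are shorter than the eligibility radius (and R0), which keeps
// the proposal symmetric; otherwise Metropolis on the FENE + bending
// energy change (positions do not move, so WCA terms cancel).
static inline double fene_u(double r, double kf, double R0) {
  double d = 1.0 - (r * r) / (R0 * R0);
  return -0.5 * kf * R0 * R0 * std::log(d);
}

// [[Rcpp::export]]
List cpp_swap_sweep(NumericMatrix posW_, NumericMatrix posU_, int n_chain,
                    int np, double box, double kf, double R0, double kappa,
                    double kBT, double elig_r, int n_attempts, double seed,
                    double ctr0) {
  int n = posW_.nrow();
  if (n != n_chain * np) stop("bead count does not match n_chain * np");
  NumericMatrix posW = clone(posW_), posU = clone(posU_);
  const uint64_t useed = (uint64_t)seed;

  auto dist_mi = [&](int i, int j) {
    double dx = mi(posW(i, 0) - posW(j, 0), box);
    double dy = mi(posW(i, 1) - posW(j, 1), box);
    double dz = mi(posW(i, 2) - posW(j, 2), box);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  // bending energy of triplet (i,j,k) via minimum-image bond composition
  auto ang_u = [&](int i, int j, int k) {
    double uxv = mi(posW(j, 0) - posW(i, 0), box),
           uyv = mi(posW(j, 1) - posW(i, 1), box),
           uzv = mi(posW(j, 2) - posW(i, 2), box);
    double vxv = mi(posW(k, 0) - posW(j, 0), box),
           vyv = mi(posW(k, 1) - posW(j, 1), box),
           vzv = mi(posW(k, 2) - posW(j, 2), box);
    double ru = std::sqrt(uxv * uxv + uyv * uyv + uzv * uzv);
    double rv = std::sqrt(vxv * vxv + vyv * vyv + vzv * vzv);
    if (ru < 1e-14 || rv < 1e-14) return 0.0;
    double cost = (uxv * vxv + uyv * vyv + uzv * vzv) / (ru * rv);
    return kappa * (1.0 - cost);
  };

  IntegerVector accepted_flags(n_attempts);
  int accepted = 0;
  uint64_t ctr = (uint64_t)ctr0;
  for (int att = 0; att < n_attempts; ++att, ++ctr) {
    int c1 = (int)(mc_u01(useed, ctr, 1) * n_chain);
    int a = (int)(mc_u01(useed, ctr, 2) * (np - 1));  // bond a -> a+1
    int c2 = (int)(mc_u01(useed, ctr, 3) * (n_chain - 1));
    if (c1 >= n_chain) c1 = n_chain - 1;
    if (a >= np - 1) a = np - 2;
    if (c2 >= n_chain - 1) c2 = n_chain - 2;
    if (c2 >= c1) c2 += 1;
    int i1 = c1 * np + a, j1 = i1 + 1;   // old bond on c1
    int i2 = c2 * np + a, j2 = i2 + 1;   // old bond on c2
    double lim = std::min(elig_r, R0);
    double r_old1 = dist_mi(i1, j1), r_old2 = dist_mi(i2, j2);
    double r_new1 = dist_mi(i1, j2), r_new2 = dist_mi(i2, j1);
    if (r_old1 >= lim || r_old2 >= lim || r_new1 >= lim || r_new2 >= lim)
      continue;
    double dU = fene_u(r_new1, kf, R0) + fene_u(r_new2, kf, R0) -
                fene_u(r_old1, kf, R0) - fene_u(r_old2, kf, R0);
    if (kappa != 0.0) {
      // triplets whose middle bond is the spliced bond
      if (a >= 1) {
        dU += ang_u(i1 - 1, i1, j2) - ang_u(i1 - 1, i1, j1);
        dU += ang_u(i2 - 1, i2, j1) - ang_u(i2 - 1, i2, j2);
      }
      if (a + 2 <= np - 1) {
        dU += ang_u(i1, j2, j2 + 1) - ang_u(i1, j1, j1 + 1);
        dU += ang_u(i2, j1, j1 + 1) - ang_u(i2, j2, j2 + 1);
      }
    }
    bool acc = dU <= 0.0 || mc_u01(useed, ctr, 4) < std::exp(-dU / kBT);
    if (!acc) continue;
    // swap tails (ranks a+1 .. np-1) between c1 and c2, then re-unwrap so
    // the spliced bond is continuous in unwrapped coordinates
    for (int r = a + 1; r < np; ++r) {
      int b1 = c1 * np + r, b2 = c2 * np + r;
      for (int d = 0; d < 3; ++d) {
        std::swap(posW(b1, d), posW(b2, d));
        std::swap(posU(b1, d), posU(b2, d));
      }
    }
    for (int hc = 0; hc < 2; ++hc) {
      int head = (hc == 0 ? i1 : i2);
      int tail0 = head + 1;
      double want[3], shift[3];
      for (int d = 0; d < 3; ++d) {
        double bond = mi(posW(tail0, d) - posW(head, d), box);
        want[d] = posU(head, d) + bond;
        shift[d] = want[d] - posU(tail0, d);
      }
      if (shift[0] != 0 || shift[1] != 0 || shift[2] != 0) {
        int cbase = (hc == 0 ? c1 : c2) * np;
        for (int r = a + 1; r < np; ++r)
          for (int d = 0; d < 3; ++d) posU(cbase + r, d) += shift[d];
      }
    }
    accepted_flags[att] = 1;
    ++accepted;
  }
  return List::create(_["posW"] = posW, _["posU"] = posU,
                      _["accepted"] = accepted, _["attempted"] = n_attempts,
                      _["accept_flags"] = accepted_flags,
                      _["ctr_end"] = (double)ctr);
}
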