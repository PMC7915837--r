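// DPD engine: soft conservative + dissipative + random pair forces with a
// pair-keyed counter RNG, harmonic bonds, rigid-body dynamics for porphyrins,
// cell-list neighbour search, and Ewald electrostatics for exponentially
// (Slater-type) smeared charges.  All quantities are in reduced DPD units
// (r_c = kT = m = 1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// minimum image for wrapped coordinates (|d| < L)
static inline double mind(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

// ---------------------------------------------------------------------------
// counter-based RNG: the random pair force is keyed by (seed, step, i < j) so
// trajectories are reproducible independent of pair iteration order
static inline uint64_t smix(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double pair_noise(uint64_t seed, uint64_t step, int i, int j) {
  if (i > j) std::swap(i, j);
  uint64_t z = smix(seed ^ smix(step));
  z = smix(z ^ (uint64_t)i);
  z = smix(z ^ ((uint64_t)j << 20));
  double u = (double)(z >> 11) * (1.0 / 9007199254740992.0);
  return 3.4641016151377544 * (u - 0.5);  // uniform, zero mean, unit variance
}

// ---------------------------------------------------------------------------
// neighbour iteration: unique pairs of `idx` within `cutoff` (minimum image);
// cell list when the box holds >= 3 cells per edge, otherwise all pairs
template <class F>
static void for_pairs(const std::vector<double>& X, const std::vector<double>& Y,
                      const std::vector<double>& Z, const std::vector<int>& idx,
                      double L, double cutoff, bool use_cells, F f) {
  const double cut2 = cutoff * cutoff;
  const int n = (int)idx.size();
  int nc = (int)std::floor(L / cutoff);
  if (!use_cells || nc < 3) {
    for (int a = 0; a < n; ++a) {
      const int i = idx[a];
      for (int b = a + 1; b < n; ++b) {
        const int j = idx[b];
        double dx = mind(X[i] - X[j], L);
        double dy = mind(Y[i] - Y[j], L);
        double dz = mind(Z[i] - Z[j], L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < cut2) f(i, j, dx, dy, dz, r2);
      }
    }
    return;
  }
  const double cell = L / nc;
  std::vector<int> head((size_t)nc * nc * nc, -1), nxt(n, -1);
  auto cidx = [&](double v) {
    int c = (int)(v / cell);
    if (c >= nc) c = nc - 1;
    if (c < 0) c = 0;
    return c;
  };
  for (int a = 0; a < n; ++a) {
    const int i = idx[a];
    int c = (cidx(Z[i]) * nc + cidx(Y[i])) * nc + cidx(X[i]);
    nxt[a] = head[c];
    head[c] = a;
  }
  static const int off[14][3] = {
    {0, 0, 0}, {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
    {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
    {1, 0, 1}, {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
  for (int cz = 0; cz < nc; ++cz)
    for (int cy = 0; cy < nc; ++cy)
      for (int cx = 0; cx < nc; ++cx) {
        const int c = (cz * nc + cy) * nc + cx;
        for (int o = 0; o < 14; ++o) {
          const int ax = (cx + off[o][0] + nc) % nc;
          const int ay = (cy + off[o][1] + nc) % nc;
          const int az = (cz + off[o][2] + nc) % nc;
          const int c2 = (az * nc + ay) * nc + ax;
          for (int a = head[c]; a >= 0; a = nxt[a]) {
            const int i = idx[a];
            for (int b = (o == 0) ? nxt[a] : head[c2]; b >= 0; b = nxt[b]) {
              const int j = idx[b];
              double dx = mind(X[i] - X[j], L);
              double dy = mind(Y[i] - Y[j], L);
              double dz = mind(Z[i] - Z[j], L);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < cut2) f(i, j, dx, dy, dz, r2);
            }
          }
        }
      }
}

// ---------------------------------------------------------------------------
// Slater-smeared charge pair interaction.  The charge density is
// rho(r) ~ exp(-2 r / lambda); the closed-form cloud-cloud energy is
// U(r) = C q_i q_j B(x) / r with x = r/lambda and
// B(x) = 1 - exp(-2x) (1 + 11x/8 + 3x^2/4 + x^3/6),
// finite at contact (U(0) = C q_i q_j 5/(8 lambda)) and Coulombic at large r.
static inline double slater_B(double x) {
  return 1.0 - std::exp(-2.0 * x) * (1.0 + x * (11.0 / 8.0 + x * (0.75 + x / 6.0)));
}

// radial force over r per (C q_i q_j): f(r)/r with f(r) = (B - x B'(x)) / r^2,
// so that multiplying by the separation vector gives the force vector
static inline double slater_fr(double r, double lam) {
  if (r < 1e-12) return 0.0;
  double x = r / lam;
  double g = 1.0 - std::exp(-2.0 * x) *
    (1.0 + x * (2.0 + x * (2.0 + x * (7.0 / 6.0 + x / 3.0))));
  return g / (r * r * r);
}

static inline double slater_U(double r, double lam) {
  if (r < 1e-12) return 5.0 / (8.0 * lam);
  return slater_B(r / lam) / r;
}

// Ewald real-space remainder for smeared charges: the full smeared pair
// interaction minus the reciprocal-space (erf-screened point) part; returns
// f(r)/r like slater_fr
static inline double ewald_real_fr(double r, double lam, double alpha) {
  if (r < 1e-12) return 0.0;
  double t = 2.0 * alpha / std::sqrt(M_PI);
  return slater_fr(r, lam) - std::erf(alpha * r) / (r * r * r) +
         t * std::exp(-alpha * alpha * r * r) / (r * r);
}

static inline double ewald_real_U(double r, double lam, double alpha) {
  if (r < 1e-12) return 5.0 / (8.0 * lam) - 2.0 * alpha / std::sqrt(M_PI);
  return (slater_B(r / lam) - std::erf(alpha * r)) / r;
}

// ---------------------------------------------------------------------------
// reciprocal-space sum
struct KSpace {
  std::vector<int> nx, ny, nz;
  std::vector<double> g;
  int nmax = 0;
  double kfac = 0.0;
  void build(double L, double alpha, int nmax_) {
    nmax = nmax_;
    kfac = 2.0 * M_PI / L;
    nx.clear(); ny.clear(); nz.clear(); g.clear();
    const double n2max = (double)nmax * nmax;
    for (int cz = 0; cz <= nmax; ++cz) {
      int ylo = (cz == 0) ? 0 : -nmax;
      for (int cy = ylo; cy <= nmax; ++cy) {
        int xlo = (cz == 0 && cy == 0) ? 1 : -nmax;
        for (int cx = xlo; cx <= nmax; ++cx) {
          double n2 = (double)cx * cx + (double)cy * cy + (double)cz * cz;
          if (n2 > n2max) continue;
          double k2 = kfac * kfac * n2;
          nx.push_back(cx); ny.push_back(cy); nz.push_back(cz);
          g.push_back(std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
        }
      }
    }
  }
};

// adds reciprocal-space forces for the charged subset; returns the energy
static double recip_forces(const std::vector<double>& X, const std::vector<double>& Y,
                           const std::vector<double>& Z, const std::vector<int>& cidx,
                           const std::vector<double>& q, const KSpace& ks,
                           double C, double L, std::vector<double>& fx,
                           std::vector<double>& fy, std::vector<double>& fz) {
  const int m = (int)cidx.size();
  const int nm = ks.nmax;
  if (m == 0 || ks.g.empty()) return 0.0;
  const int w = nm + 1;
  std::vector<double> cxT(m * w), sxT(m * w), cyT(m * w), syT(m * w),
      czT(m * w), szT(m * w);
  const double tp = 2.0 * M_PI / L;
  for (int p = 0; p < m; ++p) {
    const int i = cidx[p];
    double a1[3] = {tp * X[i], tp * Y[i], tp * Z[i]};
    double *cT[3] = {&cxT[p * w], &cyT[p * w], &czT[p * w]};
    double *sT[3] = {&sxT[p * w], &syT[p * w], &szT[p * w]};
    for (int ax = 0; ax < 3; ++ax) {
      double c1 = std::cos(a1[ax]), s1 = std::sin(a1[ax]);
      cT[ax][0] = 1.0; sT[ax][0] = 0.0;
      for (int k = 1; k <= nm; ++k) {
        cT[ax][k] = cT[ax][k - 1] * c1 - sT[ax][k - 1] * s1;
        sT[ax][k] = sT[ax][k - 1] * c1 + cT[ax][k - 1] * s1;
      }
    }
  }
  const double V = L * L * L;
  const double epref = 2.0 * C * (2.0 * M_PI / V);
  std::vector<double> reP(m), imP(m);
  double E = 0.0;
  for (size_t kk = 0; kk < ks.g.size(); ++kk) {
    const int ax = ks.nx[kk], ay = ks.ny[kk], az = ks.nz[kk];
    const int mx = std::abs(ax), my = std::abs(ay), mz = std::abs(az);
    const double sx = (ax < 0) ? -1.0 : 1.0;
    const double sy = (ay < 0) ? -1.0 : 1.0;
    double ReS = 0.0, ImS = 0.0;
    for (int p = 0; p < m; ++p) {
      const double cX = cxT[p * w + mx], sX = sx * sxT[p * w + mx];
      const double cY = cyT[p * w + my], sY = sy * syT[p * w + my];
      const double cZ = czT[p * w + mz], sZ = szT[p * w + mz];
      const double cXY = cX * cY - sX * sY;
      const double sXY = sX * cY + cX * sY;
      const double re = cXY * cZ - sXY * sZ;
      const double im = sXY * cZ + cXY * sZ;
      reP[p] = re; imP[p] = im;
      ReS += q[p] * re;
      ImS += q[p] * im;
    }
    const double gk = ks.g[kk];
    E += epref * gk * (ReS * ReS + ImS * ImS);
    const double coef = 2.0 * epref * gk;
    const double kx = ks.kfac * ax, ky = ks.kfac * ay, kz = ks.kfac * az;
    for (int p = 0; p < m; ++p) {
      const double fac = coef * q[p] * (ReS * imP[p] - ImS * reP[p]);
      const int i = cidx[p];
      fx[i] += fac * kx;
      fy[i] += fac * ky;
      fz[i] += fac * kz;
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
struct ElecParams {
  bool enabled = false;
  double C = 0.0;        // Gamma / (4 pi)
  double lambda = 0.2;
  double alpha = 1.0;
  double rcut = 3.0;
  int nmax = 0;
  bool surface = false;  // vacuum (dipole) boundary term
  KSpace ks;
};

static ElecParams parse_elec(List elec, double L) {
  ElecParams ep;
  ep.enabled = as<bool>(elec["enabled"]);
  if (!ep.enabled) return ep;
  ep.C = as<double>(elec["C"]);
  ep.lambda = as<double>(elec["lambda"]);
  ep.alpha = as<double>(elec["alpha"]);
  ep.rcut = as<double>(elec["rcut"]);
  ep.nmax = as<int>(elec["nmax"]);
  ep.surface = elec.containsElementNamed("surface") ? as<bool>(elec["surface"]) : false;
  ep.ks.build(L, ep.alpha, ep.nmax);
  return ep;
}

// full electrostatic force/energy for the charged subset (real + recip +
// self (+ optional surface)); adds into fx/fy/fz
static void elec_forces(const std::vector<double>& X, const std::vector<double>& Y,
                        const std::vector<double>& Z, const std::vector<double>& charge,
                        const std::vector<int>& cidx, const ElecParams& ep, double L,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz, double& e_real, double& e_recip) {
  const int m = (int)cidx.size();
  if (m == 0) return;
  double er = 0.0;
  for_pairs(X, Y, Z, cidx, L, ep.rcut, m > 200, [&](int i, int j, double dx,
                                                    double dy, double dz, double r2) {
    const double r = std::sqrt(r2);
    const double qq = ep.C * charge[i] * charge[j];
    const double fr = qq * ewald_real_fr(r, ep.lambda, ep.alpha);
    er += qq * ewald_real_U(r, ep.lambda, ep.alpha);
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  });
  double q2 = 0.0;
  std::vector<double> qsub(m);
  for (int p = 0; p < m; ++p) {
    qsub[p] = charge[cidx[p]];
    q2 += qsub[p] * qsub[p];
  }
  er -= ep.C * ep.alpha / std::sqrt(M_PI) * q2;  // point self term
  e_real += er;
  e_recip += recip_forces(X, Y, Z, cidx, qsub, ep.ks, ep.C, L, fx, fy, fz);
  if (ep.surface) {
    const double V = L * L * L;
    double Mx = 0, My = 0, Mz = 0;
    for (int p = 0; p < m; ++p) {
      const int i = cidx[p];
      Mx += qsub[p] * X[i]; My += qsub[p] * Y[i]; Mz += qsub[p] * Z[i];
    }
    e_real += ep.C * (2.0 * M_PI / (3.0 * V)) * (Mx * Mx + My * My + Mz * Mz);
    const double cf = ep.C * 4.0 * M_PI / (3.0 * V);
    for (int p = 0; p < m; ++p) {
      const int i = cidx[p];
      fx[i] -= cf * qsub[p] * Mx;
      fy[i] -= cf * qsub[p] * My;
      fz[i] -= cf * qsub[p] * Mz;
    }
  }
}

// ---------------------------------------------------------------------------
// one full force evaluation (conservative + bonds + optional thermostat pair
// forces + optional electrostatics)
struct ForceCtx {
  // parameters
  double L, dt, gamma, sigma, kbond, r0bond;
  bool thermostat = true;
  bool use_cells = true;
  uint64_t seed = 1;
  const std::vector<int>* all_idx = nullptr;
  const std::vector<int>* charged_idx = nullptr;
  const ElecParams* ep = nullptr;
  const std::vector<int>* bond_i = nullptr;
  const std::vector<int>* bond_j = nullptr;
  const std::vector<double>* atab = nullptr;  // 8x8 flattened
  const std::vector<int>* species = nullptr;  // 0-based
};

static void compute_forces(const std::vector<double>& X, const std::vector<double>& Y,
                           const std::vector<double>& Z, const std::vector<double>& VX,
                           const std::vector<double>& VY, const std::vector<double>& VZ,
                           const std::vector<double>& charge, const ForceCtx& c,
                           uint64_t step, std::vector<double>& fx,
                           std::vector<double>& fy, std::vector<double>& fz,
                           double& e_bond, double& e_real, double& e_recip) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  e_bond = e_real = e_recip = 0.0;
  const double inv_sqrt_dt = 1.0 / std::sqrt(c.dt);
  const std::vector<double>& a = *c.atab;
  const std::vector<int>& sp = *c.species;
  for_pairs(X, Y, Z, *c.all_idx, c.L, 1.0, c.use_cells,
            [&](int i, int j, double dx, double dy, double dz, double r2) {
    const double r = std::sqrt(r2);
    if (r < 1e-12) return;  // soft potential: force direction undefined at 0
    const double w = 1.0 - r;
    double fr = a[sp[i] * 8 + sp[j]] * w;  // conservative, per unit distance
    if (c.thermostat) {
      const double inv_r = 1.0 / r;
      const double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
      const double vrel = (VX[i] - VX[j]) * ex + (VY[i] - VY[j]) * ey +
                          (VZ[i] - VZ[j]) * ez;
      fr += -c.gamma * w * w * vrel +
            c.sigma * w * pair_noise(c.seed, step, i, j) * inv_sqrt_dt;
    }
    const double s = fr / r;
    fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
    fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
  });
  // harmonic bonds
  if (c.bond_i) {
    const std::vector<int>& bi = *c.bond_i;
    const std::vector<int>& bj = *c.bond_j;
    for (size_t b = 0; b < bi.size(); ++b) {
      const int i = bi[b], j = bj[b];
      double dx = mind(X[i] - X[j], c.L);
      double dy = mind(Y[i] - Y[j], c.L);
      double dz = mind(Z[i] - Z[j], c.L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ext = r - c.r0bond;
      e_bond += 0.5 * c.kbond * ext * ext;
      if (r > 1e-12) {
        double s = -c.kbond * ext / r;
        fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
        fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
      }
    }
  }
  if (c.ep && c.ep->enabled && c.charged_idx) {
    elec_forces(X, Y, Z, charge, *c.charged_idx, *c.ep, c.L, fx, fy, fz,
                e_real, e_recip);
  }
}

// ---------------------------------------------------------------------------
// rigid-body helpers
struct RigidBody {
  std::vector<int> beads;
  std::vector<double> ref;   // 3 * nb, body frame at run start
  double R[9];               // rotation matrix (row major)
  double com[3], vcom[3], Lang[3];
  double Ib[9];              // inertia tensor in the reference frame
  double mass;
};

static void mat3_vec(const double* M, const double* v, double* out) {
  out[0] = M[0] * v[0] + M[1] * v[1] + M[2] * v[2];
  out[1] = M[3] * v[0] + M[4] * v[1] + M[5] * v[2];
  out[2] = M[6] * v[0] + M[7] * v[1] + M[8] * v[2];
}

static void mat3_tvec(const double* M, const double* v, double* out) {
  out[0] = M[0] * v[0] + M[3] * v[1] + M[6] * v[2];
  out[1] = M[1] * v[0] + M[4] * v[1] + M[7] * v[2];
  out[2] = M[2] * v[0] + M[5] * v[1] + M[8] * v[2];
}

static void mat3_mul(const double* A, const double* B, double* out) {
  for (int r = 0; r < 3; ++r)
    for (int cc = 0; cc < 3; ++cc) {
      out[r * 3 + cc] = A[r * 3] * B[cc] + A[r * 3 + 1] * B[3 + cc] +
                        A[r * 3 + 2] * B[6 + cc];
    }
}

static bool mat3_solve(const double* A, const double* b, double* x) {
  double m[9];
  std::copy(A, A + 9, m);
  double det = m[0] * (m[4] * m[8] - m[5] * m[7]) -
               m[1] * (m[3] * m[8] - m[5] * m[6]) +
               m[2] * (m[3] * m[7] - m[4] * m[6]);
  if (std::fabs(det) < 1e-14) return false;
  double inv[9];
  inv[0] = (m[4] * m[8] - m[5] * m[7]) / det;
  inv[1] = (m[2] * m[7] - m[1] * m[8]) / det;
  inv[2] = (m[1] * m[5] - m[2] * m[4]) / det;
  inv[3] = (m[5] * m[6] - m[3] * m[8]) / det;
  inv[4] = (m[0] * m[8] - m[2] * m[6]) / det;
  inv[5] = (m[2] * m[3] - m[0] * m[5]) / det;
  inv[6] = (m[3] * m[7] - m[4] * m[6]) / det;
  inv[7] = (m[1] * m[6] - m[0] * m[7]) / det;
  inv[8] = (m[0] * m[4] - m[1] * m[3]) / det;
  mat3_vec(inv, b, x);
  return true;
}

// rotation matrix exp([w]x * dt) via Rodrigues
static void rodrigues(const double* w, double dt, double* R) {
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]) * dt;
  if (th < 1e-14) {
    R[0] = 1; R[1] = 0; R[2] = 0; R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
    return;
  }
  double nx = w[0] * dt / th, ny = w[1] * dt / th, nz = w[2] * dt / th;
  double ct = std::cos(th), st = std::sin(th), vt = 1 - ct;
  R[0] = ct + nx * nx * vt;      R[1] = nx * ny * vt - nz * st; R[2] = nx * nz * vt + ny * st;
  R[3] = nx * ny * vt + nz * st; R[4] = ct + ny * ny * vt;      R[5] = ny * nz * vt - nx * st;
  R[6] = nx * nz * vt - ny * st; R[7] = ny * nz * vt + nx * st; R[8] = ct + nz * nz * vt;
}

static void orthonormalize(double* R) {
  // Gram-Schmidt on rows
  double* r0 = R; double* r1 = R + 3; double* r2 = R + 6;
  double n0 = std::sqrt(r0[0] * r0[0] + r0[1] * r0[1] + r0[2] * r0[2]);
  for (int k = 0; k < 3; ++k) r0[k] /= n0;
  double d = r1[0] * r0[0] + r1[1] * r0[1] + r1[2] * r0[2];
  for (int k = 0; k < 3; ++k) r1[k] -= d * r0[k];
  double n1 = std::sqrt(r1[0] * r1[0] + r1[1] * r1[1] + r1[2] * r1[2]);
  for (int k = 0; k < 3; ++k) r1[k] /= n1;
  r2[0] = r0[1] * r1[2] - r0[2] * r1[1];
  r2[1] = r0[2] * r1[0] - r0[0] * r1[2];
  r2[2] = r0[0] * r1[1] - r0[1] * r1[0];
}

static void body_omega(const RigidBody& B, const double* Lang, double* omega) {
  // omega = R Ib^-1 R^T L
  double tmp[3], tmp2[3];
  mat3_tvec(B.R, Lang, tmp);
  if (!mat3_solve(B.Ib, tmp, tmp2)) {
    tmp2[0] = tmp2[1] = tmp2[2] = 0.0;
  }
  mat3_vec(B.R, tmp2, omega);
}

// write body bead positions (wrapped) and velocities into the global arrays
static void body_project(RigidBody& B, const double* omega, double L,
                         std::vector<double>& X, std::vector<double>& Y,
                         std::vector<double>& Z, std::vector<double>& VX,
                         std::vector<double>& VY, std::vector<double>& VZ) {
  const int nb = (int)B.beads.size();
  for (int k = 0; k < nb; ++k) {
    double rb[3] = {B.ref[3 * k], B.ref[3 * k + 1], B.ref[3 * k + 2]};
    double rl[3];
    mat3_vec(B.R, rb, rl);
    const int i = B.beads[k];
    double px = B.com[0] + rl[0], py = B.com[1] + rl[1], pz = B.com[2] + rl[2];
    X[i] = px - L * std::floor(px / L);
    Y[i] = py - L * std::floor(py / L);
    Z[i] = pz - L * std::floor(pz / L);
    VX[i] = B.vcom[0] + omega[1] * rl[2] - omega[2] * rl[1];
    VY[i] = B.vcom[1] + omega[2] * rl[0] - omega[0] * rl[2];
    VZ[i] = B.vcom[2] + omega[0] * rl[1] - omega[1] * rl[0];
  }
}

// ---------------------------------------------------------------------------
static List run_core(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                     NumericVector charge0, IntegerMatrix bonds, List bodies,
                     NumericMatrix atab, double L, List par, List elec,
                     int nsteps, double seed, int thermo_stride, int frame_stride,
                     int step0) {
  const int n = pos.nrow();
  std::vector<double> X(n), Y(n), Z(n), VX(n), VY(n), VZ(n), charge(n);
  std::vector<int> species(n);
  for (int i = 0; i < n; ++i) {
    X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2);
    VX[i] = vel(i, 0); VY[i] = vel(i, 1); VZ[i] = vel(i, 2);
    species[i] = species0[i] - 1;
    charge[i] = charge0[i];
  }
  std::vector<double> a(64);
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 8; ++j) a[i * 8 + j] = atab(i, j);
  std::vector<int> bond_i, bond_j;
  for (int b = 0; b < bonds.nrow(); ++b) {
    bond_i.push_back(bonds(b, 0) - 1);
    bond_j.push_back(bonds(b, 1) - 1);
  }
  // rigid bodies
  std::vector<RigidBody> rb(bodies.size());
  std::vector<bool> in_body(n, false);
  for (int b = 0; b < bodies.size(); ++b) {
    IntegerVector bi = bodies[b];
    RigidBody& B = rb[b];
    B.beads.resize(bi.size());
    for (int k = 0; k < bi.size(); ++k) {
      B.beads[k] = bi[k] - 1;
      in_body[B.beads[k]] = true;
    }
    const int nb = (int)B.beads.size();
    B.mass = nb;
    // unwrap relative to first bead, centre, derive reference frame
    double x0 = X[B.beads[0]], y0 = Y[B.beads[0]], z0 = Z[B.beads[0]];
    B.ref.resize(3 * nb);
    double cx = 0, cy = 0, cz = 0;
    for (int k = 0; k < nb; ++k) {
      const int i = B.beads[k];
      double ux = x0 + mind(X[i] - x0, L);
      double uy = y0 + mind(Y[i] - y0, L);
      double uz = z0 + mind(Z[i] - z0, L);
      B.ref[3 * k] = ux; B.ref[3 * k + 1] = uy; B.ref[3 * k + 2] = uz;
      cx += ux; cy += uy; cz += uz;
    }
    cx /= nb; cy /= nb; cz /= nb;
    B.com[0] = cx; B.com[1] = cy; B.com[2] = cz;
    for (int k = 0; k < nb; ++k) {
      B.ref[3 * k] -= cx; B.ref[3 * k + 1] -= cy; B.ref[3 * k + 2] -= cz;
    }
    std::fill(B.Ib, B.Ib + 9, 0.0);
    for (int k = 0; k < nb; ++k) {
      double rx = B.ref[3 * k], ry = B.ref[3 * k + 1], rz = B.ref[3 * k + 2];
      double r2 = rx * rx + ry * ry + rz * rz;
      B.Ib[0] += r2 - rx * rx; B.Ib[1] += -rx * ry;     B.Ib[2] += -rx * rz;
      B.Ib[3] += -ry * rx;     B.Ib[4] += r2 - ry * ry; B.Ib[5] += -ry * rz;
      B.Ib[6] += -rz * rx;     B.Ib[7] += -rz * ry;     B.Ib[8] += r2 - rz * rz;
    }
    B.R[0] = 1; B.R[1] = 0; B.R[2] = 0; B.R[3] = 0; B.R[4] = 1; B.R[5] = 0;
    B.R[6] = 0; B.R[7] = 0; B.R[8] = 1;
    // project current bead velocities onto rigid motion
    B.vcom[0] = B.vcom[1] = B.vcom[2] = 0.0;
    for (int k = 0; k < nb; ++k) {
      B.vcom[0] += VX[B.beads[k]]; B.vcom[1] += VY[B.beads[k]];
      B.vcom[2] += VZ[B.beads[k]];
    }
    for (int d = 0; d < 3; ++d) B.vcom[d] /= nb;
    B.Lang[0] = B.Lang[1] = B.Lang[2] = 0.0;
    for (int k = 0; k < nb; ++k) {
      const int i = B.beads[k];
      double rx = B.ref[3 * k], ry = B.ref[3 * k + 1], rz = B.ref[3 * k + 2];
      double vx = VX[i] - B.vcom[0], vy = VY[i] - B.vcom[1], vz = VZ[i] - B.vcom[2];
      B.Lang[0] += ry * vz - rz * vy;
      B.Lang[1] += rz * vx - rx * vz;
      B.Lang[2] += rx * vy - ry * vx;
    }
    double omega[3];
    body_omega(B, B.Lang, omega);
    body_project(B, omega, L, X, Y, Z, VX, VY, VZ);
  }
  std::vector<int> free_idx, all_idx(n), charged_idx;
  for (int i = 0; i < n; ++i) {
    all_idx[i] = i;
    if (!in_body[i]) free_idx.push_back(i);
    if (charge[i] != 0.0) charged_idx.push_back(i);
  }
  const int nfree = (int)free_idx.size();
  const int ndof = 3 * nfree + 6 * (int)rb.size() - 3;

  const double dt = as<double>(par["dt"]);
  const double gamma = as<double>(par["gamma"]);
  const double sigma = as<double>(par["sigma"]);
  const double lvv = as<double>(par["lambda_vv"]);
  const double kbond = as<double>(par["k_bond"]);
  const double r0bond = as<double>(par["r0_bond"]);
  ElecParams ep = parse_elec(elec, L);

  ForceCtx ctx;
  ctx.L = L; ctx.dt = dt; ctx.gamma = gamma; ctx.sigma = sigma;
  ctx.kbond = kbond; ctx.r0bond = r0bond;
  ctx.seed = (uint64_t)seed;
  ctx.all_idx = &all_idx; ctx.charged_idx = &charged_idx;
  ctx.ep = &ep;
  ctx.bond_i = bond_i.empty() ? nullptr : &bond_i;
  ctx.bond_j = bond_i.empty() ? nullptr : &bond_j;
  ctx.atab = &a; ctx.species = &species;

  std::vector<double> fx(n), fy(n), fz(n), fx2(n), fy2(n), fz2(n);
  double e_bond, e_real, e_recip;
  compute_forces(X, Y, Z, VX, VY, VZ, charge, ctx, (uint64_t)step0, fx, fy, fz,
                 e_bond, e_real, e_recip);

  std::vector<double> Fb(3 * rb.size()), Tb(3 * rb.size());
  auto reduce_bodies = [&](const std::vector<double>& gx, const std::vector<double>& gy,
                           const std::vector<double>& gz, std::vector<double>& F,
                           std::vector<double>& T) {
    for (size_t b = 0; b < rb.size(); ++b) {
      RigidBody& B = rb[b];
      double Fx = 0, Fy = 0, Fz = 0, Tx = 0, Ty = 0, Tz = 0;
      for (size_t k = 0; k < B.beads.size(); ++k) {
        const int i = B.beads[k];
        double rbv[3] = {B.ref[3 * k], B.ref[3 * k + 1], B.ref[3 * k + 2]};
        double rl[3];
        mat3_vec(B.R, rbv, rl);
        Fx += gx[i]; Fy += gy[i]; Fz += gz[i];
        Tx += rl[1] * gz[i] - rl[2] * gy[i];
        Ty += rl[2] * gx[i] - rl[0] * gz[i];
        Tz += rl[0] * gy[i] - rl[1] * gx[i];
      }
      F[3 * b] = Fx; F[3 * b + 1] = Fy; F[3 * b + 2] = Fz;
      T[3 * b] = Tx; T[3 * b + 1] = Ty; T[3 * b + 2] = Tz;
    }
  };
  reduce_bodies(fx, fy, fz, Fb, Tb);

  std::vector<double> thermo;
  List frames;
  std::vector<int> frame_steps;
  auto kinetic = [&]() {
    double ek = 0.0;
    for (int a2 = 0; a2 < nfree; ++a2) {
      const int i = free_idx[a2];
      ek += 0.5 * (VX[i] * VX[i] + VY[i] * VY[i] + VZ[i] * VZ[i]);
    }
    for (size_t b = 0; b < rb.size(); ++b) {
      RigidBody& B = rb[b];
      ek += 0.5 * B.mass * (B.vcom[0] * B.vcom[0] + B.vcom[1] * B.vcom[1] +
                            B.vcom[2] * B.vcom[2]);
      double omega[3];
      body_omega(B, B.Lang, omega);
      ek += 0.5 * (omega[0] * B.Lang[0] + omega[1] * B.Lang[1] +
                   omega[2] * B.Lang[2]);
    }
    return ek;
  };
  auto record_thermo = [&](int step_now) {
    double px = 0, py = 0, pz = 0;
    for (int i = 0; i < n; ++i) { px += VX[i]; py += VY[i]; pz += VZ[i]; }
    thermo.push_back(step_now);
    thermo.push_back(2.0 * kinetic() / ndof);
    thermo.push_back(e_bond);
    thermo.push_back(e_real);
    thermo.push_back(e_recip);
    thermo.push_back(px); thermo.push_back(py); thermo.push_back(pz);
  };
  auto snapshot = [&](int step_now) {
    NumericMatrix fp(n, 3);
    for (int i = 0; i < n; ++i) { fp(i, 0) = X[i]; fp(i, 1) = Y[i]; fp(i, 2) = Z[i]; }
    frames.push_back(fp);
    frame_steps.push_back(step_now);
  };

  const double max_disp = 1.0;
  for (int s = 1; s <= nsteps; ++s) {
    const uint64_t gstep = (uint64_t)(step0 + s);
    // free beads: position update + velocity prediction
    for (int a2 = 0; a2 < nfree; ++a2) {
      const int i = free_idx[a2];
      double ddx = dt * VX[i] + 0.5 * dt * dt * fx[i];
      double ddy = dt * VY[i] + 0.5 * dt * dt * fy[i];
      double ddz = dt * VZ[i] + 0.5 * dt * dt * fz[i];
      if (std::fabs(ddx) > max_disp || std::fabs(ddy) > max_disp ||
          std::fabs(ddz) > max_disp) {
        stop("integration unstable at step %d: per-step displacement exceeds "
             "the interaction range; reduce dt", step0 + s);
      }
      double px2 = X[i] + ddx, py2 = Y[i] + ddy, pz2 = Z[i] + ddz;
      X[i] = px2 - L * std::floor(px2 / L);
      Y[i] = py2 - L * std::floor(py2 / L);
      Z[i] = pz2 - L * std::floor(pz2 / L);
      VX[i] += lvv * dt * fx[i];
      VY[i] += lvv * dt * fy[i];
      VZ[i] += lvv * dt * fz[i];
    }
    // rigid bodies: translate + rotate, predict velocities
    for (size_t b = 0; b < rb.size(); ++b) {
      RigidBody& B = rb[b];
      for (int d = 0; d < 3; ++d) {
        B.com[d] += dt * B.vcom[d] + 0.5 * dt * dt * Fb[3 * b + d] / B.mass;
      }
      double omega[3];
      body_omega(B, B.Lang, omega);
      double Rrot[9], Rnew[9];
      rodrigues(omega, dt, Rrot);
      mat3_mul(Rrot, B.R, Rnew);
      std::copy(Rnew, Rnew + 9, B.R);
      orthonormalize(B.R);
      double vpred[3], Lpred[3];
      for (int d = 0; d < 3; ++d) {
        vpred[d] = B.vcom[d] + lvv * dt * Fb[3 * b + d] / B.mass;
        Lpred[d] = B.Lang[d] + lvv * dt * Tb[3 * b + d];
      }
      double omega_p[3];
      body_omega(B, Lpred, omega_p);
      double vc_save[3] = {B.vcom[0], B.vcom[1], B.vcom[2]};
      B.vcom[0] = vpred[0]; B.vcom[1] = vpred[1]; B.vcom[2] = vpred[2];
      body_project(B, omega_p, L, X, Y, Z, VX, VY, VZ);
      B.vcom[0] = vc_save[0]; B.vcom[1] = vc_save[1]; B.vcom[2] = vc_save[2];
    }
    compute_forces(X, Y, Z, VX, VY, VZ, charge, ctx, gstep, fx2, fy2, fz2,
                   e_bond, e_real, e_recip);
    // velocity correction
    for (int a2 = 0; a2 < nfree; ++a2) {
      const int i = free_idx[a2];
      // VX currently holds v + lvv dt f_old; rebuild v then correct
      VX[i] += -lvv * dt * fx[i] + 0.5 * dt * (fx[i] + fx2[i]);
      VY[i] += -lvv * dt * fy[i] + 0.5 * dt * (fy[i] + fy2[i]);
      VZ[i] += -lvv * dt * fz[i] + 0.5 * dt * (fz[i] + fz2[i]);
    }
    std::vector<double> Fb2(3 * rb.size()), Tb2(3 * rb.size());
    reduce_bodies(fx2, fy2, fz2, Fb2, Tb2);
    for (size_t b = 0; b < rb.size(); ++b) {
      RigidBody& B = rb[b];
      for (int d = 0; d < 3; ++d) {
        B.vcom[d] += 0.5 * dt * (Fb[3 * b + d] + Fb2[3 * b + d]) / B.mass;
        B.Lang[d] += 0.5 * dt * (Tb[3 * b + d] + Tb2[3 * b + d]);
      }
      double omega[3];
      body_omega(B, B.Lang, omega);
      body_project(B, omega, L, X, Y, Z, VX, VY, VZ);
    }
    fx.swap(fx2); fy.swap(fy2); fz.swap(fz2);
    Fb.swap(Fb2); Tb.swap(Tb2);
    if (thermo_stride > 0 && (s % thermo_stride == 0 || s == nsteps)) {
      record_thermo(step0 + s);
    }
    if (frame_stride > 0 && (s % frame_stride == 0 || s == nsteps)) {
      snapshot(step0 + s);
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = X[i]; pos_out(i, 1) = Y[i]; pos_out(i, 2) = Z[i];
    vel_out(i, 0) = VX[i]; vel_out(i, 1) = VY[i]; vel_out(i, 2) = VZ[i];
  }
  int nrec = (int)thermo.size() / 8;
  NumericMatrix th(nrec, 8);
  for (int r = 0; r < nrec; ++r)
    for (int c2 = 0; c2 < 8; ++c2) th(r, c2) = thermo[r * 8 + c2];
  colnames(th) = CharacterVector::create("step", "temperature", "e_bond",
                                         "e_elec_real", "e_elec_recip",
                                         "px", "py", "pz");
  return List::create(_["pos"] = pos_out, _["vel"] = vel_out, _["thermo"] = th,
                      _["frames"] = frames,
                      _["frame_steps"] = wrap(frame_steps),
                      _["ndof"] = ndof);
}

// [[Rcpp::export]]
List cpp_dpd_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                 NumericVector charge, IntegerMatrix bonds, List bodies,
                 NumericMatrix atab, double L, List par, List elec, int nsteps,
                 double seed, int thermo_stride, int frame_stride, int step0) {
  return run_core(pos, vel, species, charge, bonds, bodies, atab, L, par, elec,
                  nsteps, seed, thermo_stride, frame_stride, step0);
}

// single force evaluation on raw beads (no rigid-body reduction); used for
// force-level tests and oracles
// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, NumericMatrix vel,
                         IntegerVector species0, NumericVector charge0,
                         IntegerMatrix bonds, NumericMatrix atab, double L,
                         List par, List elec, bool use_cells, bool thermostat,
                         double seed, int step) {
  const int n = pos.nrow();
  std::vector<double> X(n), Y(n), Z(n), VX(n), VY(n), VZ(n), charge(n);
  std::vector<int> species(n), all_idx(n), charged_idx;
  for (int i = 0; i < n; ++i) {
    X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2);
    VX[i] = vel(i, 0); VY[i] = vel(i, 1); VZ[i] = vel(i, 2);
    species[i] = species0[i] - 1;
    charge[i] = charge0[i];
    all_idx[i] = i;
    if (charge[i] != 0.0) charged_idx.push_back(i);
  }
  std::vector<double> a(64);
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 8; ++j) a[i * 8 + j] = atab(i, j);
  std::vector<int> bond_i, bond_j;
  for (int b = 0; b < bonds.nrow(); ++b) {
    bond_i.push_back(bonds(b, 0) - 1);
    bond_j.push_back(bonds(b, 1) - 1);
  }
  ElecParams ep = parse_elec(elec, L);
  ForceCtx ctx;
  ctx.L = L;
  ctx.dt = as<double>(par["dt"]);
  ctx.gamma = as<double>(par["gamma"]);
  ctx.sigma = as<double>(par["sigma"]);
  ctx.kbond = as<double>(par["k_bond"]);
  ctx.r0bond = as<double>(par["r0_bond"]);
  ctx.thermostat = thermostat;
  ctx.use_cells = use_cells;
  ctx.seed = (uint64_t)seed;
  ctx.all_idx = &all_idx;
  ctx.charged_idx = &charged_idx;
  ctx.ep = &ep;
  ctx.bond_i = bond_i.empty() ? nullptr : &bond_i;
  ctx.bond_j = bond_i.empty() ? nullptr : &bond_j;
  ctx.atab = &a;
  ctx.species = &species;
  std::vector<double> fx(n), fy(n), fz(n);
  double e_bond, e_real, e_recip;
  compute_forces(X, Y, Z, VX, VY, VZ, charge, ctx, (uint64_t)step, fx, fy, fz,
                 e_bond, e_real, e_recip);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  out.attr("e_bond") = e_bond;
  out.attr("e_elec_real") = e_real;
  out.attr("e_elec_recip") = e_recip;
  return out;
}

// Ewald forces/energy for an arbitrary (neutral) charge configuration
// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector q, double L, double lambda,
               double C, double alpha, double rcut, int nmax, bool surface) {
  const int n = pos.nrow();
  std::vector<double> X(n), Y(n), Z(n), charge(n);
  std::vector<int> cidx;
  for (int i = 0; i < n; ++i) {
    X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2);
    charge[i] = q[i];
    if (q[i] != 0.0) cidx.push_back(i);
  }
  ElecParams ep;
  ep.enabled = true; ep.C = C; ep.lambda = lambda; ep.alpha = alpha;
  ep.rcut = rcut; ep.nmax = nmax; ep.surface = surface;
  ep.ks.build(L, alpha, nmax);
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  double e_real = 0.0, e_recip = 0.0;
  elec_forces(X, Y, Z, charge, cidx, ep, L, fx, fy, fz, e_real, e_recip);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return List::create(_["forces"] = out, _["energy"] = e_real + e_recip,
                      _["e_real"] = e_real, _["e_recip"] = e_recip);
}

// brute-force periodic-image sum over cubic image shells (validation oracle)
// [[Rcpp::export]]
List cpp_direct_sum(NumericMatrix pos, NumericVector q, double L, double lambda,
                    double C, int nshells) {
  const int n = pos.nrow();
  NumericMatrix f(n, 3);
  double E = 0.0;
  for (int sx = -nshells; sx <= nshells; ++sx)
    for (int sy = -nshells; sy <= nshells; ++sy)
      for (int sz = -nshells; sz <= nshells; ++sz) {
        const bool home = (sx == 0 && sy == 0 && sz == 0);
        for (int i = 0; i < n; ++i) {
          if (q[i] == 0.0) continue;
          for (int j = 0; j < n; ++j) {
            if (q[j] == 0.0) continue;
            if (home && i == j) continue;
            double dx = pos(i, 0) - pos(j, 0) + sx * L;
            double dy = pos(i, 1) - pos(j, 1) + sy * L;
            double dz = pos(i, 2) - pos(j, 2) + sz * L;
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            double qq = C * q[i] * q[j];
            E += 0.5 * qq * slater_U(r, lambda);
            double fr = qq * slater_fr(r, lambda);
            f(i, 0) += fr * dx; f(i, 1) += fr * dy; f(i, 2) += fr * dz;
          }
        }
      }
  return List::create(_["forces"] = f, _["energy"] = E);
}

// all pairs of beads within `cutoff` under minimum image (1-based indices)
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, double L, double cutoff) {
  const int n = pos.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2);
    idx[i] = i;
  }
  std::vector<int> pi, pj;
  for_pairs(X, Y, Z, idx, L, cutoff, true,
            [&](int i, int j, double, double, double, double) {
              pi.push_back(i + 1);
              pj.push_back(j + 1);
            });
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k]; out(k, 1) = pj[k];
  }
  return out;
}
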