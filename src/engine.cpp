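// Minimal coarse-grained MD kernels: shifted LJ/Coulomb nonbonded terms,
// harmonic bonds (incl. elastic network) and angles, leapfrog integration
// with a stochastic velocity-rescaling thermostat and an anisotropic
// Berendsen barostat, steepest-descent minimization, orthorhombic
// periodic boundaries with a Verlet/cell neighbor list.
//
// Units: Angstrom, fs, amu, kJ/mol.  1 amu (A/fs)^2 = 1e4 kJ/mol.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>
using namespace Rcpp;

static const double KE_UNIT = 1e4;        // kJ/mol per amu (A/fs)^2
static const double ACC_UNIT = 1e-4;      // (A/fs^2) per (kJ/mol/A / amu)
static const double KB = 8.3144621e-3;    // kJ/mol/K
static const double PRESS_UNIT = 16605.39; // bar per kJ/mol/A^3
static const double COUL_K = 1389.35458;  // kJ/mol A / e^2


// branchless single-correction minimum image: valid for |d| < 1.5 L,
// guaranteed because coordinates are wrapped into [0, L) at every
// neighbor-list rebuild and beads drift at most skin/2 between rebuilds
static inline double mi(double d, double L) {
  double h = 0.5 * L;
  if (d > h) d -= L; else if (d < -h) d += L;
  return d;
}

// ------------------------------------------------------------------ shift
// Standard shift-function for a 1/r^p term over window (r1, rc):
// force polynomial F(r) = p/r^(p+1) + A(r-r1)^2 + B(r-r1)^3 for r1<r<rc,
// with A, B chosen so F and dF/dr vanish at rc; potential is the integral,
// offset by C so it is zero at rc.  Energy and force are continuous
// everywhere and exactly zero for r >= rc.
struct ShiftPoly {
  double p, r1, rc, A, B, C;
  ShiftPoly(double p_, double r1_, double rc_) : p(p_), r1(r1_), rc(rc_) {
    double d = rc - r1;
    A = -p * ((p + 4) * rc - (p + 1) * r1) / (std::pow(rc, p + 2) * d * d);
    B =  p * ((p + 3) * rc - (p + 1) * r1) / (std::pow(rc, p + 2) * d * d * d);
    C = 1.0 / std::pow(rc, p) - A / 3.0 * d * d * d - B / 4.0 * d * d * d * d;
  }
  // phi: shifted 1/r^p ; f = -dphi/dr
  inline void eval(double r, double &phi, double &f) const {
    if (r >= rc) { phi = 0.0; f = 0.0; return; }
    double rp = std::pow(r, p);
    phi = 1.0 / rp - C;
    f = p / (rp * r);
    if (r > r1) {
      double s = r - r1;
      phi -= A / 3.0 * s * s * s + B / 4.0 * s * s * s * s;
      f += A * s * s + B * s * s * s;
    }
  }
};

// [[Rcpp::export]]
List cpp_shifted_term(NumericVector r, double p, double r1, double rc) {
  ShiftPoly sp(p, r1, rc);
  int n = r.size();
  NumericVector phi(n), f(n);
  for (int i = 0; i < n; ++i) {
    if (r[i] <= 0) stop("r must be > 0");
    sp.eval(r[i], phi[i], f[i]);
  }
  return List::create(_["phi"] = phi, _["f"] = f);
}

// --------------------------------------------------------------- topology
struct System {
  int n;
  std::vector<double> x;         // 3n coords
  std::vector<double> mass, charge;
  std::vector<int> cls;          // 0-based class per bead
  int ncls;
  std::vector<double> c12, c6;   // per class pair (ncls*ncls), 4 eps sig^k
  double eps_r;
  ShiftPoly lj12, lj6, coul;
  double rc, skin;
  bool use_coul;
  // bonded terms
  std::vector<int> bi, bj;  std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak; std::vector<double> at0, akf;
  // exclusions as sorted pair keys i*n+j (i<j)
  std::vector<long long> excl;
  // neighbor list
  std::vector<int> nl_i, nl_j;
  std::vector<double> x_ref;
  bool nl_valid = false;

  System(double lj_r1, double coul_r1, double rc_)
    : lj12(12, lj_r1, rc_), lj6(6, lj_r1, rc_), coul(1, coul_r1, rc_),
      rc(rc_), skin(2.0) {}

  inline bool excluded(int i, int j) const {
    long long key = (long long)std::min(i, j) * n + std::max(i, j);
    return std::binary_search(excl.begin(), excl.end(), key);
  }

  void wrap(const std::vector<double> &box) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        x[3*i+c] -= box[c] * std::floor(x[3*i+c] / box[c]);
  }

  void build_list(const std::vector<double> &box) {
    double rl = rc + skin;
    wrap(box);
    nl_i.clear(); nl_j.clear();
    int ncx = std::max(1, (int)(box[0] / rl));
    int ncy = std::max(1, (int)(box[1] / rl));
    int ncz = std::max(1, (int)(box[2] / rl));
    if (ncx < 3 || ncy < 3 || ncz < 3) {
      // too few cells for the 27-stencil (neighbors would duplicate):
      // fall back to an all-pairs candidate sweep
      double rl2 = rl * rl;
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) {
          double d0 = x[3*i] - x[3*j];
          double d1 = x[3*i+1] - x[3*j+1];
          double d2 = x[3*i+2] - x[3*j+2];
          d0 = mi(d0, box[0]);
          d1 = mi(d1, box[1]);
          d2 = mi(d2, box[2]);
          if (d0*d0 + d1*d1 + d2*d2 < rl2 && !excluded(i, j)) {
            nl_i.push_back(i);
            nl_j.push_back(j);
          }
        }
      x_ref = x;
      nl_valid = true;
      return;
    }
    int ncell = ncx * ncy * ncz;
    std::vector<std::vector<int>> cells(ncell);
    for (int i = 0; i < n; ++i) {
      double px = x[3*i]   - box[0] * std::floor(x[3*i]   / box[0]);
      double py = x[3*i+1] - box[1] * std::floor(x[3*i+1] / box[1]);
      double pz = x[3*i+2] - box[2] * std::floor(x[3*i+2] / box[2]);
      int cx = std::min(ncx - 1, (int)(px / box[0] * ncx));
      int cy = std::min(ncy - 1, (int)(py / box[1] * ncy));
      int cz = std::min(ncz - 1, (int)(pz / box[2] * ncz));
      cells[(cz * ncy + cy) * ncx + cx].push_back(i);
    }
    double rl2 = rl * rl;
    for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
    for (int cx = 0; cx < ncx; ++cx) {
      int c0 = (cz * ncy + cy) * ncx + cx;
      for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nx2 = (cx + dx + ncx) % ncx;
        int ny2 = (cy + dy + ncy) % ncy;
        int nz2 = (cz + dz + ncz) % ncz;
        int c1 = (nz2 * ncy + ny2) * ncx + nx2;
        if (c1 < c0) continue;
        for (size_t a = 0; a < cells[c0].size(); ++a) {
          size_t bstart = (c1 == c0) ? a + 1 : 0;
          for (size_t b = bstart; b < cells[c1].size(); ++b) {
            int i = cells[c0][a], j = cells[c1][b];
            double d0 = x[3*i] - x[3*j];
            double d1 = x[3*i+1] - x[3*j+1];
            double d2 = x[3*i+2] - x[3*j+2];
            d0 = mi(d0, box[0]);
            d1 = mi(d1, box[1]);
            d2 = mi(d2, box[2]);
            if (d0*d0 + d1*d1 + d2*d2 < rl2 && !excluded(i, j)) {
              nl_i.push_back(std::min(i, j));
              nl_j.push_back(std::max(i, j));
            }
          }
        }
      }
    }
    x_ref = x;
    nl_valid = true;
  }

  bool list_stale() const {
    if (!nl_valid) return true;
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double d0 = x[3*i] - x_ref[3*i];
      double d1 = x[3*i+1] - x_ref[3*i+1];
      double d2 = x[3*i+2] - x_ref[3*i+2];
      if (d0*d0 + d1*d1 + d2*d2 > lim) return true;
    }
    return false;
  }

  // full force/energy evaluation; forces and per-axis virial accumulated
  void forces(const std::vector<double> &box, std::vector<double> &f,
              double energy[4], double virial[3], bool brute = false) {
    std::fill(f.begin(), f.end(), 0.0);
    energy[0] = energy[1] = energy[2] = energy[3] = 0.0; // bond,angle,lj,coul
    virial[0] = virial[1] = virial[2] = 0.0;
    double rc2 = rc * rc;
    // nonbonded
    if (!brute && list_stale()) build_list(box);
    size_t npairs = brute ? 0 : nl_i.size();
    for (size_t p = 0; p < (brute ? (size_t)n * (n - 1) / 2 : npairs); ++p) {
      int i, j;
      if (brute) {
        // enumerate upper triangle
        size_t q = p; i = 0;
        size_t row = n - 1;
        while (q >= row) { q -= row; ++i; row--; }
        j = i + 1 + (int)q;
        if (excluded(i, j)) continue;
      } else { i = nl_i[p]; j = nl_j[p]; }
      double d0 = x[3*i] - x[3*j];
      double d1 = x[3*i+1] - x[3*j+1];
      double d2 = x[3*i+2] - x[3*j+2];
      d0 = mi(d0, box[0]);
      d1 = mi(d1, box[1]);
      d2 = mi(d2, box[2]);
      double r2 = d0*d0 + d1*d1 + d2*d2;
      if (r2 >= rc2 || r2 <= 0) continue;
      double r = std::sqrt(r2);
      double invr = 1.0 / r;
      int pc = cls[i] * ncls + cls[j];
      double fscal = 0.0;
      if (c12[pc] > 0) {
        // specialized shifted 12-6 evaluation (no generic pow in the
        // hot loop); same polynomial as ShiftPoly::eval
        double inv2 = invr * invr;
        double inv6 = inv2 * inv2 * inv2;
        double inv12 = inv6 * inv6;
        double phi12 = inv12 - lj12.C, phi6 = inv6 - lj6.C;
        double f12 = 12.0 * inv12 * invr, f6 = 6.0 * inv6 * invr;
        if (r > lj12.r1) {
          double s = r - lj12.r1, s2 = s * s, s3 = s2 * s;
          phi12 -= lj12.A / 3.0 * s3 + lj12.B / 4.0 * s3 * s;
          f12 += lj12.A * s2 + lj12.B * s3;
          phi6 -= lj6.A / 3.0 * s3 + lj6.B / 4.0 * s3 * s;
          f6 += lj6.A * s2 + lj6.B * s3;
        }
        energy[2] += c12[pc] * phi12 - c6[pc] * phi6;
        fscal += c12[pc] * f12 - c6[pc] * f6;
      }
      if (use_coul && charge[i] != 0 && charge[j] != 0) {
        double phic = invr - coul.C, fc = invr * invr;
        if (r > coul.r1) {
          double s = r - coul.r1, s2 = s * s, s3 = s2 * s;
          phic -= coul.A / 3.0 * s3 + coul.B / 4.0 * s3 * s;
          fc += coul.A * s2 + coul.B * s3;
        }
        double qq = COUL_K / eps_r * charge[i] * charge[j];
        energy[3] += qq * phic;
        fscal += qq * fc;
      }
      double fr = fscal * invr;
      f[3*i]   += fr * d0; f[3*j]   -= fr * d0;
      f[3*i+1] += fr * d1; f[3*j+1] -= fr * d1;
      f[3*i+2] += fr * d2; f[3*j+2] -= fr * d2;
      virial[0] += fr * d0 * d0;
      virial[1] += fr * d1 * d1;
      virial[2] += fr * d2 * d2;
    }
    // bonds (incl. elastic network): E = 1/2 k (r - r0)^2
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      double d0 = x[3*i] - x[3*j];
      double d1 = x[3*i+1] - x[3*j+1];
      double d2 = x[3*i+2] - x[3*j+2];
      d0 = mi(d0, box[0]);
      d1 = mi(d1, box[1]);
      d2 = mi(d2, box[2]);
      double r = std::sqrt(d0*d0 + d1*d1 + d2*d2);
      if (r <= 0) continue;
      double dr = r - br0[b];
      energy[0] += 0.5 * bk[b] * dr * dr;
      double fr = -bk[b] * dr / r;  // force on i along +d
      f[3*i]   += fr * d0; f[3*j]   -= fr * d0;
      f[3*i+1] += fr * d1; f[3*j+1] -= fr * d1;
      f[3*i+2] += fr * d2; f[3*j+2] -= fr * d2;
      virial[0] += fr * d0 * d0;
      virial[1] += fr * d1 * d1;
      virial[2] += fr * d2 * d2;
    }
    // harmonic angles: E = 1/2 k (theta - theta0)^2
    for (size_t a = 0; a < ai.size(); ++a) {
      int i = ai[a], j = aj[a], k = ak[a];
      double rij[3], rkj[3];
      for (int c = 0; c < 3; ++c) {
        rij[c] = x[3*i+c] - x[3*j+c];
        rij[c] = mi(rij[c], box[c]);
        rkj[c] = x[3*k+c] - x[3*j+c];
        rkj[c] = mi(rkj[c], box[c]);
      }
      double nij = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
      double nkj = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
      if (nij <= 0 || nkj <= 0) continue;
      double cost = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij * nkj);
      cost = std::max(-1.0, std::min(1.0, cost));
      double theta = std::acos(cost);
      double dth = theta - at0[a];
      energy[1] += 0.5 * akf[a] * dth * dth;
      double sint = std::sqrt(std::max(1e-12, 1.0 - cost * cost));
      double dVdtheta = akf[a] * dth;
      double fi[3], fk[3];
      for (int c = 0; c < 3; ++c) {
        fi[c] = dVdtheta / sint * (rkj[c] / (nij * nkj) - cost * rij[c] / (nij * nij));
        fk[c] = dVdtheta / sint * (rij[c] / (nij * nkj) - cost * rkj[c] / (nkj * nkj));
        f[3*i+c] += fi[c];
        f[3*k+c] += fk[c];
        f[3*j+c] -= fi[c] + fk[c];
      }
      virial[0] += fi[0] * rij[0] + fk[0] * rkj[0];
      virial[1] += fi[1] * rij[1] + fk[1] * rkj[1];
      virial[2] += fi[2] * rij[2] + fk[2] * rkj[2];
    }
  }
};

static System make_system(NumericMatrix coords, NumericVector mass,
                          NumericVector charge, IntegerVector cls,
                          NumericMatrix eps, NumericMatrix sig, double eps_r,
                          double lj_r1, double coul_r1, double rc,
                          IntegerMatrix bonds, NumericVector bond_r0,
                          NumericVector bond_k, IntegerMatrix angles,
                          NumericVector theta0, NumericVector angle_k) {
  System sys(lj_r1, coul_r1, rc);
  int n = coords.nrow();
  sys.n = n;
  sys.x.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) sys.x[3*i+c] = coords(i, c);
  sys.mass = as<std::vector<double>>(mass);
  sys.charge = as<std::vector<double>>(charge);
  sys.cls = as<std::vector<int>>(cls);
  sys.ncls = eps.nrow();
  sys.c12.resize(sys.ncls * sys.ncls);
  sys.c6.resize(sys.ncls * sys.ncls);
  for (int a = 0; a < sys.ncls; ++a)
    for (int b = 0; b < sys.ncls; ++b) {
      double e = eps(a, b), s = sig(a, b);
      sys.c12[a * sys.ncls + b] = 4.0 * e * std::pow(s, 12);
      sys.c6[a * sys.ncls + b] = 4.0 * e * std::pow(s, 6);
    }
  sys.eps_r = eps_r;
  sys.use_coul = false;
  for (int i = 0; i < n; ++i) if (charge[i] != 0) { sys.use_coul = true; break; }
  for (int b = 0; b < bonds.nrow(); ++b) {
    sys.bi.push_back(bonds(b, 0)); sys.bj.push_back(bonds(b, 1));
    sys.br0.push_back(bond_r0[b]); sys.bk.push_back(bond_k[b]);
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    sys.ai.push_back(angles(a, 0)); sys.aj.push_back(angles(a, 1));
    sys.ak.push_back(angles(a, 2));
    sys.at0.push_back(theta0[a]); sys.akf.push_back(angle_k[a]);
  }
  // nonbonded exclusions: bonded 1-2 pairs and angle 1-3 pairs
  for (size_t b = 0; b < sys.bi.size(); ++b) {
    int i = std::min(sys.bi[b], sys.bj[b]), j = std::max(sys.bi[b], sys.bj[b]);
    sys.excl.push_back((long long)i * n + j);
  }
  for (size_t a = 0; a < sys.ai.size(); ++a) {
    int i = std::min(sys.ai[a], sys.ak[a]), j = std::max(sys.ai[a], sys.ak[a]);
    sys.excl.push_back((long long)i * n + j);
  }
  std::sort(sys.excl.begin(), sys.excl.end());
  sys.excl.erase(std::unique(sys.excl.begin(), sys.excl.end()), sys.excl.end());
  return sys;
}

static NumericMatrix to_mat(const std::vector<double> &x, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) m(i, c) = x[3*i+c];
  return m;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix coords, NumericVector box,
                        NumericVector mass, NumericVector charge,
                        IntegerVector cls, NumericMatrix eps,
                        NumericMatrix sig, double eps_r, double lj_r1,
                        double coul_r1, double rc, IntegerMatrix bonds,
                        NumericVector bond_r0, NumericVector bond_k,
                        IntegerMatrix angles, NumericVector theta0,
                        NumericVector angle_k, bool brute = false) {
  System sys = make_system(coords, mass, charge, cls, eps, sig, eps_r,
                           lj_r1, coul_r1, rc, bonds, bond_r0, bond_k,
                           angles, theta0, angle_k);
  std::vector<double> bx = as<std::vector<double>>(box);
  sys.wrap(bx);
  std::vector<double> f(3 * sys.n);
  double e[4], vir[3];
  sys.forces(bx, f, e, vir, brute);
  return List::create(
    _["energy"] = e[0] + e[1] + e[2] + e[3],
    _["components"] = NumericVector::create(
      _["bond"] = e[0], _["angle"] = e[1], _["lj"] = e[2], _["coulomb"] = e[3]),
    _["forces"] = to_mat(f, sys.n),
    _["virial"] = NumericVector::create(vir[0], vir[1], vir[2]));
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, NumericVector box,
                  NumericVector mass, NumericVector charge,
                  IntegerVector cls, NumericMatrix eps, NumericMatrix sig,
                  double eps_r, double lj_r1, double coul_r1, double rc,
                  IntegerMatrix bonds, NumericVector bond_r0,
                  NumericVector bond_k, IntegerMatrix angles,
                  NumericVector theta0, NumericVector angle_k,
                  int max_steps, double init_step, double force_cap,
                  double tol, double max_step) {
  System sys = make_system(coords, mass, charge, cls, eps, sig, eps_r,
                           lj_r1, coul_r1, rc, bonds, bond_r0, bond_k,
                           angles, theta0, angle_k);
  std::vector<double> bx = as<std::vector<double>>(box);
  sys.wrap(bx);
  int n = sys.n;
  std::vector<double> f(3 * n), xtrial(3 * n), ftrial(3 * n);
  double e[4], vir[3], et[4];
  // clash capping: clamp force components so the initial gradient is finite
  auto cap = [&](std::vector<double> &ff) {
    if (force_cap <= 0) return;
    for (size_t i = 0; i < ff.size(); ++i)
      ff[i] = std::max(-force_cap, std::min(force_cap, ff[i]));
  };
  sys.forces(bx, f, e, vir);
  cap(f);
  double energy = e[0] + e[1] + e[2] + e[3];
  if (!std::isfinite(energy))
    stop("minimization error: non-finite initial energy");
  double h = init_step;
  int steps_done = 0;
  std::vector<double> trace;
  trace.push_back(energy);
  for (int it = 0; it < max_steps; ++it) {
    double fmax = 0;
    for (size_t i = 0; i < f.size(); ++i) fmax = std::max(fmax, std::fabs(f[i]));
    if (fmax < tol) break;
    for (int i = 0; i < 3 * n; ++i) xtrial[i] = sys.x[i] + h * f[i] / fmax;
    std::swap(sys.x, xtrial);
    sys.nl_valid = false;
    sys.forces(bx, ftrial, et, vir);
    cap(ftrial);
    double etrial = et[0] + et[1] + et[2] + et[3];
    if (std::isfinite(etrial) && etrial < energy) {
      energy = etrial;
      f = ftrial;
      h = std::min(h * 1.2, max_step);
    } else {
      std::swap(sys.x, xtrial);  // reject
      sys.nl_valid = false;
      h *= 0.2;
      if (h < 1e-7) break;
    }
    trace.push_back(energy);
    steps_done = it + 1;
  }
  return List::create(_["coords"] = to_mat(sys.x, n),
                      _["energy"] = energy,
                      _["steps"] = steps_done,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix coords, NumericMatrix vel, NumericVector box,
                NumericVector mass, NumericVector charge, IntegerVector cls,
                NumericMatrix eps, NumericMatrix sig, double eps_r,
                double lj_r1, double coul_r1, double rc,
                IntegerMatrix bonds, NumericVector bond_r0,
                NumericVector bond_k, IntegerMatrix angles,
                NumericVector theta0, NumericVector angle_k,
                double dt, int n_steps, int stride,
                bool thermostat, double t_ref, double tau_t,
                bool barostat, double p_ref, double tau_p,
                double kappa, bool anisotropic, bool semi_isotropic,
                int seed, double t_explode_factor) {
  System sys = make_system(coords, mass, charge, cls, eps, sig, eps_r,
                           lj_r1, coul_r1, rc, bonds, bond_r0, bond_k,
                           angles, theta0, angle_k);
  int n = sys.n;
  std::vector<double> v(3 * n), bx = as<std::vector<double>>(box);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) v[3*i+c] = vel(i, c);
  if (bx[0] < 2 * rc || bx[1] < 2 * rc || bx[2] < 2 * rc)
    stop("configuration error: box smaller than twice the cutoff");
  sys.wrap(bx);
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double nf = 3.0 * n - 3.0;
  std::vector<double> f(3 * n);
  double e[4], vir[3];
  sys.forces(bx, f, e, vir);

  int n_frames = n_steps / stride + 1;
  NumericMatrix frames(n_frames * n, 3);
  NumericVector frame_times(n_frames);
  NumericMatrix frame_boxes(n_frames, 3);
  int nlog = n_frames;
  NumericMatrix log(nlog, 12); // step T Ebond Eang Elj Ecoul Ekin Pxx Pyy Pzz + box placeholder
  int fidx = 0;

  auto kinetic = [&](const std::vector<double> &vv) {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * sys.mass[i] * (vv[3*i]*vv[3*i] + vv[3*i+1]*vv[3*i+1] +
                                 vv[3*i+2]*vv[3*i+2]);
    return ke * KE_UNIT;  // kJ/mol
  };
  auto record = [&](int step, double ke_onstep) {
    double vol = bx[0] * bx[1] * bx[2];
    double ke_ax[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        ke_ax[c] += sys.mass[i] * v[3*i+c] * v[3*i+c] * KE_UNIT;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        frames(fidx * n + i, c) = sys.x[3*i+c];
    frame_times[fidx] = step * dt;
    for (int c = 0; c < 3; ++c) frame_boxes(fidx, c) = bx[c];
    log(fidx, 0) = step;
    log(fidx, 1) = 2.0 * ke_onstep / (nf * KB);
    log(fidx, 2) = e[0]; log(fidx, 3) = e[1];
    log(fidx, 4) = e[2]; log(fidx, 5) = e[3];
    log(fidx, 6) = ke_onstep;
    for (int c = 0; c < 3; ++c)
      log(fidx, 7 + c) = (ke_ax[c] + vir[c]) / vol * PRESS_UNIT;
    log(fidx, 10) = bx[0] * bx[1] * bx[2];
    log(fidx, 11) = e[0] + e[1] + e[2] + e[3] + ke_onstep;
    fidx++;
  };
  record(0, kinetic(v));

  std::vector<double> vhalf_old(3 * n);
  for (int step = 1; step <= n_steps; ++step) {
    // leapfrog kick
    vhalf_old = v;
    for (int i = 0; i < n; ++i) {
      double a = ACC_UNIT / sys.mass[i];
      v[3*i]   += f[3*i]   * a * dt;
      v[3*i+1] += f[3*i+1] * a * dt;
      v[3*i+2] += f[3*i+2] * a * dt;
    }
    // stochastic velocity rescaling (canonical sampling of kinetic energy)
    if (thermostat) {
      double K = kinetic(v);
      if (K > 0) {
        double Kbar = 0.5 * nf * KB * t_ref;
        double c = std::exp(-dt / tau_t);
        double r1 = gauss(rng);
        std::gamma_distribution<double> gam(0.5 * (nf - 1.0), 1.0);
        double sumr2 = 2.0 * gam(rng);
        double a2 = c + (1.0 - c) * (r1 * r1 + sumr2) * Kbar / (nf * K) +
                    2.0 * r1 * std::sqrt(c * (1.0 - c) * Kbar / (nf * K));
        double alpha = std::sqrt(std::max(0.0, a2));
        for (int i = 0; i < 3 * n; ++i) v[i] *= alpha;
      }
    }
    // drift
    for (int i = 0; i < 3 * n; ++i) sys.x[i] += v[i] * dt;
    // forces at new positions
    sys.forces(bx, f, e, vir);
    // Berendsen barostat: first-order box scaling from instantaneous
    // pressure tensor diagonal; velocities untouched
    if (barostat) {
      double vol = bx[0] * bx[1] * bx[2];
      double pax[3];
      for (int c = 0; c < 3; ++c) {
        double ke_ax = 0;
        for (int i = 0; i < n; ++i)
          ke_ax += sys.mass[i] * v[3*i+c] * v[3*i+c] * KE_UNIT;
        pax[c] = (ke_ax + vir[c]) / vol * PRESS_UNIT;
      }
      if (!anisotropic) {
        double pm = (pax[0] + pax[1] + pax[2]) / 3.0;
        pax[0] = pax[1] = pax[2] = pm;
      } else if (semi_isotropic) {
        double pl = 0.5 * (pax[0] + pax[1]);
        pax[0] = pax[1] = pl;
      }
      bool scaled = false;
      for (int c = 0; c < 3; ++c) {
        double mu = std::cbrt(1.0 - dt * 1e-3 / tau_p * kappa * (p_ref - pax[c]));
        mu = std::max(0.995, std::min(1.005, mu));
        if (mu != 1.0) {
          bx[c] *= mu;
          for (int i = 0; i < n; ++i) sys.x[3*i+c] *= mu;
          scaled = true;
        }
      }
      if (scaled) {
        if (bx[0] < 2 * rc || bx[1] < 2 * rc || bx[2] < 2 * rc)
          stop("configuration error: barostat shrank box below twice the cutoff");
        sys.nl_valid = false;
        sys.forces(bx, f, e, vir);
      }
    }
    if (step % stride == 0) {
      // on-step kinetic energy from averaged half-step velocities
      double ke = 0;
      for (int i = 0; i < n; ++i) {
        double m = sys.mass[i];
        for (int c = 0; c < 3; ++c) {
          double vm = 0.5 * (vhalf_old[3*i+c] + v[3*i+c]);
          ke += 0.5 * m * vm * vm;
        }
      }
      ke *= KE_UNIT;
      double temp = 2.0 * ke / (nf * KB);
      if (t_explode_factor > 0 && thermostat && temp > t_explode_factor * t_ref)
        stop("integration error: temperature exploded (%f K)", temp);
      record(step, ke);
    }
  }
  return List::create(_["frames"] = frames, _["times"] = frame_times,
                      _["boxes"] = frame_boxes, _["log"] = log,
                      _["coords"] = to_mat(sys.x, n),
                      _["velocities"] = to_mat(v, n),
                      _["box"] = NumericVector(bx.begin(), bx.end()));
}
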