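// Core numerics: Go-model energy terms and forces, nonbonded pair
// scheduling, overdamped Brownian propagation with optional pairwise
// hydrodynamics, and in-loop binding-event monitors.
//
// Units throughout: length A, energy kcal/mol, time ps, charge e.
// Coordinates are row-major N x 3.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925287;

// ---------------------------------------------------------------------------
// Deterministic RNG: mt19937_64 (bit-specified by the C++ standard) with an
// explicit Box-Muller transform, so trajectories are reproducible across
// platforms for a given seed.
struct Rng {
  std::mt19937_64 eng;
  bool has_cache;
  double cache;
  explicit Rng(uint64_t seed) : eng(seed), has_cache(false), cache(0.0) {}
  double unif() {  // open (0,1), 53-bit mantissa
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), t = TWO_PI * u2;
    cache = r * std::sin(t);
    has_cache = true;
    return r * std::cos(t);
  }
};

// ---------------------------------------------------------------------------
// Unpacked topology + force-field view

struct FF {
  double k_bond, k_angle, V1, V3;
  double eps_rep, sigma_vdw;
  double eps_s, lambda_D, coul;
  double kBT;
  double z_wall, k_restraint, k_wall;
  double r_short, r_medium;
};

static FF read_ff(const NumericVector& v) {
  FF f;
  f.k_bond = v["k_bond"]; f.k_angle = v["k_angle"];
  f.V1 = v["V1"]; f.V3 = v["V3"];
  f.eps_rep = v["eps_rep"]; f.sigma_vdw = v["sigma_vdw"];
  f.eps_s = v["eps_s"]; f.lambda_D = v["lambda_D"]; f.coul = v["coul"];
  f.kBT = v["kBT"];
  f.z_wall = v["z_wall"]; f.k_restraint = v["k_restraint"]; f.k_wall = v["k_wall"];
  f.r_short = v["r_short"]; f.r_medium = v["r_medium"];
  return f;
}

struct Topo {
  int n;
  std::vector<double> charge, radius, z0;
  std::vector<int> chain, resno, kind, complex_id, side, is_tm;
  // bonded terms
  std::vector<int> b_i, b_j; std::vector<double> b_req;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_eq;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_phi1, d_phi3;
  // native contacts
  std::vector<int> c_i, c_j, c_form; std::vector<double> c_sigma, c_eps;
  // exclusion set for generic nonbonded terms (bonds + 1-3 pairs)
  std::unordered_set<int64_t> excl;
  std::unordered_set<int64_t> contact_set;
  int64_t key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return static_cast<int64_t>(i) * n + j;
  }
  // Nonbonded eligibility: different chains always; same protein chain needs
  // sequence separation >= 3; beads of one nucleotide complex are mutually
  // bonded, never nonbonded.
  bool nonbonded(int i, int j) const {
    if (kind[i] == 1 && kind[j] == 1 && complex_id[i] == complex_id[j]) return false;
    if (kind[i] == 0 && kind[j] == 0 && chain[i] == chain[j] &&
        std::abs(resno[i] - resno[j]) < 3) return false;
    if (excl.count(key(i, j))) return false;
    return true;
  }
};

static Topo read_topo(const List& pack) {
  Topo t;
  NumericVector charge = pack["charge"], radius = pack["radius"], z0 = pack["z0"];
  IntegerVector chain = pack["chain"], resno = pack["resno"], kind = pack["kind"],
    complex_id = pack["complex_id"], side = pack["side"], is_tm = pack["is_tm"];
  t.n = charge.size();
  t.charge.assign(charge.begin(), charge.end());
  t.radius.assign(radius.begin(), radius.end());
  t.z0.assign(z0.begin(), z0.end());
  t.chain.assign(chain.begin(), chain.end());
  t.resno.assign(resno.begin(), resno.end());
  t.kind.assign(kind.begin(), kind.end());
  t.complex_id.assign(complex_id.begin(), complex_id.end());
  t.side.assign(side.begin(), side.end());
  t.is_tm.assign(is_tm.begin(), is_tm.end());
  IntegerMatrix B = pack["bonds"];
  NumericVector breq = pack["bond_req"];
  for (int m = 0; m < B.nrow(); ++m) {
    t.b_i.push_back(B(m, 0)); t.b_j.push_back(B(m, 1));
    t.b_req.push_back(breq[m]);
    t.excl.insert(t.key(B(m, 0), B(m, 1)));
  }
  IntegerMatrix A = pack["angles"];
  NumericVector aeq = pack["angle_eq"];
  for (int m = 0; m < A.nrow(); ++m) {
    t.a_i.push_back(A(m, 0)); t.a_j.push_back(A(m, 1)); t.a_k.push_back(A(m, 2));
    t.a_eq.push_back(aeq[m]);
    t.excl.insert(t.key(A(m, 0), A(m, 2)));
  }
  IntegerMatrix D = pack["dihedrals"];
  NumericVector p1 = pack["dih_phi1"], p3 = pack["dih_phi3"];
  for (int m = 0; m < D.nrow(); ++m) {
    t.d_i.push_back(D(m, 0)); t.d_j.push_back(D(m, 1));
    t.d_k.push_back(D(m, 2)); t.d_l.push_back(D(m, 3));
    t.d_phi1.push_back(p1[m]); t.d_phi3.push_back(p3[m]);
  }
  IntegerMatrix C = pack["contacts"];
  NumericVector cs = pack["contact_sigma"], ce = pack["contact_eps"];
  IntegerVector cf = pack["contact_form"];
  for (int m = 0; m < C.nrow(); ++m) {
    t.c_i.push_back(C(m, 0)); t.c_j.push_back(C(m, 1));
    t.c_sigma.push_back(cs[m]); t.c_eps.push_back(ce[m]);
    t.c_form.push_back(cf[m]);
    t.contact_set.insert(t.key(C(m, 0), C(m, 1)));
  }
  return t;
}

// ---------------------------------------------------------------------------
// Energy terms.  Each accumulates energy and adds -grad to f.

static inline double dist3(const double* x, int i, int j, double* d) {
  d[0] = x[3 * i] - x[3 * j];
  d[1] = x[3 * i + 1] - x[3 * j + 1];
  d[2] = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

static double e_bonds(const double* x, const Topo& t, const FF& ff, double* f) {
  double e = 0, d[3];
  for (size_t m = 0; m < t.b_i.size(); ++m) {
    int i = t.b_i[m], j = t.b_j[m];
    double r = dist3(x, i, j, d);
    if (r < 1e-6) stop("singular geometry: bonded beads overlap");
    double dr = r - t.b_req[m];
    e += ff.k_bond * dr * dr;
    double g = 2.0 * ff.k_bond * dr / r;  // dE/dr / r
    for (int c = 0; c < 3; ++c) {
      f[3 * i + c] -= g * d[c];
      f[3 * j + c] += g * d[c];
    }
  }
  return e;
}

static double e_angles(const double* x, const Topo& t, const FF& ff, double* f) {
  double e = 0;
  for (size_t m = 0; m < t.a_i.size(); ++m) {
    int ia = t.a_i[m], ib = t.a_j[m], ic = t.a_k[m];
    double u[3], v[3];
    double ru = dist3(x, ia, ib, u);
    double rv = dist3(x, ic, ib, v);
    double ct = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (ru * rv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;  // regularized near-collinear gradient
    double dth = th - t.a_eq[m];
    e += ff.k_angle * dth * dth;
    double dEdth = 2.0 * ff.k_angle * dth;
    for (int c = 0; c < 3; ++c) {
      double dcu = (v[c] / rv - ct * u[c] / ru) / ru;  // d cos / d u
      double dcv = (u[c] / ru - ct * v[c] / rv) / rv;
      double fa = dEdth * dcu / st;   // F = -dE/dth * dth/da, dth/dcos = -1/st
      double fc = dEdth * dcv / st;
      f[3 * ia + c] += fa;
      f[3 * ic + c] += fc;
      f[3 * ib + c] -= fa + fc;
    }
  }
  return e;
}

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static double e_dihedrals(const double* x, const Topo& t, const FF& ff, double* f) {
  double e = 0;
  for (size_t m = 0; m < t.d_i.size(); ++m) {
    int i1 = t.d_i[m], i2 = t.d_j[m], i3 = t.d_k[m], i4 = t.d_l[m];
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = x[3 * i2 + c] - x[3 * i1 + c];
      b2[c] = x[3 * i3 + c] - x[3 * i2 + c];
      b3[c] = x[3 * i4 + c] - x[3 * i3 + c];
    }
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double n1sq = n1[0]*n1[0] + n1[1]*n1[1] + n1[2]*n1[2];
    double n2sq = n2[0]*n2[0] + n2[1]*n2[1] + n2[2]*n2[2];
    double b1sq = b1[0]*b1[0] + b1[1]*b1[1] + b1[2]*b1[2];
    double b3sq = b3[0]*b3[0] + b3[1]*b3[1] + b3[2]*b3[2];
    double b2sq = b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2];
    double lb2 = std::sqrt(b2sq);
    // the dihedral (and its torque arm |b2|/|n|) is singular when three
    // consecutive beads are collinear; the term is switched off within
    // ~4 degrees of collinearity (sin^2 theta < 5e-3), which caps the
    // force the term can exert
    if (lb2 < 1e-8 || n1sq < 5e-3 * b1sq * b2sq ||
        n2sq < 5e-3 * b2sq * b3sq) continue;
    double m1[3];
    cross3(n1, n2, m1);
    double sy = (m1[0]*b2[0] + m1[1]*b2[1] + m1[2]*b2[2]) / lb2;
    double cphi = n1[0]*n2[0] + n1[1]*n2[1] + n1[2]*n2[2];
    double phi = std::atan2(sy, cphi);
    e += 0.5 * ff.V1 * (1.0 + std::cos(phi - t.d_phi1[m]))
       + 0.5 * ff.V3 * (1.0 + std::cos(3.0 * phi - t.d_phi3[m]));
    double dEdphi = -0.5 * ff.V1 * std::sin(phi - t.d_phi1[m])
                    - 1.5 * ff.V3 * std::sin(3.0 * phi - t.d_phi3[m]);
    double dp1[3], dp4[3], dp2[3];
    double c12 = b1[0]*b2[0] + b1[1]*b2[1] + b1[2]*b2[2];
    double c32 = b3[0]*b2[0] + b3[1]*b2[1] + b3[2]*b2[2];
    for (int c = 0; c < 3; ++c) {
      dp1[c] = -(lb2 / n1sq) * n1[c];
      dp4[c] =  (lb2 / n2sq) * n2[c];
      dp2[c] = -(1.0 + c12 / (lb2 * lb2)) * dp1[c] + (c32 / (lb2 * lb2)) * dp4[c];
    }
    for (int c = 0; c < 3; ++c) {
      f[3 * i1 + c] -= dEdphi * dp1[c];
      f[3 * i2 + c] -= dEdphi * dp2[c];
      f[3 * i3 + c] -= dEdphi * (-dp1[c] - dp2[c] - dp4[c]);
      f[3 * i4 + c] -= dEdphi * dp4[c];
    }
  }
  return e;
}

static inline double dist3_sq(const double* x, int i, int j, double* d) {
  d[0] = x[3 * i] - x[3 * j];
  d[1] = x[3 * i + 1] - x[3 * j + 1];
  d[2] = x[3 * i + 2] - x[3 * j + 2];
  return d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
}

// Single native-contact pair.  Even powers only: works on r^2, no sqrt.
static inline double contact_pair(const double* x, int i, int j, double sigma,
                                  double eps, int form, double* f) {
  double d[3];
  double r2 = dist3_sq(x, i, j, d);
  if (r2 < 1e-12) stop("singular geometry: overlapping beads");
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2, s10 = s6 * s2 * s2, s12 = s10 * s2;
  double u, g;  // g = (dU/dr)/r
  if (form == 0) {  // 12-10-6, minimum -eps at r = sigma
    u = eps * (13.0 * s12 - 18.0 * s10 + 4.0 * s6);
    g = eps * (-156.0 * s12 + 180.0 * s10 - 24.0 * s6) / r2;
  } else {          // 12-10 alternative
    u = eps * (5.0 * s12 - 6.0 * s10);
    g = eps * (-60.0 * s12 + 60.0 * s10) / r2;
  }
  for (int c = 0; c < 3; ++c) {
    f[3 * i + c] -= g * d[c];
    f[3 * j + c] += g * d[c];
  }
  return u;
}

static inline double repulsive_pair(const double* x, int i, int j, const FF& ff,
                                    double* f) {
  double d[3];
  double r2 = dist3_sq(x, i, j, d);
  if (r2 < 1e-12) stop("singular geometry: overlapping beads");
  double s2 = ff.sigma_vdw * ff.sigma_vdw / r2;
  double s12 = s2 * s2 * s2; s12 *= s12;
  double u = ff.eps_rep * s12;
  double g = -12.0 * u / r2;
  for (int c = 0; c < 3; ++c) {
    f[3 * i + c] -= g * d[c];
    f[3 * j + c] += g * d[c];
  }
  return u;
}

static inline double elec_pair(const double* x, int i, int j, const Topo& t,
                               const FF& ff, double* f) {
  double d[3];
  double r = dist3(x, i, j, d);
  if (r < 1e-6) stop("singular geometry: overlapping beads");
  double u = ff.coul * t.charge[i] * t.charge[j] *
             std::exp(-r / ff.lambda_D) / (ff.eps_s * r);
  double dudr = -u * (1.0 / r + 1.0 / ff.lambda_D);
  double g = dudr / r;
  for (int c = 0; c < 3; ++c) {
    f[3 * i + c] -= g * d[c];
    f[3 * j + c] += g * d[c];
  }
  return u;
}

static double e_membrane(const double* x, const Topo& t, const FF& ff, double* f) {
  double e = 0;
  for (int i = 0; i < t.n; ++i) {
    double z = x[3 * i + 2];
    if (t.is_tm[i]) {
      double dz = z - t.z0[i];
      e += ff.k_restraint * dz * dz;
      f[3 * i + 2] -= 2.0 * ff.k_restraint * dz;
    } else if (t.side[i] == 1) {         // extracellular: kept above +z_wall
      if (z < ff.z_wall) {
        double dz = z - ff.z_wall;
        e += ff.k_wall * dz * dz;
        f[3 * i + 2] -= 2.0 * ff.k_wall * dz;
      }
    } else if (t.side[i] == -1) {        // intracellular / nucleotide: below -z_wall
      if (z > -ff.z_wall) {
        double dz = z + ff.z_wall;
        e += ff.k_wall * dz * dz;
        f[3 * i + 2] -= 2.0 * ff.k_wall * dz;
      }
    }
  }
  return e;
}

// ---------------------------------------------------------------------------
// Exact full evaluation (no scheduling): used by the R energy-term functions.

// [[Rcpp::export(name = ".cgp_energy")]]
List cgp_energy(List pack, NumericMatrix coords, NumericVector ffvec,
                LogicalVector which_terms) {
  Topo t = read_topo(pack);
  FF ff = read_ff(ffvec);
  int n = t.n;
  if (coords.nrow() != n) stop("coords/topology size mismatch");
  std::vector<double> x(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  bool w_bond = which_terms[0], w_angle = which_terms[1], w_dih = which_terms[2],
       w_con = which_terms[3], w_rep = which_terms[4], w_elec = which_terms[5],
       w_mem = which_terms[6];
  NumericVector terms = NumericVector::create(
      _["bond"] = 0.0, _["angle"] = 0.0, _["dihedral"] = 0.0,
      _["contact"] = 0.0, _["repulsive"] = 0.0, _["electrostatic"] = 0.0,
      _["membrane"] = 0.0);
  if (w_bond) terms["bond"] = e_bonds(x.data(), t, ff, f.data());
  if (w_angle) terms["angle"] = e_angles(x.data(), t, ff, f.data());
  if (w_dih) terms["dihedral"] = e_dihedrals(x.data(), t, ff, f.data());
  if (w_con) {
    double e = 0;
    for (size_t m = 0; m < t.c_i.size(); ++m)
      e += contact_pair(x.data(), t.c_i[m], t.c_j[m], t.c_sigma[m], t.c_eps[m],
                        t.c_form[m], f.data());
    terms["contact"] = e;
  }
  if (w_rep) {
    double e = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (!t.nonbonded(i, j) || t.contact_set.count(t.key(i, j))) continue;
        double d[3];
        if (dist3(x.data(), i, j, d) > ff.r_medium) continue;
        e += repulsive_pair(x.data(), i, j, ff, f.data());
      }
    terms["repulsive"] = e;
  }
  if (w_elec) {
    double e = 0;
    for (int i = 0; i < n; ++i) {
      if (t.charge[i] == 0.0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (t.charge[j] == 0.0 || !t.nonbonded(i, j)) continue;
        e += elec_pair(x.data(), i, j, t, ff, f.data());
      }
    }
    terms["electrostatic"] = e;
  }
  if (w_mem) terms["membrane"] = e_membrane(x.data(), t, ff, f.data());
  NumericMatrix forces(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) forces(i, c) = f[3 * i + c];
  double tot = 0;
  for (int k = 0; k < terms.size(); ++k) tot += terms[k];
  return List::create(_["terms"] = terms, _["total"] = tot,
                      _["forces"] = forces);
}

// Exact distance-class pair lists at the current coordinates (no skin).
// [[Rcpp::export(name = ".cgp_pair_classes")]]
List cgp_pair_classes(List pack, NumericMatrix coords, NumericVector ffvec) {
  Topo t = read_topo(pack);
  FF ff = read_ff(ffvec);
  int n = t.n;
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  std::vector<int> si, sj, mi, mj, fi, fj;
  double d[3];
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (!t.nonbonded(i, j)) continue;
      double r = dist3(x.data(), i, j, d);
      bool charged = t.charge[i] != 0.0 && t.charge[j] != 0.0;
      if (r <= ff.r_short) { si.push_back(i + 1); sj.push_back(j + 1); }
      else if (r < ff.r_medium) { mi.push_back(i + 1); mj.push_back(j + 1); }
      else if (charged) { fi.push_back(i + 1); fj.push_back(j + 1); }
    }
  auto mk = [](std::vector<int>& a, std::vector<int>& b) {
    IntegerMatrix m(a.size(), 2);
    for (size_t k = 0; k < a.size(); ++k) { m(k, 0) = a[k]; m(k, 1) = b[k]; }
    return m;
  };
  return List::create(_["short"] = mk(si, sj), _["medium"] = mk(mi, mj),
                      _["electrostatic_far"] = mk(fi, fj));
}

// ---------------------------------------------------------------------------
// Rotne-Prager-Yamakawa pairwise mobility (3N x 3N), units A^2/ps.

static void rpy_fill(const std::vector<double>& x, const std::vector<double>& a,
                     double kBT_over_eta, std::vector<double>& D, int n) {
  // kBT_over_eta supplied in units such that kBT/(6 pi eta a[A]) is A^2/ps
  int dim = 3 * n;
  std::fill(D.begin(), D.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    double dii = kBT_over_eta / (6.0 * M_PI * a[i]);
    for (int c = 0; c < 3; ++c) D[(3 * i + c) * dim + (3 * i + c)] = dii;
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double r = std::sqrt(r2);
      double ai = a[i], aj = a[j];
      double blk[9];
      if (r > ai + aj) {
        double pre = kBT_over_eta / (8.0 * M_PI * r);
        double asq = (ai * ai + aj * aj) / r2;
        double c1 = pre * (1.0 + asq / 3.0);
        double c2 = pre * (1.0 - asq) / r2;
        for (int p = 0; p < 3; ++p)
          for (int q = 0; q < 3; ++q)
            blk[3 * p + q] = (p == q ? c1 : 0.0) + c2 * d[p] * d[q];
      } else {
        // overlap regularization with the mean radius
        double am = 0.5 * (ai + aj);
        double pre = kBT_over_eta / (6.0 * M_PI * am);
        double c1 = pre * (1.0 - 9.0 * r / (32.0 * am));
        double c2 = (r > 1e-8) ? pre * 3.0 / (32.0 * am * r) : 0.0;
        for (int p = 0; p < 3; ++p)
          for (int q = 0; q < 3; ++q)
            blk[3 * p + q] = (p == q ? c1 : 0.0) + c2 * d[p] * d[q];
      }
      for (int p = 0; p < 3; ++p)
        for (int q = 0; q < 3; ++q) {
          D[(3 * i + p) * dim + (3 * j + q)] = blk[3 * p + q];
          D[(3 * j + q) * dim + (3 * i + p)] = blk[3 * p + q];
        }
    }
}

// [[Rcpp::export(name = ".cgp_rpy_tensor")]]
NumericMatrix cgp_rpy_tensor(NumericMatrix coords, NumericVector radii,
                             double kBT_over_eta) {
  int n = coords.nrow(), dim = 3 * n;
  std::vector<double> x(3 * n), a(radii.begin(), radii.end());
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  std::vector<double> D(dim * dim);
  rpy_fill(x, a, kBT_over_eta, D, n);
  NumericMatrix out(dim, dim);
  for (int p = 0; p < dim; ++p)
    for (int q = 0; q < dim; ++q) out(p, q) = D[p * dim + q];
  return out;
}

// In-place lower Cholesky; returns false if not positive definite.
static bool cholesky(std::vector<double>& A, int dim) {
  for (int i = 0; i < dim; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * dim + j];
      for (int k = 0; k < j; ++k) s -= A[i * dim + k] * A[j * dim + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * dim + i] = std::sqrt(s);
      } else {
        A[i * dim + j] = s / A[j * dim + j];
      }
    }
    for (int j = i + 1; j < dim; ++j) A[i * dim + j] = 0.0;
  }
  return true;
}

// Truncated-expansion noise factor: B_ij = b_i (delta_ij sqrt(D_ii)
// + beta (1-delta_ij) D_ij / sqrt(D_jj)), with b_i chosen so the marginal
// variance (B B^T)_ii equals D_ii exactly.  beta = 1/2 is the first-order
// expansion of the matrix square root about the diagonal.
static void tea_factor(const std::vector<double>& D, std::vector<double>& B,
                       int dim, double beta) {
  for (int i = 0; i < dim; ++i) {
    double dii = D[i * dim + i];
    double acc = 0.0;
    for (int j = 0; j < dim; ++j) {
      if (j == i) continue;
      double djj = D[j * dim + j];
      double eps = D[i * dim + j] * D[i * dim + j] / (dii * djj);
      acc += eps;
    }
    double bi = std::sqrt(dii / (dii + beta * beta * acc * dii));
    for (int j = 0; j < dim; ++j) {
      if (j == i) B[i * dim + j] = bi * std::sqrt(dii);
      else B[i * dim + j] = bi * beta * D[i * dim + j] / std::sqrt(D[j * dim + j]);
    }
  }
}

// [[Rcpp::export(name = ".cgp_noise_factor")]]
NumericMatrix cgp_noise_factor(NumericMatrix D, std::string scheme, double beta) {
  int dim = D.nrow();
  std::vector<double> A(dim * dim);
  for (int p = 0; p < dim; ++p)
    for (int q = 0; q < dim; ++q) A[p * dim + q] = D(p, q);
  std::vector<double> B(dim * dim, 0.0);
  if (scheme == "cholesky") {
    if (!cholesky(A, dim)) stop("mobility tensor not positive definite");
    B = A;
  } else {
    tea_factor(A, B, dim, beta);
  }
  NumericMatrix out(dim, dim);
  for (int p = 0; p < dim; ++p)
    for (int q = 0; q < dim; ++q) out(p, q) = B[p * dim + q];
  return out;
}

// ---------------------------------------------------------------------------
// Brownian propagation with the production pair schedule.

struct Monitor {
  std::vector<int> i, j;
  std::vector<double> sigma;
  double gamma;
  int trigger;
  bool terminating;
};

// [[Rcpp::export(name = ".cgp_run_bd")]]
List cgp_run_bd(List pack, NumericMatrix coords, NumericVector ffvec,
                NumericVector Dfree, List opts, List monitors,
                IntegerMatrix dist_pairs, double seed) {
  Topo t = read_topo(pack);
  FF ff = read_ff(ffvec);
  int n = t.n;
  if (coords.nrow() != n) stop("coords/topology size mismatch");

  double dt = as<double>(opts["dt_ps"]);
  long nsteps = as<double>(opts["nsteps"]);
  int list_every = as<int>(opts["list_every"]);
  int medium_every = as<int>(opts["medium_every"]);
  int check_every = as<int>(opts["check_every"]);
  int snap_every = as<int>(opts["snap_every"]);          // 0 = none
  bool store_coords = as<bool>(opts["store_coords"]);
  bool record_monitors = as<bool>(opts["record_monitors"]);
  bool record_energy = as<bool>(opts["record_energy"]);
  double max_disp = as<double>(opts["max_disp"]);
  double max_step = as<double>(opts["max_step"]);  // clamp; <=0 disables
  long n_capped = 0;
  bool tensor_mode = as<bool>(opts["tensor_mode"]);
  int tensor_every = as<int>(opts["tensor_every"]);
  std::string noise_scheme = as<std::string>(opts["noise_scheme"]);
  double tea_beta = as<double>(opts["tea_beta"]);
  double kBT_over_eta = as<double>(opts["kBT_over_eta"]);
  double skin = as<double>(opts["skin"]);

  std::vector<Monitor> mons;
  for (int g = 0; g < monitors.size(); ++g) {
    List mg = monitors[g];
    Monitor mm;
    IntegerVector gi = mg["i"], gj = mg["j"];
    NumericVector gs = mg["sigma"];
    for (int k = 0; k < gi.size(); ++k) {
      mm.i.push_back(gi[k] - 1); mm.j.push_back(gj[k] - 1);
      mm.sigma.push_back(gs[k]);
    }
    mm.gamma = as<double>(mg["gamma"]);
    mm.trigger = as<int>(mg["trigger"]);
    mm.terminating = as<bool>(mg["terminating"]);
    mons.push_back(mm);
  }

  std::vector<double> x(3 * n), f(3 * n), fheld(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);

  Rng rng(static_cast<uint64_t>(seed));

  // precomputed per-bead stepping factors (free-draining)
  std::vector<double> drift(n), sq(n);
  for (int i = 0; i < n; ++i) {
    drift[i] = dt * Dfree[i] / ff.kBT;
    sq[i] = std::sqrt(2.0 * Dfree[i] * dt);
  }

  int dim = 3 * n;
  std::vector<double> Dt, Bt, xi, corr;
  if (tensor_mode) {
    Dt.resize(dim * dim); Bt.resize(dim * dim);
    xi.resize(dim); corr.resize(dim);
  }

  // pair lists (with skin)
  std::vector<int> rs_i, rs_j, rm_i, rm_j;            // repulsive short/medium
  std::vector<int> cs_idx, cm_idx;                    // contact indices by class
  std::vector<int> es_i, es_j, em_i, em_j;            // electrostatic short/held
  std::vector<double> a_radii(t.radius);

  // per-pair classification, computed once: bit0 = generic repulsion applies,
  // bit1 = both charged (electrostatics applies)
  std::vector<unsigned char> ptype(static_cast<size_t>(n) * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (!t.nonbonded(i, j)) continue;
      unsigned char v = t.contact_set.count(t.key(i, j)) ? 0 : 1;
      if (t.charge[i] != 0.0 && t.charge[j] != 0.0) v |= 2;
      ptype[static_cast<size_t>(i) * n + j] = v;
    }

  auto rebuild = [&]() {
    rs_i.clear(); rs_j.clear(); rm_i.clear(); rm_j.clear();
    es_i.clear(); es_j.clear(); em_i.clear(); em_j.clear();
    cs_idx.clear(); cm_idx.clear();
    double rshort2 = (ff.r_short + skin) * (ff.r_short + skin);
    double rmed2 = (ff.r_medium + skin) * (ff.r_medium + skin);
    double d[3];
    for (int i = 0; i < n; ++i) {
      const unsigned char* row = &ptype[static_cast<size_t>(i) * n];
      for (int j = i + 1; j < n; ++j) {
        unsigned char v = row[j];
        if (!v) continue;
        double r2 = dist3_sq(x.data(), i, j, d);
        if (v & 1) {
          if (r2 <= rshort2) { rs_i.push_back(i); rs_j.push_back(j); }
          else if (r2 < rmed2) { rm_i.push_back(i); rm_j.push_back(j); }
        }
        if (v & 2) {
          if (r2 <= rshort2) { es_i.push_back(i); es_j.push_back(j); }
          else { em_i.push_back(i); em_j.push_back(j); }  // no cutoff
        }
      }
    }
    double rshort = ff.r_short + skin, rmed = ff.r_medium + skin;
    for (size_t m = 0; m < t.c_i.size(); ++m) {
      double r = dist3(x.data(), t.c_i[m], t.c_j[m], d);
      if (r <= rshort) cs_idx.push_back(m);
      else if (r < rmed) cm_idx.push_back(m);
    }
  };

  auto eval_short = [&](double* acc) {
    e_bonds(x.data(), t, ff, acc);
    e_angles(x.data(), t, ff, acc);
    e_dihedrals(x.data(), t, ff, acc);
    e_membrane(x.data(), t, ff, acc);
    for (size_t k = 0; k < rs_i.size(); ++k)
      repulsive_pair(x.data(), rs_i[k], rs_j[k], ff, acc);
    for (size_t k = 0; k < cs_idx.size(); ++k) {
      int m = cs_idx[k];
      contact_pair(x.data(), t.c_i[m], t.c_j[m], t.c_sigma[m], t.c_eps[m],
                   t.c_form[m], acc);
    }
    for (size_t k = 0; k < es_i.size(); ++k)
      elec_pair(x.data(), es_i[k], es_j[k], t, ff, acc);
  };

  auto eval_medium = [&](double* acc) {
    for (size_t k = 0; k < rm_i.size(); ++k)
      repulsive_pair(x.data(), rm_i[k], rm_j[k], ff, acc);
    for (size_t k = 0; k < cm_idx.size(); ++k) {
      int m = cm_idx[k];
      contact_pair(x.data(), t.c_i[m], t.c_j[m], t.c_sigma[m], t.c_eps[m],
                   t.c_form[m], acc);
    }
    for (size_t k = 0; k < em_i.size(); ++k)
      elec_pair(x.data(), em_i[k], em_j[k], t, ff, acc);
  };

  auto count_formed = [&](const Monitor& mm) {
    int cnt = 0;
    double d[3];
    for (size_t k = 0; k < mm.i.size(); ++k) {
      double r = dist3(x.data(), mm.i[k], mm.j[k], d);
      if (r <= mm.gamma * mm.sigma[k]) ++cnt;
    }
    return cnt;
  };

  // output buffers
  long nframes = (snap_every > 0) ? (nsteps / snap_every + 1) : 0;
  NumericMatrix snaps(store_coords && nframes > 0 ? nframes : 0,
                      store_coords && nframes > 0 ? dim : 0);
  std::vector<double> frame_times;
  std::vector<std::vector<int>> mon_trace;   // per frame, per group
  std::vector<std::vector<double>> dist_trace;
  std::vector<double> energy_trace;
  int fired_group = -1;
  long fired_step = -1;
  int status = 0;  // 0 timeout, 1 event, 2 NaN abort
  long frame_count = 0;

  auto snapshot = [&](long stepnum) {
    frame_times.push_back(stepnum * dt);
    if (store_coords && frame_count < snaps.nrow()) {
      for (int p = 0; p < dim; ++p) snaps(frame_count, p) = x[p];
    }
    if (record_monitors) {
      std::vector<int> row;
      for (auto& mm : mons) row.push_back(count_formed(mm));
      mon_trace.push_back(row);
    }
    if (dist_pairs.nrow() > 0) {
      std::vector<double> row;
      double d[3];
      for (int p = 0; p < dist_pairs.nrow(); ++p)
        row.push_back(dist3(x.data(), dist_pairs(p, 0) - 1,
                            dist_pairs(p, 1) - 1, d));
      dist_trace.push_back(row);
    }
    if (record_energy) {
      double e = 0;
      std::vector<double> tmp(dim, 0.0);
      e += e_bonds(x.data(), t, ff, tmp.data());
      e += e_angles(x.data(), t, ff, tmp.data());
      e += e_dihedrals(x.data(), t, ff, tmp.data());
      e += e_membrane(x.data(), t, ff, tmp.data());
      for (size_t m = 0; m < t.c_i.size(); ++m)
        e += contact_pair(x.data(), t.c_i[m], t.c_j[m], t.c_sigma[m],
                          t.c_eps[m], t.c_form[m], tmp.data());
      for (size_t k = 0; k < rs_i.size(); ++k)
        e += repulsive_pair(x.data(), rs_i[k], rs_j[k], ff, tmp.data());
      for (size_t k = 0; k < rm_i.size(); ++k)
        e += repulsive_pair(x.data(), rm_i[k], rm_j[k], ff, tmp.data());
      for (size_t k = 0; k < es_i.size(); ++k)
        e += elec_pair(x.data(), es_i[k], es_j[k], t, ff, tmp.data());
      for (size_t k = 0; k < em_i.size(); ++k)
        e += elec_pair(x.data(), em_i[k], em_j[k], t, ff, tmp.data());
      energy_trace.push_back(e);
    }
    ++frame_count;
  };

  rebuild();
  std::fill(fheld.begin(), fheld.end(), 0.0);
  eval_medium(fheld.data());
  snapshot(0);

  // initial event check (a pre-docked start fires immediately)
  for (size_t g = 0; g < mons.size(); ++g) {
    if (mons[g].terminating && count_formed(mons[g]) >= mons[g].trigger) {
      fired_group = g; fired_step = 0; status = 1;
    }
  }

  long step = 0;
  if (status != 1) {
    for (step = 1; step <= nsteps; ++step) {
      if ((step - 1) % list_every == 0 && step > 1) {
        rebuild();
      }
      if ((step - 1) % medium_every == 0) {
        std::fill(fheld.begin(), fheld.end(), 0.0);
        eval_medium(fheld.data());
      }
      std::fill(f.begin(), f.end(), 0.0);
      eval_short(f.data());
      for (int p = 0; p < dim; ++p) f[p] += fheld[p];

      if (tensor_mode) {
        if ((step - 1) % tensor_every == 0) {
          rpy_fill(x, a_radii, kBT_over_eta, Dt, n);
          if (noise_scheme == "cholesky") {
            std::vector<double> A(Dt);
            if (!cholesky(A, dim)) {
              // fallback: free-draining noise
              std::fill(Bt.begin(), Bt.end(), 0.0);
              for (int i = 0; i < n; ++i)
                for (int c = 0; c < 3; ++c)
                  Bt[(3 * i + c) * dim + (3 * i + c)] = std::sqrt(Dfree[i]);
            } else Bt = A;
          } else {
            tea_factor(Dt, Bt, dim, tea_beta);
          }
        }
        for (int p = 0; p < dim; ++p) xi[p] = rng.norm();
        double sdt = std::sqrt(2.0 * dt);
        for (int p = 0; p < dim; ++p) {
          double drft = 0.0, nse = 0.0;
          const double* Drow = &Dt[p * dim];
          const double* Brow = &Bt[p * dim];
          for (int q = 0; q < dim; ++q) {
            drft += Drow[q] * f[q];
            nse += Brow[q] * xi[q];
          }
          double dxp = dt * drft / ff.kBT + sdt * nse;
          if (max_step > 0 && std::abs(dxp) > max_step) {
            dxp = (dxp > 0 ? max_step : -max_step);
            ++n_capped;
          } else if (std::abs(dxp) > max_disp) {
            stop("instability: displacement exceeded %0.1f A in one step; "
                 "reduce the time step", max_disp);
          }
          x[p] += dxp;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          for (int c = 0; c < 3; ++c) {
            double dxp = drift[i] * f[3 * i + c] + sq[i] * rng.norm();
            if (max_step > 0 && std::abs(dxp) > max_step) {
              dxp = (dxp > 0 ? max_step : -max_step);
              ++n_capped;
            } else if (std::abs(dxp) > max_disp) {
              stop("instability: displacement exceeded %0.1f A in one step; "
                   "reduce the time step", max_disp);
            }
            x[3 * i + c] += dxp;
          }
        }
      }

      if (step % check_every == 0) {
        bool bad = false;
        for (int p = 0; p < dim; ++p)
          if (!std::isfinite(x[p])) { bad = true; break; }
        if (bad) { status = 2; break; }
        bool done = false;
        for (size_t g = 0; g < mons.size(); ++g) {
          if (mons[g].terminating && count_formed(mons[g]) >= mons[g].trigger) {
            fired_group = g; fired_step = step; status = 1; done = true;
            break;
          }
        }
        if (done) { if (snap_every > 0) snapshot(step); break; }
      }
      if (snap_every > 0 && step % snap_every == 0) snapshot(step);
      if (step % 20000 == 0) Rcpp::checkUserInterrupt();
    }
  }
  if (step > nsteps) step = nsteps;

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) final_coords(i, c) = x[3 * i + c];

  List out;
  out["coords"] = final_coords;
  out["status"] = status;
  out["steps_done"] = static_cast<double>(status == 1 ? fired_step : step);
  out["time_ps"] = static_cast<double>(status == 1 ? fired_step : step) * dt;
  out["event_group"] = fired_group + 1;  // 0 if none
  out["n_capped"] = static_cast<double>(n_capped);
  out["frame_times"] = wrap(frame_times);
  if (store_coords) out["frames"] = snaps;
  if (record_monitors) {
    IntegerMatrix mt(mon_trace.size(), mons.size());
    for (size_t r = 0; r < mon_trace.size(); ++r)
      for (size_t g = 0; g < mons.size(); ++g) mt(r, g) = mon_trace[r][g];
    out["monitor_counts"] = mt;
  }
  if (dist_pairs.nrow() > 0) {
    NumericMatrix dtm(dist_trace.size(), dist_pairs.nrow());
    for (size_t r = 0; r < dist_trace.size(); ++r)
      for (int p = 0; p < dist_pairs.nrow(); ++p) dtm(r, p) = dist_trace[r][p];
    out["distances"] = dtm;
  }
  if (record_energy) out["energy"] = wrap(energy_trace);
  return out;
}
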