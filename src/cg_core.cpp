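// Coarse-grained energy/force kernels, BAOAB Langevin integrator, and a 1-D
// umbrella sampler. Units: kcal/mol, Angstrom, reduced time; kB in kcal/mol/K.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K
static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// counter-based RNG: splitmix64 finalizer over (seed, counter) -> U(0,1),
// Box-Muller for normals.  Deterministic and restartable by global step index.
static inline uint64_t sm64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static inline double u01(uint64_t seed, uint64_t ctr) {
  uint64_t h = sm64(seed ^ (ctr * 0xda942042e4dd58b5ULL));
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0); // in (0,1)
}
// one Box-Muller pair per counter (both outputs used where possible)
static inline void gauss2_ctr(uint64_t seed, uint64_t ctr, double* z0,
                              double* z1) {
  double u1 = u01(seed, 2u * ctr + 1u);
  double u2 = u01(seed, 2u * ctr + 2u);
  double R = std::sqrt(-2.0 * std::log(u1));
  *z0 = R * std::cos(TWO_PI * u2);
  *z1 = R * std::sin(TWO_PI * u2);
}
static inline double gauss_ctr(uint64_t seed, uint64_t ctr) {
  double z0, z1;
  gauss2_ctr(seed, ctr, &z0, &z1);
  return z0;
}

// ---------------------------------------------------------------------------
// energy categories (keep in sync with R side)
enum Cat {
  LOCAL_FOLDED = 0, LOCAL_DISORDERED, CONTACT_INTRA, CONTACT_CORE_RE,
  CONTACT_CORE_CORE, LINKER_PAIRS, DNA_BONDED, DNA_STACK_PAIR,
  ELECTROSTATIC, EXCLUDED_VOLUME, BIAS, CONTAINER, NCAT
};

struct System {
  int n;
  std::vector<double> charge, radius, mass;
  std::vector<int> fixed;
  // bonds
  std::vector<int> b_i, b_j, b_cat;
  std::vector<double> b_k, b_r0;
  // angles
  std::vector<int> a_i, a_j, a_k, a_type, a_cls, a_cat;
  std::vector<double> a_kf, a_th0;
  // dihedrals
  std::vector<int> d_i, d_j, d_k, d_l, d_type, d_cls, d_cat;
  std::vector<double> d_kf, d_phi0;
  // contacts (Go 12-10); cat maps to Cat slices
  std::vector<int> c_i, c_j, c_cat;
  std::vector<double> c_r0, c_eps;
  // statistical tables: row-major [ncls x ng]
  int ang_ng = 0, dih_ng = 0, ncls = 0;
  std::vector<double> ang_tab, dih_tab;
  // nonbonded
  double ev_eps = 0.2, elec_cutoff = 50.0, lB = 0.0, lambdaD = 1.0;
  std::unordered_set<long long> excl_ev, excl_dh;
  // container
  bool has_container = false;
  double cont_cx = 0, cont_cy = 0, cont_cz = 0, cont_R = 0, cont_k = 10.0;
  // bias on centroid distance
  bool has_bias = false, bias_half = true;
  double bias_k = 0, bias_r0 = 0;
  std::vector<int> biasA, biasB;
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

static System parse_system(const List& s) {
  System S;
  NumericVector q = s["charge"], rad = s["radius"], m = s["mass"];
  IntegerVector fx = s["fixed"];
  S.n = q.size();
  S.charge.assign(q.begin(), q.end());
  S.radius.assign(rad.begin(), rad.end());
  S.mass.assign(m.begin(), m.end());
  S.fixed.assign(fx.begin(), fx.end());
  IntegerVector bi = s["b_i"], bj = s["b_j"], bc = s["b_cat"];
  NumericVector bk = s["b_k"], br = s["b_r0"];
  S.b_i.assign(bi.begin(), bi.end()); S.b_j.assign(bj.begin(), bj.end());
  S.b_cat.assign(bc.begin(), bc.end());
  S.b_k.assign(bk.begin(), bk.end()); S.b_r0.assign(br.begin(), br.end());
  IntegerVector ai = s["a_i"], aj = s["a_j"], ak = s["a_k"], at = s["a_type"],
    acl = s["a_cls"], aca = s["a_cat"];
  NumericVector akf = s["a_kf"], ath = s["a_th0"];
  S.a_i.assign(ai.begin(), ai.end()); S.a_j.assign(aj.begin(), aj.end());
  S.a_k.assign(ak.begin(), ak.end()); S.a_type.assign(at.begin(), at.end());
  S.a_cls.assign(acl.begin(), acl.end()); S.a_cat.assign(aca.begin(), aca.end());
  S.a_kf.assign(akf.begin(), akf.end()); S.a_th0.assign(ath.begin(), ath.end());
  IntegerVector di = s["d_i"], dj = s["d_j"], dk = s["d_k"], dl = s["d_l"],
    dt = s["d_type"], dcl = s["d_cls"], dca = s["d_cat"];
  NumericVector dkf = s["d_kf"], dph = s["d_phi0"];
  S.d_i.assign(di.begin(), di.end()); S.d_j.assign(dj.begin(), dj.end());
  S.d_k.assign(dk.begin(), dk.end()); S.d_l.assign(dl.begin(), dl.end());
  S.d_type.assign(dt.begin(), dt.end()); S.d_cls.assign(dcl.begin(), dcl.end());
  S.d_cat.assign(dca.begin(), dca.end());
  S.d_kf.assign(dkf.begin(), dkf.end()); S.d_phi0.assign(dph.begin(), dph.end());
  IntegerVector ci = s["c_i"], cj = s["c_j"], cc = s["c_cat"];
  NumericVector cr = s["c_r0"], ce = s["c_eps"];
  S.c_i.assign(ci.begin(), ci.end()); S.c_j.assign(cj.begin(), cj.end());
  S.c_cat.assign(cc.begin(), cc.end());
  S.c_r0.assign(cr.begin(), cr.end()); S.c_eps.assign(ce.begin(), ce.end());
  NumericMatrix atab = s["ang_tab"], dtab = s["dih_tab"];
  S.ncls = atab.nrow(); S.ang_ng = atab.ncol(); S.dih_ng = dtab.ncol();
  S.ang_tab.assign(atab.begin(), atab.end()); // column-major; we index manually
  S.dih_tab.assign(dtab.begin(), dtab.end());
  S.ev_eps = as<double>(s["ev_eps"]);
  S.elec_cutoff = as<double>(s["elec_cutoff"]);
  S.lB = as<double>(s["lB"]);
  S.lambdaD = as<double>(s["lambdaD"]);
  IntegerVector eei = s["excl_ev_i"], eej = s["excl_ev_j"];
  for (int t = 0; t < eei.size(); ++t) S.excl_ev.insert(pkey(eei[t], eej[t], S.n));
  IntegerVector edi = s["excl_dh_i"], edj = s["excl_dh_j"];
  for (int t = 0; t < edi.size(); ++t) S.excl_dh.insert(pkey(edi[t], edj[t], S.n));
  List cont = s["container"];
  S.has_container = as<bool>(cont["has"]);
  if (S.has_container) {
    NumericVector cen = cont["center"];
    S.cont_cx = cen[0]; S.cont_cy = cen[1]; S.cont_cz = cen[2];
    S.cont_R = as<double>(cont["radius"]);
    S.cont_k = as<double>(cont["k"]);
  }
  List bias = s["bias"];
  S.has_bias = as<bool>(bias["has"]);
  if (S.has_bias) {
    S.bias_k = as<double>(bias["k"]);
    S.bias_r0 = as<double>(bias["r0"]);
    S.bias_half = as<bool>(bias["half"]);
    IntegerVector ga = bias["groupA"], gb = bias["groupB"];
    S.biasA.assign(ga.begin(), ga.end());
    S.biasB.assign(gb.begin(), gb.end());
  }
  return S;
}

// table value at column-major (cls, col) for tab with ncls rows
static inline double tabv(const std::vector<double>& tab, int ncls, int cls, int col) {
  return tab[(size_t)col * ncls + cls];
}

// Catmull-Rom on a uniform grid over [x0, x0 + (ng-1)*dx].
// periodic: wrap indices (grid covers one period of ng points, point ng == point 0
// conceptually lives at x0 + ng*dx). clamped: one-sided tangents at the ends.
static double table_eval(const std::vector<double>& tab, int ncls, int cls, int ng,
                         double x0, double dx, bool periodic, double x, double* dE) {
  double t;
  int k0;
  if (periodic) {
    double period = ng * dx;
    double u = (x - x0) - std::floor((x - x0) / period) * period;
    if (u < 0) u += period;
    if (u >= period) u -= period;
    k0 = (int)std::floor(u / dx);
    if (k0 >= ng) k0 = ng - 1;
    t = u / dx - k0;
  } else {
    double u = (x - x0) / dx;
    if (u <= 0) { u = 0; }
    if (u >= ng - 1) { u = ng - 1 - 1e-12; }
    k0 = (int)std::floor(u);
    t = u - k0;
  }
  auto Y = [&](int k) -> double {
    if (periodic) { k = ((k % ng) + ng) % ng; }
    else { if (k < 0) k = 0; if (k > ng - 1) k = ng - 1; }
    return tabv(tab, ncls, cls, k);
  };
  double ym1 = Y(k0 - 1), y0 = Y(k0), y1 = Y(k0 + 1), y2 = Y(k0 + 2);
  double m0, m1;
  if (!periodic && k0 == 0) m0 = y1 - y0; else m0 = 0.5 * (y1 - ym1);
  if (!periodic && k0 >= ng - 2) m1 = y1 - y0; else m1 = 0.5 * (y2 - y0);
  double t2 = t * t, t3 = t2 * t;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  double val = h00 * y0 + h10 * m0 + h01 * y1 + h11 * m1;
  double dh00 = 6 * t2 - 6 * t, dh10 = 3 * t2 - 4 * t + 1;
  double dh01 = -6 * t2 + 6 * t, dh11 = 3 * t2 - 2 * t;
  *dE = (dh00 * y0 + dh10 * m0 + dh01 * y1 + dh11 * m1) / dx;
  return val;
}

struct NbList {
  std::vector<int> ev_i, ev_j;     // excluded-volume pairs
  std::vector<int> dh_i, dh_j;     // charged pairs
  std::vector<double> ref;         // coords at build time
  double skin = 4.0;
  bool built = false;
};

static void build_nblist(const System& S, const std::vector<double>& x, NbList& nb) {
  nb.ev_i.clear(); nb.ev_j.clear(); nb.dh_i.clear(); nb.dh_j.clear();
  int n = S.n;
  double dh_cut = S.elec_cutoff + nb.skin;
  double dh_cut2 = dh_cut * dh_cut;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      long long key = pkey(i, j, n);
      double sig = S.radius[i] + S.radius[j];
      double ev_cut = 2.0 * sig + nb.skin;
      if (r2 < ev_cut * ev_cut && !S.excl_ev.count(key)) {
        nb.ev_i.push_back(i); nb.ev_j.push_back(j);
      }
      if (S.charge[i] != 0 && S.charge[j] != 0 && r2 < dh_cut2 &&
          !S.excl_dh.count(key)) {
        nb.dh_i.push_back(i); nb.dh_j.push_back(j);
      }
    }
  }
  nb.ref = x;
  nb.built = true;
}

static bool nblist_stale(const std::vector<double>& x, const NbList& nb) {
  if (!nb.built) return true;
  double lim = 0.25 * nb.skin * nb.skin; // (skin/2)^2
  for (size_t i = 0; i < x.size(); i += 3) {
    double dx = x[i] - nb.ref[i], dy = x[i + 1] - nb.ref[i + 1],
           dz = x[i + 2] - nb.ref[i + 2];
    if (dx * dx + dy * dy + dz * dz > lim) return true;
  }
  return false;
}

// Go 12-10 contact: U = eps*(5 s^12 - 6 s^10), s = r0/r; r clamped to >= 0.5 r0
// below which energy/force are held at the clamp point (documented).
static inline double go1210(double r, double r0, double eps, double* dUdr) {
  double rc = (r < 0.5 * r0) ? 0.5 * r0 : r;
  double s = r0 / rc;
  double s2 = s * s, s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
  double U = eps * (5.0 * s12 - 6.0 * s10);
  *dUdr = (r < 0.5 * r0) ? 0.0 : 60.0 * eps * (s10 - s12) / rc;
  return U;
}

// main energy + force evaluation
static void energy_forces(const System& S, const std::vector<double>& x,
                          const NbList& nb, std::vector<double>& F,
                          std::vector<double>& E, double* rc_out) {
  int n = S.n;
  F.assign(3 * n, 0.0);
  E.assign(NCAT, 0.0);
  auto addf = [&](int i, double fx, double fy, double fz) {
    F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz;
  };
  // bonds: U = k (r - r0)^2  (CafeMol convention, no 1/2)
  for (size_t t = 0; t < S.b_i.size(); ++t) {
    int i = S.b_i[t], j = S.b_j[t];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.b_r0[t];
    E[S.b_cat[t]] += S.b_k[t] * dr * dr;
    double c = -2.0 * S.b_k[t] * dr / (r > 1e-12 ? r : 1e-12);
    addf(i, c * dx, c * dy, c * dz);
    addf(j, -c * dx, -c * dy, -c * dz);
  }
  // angles
  for (size_t t = 0; t < S.a_i.size(); ++t) {
    int i = S.a_i[t], j = S.a_j[t], k = S.a_k[t];
    double rijx = x[3 * i] - x[3 * j], rijy = x[3 * i + 1] - x[3 * j + 1],
           rijz = x[3 * i + 2] - x[3 * j + 2];
    double rkjx = x[3 * k] - x[3 * j], rkjy = x[3 * k + 1] - x[3 * j + 1],
           rkjz = x[3 * k + 2] - x[3 * j + 2];
    double rij = std::sqrt(rijx * rijx + rijy * rijy + rijz * rijz);
    double rkj = std::sqrt(rkjx * rkjx + rkjy * rkjy + rkjz * rkjz);
    double dot = rijx * rkjx + rijy * rkjy + rijz * rkjz;
    double cosv = dot / (rij * rkj);
    if (cosv > 1.0) cosv = 1.0; if (cosv < -1.0) cosv = -1.0;
    double th = std::acos(cosv);
    double Ea, dEdth;
    if (S.a_type[t] == 0) {
      double d = th - S.a_th0[t];
      Ea = S.a_kf[t] * d * d;
      dEdth = 2.0 * S.a_kf[t] * d;
    } else {
      Ea = table_eval(S.ang_tab, S.ncls, S.a_cls[t], S.ang_ng, 0.0,
                      M_PI / (S.ang_ng - 1), false, th, &dEdth);
      Ea *= S.a_kf[t]; dEdth *= S.a_kf[t];
    }
    E[S.a_cat[t]] += Ea;
    double sinv = std::sqrt(1.0 - cosv * cosv);
    if (sinv < 1e-8) sinv = 1e-8;
    double c = -dEdth / sinv; // dU/dcos = -dU/dth / sin
    // d cos / d ri etc.
    double inv_ij = 1.0 / rij, inv_kj = 1.0 / rkj;
    double fix = c * (rkjx * inv_ij * inv_kj - cosv * rijx * inv_ij * inv_ij);
    double fiy = c * (rkjy * inv_ij * inv_kj - cosv * rijy * inv_ij * inv_ij);
    double fiz = c * (rkjz * inv_ij * inv_kj - cosv * rijz * inv_ij * inv_ij);
    double fkx = c * (rijx * inv_ij * inv_kj - cosv * rkjx * inv_kj * inv_kj);
    double fky = c * (rijy * inv_ij * inv_kj - cosv * rkjy * inv_kj * inv_kj);
    double fkz = c * (rijz * inv_ij * inv_kj - cosv * rkjz * inv_kj * inv_kj);
    addf(i, -fix, -fiy, -fiz);     // F = -dU/dx; c already has the minus for dU/dth
    addf(k, -fkx, -fky, -fkz);
    addf(j, fix + fkx, fiy + fky, fiz + fkz);
  }
  // dihedrals
  for (size_t t = 0; t < S.d_i.size(); ++t) {
    int i = S.d_i[t], j = S.d_j[t], k = S.d_k[t], l = S.d_l[t];
    double b1x = x[3 * j] - x[3 * i], b1y = x[3 * j + 1] - x[3 * i + 1],
           b1z = x[3 * j + 2] - x[3 * i + 2];
    double b2x = x[3 * k] - x[3 * j], b2y = x[3 * k + 1] - x[3 * j + 1],
           b2z = x[3 * k + 2] - x[3 * j + 2];
    double b3x = x[3 * l] - x[3 * k], b3y = x[3 * l + 1] - x[3 * k + 1],
           b3z = x[3 * l + 2] - x[3 * k + 2];
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
           n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
           n2z = b2x * b3y - b2y * b3x;
    double b2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double mx = n1y * b2z - n1z * b2y, my = n1z * b2x - n1x * b2z,
           mz = n1x * b2y - n1y * b2x;
    double xx = n1x * n2x + n1y * n2y + n1z * n2z;
    double yy = (mx * n2x + my * n2y + mz * n2z) / (b2n > 1e-12 ? b2n : 1e-12);
    double phi = std::atan2(yy, xx);
    double Ed, dEdphi;
    if (S.d_type[t] == 0) {
      // U = kf (1 - cos(phi - phi0))
      Ed = S.d_kf[t] * (1.0 - std::cos(phi - S.d_phi0[t]));
      dEdphi = S.d_kf[t] * std::sin(phi - S.d_phi0[t]);
    } else {
      Ed = table_eval(S.dih_tab, S.ncls, S.d_cls[t], S.dih_ng, -M_PI,
                      TWO_PI / S.dih_ng, true, phi, &dEdphi);
      Ed *= S.d_kf[t]; dEdphi *= S.d_kf[t];
    }
    E[S.d_cat[t]] += Ed;
    double n1sq = n1x * n1x + n1y * n1y + n1z * n1z;
    double n2sq = n2x * n2x + n2y * n2y + n2z * n2z;
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;
    // analytic dihedral gradient for phi = atan2((n1 x b2).n2/|b2|, n1.n2):
    // dphi/dri = +(|b2|/|n1|^2) n1, dphi/drl = -(|b2|/|n2|^2) n2,
    // dphi/drj = -(1+c1) dphi/dri + c3 dphi/drl,
    // dphi/drk = c1 dphi/dri - (1+c3) dphi/drl,
    // c1 = b1.b2/|b2|^2, c3 = b3.b2/|b2|^2 (verified by finite differences)
    double gix = b2n / n1sq * n1x, giy = b2n / n1sq * n1y,
           giz = b2n / n1sq * n1z;
    double glx = -b2n / n2sq * n2x, gly = -b2n / n2sq * n2y,
           glz = -b2n / n2sq * n2z;
    double c1 = (b1x * b2x + b1y * b2y + b1z * b2z) / (b2n * b2n);
    double c3 = (b3x * b2x + b3y * b2y + b3z * b2z) / (b2n * b2n);
    double gjx = -(1 + c1) * gix + c3 * glx;
    double gjy = -(1 + c1) * giy + c3 * gly;
    double gjz = -(1 + c1) * giz + c3 * glz;
    double gkx = c1 * gix - (1 + c3) * glx;
    double gky = c1 * giy - (1 + c3) * gly;
    double gkz = c1 * giz - (1 + c3) * glz;
    addf(i, -dEdphi * gix, -dEdphi * giy, -dEdphi * giz);
    addf(j, -dEdphi * gjx, -dEdphi * gjy, -dEdphi * gjz);
    addf(k, -dEdphi * gkx, -dEdphi * gky, -dEdphi * gkz);
    addf(l, -dEdphi * glx, -dEdphi * gly, -dEdphi * glz);
  }
  // contacts
  for (size_t t = 0; t < S.c_i.size(); ++t) {
    int i = S.c_i[t], j = S.c_j[t];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dUdr;
    E[S.c_cat[t]] += go1210(r, S.c_r0[t], S.c_eps[t], &dUdr);
    double c = -dUdr / (r > 1e-12 ? r : 1e-12);
    addf(i, c * dx, c * dy, c * dz);
    addf(j, -c * dx, -c * dy, -c * dz);
  }
  // excluded volume: U = eps (sig/r)^12 - eps (1/2)^12, zero beyond 2 sig
  for (size_t t = 0; t < nb.ev_i.size(); ++t) {
    int i = nb.ev_i[t], j = nb.ev_j[t];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double sig = S.radius[i] + S.radius[j];
    if (r2 >= 4.0 * sig * sig) continue;
    double r = std::sqrt(r2);
    double rcl = (r < 0.4 * sig) ? 0.4 * sig : r;
    double s = sig / rcl;
    double s2 = s * s, s6 = s2 * s2 * s2, s12 = s6 * s6;
    double shift = S.ev_eps * std::pow(0.5, 12.0);
    E[EXCLUDED_VOLUME] += S.ev_eps * s12 - shift;
    double dUdr = (r < 0.4 * sig) ? 0.0 : -12.0 * S.ev_eps * s12 / rcl;
    double c = -dUdr / (r > 1e-12 ? r : 1e-12);
    addf(i, c * dx, c * dy, c * dz);
    addf(j, -c * dx, -c * dy, -c * dz);
  }
  // Debye-Hueckel, truncated and shifted at elec_cutoff
  {
    double rc = S.elec_cutoff;
    double ushift = std::exp(-rc / S.lambdaD) / rc;
    for (size_t t = 0; t < nb.dh_i.size(); ++t) {
      int i = nb.dh_i[t], j = nb.dh_j[t];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      double pre = S.lB * S.charge[i] * S.charge[j];
      double ex = std::exp(-r / S.lambdaD);
      E[ELECTROSTATIC] += pre * (ex / r - ushift);
      double dUdr = -pre * ex * (1.0 / (r * r) + 1.0 / (S.lambdaD * r));
      double c = -dUdr / r;
      addf(i, c * dx, c * dy, c * dz);
      addf(j, -c * dx, -c * dy, -c * dz);
    }
  }
  // container: half-harmonic wall, U = 1/2 k (d - R)^2 outside
  if (S.has_container) {
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - S.cont_cx, dy = x[3 * i + 1] - S.cont_cy,
             dz = x[3 * i + 2] - S.cont_cz;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > S.cont_R) {
        double exc = d - S.cont_R;
        E[CONTAINER] += 0.5 * S.cont_k * exc * exc;
        double c = -S.cont_k * exc / d;
        addf(i, c * dx, c * dy, c * dz);
      }
    }
  }
  // centroid-distance bias
  double rc_val = NA_REAL;
  if (S.has_bias || (S.biasA.size() && S.biasB.size())) {
    double ax = 0, ay = 0, az = 0, bx = 0, by = 0, bz = 0;
    int na = S.biasA.size(), nbg = S.biasB.size();
    for (int t = 0; t < na; ++t) {
      ax += x[3 * S.biasA[t]]; ay += x[3 * S.biasA[t] + 1]; az += x[3 * S.biasA[t] + 2];
    }
    for (int t = 0; t < nbg; ++t) {
      bx += x[3 * S.biasB[t]]; by += x[3 * S.biasB[t] + 1]; bz += x[3 * S.biasB[t] + 2];
    }
    ax /= na; ay /= na; az /= na; bx /= nbg; by /= nbg; bz /= nbg;
    double dx = ax - bx, dy = ay - by, dz = az - bz;
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    rc_val = d;
    if (S.has_bias && S.bias_k > 0) {
      double dd = d - S.bias_r0;
      double fac = S.bias_half ? 0.5 : 1.0;
      E[BIAS] += fac * S.bias_k * dd * dd;
      double dUdr = 2.0 * fac * S.bias_k * dd;
      double c = -dUdr / (d > 1e-12 ? d : 1e-12);
      for (int t = 0; t < na; ++t)
        addf(S.biasA[t], c * dx / na, c * dy / na, c * dz / na);
      for (int t = 0; t < nbg; ++t)
        addf(S.biasB[t], -c * dx / nbg, -c * dy / nbg, -c * dz / nbg);
    }
  }
  if (rc_out) *rc_out = rc_val;
}

// [[Rcpp::export]]
List cpp_energy_forces(List sys, NumericMatrix coords) {
  System S = parse_system(sys);
  std::vector<double> x(3 * S.n);
  for (int i = 0; i < S.n; ++i) {
    x[3 * i] = coords(i, 0); x[3 * i + 1] = coords(i, 1); x[3 * i + 2] = coords(i, 2);
    if (!R_finite(coords(i, 0)) || !R_finite(coords(i, 1)) || !R_finite(coords(i, 2)))
      stop("non-finite coordinate at bead %d", i + 1);
  }
  NbList nb; nb.skin = 0.0;
  build_nblist(S, x, nb);
  std::vector<double> F, E;
  double rc;
  energy_forces(S, x, nb, F, E, &rc);
  NumericMatrix Fm(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    Fm(i, 0) = F[3 * i]; Fm(i, 1) = F[3 * i + 1]; Fm(i, 2) = F[3 * i + 2];
  }
  NumericVector Ev(E.begin(), E.end());
  Ev.attr("names") = CharacterVector::create(
    "local_folded", "local_disordered", "contacts_intra", "contacts_CoreRE",
    "contacts_CoreCore", "linker_pairs", "dna_bonded", "dna_stack_pair",
    "electrostatic", "excluded_volume", "bias", "container");
  double tot = 0; for (int c = 0; c < NCAT; ++c) tot += E[c];
  return List::create(_["breakdown"] = Ev, _["total"] = tot, _["forces"] = Fm,
                      _["rc"] = rc);
}

// BAOAB Langevin run. Returns frames (stride), energy log, rc samples, final state.
// [[Rcpp::export]]
List cpp_run(List sys, NumericMatrix coords, NumericMatrix vels, int nsteps,
             double dt, double gamma, double temperature, double seed_d,
             int step0, int stride, int rc_stride) {
  System S = parse_system(sys);
  uint64_t seed = (uint64_t)seed_d;
  int n = S.n;
  std::vector<double> x(3 * n), v(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3 * i + d] = coords(i, d); v[3 * i + d] = vels(i, d); }
  for (int i = 0; i < n; ++i)
    if (S.fixed[i]) { v[3 * i] = v[3 * i + 1] = v[3 * i + 2] = 0.0; }

  NbList nb;
  build_nblist(S, x, nb);
  std::vector<double> F, E;
  double rcv;
  energy_forces(S, x, nb, F, E, &rcv);

  int nframes = (stride > 0) ? (nsteps / stride) : 0;
  NumericVector frames((R_xlen_t)nframes * n * 3);
  NumericMatrix elog(nframes, NCAT + 3); // step, cats..., total, kinT
  std::vector<double> rcs;
  int fidx = 0;

  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double kT = KB * temperature;

  for (int t = 0; t < nsteps; ++t) {
    uint64_t gstep = (uint64_t)(step0 + t);
    // B
    for (int i = 0; i < n; ++i) {
      if (S.fixed[i]) continue;
      double hm = 0.5 * dt / S.mass[i];
      v[3 * i] += hm * F[3 * i]; v[3 * i + 1] += hm * F[3 * i + 1];
      v[3 * i + 2] += hm * F[3 * i + 2];
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (S.fixed[i]) continue;
      x[3 * i] += 0.5 * dt * v[3 * i]; x[3 * i + 1] += 0.5 * dt * v[3 * i + 1];
      x[3 * i + 2] += 0.5 * dt * v[3 * i + 2];
    }
    // O
    if (gamma > 0) {
      double c2 = std::sqrt((1.0 - c1 * c1));
      for (int i = 0; i < n; ++i) {
        if (S.fixed[i]) continue;
        double sd = c2 * std::sqrt(kT / S.mass[i]);
        uint64_t base = (gstep * (uint64_t)n + (uint64_t)i) * 2u;
        double z0, z1, z2, zspare;
        gauss2_ctr(seed, base, &z0, &z1);
        gauss2_ctr(seed, base + 1, &z2, &zspare);
        v[3 * i] = c1 * v[3 * i] + sd * z0;
        v[3 * i + 1] = c1 * v[3 * i + 1] + sd * z1;
        v[3 * i + 2] = c1 * v[3 * i + 2] + sd * z2;
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (S.fixed[i]) continue;
      x[3 * i] += 0.5 * dt * v[3 * i]; x[3 * i + 1] += 0.5 * dt * v[3 * i + 1];
      x[3 * i + 2] += 0.5 * dt * v[3 * i + 2];
    }
    if (nblist_stale(x, nb)) build_nblist(S, x, nb);
    energy_forces(S, x, nb, F, E, &rcv);
    // B
    for (int i = 0; i < n; ++i) {
      if (S.fixed[i]) continue;
      double hm = 0.5 * dt / S.mass[i];
      v[3 * i] += hm * F[3 * i]; v[3 * i + 1] += hm * F[3 * i + 1];
      v[3 * i + 2] += hm * F[3 * i + 2];
    }
    for (size_t q = 0; q < x.size(); ++q)
      if (!R_finite(x[q])) stop("non-finite coordinate at step %d", step0 + t + 1);
    if (rc_stride > 0 && ((t + 1) % rc_stride == 0)) rcs.push_back(rcv);
    if (stride > 0 && ((t + 1) % stride == 0)) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)fidx * n * 3 + (R_xlen_t)i * 3 + d] = x[3 * i + d];
      double ke = 0; int nfree = 0;
      for (int i = 0; i < n; ++i) {
        if (S.fixed[i]) continue;
        nfree++;
        ke += 0.5 * S.mass[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                                 v[3 * i + 2] * v[3 * i + 2]);
      }
      elog(fidx, 0) = step0 + t + 1;
      double tot = 0;
      for (int c = 0; c < NCAT; ++c) { elog(fidx, c + 1) = E[c]; tot += E[c]; }
      elog(fidx, NCAT + 1) = tot;
      elog(fidx, NCAT + 2) = (nfree > 0) ? 2.0 * ke / (3.0 * nfree * KB) : NA_REAL;
      fidx++;
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { xf(i, d) = x[3 * i + d]; vf(i, d) = v[3 * i + d]; }
  frames.attr("dim") = IntegerVector::create(3, n, nframes);
  return List::create(_["frames"] = frames, _["elog"] = elog,
                      _["rc"] = NumericVector(rcs.begin(), rcs.end()),
                      _["coords"] = xf, _["vels"] = vf,
                      _["step"] = step0 + nsteps);
}

// ---------------------------------------------------------------------------
// 1-D Langevin sampler on a polynomial potential U(x) = sum coef[k] x^k plus an
// optional harmonic bias fac*kb*(x-x0b)^2 (fac = 0.5 or 1).  BAOAB.
// [[Rcpp::export]]
List cpp_run_1d(NumericVector coef, double kb, double x0b, double bias_fac,
                double x0, double v0, int nsteps, double dt, double gamma,
                double temperature, double mass, double seed_d, int step0,
                int sstride) {
  uint64_t seed = (uint64_t)seed_d;
  int nc = coef.size();
  auto force = [&](double x) {
    // -dU/dx with dU/dx = sum_k k coef[k] x^(k-1)
    double f = 0, xp = 1;
    for (int k = 1; k < nc; ++k) { f -= k * coef[k] * xp; xp *= x; }
    if (kb > 0) f -= 2.0 * bias_fac * kb * (x - x0b);
    return f;
  };
  double x = x0, v = v0;
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double kT = KB * temperature;
  double F = force(x);
  std::vector<double> samples;
  samples.reserve(sstride > 0 ? nsteps / sstride : 0);
  for (int t = 0; t < nsteps; ++t) {
    uint64_t gstep = (uint64_t)(step0 + t);
    v += 0.5 * dt * F / mass;
    x += 0.5 * dt * v;
    if (gamma > 0) {
      double c2 = std::sqrt(1.0 - c1 * c1);
      v = c1 * v + c2 * std::sqrt(kT / mass) * gauss_ctr(seed, gstep);
    }
    x += 0.5 * dt * v;
    F = force(x);
    v += 0.5 * dt * F / mass;
    if (sstride > 0 && ((t + 1) % sstride == 0)) samples.push_back(x);
  }
  return List::create(_["samples"] = NumericVector(samples.begin(), samples.end()),
                      _["x"] = x, _["v"] = v, _["step"] = step0 + nsteps);
}
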