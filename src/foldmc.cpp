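// Compiled kernels: geometry, force-field energy terms, Born radii, SASA,
// fraction of native contacts, and the Metropolis Monte Carlo inner loop.
// All atom indices arriving here are 0-based (converted on the R side).
// Random draws use R's RNG stream (unif_rand / norm_rand), so runs are
// reproducible from set.seed() and bit-identical to the R-level step path.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double sq(double x) { return x * x; }

static inline double dist3(const double* X, int n, int i, int j) {
  const double dx = X[i] - X[j];
  const double dy = X[i + n] - X[j + n];
  const double dz = X[i + 2 * n] - X[j + 2 * n];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Rodrigues rotation of the atoms in idx about the axis p1 -> p2 by ang
// (radians).  Operates in place on a raw column-major coordinate block.
static void rotate_about_axis(double* X, int n, const std::vector<int>& idx,
                              const double* p1, const double* p2, double ang) {
  double kx = p2[0] - p1[0], ky = p2[1] - p1[1], kz = p2[2] - p1[2];
  const double nrm = std::sqrt(kx * kx + ky * ky + kz * kz);
  if (nrm <= 0.0) stop("degenerate rotation axis");
  kx /= nrm; ky /= nrm; kz /= nrm;
  const double c = std::cos(ang), s = std::sin(ang), C = 1.0 - c;
  for (size_t m = 0; m < idx.size(); ++m) {
    const int i = idx[m];
    const double vx = X[i] - p1[0];
    const double vy = X[i + n] - p1[1];
    const double vz = X[i + 2 * n] - p1[2];
    const double kv = kx * vx + ky * vy + kz * vz;
    const double cx = ky * vz - kz * vy;
    const double cy = kz * vx - kx * vz;
    const double cz = kx * vy - ky * vx;
    X[i]         = p1[0] + vx * c + cx * s + kx * kv * C;
    X[i + n]     = p1[1] + vy * c + cy * s + ky * kv * C;
    X[i + 2 * n] = p1[2] + vz * c + cz * s + kz * kv * C;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_about_axis(NumericMatrix xyz, IntegerVector idx0,
                                    NumericVector p1, NumericVector p2,
                                    double ang) {
  NumericMatrix out = clone(xyz);
  std::vector<int> idx(idx0.begin(), idx0.end());
  rotate_about_axis(REAL(out), out.nrow(), idx, REAL(p1), REAL(p2), ang);
  return out;
}

// Geometric center with plain double accumulation (same arithmetic as the
// MC loop, so the R-level rigid move reproduces it bit for bit).
// [[Rcpp::export]]
NumericVector cpp_geometric_center(NumericMatrix xyz) {
  const int n = xyz.nrow();
  const double* X = REAL(xyz);
  double cen[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    cen[0] += X[i]; cen[1] += X[i + n]; cen[2] += X[i + 2 * n];
  }
  return NumericVector::create(cen[0] / n, cen[1] / n, cen[2] / n);
}

// Dihedral angle (radians, in (-pi, pi]) for atoms i-j-k-l.
static double dihedral_angle(const double* X, int n, int i, int j, int k,
                             int l) {
  double b1[3], b2[3], b3[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = X[j + d * n] - X[i + d * n];
    b2[d] = X[k + d * n] - X[j + d * n];
    b3[d] = X[l + d * n] - X[k + d * n];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  const double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m[3] = {n1[1] * b2[2] - n1[2] * b2[1], n1[2] * b2[0] - n1[0] * b2[2],
                 n1[0] * b2[1] - n1[1] * b2[0]};
  const double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  const double y = (m[0] * n2[0] + m[1] * n2[1] + m[2] * n2[2]) / nb2;
  return std::atan2(y, x);
}

// [[Rcpp::export]]
double cpp_dihedral_angle(NumericMatrix xyz, int i, int j, int k, int l) {
  return dihedral_angle(REAL(xyz), xyz.nrow(), i, j, k, l);
}

// ------------------------------------------------------------------
// Energy terms.  Parameters arrive pre-packed (see pack_energy() in R).
// ------------------------------------------------------------------

struct EnergyPack {
  bool use_bonded, use_nb, use_gb, use_sasa;
  // bonded
  std::vector<int> b_i, b_j; std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_kth, a_th0;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_kphi, d_per,
      d_phase; std::vector<int> d_improper;
  // nonbonded pair list (exclusions removed, 1-4 scaling folded in)
  std::vector<int> nb_i, nb_j; std::vector<double> nb_qq, nb_a, nb_b;
  // GB
  std::vector<double> q, gb_rho, gb_sj, gb_rint;
  double gb_alpha, gb_beta, gb_gamma, gb_pref;
  // SASA
  std::vector<double> sasa_rad; double probe, gamma_kcal;
  std::vector<double> pts; int npts;
  double delta;
};

static std::vector<int> as_ivec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}

static EnergyPack parse_pack(const List& pack) {
  EnergyPack P;
  P.use_bonded = as<bool>(pack["use_bonded"]);
  P.use_nb = as<bool>(pack["use_nb"]);
  P.use_gb = as<bool>(pack["use_gb"]);
  P.use_sasa = as<bool>(pack["use_sasa"]);
  P.delta = as<double>(pack["delta"]);
  P.b_i = as_ivec(pack["b_i"]); P.b_j = as_ivec(pack["b_j"]);
  P.b_k = as_dvec(pack["b_kb"]); P.b_r0 = as_dvec(pack["b_r0"]);
  P.a_i = as_ivec(pack["a_i"]); P.a_j = as_ivec(pack["a_j"]);
  P.a_k = as_ivec(pack["a_k"]);
  P.a_kth = as_dvec(pack["a_kth"]); P.a_th0 = as_dvec(pack["a_th0"]);
  P.d_i = as_ivec(pack["d_i"]); P.d_j = as_ivec(pack["d_j"]);
  P.d_k = as_ivec(pack["d_k"]); P.d_l = as_ivec(pack["d_l"]);
  P.d_kphi = as_dvec(pack["d_kphi"]); P.d_per = as_dvec(pack["d_per"]);
  P.d_phase = as_dvec(pack["d_phase"]);
  P.d_improper = as_ivec(pack["d_improper"]);
  P.nb_i = as_ivec(pack["nb_i"]); P.nb_j = as_ivec(pack["nb_j"]);
  P.nb_qq = as_dvec(pack["nb_qq"]);
  P.nb_a = as_dvec(pack["nb_a"]); P.nb_b = as_dvec(pack["nb_b"]);
  P.q = as_dvec(pack["charge"]);
  P.gb_rho = as_dvec(pack["gb_rho"]); P.gb_sj = as_dvec(pack["gb_sj"]);
  P.gb_rint = as_dvec(pack["gb_rint"]);
  P.gb_alpha = as<double>(pack["gb_alpha"]);
  P.gb_beta = as<double>(pack["gb_beta"]);
  P.gb_gamma = as<double>(pack["gb_gamma"]);
  P.gb_pref = as<double>(pack["gb_pref"]);
  P.sasa_rad = as_dvec(pack["sasa_rad"]);
  P.probe = as<double>(pack["probe"]);
  P.gamma_kcal = as<double>(pack["gamma_kcal"]);
  NumericMatrix pm(as<NumericMatrix>(pack["sphere_pts"]));
  P.npts = pm.nrow();
  P.pts.assign(REAL(pm), REAL(pm) + 3 * P.npts);
  return P;
}

// E_bond, E_angle, E_torsion, E_improper
static void bonded_terms(const double* X, int n, const EnergyPack& P,
                         double* out) {
  double eb = 0.0, ea = 0.0, et = 0.0, ei = 0.0;
  for (size_t m = 0; m < P.b_i.size(); ++m)
    eb += P.b_k[m] * sq(dist3(X, n, P.b_i[m], P.b_j[m]) - P.b_r0[m]);
  for (size_t m = 0; m < P.a_i.size(); ++m) {
    const int i = P.a_i[m], j = P.a_j[m], k = P.a_k[m];
    double ux = X[i] - X[j], uy = X[i + n] - X[j + n],
           uz = X[i + 2 * n] - X[j + 2 * n];
    double vx = X[k] - X[j], vy = X[k + n] - X[j + n],
           vz = X[k + 2 * n] - X[j + 2 * n];
    double cu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double cv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double cth = (ux * vx + uy * vy + uz * vz) / (cu * cv);
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    ea += P.a_kth[m] * sq(std::acos(cth) - P.a_th0[m]);
  }
  for (size_t m = 0; m < P.d_i.size(); ++m) {
    const double phi =
        dihedral_angle(X, n, P.d_i[m], P.d_j[m], P.d_k[m], P.d_l[m]);
    const double e =
        P.d_kphi[m] * (1.0 + std::cos(P.d_per[m] * phi - P.d_phase[m]));
    if (P.d_improper[m]) ei += e; else et += e;
  }
  out[0] = eb; out[1] = ea; out[2] = et; out[3] = ei;
}

// E_LJ, E_Coulomb over the precomputed non-excluded pair list; distances
// carry the +delta offset regularization.
static void nonbonded_terms(const double* X, int n, const EnergyPack& P,
                            double* out) {
  double elj = 0.0, ec = 0.0;
  for (size_t m = 0; m < P.nb_i.size(); ++m) {
    const double r = dist3(X, n, P.nb_i[m], P.nb_j[m]) + P.delta;
    ec += P.nb_qq[m] / r;
    if (P.nb_a[m] != 0.0 || P.nb_b[m] != 0.0) {
      const double ir2 = 1.0 / (r * r);
      const double ir6 = ir2 * ir2 * ir2;
      elj += P.nb_a[m] * ir6 * ir6 - P.nb_b[m] * ir6;
    }
  }
  out[0] = elj; out[1] = ec;
}

// OBC-II pairwise descreening Born radii (HCT integrals + tanh rescaling).
static void born_radii(const double* X, int n, const EnergyPack& P,
                       std::vector<double>& B) {
  B.resize(n);
  for (int i = 0; i < n; ++i) {
    const double rho = P.gb_rho[i];
    double I = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double r = dist3(X, n, i, j) + P.delta;
      const double s = P.gb_sj[j];
      if (rho >= r + s) continue;  // descreener buried inside atom i
      const double U = r + s;
      double L = std::fabs(r - s);
      if (L < rho) L = rho;
      I += 0.5 * (1.0 / L - 1.0 / U +
                  0.25 * (r - s * s / r) * (1.0 / (U * U) - 1.0 / (L * L)) +
                  0.5 / r * std::log(L / U));
      if (rho < s - r) I += 1.0 / rho - 1.0 / L;
    }
    const double psi = I * rho;
    const double t = std::tanh(P.gb_alpha * psi - P.gb_beta * psi * psi +
                               P.gb_gamma * psi * psi * psi);
    B[i] = 1.0 / (1.0 / rho - t / P.gb_rint[i]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_born_radii(NumericMatrix xyz, NumericVector rho,
                             NumericVector sj, NumericVector rint,
                             double delta, double alpha, double beta,
                             double gamma) {
  EnergyPack P;
  P.gb_rho = std::vector<double>(rho.begin(), rho.end());
  P.gb_sj = std::vector<double>(sj.begin(), sj.end());
  P.gb_rint = std::vector<double>(rint.begin(), rint.end());
  P.delta = delta; P.gb_alpha = alpha; P.gb_beta = beta; P.gb_gamma = gamma;
  std::vector<double> B;
  born_radii(REAL(xyz), xyz.nrow(), P, B);
  return wrap(B);
}

// Still pairwise f_GB with self terms; r' = r + delta for i != j only.
static double gb_energy(const double* X, int n, const EnergyPack& P,
                        const std::vector<double>& B) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    if (P.q[i] != 0.0) s += P.q[i] * P.q[i] / B[i];
    for (int j = i + 1; j < n; ++j) {
      const double qq = P.q[i] * P.q[j];
      if (qq == 0.0) continue;
      const double r = dist3(X, n, i, j) + P.delta;
      const double bb = B[i] * B[j];
      const double f = std::sqrt(r * r + bb * std::exp(-r * r / (4.0 * bb)));
      s += 2.0 * qq / f;
    }
  }
  return P.gb_pref * s;
}

// [[Rcpp::export]]
double cpp_gb_energy(NumericMatrix xyz, NumericVector charge,
                     NumericVector born, double delta, double pref) {
  EnergyPack P;
  P.q = std::vector<double>(charge.begin(), charge.end());
  P.delta = delta; P.gb_pref = pref;
  std::vector<double> B(born.begin(), born.end());
  return gb_energy(REAL(xyz), xyz.nrow(), P, B);
}

// Orthonormal frame derived covariantly from the coordinates: under any
// proper rigid transform of the molecule the frame co-rotates, so the
// sphere quadrature below rotates with the molecule and the computed
// areas are exactly frame invariant (no quadrature orientation noise).
static void molecular_frame(const double* X, int n, double F[9]) {
  // default: identity
  F[0] = 1; F[1] = 0; F[2] = 0;
  F[3] = 0; F[4] = 1; F[5] = 0;
  F[6] = 0; F[7] = 0; F[8] = 1;
  int j = -1;
  double e1[3] = {0, 0, 0};
  for (int t = 1; t < n; ++t) {
    e1[0] = X[t] - X[0]; e1[1] = X[t + n] - X[0 + n];
    e1[2] = X[t + 2 * n] - X[0 + 2 * n];
    const double nn = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] +
                                e1[2] * e1[2]);
    if (nn > 1e-8) { e1[0] /= nn; e1[1] /= nn; e1[2] /= nn; j = t; break; }
  }
  if (j < 0) return;
  double e3[3] = {0, 0, 0};
  bool have3 = false;
  for (int t = j + 1; t < n; ++t) {
    const double d[3] = {X[t] - X[0], X[t + n] - X[0 + n],
                         X[t + 2 * n] - X[0 + 2 * n]};
    e3[0] = e1[1] * d[2] - e1[2] * d[1];
    e3[1] = e1[2] * d[0] - e1[0] * d[2];
    e3[2] = e1[0] * d[1] - e1[1] * d[0];
    const double nn = std::sqrt(e3[0] * e3[0] + e3[1] * e3[1] +
                                e3[2] * e3[2]);
    if (nn > 1e-8) {
      e3[0] /= nn; e3[1] /= nn; e3[2] /= nn;
      have3 = true; break;
    }
  }
  if (!have3) {
    // collinear molecule: any fixed perpendicular (occlusion is
    // axisymmetric about e1, so the azimuth does not matter)
    int ax = 0;
    if (std::fabs(e1[1]) < std::fabs(e1[ax])) ax = 1;
    if (std::fabs(e1[2]) < std::fabs(e1[ax])) ax = 2;
    double u[3] = {0, 0, 0}; u[ax] = 1.0;
    e3[0] = e1[1] * u[2] - e1[2] * u[1];
    e3[1] = e1[2] * u[0] - e1[0] * u[2];
    e3[2] = e1[0] * u[1] - e1[1] * u[0];
    const double nn = std::sqrt(e3[0] * e3[0] + e3[1] * e3[1] +
                                e3[2] * e3[2]);
    e3[0] /= nn; e3[1] /= nn; e3[2] /= nn;
  }
  double e2[3] = {e3[1] * e1[2] - e3[2] * e1[1],
                  e3[2] * e1[0] - e3[0] * e1[2],
                  e3[0] * e1[1] - e3[1] * e1[0]};
  F[0] = e1[0]; F[1] = e1[1]; F[2] = e1[2];
  F[3] = e2[0]; F[4] = e2[1]; F[5] = e2[2];
  F[6] = e3[0]; F[7] = e3[1]; F[8] = e3[2];
}

// Shrake-Rupley SASA on a shared unit-sphere point set oriented along the
// molecular frame.  Atoms with nonpositive radius are transparent (no
// area, no blocking).
static void sasa_areas(const double* X, int n, const EnergyPack& P,
                       std::vector<double>& area) {
  area.assign(n, 0.0);
  const double fourpi = 4.0 * M_PI;
  double F[9];
  molecular_frame(X, n, F);
  std::vector<double> rp(3 * P.npts);
  for (int p = 0; p < P.npts; ++p) {
    const double a = P.pts[p], b = P.pts[p + P.npts],
                 c = P.pts[p + 2 * P.npts];
    rp[3 * p] = a * F[0] + b * F[3] + c * F[6];
    rp[3 * p + 1] = a * F[1] + b * F[4] + c * F[7];
    rp[3 * p + 2] = a * F[2] + b * F[5] + c * F[8];
  }
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    if (P.sasa_rad[i] <= 0.0) continue;
    const double Ri = P.sasa_rad[i] + P.probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || P.sasa_rad[j] <= 0.0) continue;
      const double Rj = P.sasa_rad[j] + P.probe;
      if (dist3(X, n, i, j) < Ri + Rj) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < P.npts; ++p) {
      const double px = X[i] + Ri * rp[3 * p];
      const double py = X[i + n] + Ri * rp[3 * p + 1];
      const double pz = X[i + 2 * n] + Ri * rp[3 * p + 2];
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double Rj = P.sasa_rad[j] + P.probe;
        const double dx = px - X[j], dy = py - X[j + n],
                     dz = pz - X[j + 2 * n];
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = fourpi * Ri * Ri * (double)acc / (double)P.npts;
  }
}

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector rad, double probe,
                       NumericMatrix pts) {
  EnergyPack P;
  P.sasa_rad = std::vector<double>(rad.begin(), rad.end());
  P.probe = probe;
  P.npts = pts.nrow();
  P.pts.assign(REAL(pts), REAL(pts) + 3 * P.npts);
  std::vector<double> a;
  sasa_areas(REAL(xyz), xyz.nrow(), P, a);
  return wrap(a);
}

// Full breakdown: bond angle torsion improper lj coul gb nonpolar
static void eval_energy(const double* X, int n, const EnergyPack& P,
                        double* comp) {
  for (int t = 0; t < 8; ++t) comp[t] = 0.0;
  if (P.use_bonded) bonded_terms(X, n, P, comp);
  if (P.use_nb) nonbonded_terms(X, n, P, comp + 4);
  if (P.use_gb) {
    std::vector<double> B;
    born_radii(X, n, P, B);
    comp[6] = gb_energy(X, n, P, B);
  }
  if (P.use_sasa) {
    std::vector<double> a;
    sasa_areas(X, n, P, a);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += a[i];
    comp[7] = P.gamma_kcal * tot;
  }
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix xyz, List pack) {
  EnergyPack P = parse_pack(pack);
  NumericVector comp(8);
  eval_energy(REAL(xyz), xyz.nrow(), P, REAL(comp));
  return comp;
}

// ------------------------------------------------------------------
// Fraction of native contacts: a pair is formed when the minimum
// heavy-atom distance is below its per-contact threshold.
// ------------------------------------------------------------------

struct ContactPack {
  std::vector<std::vector<int> > ai, aj;
  std::vector<double> thresh;
};

static ContactPack parse_contacts(const List& cts) {
  ContactPack C;
  List ai(cts["atoms_i"]), aj(cts["atoms_j"]);
  NumericVector th(cts["threshold"]);
  const int m = th.size();
  C.thresh.assign(th.begin(), th.end());
  C.ai.resize(m); C.aj.resize(m);
  for (int c = 0; c < m; ++c) {
    C.ai[c] = as_ivec(ai[c]);
    C.aj[c] = as_ivec(aj[c]);
  }
  return C;
}

static int contact_formed(const double* X, int n, const ContactPack& C,
                          int c) {
  const double t2 = C.thresh[c] * C.thresh[c];
  for (size_t a = 0; a < C.ai[c].size(); ++a) {
    const int i = C.ai[c][a];
    for (size_t b = 0; b < C.aj[c].size(); ++b) {
      const int j = C.aj[c][b];
      const double dx = X[i] - X[j];
      const double dy = X[i + n] - X[j + n];
      const double dz = X[i + 2 * n] - X[j + 2 * n];
      if (dx * dx + dy * dy + dz * dz < t2) return 1;
    }
  }
  return 0;
}

// [[Rcpp::export]]
IntegerVector cpp_contacts_formed(NumericMatrix xyz, List cts) {
  ContactPack C = parse_contacts(cts);
  const int m = C.thresh.size();
  IntegerVector out(m);
  for (int c = 0; c < m; ++c)
    out[c] = contact_formed(REAL(xyz), xyz.nrow(), C, c);
  return out;
}

static double q_value(const double* X, int n, const ContactPack& C) {
  const int m = C.thresh.size();
  if (m == 0) return NA_REAL;
  int f = 0;
  for (int c = 0; c < m; ++c) f += contact_formed(X, n, C, c);
  return (double)f / (double)m;
}

// ------------------------------------------------------------------
// Metropolis Monte Carlo inner loop.
//
// Per-step draw protocol (mirrored exactly by the R-level mc_step):
//   u_kind; then per kind
//     dihedral : u_pick, z_angle
//     concerted: u_pick, z_angle
//     rigid    : u_z, u_azimuth, u_angle
//   u_accept (always drawn).
// ------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix xyz0, List pack, List moves, List cfg) {
  EnergyPack P = parse_pack(pack);
  NumericMatrix X = clone(xyz0);
  double* Xp = REAL(X);
  const int n = X.nrow();

  // moves
  NumericVector w(moves["weights"]);  // length 3, sums to 1
  const double w0 = w[0], w1 = w[1];
  std::vector<int> dih_b = as_ivec(moves["dih_b"]);
  std::vector<int> dih_c = as_ivec(moves["dih_c"]);
  List dlist(moves["dih_down"]);
  std::vector<std::vector<int> > dih_down(dlist.size());
  for (int i = 0; i < dlist.size(); ++i) dih_down[i] = as_ivec(dlist[i]);
  std::vector<int> win_a1 = as_ivec(moves["win_a1"]);
  std::vector<int> win_a2 = as_ivec(moves["win_a2"]);
  List wlist(moves["win_moved"]);
  std::vector<std::vector<int> > win_moved(wlist.size());
  for (int i = 0; i < wlist.size(); ++i) win_moved[i] = as_ivec(wlist[i]);
  const double width_dih = as<double>(moves["width_dih"]);
  const double width_conc = as<double>(moves["width_conc"]);
  const double rigid_max = as<double>(moves["rigid_max"]);
  const int ndih = dih_b.size(), nwin = win_a1.size();
  std::vector<int> allidx(n);
  for (int i = 0; i < n; ++i) allidx[i] = i;

  // config
  const int n_steps = as<int>(cfg["n_steps"]);
  const int stride = as<int>(cfg["stride"]);
  const bool rec_coords = as<bool>(cfg["record_coords"]);
  const double kBT = as<double>(cfg["kB"]) * as<double>(cfg["temperature"]);
  const bool restraint_on = as<bool>(cfg["restraint_on"]);
  const double Q0 = as<double>(cfg["Q0"]);
  const double kQ = as<double>(cfg["kQ"]);
  const bool have_contacts = as<bool>(cfg["have_contacts"]);
  ContactPack C;
  if (have_contacts) C = parse_contacts(cfg["contacts"]);

  double comp[8], newcomp[8];
  eval_energy(Xp, n, P, comp);
  double curQ = have_contacts ? q_value(Xp, n, C) : NA_REAL;
  double curR = (restraint_on && curQ < Q0) ? kQ * sq(Q0 - curQ) : 0.0;
  double curE = curR;
  for (int t = 0; t < 8; ++t) curE += comp[t];

  const int n_rec = n_steps / stride;
  NumericMatrix records(n_rec, 12);  // step, 8 comps, restraint, total, Q
  NumericMatrix coords_rec(rec_coords ? n_rec : 0, rec_coords ? 3 * n : 0);
  IntegerVector proposed(3), accepted(3);

  std::vector<double> buf(3 * n);
  std::vector<int>* movedp = NULL;
  int rec = 0;

  for (int step = 1; step <= n_steps; ++step) {
    const double uk = unif_rand();
    int kind;
    if (uk < w0) kind = 0; else if (uk < w0 + w1) kind = 1; else kind = 2;
    ++proposed[kind];

    if (kind == 0) {
      int m = (int)(unif_rand() * ndih); if (m >= ndih) m = ndih - 1;
      const double ang = norm_rand() * width_dih;
      movedp = &dih_down[m];
      for (size_t t = 0; t < movedp->size(); ++t) {
        const int i = (*movedp)[t];
        buf[3 * t] = Xp[i]; buf[3 * t + 1] = Xp[i + n];
        buf[3 * t + 2] = Xp[i + 2 * n];
      }
      double p1[3] = {Xp[dih_b[m]], Xp[dih_b[m] + n], Xp[dih_b[m] + 2 * n]};
      double p2[3] = {Xp[dih_c[m]], Xp[dih_c[m] + n], Xp[dih_c[m] + 2 * n]};
      rotate_about_axis(Xp, n, *movedp, p1, p2, ang);
    } else if (kind == 1) {
      int m = (int)(unif_rand() * nwin); if (m >= nwin) m = nwin - 1;
      const double ang = norm_rand() * width_conc;
      movedp = &win_moved[m];
      for (size_t t = 0; t < movedp->size(); ++t) {
        const int i = (*movedp)[t];
        buf[3 * t] = Xp[i]; buf[3 * t + 1] = Xp[i + n];
        buf[3 * t + 2] = Xp[i + 2 * n];
      }
      double p1[3] = {Xp[win_a1[m]], Xp[win_a1[m] + n], Xp[win_a1[m] + 2 * n]};
      double p2[3] = {Xp[win_a2[m]], Xp[win_a2[m] + n], Xp[win_a2[m] + 2 * n]};
      rotate_about_axis(Xp, n, *movedp, p1, p2, ang);
    } else {
      const double z = 2.0 * unif_rand() - 1.0;
      const double az = 2.0 * M_PI * unif_rand();
      const double ang = unif_rand() * rigid_max;
      const double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
      double cen[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < n; ++i) {
        cen[0] += Xp[i]; cen[1] += Xp[i + n]; cen[2] += Xp[i + 2 * n];
      }
      cen[0] /= n; cen[1] /= n; cen[2] /= n;
      double p2[3] = {cen[0] + rho * std::cos(az), cen[1] + rho * std::sin(az),
                      cen[2] + z};
      movedp = &allidx;
      for (size_t t = 0; t < movedp->size(); ++t) {
        const int i = (*movedp)[t];
        buf[3 * t] = Xp[i]; buf[3 * t + 1] = Xp[i + n];
        buf[3 * t + 2] = Xp[i + 2 * n];
      }
      rotate_about_axis(Xp, n, *movedp, cen, p2, ang);
    }

    eval_energy(Xp, n, P, newcomp);
    double newQ = curQ, newR = 0.0;
    if (restraint_on && have_contacts) {
      newQ = q_value(Xp, n, C);
      if (newQ < Q0) newR = kQ * sq(Q0 - newQ);
    }
    double newE = newR;
    for (int t = 0; t < 8; ++t) newE += newcomp[t];
    const double dE = newE - curE;
    const double ua = unif_rand();
    const bool accept = (dE <= 0.0) || (ua < std::exp(-dE / kBT));
    if (accept) {
      ++accepted[kind];
      for (int t = 0; t < 8; ++t) comp[t] = newcomp[t];
      curE = newE; curR = newR; curQ = newQ;
    } else {
      for (size_t t = 0; t < movedp->size(); ++t) {
        const int i = (*movedp)[t];
        Xp[i] = buf[3 * t]; Xp[i + n] = buf[3 * t + 1];
        Xp[i + 2 * n] = buf[3 * t + 2];
      }
    }

    if (step % stride == 0) {
      // with the restraint off Q is tracked lazily: recompute at record time
      double recQ = NA_REAL;
      if (have_contacts)
        recQ = restraint_on ? curQ : q_value(Xp, n, C);
      records(rec, 0) = step;
      for (int t = 0; t < 8; ++t) records(rec, 1 + t) = comp[t];
      records(rec, 9) = curR;
      records(rec, 10) = curE;
      records(rec, 11) = recQ;
      if (rec_coords)
        for (int d = 0; d < 3 * n; ++d) coords_rec(rec, d) = Xp[d];
      ++rec;
    }
  }

  return List::create(_["records"] = records, _["coords"] = coords_rec,
                      _["proposed"] = proposed, _["accepted"] = accepted,
                      _["final_xyz"] = X, _["final_energy"] = curE);
}
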