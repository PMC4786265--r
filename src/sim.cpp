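// Reduced-units Langevin dynamics kernels for structure-based Hamiltonians.
// Units: epsilon = 1, k_B = 1, length nm, mass 1 (unless overridden).
// Deterministic given the seed: one counter-based PCG32 stream, Gaussian
// draws in fixed atom order each step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PCG32 + Box-Muller
// ---------------------------------------------------------------------------
struct PCG32 {
  uint64_t state, inc;
  PCG32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() {  // in (0, 1)
    return (next() + 1.0) * (1.0 / 4294967297.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double gaussian() {
    if (have_spare) { have_spare = false; return spare; }
    double u = uniform(), v = uniform();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 2.0 * M_PI * v;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// topology unpacked into plain arrays
// ---------------------------------------------------------------------------
struct Topo {
  int n;
  std::vector<double> mass, c12;                 // per atom
  std::vector<int> b_i, b_j;                     // bonds
  std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;                // angles
  std::vector<double> a_t0, a_kt;
  std::vector<int> d_i, d_j, d_k, d_l;           // dihedrals
  std::vector<double> d_p0, d_kd, d_c0, d_s0;    // incl. cos/sin of phi0
  std::vector<int> c_i, c_j, c_form;             // contacts (form 1=12-10,2=gauss,3=harm)
  std::vector<double> c_r0, c_eps, c_w;
  std::vector<std::vector<int>> excl;            // sorted exclusion partners per atom
};

static Topo unpack_topo(List top) {
  Topo t;
  NumericVector mass = top["mass"], c12 = top["c12"];
  t.n = mass.size();
  t.mass.assign(mass.begin(), mass.end());
  t.c12.assign(c12.begin(), c12.end());

  NumericMatrix B = top["bonds"];
  for (int r = 0; r < B.nrow(); ++r) {
    t.b_i.push_back((int)B(r,0) - 1); t.b_j.push_back((int)B(r,1) - 1);
    t.b_r0.push_back(B(r,2)); t.b_k.push_back(B(r,3));
  }
  NumericMatrix A = top["angles"];
  for (int r = 0; r < A.nrow(); ++r) {
    t.a_i.push_back((int)A(r,0) - 1); t.a_j.push_back((int)A(r,1) - 1);
    t.a_k.push_back((int)A(r,2) - 1);
    t.a_t0.push_back(A(r,3)); t.a_kt.push_back(A(r,4));
  }
  NumericMatrix D = top["dihedrals"];
  for (int r = 0; r < D.nrow(); ++r) {
    t.d_i.push_back((int)D(r,0) - 1); t.d_j.push_back((int)D(r,1) - 1);
    t.d_k.push_back((int)D(r,2) - 1); t.d_l.push_back((int)D(r,3) - 1);
    t.d_p0.push_back(D(r,4)); t.d_kd.push_back(D(r,5));
    t.d_c0.push_back(std::cos(D(r,4))); t.d_s0.push_back(std::sin(D(r,4)));
  }
  NumericMatrix C = top["contacts"];
  for (int r = 0; r < C.nrow(); ++r) {
    t.c_i.push_back((int)C(r,0) - 1); t.c_j.push_back((int)C(r,1) - 1);
    t.c_r0.push_back(C(r,2)); t.c_eps.push_back(C(r,3));
    t.c_form.push_back((int)C(r,4)); t.c_w.push_back(C(r,5));
  }
  IntegerMatrix E = top["exclusions"];
  t.excl.assign(t.n, std::vector<int>());
  for (int r = 0; r < E.nrow(); ++r) {
    int i = E(r,0) - 1, j = E(r,1) - 1;
    t.excl[i].push_back(j); t.excl[j].push_back(i);
  }
  for (int i = 0; i < t.n; ++i) std::sort(t.excl[i].begin(), t.excl[i].end());
  return t;
}

static inline bool is_excluded(const Topo& t, int i, int j) {
  const std::vector<int>& v = t.excl[i];
  return std::binary_search(v.begin(), v.end(), j);
}

struct Energies {
  double bonds = 0, angles = 0, dihedrals = 0, contacts = 0, excluded = 0;
  double total() const { return bonds + angles + dihedrals + contacts + excluded; }
};

static inline double wrap_pi(double x) {
  // wrap to (-pi, pi] without fmod (portable across libm symbol versions)
  x -= 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
  if (x <= -M_PI) x += 2.0 * M_PI;
  if (x > M_PI) x -= 2.0 * M_PI;
  return x;
}

// F_D(dphi) = [1 - cos(dphi)] + 0.5 [1 - cos(3 dphi)]
static inline double fd_value(double dphi) {
  return (1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi));
}
static inline double fd_deriv(double dphi) {
  return std::sin(dphi) + 1.5 * std::sin(3.0 * dphi);
}

// bonded + contact terms; forces accumulated into f (may be null)
static Energies bonded_energy_forces(const Topo& t, const std::vector<double>& x,
                                     std::vector<double>* f) {
  Energies e;
  // bonds
  for (size_t r = 0; r < t.b_i.size(); ++r) {
    int i = t.b_i[r], j = t.b_j[r];
    double dx = x[3*j] - x[3*i], dy = x[3*j+1] - x[3*i+1], dz = x[3*j+2] - x[3*i+2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dd = d - t.b_r0[r];
    e.bonds += 0.5 * t.b_k[r] * dd * dd;
    if (f && d > 1e-12) {
      double g = t.b_k[r] * dd / d;  // dV/dd / d
      (*f)[3*i]   += g * dx; (*f)[3*i+1] += g * dy; (*f)[3*i+2] += g * dz;
      (*f)[3*j]   -= g * dx; (*f)[3*j+1] -= g * dy; (*f)[3*j+2] -= g * dz;
    }
  }
  // angles
  for (size_t r = 0; r < t.a_i.size(); ++r) {
    int i = t.a_i[r], j = t.a_j[r], k = t.a_k[r];
    double ux = x[3*i]-x[3*j], uy = x[3*i+1]-x[3*j+1], uz = x[3*i+2]-x[3*j+2];
    double vx = x[3*k]-x[3*j], vy = x[3*k+1]-x[3*j+1], vz = x[3*k+2]-x[3*j+2];
    double nu = std::sqrt(ux*ux+uy*uy+uz*uz), nv = std::sqrt(vx*vx+vy*vy+vz*vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double c = (ux*vx + uy*vy + uz*vz) / (nu*nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - t.a_t0[r];
    e.angles += 0.5 * t.a_kt[r] * dth * dth;
    if (f) {
      double s = std::sqrt(1.0 - c*c);
      if (s < 1e-8) s = 1e-8;  // regularize near-collinear geometry
      double dVdth = t.a_kt[r] * dth;
      // V = (k/2)(acos(c) - t0)^2; dV/dc = -k*dth/sin(theta); F = -dV/dr
      double coef = dVdth / s;
      // dtheta/dri etc.
      double fix = coef * (vx/(nu*nv) - c*ux/(nu*nu));
      double fiy = coef * (vy/(nu*nv) - c*uy/(nu*nu));
      double fiz = coef * (vz/(nu*nv) - c*uz/(nu*nu));
      double fkx = coef * (ux/(nu*nv) - c*vx/(nv*nv));
      double fky = coef * (uy/(nu*nv) - c*vy/(nv*nv));
      double fkz = coef * (uz/(nu*nv) - c*vz/(nv*nv));
      (*f)[3*i] += fix; (*f)[3*i+1] += fiy; (*f)[3*i+2] += fiz;
      (*f)[3*k] += fkx; (*f)[3*k+1] += fky; (*f)[3*k+2] += fkz;
      (*f)[3*j] -= fix + fkx; (*f)[3*j+1] -= fiy + fky; (*f)[3*j+2] -= fiz + fkz;
    }
  }
  // dihedrals
  for (size_t r = 0; r < t.d_i.size(); ++r) {
    int i = t.d_i[r], j = t.d_j[r], k = t.d_k[r], l = t.d_l[r];
    double b1x = x[3*j]-x[3*i], b1y = x[3*j+1]-x[3*i+1], b1z = x[3*j+2]-x[3*i+2];
    double b2x = x[3*k]-x[3*j], b2y = x[3*k+1]-x[3*j+1], b2z = x[3*k+2]-x[3*j+2];
    double b3x = x[3*l]-x[3*k], b3y = x[3*l+1]-x[3*k+1], b3z = x[3*l+2]-x[3*k+2];
    double mx = b1y*b2z - b1z*b2y, my = b1z*b2x - b1x*b2z, mz = b1x*b2y - b1y*b2x;
    double nx = b2y*b3z - b2z*b3y, ny = b2z*b3x - b2x*b3z, nz = b2x*b3y - b2y*b3x;
    double m2 = mx*mx + my*my + mz*mz, n2 = nx*nx + ny*ny + nz*nz;
    double nb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    if (m2 < 1e-16 || n2 < 1e-16 || nb2 < 1e-12) continue;  // regularized
    double cx = my*nz - mz*ny, cy = mz*nx - mx*nz, cz = mx*ny - my*nx;
    // sin/cos of phi from vector products, then of dphi = phi - phi0 by
    // angle subtraction, and of 3*dphi by triple-angle identities: no
    // trigonometric calls in the inner loop
    double inv_mn = 1.0 / std::sqrt(m2 * n2);
    double cphi = (mx*nx + my*ny + mz*nz) * inv_mn;
    double sphi = (cx*b2x + cy*b2y + cz*b2z) * inv_mn / nb2;
    double cd = cphi * t.d_c0[r] + sphi * t.d_s0[r];
    double sd = sphi * t.d_c0[r] - cphi * t.d_s0[r];
    double c3 = cd * (4.0 * cd * cd - 3.0);
    double s3 = sd * (3.0 - 4.0 * sd * sd);
    e.dihedrals += t.d_kd[r] * ((1.0 - cd) + 0.5 * (1.0 - c3));
    if (f) {
      double dVdphi = t.d_kd[r] * (sd + 1.5 * s3);
      double fi_x =  dVdphi * nb2 / m2 * mx;
      double fi_y =  dVdphi * nb2 / m2 * my;
      double fi_z =  dVdphi * nb2 / m2 * mz;
      double fl_x = -dVdphi * nb2 / n2 * nx;
      double fl_y = -dVdphi * nb2 / n2 * ny;
      double fl_z = -dVdphi * nb2 / n2 * nz;
      double tb = (b1x*b2x + b1y*b2y + b1z*b2z) / (nb2*nb2);
      double sb = (b3x*b2x + b3y*b2y + b3z*b2z) / (nb2*nb2);
      double sv_x = tb*fi_x - sb*fl_x;
      double sv_y = tb*fi_y - sb*fl_y;
      double sv_z = tb*fi_z - sb*fl_z;
      (*f)[3*i] += fi_x; (*f)[3*i+1] += fi_y; (*f)[3*i+2] += fi_z;
      (*f)[3*j] += -fi_x - sv_x; (*f)[3*j+1] += -fi_y - sv_y; (*f)[3*j+2] += -fi_z - sv_z;
      (*f)[3*k] += -fl_x + sv_x; (*f)[3*k+1] += -fl_y + sv_y; (*f)[3*k+2] += -fl_z + sv_z;
      (*f)[3*l] += fl_x; (*f)[3*l+1] += fl_y; (*f)[3*l+2] += fl_z;
    }
  }
  // contacts
  for (size_t r = 0; r < t.c_i.size(); ++r) {
    int i = t.c_i[r], j = t.c_j[r];
    double dx = x[3*j]-x[3*i], dy = x[3*j+1]-x[3*i+1], dz = x[3*j+2]-x[3*i+2];
    double d2 = dx*dx + dy*dy + dz*dz;
    double d = std::sqrt(d2);
    if (d < 1e-9) stop("contact pair at zero distance (overflow guard)");
    double V = 0, dVdr = 0;
    double r0 = t.c_r0[r], eps = t.c_eps[r];
    switch (t.c_form[r]) {
    case 1: {  // 12-10
      double q = r0 / d;
      double q2 = q * q, q4 = q2 * q2;
      double q10 = q4 * q4 * q2, q12 = q10 * q2;
      V = eps * (5.0 * q12 - 6.0 * q10);
      dVdr = eps * 60.0 * (q10 - q12) / d;
      break; }
    case 2: {  // gaussian well
      double w = t.c_w[r];
      double g = std::exp(-(d - r0)*(d - r0) / (2.0 * w * w));
      V = -eps * g;
      dVdr = eps * (d - r0) / (w * w) * g;
      break; }
    case 3: {  // harmonic spring
      V = 0.5 * eps * (d - r0) * (d - r0);
      dVdr = eps * (d - r0);
      break; }
    }
    e.contacts += V;
    if (f) {
      double g = dVdr / d;
      (*f)[3*i] += g * dx; (*f)[3*i+1] += g * dy; (*f)[3*i+2] += g * dz;
      (*f)[3*j] -= g * dx; (*f)[3*j+1] -= g * dy; (*f)[3*j+2] -= g * dz;
    }
  }
  return e;
}

// excluded volume for one pair; cutoff <= 0 means no truncation
static double excluded_pair_energy_forces(const std::vector<double>& x,
                                          int i, int j, double c12, double cutoff2,
                                          std::vector<double>* f) {
  double dx = x[3*j]-x[3*i], dy = x[3*j+1]-x[3*i+1], dz = x[3*j+2]-x[3*i+2];
  double d2 = dx*dx + dy*dy + dz*dz;
  if (cutoff2 > 0 && d2 > cutoff2) return 0.0;
  if (c12 == 0) return 0.0;
  if (d2 < 1e-18) stop("excluded-volume pair at zero distance (overflow guard)");
  double inv2 = 1.0 / d2;
  double inv12 = inv2 * inv2 * inv2; inv12 *= inv12;
  double V = c12 * inv12;
  if (cutoff2 > 0) {
    double ci2 = 1.0 / cutoff2;
    double ci12 = ci2 * ci2 * ci2; ci12 *= ci12;
    V -= c12 * ci12;  // potential shift for continuity at the cutoff
  }
  if (f) {
    double g = -12.0 * c12 * inv12 * inv2;  // dV/dd / d
    (*f)[3*i] += g * dx; (*f)[3*i+1] += g * dy; (*f)[3*i+2] += g * dz;
    (*f)[3*j] -= g * dx; (*f)[3*j+1] -= g * dy; (*f)[3*j+2] -= g * dz;
  }
  return V;
}

// full O(N^2) excluded volume
static double excluded_all(const Topo& t, const std::vector<double>& x,
                           double cutoff2, std::vector<double>* f) {
  double e = 0;
  for (int i = 0; i < t.n; ++i)
    for (int j = i + 1; j < t.n; ++j) {
      if (is_excluded(t, i, j)) continue;
      e += excluded_pair_energy_forces(x, i, j, std::sqrt(t.c12[i] * t.c12[j]),
                                       cutoff2, f);
    }
  return e;
}

// [[Rcpp::export(name = ".sbm_energy_forces_cpp")]]
List sbm_energy_forces_cpp(NumericMatrix coords, List top, double nb_cutoff,
                           bool want_forces) {
  Topo t = unpack_topo(top);
  int n = coords.nrow();
  if (n != t.n) stop("coordinate/atom count mismatch: %d vs %d", n, t.n);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i + d] = coords(i, d);
  std::vector<double> f(3 * n, 0.0);
  std::vector<double>* fp = want_forces ? &f : nullptr;
  Energies e = bonded_energy_forces(t, x, fp);
  double c2 = nb_cutoff > 0 ? nb_cutoff * nb_cutoff : -1.0;
  e.excluded = excluded_all(t, x, c2, fp);
  NumericMatrix F(n, 3);
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) F(i, d) = f[3*i + d];
  return List::create(
    _["bonds"] = e.bonds, _["angles"] = e.angles, _["dihedrals"] = e.dihedrals,
    _["contacts"] = e.contacts, _["excluded"] = e.excluded,
    _["total"] = e.total(), _["forces"] = F);
}

// ---------------------------------------------------------------------------
// Langevin dynamics (BAOAB splitting)
// ---------------------------------------------------------------------------
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> pc12;   // precombined c12 per listed pair
  std::vector<double> x_ref;
  double rlist2;
  void build(const Topo& t, const std::vector<double>& x, double rlist) {
    pi.clear(); pj.clear(); pc12.clear();
    rlist2 = rlist * rlist;
    for (int i = 0; i < t.n; ++i)
      for (int j = i + 1; j < t.n; ++j) {
        if (is_excluded(t, i, j)) continue;
        double dx = x[3*j]-x[3*i], dy = x[3*j+1]-x[3*i+1], dz = x[3*j+2]-x[3*i+2];
        if (dx*dx + dy*dy + dz*dz <= rlist2) {
          pi.push_back(i); pj.push_back(j);
          pc12.push_back(std::sqrt(t.c12[i] * t.c12[j]));
        }
      }
    x_ref = x;
  }
  bool stale(const std::vector<double>& x, double skin) const {
    double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i]-x_ref[i], dy = x[i+1]-x_ref[i+1], dz = x[i+2]-x_ref[i+2];
      if (dx*dx + dy*dy + dz*dz > lim2) return true;
    }
    return false;
  }
};

static double forces_md(const Topo& t, const std::vector<double>& x,
                        const NeighborList& nl, double cutoff2,
                        std::vector<double>& f, Energies& e) {
  std::fill(f.begin(), f.end(), 0.0);
  e = bonded_energy_forces(t, x, &f);
  double ee = 0;
  for (size_t p = 0; p < nl.pi.size(); ++p)
    ee += excluded_pair_energy_forces(x, nl.pi[p], nl.pj[p], nl.pc12[p], cutoff2, &f);
  e.excluded = ee;
  return e.total();
}

// [[Rcpp::export(name = ".sbm_run_langevin_cpp")]]
List sbm_run_langevin_cpp(NumericMatrix coords0, List top, double dt, double gamma,
                          double temperature, double n_steps_d, int save_every,
                          int seed, double nb_cutoff, double skin) {
  Topo t = unpack_topo(top);
  int n = coords0.nrow();
  long long n_steps = (long long)n_steps_d;
  if (n != t.n) stop("coordinate/atom count mismatch");
  if (dt <= 0) stop("dt must be positive");
  if (temperature < 0) stop("temperature must be >= 0");

  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i + d] = coords0(i, d);

  PCG32 rng((uint64_t)seed);
  // initial velocities from Maxwell-Boltzmann at the target temperature
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(temperature / t.mass[i]);
    for (int d = 0; d < 3; ++d) v[3*i + d] = s * rng.gaussian();
  }

  double cutoff2 = nb_cutoff > 0 ? nb_cutoff * nb_cutoff : -1.0;
  double rlist = nb_cutoff > 0 ? nb_cutoff + skin : 0.0;
  NeighborList nl;
  if (nb_cutoff > 0) nl.build(t, x, rlist);
  else nl.build(t, x, 1e9);  // effectively all pairs

  Energies e;
  forces_md(t, x, nl, cutoff2, f, e);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  long long n_frames = n_steps / save_every + 1;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  NumericMatrix energies(n_frames, 8);  // step,bonds,angles,dih,contacts,excl,pot,kin
  long long fr = 0;

  auto save_frame = [&](long long step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[fr * n * 3 + i * 3 + d] = x[3*i + d];
    double kin = 0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) kin += 0.5 * t.mass[i] * v[3*i+d]*v[3*i+d];
    energies(fr, 0) = (double)step;
    energies(fr, 1) = e.bonds;   energies(fr, 2) = e.angles;
    energies(fr, 3) = e.dihedrals; energies(fr, 4) = e.contacts;
    energies(fr, 5) = e.excluded; energies(fr, 6) = e.total();
    energies(fr, 7) = kin;
    ++fr;
  };
  save_frame(0);

  for (long long step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3*i+d] += 0.5 * dt * f[3*i+d] / t.mass[i];
    // A: half drift
    for (int i = 0; i < 3*n; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck (fixed atom order)
    for (int i = 0; i < n; ++i) {
      double s = c2 * std::sqrt(temperature / t.mass[i]);
      for (int d = 0; d < 3; ++d) v[3*i+d] = c1 * v[3*i+d] + s * rng.gaussian();
    }
    // A: half drift
    for (int i = 0; i < 3*n; ++i) x[i] += 0.5 * dt * v[i];

    if (nb_cutoff > 0 && nl.stale(x, skin)) nl.build(t, x, rlist);
    forces_md(t, x, nl, cutoff2, f, e);
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3*i+d] += 0.5 * dt * f[3*i+d] / t.mass[i];

    if (step % save_every == 0) {
      for (int i = 0; i < 3*n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6)
          stop("coordinate blow-up at step %lld (|x| > 1e6 or non-finite); reduce dt or check the topology",
               step);
      save_frame(step);
      Rcpp::checkUserInterrupt();
    }
  }

  frames.attr("dim") = IntegerVector::create(3, n, n_frames);
  return List::create(_["frames"] = frames, _["energies"] = energies);
}
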