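// Langevin dynamics core for the bead-spring chromatin fiber.
//
// Potentials (reduced units: sigma = 2.5 nm, kT = 1, m = 1):
//   bonds    U = 1/2 k (r - r0)^2             consecutive beads, r0 = sum of radii
//   bending  U = K (1 + cos theta)            DNA-DNA-DNA triplets only
//   pairs    WCA repulsion, additive contact distances d_ij = (d_i + d_j)/2;
//            optional cut-shifted Lennard-Jones of depth eps_n between
//            nucleosome beads when eps_n > 0.  Directly bonded (1-2) pairs
//            are excluded so a straight chain at rest lengths is force-free.
//
// Integrator: BAOAB Langevin splitting; at gamma = 0 it reduces to velocity
// Verlet, so the same code path is used for the NVE energy-drift check.
// Thermostat noise is uniform with matched variance; velocities are
// initialised from the Maxwell-Boltzmann distribution.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ (public-domain algorithm): portable, fast, deterministic
// across platforms for a given seed, unlike std:: distributions.
struct Rng {
  std::uint64_t s[4];
  static std::uint64_t splitmix(std::uint64_t& z) {
    z += 0x9e3779b97f4a7c15ULL;
    std::uint64_t r = z;
    r = (r ^ (r >> 30)) * 0xbf58476d1ce4e5b9ULL;
    r = (r ^ (r >> 27)) * 0x94d049bb133111ebULL;
    return r ^ (r >> 31);
  }
  explicit Rng(std::uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif01() { return (next() >> 11) * 0x1.0p-53; }   // [0, 1)
  double unif_pm1() { return 2.0 * unif01() - 1.0; }       // [-1, 1)
  double gauss() {                                          // Box-Muller
    double u1 = unif01(), u2 = unif01();
    while (u1 <= 0.0) u1 = unif01();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

constexpr double WCA_CUT = 1.1224620483093730; // 2^(1/6)

struct System {
  int n;
  std::vector<double> diam;
  std::vector<int> isnuc;
  std::vector<int> bi, bj;          // 0-based bond endpoints
  std::vector<double> br0;
  std::vector<int> ai, aj, ak;      // 0-based bend triplets
  double k_bond, k_bend, eps, eps_n, attr_cut_factor;
  // neighbour list state
  double rl2;                        // (list radius)^2
  double skin;
  std::vector<int> nb_i, nb_j;
  std::vector<double> ref;           // coords at last rebuild
  std::vector<int> bonded_to;        // flattened pairs marked via |i-j| check + bond table
  std::vector<std::vector<int> > partners;

  bool bonded(int i, int j) const {
    for (int p : partners[i]) if (p == j) return true;
    return false;
  }

  double max_cut() const {
    double dmax = 0.0, nucmax = 0.0;
    for (int i = 0; i < n; ++i) {
      if (diam[i] > dmax) dmax = diam[i];
      if (isnuc[i] && diam[i] > nucmax) nucmax = diam[i];
    }
    double rc = WCA_CUT * dmax;
    if (eps_n > 0.0 && nucmax > 0.0) {
      double rca = attr_cut_factor * nucmax;
      if (rca > rc) rc = rca;
    }
    return rc;
  }

  void build_list(const std::vector<double>& x) {
    nb_i.clear(); nb_j.clear();
    for (int i = 0; i < n - 1; ++i) {
      const double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
      for (int j = i + 1; j < n; ++j) {
        const double dx = x[3 * j] - xi, dy = x[3 * j + 1] - yi, dz = x[3 * j + 2] - zi;
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rl2 && !bonded(i, j)) { nb_i.push_back(i); nb_j.push_back(j); }
      }
    }
    ref = x;
  }

  bool needs_rebuild(const std::vector<double>& x) const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < 3 * n; i += 3) {
      const double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1], dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// total potential energy + forces; neighbour list must be current
double energy_forces(System& sys, const std::vector<double>& x, std::vector<double>& f) {
  const int n = sys.n;
  std::fill(f.begin(), f.end(), 0.0);
  double U = 0.0;

  // bonds
  for (size_t b = 0; b < sys.bi.size(); ++b) {
    const int i = sys.bi[b], j = sys.bj[b];
    const double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
                 dz = x[3 * j + 2] - x[3 * i + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0) stop("coincident bonded beads (r = 0)");
    const double dr = r - sys.br0[b];
    U += 0.5 * sys.k_bond * dr * dr;
    const double fac = -sys.k_bond * dr / r;   // force on j along dx
    f[3 * j] += fac * dx;  f[3 * j + 1] += fac * dy;  f[3 * j + 2] += fac * dz;
    f[3 * i] -= fac * dx;  f[3 * i + 1] -= fac * dy;  f[3 * i + 2] -= fac * dz;
  }

  // Kratky-Porod bending: U = K (1 + cos theta), theta the i-j-k angle
  for (size_t t = 0; t < sys.ai.size(); ++t) {
    const int i = sys.ai[t], j = sys.aj[t], k = sys.ak[t];
    const double ax = x[3 * i] - x[3 * j], ay = x[3 * i + 1] - x[3 * j + 1],
                 az = x[3 * i + 2] - x[3 * j + 2];
    const double bx = x[3 * k] - x[3 * j], by = x[3 * k + 1] - x[3 * j + 1],
                 bz = x[3 * k + 2] - x[3 * j + 2];
    const double a2 = ax * ax + ay * ay + az * az;
    const double b2 = bx * bx + by * by + bz * bz;
    const double la = std::sqrt(a2), lb = std::sqrt(b2);
    if (la <= 0.0 || lb <= 0.0) stop("degenerate bend triplet");
    const double dot = ax * bx + ay * by + az * bz;
    const double c = dot / (la * lb);
    U += sys.k_bend * (1.0 + c);
    // dU/dcos = K ; grad_i cos = b/(|a||b|) - c a/|a|^2 ; F = -grad U
    const double K = sys.k_bend;
    const double fix = -K * (bx / (la * lb) - c * ax / a2);
    const double fiy = -K * (by / (la * lb) - c * ay / a2);
    const double fiz = -K * (bz / (la * lb) - c * az / a2);
    const double fkx = -K * (ax / (la * lb) - c * bx / b2);
    const double fky = -K * (ay / (la * lb) - c * by / b2);
    const double fkz = -K * (az / (la * lb) - c * bz / b2);
    f[3 * i] += fix;  f[3 * i + 1] += fiy;  f[3 * i + 2] += fiz;
    f[3 * k] += fkx;  f[3 * k + 1] += fky;  f[3 * k + 2] += fkz;
    f[3 * j] -= fix + fkx;  f[3 * j + 1] -= fiy + fky;  f[3 * j + 2] -= fiz + fkz;
  }

  // non-bonded pairs
  const double eps = sys.eps, eps_n = sys.eps_n, acf = sys.attr_cut_factor;
  for (size_t p = 0; p < sys.nb_i.size(); ++p) {
    const int i = sys.nb_i[p], j = sys.nb_j[p];
    const double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
                 dz = x[3 * j + 2] - x[3 * i + 2];
    const double r2 = dx * dx + dy * dy + dz * dz;
    const double d = 0.5 * (sys.diam[i] + sys.diam[j]);
    const bool attr = eps_n > 0.0 && sys.isnuc[i] && sys.isnuc[j];
    const double rc = attr ? acf * d : WCA_CUT * d;
    if (r2 >= rc * rc) continue;
    if (r2 <= 0.0) stop("coincident bead pair (r = 0): singular repulsion");
    const double e = attr ? eps_n : eps;
    const double s2 = d * d / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
    double u = 4.0 * e * (s12 - s6);
    if (attr) {
      const double sc2 = 1.0 / (acf * acf), sc6 = sc2 * sc2 * sc2;
      u -= 4.0 * e * (sc6 * sc6 - sc6);       // shift to zero at cutoff
    } else {
      u += e;                                  // WCA shift
    }
    U += u;
    const double fac = 24.0 * e * (2.0 * s12 - s6) / r2;  // on j along +dx
    f[3 * j] += fac * dx;  f[3 * j + 1] += fac * dy;  f[3 * j + 2] += fac * dz;
    f[3 * i] -= fac * dx;  f[3 * i + 1] -= fac * dy;  f[3 * i + 2] -= fac * dz;
  }
  return U;
}

System make_system(NumericMatrix coords, NumericVector diam, IntegerVector isnuc,
                   IntegerVector bond_i, IntegerVector bond_j, NumericVector bond_r0,
                   IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_k,
                   double k_bond, double k_bend, double eps, double eps_n,
                   double attr_cut_factor, double skin) {
  System sys;
  sys.n = coords.nrow();
  sys.diam.assign(diam.begin(), diam.end());
  sys.isnuc.assign(isnuc.begin(), isnuc.end());
  sys.bi.assign(bond_i.begin(), bond_i.end());
  sys.bj.assign(bond_j.begin(), bond_j.end());
  sys.br0.assign(bond_r0.begin(), bond_r0.end());
  sys.ai.assign(ang_i.begin(), ang_i.end());
  sys.aj.assign(ang_j.begin(), ang_j.end());
  sys.ak.assign(ang_k.begin(), ang_k.end());
  sys.k_bond = k_bond; sys.k_bend = k_bend; sys.eps = eps; sys.eps_n = eps_n;
  sys.attr_cut_factor = attr_cut_factor;
  sys.skin = skin;
  sys.partners.assign(sys.n, std::vector<int>());
  for (size_t b = 0; b < sys.bi.size(); ++b) {
    sys.partners[sys.bi[b]].push_back(sys.bj[b]);
    sys.partners[sys.bj[b]].push_back(sys.bi[b]);
  }
  const double rl = sys.max_cut() + skin;
  sys.rl2 = rl * rl;
  return sys;
}

std::vector<double> flatten(NumericMatrix m) {
  std::vector<double> x(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = m(i, d);
  return x;
}

} // namespace

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, NumericVector diam, IntegerVector isnuc,
                       IntegerVector bond_i, IntegerVector bond_j, NumericVector bond_r0,
                       IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_k,
                       double k_bond, double k_bend, double eps, double eps_n,
                       double attr_cut_factor) {
  System sys = make_system(coords, diam, isnuc, bond_i, bond_j, bond_r0,
                           ang_i, ang_j, ang_k, k_bond, k_bend, eps, eps_n,
                           attr_cut_factor, 0.5);
  std::vector<double> x = flatten(coords);
  sys.build_list(x);
  std::vector<double> f(3 * sys.n);
  const double U = energy_forces(sys, x, f);
  NumericMatrix forces(sys.n, 3);
  for (int i = 0; i < sys.n; ++i)
    for (int d = 0; d < 3; ++d) forces(i, d) = f[3 * i + d];
  return List::create(_["energy"] = U, _["forces"] = forces);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix coords0, NumericVector diam, IntegerVector isnuc,
             IntegerVector bond_i, IntegerVector bond_j, NumericVector bond_r0,
             IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_k,
             double k_bond, double k_bend, double eps, double eps_n,
             double attr_cut_factor,
             double dt, double gamma, double kT,
             int n_equil, int n_run, int snap_every, double seed) {
  System sys = make_system(coords0, diam, isnuc, bond_i, bond_j, bond_r0,
                           ang_i, ang_j, ang_k, k_bond, k_bend, eps, eps_n,
                           attr_cut_factor, 1.0);
  const int n = sys.n;
  std::vector<double> x = flatten(coords0), v(3 * n), f(3 * n);

  Rng rng(static_cast<std::uint64_t>(seed));
  const double sqrt3 = std::sqrt(3.0);

  for (int i = 0; i < 3 * n; ++i) v[i] = std::sqrt(kT) * rng.gauss();

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT);

  sys.build_list(x);
  double U = energy_forces(sys, x, f);
  long n_rebuild = 0;

  const int n_steps = n_equil + n_run;
  const int n_snap = (snap_every > 0 && n_run > 0) ? n_run / snap_every : 0;
  NumericVector snaps(static_cast<R_xlen_t>(n) * 3 * std::max(n_snap, 1));
  NumericVector ke_out(std::max(n_snap, 1)), pe_out(std::max(n_snap, 1)),
                t_out(std::max(n_snap, 1));
  int isnap = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck (identity when gamma = 0)
    if (gamma > 0.0) {
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * sqrt3 * rng.unif_pm1();
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // force refresh
    if (sys.needs_rebuild(x)) { sys.build_list(x); ++n_rebuild; }
    U = energy_forces(sys, x, f);
    // B: half kick
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];

    if (step > n_equil && snap_every > 0 && (step - n_equil) % snap_every == 0
        && isnap < n_snap) {
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * v[i] * v[i];
      if (!std::isfinite(ke) || !std::isfinite(U) || !std::isfinite(x[0]))
        stop("simulation diverged (non-finite coordinates) at step %d; reduce dt",
             step);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          snaps[static_cast<R_xlen_t>(isnap) * 3 * n + static_cast<R_xlen_t>(d) * n + i] =
              x[3 * i + d];
      ke_out[isnap] = ke;
      pe_out[isnap] = U;
      t_out[isnap] = (step - n_equil) * dt;
      ++isnap;
    }
    if (step % 10000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) final_coords(i, d) = x[3 * i + d];

  snaps.attr("dim") = IntegerVector::create(n, 3, std::max(n_snap, 1));
  return List::create(_["snapshots"] = snaps, _["kinetic"] = ke_out,
                      _["potential"] = pe_out, _["time"] = t_out,
                      _["n_snap"] = isnap, _["final"] = final_coords,
                      _["n_rebuild"] = static_cast<double>(n_rebuild));
}
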