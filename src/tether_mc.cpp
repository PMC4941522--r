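// Metropolis Monte Carlo sampler for a surface-tethered discrete worm-like
// chain with a reporter bead.
//
// Geometry: vertices v[0..n] with v[0] anchored at the origin on the glass
// surface (z = 0 plane), unit tangents t[i] = (v[i+1]-v[i])/b. The bead
// centre sits at v[n] + R*u for a unit vector u with a uniform prior.
// Hard constraints: v[i].z >= 0 for all vertices and bead centre z >= R
// (bead-surface exclusion). Chain-bead overlap is ignored (the dominant
// volume effect at this geometry is bead-surface exclusion).
//
// Energy (units of kBT): sum over interior joints of
//   kappa[j] * (1 - cos(theta_j - theta0[j]))
// where theta_j is the polar angle between t[j-1] and t[j]; theta0[j] = 0 for
// plain DNA joints and a fixed kink angle for protein-bent joints (azimuth
// free). Bridging constraints are stiff harmonic springs between vertex
// pairs: E = k/2 * |v_a - v_b|^2.
//
// Moves: pivot (rotate the tail beyond a joint about a random axis; joint 0
// is the free surface hinge, so pivots there rotate the whole chain at zero
// energy cost) and crankshaft (rotate 2-4 interior vertices about the chord).
// Rejection handles the hard constraints. Uses R's RNG, so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 sub(const V3 &a, const V3 &b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double dist2(const V3 &a, const V3 &b) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  return dx * dx + dy * dy + dz * dz;
}

static inline void rand_unit(double &x, double &y, double &z) {
  double a, b, s;
  do {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s == 0.0);
  double r = 2.0 * std::sqrt(1.0 - s);
  x = a * r; y = b * r; z = 1.0 - 2.0 * s;
}

// Rodrigues rotation of w about unit axis k by angle ang
static inline V3 rotate(const V3 &w, const V3 &k, double c, double s) {
  double kd = dot(k, w);
  return V3{
    w.x * c + (k.y * w.z - k.z * w.y) * s + k.x * kd * (1 - c),
    w.y * c + (k.z * w.x - k.x * w.z) * s + k.y * kd * (1 - c),
    w.z * c + (k.x * w.y - k.y * w.x) * s + k.z * kd * (1 - c)};
}

static inline double joint_energy(const V3 &tp, const V3 &tc,
                                  double kappa, double theta0) {
  double d = dot(tp, tc);
  if (d > 1.0) d = 1.0;
  if (d < -1.0) d = -1.0;
  if (theta0 == 0.0) return kappa * (1.0 - d);
  return kappa * (1.0 - std::cos(std::acos(d) - theta0));
}

// [[Rcpp::export]]
List tether_mc_cpp(int nseg, double b,
                   NumericVector kappa, NumericVector theta0,
                   double bead_radius,
                   int n_samples, int thin, int burnin,
                   IntegerVector spring_a, IntegerVector spring_b,
                   double spring_k,
                   bool free_chain, bool store_chains) {
  if (nseg < 2) stop("need at least 2 segments");
  if ((int)kappa.size() != nseg || (int)theta0.size() != nseg)
    stop("kappa/theta0 must have length nseg (entry 0 unused)");

  std::vector<V3> t(nseg), v(nseg + 1);
  std::vector<V3> t_old(nseg), v_old(nseg + 1);
  int nspr = spring_a.size();

  // start straight up: satisfies all constraints
  for (int i = 0; i < nseg; ++i) t[i] = V3{0, 0, 1};
  v[0] = V3{0, 0, 0};
  for (int i = 0; i < nseg; ++i)
    v[i + 1] = V3{v[i].x + b * t[i].x, v[i].y + b * t[i].y, v[i].z + b * t[i].z};
  V3 u{0, 0, 1};  // bead orientation

  // per-joint pivot amplitudes: free hinge at joint 0, thermal scale elsewhere
  std::vector<double> amp(nseg);
  amp[0] = M_PI;
  for (int j = 1; j < nseg; ++j) {
    double k = kappa[j] > 1e-8 ? kappa[j] : 1e-8;
    double a = 2.5 / std::sqrt(k);
    amp[j] = a < M_PI ? a : M_PI;
  }

  long long att = 0, acc = 0;
  NumericMatrix bead(n_samples, 3);
  NumericVector chains;
  if (store_chains) chains = NumericVector(Dimension(n_samples, nseg + 1, 3));

  auto spring_energy_touching = [&](int lo_moved) -> double {
    // springs with exactly one endpoint in the moved tail {lo_moved..nseg}
    double e = 0.0;
    for (int s = 0; s < nspr; ++s) {
      bool ma = spring_a[s] >= lo_moved, mb = spring_b[s] >= lo_moved;
      if (ma != mb) e += 0.5 * spring_k * dist2(v[spring_a[s]], v[spring_b[s]]);
    }
    return e;
  };
  auto spring_energy_range = [&](int lo, int hi) -> double {
    // springs with exactly one endpoint strictly inside (lo, hi)
    double e = 0.0;
    for (int s = 0; s < nspr; ++s) {
      bool ma = spring_a[s] > lo && spring_a[s] < hi;
      bool mb = spring_b[s] > lo && spring_b[s] < hi;
      if (ma != mb) e += 0.5 * spring_k * dist2(v[spring_a[s]], v[spring_b[s]]);
    }
    return e;
  };

  auto do_pivot = [&]() {
    int j = (int)(unif_rand() * nseg);
    if (j >= nseg) j = nseg - 1;
    double ang = amp[j] * (2.0 * unif_rand() - 1.0);
    V3 ax; rand_unit(ax.x, ax.y, ax.z);
    double c = std::cos(ang), s = std::sin(ang);

    double e_old = 0.0;
    if (j >= 1) e_old += joint_energy(t[j - 1], t[j], kappa[j], theta0[j]);
    if (nspr) e_old += spring_energy_touching(j + 1);

    for (int i = j; i < nseg; ++i) t_old[i] = t[i];
    for (int i = j + 1; i <= nseg; ++i) v_old[i] = v[i];

    for (int i = j; i < nseg; ++i) t[i] = rotate(t[i], ax, c, s);
    bool ok = true;
    for (int i = j; i < nseg; ++i) {
      v[i + 1] = V3{v[i].x + b * t[i].x, v[i].y + b * t[i].y, v[i].z + b * t[i].z};
      if (!free_chain && v[i + 1].z < 0) { ok = false; break; }
    }
    if (ok && !free_chain && v[nseg].z + bead_radius * u.z < bead_radius) ok = false;
    if (ok) {
      double e_new = 0.0;
      if (j >= 1) e_new += joint_energy(t[j - 1], t[j], kappa[j], theta0[j]);
      if (nspr) {
        // recompute vertices fully before spring eval (done above for moved)
        e_new += spring_energy_touching(j + 1);
      }
      double de = e_new - e_old;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) { ++acc; return; }
    }
    for (int i = j; i < nseg; ++i) t[i] = t_old[i];
    for (int i = j + 1; i <= nseg; ++i) v[i] = v_old[i];
  };

  auto do_crank = [&]() {
    int a = (int)(unif_rand() * (nseg - 1));
    if (a >= nseg - 1) a = nseg - 2;
    int len = 2 + (int)(unif_rand() * 3.0);  // 2..4 segments
    int cidx = a + len;
    if (cidx > nseg) cidx = nseg;
    if (cidx - a < 2) return;
    V3 chord = sub(v[cidx], v[a]);
    double cn = std::sqrt(dot(chord, chord));
    if (cn < 1e-9) return;
    V3 ax{chord.x / cn, chord.y / cn, chord.z / cn};
    double kmax = 1e-8;
    if (a >= 1 && kappa[a] > kmax) kmax = kappa[a];
    if (cidx <= nseg - 1 && kappa[cidx] > kmax) kmax = kappa[cidx];
    double ampc = 2.5 / std::sqrt(kmax);
    if (ampc > M_PI) ampc = M_PI;
    double ang = ampc * (2.0 * unif_rand() - 1.0);
    double c = std::cos(ang), s = std::sin(ang);

    double e_old = 0.0;
    if (a >= 1) e_old += joint_energy(t[a - 1], t[a], kappa[a], theta0[a]);
    if (cidx <= nseg - 1)
      e_old += joint_energy(t[cidx - 1], t[cidx], kappa[cidx], theta0[cidx]);
    if (nspr) e_old += spring_energy_range(a, cidx);

    for (int i = a; i < cidx; ++i) t_old[i] = t[i];
    for (int i = a + 1; i < cidx; ++i) v_old[i] = v[i];

    for (int i = a; i < cidx; ++i) t[i] = rotate(t[i], ax, c, s);
    bool ok = true;
    for (int i = a; i < cidx - 1; ++i) {
      v[i + 1] = V3{v[i].x + b * t[i].x, v[i].y + b * t[i].y, v[i].z + b * t[i].z};
      if (!free_chain && v[i + 1].z < 0) { ok = false; break; }
    }
    if (ok) {
      double e_new = 0.0;
      if (a >= 1) e_new += joint_energy(t[a - 1], t[a], kappa[a], theta0[a]);
      if (cidx <= nseg - 1)
        e_new += joint_energy(t[cidx - 1], t[cidx], kappa[cidx], theta0[cidx]);
      if (nspr) e_new += spring_energy_range(a, cidx);
      double de = e_new - e_old;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) { ++acc; return; }
    }
    for (int i = a; i < cidx; ++i) t[i] = t_old[i];
    for (int i = a + 1; i < cidx; ++i) v[i] = v_old[i];
  };

  auto do_bead = [&]() {
    V3 up; rand_unit(up.x, up.y, up.z);
    if (v[nseg].z + bead_radius * up.z >= bead_radius) { u = up; ++acc; }
  };

  auto sweep = [&]() {
    for (int k = 0; k < nseg; ++k) {
      ++att;
      if (unif_rand() < 0.6) do_pivot(); else do_crank();
    }
    if (!free_chain) { att += 2; do_bead(); do_bead(); }
  };

  auto renorm = [&]() {
    for (int i = 0; i < nseg; ++i) {
      double nrm = std::sqrt(dot(t[i], t[i]));
      t[i] = V3{t[i].x / nrm, t[i].y / nrm, t[i].z / nrm};
    }
    for (int i = 0; i < nseg; ++i)
      v[i + 1] = V3{v[i].x + b * t[i].x, v[i].y + b * t[i].y, v[i].z + b * t[i].z};
  };

  long long sweeps_done = 0;
  for (int i = 0; i < burnin; ++i) {
    sweep();
    if (++sweeps_done % 500 == 0) renorm();
  }
  for (int smp = 0; smp < n_samples; ++smp) {
    for (int i = 0; i < thin; ++i) {
      sweep();
      if (++sweeps_done % 500 == 0) renorm();
    }
    bead(smp, 0) = v[nseg].x + bead_radius * u.x;
    bead(smp, 1) = v[nseg].y + bead_radius * u.y;
    bead(smp, 2) = v[nseg].z + bead_radius * u.z;
    if (store_chains) {
      for (int i = 0; i <= nseg; ++i) {
        chains[smp + n_samples * i] = v[i].x;
        chains[smp + n_samples * (nseg + 1) + n_samples * i] = v[i].y;
        chains[smp + n_samples * 2 * (nseg + 1) + n_samples * i] = v[i].z;
      }
    }
    if (smp % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  double acc_rate = att > 0 ? (double)acc / (double)att : 0.0;
  return List::create(_["bead"] = bead,
                      _["acceptance_rate"] = acc_rate,
                      _["chains"] = store_chains ? (SEXP)chains : R_NilValue);
}
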