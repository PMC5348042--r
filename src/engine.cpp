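// Coarse-grained MD engine for the axon membrane-skeleton model.
//
// Reduced units throughout (sigma = eps = m = 1). Particle kinds:
// 0 = actin, 1 = spectrin, 2 = ankyrin. All state lives in R; each call
// receives positions/velocities/topology/parameters and returns the
// updated state plus observer records, so runs are fully deterministic
// functions of (state, options, seed).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Params {
  double kT, dt;
  double k0, req_ss, kA, req_aa, kSK, req_sk;
  double kb, theta0, dtheta_max;
  double kmt, deq, ddmax;
  double kc, r0_spectrin, r0_ankyrin;
  double as_sigma, as_r_inflex, as_r_capture;
  double steric_scale[3][3], steric_eps[3][3], steric_cut[3][3];
  double r_wall_S, r_wall_A;
  double sk_gap; // r0_ankyrin - r0_spectrin, kept when tracking the wall
};

struct Topo {
  std::vector<int> ss_i, ss_j, aa_i, aa_j, sk_i, sk_j;
  std::vector<int> an_i, an_j, an_k;           // angle triplets i-j-k
  std::vector<int> as_a, as_s;                 // junction pairs
  std::vector<int> as_state;                   // 1 intact, 0 broken
  std::vector<int> suppress;                   // recapture suppressed
  std::vector<int> ring_id;                    // 1..n_rings, 0 otherwise
  int n_rings;
  bool confine;
};

struct EnergyBreakdown {
  double ss = 0, aa = 0, sk = 0, angle = 0, mt = 0, as = 0,
         steric = 0, confine = 0, wall = 0;
  double total() const {
    return ss + aa + sk + angle + mt + as + steric + confine + wall;
  }
};

Params read_params(const List& p) {
  Params pp;
  pp.kT = p["kT"]; pp.dt = p["dt"];
  pp.k0 = p["k0"]; pp.req_ss = p["req_ss"];
  pp.kA = p["kA"]; pp.req_aa = p["req_aa"];
  pp.kSK = p["kSK"]; pp.req_sk = p["req_sk"];
  pp.kb = p["kb"]; pp.theta0 = p["theta0"]; pp.dtheta_max = p["dtheta_max"];
  pp.kmt = p["kmt"]; pp.deq = p["deq"]; pp.ddmax = p["ddmax"];
  pp.kc = p["kc"];
  pp.r0_spectrin = p["r0_spectrin"]; pp.r0_ankyrin = p["r0_ankyrin"];
  pp.as_sigma = p["as_sigma"]; pp.as_r_inflex = p["as_r_inflex"];
  pp.as_r_capture = p["as_r_capture"];
  NumericMatrix sc = p["steric_scale"], se = p["steric_eps"],
                cu = p["steric_cut"];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      pp.steric_scale[a][b] = sc(a, b);
      pp.steric_eps[a][b] = se(a, b);
      pp.steric_cut[a][b] = cu(a, b);
    }
  pp.r_wall_S = p["r_wall_S"]; pp.r_wall_A = p["r_wall_A"];
  pp.sk_gap = pp.r0_ankyrin - pp.r0_spectrin;
  return pp;
}

std::vector<int> col_as_int(const IntegerMatrix& m, int col) {
  std::vector<int> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = m(i, col) - 1; // 0-based
  return v;
}

Topo read_topo(const List& t) {
  Topo tp;
  IntegerMatrix ss = t["ss_bonds"], aa = t["aa_bonds"], an = t["angles"],
                sk = t["sk_bonds"], asp = t["as_pairs"];
  tp.ss_i = col_as_int(ss, 0); tp.ss_j = col_as_int(ss, 1);
  tp.aa_i = col_as_int(aa, 0); tp.aa_j = col_as_int(aa, 1);
  tp.an_i = col_as_int(an, 0); tp.an_j = col_as_int(an, 1);
  tp.an_k = col_as_int(an, 2);
  tp.sk_i = col_as_int(sk, 0); tp.sk_j = col_as_int(sk, 1);
  tp.as_a = col_as_int(asp, 0); tp.as_s = col_as_int(asp, 1);
  IntegerVector st = t["as_state"];
  tp.as_state.assign(st.begin(), st.end());
  tp.suppress.assign(tp.as_state.size(), 0);
  IntegerVector rid = t["ring_id"];
  tp.ring_id.assign(rid.begin(), rid.end());
  tp.n_rings = as<int>(t["n_rings"]);
  tp.confine = as<bool>(t["confine"]);
  return tp;
}

// Verlet neighbor list for the all-pairs steric repulsion, built from a
// cell grid at the largest pair cutoff + skin. Junction (actin-spectrin
// association) pairs are excluded: their repulsive core belongs to the
// breakable attraction itself.
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> ref; // positions at build time (3N)
  double skin = 1.0;

  void build(const std::vector<double>& r, const std::vector<int>& kind,
             const Params& p,
             const std::unordered_set<std::uint64_t>& excl) {
    const int n = (int)kind.size();
    pi.clear(); pj.clear();
    ref = r;
    double rcmax = 0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        rcmax = std::max(rcmax, p.steric_cut[a][b]);
    const double cell = rcmax + skin;
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], r[3 * i + d]);
        hi[d] = std::max(hi[d], r[3 * i + d]);
      }
    int nc[3];
    for (int d = 0; d < 3; ++d)
      nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
    auto cidx = [&](int i, int d) {
      int c = (int)std::floor((r[3 * i + d] - lo[d]) / cell);
      return std::min(std::max(c, 0), nc[d] - 1);
    };
    std::vector<int> head(nc[0] * nc[1] * nc[2], -1), nxt(n, -1);
    auto flat = [&](int cx, int cy, int cz) {
      return (cz * nc[1] + cy) * nc[0] + cx;
    };
    for (int i = 0; i < n; ++i) {
      int c = flat(cidx(i, 0), cidx(i, 1), cidx(i, 2));
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; ++i) {
      int cx = cidx(i, 0), cy = cidx(i, 1), cz = cidx(i, 2);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ex = cx + dx, ey = cy + dy, ez = cz + dz;
            if (ex < 0 || ey < 0 || ez < 0 ||
                ex >= nc[0] || ey >= nc[1] || ez >= nc[2]) continue;
            for (int j = head[flat(ex, ey, ez)]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double rl = p.steric_cut[kind[i]][kind[j]] + skin;
              double ddx = r[3 * i] - r[3 * j];
              double ddy = r[3 * i + 1] - r[3 * j + 1];
              double ddz = r[3 * i + 2] - r[3 * j + 2];
              if (ddx * ddx + ddy * ddy + ddz * ddz > rl * rl) continue;
              std::uint64_t key =
                  (std::uint64_t)std::min(i, j) * (std::uint64_t)n +
                  (std::uint64_t)std::max(i, j);
              if (excl.count(key)) continue;
              pi.push_back(i); pj.push_back(j);
            }
          }
    }
  }

  bool stale(const std::vector<double>& r) const {
    const double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i + 2 < r.size(); i += 3) {
      double dx = r[i] - ref[i], dy = r[i + 1] - ref[i + 1],
             dz = r[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

inline void add_pair_force(std::vector<double>& f, int i, int j,
                           double fx, double fy, double fz) {
  f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
  f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
}

// shifted purely repulsive LJ: U = 4e[(s/r)^12-(s/r)^6]+e for r < 2^(1/6)s
inline double rep_lj(double r2, double s, double e, double cut,
                     double& fr_over_r) {
  if (r2 >= cut * cut) { fr_over_r = 0; return 0; }
  double s2 = s * s / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
  fr_over_r = 24.0 * e * (2.0 * s12 - s6) / r2; // along r_i - r_j, repulsive
  return 4.0 * e * (s12 - s6) + e;
}

// Wall force evaluation context
struct Wall {
  bool active = false;
  double rc = 0;
  int conf_track = 0; // 1: confinement radii follow the wall
};

// Full force/energy evaluation. Optionally accumulates the outward wall
// force per stripe group (group id per particle: 0 none, 1 ring stripe,
// 2 between stripe).
EnergyBreakdown forces(const std::vector<double>& r,
                       const std::vector<int>& kind,
                       const Topo& tp, const Params& p, const Wall& w,
                       NeighborList& nl,
                       const std::unordered_set<std::uint64_t>& excl,
                       std::vector<double>& f,
                       const std::vector<int>* stripe_group = nullptr,
                       double* wall_force_group = nullptr,
                       bool* fene_overrun = nullptr) {
  const int n = (int)kind.size();
  EnergyBreakdown eb;
  std::fill(f.begin(), f.end(), 0.0);

  auto harm = [&](const std::vector<int>& I, const std::vector<int>& J,
                  double k, double req, double& epot) {
    for (size_t b = 0; b < I.size(); ++b) {
      int i = I[b], j = J[b];
      double dx = r[3 * i] - r[3 * j], dy = r[3 * i + 1] - r[3 * j + 1],
             dz = r[3 * i + 2] - r[3 * j + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-12) continue;
      double dev = d - req;
      epot += 0.5 * k * dev * dev;
      double fr = -k * dev / d;
      add_pair_force(f, i, j, fr * dx, fr * dy, fr * dz);
    }
  };
  harm(tp.ss_i, tp.ss_j, p.k0, p.req_ss, eb.ss);
  harm(tp.aa_i, tp.aa_j, p.kA, p.req_aa, eb.aa);
  harm(tp.sk_i, tp.sk_j, p.kSK, p.req_sk, eb.sk);

  // FENE angle bending
  for (size_t b = 0; b < tp.an_i.size(); ++b) {
    int i = tp.an_i[b], j = tp.an_j[b], k = tp.an_k[b];
    double ux = r[3 * i] - r[3 * j], uy = r[3 * i + 1] - r[3 * j + 1],
           uz = r[3 * i + 2] - r[3 * j + 2];
    double vx = r[3 * k] - r[3 * j], vy = r[3 * k + 1] - r[3 * j + 1],
           vz = r[3 * k + 2] - r[3 * j + 2];
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (lu < 1e-12 || lv < 1e-12) continue;
    double ct = (ux * vx + uy * vy + uz * vz) / (lu * lv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double t = (th - p.theta0) / p.dtheta_max;
    if (std::fabs(t) >= 1.0) {
      if (fene_overrun) { *fene_overrun = true; t = t > 0 ? 0.999999 : -0.999999; }
      else stop("FENE bending restraint exceeded (|theta-theta0| >= dtheta_max)");
    }
    eb.angle += -0.5 * p.kb * p.dtheta_max * std::log(1.0 - t * t);
    double dEdth = p.kb * t / (1.0 - t * t);
    double st = std::sqrt(std::max(1.0 - ct * ct, 0.0));
    if (st < 1e-8) continue; // straight/collapsed: torque -> 0 for theta0=pi
    // dtheta/dri = (ct*u_hat - v_hat)/(lu*st), similarly for rk
    double gix = (ct * ux / lu - vx / lv) / (lu * st);
    double giy = (ct * uy / lu - vy / lv) / (lu * st);
    double giz = (ct * uz / lu - vz / lv) / (lu * st);
    double gkx = (ct * vx / lv - ux / lu) / (lv * st);
    double gky = (ct * vy / lv - uy / lu) / (lv * st);
    double gkz = (ct * vz / lv - uz / lu) / (lv * st);
    f[3 * i] -= dEdth * gix; f[3 * i + 1] -= dEdth * giy;
    f[3 * i + 2] -= dEdth * giz;
    f[3 * k] -= dEdth * gkx; f[3 * k + 1] -= dEdth * gky;
    f[3 * k + 2] -= dEdth * gkz;
    f[3 * j] += dEdth * (gix + gkx);
    f[3 * j + 1] += dEdth * (giy + gky);
    f[3 * j + 2] += dEdth * (giz + gkz);
  }

  // inter-ring FENE on ring-centre z distances (axial only)
  if (tp.n_rings >= 2) {
    std::vector<double> zbar(tp.n_rings, 0.0);
    std::vector<int> cnt(tp.n_rings, 0);
    for (int i = 0; i < n; ++i)
      if (tp.ring_id[i] > 0) {
        zbar[tp.ring_id[i] - 1] += r[3 * i + 2];
        cnt[tp.ring_id[i] - 1]++;
      }
    for (int g = 0; g < tp.n_rings; ++g) zbar[g] /= std::max(cnt[g], 1);
    for (int g = 0; g + 1 < tp.n_rings; ++g) {
      double d = zbar[g + 1] - zbar[g];
      double u = (d - p.deq) / p.ddmax;
      if (std::fabs(u) >= 1.0) {
        if (fene_overrun) { *fene_overrun = true; u = u > 0 ? 0.999999 : -0.999999; }
        else stop("inter-ring FENE restraint exceeded (|d-deq| >= ddmax)");
      }
      eb.mt += -0.5 * p.kmt * p.ddmax * std::log(1.0 - u * u);
      double dEdd = p.kmt * u / (1.0 - u * u);
      double fz = dEdd; // distributed over the beads via the mean
      for (int i = 0; i < n; ++i) {
        if (tp.ring_id[i] == g + 1) f[3 * i + 2] += fz / cnt[g];
        else if (tp.ring_id[i] == g + 2) f[3 * i + 2] -= fz / cnt[g + 1];
      }
    }
  }

  // breakable actin-spectrin association (state fixed within a call;
  // transitions are handled by the integrator loop)
  const double as_cut_rep = std::pow(2.0, 1.0 / 6.0) * p.as_sigma;
  for (size_t b = 0; b < tp.as_a.size(); ++b) {
    int i = tp.as_a[b], j = tp.as_s[b];
    double dx = r[3 * i] - r[3 * j], dy = r[3 * i + 1] - r[3 * j + 1],
           dz = r[3 * i + 2] - r[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double fr = 0, e = 0;
    if (tp.as_state[b] == 1) {
      // full attraction at any distance while intact; the inflexion point
      // only acts as the break criterion in the state machine
      double s2 = p.as_sigma * p.as_sigma / r2, s6 = s2 * s2 * s2,
             s12 = s6 * s6;
      e = 4.0 * (s12 - s6);
      fr = 24.0 * (2.0 * s12 - s6) / r2;
    } else {
      e = rep_lj(r2, p.as_sigma, 1.0, as_cut_rep, fr);
    }
    eb.as += e;
    add_pair_force(f, i, j, fr * dx, fr * dy, fr * dz);
  }

  // all-pairs steric repulsion via the neighbor list
  if (nl.stale(r)) nl.build(r, kind, p, excl);
  for (size_t q = 0; q < nl.pi.size(); ++q) {
    int i = nl.pi[q], j = nl.pj[q];
    int a = kind[i], b = kind[j];
    double dx = r[3 * i] - r[3 * j], dy = r[3 * i + 1] - r[3 * j + 1],
           dz = r[3 * i + 2] - r[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double fr;
    eb.steric += rep_lj(r2, p.steric_scale[a][b], p.steric_eps[a][b],
                        p.steric_cut[a][b], fr);
    if (fr != 0) add_pair_force(f, i, j, fr * dx, fr * dy, fr * dz);
  }

  // bilayer confinement: one-sided (outward) for spectrin, two-sided for
  // ankyrin; radii follow the expansion wall when conf_track is set
  if (tp.confine) {
    double r0s = p.r0_spectrin, r0k = p.r0_ankyrin;
    if (w.active && w.conf_track) { r0s = w.rc; r0k = w.rc + p.sk_gap; }
    for (int i = 0; i < n; ++i) {
      if (kind[i] == 0) continue;
      double rr = std::sqrt(r[3 * i] * r[3 * i] + r[3 * i + 1] * r[3 * i + 1]);
      if (rr < 1e-12) continue;
      double dev;
      if (kind[i] == 1) {
        dev = rr - r0s;
        if (dev <= 0) continue;
      } else {
        dev = rr - r0k;
      }
      eb.confine += 0.5 * p.kc * dev * dev;
      double fr = -p.kc * dev / rr;
      f[3 * i] += fr * r[3 * i];
      f[3 * i + 1] += fr * r[3 * i + 1];
    }
  }

  // expanding cylindrical wall (spectrin and actin only)
  if (w.active) {
    for (int i = 0; i < n; ++i) {
      if (kind[i] == 2) continue;
      double rw = (kind[i] == 0) ? p.r_wall_A : p.r_wall_S;
      double scale = 2.0 * rw / std::pow(2.0, 1.0 / 6.0);
      double rr = std::sqrt(r[3 * i] * r[3 * i] + r[3 * i + 1] * r[3 * i + 1]);
      double d = rr - (w.rc - rw);
      if (d >= 2.0 * rw || rr < 1e-12) continue;
      if (d < 0.05 * scale) d = 0.05 * scale; // capped near the singularity
      double s2 = scale * scale / (d * d), s6 = s2 * s2 * s2, s12 = s6 * s6;
      eb.wall += 4.0 * (s12 - s6) + 1.0;
      double fd = 24.0 * (2.0 * s12 - s6) / d; // > 0: pushes outward
      f[3 * i] += fd * r[3 * i] / rr;
      f[3 * i + 1] += fd * r[3 * i + 1] / rr;
      if (stripe_group && wall_force_group) {
        int g = (*stripe_group)[i];
        if (g > 0) wall_force_group[g - 1] += fd;
        wall_force_group[2] += fd;
      }
    }
  }
  return eb;
}

} // namespace

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector kind, List topology,
                       List params, double wall_rc = -1.0,
                       int conf_track = 0) {
  const int n = pos.nrow();
  Params p = read_params(params);
  Topo tp = read_topo(topology);
  std::vector<double> r(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) r[3 * i + d] = pos(i, d);
  std::vector<int> kv(kind.begin(), kind.end());
  std::unordered_set<std::uint64_t> excl;
  for (size_t b = 0; b < tp.as_a.size(); ++b) {
    int i = tp.as_a[b], j = tp.as_s[b];
    excl.insert((std::uint64_t)std::min(i, j) * (std::uint64_t)n +
                (std::uint64_t)std::max(i, j));
  }
  NeighborList nl;
  nl.build(r, kv, p, excl);
  Wall w; w.active = wall_rc > 0; w.rc = wall_rc; w.conf_track = conf_track;
  EnergyBreakdown eb = forces(r, kv, tp, p, w, nl, excl, f);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  return List::create(
      _["energy"] = eb.total(), _["forces"] = fm,
      _["breakdown"] = List::create(
          _["ss"] = eb.ss, _["aa"] = eb.aa, _["sk"] = eb.sk,
          _["angle"] = eb.angle, _["mt"] = eb.mt, _["as"] = eb.as,
          _["steric"] = eb.steric, _["confine"] = eb.confine,
          _["wall"] = eb.wall));
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
                LogicalVector clamped, List topology, List params,
                List opts) {
  const int n = pos.nrow();
  Params p = read_params(params);
  Topo tp = read_topo(topology);

  const int n_steps = as<int>(opts["n_steps"]);
  const bool thermostat = as<bool>(opts["thermostat"]);
  const double tauT = as<double>(opts["tauT"]);
  const double cap = as<double>(opts["cap_force"]);
  const bool reinit_vel = as<bool>(opts["reinit_vel"]);
  const unsigned int seed = as<unsigned int>(opts["seed"]);
  const bool as_dynamic = as<bool>(opts["as_dynamic"]);
  const int traj_stride = as<int>(opts["traj_stride"]);
  IntegerVector traj_idx = opts["traj_idx"]; // 1-based
  const int thermo_stride = as<int>(opts["thermo_stride"]);
  const int as_log_stride = as<int>(opts["as_log_stride"]);
  const int andersen_stride = as<int>(opts["andersen_stride"]);
  NumericVector wall_rc_sched = opts["wall_rc"];
  const int conf_track = as<int>(opts["conf_track"]);
  LogicalVector measure = opts["measure_steps"];
  NumericVector deq_sched = opts["deq_schedule"];
  LogicalVector suppress = opts["suppress_capture"];
  const double ring_half_width = as<double>(opts["ring_half_width"]);

  if (suppress.size() == (int)tp.as_state.size())
    for (int b = 0; b < suppress.size(); ++b) tp.suppress[b] = suppress[b];

  std::vector<double> r(3 * n), v(3 * n), f(3 * n), a(3 * n), ap(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      r[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
    }
  std::vector<int> kv(kind.begin(), kind.end());
  std::vector<bool> cl(clamped.begin(), clamped.end());
  int n_mobile = 0;
  for (int i = 0; i < n; ++i) if (!cl[i]) n_mobile++;
  const int ndof = 3 * n_mobile;

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  auto mb_init = [&]() {
    double sd = std::sqrt(p.kT);
    double com[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (cl[i]) { v[3 * i] = v[3 * i + 1] = v[3 * i + 2] = 0; continue; }
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] = sd * gauss(rng);
        com[d] += v[3 * i + d];
      }
    }
    // remove the centre-of-mass velocity only for free systems: clamps
    // break momentum conservation, and conditioning the bath on zero net
    // momentum would drain the soft modes that carry net momentum
    if (n_mobile < n) return;
    for (int d = 0; d < 3; ++d) com[d] /= std::max(n_mobile, 1);
    for (int i = 0; i < n; ++i)
      if (!cl[i]) for (int d = 0; d < 3; ++d) v[3 * i + d] -= com[d];
  };
  if (reinit_vel) mb_init();

  // Rigid-body drift removal: with Berendsen rescaling, conserved
  // zero-dissipation modes (net translation; net rotation, which both the
  // isolated chain and the axially symmetric confined axon possess) are
  // pumped at the expense of internal modes (the "flying ice cube"
  // artifact), which would centrifugally stretch free chains and spin the
  // axon azimuthally. Subtract the rigid modes periodically.
  auto remove_drift = [&]() {
    double com[3] = {0, 0, 0}, vcm[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        com[d] += r[3 * i + d];
        vcm[d] += v[3 * i + d];
      }
    for (int d = 0; d < 3; ++d) { com[d] /= n; vcm[d] /= n; }
    double L[3] = {0, 0, 0}, I[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int i = 0; i < n; ++i) {
      double q[3], u[3];
      for (int d = 0; d < 3; ++d) {
        q[d] = r[3 * i + d] - com[d];
        u[d] = v[3 * i + d] - vcm[d];
      }
      L[0] += q[1] * u[2] - q[2] * u[1];
      L[1] += q[2] * u[0] - q[0] * u[2];
      L[2] += q[0] * u[1] - q[1] * u[0];
      double q2 = q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
      for (int a2 = 0; a2 < 3; ++a2) {
        I[a2][a2] += q2;
        for (int b2 = 0; b2 < 3; ++b2) I[a2][b2] -= q[a2] * q[b2];
      }
    }
    // solve I w = L (3x3, with diagonal regularization for degenerate
    // geometries such as a perfectly straight chain)
    for (int d = 0; d < 3; ++d) I[d][d] += 1e-10 * (I[0][0] + I[1][1] + I[2][2] + 1.0);
    double w3[3];
    {
      double a11 = I[0][0], a12 = I[0][1], a13 = I[0][2],
             a22 = I[1][1], a23 = I[1][2], a33 = I[2][2];
      double det = a11 * (a22 * a33 - a23 * a23) -
                   a12 * (a12 * a33 - a23 * a13) +
                   a13 * (a12 * a23 - a22 * a13);
      if (std::fabs(det) < 1e-30) { w3[0] = w3[1] = w3[2] = 0; }
      else {
        w3[0] = (L[0] * (a22 * a33 - a23 * a23) +
                 L[1] * (a13 * a23 - a12 * a33) +
                 L[2] * (a12 * a23 - a13 * a22)) / det;
        w3[1] = (L[0] * (a23 * a13 - a12 * a33) +
                 L[1] * (a11 * a33 - a13 * a13) +
                 L[2] * (a12 * a13 - a11 * a23)) / det;
        w3[2] = (L[0] * (a12 * a23 - a22 * a13) +
                 L[1] * (a12 * a13 - a11 * a23) +
                 L[2] * (a11 * a22 - a12 * a12)) / det;
      }
    }
    for (int i = 0; i < n; ++i) {
      double q[3];
      for (int d = 0; d < 3; ++d) q[d] = r[3 * i + d] - com[d];
      v[3 * i] -= vcm[0] + (w3[1] * q[2] - w3[2] * q[1]);
      v[3 * i + 1] -= vcm[1] + (w3[2] * q[0] - w3[0] * q[2]);
      v[3 * i + 2] -= vcm[2] + (w3[0] * q[1] - w3[1] * q[0]);
    }
  };
  // Constraining angular momentum to zero throughout would bias the
  // configurational measure by det(I)^(-1/2); with Andersen collisions the
  // momenta (including L) are resampled canonically, so drift removal is
  // only used for purely deterministic thermostatted runs.
  const bool drift_removal = thermostat && n_mobile == n &&
                             as<int>(opts["andersen_stride"]) == 0;

  std::unordered_set<std::uint64_t> excl;
  for (size_t b = 0; b < tp.as_a.size(); ++b) {
    int i = tp.as_a[b], j = tp.as_s[b];
    excl.insert((std::uint64_t)std::min(i, j) * (std::uint64_t)n +
                (std::uint64_t)std::max(i, j));
  }
  NeighborList nl;
  nl.build(r, kv, p, excl);

  // stripe membership for wall-pressure accounting, from the initial ring
  // planes (rings only drift thermally; bands are re-derived per record)
  std::vector<int> stripe(n, 0);
  std::vector<double> ring_z0(tp.n_rings, 0.0);
  {
    std::vector<int> cnt(tp.n_rings, 0);
    for (int i = 0; i < n; ++i)
      if (tp.ring_id[i] > 0) {
        ring_z0[tp.ring_id[i] - 1] += r[3 * i + 2];
        cnt[tp.ring_id[i] - 1]++;
      }
    for (int g = 0; g < tp.n_rings; ++g)
      if (cnt[g]) ring_z0[g] /= cnt[g];
  }
  auto assign_stripes = [&]() {
    for (int i = 0; i < n; ++i) {
      stripe[i] = 0;
      if (kv[i] == 2) continue;
      double z = r[3 * i + 2];
      bool in_ring = false, in_between = false;
      for (int g = 0; g < tp.n_rings; ++g)
        if (std::fabs(z - ring_z0[g]) <= ring_half_width) in_ring = true;
      if (!in_ring && tp.n_rings >= 2 &&
          z > ring_z0[0] && z < ring_z0[tp.n_rings - 1]) in_between = true;
      if (in_ring) stripe[i] = 1;
      else if (in_between) stripe[i] = 2;
    }
  };
  assign_stripes();

  Wall w;
  auto wall_at = [&](int step) {
    if (wall_rc_sched.size() == 0) { w.active = false; return; }
    w.active = true;
    w.conf_track = conf_track;
    w.rc = (wall_rc_sched.size() == 1) ? wall_rc_sched[0]
                                       : wall_rc_sched[step];
  };
  const double ddfrac = p.ddmax / p.deq;
  auto deq_at = [&](int step) {
    if (deq_sched.size() == 0) return;
    p.deq = (deq_sched.size() == 1) ? deq_sched[0] : deq_sched[step];
    p.ddmax = ddfrac * p.deq; // max deformation tracks the target spacing
  };

  auto apply_cap_and_clamp = [&]() {
    for (int i = 0; i < n; ++i) {
      if (cl[i]) { f[3 * i] = f[3 * i + 1] = f[3 * i + 2] = 0; continue; }
      if (cap > 0) {
        double fm2 = f[3 * i] * f[3 * i] + f[3 * i + 1] * f[3 * i + 1] +
                     f[3 * i + 2] * f[3 * i + 2];
        if (fm2 > cap * cap) {
          double s = cap / std::sqrt(fm2);
          f[3 * i] *= s; f[3 * i + 1] *= s; f[3 * i + 2] *= s;
        }
      }
    }
  };

  // observer buffers
  int n_traj = (traj_stride > 0) ? (n_steps / traj_stride) : 0;
  NumericMatrix traj(n_traj * (int)traj_idx.size(), 4); // t, x, y, z
  int traj_row = 0;
  int n_thermo = (thermo_stride > 0) ? (n_steps / thermo_stride + 1) : 0;
  NumericMatrix thermo(std::max(n_thermo, 0), 4); // step, kT, Epot, Ekin
  int thermo_row = 0;
  std::vector<double> pr_step, pr_rc, pr_f1, pr_f2, pr_fall;
  int n_aslog = (as_log_stride > 0) ? (n_steps / as_log_stride + 1) : 0;
  IntegerMatrix as_log(std::max(n_aslog, 0),
                       (int)tp.as_state.size() + 1);
  int as_row = 0;
  bool fene_hit = false;

  double wall_grp[3];
  auto eval = [&](bool record_pressure) {
    wall_grp[0] = wall_grp[1] = wall_grp[2] = 0;
    EnergyBreakdown eb = forces(r, kv, tp, p, w, nl, excl, f,
                                record_pressure ? &stripe : nullptr,
                                record_pressure ? wall_grp : nullptr,
                                cap > 0 ? &fene_hit : nullptr);
    apply_cap_and_clamp();
    return eb;
  };

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      if (!cl[i])
        ke += 0.5 * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                     v[3 * i + 2] * v[3 * i + 2]);
    return ke;
  };

  auto log_thermo = [&](int step, double epot) {
    if (thermo_stride <= 0 || thermo_row >= thermo.nrow()) return;
    double ke = kinetic();
    thermo(thermo_row, 0) = step;
    thermo(thermo_row, 1) = 2.0 * ke / ndof;
    thermo(thermo_row, 2) = epot;
    thermo(thermo_row, 3) = ke;
    thermo_row++;
  };
  auto log_as = [&](int step) {
    if (as_log_stride <= 0 || as_row >= as_log.nrow()) return;
    as_log(as_row, 0) = step;
    for (size_t b = 0; b < tp.as_state.size(); ++b)
      as_log(as_row, (int)b + 1) = tp.as_state[b];
    as_row++;
  };

  const double dt = p.dt, dt2 = dt * dt;
  wall_at(0); deq_at(0);
  EnergyBreakdown eb = eval(false);
  for (int i = 0; i < 3 * n; ++i) { a[i] = f[i]; ap[i] = f[i]; }
  log_thermo(0, eb.total());
  log_as(0);

  for (int step = 0; step < n_steps; ++step) {
    wall_at(step); deq_at(step);
    bool first = (step == 0);
    // positions
    for (int i = 0; i < n; ++i) {
      if (cl[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int q = 3 * i + d;
        r[q] += first
          ? v[q] * dt + 0.5 * a[q] * dt2
          : v[q] * dt + (4.0 * a[q] - ap[q]) * dt2 / 6.0;
      }
    }
    // breakable-bond state machine at the new configuration
    if (as_dynamic) {
      for (size_t b = 0; b < tp.as_a.size(); ++b) {
        int i = tp.as_a[b], j = tp.as_s[b];
        double dx = r[3 * i] - r[3 * j], dy = r[3 * i + 1] - r[3 * j + 1],
               dz = r[3 * i + 2] - r[3 * j + 2];
        double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (tp.as_state[b] == 1 && rr > p.as_r_inflex) tp.as_state[b] = 0;
        else if (tp.as_state[b] == 0 && !tp.suppress[b] &&
                 rr < p.as_r_capture) tp.as_state[b] = 1;
      }
    }
    bool rec = measure.size() == n_steps && measure[step];
    eb = eval(rec);
    if (rec) {
      pr_step.push_back(step + 1);
      pr_rc.push_back(w.rc);
      pr_f1.push_back(wall_grp[0]);
      pr_f2.push_back(wall_grp[1]);
      pr_fall.push_back(wall_grp[2]);
    }
    // velocities
    for (int i = 0; i < n; ++i) {
      if (cl[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int q = 3 * i + d;
        v[q] += first ? 0.5 * (a[q] + f[q]) * dt
                      : (2.0 * f[q] + 5.0 * a[q] - ap[q]) * dt / 6.0;
        ap[q] = a[q];
        a[q] = f[q];
      }
    }
    if (thermostat) {
      double ke = kinetic();
      double kT_inst = 2.0 * ke / ndof;
      if (kT_inst < 1e-14) {
        mb_init();
      } else {
        double lam = std::sqrt(1.0 + (dt / tauT) * (p.kT / kT_inst - 1.0));
        for (int i = 0; i < n; ++i)
          if (!cl[i]) for (int d = 0; d < 3; ++d) v[3 * i + d] *= lam;
      }
      if (drift_removal && (step + 1) % 100 == 0) remove_drift();
    }
    // Andersen-style massive collision: redraw all velocities from the
    // Maxwell-Boltzmann distribution. Restores ergodic canonical sampling
    // for weakly chaotic systems (e.g. a free chain, whose conformational
    // modes mix very slowly under purely deterministic dynamics).
    if (andersen_stride > 0 && (step + 1) % andersen_stride == 0) mb_init();
    int s1 = step + 1;
    if (traj_stride > 0 && s1 % traj_stride == 0 && traj_row < traj.nrow()) {
      for (int t = 0; t < traj_idx.size(); ++t) {
        int i = traj_idx[t] - 1;
        traj(traj_row, 0) = s1;
        traj(traj_row, 1) = r[3 * i];
        traj(traj_row, 2) = r[3 * i + 1];
        traj(traj_row, 3) = r[3 * i + 2];
        traj_row++;
      }
    }
    if (thermo_stride > 0 && s1 % thermo_stride == 0) log_thermo(s1, eb.total());
    if (as_log_stride > 0 && s1 % as_log_stride == 0) log_as(s1);
    if (s1 % 1000 == 0) {
      for (int q = 0; q < 3 * n; q += 97)
        if (!std::isfinite(r[q]))
          stop("non-finite coordinates at step %d", s1);
    }
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pout(i, d) = r[3 * i + d];
      vout(i, d) = v[3 * i + d];
    }
  int np = (int)pr_step.size();
  NumericMatrix pressure(np, 5);
  for (int q = 0; q < np; ++q) {
    pressure(q, 0) = pr_step[q]; pressure(q, 1) = pr_rc[q];
    pressure(q, 2) = pr_f1[q]; pressure(q, 3) = pr_f2[q];
    pressure(q, 4) = pr_fall[q];
  }
  return List::create(
      _["pos"] = pout, _["vel"] = vout,
      _["as_state"] = IntegerVector(tp.as_state.begin(), tp.as_state.end()),
      _["traj"] = traj, _["thermo"] = thermo, _["pressure"] = pressure,
      _["as_log"] = as_log, _["fene_overrun"] = fene_hit,
      _["final_energy"] = eb.total());
}
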