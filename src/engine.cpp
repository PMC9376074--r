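// Event-driven discrete molecular dynamics core.
//
// Particles move ballistically between instantaneous events: shell crossings
// of piecewise-constant pair potentials, reflective wall bounces, Anderson
// thermostat velocity resamplings, periodic steering impulses, and frame
// emissions.  Two scheduling modes share every state-mutating code path and
// every prediction function:
//   mode 0 ("fast")      — binary heap with lazy invalidation via per-bead
//                          stamps, plus a scheduling horizon with per-bead
//                          refresh events to bound heap size;
//   mode 1 ("reference") — naive full re-prediction over all pairs after
//                          every event, no heap.
// Because every prediction is a pure function of the stored per-bead states
// (position, local time, velocity), and ties are broken deterministically on
// (time, kind, i, j), both modes execute the identical event sequence and
// produce bit-identical trajectories.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <queue>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double TIME_TOL = 1e-9;   // event-time regression tolerance (t.u.)
static const double DIST_TOL = 1e-7;   // boundary classification tolerance (A)

// ---------------------------------------------------------------------------
// Deterministic RNG: xorshift128+ seeded with splitmix64.  Self-contained so
// that trajectories are bit-reproducible independent of R's RNG state.
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t s = seed;
    auto sm = [&s]() {
      s += 0x9E3779B97F4A7C15ULL;
      uint64_t z = s;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next_u64() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform on (0,1)
  double unif() { return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  // standard normal, Box-Muller (cosine branch only: deterministic, stateless)
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// Step potential: boundaries b[0..m] (b[0] = hard core), energies E[0..m-1]
// for shells (b[k], b[k+1]]; region m+0-based beyond b[m] has energy 0 unless
// inf_outer (bond window), in which case b[m] is an infinite wall.
struct Pot {
  std::vector<double> b, b2, E;
  bool inf_outer;
  int nshell() const { return (int)E.size(); }
  // region index: 0 = inside hard core (forbidden), 1..m = shells,
  // m+1 = outside last boundary.  'outward' disambiguates exact boundaries.
  int region(double r2, bool outward) const {
    int m = nshell();
    for (int k = 0; k <= m; ++k) {
      double d2 = b2[k];
      if (std::fabs(r2 - d2) <= 2.0 * DIST_TOL * std::sqrt(d2 > 0 ? d2 : 1.0)) {
        // a pair on the outermost boundary of a bond window is always
        // inside it (the wall is impenetrable)
        if (k == m && inf_outer) return m;
        return outward ? (k + 1) : k;
      }
      if (r2 < d2) return k;
    }
    return m + 1;
  }
  double energy_of_region(int reg) const {
    int m = nshell();
    if (reg <= 0) return INF;
    if (reg <= m) return E[reg - 1];
    return inf_outer ? INF : 0.0;
  }
};

enum EvKind { EV_PAIR = 0, EV_WALL = 1, EV_STEER = 2, EV_THERMO = 3,
              EV_FRAME = 4, EV_REFRESH = 5 };

struct Ev {
  double t;
  int kind;
  int i, j;        // pair: i<j; wall/refresh: i, j=-1; system events: i=j=-1
  int boundary;    // pair: boundary index crossed; wall: axis (0,1,2)
  int dir;         // pair: +1 outward, -1 inward; wall: +1 hi wall, -1 lo wall
  uint32_t si, sj; // validity stamps at scheduling time
};

static inline bool earlier(const Ev& a, const Ev& b) {
  if (a.t != b.t) return a.t < b.t;
  if (a.kind != b.kind) return a.kind < b.kind;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

struct EvLater {
  bool operator()(const Ev& a, const Ev& b) const { return earlier(b, a); }
};

// ---------------------------------------------------------------------------
struct Engine {
  int n;
  std::vector<double> x, v;        // 3n, bead-local positions/velocities
  std::vector<double> tloc;        // per-bead local time
  std::vector<double> mass;
  std::vector<int> type;           // 0-based
  std::vector<char> mobile;
  std::vector<uint32_t> stamp;

  std::vector<Pot> pots;
  std::vector<int> nb;             // ntypes x ntypes -> pot index (-1 none)
  int ntypes;
  std::unordered_map<uint64_t, int> override_pot;

  double box;                      // side length; <=0 means unbounded
  double kT;
  double thermo_rate;              // per mobile bead per t.u.
  int n_mobile;

  // steering
  std::vector<int> steer_group;
  double steer_interval;
  double steer_dv[3];              // velocity increment per impulse (uniform)
  bool steering;

  Rng rng;
  double t_now, t_end, frame_stride;
  double next_thermo, next_steer, next_frame;
  double horizon;

  // track pair (for exact time-weighted shell occupancy)
  int trk_i, trk_j, trk_pot;
  std::vector<double> trk_time;    // time spent per region index
  int trk_region;
  double trk_last_t;

  // accounting
  double E0, cum_thermo, cum_steer, max_ledger_dev;
  long long nev_pair, nev_wall, nev_thermo, nev_steer;
  bool overlap_seen;

  // output
  bool store_frames;
  std::vector<double> frame_times;
  std::vector<std::vector<double>> frames;
  std::vector<double> trk_dist;    // tracked pair distance per frame

  std::priority_queue<Ev, std::vector<Ev>, EvLater> heap;
  std::vector<double> next_refresh;
  int mode;                        // 0 fast, 1 reference

  Engine(uint64_t seed) : rng(seed) {}

  inline int pot_index(int i, int j) const {
    int a = i < j ? i : j, b_ = i < j ? j : i;
    uint64_t key = (uint64_t)a * (uint64_t)n + (uint64_t)b_;
    auto it = override_pot.find(key);
    if (it != override_pot.end()) return it->second;
    return nb[type[a] * ntypes + type[b_]];
  }

  inline void advance_bead(int i, double t) {
    double dt = t - tloc[i];
    if (dt != 0.0) {
      x[3*i]   += v[3*i]   * dt;
      x[3*i+1] += v[3*i+1] * dt;
      x[3*i+2] += v[3*i+2] * dt;
      tloc[i] = t;
    }
  }

  // --- predictions: pure functions of stored bead states ---------------

  // Relative state of (i, j) at tref = max(tloc_i, tloc_j).
  bool predict_pair(int i, int j, Ev& ev) const {
    int pi = pot_index(i, j);
    if (pi < 0) return false;
    if (!mobile[i] && !mobile[j]) return false;
    const Pot& P = pots[pi];
    double tref = tloc[i] > tloc[j] ? tloc[i] : tloc[j];
    double r[3], w[3];
    for (int k = 0; k < 3; ++k) {
      double xi = x[3*i+k] + v[3*i+k] * (tref - tloc[i]);
      double xj = x[3*j+k] + v[3*j+k] * (tref - tloc[j]);
      r[k] = xi - xj;
      w[k] = v[3*i+k] - v[3*j+k];
    }
    double a = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
    if (a <= 0.0) return false;
    double bq = r[0]*w[0] + r[1]*w[1] + r[2]*w[2];
    double c2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    int reg = P.region(c2, bq > 0.0);
    if (reg == 0) reg = 1;  // defensive: never predict from inside the core
    int m = P.nshell();
    double best_t = INF; int best_b = -1, best_dir = 0;
    // inward crossing of boundary reg-1 (approach)
    int bin = (reg <= m ? reg - 1 : m);
    if (bin >= 0 && bq < 0.0) {
      double d2 = P.b2[bin];
      double disc = bq*bq - a*(c2 - d2);
      if (disc >= 0.0) {
        double tt = (-bq - std::sqrt(disc)) / a;
        if (tt < 0.0) tt = 0.0;
        best_t = tref + tt; best_b = bin; best_dir = -1;
      }
    }
    // outward crossing of boundary reg (escape).  A pair classified inside
    // b[reg] always has a real outward root (straight-line motion diverges);
    // computing it from the classified region, not from a raw c2-vs-d2
    // comparison, keeps pairs sitting exactly on a boundary from slipping
    // through without an event.
    if (reg <= m && reg >= 0) {
      int bout = reg;
      double d2 = P.b2[bout];
      double gap = c2 - d2;
      if (gap > 0.0) gap = 0.0;  // boundary-sitting pair: treat as inside
      double disc = bq*bq - a*gap;
      double tt = (-bq + std::sqrt(disc)) / a;
      if (tt < 0.0) tt = 0.0;
      double tabs = tref + tt;
      if (best_b < 0 || tabs < best_t) { best_t = tabs; best_b = bout; best_dir = +1; }
    }
    if (best_b < 0) return false;
    ev.t = best_t; ev.kind = EV_PAIR; ev.i = i; ev.j = j;
    ev.boundary = best_b; ev.dir = best_dir;
    ev.si = stamp[i]; ev.sj = stamp[j];
    return true;
  }

  bool predict_wall(int i, Ev& ev) const {
    if (box <= 0.0 || !mobile[i]) return false;
    double best_t = INF; int best_ax = -1, best_dir = 0;
    for (int k = 0; k < 3; ++k) {
      double vi = v[3*i+k];
      if (vi > 0.0) {
        double tt = (box - x[3*i+k]) / vi;
        if (tt < 0.0) tt = 0.0;
        double tabs = tloc[i] + tt;
        if (best_ax < 0 || tabs < best_t) { best_t = tabs; best_ax = k; best_dir = +1; }
      } else if (vi < 0.0) {
        double tt = (0.0 - x[3*i+k]) / vi;
        if (tt < 0.0) tt = 0.0;
        double tabs = tloc[i] + tt;
        if (best_ax < 0 || tabs < best_t) { best_t = tabs; best_ax = k; best_dir = -1; }
      }
    }
    if (best_ax < 0) return false;
    ev.t = best_t; ev.kind = EV_WALL; ev.i = i; ev.j = -1;
    ev.boundary = best_ax; ev.dir = best_dir;
    ev.si = stamp[i]; ev.sj = 0;
    return true;
  }

  // --- scheduling (fast mode) ------------------------------------------
  void schedule_bead(int i) {
    Ev ev;
    double lim = t_now + horizon;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      int a = i < j ? i : j, b_ = i < j ? j : i;
      if (predict_pair(a, b_, ev) && ev.t <= lim) heap.push(ev);
    }
    if (predict_wall(i, ev) && ev.t <= lim) heap.push(ev);
  }

  // --- state mutations (shared by both modes) ---------------------------
  void exec_pair(const Ev& e) {
    int i = e.i, j = e.j;
    advance_bead(i, e.t);
    advance_bead(j, e.t);
    const Pot& P = pots[pot_index(i, j)];
    double r[3], w[3];
    for (int k = 0; k < 3; ++k) {
      r[k] = x[3*i+k] - x[3*j+k];
      w[k] = v[3*i+k] - v[3*j+k];
    }
    double d = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
    double bd = P.b[e.boundary];
    if (std::fabs(d - bd) > 1e-5 * (bd > 1.0 ? bd : 1.0) + 1e-6)
      stop("event-queue corruption: pair (%d,%d) at r=%g, expected boundary %g (t=%g)",
           i + 1, j + 1, d, bd, e.t);
    double rh[3] = { r[0]/d, r[1]/d, r[2]/d };
    double u = w[0]*rh[0] + w[1]*rh[1] + w[2]*rh[2];
    double mi = mass[i], mj = mass[j];
    double mu;
    if (!mobile[i]) mu = mj; else if (!mobile[j]) mu = mi;
    else mu = mi * mj / (mi + mj);
    int m = P.nshell();
    // region being left / entered
    double dE; bool wall = false;
    if (e.dir > 0) { // outward through boundary e.boundary
      if (e.boundary == m && P.inf_outer) wall = true;
      else dE = P.energy_of_region(e.boundary + 1) - P.energy_of_region(e.boundary);
    } else {         // inward through boundary e.boundary
      if (e.boundary == 0) wall = true;
      else dE = P.energy_of_region(e.boundary) - P.energy_of_region(e.boundary + 1);
    }
    // self-healing: a pair found on the wrong side of an infinite wall
    // (possible only through accumulated round-off) transmits freely back
    if (!wall && !std::isfinite(dE)) dE = 0.0;
    double unew;
    if (wall) {
      unew = -u;
    } else {
      double ke_rad = 0.5 * mu * u * u;
      if (dE > 0.0 && ke_rad <= dE) {
        unew = -u;                       // reflect off the step
      } else {
        double u2 = u*u - 2.0 * dE / mu; // transmit, energy conserved
        double s = std::sqrt(u2 > 0.0 ? u2 : 0.0);
        unew = (u >= 0.0) ? s : -s;
      }
    }
    double dp = mu * (unew - u);
    for (int k = 0; k < 3; ++k) {
      double imp = dp * rh[k];
      if (mobile[i]) v[3*i+k] += imp / mi;
      if (mobile[j]) v[3*j+k] -= imp / mj;
    }
    stamp[i]++; stamp[j]++;
    nev_pair++;
    if (trk_pot >= 0 && ((i == trk_i && j == trk_j))) track_update(e.t);
  }

  void exec_wall(const Ev& e) {
    int i = e.i;
    advance_bead(i, e.t);
    v[3*i + e.boundary] = -v[3*i + e.boundary];
    stamp[i]++;
    nev_wall++;
  }

  void exec_thermo(double t) {
    // pick a mobile bead uniformly, resample its velocity at kT
    int pick = (int)(rng.unif() * n_mobile);
    if (pick >= n_mobile) pick = n_mobile - 1;
    int i = -1, c = -1;
    for (int k = 0; k < n; ++k) { if (mobile[k]) { if (++c == pick) { i = k; break; } } }
    advance_bead(i, t);
    double ke0 = 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    double sd = std::sqrt(kT / mass[i]);
    v[3*i]   = sd * rng.norm();
    v[3*i+1] = sd * rng.norm();
    v[3*i+2] = sd * rng.norm();
    double ke1 = 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    cum_thermo += ke1 - ke0;
    stamp[i]++;
    last_thermo_bead = i;
    nev_thermo++;
    next_thermo = t - std::log(rng.unif()) / (thermo_rate * n_mobile);
  }

  void exec_steer(double t) {
    for (size_t g = 0; g < steer_group.size(); ++g) {
      int i = steer_group[g];
      advance_bead(i, t);
      double ke0 = 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
      v[3*i]   += steer_dv[0];
      v[3*i+1] += steer_dv[1];
      v[3*i+2] += steer_dv[2];
      double ke1 = 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
      cum_steer += ke1 - ke0;
      stamp[i]++;
    }
    nev_steer++;
    next_steer = next_steer + steer_interval;
  }

  // --- energies ----------------------------------------------------------
  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    return ke;
  }

  double potential(bool* overlap) const {
    double pe = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        int pi = pot_index(i, j);
        if (pi < 0) continue;
        const Pot& P = pots[pi];
        double r2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double dx = (x[3*i+k] + v[3*i+k] * (t_now - tloc[i]))
                    - (x[3*j+k] + v[3*j+k] * (t_now - tloc[j]));
          r2 += dx * dx;
        }
        if (r2 > P.b2.back() && !P.inf_outer) continue;
        int reg = P.region(r2, false);
        if (reg == 0) {
          if (r2 < P.b2[0] * (1.0 - 1e-6)) { if (overlap) *overlap = true; }
          reg = 1; // boundary-sitting pair: count as innermost shell
        }
        double e = P.energy_of_region(reg);
        if (std::isfinite(e)) pe += e;
        else if (overlap) *overlap = true;
      }
    }
    return pe;
  }

  // --- tracked pair shell occupancy --------------------------------------
  // Region of the tracked pair at time t (beads virtually advanced); the
  // radial-velocity sign disambiguates a pair sitting exactly on a boundary.
  int track_region_at(double t) const {
    int i = trk_i, j = trk_j;
    double r2 = 0.0, bq = 0.0;
    for (int k = 0; k < 3; ++k) {
      double dx = (x[3*i+k] + v[3*i+k] * (t - tloc[i]))
                - (x[3*j+k] + v[3*j+k] * (t - tloc[j]));
      double dv = v[3*i+k] - v[3*j+k];
      r2 += dx * dx;
      bq += dx * dv;
    }
    return pots[trk_pot].region(r2, bq > 0.0);
  }

  void track_update(double t) {
    trk_time[trk_region] += t - trk_last_t;
    trk_last_t = t;
    trk_region = track_region_at(t);
  }

  // --- frame emission -----------------------------------------------------
  // Frames are virtual views at time t: stored bead states are never touched
  // here, so cached event predictions (pure functions of stored states)
  // remain bit-exactly reproducible by the naive scheduler.
  void emit_frame(double t) {
    frame_times.push_back(t);
    if (store_frames) {
      std::vector<double> fx(3 * n);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          fx[3*i+k] = x[3*i+k] + v[3*i+k] * (t - tloc[i]);
      frames.push_back(fx);
    }
    if (trk_pot >= 0) {
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dx = (x[3*trk_i+k] + v[3*trk_i+k] * (t - tloc[trk_i]))
                  - (x[3*trk_j+k] + v[3*trk_j+k] * (t - tloc[trk_j]));
        r2 += dx * dx;
      }
      trk_dist.push_back(std::sqrt(r2));
    }
    bool ov = false;
    double led = kinetic() + potential(&ov) - E0 - cum_thermo - cum_steer;
    if (ov) overlap_seen = true;
    double scale = std::fabs(E0) > 1.0 ? std::fabs(E0) : 1.0;
    double dev = std::fabs(led) / scale;
    if (dev > max_ledger_dev) max_ledger_dev = dev;
  }

  // --- main loops ---------------------------------------------------------
  bool system_event(Ev& ev) const {
    ev.t = INF; ev.kind = 99; ev.i = -1; ev.j = -1; ev.boundary = 0; ev.dir = 0;
    Ev c;
    c.i = c.j = -1; c.boundary = 0; c.dir = 0; c.si = c.sj = 0;
    c.t = next_steer; c.kind = EV_STEER;
    if (steering && earlier(c, ev)) ev = c;
    c.t = next_thermo; c.kind = EV_THERMO;
    if (thermo_rate > 0.0 && n_mobile > 0 && earlier(c, ev)) ev = c;
    c.t = next_frame; c.kind = EV_FRAME;
    if (earlier(c, ev)) ev = c;
    return std::isfinite(ev.t);
  }

  long long max_events;

  void dispatch(const Ev& e) {
    if (e.t < t_now - TIME_TOL)
      stop("event-time regression: scheduled %g < current %g", e.t, t_now);
    if (nev_pair + nev_wall + nev_thermo + nev_steer > max_events)
      stop("event budget exceeded (%lld events): runaway event cascade?", max_events);
    t_now = e.t > t_now ? e.t : t_now;
    switch (e.kind) {
      case EV_PAIR:   exec_pair(e); break;
      case EV_WALL:   exec_wall(e); break;
      case EV_STEER:  exec_steer(t_now); break;
      case EV_THERMO: exec_thermo(t_now); break;
      default: break;
    }
  }

  void run_fast() {
    heap = std::priority_queue<Ev, std::vector<Ev>, EvLater>();
    next_refresh.assign(n, horizon);
    for (int i = 0; i < n; ++i) schedule_bead(i);
    emit_frame(0.0);
    next_frame = frame_stride;
    while (true) {
      // next refresh event
      Ev best; bool have = false;
      while (!heap.empty()) {
        const Ev& top = heap.top();
        bool stale = (top.si != stamp[top.i]) ||
                     (top.kind == EV_PAIR && top.sj != stamp[top.j]);
        if (stale) { heap.pop(); continue; }
        best = top; have = true; break;
      }
      int rbead = -1; double rt = INF;
      for (int i = 0; i < n; ++i)
        if (next_refresh[i] < rt) { rt = next_refresh[i]; rbead = i; }
      Ev rev; rev.t = rt; rev.kind = EV_REFRESH; rev.i = rbead; rev.j = -1;
      rev.boundary = 0; rev.dir = 0; rev.si = rev.sj = 0;
      Ev sys; system_event(sys);
      Ev e;
      if (have) e = best; else e = sys;
      if (have && earlier(sys, e)) e = sys;
      if (rbead >= 0 && earlier(rev, e)) e = rev;
      if (e.kind == EV_FRAME) {
        if (e.t < t_now - TIME_TOL)
          stop("event-time regression at frame: %g < %g", e.t, t_now);
        t_now = e.t;
        emit_frame(t_now);
        if (t_now >= t_end - TIME_TOL) break;
        next_frame += frame_stride;
        continue;
      }
      if (e.kind == EV_REFRESH) {
        t_now = e.t > t_now ? e.t : t_now;
        next_refresh[e.i] = e.t + horizon;
        schedule_bead(e.i);
        continue;
      }
      if (have && e.kind == best.kind && e.t == best.t &&
          e.i == best.i && e.j == best.j) heap.pop();
      int bi = e.i, bj = e.j;
      dispatch(e);
      if (e.kind == EV_PAIR) { schedule_bead(bi); schedule_bead(bj); }
      else if (e.kind == EV_WALL) { schedule_bead(bi); }
      else if (e.kind == EV_STEER) {
        for (size_t g = 0; g < steer_group.size(); ++g) schedule_bead(steer_group[g]);
      } else if (e.kind == EV_THERMO) {
        // the resampled bead is found by stamp change; reschedule all changed
        // beads (exec_thermo bumped exactly one stamp; find it)
        // simpler: reschedule every mobile bead whose stamp changed is unknown
        // here, so exec_thermo records it:
        schedule_bead(last_thermo_bead);
      }
    }
  }

  int last_thermo_bead;

  void run_reference() {
    emit_frame(0.0);
    next_frame = frame_stride;
    Ev ev;
    while (true) {
      Ev best; best.t = INF; best.kind = 99; best.i = -2; best.j = -2;
      bool have = false;
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j)
          if (predict_pair(i, j, ev) && (!have || earlier(ev, best))) { best = ev; have = true; }
        if (predict_wall(i, ev) && (!have || earlier(ev, best))) { best = ev; have = true; }
      }
      Ev sys; system_event(sys);
      Ev e = have ? best : sys;
      if (have && earlier(sys, e)) e = sys;
      if (e.kind == EV_FRAME) {
        if (e.t < t_now - TIME_TOL)
          stop("event-time regression at frame: %g < %g", e.t, t_now);
        t_now = e.t;
        emit_frame(t_now);
        if (t_now >= t_end - TIME_TOL) break;
        next_frame += frame_stride;
        continue;
      }
      dispatch(e);
    }
  }
};

// [[Rcpp::export(name = ".dmd_run_cpp")]]
List dmd_run_cpp(NumericMatrix positions, NumericMatrix velocities,
                 NumericVector mass, IntegerVector type, LogicalVector mobile,
                 List potentials, IntegerMatrix nb_table,
                 IntegerMatrix overrides, IntegerVector override_pot,
                 double box, double kT, double thermo_rate,
                 IntegerVector steer_group, double steer_interval,
                 NumericVector steer_dv,
                 double duration, double frame_stride,
                 double seed, int mode, bool store_frames,
                 IntegerVector track_pair) {
  int n = positions.nrow();
  Engine eng((uint64_t)seed);
  eng.n = n;
  eng.x.resize(3 * n); eng.v.resize(3 * n);
  eng.tloc.assign(n, 0.0);
  eng.mass.assign(mass.begin(), mass.end());
  eng.type.resize(n);
  eng.mobile.resize(n);
  eng.stamp.assign(n, 0u);
  eng.n_mobile = 0;
  for (int i = 0; i < n; ++i) {
    eng.x[3*i] = positions(i, 0); eng.x[3*i+1] = positions(i, 1); eng.x[3*i+2] = positions(i, 2);
    bool mb = mobile[i];
    eng.mobile[i] = mb ? 1 : 0;
    if (mb) eng.n_mobile++;
    eng.v[3*i]   = mb ? velocities(i, 0) : 0.0;
    eng.v[3*i+1] = mb ? velocities(i, 1) : 0.0;
    eng.v[3*i+2] = mb ? velocities(i, 2) : 0.0;
    eng.type[i] = type[i] - 1;
  }
  // potentials
  int np = potentials.size();
  eng.pots.resize(np);
  for (int p = 0; p < np; ++p) {
    List P = potentials[p];
    NumericVector b = P["boundaries"];
    NumericVector E = P["energies"];
    eng.pots[p].b.assign(b.begin(), b.end());
    eng.pots[p].E.assign(E.begin(), E.end());
    eng.pots[p].inf_outer = as<bool>(P["infinite_outer_wall"]);
    eng.pots[p].b2.resize(b.size());
    for (int k = 0; k < b.size(); ++k) eng.pots[p].b2[k] = b[k] * b[k];
  }
  eng.ntypes = nb_table.nrow();
  eng.nb.resize(eng.ntypes * eng.ntypes);
  for (int a = 0; a < eng.ntypes; ++a)
    for (int b_ = 0; b_ < eng.ntypes; ++b_)
      eng.nb[a * eng.ntypes + b_] = nb_table(a, b_) - 1; // 0 in R = none -> -1
  for (int k = 0; k < overrides.nrow(); ++k) {
    int a = overrides(k, 0) - 1, b_ = overrides(k, 1) - 1;
    if (a > b_) std::swap(a, b_);
    eng.override_pot[(uint64_t)a * (uint64_t)n + (uint64_t)b_] = override_pot[k] - 1;
  }
  eng.box = box;
  eng.kT = kT;
  eng.thermo_rate = thermo_rate;
  eng.steering = steer_group.size() > 0;
  eng.steer_group.clear();
  for (int k = 0; k < steer_group.size(); ++k) eng.steer_group.push_back(steer_group[k] - 1);
  eng.steer_interval = eng.steering ? steer_interval : INF;
  eng.steer_dv[0] = steer_dv[0]; eng.steer_dv[1] = steer_dv[1]; eng.steer_dv[2] = steer_dv[2];
  eng.t_now = 0.0;
  eng.t_end = duration;
  eng.frame_stride = frame_stride;
  eng.horizon = 8.0;
  eng.next_steer = eng.steering ? steer_interval : INF;
  eng.next_thermo = (thermo_rate > 0.0 && eng.n_mobile > 0)
    ? -std::log(eng.rng.unif()) / (thermo_rate * eng.n_mobile) : INF;
  eng.next_frame = frame_stride;
  eng.store_frames = store_frames;
  eng.mode = mode;
  eng.cum_thermo = eng.cum_steer = 0.0;
  eng.max_ledger_dev = 0.0;
  eng.nev_pair = eng.nev_wall = eng.nev_thermo = eng.nev_steer = 0;
  eng.overlap_seen = false;
  eng.last_thermo_bead = -1;
  eng.max_events = 2000000000LL;
  // tracked pair
  eng.trk_pot = -1; eng.trk_i = eng.trk_j = -1;
  if (track_pair.size() == 2 && track_pair[0] > 0) {
    int a = track_pair[0] - 1, b_ = track_pair[1] - 1;
    if (a > b_) std::swap(a, b_);
    eng.trk_i = a; eng.trk_j = b_;
    eng.trk_pot = eng.pot_index(a, b_);
    if (eng.trk_pot >= 0) {
      eng.trk_time.assign(eng.pots[eng.trk_pot].nshell() + 2, 0.0);
      eng.trk_last_t = 0.0;
      eng.trk_region = eng.track_region_at(0.0);
    }
  }
  bool ov0 = false;
  eng.E0 = eng.kinetic() + eng.potential(&ov0);
  if (ov0 || !std::isfinite(eng.E0))
    stop("initial configuration has hard-core overlaps or infinite energy");

  if (mode == 0) eng.run_fast(); else eng.run_reference();

  for (int i = 0; i < n; ++i) eng.advance_bead(i, eng.t_end);
  if (eng.trk_pot >= 0) eng.track_update(eng.t_end);

  NumericMatrix fin_x(n, 3), fin_v(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { fin_x(i, k) = eng.x[3*i+k]; fin_v(i, k) = eng.v[3*i+k]; }
  List fr;
  if (store_frames) {
    fr = List(eng.frames.size());
    for (size_t f = 0; f < eng.frames.size(); ++f) {
      NumericMatrix M(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) M(i, k) = eng.frames[f][3*i+k];
      fr[f] = M;
    }
  }
  return List::create(
    _["times"] = wrap(eng.frame_times),
    _["frames"] = fr,
    _["final_positions"] = fin_x,
    _["final_velocities"] = fin_v,
    _["track_distances"] = wrap(eng.trk_dist),
    _["track_region_time"] = wrap(eng.trk_time),
    _["n_events"] = NumericVector::create(
      _["pair"] = (double)eng.nev_pair, _["wall"] = (double)eng.nev_wall,
      _["thermostat"] = (double)eng.nev_thermo, _["steer"] = (double)eng.nev_steer),
    _["max_ledger_dev"] = eng.max_ledger_dev,
    _["steer_work"] = eng.cum_steer,
    _["thermo_increment"] = eng.cum_thermo,
    _["overlap_seen"] = eng.overlap_seen);
}
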