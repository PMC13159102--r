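// Overdamped 2-D Brownian-dynamics engine for microtubule / motor /
// condensate-complex simulations.
//
// Numerical scheme: explicit forces with a diagonal (Jacobi) implicit
// correction for the stiff spring terms,
//     dx = dt * F(x) / (gamma + dt * S),
// where S is the sum of spring constants acting on the point.  This is
// unconditionally stable in the on-diagonal stiffness while keeping the
// cheap explicit treatment of the off-diagonal couplings.  Filament
// inextensibility is enforced exactly by a follow-the-leader
// reprojection from the minus end after every step, so segment rest
// lengths are conserved to machine precision.
//
// All randomness flows through a single PCG32 stream whose state is
// serialized into the R-level state object, making every trajectory a
// pure function of (config, seed).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstdio>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------
// PCG32 (O'Neill 2014), minimal: enough statistical quality for
// Brownian dynamics and fully reproducible across platforms.
struct Pcg32 {
  uint64_t state = 0, inc = 1;
  bool have_cached = false;
  double cached = 0.0;

  void seed(uint64_t s, uint64_t seq) {
    state = 0U;
    inc = (seq << 1u) | 1u;
    next();
    state += s;
    next();
    have_cached = false;
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double runif() {  // (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  double rnorm() {  // Box-Muller, cached pair
    if (have_cached) { have_cached = false; return cached; }
    double u1 = runif(), u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925287 * u2;
    cached = r * std::sin(th);
    have_cached = true;
    return r * std::cos(th);
  }
};

std::string u64_to_str(uint64_t v) {
  char buf[32];
  std::snprintf(buf, sizeof(buf), "%llu", static_cast<unsigned long long>(v));
  return std::string(buf);
}
uint64_t str_to_u64(const std::string& s) {
  // manual parse: avoids the __isoc23_strtoull symbol from glibc >= 2.38,
  // which is newer than the system loader on some hosts
  uint64_t v = 0;
  for (char c : s) {
    if (c < '0' || c > '9') break;
    v = v * 10u + static_cast<uint64_t>(c - '0');
  }
  return v;
}

double cfg_num(const List& c, const char* name) {
  if (!c.containsElementNamed(name))
    stop("config is missing field '%s'", name);
  return as<double>(c[name]);
}
bool cfg_flag(const List& c, const char* name) {
  if (!c.containsElementNamed(name))
    stop("config is missing field '%s'", name);
  return as<bool>(c[name]);
}

struct Config {
  double arena_radius, dt, t_bundle, t_total;
  int n_filaments;
  double filament_length, filament_rigidity, segment_length;
  int n_hset;
  double hset_binding_rate, hset_unbinding_rate, hset_speed,
      hset_stall_force, hset_link_stiffness, hset_capture_range;
  int n_complexes;
  double adh_on, adh_off, adh_range, adh_stiffness, adh_rest_length;
  double lat_on, lat_off, lat_stiffness;
  bool nucleation;
  double nucleation_growth_time, anchor_stiffness, confinement_stiffness;
  double viscosity, kT, motor_drag_length, complex_drag_length;
  uint64_t seed;

  void read(const List& c) {
    arena_radius = cfg_num(c, "arena_radius");
    dt = cfg_num(c, "dt");
    t_bundle = cfg_num(c, "t_bundle");
    t_total = cfg_num(c, "t_total");
    n_filaments = static_cast<int>(cfg_num(c, "n_filaments"));
    filament_length = cfg_num(c, "filament_length");
    filament_rigidity = cfg_num(c, "filament_rigidity");
    segment_length = cfg_num(c, "segment_length");
    n_hset = static_cast<int>(cfg_num(c, "n_hset"));
    hset_binding_rate = cfg_num(c, "hset_binding_rate");
    hset_unbinding_rate = cfg_num(c, "hset_unbinding_rate");
    hset_speed = cfg_num(c, "hset_speed");
    hset_stall_force = cfg_num(c, "hset_stall_force");
    hset_link_stiffness = cfg_num(c, "hset_link_stiffness");
    hset_capture_range = cfg_num(c, "hset_capture_range");
    n_complexes = static_cast<int>(cfg_num(c, "n_complexes"));
    adh_on = cfg_num(c, "complex_adhesive_on_rate");
    adh_off = cfg_num(c, "complex_adhesive_off_rate");
    adh_range = cfg_num(c, "complex_adhesive_range");
    adh_stiffness = cfg_num(c, "complex_adhesive_stiffness");
    adh_rest_length = cfg_num(c, "complex_adhesive_rest_length");
    lat_on = cfg_num(c, "lattice_binding_rate");
    lat_off = cfg_num(c, "lattice_unbinding_rate");
    lat_stiffness = cfg_num(c, "lattice_link_stiffness");
    nucleation = cfg_flag(c, "nucleation_enabled");
    nucleation_growth_time = cfg_num(c, "nucleation_growth_time");
    anchor_stiffness = cfg_num(c, "anchor_stiffness");
    confinement_stiffness = cfg_num(c, "confinement_stiffness");
    viscosity = cfg_num(c, "viscosity");
    kT = cfg_num(c, "temperature_kT");
    motor_drag_length = cfg_num(c, "motor_drag_length");
    complex_drag_length = cfg_num(c, "complex_drag_length");
    seed = static_cast<uint64_t>(cfg_num(c, "seed"));
  }
};

// Column layout of the state matrices (documented in R/sim_state.R).
// fil:   nv, rest_seg, seg_target, growth_rate
// motor: x, y, filA, absA, filB, absB         (-1 = free head)
// cplx:  x, y, mfil, mabs, lfil, labs, adhA, adhB, nucfil
enum { F_NV = 0, F_REST = 1, F_TARGET = 2, F_GROW = 3, F_NCOL = 4 };
enum { M_X = 0, M_Y = 1, M_FA = 2, M_AA = 3, M_FB = 4, M_AB = 5, M_NCOL = 6 };
enum { C_X = 0, C_Y = 1, C_MF = 2, C_MA = 3, C_LF = 4, C_LA = 5,
       C_A1 = 6, C_A2 = 7, C_NUC = 8, C_NCOL = 9 };

struct Sim {
  Config cf;
  Pcg32 rng;
  double time = 0.0;
  bool complexes_added = false;

  int nfil = 0;
  std::vector<int> fil_nv, fil_off;
  std::vector<double> fil_rest, fil_target, fil_grow;
  std::vector<double> vx, vy;              // flattened vertices
  std::vector<double> mx, my;              // motor bead positions
  std::vector<int> mfa, mfb;               // head filament ids (-1 free)
  std::vector<double> maa, mab;            // head abscissae (um from minus end)
  std::vector<double> cx_, cy_;            // complex positions
  std::vector<int> cmf, clf, ca1, ca2, cnuc;
  std::vector<double> cma, cla;

  // scratch force / stiffness accumulators
  std::vector<double> fvx, fvy, sv;        // vertices
  std::vector<double> fmx, fmy, sm;        // motors
  std::vector<double> fcx, fcy, sc;        // complexes

  void rebuild_offsets() {
    fil_off.resize(nfil);
    int off = 0;
    for (int f = 0; f < nfil; ++f) { fil_off[f] = off; off += fil_nv[f]; }
  }
  double fil_length(int f) const { return (fil_nv[f] - 1) * fil_rest[f]; }

  void point_on(int f, double a, double& px, double& py,
                int& seg, double& w) const {
    int nv = fil_nv[f];
    double rest = fil_rest[f];
    double s = a / rest;
    seg = static_cast<int>(s);
    if (seg > nv - 2) seg = nv - 2;
    if (seg < 0) seg = 0;
    w = s - seg;
    if (w < 0) w = 0;
    if (w > 1) w = 1;
    int o = fil_off[f] + seg;
    px = (1 - w) * vx[o] + w * vx[o + 1];
    py = (1 - w) * vy[o] + w * vy[o + 1];
  }

  void tangent(int f, int seg, double& tx, double& ty) const {
    int o = fil_off[f] + seg;
    double dx = vx[o + 1] - vx[o], dy = vy[o + 1] - vy[o];
    double n = std::sqrt(dx * dx + dy * dy);
    if (n < 1e-12) { tx = 1; ty = 0; return; }
    tx = dx / n; ty = dy / n;
  }

  // Hookean link between a point entity (px,py) and a filament station.
  // Adds +F to (fx,fy,ss) of the entity, -F spread over the two segment
  // vertices, and returns the load component along +tangent (used for
  // the motor force-velocity relation).
  double apply_link(double px, double py, int f, double a, double k,
                    double& fx, double& fy, double& ss) {
    int seg; double w, qx, qy;
    point_on(f, a, qx, qy, seg, w);
    double Fx = k * (qx - px), Fy = k * (qy - py);
    fx += Fx; fy += Fy; ss += k;
    int o = fil_off[f] + seg;
    fvx[o] -= (1 - w) * Fx; fvy[o] -= (1 - w) * Fy; sv[o] += (1 - w) * k;
    fvx[o + 1] -= w * Fx;   fvy[o + 1] -= w * Fy;   sv[o + 1] += w * k;
    double tx, ty;
    tangent(f, seg, tx, ty);
    // spring force ON the head is -F (pulls head toward the entity)
    double load = -(Fx * tx + Fy * ty);
    return load > 0 ? load : 0.0;
  }

  void confine(double px, double py, double& fx, double& fy, double& ss) {
    double r = std::sqrt(px * px + py * py);
    if (r > cf.arena_radius && r > 1e-12) {
      double k = cf.confinement_stiffness;
      double mag = k * (r - cf.arena_radius);
      fx -= mag * px / r; fy -= mag * py / r; ss += k;
    }
  }

  // Nearest filament station within `range` of (px,py); returns true and
  // fills (f,a) on success.  `exclude` skips one filament id (a complex
  // must not tether to its own nucleated filament, whose minus end is
  // anchored at the complex itself).
  bool capture(double px, double py, double range, int& bf, double& ba,
               int exclude = -1) {
    double best = range * range;
    bool found = false;
    for (int f = 0; f < nfil; ++f) {
      if (f == exclude) continue;
      int o = fil_off[f], nv = fil_nv[f];
      double rest = fil_rest[f];
      for (int s = 0; s < nv - 1; ++s) {
        double ax = vx[o + s], ay = vy[o + s];
        double bx2 = vx[o + s + 1], by2 = vy[o + s + 1];
        double dx = bx2 - ax, dy = by2 - ay;
        double len2 = dx * dx + dy * dy;
        double t = len2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / len2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double ex = ax + t * dx - px, ey = ay + t * dy - py;
        double d2 = ex * ex + ey * ey;
        if (d2 < best) {
          best = d2; found = true;
          bf = f; ba = (s + t) * rest;
        }
      }
    }
    return found;
  }

  void check_finite(const char* what, int id, double x, double y) {
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("numerical instability: %s %d has non-finite position "
           "(reduce dt or stiffness)", what, id + 1);
  }

  void step_once() {
    const double dt = cf.dt;
    const double gam_v = cf.viscosity * cf.segment_length;
    const double gam_m = cf.viscosity * cf.motor_drag_length;
    const double gam_c = cf.viscosity * cf.complex_drag_length;
    const double noise_v = std::sqrt(2.0 * cf.kT * dt / gam_v);
    const double noise_m = std::sqrt(2.0 * cf.kT * dt / gam_m);
    const double noise_c = std::sqrt(2.0 * cf.kT * dt / gam_c);
    const double p_hset_on = 1.0 - std::exp(-cf.hset_binding_rate * dt);
    const double p_hset_off = 1.0 - std::exp(-cf.hset_unbinding_rate * dt);
    const double p_lat_on = 1.0 - std::exp(-cf.lat_on * dt);
    const double p_lat_off = 1.0 - std::exp(-cf.lat_off * dt);
    const double p_adh_on = 1.0 - std::exp(-cf.adh_on * dt);
    const double p_adh_off = 1.0 - std::exp(-cf.adh_off * dt);

    size_t V = vx.size();
    int nm = static_cast<int>(mx.size());
    int nc = static_cast<int>(cx_.size());
    fvx.assign(V, 0.0); fvy.assign(V, 0.0); sv.assign(V, 0.0);
    fmx.assign(nm, 0.0); fmy.assign(nm, 0.0); sm.assign(nm, 0.0);
    fcx.assign(nc, 0.0); fcy.assign(nc, 0.0); sc.assign(nc, 0.0);

    // --- filament bending + confinement ------------------------------
    for (int f = 0; f < nfil; ++f) {
      int o = fil_off[f], nv = fil_nv[f];
      double l = fil_target[f] > 0 ? fil_target[f] : fil_rest[f];
      double c = cf.filament_rigidity / (l * l * l);
      for (int i = 1; i < nv - 1; ++i) {
        double bx2 = vx[o + i - 1] - 2 * vx[o + i] + vx[o + i + 1];
        double by2 = vy[o + i - 1] - 2 * vy[o + i] + vy[o + i + 1];
        fvx[o + i - 1] -= c * bx2; fvy[o + i - 1] -= c * by2;
        fvx[o + i] += 2 * c * bx2; fvy[o + i] += 2 * c * by2;
        fvx[o + i + 1] -= c * bx2; fvy[o + i + 1] -= c * by2;
      }
      if (nv >= 3) {
        for (int i = 0; i < nv; ++i) sv[o + i] += 6.0 * c;
      }
      for (int i = 0; i < nv; ++i)
        confine(vx[o + i], vy[o + i], fvx[o + i], fvy[o + i], sv[o + i]);
    }

    // --- motor coupler springs (and walking loads) -------------------
    std::vector<double> load_a(nm, 0.0), load_b(nm, 0.0);
    for (int m = 0; m < nm; ++m) {
      if (mfa[m] >= 0)
        load_a[m] = apply_link(mx[m], my[m], mfa[m], maa[m],
                               cf.hset_link_stiffness,
                               fmx[m], fmy[m], sm[m]);
      if (mfb[m] >= 0)
        load_b[m] = apply_link(mx[m], my[m], mfb[m], mab[m],
                               cf.hset_link_stiffness,
                               fmx[m], fmy[m], sm[m]);
      confine(mx[m], my[m], fmx[m], fmy[m], sm[m]);
    }

    // --- complex springs ---------------------------------------------
    std::vector<double> load_c(nc, 0.0);
    for (int i = 0; i < nc; ++i) {
      if (cmf[i] >= 0)
        load_c[i] = apply_link(cx_[i], cy_[i], cmf[i], cma[i],
                               cf.hset_link_stiffness,
                               fcx[i], fcy[i], sc[i]);
      if (clf[i] >= 0)
        apply_link(cx_[i], cy_[i], clf[i], cla[i], cf.lat_stiffness,
                   fcx[i], fcy[i], sc[i]);
      if (cnuc[i] >= 0) {
        int o = fil_off[cnuc[i]];
        double k = cf.anchor_stiffness;
        double Fx = k * (vx[o] - cx_[i]), Fy = k * (vy[o] - cy_[i]);
        fcx[i] += Fx; fcy[i] += Fy; sc[i] += k;
        fvx[o] -= Fx; fvy[o] -= Fy; sv[o] += k;
      }
      // adhesive bonds: apply once per pair (when partner id > self)
      int partners[2] = { ca1[i], ca2[i] };
      for (int s = 0; s < 2; ++s) {
        int j = partners[s];
        if (j > i) {
          double dx = cx_[j] - cx_[i], dy = cy_[j] - cy_[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d > 1e-9) {
            double mag = cf.adh_stiffness * (d - cf.adh_rest_length);
            double Fx = mag * dx / d, Fy = mag * dy / d;
            fcx[i] += Fx; fcy[i] += Fy; sc[i] += cf.adh_stiffness;
            fcx[j] -= Fx; fcy[j] -= Fy; sc[j] += cf.adh_stiffness;
          }
        }
      }
      confine(cx_[i], cy_[i], fcx[i], fcy[i], sc[i]);
    }

    // --- walking: minus-end-directed, linear force-velocity ----------
    auto walk = [&](int f, double& a, double load) {
      double v = cf.hset_speed;
      if (cf.hset_stall_force > 0) {
        double red = 1.0 - load / cf.hset_stall_force;
        v *= red > 0 ? red : 0.0;
      }
      a -= v * dt;
      if (a < 0) a = 0;         // dwell at the minus end until unbinding
      double L = fil_length(f);
      if (a > L) a = L;
    };
    for (int m = 0; m < nm; ++m) {
      if (mfa[m] >= 0) walk(mfa[m], maa[m], load_a[m]);
      if (mfb[m] >= 0) walk(mfb[m], mab[m], load_b[m]);
    }
    for (int i = 0; i < nc; ++i)
      if (cmf[i] >= 0) walk(cmf[i], cma[i], load_c[i]);

    // --- integrate ----------------------------------------------------
    for (size_t v = 0; v < V; ++v) {
      double denom = gam_v + dt * sv[v];
      vx[v] += dt * fvx[v] / denom + noise_v * rng.rnorm();
      vy[v] += dt * fvy[v] / denom + noise_v * rng.rnorm();
    }
    for (int m = 0; m < nm; ++m) {
      double denom = gam_m + dt * sm[m];
      mx[m] += dt * fmx[m] / denom + noise_m * rng.rnorm();
      my[m] += dt * fmy[m] / denom + noise_m * rng.rnorm();
      check_finite("motor", m, mx[m], my[m]);
    }
    for (int i = 0; i < nc; ++i) {
      double denom = gam_c + dt * sc[i];
      cx_[i] += dt * fcx[i] / denom + noise_c * rng.rnorm();
      cy_[i] += dt * fcy[i] / denom + noise_c * rng.rnorm();
      check_finite("complex", i, cx_[i], cy_[i]);
    }

    // --- filament growth + follow-the-leader reprojection ------------
    for (int f = 0; f < nfil; ++f) {
      if (fil_grow[f] > 0 && fil_rest[f] < fil_target[f]) {
        fil_rest[f] += fil_grow[f] * dt;
        if (fil_rest[f] > fil_target[f]) fil_rest[f] = fil_target[f];
      }
      int o = fil_off[f], nv = fil_nv[f];
      double rest = fil_rest[f];
      check_finite("filament", f, vx[o], vy[o]);
      for (int i = 1; i < nv; ++i) {
        double dx = vx[o + i] - vx[o + i - 1];
        double dy = vy[o + i] - vy[o + i - 1];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1e-12) { dx = 1; dy = 0; d = 1; }
        vx[o + i] = vx[o + i - 1] + rest * dx / d;
        vy[o + i] = vy[o + i - 1] + rest * dy / d;
      }
    }

    // --- stochastic unbinding ----------------------------------------
    for (int m = 0; m < nm; ++m) {
      if (mfa[m] >= 0 && rng.runif() < p_hset_off) mfa[m] = -1;
      if (mfb[m] >= 0 && rng.runif() < p_hset_off) mfb[m] = -1;
    }
    for (int i = 0; i < nc; ++i) {
      if (cmf[i] >= 0 && rng.runif() < p_hset_off) cmf[i] = -1;
      if (clf[i] >= 0 && rng.runif() < p_lat_off) clf[i] = -1;
    }

    // --- stochastic binding (rate gate first, then capture search) ---
    if (nfil > 0) {
      for (int m = 0; m < nm; ++m) {
        if (mfa[m] < 0 && p_hset_on > 0 && rng.runif() < p_hset_on) {
          int f; double a;
          if (capture(mx[m], my[m], cf.hset_capture_range, f, a)) {
            mfa[m] = f; maa[m] = a;
          }
        }
        if (mfb[m] < 0 && p_hset_on > 0 && rng.runif() < p_hset_on) {
          int f; double a;
          if (capture(mx[m], my[m], cf.hset_capture_range, f, a)) {
            if (mfa[m] != f) { mfb[m] = f; mab[m] = a; }
          }
        }
      }
      for (int i = 0; i < nc; ++i) {
        if (cmf[i] < 0 && p_hset_on > 0 && rng.runif() < p_hset_on) {
          int f; double a;
          if (capture(cx_[i], cy_[i], cf.hset_capture_range, f, a, cnuc[i])) {
            cmf[i] = f; cma[i] = a;
          }
        }
        if (clf[i] < 0 && p_lat_on > 0 && rng.runif() < p_lat_on) {
          int f; double a;
          if (capture(cx_[i], cy_[i], cf.hset_capture_range, f, a, cnuc[i])) {
            clf[i] = f; cla[i] = a;
          }
        }
      }
    }

    // --- adhesive bond breakage and formation ------------------------
    for (int i = 0; i < nc; ++i) {
      int* slots[2] = { &ca1[i], &ca2[i] };
      for (int s = 0; s < 2; ++s) {
        int j = *slots[s];
        if (j > i && rng.runif() < p_adh_off) {
          *slots[s] = -1;
          if (ca1[j] == i) ca1[j] = -1; else if (ca2[j] == i) ca2[j] = -1;
        }
      }
    }
    if (cf.adh_on > 0) {
      double r2 = cf.adh_range * cf.adh_range;
      for (int i = 0; i < nc; ++i) {
        if (ca1[i] >= 0 && ca2[i] >= 0) continue;
        for (int j = i + 1; j < nc; ++j) {
          if (ca1[j] >= 0 && ca2[j] >= 0) continue;
          if (ca1[i] == j || ca2[i] == j) continue;  // already bonded
          double dx = cx_[j] - cx_[i], dy = cy_[j] - cy_[i];
          if (dx * dx + dy * dy > r2) continue;
          if (rng.runif() < p_adh_on) {
            if (ca1[i] < 0) ca1[i] = j; else ca2[i] = j;
            if (ca1[j] < 0) ca1[j] = i; else ca2[j] = i;
            if (ca1[i] >= 0 && ca2[i] >= 0) break;
          }
        }
      }
    }

    time += dt;
  }

  // ------------------------------------------------------------------
  void from_state(const List& st) {
    time = as<double>(st["time"]);
    complexes_added = as<bool>(st["complexes_added"]);
    NumericMatrix fil = st["fil"];
    nfil = fil.nrow();
    fil_nv.resize(nfil); fil_rest.resize(nfil);
    fil_target.resize(nfil); fil_grow.resize(nfil);
    for (int f = 0; f < nfil; ++f) {
      fil_nv[f] = static_cast<int>(fil(f, F_NV));
      fil_rest[f] = fil(f, F_REST);
      fil_target[f] = fil(f, F_TARGET);
      fil_grow[f] = fil(f, F_GROW);
    }
    rebuild_offsets();
    NumericMatrix vert = st["vert"];
    size_t V = vert.nrow();
    vx.resize(V); vy.resize(V);
    for (size_t v = 0; v < V; ++v) { vx[v] = vert(v, 0); vy[v] = vert(v, 1); }
    NumericMatrix mo = st["motor"];
    int nm = mo.nrow();
    mx.resize(nm); my.resize(nm);
    mfa.resize(nm); maa.resize(nm); mfb.resize(nm); mab.resize(nm);
    for (int m = 0; m < nm; ++m) {
      mx[m] = mo(m, M_X); my[m] = mo(m, M_Y);
      mfa[m] = static_cast<int>(mo(m, M_FA)); maa[m] = mo(m, M_AA);
      mfb[m] = static_cast<int>(mo(m, M_FB)); mab[m] = mo(m, M_AB);
    }
    NumericMatrix cp = st["cplx"];
    int nc = cp.nrow();
    cx_.resize(nc); cy_.resize(nc);
    cmf.resize(nc); cma.resize(nc); clf.resize(nc); cla.resize(nc);
    ca1.resize(nc); ca2.resize(nc); cnuc.resize(nc);
    for (int i = 0; i < nc; ++i) {
      cx_[i] = cp(i, C_X); cy_[i] = cp(i, C_Y);
      cmf[i] = static_cast<int>(cp(i, C_MF)); cma[i] = cp(i, C_MA);
      clf[i] = static_cast<int>(cp(i, C_LF)); cla[i] = cp(i, C_LA);
      ca1[i] = static_cast<int>(cp(i, C_A1));
      ca2[i] = static_cast<int>(cp(i, C_A2));
      cnuc[i] = static_cast<int>(cp(i, C_NUC));
    }
    rng.state = str_to_u64(as<std::string>(st["rng_state"]));
    rng.inc = str_to_u64(as<std::string>(st["rng_inc"]));
    rng.have_cached = false;
  }

  List to_state() const {
    NumericMatrix fil(nfil, F_NCOL);
    for (int f = 0; f < nfil; ++f) {
      fil(f, F_NV) = fil_nv[f]; fil(f, F_REST) = fil_rest[f];
      fil(f, F_TARGET) = fil_target[f]; fil(f, F_GROW) = fil_grow[f];
    }
    colnames(fil) = CharacterVector::create("nv", "rest_seg", "seg_target",
                                            "growth_rate");
    size_t V = vx.size();
    NumericMatrix vert(static_cast<int>(V), 2);
    for (size_t v = 0; v < V; ++v) { vert(v, 0) = vx[v]; vert(v, 1) = vy[v]; }
    colnames(vert) = CharacterVector::create("x", "y");
    int nm = static_cast<int>(mx.size());
    NumericMatrix mo(nm, M_NCOL);
    for (int m = 0; m < nm; ++m) {
      mo(m, M_X) = mx[m]; mo(m, M_Y) = my[m];
      mo(m, M_FA) = mfa[m]; mo(m, M_AA) = maa[m];
      mo(m, M_FB) = mfb[m]; mo(m, M_AB) = mab[m];
    }
    colnames(mo) = CharacterVector::create("x", "y", "fil_a", "abs_a",
                                           "fil_b", "abs_b");
    int nc = static_cast<int>(cx_.size());
    NumericMatrix cp(nc, C_NCOL);
    for (int i = 0; i < nc; ++i) {
      cp(i, C_X) = cx_[i]; cp(i, C_Y) = cy_[i];
      cp(i, C_MF) = cmf[i]; cp(i, C_MA) = cma[i];
      cp(i, C_LF) = clf[i]; cp(i, C_LA) = cla[i];
      cp(i, C_A1) = ca1[i]; cp(i, C_A2) = ca2[i];
      cp(i, C_NUC) = cnuc[i];
    }
    colnames(cp) = CharacterVector::create(
        "x", "y", "motor_fil", "motor_abs", "lattice_fil", "lattice_abs",
        "adh_a", "adh_b", "nuc_fil");
    return List::create(
        _["time"] = time,
        _["complexes_added"] = complexes_added,
        _["fil"] = fil, _["vert"] = vert, _["motor"] = mo, _["cplx"] = cp,
        _["rng_state"] = u64_to_str(rng.state),
        _["rng_inc"] = u64_to_str(rng.inc));
  }
};

}  // namespace

// [[Rcpp::export]]
List cx_init(List config) {
  Sim s;
  s.cf.read(config);
  const Config& cf = s.cf;
  if (cf.arena_radius <= 0) stop("arena_radius must be positive");
  if (cf.n_filaments > 0 && cf.filament_length <= 0)
    stop("filament_length must be positive");
  s.rng.seed(cf.seed, 0xda3e39cb94b95bdbULL);
  s.time = 0.0;
  s.complexes_added = false;

  int nseg = cf.filament_length > 0
                 ? std::max(1, static_cast<int>(
                       std::lround(cf.filament_length / cf.segment_length)))
                 : 1;
  double rest = cf.n_filaments > 0 ? cf.filament_length / nseg : 0.0;
  s.nfil = cf.n_filaments;
  s.fil_nv.assign(s.nfil, nseg + 1);
  s.fil_rest.assign(s.nfil, rest);
  s.fil_target.assign(s.nfil, rest);
  s.fil_grow.assign(s.nfil, 0.0);
  s.rebuild_offsets();
  s.vx.assign(static_cast<size_t>(s.nfil) * (nseg + 1), 0.0);
  s.vy.assign(static_cast<size_t>(s.nfil) * (nseg + 1), 0.0);
  double rmax = cf.arena_radius - cf.filament_length / 2.0;
  if (rmax < 0) rmax = 0;
  for (int f = 0; f < s.nfil; ++f) {
    double r = rmax * std::sqrt(s.rng.runif());
    double phi = 6.283185307179586 * s.rng.runif();
    double theta = 6.283185307179586 * s.rng.runif();
    double cxm = r * std::cos(phi), cym = r * std::sin(phi);
    double ux = std::cos(theta), uy = std::sin(theta);
    int o = s.fil_off[f];
    for (int i = 0; i <= nseg; ++i) {
      double a = (i - nseg / 2.0) * rest;
      s.vx[o + i] = cxm + a * ux;
      s.vy[o + i] = cym + a * uy;
    }
  }

  int nm = cf.n_hset;
  s.mx.resize(nm); s.my.resize(nm);
  s.mfa.assign(nm, -1); s.mfb.assign(nm, -1);
  s.maa.assign(nm, 0.0); s.mab.assign(nm, 0.0);
  for (int m = 0; m < nm; ++m) {
    double r = cf.arena_radius * std::sqrt(s.rng.runif());
    double phi = 6.283185307179586 * s.rng.runif();
    s.mx[m] = r * std::cos(phi);
    s.my[m] = r * std::sin(phi);
  }
  return s.to_state();
}

// [[Rcpp::export]]
List cx_step(List state, List config, int n_steps) {
  Sim s;
  s.cf.read(config);
  s.from_state(state);
  for (int i = 0; i < n_steps; ++i) s.step_once();
  return s.to_state();
}

// [[Rcpp::export]]
List cx_add_complexes(List state, List config) {
  Sim s;
  s.cf.read(config);
  s.from_state(state);
  if (s.complexes_added) stop("complexes have already been added");
  const Config& cf = s.cf;
  int nc = cf.n_complexes;
  s.cx_.resize(nc); s.cy_.resize(nc);
  s.cmf.assign(nc, -1); s.cma.assign(nc, 0.0);
  s.clf.assign(nc, -1); s.cla.assign(nc, 0.0);
  s.ca1.assign(nc, -1); s.ca2.assign(nc, -1);
  s.cnuc.assign(nc, -1);
  for (int i = 0; i < nc; ++i) {
    double r = cf.arena_radius * std::sqrt(s.rng.runif());
    double phi = 6.283185307179586 * s.rng.runif();
    s.cx_[i] = r * std::cos(phi);
    s.cy_[i] = r * std::sin(phi);
  }
  if (cf.nucleation && nc > 0) {
    int nseg = std::max(1, static_cast<int>(std::lround(
                       cf.filament_length / cf.segment_length)));
    double seg_target = cf.filament_length / nseg;
    double rest0 = std::min(0.02, seg_target);
    double grow = cf.nucleation_growth_time > 0
                      ? (seg_target - rest0) / cf.nucleation_growth_time
                      : 0.0;
    for (int i = 0; i < nc; ++i) {
      double theta = 6.283185307179586 * s.rng.runif();
      double ux = std::cos(theta), uy = std::sin(theta);
      int fid = s.nfil;
      s.fil_nv.push_back(nseg + 1);
      s.fil_rest.push_back(rest0);
      s.fil_target.push_back(seg_target);
      s.fil_grow.push_back(grow);
      ++s.nfil;
      for (int k = 0; k <= nseg; ++k) {
        s.vx.push_back(s.cx_[i] + k * rest0 * ux);
        s.vy.push_back(s.cy_[i] + k * rest0 * uy);
      }
      s.rebuild_offsets();
      s.cnuc[i] = fid;
      if (grow <= 0) s.fil_rest[fid] = seg_target;
    }
  }
  s.complexes_added = true;
  return s.to_state();
}
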