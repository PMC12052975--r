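// 1-D Langevin propagation on translocation landscapes, with harmonic walls,
// static or well-tempered metadynamics bias, and moving harmonic restraints.
// Units follow the GROMACS convention (kJ/mol, nm, ps, g/mol), under which
// force/mass has units nm/ps^2 with no conversion factor.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

// ---------------------------------------------------------------------------
// Portable RNG: mt19937_64 + explicit Box-Muller so trajectories are
// bit-reproducible across standard libraries (std::normal_distribution is
// implementation-defined).
struct Rng {
  std::mt19937_64 g;
  bool have_spare;
  double spare;
  explicit Rng(std::uint64_t seed) : g(seed), have_spare(false), spare(0.0) {}
  double unif() { // open (0,1)
    return (static_cast<double>(g() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double t = 6.283185307179586476925287 * u2;
    spare = r * std::sin(t);
    have_spare = true;
    return r * std::cos(t);
  }
};

// ---------------------------------------------------------------------------
// Landscape: closed-form archetypes plus tabulated profiles.
// kinds: 0 flat, 1 harmonic, 2 double_well, 3 linear trend + Gaussian
// barriers (downhill / entry-barrier archetypes), 4 tabulated.
struct LandscapeC {
  int kind;
  double k, z0;      // harmonic: F = k/2 (z - z0)^2
  double h, a;       // double well: F = h ((z^2 - a^2)^2) / a^4
  double slope, ref; // trend: F = -slope * (z - ref) + sum of Gaussians
  std::vector<double> bh, bc, bw; // Gaussian barrier heights/centers/widths
  std::vector<double> tz, tf;     // tabulated nodes
  double zlo, zhi;

  // energy F and force (-dF/dz) at z; callers clamp to domain beforehand
  void eval(double z, double &F, double &force) const {
    switch (kind) {
    case 0: F = 0.0; force = 0.0; return;
    case 1: {
      double d = z - z0;
      F = 0.5 * k * d * d;
      force = -k * d;
      return;
    }
    case 2: {
      double q = z * z - a * a, a4 = a * a * a * a;
      F = h * q * q / a4;
      force = -4.0 * h * z * q / a4;
      return;
    }
    case 3: {
      F = -slope * (z - ref);
      force = slope;
      for (size_t i = 0; i < bh.size(); ++i) {
        double d = z - bc[i], w2 = bw[i] * bw[i];
        double g = bh[i] * std::exp(-0.5 * d * d / w2);
        F += g;
        force += g * d / w2;
      }
      return;
    }
    case 4: {
      // linear interpolation; one-sided derivative convention: each node
      // takes the slope of the segment to its right (last node: left)
      size_t n = tz.size();
      if (z <= tz[0]) { F = tf[0]; force = -(tf[1] - tf[0]) / (tz[1] - tz[0]); return; }
      if (z >= tz[n - 1]) {
        F = tf[n - 1];
        force = -(tf[n - 1] - tf[n - 2]) / (tz[n - 1] - tz[n - 2]);
        return;
      }
      size_t lo = 0, hi = n - 1;
      while (hi - lo > 1) { size_t mid = (lo + hi) / 2; if (tz[mid] <= z) lo = mid; else hi = mid; }
      double s = (tf[lo + 1] - tf[lo]) / (tz[lo + 1] - tz[lo]);
      F = tf[lo] + s * (z - tz[lo]);
      force = -s;
      return;
    }
    default:
      stop("unknown landscape kind code %d", kind);
    }
  }
};

static LandscapeC parse_landscape(const List &land) {
  LandscapeC L;
  L.kind = as<int>(land["kind_code"]);
  NumericVector dom = land["domain"];
  L.zlo = dom[0]; L.zhi = dom[1];
  L.k = L.z0 = L.h = L.a = L.slope = L.ref = 0.0;
  List p = land["params"];
  if (L.kind == 1) { L.k = as<double>(p["k"]); L.z0 = as<double>(p["z0"]); }
  if (L.kind == 2) { L.h = as<double>(p["barrier"]); L.a = as<double>(p["minima"]); }
  if (L.kind == 3) {
    L.slope = as<double>(p["slope"]); L.ref = as<double>(p["ref"]);
    NumericVector bh = p["barrier_heights"], bc = p["barrier_centers"], bw = p["barrier_widths"];
    L.bh = as<std::vector<double>>(bh);
    L.bc = as<std::vector<double>>(bc);
    L.bw = as<std::vector<double>>(bw);
  }
  if (L.kind == 4) {
    NumericVector tz = land["grid"], tf = land["values"];
    L.tz = as<std::vector<double>>(tz);
    L.tf = as<std::vector<double>>(tf);
  }
  return L;
}

// ---------------------------------------------------------------------------
struct WallC {
  double lo, hi, kappa;
  int expo;
  void eval(double z, double &E, double &force) const {
    E = 0.0; force = 0.0;
    if (kappa <= 0.0) return;
    if (z > hi) {
      double d = z - hi;
      E = 0.5 * kappa * std::pow(d, expo);
      force = -0.5 * kappa * expo * std::pow(d, expo - 1);
    } else if (z < lo) {
      double d = lo - z;
      E = 0.5 * kappa * std::pow(d, expo);
      force = 0.5 * kappa * expo * std::pow(d, expo - 1);
    }
  }
};

static WallC parse_walls(const List &walls) {
  WallC w;
  w.lo = as<double>(walls["lower_at"]);
  w.hi = as<double>(walls["upper_at"]);
  w.kappa = as<double>(walls["kappa"]);
  w.expo = as<int>(walls["exponent"]);
  return w;
}

// ---------------------------------------------------------------------------
// Gaussian hill set with spatial buckets. The online evaluation truncates
// each hill at 9 sigma, where a single neglected hill contributes
// < 3e-18 kJ/mol, so truncation never shows at the 1e-9 level against the
// untruncated offline summation.
struct HillSet {
  double sigma, inv2s2, cutoff, bmin, bwidth;
  int nbuckets;
  std::vector<double> c, h;
  std::vector<std::vector<int>> buckets;

  void init(double range_lo, double range_hi, double sigma_) {
    sigma = sigma_;
    inv2s2 = 1.0 / (2.0 * sigma * sigma);
    cutoff = 9.0 * sigma;
    bmin = range_lo - 1.0;
    bwidth = cutoff;
    nbuckets = static_cast<int>(std::ceil((range_hi + 1.0 - bmin) / bwidth)) + 1;
    buckets.assign(nbuckets, std::vector<int>());
  }
  int bucket_of(double z) const {
    int b = static_cast<int>(std::floor((z - bmin) / bwidth));
    if (b < 0) b = 0;
    if (b >= nbuckets) b = nbuckets - 1;
    return b;
  }
  void add(double center, double height) {
    c.push_back(center);
    h.push_back(height);
    buckets[bucket_of(center)].push_back(static_cast<int>(c.size()) - 1);
  }
  void eval(double z, double &V, double &force) const {
    V = 0.0; force = 0.0;
    if (c.empty()) return;
    int b = bucket_of(z);
    for (int bb = b - 1; bb <= b + 1; ++bb) {
      if (bb < 0 || bb >= nbuckets) continue;
      for (int idx : buckets[bb]) {
        double d = z - c[idx];
        if (std::fabs(d) > cutoff) continue;
        double g = h[idx] * std::exp(-d * d * inv2s2);
        V += g;
        force += g * d / (sigma * sigma);
      }
    }
  }
};

static inline double clampd(double z, double lo, double hi) {
  return z < lo ? lo : (z > hi ? hi : z);
}

// ---------------------------------------------------------------------------
// BAOAB step shared by all propagators. f is the total force at current z;
// on return z, v, f are advanced one step.
struct Baoab {
  double dt, m, c1, c2, sv;
  void setup(double dt_, double m_, double friction, double kT) {
    dt = dt_; m = m_;
    c1 = std::exp(-friction * dt);
    c2 = std::sqrt(1.0 - c1 * c1);
    sv = std::sqrt(kT / m);
  }
};

// [[Rcpp::export]]
List cpp_eval_landscape(List land, NumericVector z) {
  LandscapeC L = parse_landscape(land);
  int n = z.size();
  NumericVector E(n), F(n);
  for (int i = 0; i < n; ++i) {
    double zz = clampd(z[i], L.zlo, L.zhi);
    double e, f;
    L.eval(zz, e, f);
    E[i] = e; F[i] = f;
  }
  return List::create(_["energy"] = E, _["force"] = F);
}

// [[Rcpp::export]]
List cpp_eval_wall(List walls, NumericVector z) {
  WallC W = parse_walls(walls);
  int n = z.size();
  NumericVector E(n), F(n);
  for (int i = 0; i < n; ++i) { double e, f; W.eval(z[i], e, f); E[i] = e; F[i] = f; }
  return List::create(_["energy"] = E, _["force"] = F);
}

// Static-bias Langevin run. hills may be R_NilValue or a list with
// center/height/sigma vectors (already well-tempered-scaled heights).
// [[Rcpp::export]]
List cpp_run_langevin(List land, List lp, List walls, SEXP hills, int n_steps,
                      double z0, int seed, int stride, SEXP v0) {
  LandscapeC L = parse_landscape(land);
  WallC W = parse_walls(walls);
  double T = as<double>(lp["temperature"]);
  double dt = as<double>(lp["timestep"]);
  double fric = as<double>(lp["friction"]);
  double m = as<double>(lp["mass"]);
  Baoab S; S.setup(dt, m, fric, KB * T);

  HillSet H;
  bool has_hills = !Rf_isNull(hills);
  if (has_hills) {
    List hl(hills);
    NumericVector hc = hl["center"], hh = hl["height"];
    double hs = as<double>(hl["sigma"]);
    H.init(L.zlo, L.zhi, hs);
    for (int i = 0; i < hc.size(); ++i) H.add(hc[i], hh[i]);
  }

  Rng rng(static_cast<std::uint64_t>(seed));
  double z = z0;
  double v = Rf_isNull(v0) ? S.sv * rng.norm() : as<double>(v0);

  auto total_force = [&](double zz, double &bias_e) {
    double e, fl, ew, fw, bv = 0.0, bf = 0.0;
    L.eval(clampd(zz, L.zlo, L.zhi), e, fl);
    W.eval(zz, ew, fw);
    if (has_hills) H.eval(zz, bv, bf);
    bias_e = bv;
    return fl + fw + bf;
  };

  double bias_e;
  double f = total_force(z, bias_e);

  int n_rec = n_steps / stride + 1;
  NumericVector rt(n_rec), rz(n_rec), rv(n_rec), rb(n_rec), rf(n_rec);
  int ir = 0;
  rt[0] = 0.0; rz[0] = z; rv[0] = v; rb[0] = bias_e; rf[0] = f;
  ir = 1;

  for (int step = 1; step <= n_steps; ++step) {
    v += 0.5 * dt * f / m;
    z += 0.5 * dt * v;
    v = S.c1 * v + S.c2 * S.sv * rng.norm();
    z += 0.5 * dt * v;
    f = total_force(z, bias_e);
    if (!std::isfinite(f))
      stop("non-finite force at step %d (z = %g)", step, z);
    v += 0.5 * dt * f / m;
    if (step % stride == 0) {
      rt[ir] = step * dt; rz[ir] = z; rv[ir] = v; rb[ir] = bias_e; rf[ir] = f;
      ++ir;
    }
  }
  return List::create(_["time"] = rt, _["z"] = rz, _["velocity"] = rv,
                      _["bias_energy"] = rb, _["total_force"] = rf);
}

// Well-tempered metadynamics with synchronous multiple walkers sharing one
// hill set. Walkers propagate pace_steps with the bias frozen, then deposit
// in walker-index order; each deposition's height is scaled on the bias
// accumulated so far (including same-round earlier walkers).
// [[Rcpp::export]]
List cpp_run_metad(List land, List lp, List walls, List mcfg,
                   int n_steps_per_walker, int seed, int stride,
                   NumericVector probe_z, NumericVector z_start) {
  LandscapeC L = parse_landscape(land);
  WallC W = parse_walls(walls);
  double T = as<double>(lp["temperature"]);
  double dt = as<double>(lp["timestep"]);
  double fric = as<double>(lp["friction"]);
  double m = as<double>(lp["mass"]);
  Baoab S; S.setup(dt, m, fric, KB * T);

  int pace = as<int>(mcfg["pace_steps"]);
  double h0 = as<double>(mcfg["height0"]);
  double sigma = as<double>(mcfg["sigma"]);
  double gamma = as<double>(mcfg["biasfactor"]);
  double Tbias = as<double>(mcfg["temperature"]);
  int nw = as<int>(mcfg["n_walkers"]);
  double wtfac = 1.0 / (KB * (gamma - 1.0) * Tbias);

  HillSet H;
  H.init(std::min(L.zlo, as<double>(mcfg["grid_min"])),
         std::max(L.zhi, as<double>(mcfg["grid_max"])), sigma);

  std::vector<Rng> rng;
  rng.reserve(nw);
  for (int w = 0; w < nw; ++w) rng.emplace_back(static_cast<std::uint64_t>(seed + w));

  std::vector<double> z(nw), v(nw), f(nw);
  auto total_force = [&](double zz, double &bias_e) {
    double e, fl, ew, fw, bv, bf;
    L.eval(clampd(zz, L.zlo, L.zhi), e, fl);
    W.eval(zz, ew, fw);
    H.eval(zz, bv, bf);
    bias_e = bv;
    return fl + fw + bf;
  };

  double be;
  for (int w = 0; w < nw; ++w) {
    z[w] = z_start[w];
    v[w] = S.sv * rng[w].norm();
    f[w] = total_force(z[w], be);
  }

  int n_rounds = n_steps_per_walker / pace;
  int n_hills = n_rounds * nw;
  NumericVector hill_time(n_hills), hill_center(n_hills), hill_height(n_hills);
  int n_probe = probe_z.size();
  NumericMatrix probe_bias(n_rounds, std::max(n_probe, 1));

  int n_rec = n_steps_per_walker / stride + 1;
  std::vector<NumericVector> rt(nw), rz(nw), rv(nw), rb(nw), rf(nw);
  std::vector<int> ir(nw, 0);
  for (int w = 0; w < nw; ++w) {
    rt[w] = NumericVector(n_rec); rz[w] = NumericVector(n_rec);
    rv[w] = NumericVector(n_rec); rb[w] = NumericVector(n_rec);
    rf[w] = NumericVector(n_rec);
    double b; double ftot = total_force(z[w], b);
    rt[w][0] = 0.0; rz[w][0] = z[w]; rv[w][0] = v[w]; rb[w][0] = b; rf[w][0] = ftot;
    ir[w] = 1;
  }

  int ih = 0;
  long step_global = 0;
  for (int round = 0; round < n_rounds; ++round) {
    for (int w = 0; w < nw; ++w) {
      for (int s = 1; s <= pace; ++s) {
        long step = step_global + s;
        v[w] += 0.5 * dt * f[w] / m;
        z[w] += 0.5 * dt * v[w];
        v[w] = S.c1 * v[w] + S.c2 * S.sv * rng[w].norm();
        z[w] += 0.5 * dt * v[w];
        f[w] = total_force(z[w], be);
        if (!std::isfinite(f[w]))
          stop("non-finite force in walker %d at step %ld", w + 1, step);
        v[w] += 0.5 * dt * f[w] / m;
        if (step % stride == 0) {
          rt[w][ir[w]] = step * dt; rz[w][ir[w]] = z[w]; rv[w][ir[w]] = v[w];
          rb[w][ir[w]] = be; rf[w][ir[w]] = f[w];
          ++ir[w];
        }
      }
    }
    step_global += pace;
    double t_dep = step_global * dt;
    for (int w = 0; w < nw; ++w) {
      double bv, bf;
      H.eval(z[w], bv, bf);
      double height = h0 * std::exp(-bv * wtfac);
      H.add(z[w], height);
      hill_time[ih] = t_dep;
      hill_center[ih] = z[w];
      hill_height[ih] = height;
      ++ih;
    }
    for (int p = 0; p < n_probe; ++p) {
      double bv, bf;
      H.eval(probe_z[p], bv, bf);
      probe_bias(round, p) = bv;
    }
    // bias changed: refresh cached forces
    for (int w = 0; w < nw; ++w) f[w] = total_force(z[w], be);
  }
  // trailing steps beyond the last full round propagate without deposition
  int trailing = n_steps_per_walker - n_rounds * pace;
  for (int w = 0; w < nw; ++w) {
    for (int s = 1; s <= trailing; ++s) {
      long step = step_global + s;
      v[w] += 0.5 * dt * f[w] / m;
      z[w] += 0.5 * dt * v[w];
      v[w] = S.c1 * v[w] + S.c2 * S.sv * rng[w].norm();
      z[w] += 0.5 * dt * v[w];
      f[w] = total_force(z[w], be);
      v[w] += 0.5 * dt * f[w] / m;
      if (step % stride == 0) {
        rt[w][ir[w]] = step * dt; rz[w][ir[w]] = z[w]; rv[w][ir[w]] = v[w];
        rb[w][ir[w]] = be; rf[w][ir[w]] = f[w];
        ++ir[w];
      }
    }
  }

  List trajs(nw);
  for (int w = 0; w < nw; ++w)
    trajs[w] = List::create(_["time"] = rt[w], _["z"] = rz[w],
                            _["velocity"] = rv[w], _["bias_energy"] = rb[w],
                            _["total_force"] = rf[w]);
  return List::create(
      _["trajectories"] = trajs,
      _["hill_time"] = hill_time, _["hill_center"] = hill_center,
      _["hill_height"] = hill_height, _["probe_bias"] = probe_bias);
}

// Langevin run under a piecewise-linear moving harmonic restraint
// (center/kappa interpolated in step number, held beyond the last stage).
// Frames record time, z, restraint center/kappa and the restraint force
// kappa * (center - z).
// [[Rcpp::export]]
List cpp_run_restrained(List land, List lp, List walls,
                        NumericVector sched_step, NumericVector sched_at,
                        NumericVector sched_kappa, int n_steps, double z0,
                        int seed, int frame_stride) {
  LandscapeC L = parse_landscape(land);
  WallC W = parse_walls(walls);
  double T = as<double>(lp["temperature"]);
  double dt = as<double>(lp["timestep"]);
  double fric = as<double>(lp["friction"]);
  double m = as<double>(lp["mass"]);
  Baoab S; S.setup(dt, m, fric, KB * T);
  Rng rng(static_cast<std::uint64_t>(seed));

  int ns = sched_step.size();
  auto restraint_at = [&](double step, double &center, double &kappa) {
    if (step <= sched_step[0]) { center = sched_at[0]; kappa = sched_kappa[0]; return; }
    if (step >= sched_step[ns - 1]) { center = sched_at[ns - 1]; kappa = sched_kappa[ns - 1]; return; }
    int lo = 0;
    while (lo + 1 < ns && sched_step[lo + 1] <= step) ++lo;
    double w = (step - sched_step[lo]) / (sched_step[lo + 1] - sched_step[lo]);
    center = sched_at[lo] + w * (sched_at[lo + 1] - sched_at[lo]);
    kappa = sched_kappa[lo] + w * (sched_kappa[lo + 1] - sched_kappa[lo]);
  };

  double z = z0, center, kappa;
  restraint_at(0.0, center, kappa);
  double v = S.sv * rng.norm();

  auto total_force = [&](double zz, double cen, double kap) {
    double e, fl, ew, fw;
    L.eval(clampd(zz, L.zlo, L.zhi), e, fl);
    W.eval(zz, ew, fw);
    return fl + fw + kap * (cen - zz);
  };
  double f = total_force(z, center, kappa);

  int n_rec = n_steps / frame_stride + 1;
  NumericVector rt(n_rec), rz(n_rec), rc(n_rec), rk(n_rec), rF(n_rec);
  rt[0] = 0.0; rz[0] = z; rc[0] = center; rk[0] = kappa; rF[0] = kappa * (center - z);
  int ir = 1;

  for (int step = 1; step <= n_steps; ++step) {
    restraint_at(static_cast<double>(step), center, kappa);
    v += 0.5 * dt * f / m;
    z += 0.5 * dt * v;
    v = S.c1 * v + S.c2 * S.sv * rng.norm();
    z += 0.5 * dt * v;
    f = total_force(z, center, kappa);
    if (!std::isfinite(f))
      stop("non-finite force at step %d (z = %g)", step, z);
    v += 0.5 * dt * f / m;
    if (step % frame_stride == 0) {
      rt[ir] = step * dt; rz[ir] = z; rc[ir] = center; rk[ir] = kappa;
      rF[ir] = kappa * (center - z);
      ++ir;
    }
  }
  return List::create(_["time"] = rt, _["z"] = rz, _["restraint_center"] = rc,
                      _["restraint_kappa"] = rk, _["pull_force"] = rF);
}
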