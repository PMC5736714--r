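#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 2.0 * M_PI;

static inline double wrap_angle(double a) {
  a -= TWO_PI * std::floor(a / TWO_PI);
  if (a >= TWO_PI || a < 0) a = 0.0;   // rounding guard at the seam
  return a;
}

// ---------------------------------------------------------------------------
// Light schedule: piecewise-constant segments, each either a direction at
// infinity (mode 0, angle) or a finite point source (mode 1, position).
// ---------------------------------------------------------------------------
struct LightSpec {
  std::vector<double> t_start, angle, px, py;
  std::vector<int> mode;
};

static LightSpec read_light(const List& light) {
  LightSpec L;
  NumericVector ts = light["t_start"], an = light["angle"],
                px = light["px"], py = light["py"];
  IntegerVector md = light["mode"];
  if (ts.size() == 0) stop("light schedule must have at least one segment");
  for (int k = 0; k < ts.size(); ++k) {
    L.t_start.push_back(ts[k]);
    L.angle.push_back(an[k]);
    L.px.push_back(px[k]);
    L.py.push_back(py[k]);
    L.mode.push_back(md[k]);
  }
  return L;
}

static double light_direction_at(const LightSpec& L, double t, double x, double y) {
  int seg = 0;
  for (size_t k = 0; k < L.t_start.size(); ++k)
    if (L.t_start[k] <= t) seg = (int)k;
  if (L.mode[seg] == 0) return wrap_angle(L.angle[seg]);
  return wrap_angle(std::atan2(L.py[seg] - y, L.px[seg] - x));
}

// ---------------------------------------------------------------------------
// Model parameters
// ---------------------------------------------------------------------------
struct Params {
  double R, A, gamma0, k1, k2, S0, S_max, S_rate, p_photo,
         f_bias, step_cap, S_floor, spacing;
  int a;
};

static Params read_params(const List& p) {
  Params q;
  q.R = as<double>(p["R"]);         q.A = as<double>(p["A"]);
  q.a = as<int>(p["a"]);            q.gamma0 = as<double>(p["gamma0"]);
  q.k1 = as<double>(p["k1"]);       q.k2 = as<double>(p["k2"]);
  q.S0 = as<double>(p["S0"]);       q.S_max = as<double>(p["S_max"]);
  q.S_rate = as<double>(p["S_rate"]); q.p_photo = as<double>(p["p_photo"]);
  q.f_bias = as<double>(p["f_bias"]); q.step_cap = as<double>(p["step_cap"]);
  q.S_floor = as<double>(p["S_floor"]); q.spacing = as<double>(p["spacing"]);
  return q;
}

// Pair force magnitude, sigmoidal in centre distance (soft-core repulsion
// below contact, saturating attraction beyond).
static inline double pair_force(double D, double R, double k1, double k2, double a) {
  return (1.0 + k1 * (std::tanh(k2 * (D - 2.0 * R)) - 1.0)) / a;
}

// ---------------------------------------------------------------------------
// Slime lattice: dense column-major grid with lazy growth; untouched sites
// read as 0. Site (r, c) sits at (x = c * spacing, y = r * spacing).
// ---------------------------------------------------------------------------
struct Grid {
  std::vector<double> v;
  long r0, c0, nr, nc;   // v[i + nr * j] is site (r0 + i, c0 + j)
  double S_max;

  double read(long r, long c) const {
    long i = r - r0, j = c - c0;
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0.0;
    return v[i + nr * j];
  }

  void grow_to(long r, long c) {
    if (r >= r0 && c >= c0 && r < r0 + nr && c < c0 + nc) return;
    const long margin = 32;
    long nr0 = std::min(r0, r - margin), nc0 = std::min(c0, c - margin);
    long nr1 = std::max(r0 + nr, r + margin + 1);
    long nc1 = std::max(c0 + nc, c + margin + 1);
    long new_nr = nr1 - nr0, new_nc = nc1 - nc0;
    std::vector<double> nv((size_t)(new_nr * new_nc), 0.0);
    for (long j = 0; j < nc; ++j) {
      double* dst = &nv[(r0 - nr0) + new_nr * (j + (c0 - nc0))];
      const double* src = &v[nr * j];
      std::copy(src, src + nr, dst);
    }
    v.swap(nv); r0 = nr0; c0 = nc0; nr = new_nr; nc = new_nc;
  }

  void deposit(long r, long c, double amt) {
    grow_to(r, c);
    double& s = v[(r - r0) + nr * (c - c0)];
    s = std::min(s + amt, S_max);
  }
};

static inline long site_of(double coord, double spacing) {
  return (long)std::lround(coord / spacing);
}

// ---------------------------------------------------------------------------
// Per-step internals. RNG draw order is fixed: headings for cells 1..n, then
// tug selections for donors 1..n, then (only when a pair is exactly
// coincident) a separation direction per such pair in donor order.
// ---------------------------------------------------------------------------
static void update_headings_impl(int n, double* th, const int* freeload,
                                 const double* x, const double* y,
                                 const LightSpec& L, double t, double p_photo) {
  for (int i = 0; i < n; ++i) {
    double ang;
    if (freeload[i]) {
      ang = TWO_PI * unif_rand();
    } else {
      double u = unif_rand();
      if (u < p_photo) ang = light_direction_at(L, t, x[i], y[i]);
      else ang = TWO_PI * unif_rand();
    }
    th[i] = wrap_angle(ang);
  }
}

typedef std::unordered_map<long long, std::vector<int> > BinMap;

static inline long long bin_key(long bx, long by) {
  return (static_cast<long long>(bx) << 32) ^
         (static_cast<long long>(static_cast<unsigned int>(by)));
}

static void build_bins(int n, const double* x, const double* y,
                       double cs, BinMap& bins) {
  bins.clear();
  for (int i = 0; i < n; ++i) {
    long bx = (long)std::floor(x[i] / cs), by = (long)std::floor(y[i] / cs);
    bins[bin_key(bx, by)].push_back(i);
  }
}

static void eligible_of(int j, const double* x, const double* y,
                        double cutoff2, double cs, const BinMap& bins,
                        std::vector<int>& out) {
  out.clear();
  long bx = (long)std::floor(x[j] / cs), by = (long)std::floor(y[j] / cs);
  for (long dx = -1; dx <= 1; ++dx) for (long dy = -1; dy <= 1; ++dy) {
    BinMap::const_iterator it = bins.find(bin_key(bx + dx, by + dy));
    if (it == bins.end()) continue;
    for (size_t m = 0; m < it->second.size(); ++m) {
      int i = it->second[m];
      if (i == j) continue;
      double ddx = x[i] - x[j], ddy = y[i] - y[j];
      if (ddx * ddx + ddy * ddy <= cutoff2) out.push_back(i);
    }
  }
  std::sort(out.begin(), out.end());
}

// Donor-selected tugs: each donor picks at most `a` recipients uniformly
// without replacement from the cells within 2R + A of its centre. The
// eligible list is sorted so the draw is independent of the bin layout.
static void select_tugs_impl(int n, const double* x, const double* y,
                             double cutoff, int a,
                             std::vector<int>& donors, std::vector<int>& recips) {
  donors.clear(); recips.clear();
  double cutoff2 = cutoff * cutoff;
  BinMap bins;
  build_bins(n, x, y, cutoff, bins);
  std::vector<int> elig;
  for (int j = 0; j < n; ++j) {
    eligible_of(j, x, y, cutoff2, cutoff, bins, elig);
    int sz = (int)elig.size();
    int k = std::min(a, sz);
    for (int m = 0; m < k; ++m) {
      int pick = m + (int)(unif_rand() * (sz - m));
      if (pick >= sz) pick = sz - 1;
      std::swap(elig[m], elig[pick]);
      donors.push_back(j);
      recips.push_back(elig[m]);
    }
  }
}

// Tug force on each recipient plus the heading bias force G. The force a
// donor j applies to recipient i acts along the unit vector from i toward j:
// attraction where the pair force is positive, separation where negative.
static void net_forces_impl(int n, const double* x, const double* y,
                            const double* th,
                            const std::vector<int>& donors,
                            const std::vector<int>& recips,
                            const Params& P,
                            double* Fx, double* Fy, double* Gx, double* Gy) {
  std::fill(Fx, Fx + n, 0.0);
  std::fill(Fy, Fy + n, 0.0);
  for (size_t m = 0; m < donors.size(); ++m) {
    int j = donors[m], i = recips[m];
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double D = std::sqrt(dx * dx + dy * dy);
    double K = pair_force(D, P.R, P.k1, P.k2, (double)P.a);
    double ux, uy;
    if (D > 0) { ux = dx / D; uy = dy / D; }
    else {     // coincident centres: random separation direction this step
      double phi = TWO_PI * unif_rand();
      ux = std::cos(phi); uy = std::sin(phi);
    }
    Fx[i] += K * ux;
    Fy[i] += K * uy;
  }
  for (int i = 0; i < n; ++i) {
    Gx[i] = P.f_bias * std::cos(th[i]);
    Gy[i] = P.f_bias * std::sin(th[i]);
  }
}

// Overdamped move: displacement (G + F) / gamma with gamma read from the
// slime under the cell centre, clamped to the maximum step length.
static double move_impl(int n, double* x, double* y,
                        const double* Fx, const double* Fy,
                        const double* Gx, const double* Gy,
                        const Grid& g, const Params& P, double t) {
  double max_disp = 0.0;
  for (int i = 0; i < n; ++i) {
    double S = g.read(site_of(y[i], P.spacing), site_of(x[i], P.spacing));
    double gamma = P.gamma0 * P.S0 / std::max(S, P.S_floor);
    double dx = (Gx[i] + Fx[i]) / gamma, dy = (Gy[i] + Fy[i]) / gamma;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > P.step_cap) { dx *= P.step_cap / d; dy *= P.step_cap / d; d = P.step_cap; }
    x[i] += dx; y[i] += dy;
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
      stop("non-finite cell position at step t = %g (cell %d)", t, i + 1);
    if (d > max_disp) max_disp = d;
  }
  return max_disp;
}

static void deposit_impl(int n, const double* x, const double* y,
                         Grid& g, const Params& P) {
  for (int i = 0; i < n; ++i)
    g.deposit(site_of(y[i], P.spacing), site_of(x[i], P.spacing), P.S_rate);
}

// ---------------------------------------------------------------------------
// Exported wrappers (unit surface) and the chunked run loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_pair_force(NumericVector D, double R, double k1, double k2,
                             double a) {
  int n = D.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pair_force(D[i], R, k1, k2, a);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_light_direction(NumericMatrix pos, List light, double t) {
  LightSpec L = read_light(light);
  int n = pos.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = light_direction_at(L, t, pos(i, 0), pos(i, 1));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_update_headings(NumericMatrix pos, NumericVector headings,
                                  LogicalVector freeloader, List light,
                                  double t, double p_photo) {
  int n = pos.nrow();
  LightSpec L = read_light(light);
  std::vector<double> th(headings.begin(), headings.end());
  std::vector<int> fl(n);
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    fl[i] = freeloader[i] ? 1 : 0;
    x[i] = pos(i, 0); y[i] = pos(i, 1);
  }
  update_headings_impl(n, th.data(), fl.data(), x.data(), y.data(), L, t, p_photo);
  return NumericVector(th.begin(), th.end());
}

// [[Rcpp::export]]
IntegerMatrix cpp_select_tugs(NumericMatrix pos, double R, double A, int a) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  std::vector<int> donors, recips;
  select_tugs_impl(n, x.data(), y.data(), 2.0 * R + A, a, donors, recips);
  IntegerMatrix out((int)donors.size(), 2);
  for (size_t m = 0; m < donors.size(); ++m) {
    out(m, 0) = donors[m] + 1;
    out(m, 1) = recips[m] + 1;
  }
  colnames(out) = CharacterVector::create("donor", "recipient");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  BinMap bins;
  build_bins(n, x.data(), y.data(), cutoff, bins);
  double cutoff2 = cutoff * cutoff;
  std::vector<int> elig;
  std::vector<int> pi, pj;
  for (int j = 0; j < n; ++j) {
    eligible_of(j, x.data(), y.data(), cutoff2, cutoff, bins, elig);
    for (size_t m = 0; m < elig.size(); ++m)
      if (elig[m] > j) { pi.push_back(j + 1); pj.push_back(elig[m] + 1); }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t m = 0; m < pi.size(); ++m) { out(m, 0) = pi[m]; out(m, 1) = pj[m]; }
  return out;
}

// [[Rcpp::export]]
List cpp_net_forces(NumericMatrix pos, IntegerMatrix tugs, NumericVector headings,
                    List params) {
  Params P = read_params(params);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), th(headings.begin(), headings.end());
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  std::vector<int> donors(tugs.nrow()), recips(tugs.nrow());
  for (int m = 0; m < tugs.nrow(); ++m) {
    donors[m] = tugs(m, 0) - 1; recips[m] = tugs(m, 1) - 1;
  }
  NumericMatrix F(n, 2), G(n, 2);
  std::vector<double> Fx(n), Fy(n), Gx(n), Gy(n);
  net_forces_impl(n, x.data(), y.data(), th.data(), donors, recips, P,
                  Fx.data(), Fy.data(), Gx.data(), Gy.data());
  for (int i = 0; i < n; ++i) {
    F(i, 0) = Fx[i]; F(i, 1) = Fy[i];
    G(i, 0) = Gx[i]; G(i, 1) = Gy[i];
  }
  return List::create(_["F"] = F, _["G"] = G);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericVector headings, LogicalVector freeloader,
             NumericMatrix slime, int r_min, int c_min,
             List params, List light, double t0,
             int n_steps, int record_every, bool record_headings,
             int slime_every) {
  Params P = read_params(params);
  LightSpec L = read_light(light);
  int n = pos.nrow();

  std::vector<double> x(n), y(n), th(headings.begin(), headings.end());
  std::vector<int> fl(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1);
    fl[i] = freeloader[i] ? 1 : 0;
  }

  Grid g;
  g.r0 = r_min; g.c0 = c_min;
  g.nr = slime.nrow(); g.nc = slime.ncol();
  g.S_max = P.S_max;
  g.v.assign(slime.begin(), slime.end());

  // count recorded steps up front
  int n_rec = 0, n_srec = 0;
  for (int s = 1; s <= n_steps; ++s) {
    if (s % record_every == 0 || s == n_steps) ++n_rec;
    if (slime_every > 0 && (s % slime_every == 0 || s == n_steps)) ++n_srec;
  }
  NumericVector rec_pos((R_xlen_t)n_rec * n * 2);
  rec_pos.attr("dim") = IntegerVector::create(n_rec, n, 2);
  NumericVector rec_head(record_headings ? (R_xlen_t)n_rec * n : 0);
  if (record_headings) rec_head.attr("dim") = IntegerVector::create(n_rec, n);
  NumericVector rec_times(n_rec);
  List slime_snaps(n_srec);
  NumericVector slime_times(n_srec);

  std::vector<double> Fx(n), Fy(n), Gx(n), Gy(n);
  std::vector<int> donors, recips;
  double max_disp = 0.0;
  int ri = 0, si = 0;

  for (int s = 1; s <= n_steps; ++s) {
    double t = t0 + (s - 1);
    update_headings_impl(n, th.data(), fl.data(), x.data(), y.data(), L, t,
                         P.p_photo);
    select_tugs_impl(n, x.data(), y.data(), 2.0 * P.R + P.A, P.a, donors, recips);
    net_forces_impl(n, x.data(), y.data(), th.data(), donors, recips, P,
                    Fx.data(), Fy.data(), Gx.data(), Gy.data());
    double md = move_impl(n, x.data(), y.data(), Fx.data(), Fy.data(),
                          Gx.data(), Gy.data(), g, P, t);
    if (md > max_disp) max_disp = md;
    deposit_impl(n, x.data(), y.data(), g, P);

    if (s % record_every == 0 || s == n_steps) {
      for (int i = 0; i < n; ++i) {
        rec_pos[ri + (R_xlen_t)n_rec * i] = x[i];
        rec_pos[ri + (R_xlen_t)n_rec * (i + n)] = y[i];
        if (record_headings) rec_head[ri + (R_xlen_t)n_rec * i] = th[i];
      }
      rec_times[ri] = t0 + s;
      ++ri;
    }
    if (slime_every > 0 && (s % slime_every == 0 || s == n_steps)) {
      NumericMatrix sm((int)g.nr, (int)g.nc);
      std::copy(g.v.begin(), g.v.end(), sm.begin());
      slime_snaps[si] = List::create(_["values"] = sm,
                                     _["r_min"] = (int)g.r0,
                                     _["c_min"] = (int)g.c0);
      slime_times[si] = t0 + s;
      ++si;
    }
    if (s % 4096 == 0) checkUserInterrupt();
  }

  NumericMatrix fpos(n, 2);
  NumericVector fhead(n);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = x[i]; fpos(i, 1) = y[i]; fhead[i] = th[i];
  }
  NumericMatrix fslime((int)g.nr, (int)g.nc);
  std::copy(g.v.begin(), g.v.end(), fslime.begin());

  return List::create(
    _["times"] = rec_times,
    _["positions"] = rec_pos,
    _["headings"] = record_headings ? (SEXP)rec_head : R_NilValue,
    _["slime_times"] = slime_times,
    _["slime_snaps"] = slime_snaps,
    _["final_positions"] = fpos,
    _["final_headings"] = fhead,
    _["final_slime"] = fslime,
    _["r_min"] = (int)g.r0,
    _["c_min"] = (int)g.c0,
    _["t_end"] = t0 + n_steps,
    _["max_disp"] = max_disp);
}
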