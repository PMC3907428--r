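// Compute kernels for 2D monodomain tissue simulation.
//
// One inline cell update (gate kinetics -> currents -> calcium -> Vm) is
// shared by every backend, mirroring how a single brgates/brcurrents pair
// is reused across kernel variants; the backends differ only in memory
// layout (AoS vs SoA) and loop structure (plain, cache-tiled, strip
// parallel, gather vs scatter stencil).  All read-only backends therefore
// produce bit-identical trajectories; the scatter backend accumulates
// neighbour contributions in the same source order as the gather loop and
// in practice matches bitwise as well.
//
// Grid layout matches R matrices: column-major with ny rows (y index) and
// nx columns (x index); node (x, y) zero-based lives at x*ny + y.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <chrono>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

static constexpr double SING_HALFWIDTH = 1e-6;

struct Params {
  double gNa, ENa, gNaC, gs, Cm, cai_floor;
  bool use_j;
  double sc[6];       // rate multipliers: m h j d f x1
  double rc[12][10];  // alpha/beta rows: C1..C7, has_sing, sing_V, sing_limit
};

// canonical rate form (C1*exp(C2*(V+C3)) + C4*(V+C5)) / (exp(C6*(V+C3)) + C7)
// with removable singularities replaced by their stored analytic limit
static inline double rate_eval(double V, const double* c) {
  if (c[7] != 0.0 && std::fabs(V - c[8]) < SING_HALFWIDTH) return c[9];
  const double x = V + c[2];
  double num = 0.0;
  if (c[0] != 0.0) num = (c[1] != 0.0) ? c[0] * std::exp(c[1] * x) : c[0];
  if (c[3] != 0.0) num += c[3] * (V + c[4]);
  const double den = (c[5] != 0.0 ? std::exp(c[5] * x) : 1.0) + c[6];
  return num / den;
}

static inline double gate_step(double g, double a, double b, double dt) {
  g += dt * (a * (1.0 - g) - b * g);
  return g < 0.0 ? 0.0 : (g > 1.0 ? 1.0 : g);
}

// time-independent potassium current; the (V+23) factor has a removable
// singularity at V = -23 with limit 1/0.04
static inline double ik1_of_v(double v) {
  // exp(0.08(v+53)) = e^2 and exp(0.04(v+85)) = e * exp(1.28) with
  // e = exp(0.04(v+53)): one exponential serves all three factors
  static const double K85 = std::exp(0.04 * 32.0);
  const double e = std::exp(0.04 * (v + 53.0));
  const double t1 = 4.0 * (e * K85 - 1.0) / (e * e + e);
  const double x = v + 23.0;
  const double t2 = (std::fabs(x) < SING_HALFWIDTH)
                        ? (1.0 / 0.04)
                        : x / (1.0 - std::exp(-0.04 * x));
  return 0.35 * (t1 + 0.2 * t2);
}

// time-activated outward current; (exp(0.04(v+77)) - 1)/exp(0.04(v+35))
// = exp(0.04*42) - exp(-0.04(v+35))
static inline double ix1_of_v(double v, double x1) {
  static const double K77 = std::exp(0.04 * 42.0);
  return x1 * 0.8 * (K77 - std::exp(-0.04 * (v + 35.0)));
}

// canonical update order: gates (pre-step Vm) -> currents (updated gates,
// pre-step Vm) -> Cai -> Vm
static inline void cell_update(double& vm, double& m, double& h, double& j,
                               double& d, double& f, double& x1, double& cai,
                               double diff, double istim, double dt,
                               const Params& P) {
  const double v = vm;
  m = gate_step(m, P.sc[0] * rate_eval(v, P.rc[0]),
                P.sc[0] * rate_eval(v, P.rc[1]), dt);
  h = gate_step(h, P.sc[1] * rate_eval(v, P.rc[2]),
                P.sc[1] * rate_eval(v, P.rc[3]), dt);
  if (P.use_j)
    j = gate_step(j, P.sc[2] * rate_eval(v, P.rc[4]),
                  P.sc[2] * rate_eval(v, P.rc[5]), dt);
  d = gate_step(d, P.sc[3] * rate_eval(v, P.rc[6]),
                P.sc[3] * rate_eval(v, P.rc[7]), dt);
  f = gate_step(f, P.sc[4] * rate_eval(v, P.rc[8]),
                P.sc[4] * rate_eval(v, P.rc[9]), dt);
  x1 = gate_step(x1, P.sc[5] * rate_eval(v, P.rc[10]),
                 P.sc[5] * rate_eval(v, P.rc[11]), dt);
  const double ina = (P.gNa * m * m * m * h * (P.use_j ? j : 1.0) + P.gNaC) *
                     (v - P.ENa);
  const double es = -82.3 - 13.0287 * std::log(cai);
  const double is = P.gs * d * f * (v - es);
  const double itot = ina + is + ik1_of_v(v) + ix1_of_v(v, x1);
  cai += dt * (-1.0e-7 * is + 0.07 * (1.0e-7 - cai));
  if (cai < P.cai_floor) cai = P.cai_floor;
  vm = v + dt * (diff + (istim - itot) / P.Cm);
}

static Params make_params(const NumericMatrix& rates,
                          const NumericVector& mc) {
  Params P;
  P.gNa = mc[0];
  P.ENa = mc[1];
  P.gNaC = mc[2];
  P.gs = mc[3];
  P.Cm = mc[4];
  P.cai_floor = mc[5];
  P.use_j = mc[6] != 0.0;
  for (int i = 0; i < 6; i++) P.sc[i] = mc[7 + i];
  for (int r = 0; r < 12; r++)
    for (int c = 0; c < 10; c++) P.rc[r][c] = rates(r, c);
  return P;
}

// ---------------------------------------------------------------------------
// ghost-cell frame (no-flux): pad_type 0 = reflection about the boundary
// face (ghost = edge value; conservative), 1 = reflection about the
// boundary node (ghost = first interior neighbour)
static void fill_ghosts(std::vector<double>& pad, int nx, int ny,
                        int pad_type) {
  const int pny = ny + 2;
  const int off = (pad_type == 0) ? 1 : 2;
  for (int y = 1; y <= ny; y++) {
    pad[0 * pny + y] = pad[off * pny + y];
    pad[(nx + 1) * pny + y] = pad[(nx + 1 - off) * pny + y];
  }
  for (int x = 1; x <= nx; x++) {
    pad[x * pny + 0] = pad[x * pny + off];
    pad[x * pny + ny + 1] = pad[x * pny + ny + 1 - off];
  }
  pad[0 * pny + 0] = pad[off * pny + off];
  pad[0 * pny + ny + 1] = pad[off * pny + ny + 1 - off];
  pad[(nx + 1) * pny + 0] = pad[(nx + 1 - off) * pny + off];
  pad[(nx + 1) * pny + ny + 1] = pad[(nx + 1 - off) * pny + ny + 1 - off];
}

static inline const double* node_w(const double* W, bool wuni, int id) {
  return wuni ? W : W + 9 * id;
}

// weight flat index for offset (ox, oy) in {-1,0,1}^2: (ox+1)*3 + (oy+1),
// i.e. the column-major order of a 3x3 R matrix with rows = y offset.
// The nine terms are grouped into commutative pairs that map onto each
// other under left-right mirroring and transposition, so mirrored or
// transposed fields evolve exactly symmetrically (IEEE addition commutes;
// only the grouping is fixed here).
static inline double gather_node(const std::vector<double>& pad, int pny,
                                 int x, int y, const double* w) {
  const double* pc = &pad[(x + 1) * pny + (y + 1)];
  const double diag1 = w[0] * pc[-pny - 1] + w[8] * pc[pny + 1];  // SW + NE
  const double diag2 = w[2] * pc[-pny + 1] + w[6] * pc[pny - 1];  // NW + SE
  const double ax = w[1] * pc[-pny] + w[7] * pc[pny];             // W + E
  const double ay = w[3] * pc[-1] + w[5] * pc[1];                 // S + N
  return ((diag1 + diag2) + (ax + ay)) + w[4] * pc[0];
}

static void diffusion_gather(const std::vector<double>& pad, int nx, int ny,
                             const double* W, bool wuni,
                             std::vector<double>& out) {
  const int pny = ny + 2;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      const int id = x * ny + y;
      out[id] = gather_node(pad, pny, x, y, node_w(W, wuni, id));
    }
}

// each node (and ghost) scatters its value into the 9 target slots; the
// destination node's weights are used so that nonuniform-fiber grids match
// the gather formulation, and sources are visited in ascending column-major
// order so each target accumulates contributions in the gather order
static void diffusion_scatter(const std::vector<double>& pad, int nx, int ny,
                              const double* W, bool wuni,
                              std::vector<double>& out) {
  const int pny = ny + 2;
  std::fill(out.begin(), out.end(), 0.0);
  for (int sx = -1; sx <= nx; sx++)
    for (int sy = -1; sy <= ny; sy++) {
      const double v = pad[(sx + 1) * pny + (sy + 1)];
      for (int ox = -1; ox <= 1; ox++) {
        const int tx = sx + ox;
        if (tx < 0 || tx >= nx) continue;
        for (int oy = -1; oy <= 1; oy++) {
          const int ty = sy + oy;
          if (ty < 0 || ty >= ny) continue;
          const int id = tx * ny + ty;
          const double* w = node_w(W, wuni, id);
          out[id] += w[(1 - ox) * 3 + (1 - oy)] * v;
        }
      }
    }
}

static void diffusion_tiled(const std::vector<double>& pad, int nx, int ny,
                            const double* W, bool wuni, int tile_x, int tile_y,
                            std::vector<double>& out) {
  const int pny = ny + 2;
  for (int bx = 0; bx < nx; bx += tile_x)
    for (int by = 0; by < ny; by += tile_y) {
      const int ex = std::min(bx + tile_x, nx);
      const int ey = std::min(by + tile_y, ny);
      for (int x = bx; x < ex; x++)
        for (int y = by; y < ey; y++) {
          const int id = x * ny + y;
          out[id] = gather_node(pad, pny, x, y, node_w(W, wuni, id));
        }
    }
}

static void diffusion_parallel(const std::vector<double>& pad, int nx, int ny,
                               const double* W, bool wuni, int workers,
                               std::vector<double>& out) {
  const int pny = ny + 2;
#ifdef _OPENMP
#pragma omp parallel for schedule(static) num_threads(workers)
#endif
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      const int id = x * ny + y;
      out[id] = gather_node(pad, pny, x, y, node_w(W, wuni, id));
    }
  (void)workers;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_diffusion(NumericMatrix vm, NumericMatrix weights,
                                  int mode, int pad_type) {
  const int ny = vm.nrow(), nx = vm.ncol(), n = nx * ny;
  std::vector<double> pad((nx + 2) * (ny + 2)), out(n);
  const int pny = ny + 2;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      pad[(x + 1) * pny + (y + 1)] = vm[x * ny + y];
  fill_ghosts(pad, nx, ny, pad_type);
  const bool wuni = (weights.ncol() == 1);
  if (mode == 0)
    diffusion_gather(pad, nx, ny, weights.begin(), wuni, out);
  else
    diffusion_scatter(pad, nx, ny, weights.begin(), wuni, out);
  NumericMatrix res(ny, nx);
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_cell_step(NumericVector state, NumericMatrix rates,
                            NumericVector memconst, double istim, double dt) {
  Params P = make_params(rates, memconst);
  NumericVector s = clone(state);
  cell_update(s[0], s[1], s[2], s[3], s[4], s[5], s[6], s[7], 0.0, istim, dt,
              P);
  return s;
}

// stim rows for the single-cell runner: t_start, t_end, amplitude
// [[Rcpp::export]]
List cpp_run_single_cell(NumericVector state, NumericMatrix rates,
                         NumericVector memconst, NumericMatrix stim, double dt,
                         int nsteps, double t0) {
  Params P = make_params(rates, memconst);
  double v[8];
  for (int i = 0; i < 8; i++) v[i] = state[i];
  NumericMatrix traj(nsteps + 1, 8);
  NumericVector times(nsteps + 1);
  for (int i = 0; i < 8; i++) traj(0, i) = v[i];
  times[0] = t0;
  const int nev = stim.nrow();
  for (int s = 0; s < nsteps; s++) {
    const double t = t0 + s * dt;
    double istim = 0.0;
    for (int e = 0; e < nev; e++)
      if (t >= stim(e, 0) && t < stim(e, 1)) istim += stim(e, 2);
    cell_update(v[0], v[1], v[2], v[3], v[4], v[5], v[6], v[7], 0.0, istim, dt,
                P);
    for (int i = 0; i < 8; i++) traj(s + 1, i) = v[i];
    times[s + 1] = t0 + (s + 1) * dt;
  }
  return List::create(_["times"] = times, _["traj"] = traj);
}

// ---------------------------------------------------------------------------
// full tissue run
//
// stim event rows (12 columns):
//   0 type (0 fixed, 1 auto)   1 t_start   2 t_end
//   3 x0   4 x1   5 y0   6 y1  (zero-based, half-open)
//   7 amplitude   8 monitor node (zero-based)   9 threshold
//  10 duration (auto events)  11 latched flag

struct Cell {
  double vm, m, h, j, d, f, x1, cai;
};

// [[Rcpp::export]]
List cpp_run(List st, int nx, int ny, NumericMatrix rates,
             NumericVector memconst, NumericMatrix weights,
             NumericMatrix stim_in, int backend, int tile_x, int tile_y,
             int workers, double dt, int nsteps, double t0, int step0,
             int probe_idx, int snap_stride, bool record_snaps,
             double excite_thr, double vm_lo, double vm_hi) {
  const int n = nx * ny, pny = ny + 2;
  Params P = make_params(rates, memconst);

  std::vector<double> vm = as<std::vector<double>>(st["vm"]);
  std::vector<double> m = as<std::vector<double>>(st["m"]);
  std::vector<double> h = as<std::vector<double>>(st["h"]);
  std::vector<double> j = as<std::vector<double>>(st["j"]);
  std::vector<double> d = as<std::vector<double>>(st["d"]);
  std::vector<double> f = as<std::vector<double>>(st["f"]);
  std::vector<double> x1 = as<std::vector<double>>(st["x1"]);
  std::vector<double> cai = as<std::vector<double>>(st["cai"]);

  const bool aos = (backend == 0);
  std::vector<Cell> cells;
  if (aos) {
    cells.resize(n);
    for (int i = 0; i < n; i++)
      cells[i] = Cell{vm[i], m[i], h[i], j[i], d[i], f[i], x1[i], cai[i]};
  }
  auto vm_at = [&](int id) { return aos ? cells[id].vm : vm[id]; };

  const bool wuni = (weights.ncol() == 1);
  const double* W = weights.begin();
  std::vector<double> pad((nx + 2) * (ny + 2)), diffv(n);

  NumericMatrix stim = clone(stim_in);
  const int nev = stim.nrow();
  std::vector<double> prevmon(nev, 0.0);
  for (int e = 0; e < nev; e++)
    if (stim(e, 0) == 1.0) prevmon[e] = vm_at((int)stim(e, 8));

  const int nsnap = nsteps / snap_stride + 1;
  NumericMatrix snaps(record_snaps ? n : 0, record_snaps ? nsnap : 0);
  NumericVector snap_times(nsnap);
  IntegerVector excited(nsnap);
  NumericMatrix trace(nsteps + 1, 2);
  int nsnap_done = 0;
  auto record_snap = [&](int k, double t) {
    snap_times[k] = t;
    int c = 0;
    for (int i = 0; i < n; i++) {
      const double v = vm_at(i);
      if (record_snaps) snaps(i, k) = v;
      if (v > excite_thr) c++;
    }
    excited[k] = c;
    nsnap_done = k + 1;
  };
  trace(0, 0) = t0;
  trace(0, 1) = vm_at(probe_idx);
  record_snap(0, t0);

  int instab_step = -1, instab_node = -1;
  double elapsed = 0.0;
  int completed = 0;
  std::vector<int> active;

  for (int s = 0; s < nsteps; s++) {
    const double t = t0 + s * dt;
    // auto-triggered events latch when the monitor node falls through the
    // threshold (repolarization); latched exactly once
    for (int e = 0; e < nev; e++) {
      if (stim(e, 0) == 1.0) {
        const double mv = vm_at((int)stim(e, 8));
        if (stim(e, 11) == 0.0 && prevmon[e] > stim(e, 9) &&
            mv <= stim(e, 9)) {
          stim(e, 11) = 1.0;
          stim(e, 1) = t;
          stim(e, 2) = t + stim(e, 10);
        }
        prevmon[e] = mv;
      }
    }
    active.clear();
    for (int e = 0; e < nev; e++) {
      const bool armed = (stim(e, 0) == 0.0) || (stim(e, 11) == 1.0);
      if (armed && t >= stim(e, 1) && t < stim(e, 2)) active.push_back(e);
    }

    const auto tic = std::chrono::steady_clock::now();
    // bcs stage: refresh the ghost frame (serialized)
    if (aos) {
      for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
          pad[(x + 1) * pny + (y + 1)] = cells[x * ny + y].vm;
    } else {
      for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
          pad[(x + 1) * pny + (y + 1)] = vm[x * ny + y];
    }
    fill_ghosts(pad, nx, ny, 0);

    if (aos) {
      // reference: nested spatial loops, per-node stencil + membrane update
      for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++) {
          const int id = x * ny + y;
          const double diff = gather_node(pad, pny, x, y, node_w(W, wuni, id));
          double istim = 0.0;
          for (int a : active)
            if (x >= stim(a, 3) && x < stim(a, 4) && y >= stim(a, 5) &&
                y < stim(a, 6))
              istim += stim(a, 7);
          Cell& c = cells[id];
          cell_update(c.vm, c.m, c.h, c.j, c.d, c.f, c.x1, c.cai, diff, istim,
                      dt, P);
        }
    } else {
      switch (backend) {
        case 1:
          diffusion_gather(pad, nx, ny, W, wuni, diffv);
          break;
        case 2:
          diffusion_scatter(pad, nx, ny, W, wuni, diffv);
          break;
        case 3:
          diffusion_tiled(pad, nx, ny, W, wuni, tile_x, tile_y, diffv);
          break;
        case 4:
          diffusion_parallel(pad, nx, ny, W, wuni, workers, diffv);
          break;
        default:
          stop("unknown backend code");
      }
#ifdef _OPENMP
#pragma omp parallel for schedule(static) num_threads(workers) if (backend == 4)
#endif
      for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++) {
          const int id = x * ny + y;
          double istim = 0.0;
          for (size_t ai = 0; ai < active.size(); ai++) {
            const int a = active[ai];
            if (x >= stim(a, 3) && x < stim(a, 4) && y >= stim(a, 5) &&
                y < stim(a, 6))
              istim += stim(a, 7);
          }
          cell_update(vm[id], m[id], h[id], j[id], d[id], f[id], x1[id],
                      cai[id], diffv[id], istim, dt, P);
        }
    }
    elapsed += std::chrono::duration<double>(std::chrono::steady_clock::now() -
                                             tic)
                   .count();

    // sanity scan: any Vm outside bounds signals numerical instability
    for (int i = 0; i < n; i++) {
      const double v = vm_at(i);
      if (!std::isfinite(v) || v < vm_lo || v > vm_hi) {
        instab_step = step0 + s + 1;
        instab_node = i;
        break;
      }
    }

    const double tn = t0 + (s + 1) * dt;
    trace(s + 1, 0) = tn;
    trace(s + 1, 1) = vm_at(probe_idx);
    completed = s + 1;
    if ((s + 1) % snap_stride == 0) record_snap((s + 1) / snap_stride, tn);
    if (instab_step >= 0) break;
  }

  if (aos)
    for (int i = 0; i < n; i++) {
      vm[i] = cells[i].vm;
      m[i] = cells[i].m;
      h[i] = cells[i].h;
      j[i] = cells[i].j;
      d[i] = cells[i].d;
      f[i] = cells[i].f;
      x1[i] = cells[i].x1;
      cai[i] = cells[i].cai;
    }

  return List::create(
      _["vm"] = wrap(vm), _["m"] = wrap(m), _["h"] = wrap(h),
      _["j"] = wrap(j), _["d"] = wrap(d), _["f"] = wrap(f),
      _["x1"] = wrap(x1), _["cai"] = wrap(cai),
      _["time"] = t0 + completed * dt, _["step"] = step0 + completed,
      _["completed"] = completed, _["trace"] = trace, _["snaps"] = snaps,
      _["snap_times"] = snap_times, _["excited"] = excited,
      _["nsnap_done"] = nsnap_done, _["stim_resolved"] = stim,
      _["elapsed_s"] = elapsed,
      _["node_updates"] = (double)completed * (double)n,
      _["instab_step"] = instab_step, _["instab_node"] = instab_node);
}

// [[Rcpp::export]]
bool cpp_has_openmp() {
#ifdef _OPENMP
  return true;
#else
  return false;
#endif
}
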