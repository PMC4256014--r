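// Core integrator for the starburst-amacrine-cell reaction-diffusion model.
//
// State per lattice cell: v (membrane potential, mV), r (K+ gate / fast
// refractory fraction), s (sAHP activation), a (extracellular ACh, nM).
// Only a diffuses. Units: C in nF, conductances in nS, time in s, so
// nS*mV = pA and pA/nF = mV/s.
//
// Time stepping is Strang-split: half-step of locally one-dimensional
// Crank-Nicolson diffusion (x-then-y), full Heun (two-stage Runge-Kutta)
// reaction step, half-step of diffusion (y-then-x). Zero-flux boundaries.
// All randomness is drawn from R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// parameter vector layout (keep in sync with R/params.R)
enum {
  P_C = 0, P_EK, P_ECA, P_EL, P_EA,
  P_GL, P_GK, P_GCA, P_GA, P_GN,
  P_V1, P_V2, P_V3, P_V4, P_TAUW,
  P_SHALF, P_SSLOPE, P_TAUSACT, P_TAUSDEC, P_KAPPA,
  P_RELHALF, P_RELSLOPE, P_BETA, P_TAUA, P_AHALF, P_HILL,
  P_D, P_NRATE, P_NDT, P_LEN, P_NPAR
};

struct Kin {
  double C, eK, eCa, eL, eA, gL, gK, gCa, gA, gN;
  double v1, v2, v3, v4, tauW;
  double sHalf, sSlope, tauSact, tauSdec, kappa;
  double relHalf, relSlope, beta, tauA, aHalf, hill;
  explicit Kin(const NumericVector& p) {
    C = p[P_C]; eK = p[P_EK]; eCa = p[P_ECA]; eL = p[P_EL]; eA = p[P_EA];
    gL = p[P_GL]; gK = p[P_GK]; gCa = p[P_GCA]; gA = p[P_GA]; gN = p[P_GN];
    v1 = p[P_V1]; v2 = p[P_V2]; v3 = p[P_V3]; v4 = p[P_V4]; tauW = p[P_TAUW];
    sHalf = p[P_SHALF]; sSlope = p[P_SSLOPE];
    tauSact = p[P_TAUSACT]; tauSdec = p[P_TAUSDEC]; kappa = p[P_KAPPA];
    relHalf = p[P_RELHALF]; relSlope = p[P_RELSLOPE];
    beta = p[P_BETA]; tauA = p[P_TAUA]; aHalf = p[P_AHALF]; hill = p[P_HILL];
  }
  // lookup tables for the voltage sigmoids (used in the long-run integrator;
  // piecewise-linear on a 0.005 mV grid, interpolation error ~1e-9)
  bool useTab = false;
  static const int TABN = 60001;
  static constexpr double TABLO = -160.0, TABHI = 140.0;
  std::vector<double> tab;   // interleaved rows: minf, winf, lamw, sinf, 1/taus, rel

  inline double minf(double v) const { return 0.5 * (1.0 + tanh((v - v1) / v2)); }
  inline double winf(double v) const { return 0.5 * (1.0 + tanh((v - v3) / v4)); }
  inline double lamw(double v) const { return cosh((v - v3) / (2.0 * v4)) / tauW; }
  inline double sinf(double v) const { return 0.5 * (1.0 + tanh((v - sHalf) / sSlope)); }
  inline double taus(double v) const {
    double si = sinf(v);
    return tauSdec + (tauSact - tauSdec) * si;
  }
  inline double rel(double v) const { return 0.5 * (1.0 + tanh((v - relHalf) / relSlope)); }
  inline double achg(double a) const {
    if (a <= 0.0) return 0.0;
    if (hill == 2.0) { double a2 = a * a; return a2 / (a2 + aHalf * aHalf); }
    double an = pow(a, hill);
    return an / (an + pow(aHalf, hill));
  }
  void initTables() {
    const double h = (TABHI - TABLO) / (TABN - 1);
    tab.resize(6 * TABN);
    for (int i = 0; i < TABN; ++i) {
      double v = TABLO + h * i;
      tab[6 * i] = minf(v); tab[6 * i + 1] = winf(v);
      tab[6 * i + 2] = lamw(v); tab[6 * i + 3] = sinf(v);
      tab[6 * i + 4] = 1.0 / taus(v); tab[6 * i + 5] = rel(v);
    }
    useTab = true;
  }
  inline void look6(double v, double* out) const {
    double x = (v - TABLO) * ((TABN - 1) / (TABHI - TABLO));
    if (x <= 0.0) x = 0.0;
    if (x >= TABN - 1) x = TABN - 1 - 1e-9;
    int i = (int)x;
    double w = x - i;
    const double* lo = &tab[6 * i];
    for (int k = 0; k < 6; ++k) out[k] = lo[k] + w * (lo[k + 6] - lo[k]);
  }
  // local kinetics; gx = extra excitatory conductance (noise channel), iext in pA
  inline void rhs(double v, double r, double s, double a,
                  double gx, double iext,
                  double& dv, double& dr, double& ds, double& da) const {
    double mi, wi, lw, si, its, rl;
    if (useTab) {
      double q[6];
      look6(v, q);
      mi = q[0]; wi = q[1]; lw = q[2]; si = q[3]; its = q[4]; rl = q[5];
    } else {
      mi = minf(v); wi = winf(v); lw = lamw(v);
      si = sinf(v); its = 1.0 / taus(v); rl = rel(v);
    }
    double iion = -gL * (v - eL) - gK * r * (v - eK) - gCa * mi * (v - eCa)
                  - (gA * achg(a) + gx) * (v - eA) + iext;
    dv = iion / C;
    dr = lw * (wi + kappa * s - r);
    ds = (si - s) * its;
    da = beta * rl - a / tauA;
  }
};

// Thomas solve for (I - mu * Lap1d) x = d with zero-flux Laplacian, in place.
// Lap1d: (x[i-1] - 2x[i] + x[i+1]), ends reflect (single flux).
static void cn_solve_line(double* d, int n, double mu,
                          std::vector<double>& cp, std::vector<double>& dp) {
  // coefficients: interior: -mu, 1+2mu, -mu ; ends: 1+mu, -mu
  double b0 = 1.0 + mu, bi = 1.0 + 2.0 * mu, a = -mu;
  cp[0] = a / b0;
  dp[0] = d[0] / b0;
  for (int i = 1; i < n - 1; ++i) {
    double m = bi - a * cp[i - 1];
    cp[i] = a / m;
    dp[i] = (d[i] - a * dp[i - 1]) / m;
  }
  double m = b0 - a * cp[n - 2];
  dp[n - 1] = (d[n - 1] - a * dp[n - 2]) / m;
  d[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = dp[i] - cp[i] * d[i + 1];
}

// one Crank-Nicolson sweep along x (stride 1) or y (stride nx) for all lines
static void cn_sweep(std::vector<double>& a, int nx, int ny, double mu, bool alongX,
                     std::vector<double>& line, std::vector<double>& cp,
                     std::vector<double>& dp) {
  int n = alongX ? nx : ny;
  int nlines = alongX ? ny : nx;
  if (n < 2) return;
  for (int l = 0; l < nlines; ++l) {
    // gather rhs: (I + mu * Lap) a
    for (int i = 0; i < n; ++i) {
      int idx = alongX ? (l * nx + i) : (i * nx + l);
      double c = a[idx];
      double left = (i > 0) ? a[alongX ? (l * nx + i - 1) : ((i - 1) * nx + l)] : c;
      double right = (i < n - 1) ? a[alongX ? (l * nx + i + 1) : ((i + 1) * nx + l)] : c;
      line[i] = c + mu * (left - 2.0 * c + right);
    }
    cn_solve_line(line.data(), n, mu, cp, dp);
    for (int i = 0; i < n; ++i) {
      int idx = alongX ? (l * nx + i) : (i * nx + l);
      a[idx] = line[i];
    }
  }
}

// diffusion over dt via LOD Crank-Nicolson; order: x-then-y if xFirst
static void diffuse(std::vector<double>& a, int nx, int ny, double D, double dt,
                    double dx, bool xFirst,
                    std::vector<double>& line, std::vector<double>& cp,
                    std::vector<double>& dp) {
  if (D <= 0.0) return;
  double mu = 0.5 * D * dt / (dx * dx);
  if (xFirst) {
    cn_sweep(a, nx, ny, mu, true, line, cp, dp);
    if (ny > 1) cn_sweep(a, nx, ny, mu, false, line, cp, dp);
  } else {
    if (ny > 1) cn_sweep(a, nx, ny, mu, false, line, cp, dp);
    cn_sweep(a, nx, ny, mu, true, line, cp, dp);
  }
}

// [[Rcpp::export]]
NumericVector cpp_step_diffusion(NumericVector afield, int nx, int ny,
                                 double D, double dt, double dx) {
  std::vector<double> a(afield.begin(), afield.end());
  std::vector<double> line(std::max(nx, ny)), cp(std::max(nx, ny)), dp(std::max(nx, ny));
  diffuse(a, nx, ny, D, 0.5 * dt, dx, true, line, cp, dp);
  diffuse(a, nx, ny, D, 0.5 * dt, dx, false, line, cp, dp);
  return NumericVector(a.begin(), a.end());
}

// [[Rcpp::export]]
List cpp_step_reaction(NumericVector p, NumericVector v, NumericVector r,
                       NumericVector s, NumericVector a, double dt,
                       NumericVector gx, NumericVector iext, bool freezeS) {
  Kin k(p);
  int n = v.size();
  NumericVector vo(n), ro(n), so(n), ao(n);
  for (int i = 0; i < n; ++i) {
    double dv1, dr1, ds1, da1, dv2, dr2, ds2, da2;
    k.rhs(v[i], r[i], s[i], a[i], gx[i], iext[i], dv1, dr1, ds1, da1);
    if (freezeS) ds1 = 0.0;
    double vp = v[i] + dt * dv1, rp = r[i] + dt * dr1;
    double sp = s[i] + dt * ds1, ap = a[i] + dt * da1;
    k.rhs(vp, rp, sp, ap, gx[i], iext[i], dv2, dr2, ds2, da2);
    if (freezeS) ds2 = 0.0;
    vo[i] = v[i] + 0.5 * dt * (dv1 + dv2);
    ro[i] = r[i] + 0.5 * dt * (dr1 + dr2);
    so[i] = s[i] + 0.5 * dt * (ds1 + ds2);
    ao[i] = a[i] + 0.5 * dt * (da1 + da2);
    if (ao[i] < 0.0) ao[i] = 0.0;
  }
  return List::create(_["v"] = vo, _["r"] = ro, _["s"] = so, _["a"] = ao);
}

// Full grid run. recordMode: 0 = full fields at snapdt, 1 = activity mask at
// snapdt plus full fields at coarsedt, 2 = final state only.
// stim rows: (start_s, end_s, amplitude_pA, cell_index_0based).
// [[Rcpp::export]]
List cpp_run_grid(NumericVector p, int nx, int ny, double dt, double duration,
                  double warmup, double snapdt, bool noiseOn, double actThreshold,
                  int recordMode, double coarsedt,
                  NumericVector v0, NumericVector r0, NumericVector s0,
                  NumericVector a0, NumericMatrix stim, bool freezeS,
                  bool collectEvents, double eventThreshold,
                  double selfDrain = 0.0) {
  Kin k(p);
  k.initTables();
  const int ncell = nx * ny;
  const double D = p[P_D], len = p[P_LEN];
  const double dx = len / nx;  // lattice spacing, mm
  const double nDt = p[P_NDT];
  const double pOpen = p[P_NRATE] * nDt;
  if (noiseOn && (pOpen < 0.0 || pOpen > 1.0))
    stop("noise open probability per update outside [0,1]");

  std::vector<double> v(v0.begin(), v0.end()), r(r0.begin(), r0.end());
  std::vector<double> s(s0.begin(), s0.end()), a(a0.begin(), a0.end());
  if ((int)v.size() != ncell) stop("initial state length != nx*ny");
  std::vector<double> gx(ncell, 0.0), ie(ncell, 0.0);
  std::vector<int> mask(ncell, 0);
  std::vector<double> line(std::max(nx, ny)), cp(std::max(nx, ny)), dp(std::max(nx, ny));

  const long nsteps = (long)std::llround((warmup + duration) / dt);
  const long wsteps = (long)std::llround(warmup / dt);
  const long snapEvery = std::max(1L, (long)std::llround(snapdt / dt));
  const long coarseEvery = std::max(1L, (long)std::llround(coarsedt / dt));
  const long noiseEvery = std::max(1L, (long)std::llround(nDt / dt));

  const long nsnap = (nsteps - wsteps) / snapEvery + 1;
  const long ncoarse = (nsteps - wsteps) / coarseEvery + 1;

  NumericVector snapTimes, coarseTimes;
  NumericVector fv, fr, fs, fa;       // full fields (mode 0)
  RawVector act;                      // activity mask (mode 1)
  NumericVector cv, cr, cs, ca;       // coarse fields (mode 1)
  if (recordMode == 0) {
    fv = NumericVector((R_xlen_t)ncell * nsnap);
    fr = NumericVector((R_xlen_t)ncell * nsnap);
    fs = NumericVector((R_xlen_t)ncell * nsnap);
    fa = NumericVector((R_xlen_t)ncell * nsnap);
    snapTimes = NumericVector(nsnap);
  } else if (recordMode == 1) {
    act = RawVector((R_xlen_t)ncell * nsnap);
    snapTimes = NumericVector(nsnap);
    cv = NumericVector((R_xlen_t)ncell * ncoarse);
    cr = NumericVector((R_xlen_t)ncell * ncoarse);
    cs = NumericVector((R_xlen_t)ncell * ncoarse);
    ca = NumericVector((R_xlen_t)ncell * ncoarse);
    coarseTimes = NumericVector(ncoarse);
  }
  std::vector<double> evTime;
  std::vector<int> evCell;
  std::vector<double> vprev;
  if (collectEvents) vprev = v;

  const int nstim = stim.nrow();
  long isnap = 0, icoarse = 0;

  // record initial post-warmup state lazily below (step == wsteps)
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    // record
    if (step >= wsteps && recordMode != 2) {
      long rel = step - wsteps;
      if (rel % snapEvery == 0) {
        if (recordMode == 0) {
          R_xlen_t off = (R_xlen_t)isnap * ncell;
          for (int i = 0; i < ncell; ++i) {
            fv[off + i] = v[i]; fr[off + i] = r[i];
            fs[off + i] = s[i]; fa[off + i] = a[i];
          }
        } else {
          R_xlen_t off = (R_xlen_t)isnap * ncell;
          for (int i = 0; i < ncell; ++i)
            act[off + i] = (Rbyte)(v[i] > actThreshold ? 1 : 0);
        }
        snapTimes[isnap++] = t - warmup;
      }
      if (recordMode == 1 && rel % coarseEvery == 0) {
        R_xlen_t off = (R_xlen_t)icoarse * ncell;
        for (int i = 0; i < ncell; ++i) {
          cv[off + i] = v[i]; cr[off + i] = r[i];
          cs[off + i] = s[i]; ca[off + i] = a[i];
        }
        coarseTimes[icoarse++] = t - warmup;
      }
    }
    if (step == nsteps) break;

    // noise update at interval boundaries
    if (noiseOn && step % noiseEvery == 0) {
      for (int i = 0; i < ncell; ++i) {
        mask[i] = (unif_rand() < pOpen) ? 1 : 0;
        gx[i] = mask[i] ? k.gN : 0.0;
      }
    }
    // stimulation currents
    if (nstim > 0) {
      std::fill(ie.begin(), ie.end(), 0.0);
      for (int q = 0; q < nstim; ++q) {
        if (t >= stim(q, 0) && t < stim(q, 1)) {
          int ci = (int)stim(q, 3);
          if (ci >= 0 && ci < ncell) ie[ci] += stim(q, 2);
        }
      }
    }

    // Strang: diffusion half (x,y) -> reaction -> diffusion half (y,x)
    diffuse(a, nx, ny, D, 0.5 * dt, dx, true, line, cp, dp);
    for (int i = 0; i < ncell; ++i) {
      double dv1, dr1, ds1, da1, dv2, dr2, ds2, da2;
      k.rhs(v[i], r[i], s[i], a[i], gx[i], ie[i], dv1, dr1, ds1, da1);
      if (freezeS) ds1 = 0.0;
      da1 -= selfDrain * a[i];
      double vp = v[i] + dt * dv1, rp = r[i] + dt * dr1;
      double sp = s[i] + dt * ds1, ap = a[i] + dt * da1;
      k.rhs(vp, rp, sp, ap, gx[i], ie[i], dv2, dr2, ds2, da2);
      if (freezeS) ds2 = 0.0;
      da2 -= selfDrain * ap;
      v[i] += 0.5 * dt * (dv1 + dv2);
      r[i] += 0.5 * dt * (dr1 + dr2);
      if (!freezeS) s[i] += 0.5 * dt * (ds1 + ds2);
      a[i] += 0.5 * dt * (da1 + da2);
      if (a[i] < 0.0) a[i] = 0.0;
    }
    diffuse(a, nx, ny, D, 0.5 * dt, dx, false, line, cp, dp);

    if (!std::isfinite(v[0]))
      stop("numerical blow-up at t = %f s (step %ld)", t, step);

    if (collectEvents) {
      for (int i = 0; i < ncell; ++i) {
        if (vprev[i] <= eventThreshold && v[i] > eventThreshold) {
          evTime.push_back(t + dt - warmup);
          evCell.push_back(i + 1);
        }
        vprev[i] = v[i];
      }
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["finalV"] = NumericVector(v.begin(), v.end()),
    _["finalR"] = NumericVector(r.begin(), r.end()),
    _["finalS"] = NumericVector(s.begin(), s.end()),
    _["finalA"] = NumericVector(a.begin(), a.end()));
  if (recordMode == 0) {
    out["times"] = snapTimes; out["v"] = fv; out["r"] = fr;
    out["s"] = fs; out["a"] = fa;
  } else if (recordMode == 1) {
    out["times"] = snapTimes; out["activity"] = act;
    out["coarseTimes"] = coarseTimes;
    out["v"] = cv; out["r"] = cr; out["s"] = cs; out["a"] = ca;
  }
  if (collectEvents) {
    out["eventTimes"] = NumericVector(evTime.begin(), evTime.end());
    out["eventCells"] = IntegerVector(evCell.begin(), evCell.end());
  }
  return out;
}
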