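// Fixed-step RK4 method-of-steps engine for delay differential equations,
// with cubic Hermite interpolation of the stored solution for delayed
// lookups, plus batch drivers for basin-stability sampling, transverse
// Lyapunov exponents (master stability function) and delay-coupled
// network synchronization checks.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double kPi = 3.141592653589793238462643383279502884;

// ---------------------------------------------------------------------------
// Basis families. fam: 1 trigonometric on [-pi,pi], 2 Legendre on [-1,1]
// (both normalized to unit L2 norm), 3 Bernstein of degree n-1 on [0,1].
// Trigonometric ordering: constant, then cos/sin pairs of increasing k.
static void basis_eval_raw(int fam, int n, double th, double* e) {
  if (fam == 1) {
    e[0] = 1.0 / std::sqrt(2.0 * kPi);
    int i = 1, k = 1;
    const double c = 1.0 / std::sqrt(kPi);
    while (i < n) {
      e[i++] = std::cos(k * th) * c;
      if (i < n) e[i++] = std::sin(k * th) * c;
      ++k;
    }
  } else if (fam == 2) {
    double Pprev = 1.0, Pcur = th;
    for (int k = 0; k < n; ++k) {
      double P;
      if (k == 0) P = 1.0;
      else if (k == 1) P = th;
      else {
        P = ((2.0 * k - 1.0) * th * Pcur - (k - 1.0) * Pprev) / k;
        Pprev = Pcur; Pcur = P;
      }
      e[k] = std::sqrt((2.0 * k + 1.0) / 2.0) * P;
    }
  } else {
    // Bernstein B_{i,m}, m = n - 1; partition of unity, not orthogonal
    int m = n - 1;
    double s = 1.0 - th;
    // binomial coefficients C(m, i) built incrementally
    double binom = 1.0;
    for (int i = 0; i <= m; ++i) {
      e[i] = binom * std::pow(th, i) * std::pow(s, m - i);
      binom = binom * (m - i) / (i + 1.0);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_basis_matrix(int fam, int n, NumericVector theta) {
  NumericMatrix out(theta.size(), n);
  std::vector<double> e(n);
  for (R_xlen_t r = 0; r < theta.size(); ++r) {
    basis_eval_raw(fam, n, theta[r], e.data());
    for (int j = 0; j < n; ++j) out(r, j) = e[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// History function: constant vector, basis expansion (optionally around a
// constant offset), or an R function of t.
struct History {
  int type = 0;           // 0 const, 1 basis, 2 R function
  int s = 1;
  const double* cvec = nullptr;     // type 0
  int fam = 1, n = 1;
  const double* coef = nullptr;     // type 1: s x n column-major
  const double* offset = nullptr;   // type 1: optional constant added
  double tau = 1.0;                 // domain [-tau, 0]
  double dlo = -kPi, dhi = kPi;     // natural domain of the basis
  Function* rf = nullptr;           // type 2
  std::vector<double> ebuf;

  void prepare() { if (type == 1) ebuf.resize(n); }

  void eval(double t, double* out) {
    if (t < -tau) t = -tau;
    if (t > 0.0) t = 0.0;
    if (type == 0) {
      for (int j = 0; j < s; ++j) out[j] = cvec[j];
      return;
    }
    if (type == 1) {
      double th = (tau > 0.0) ? dlo + (t + tau) * (dhi - dlo) / tau : dhi;
      basis_eval_raw(fam, n, th, ebuf.data());
      for (int j = 0; j < s; ++j) {
        double v = offset ? offset[j] : 0.0;
        for (int i = 0; i < n; ++i) v += coef[j + (size_t)i * s] * ebuf[i];
        out[j] = v;
      }
      return;
    }
    NumericVector v = (*rf)(t);
    for (int j = 0; j < s; ++j) out[j] = v[j];
  }
};

static void set_domain(History& h) {
  if (h.fam == 1)      { h.dlo = -kPi; h.dhi = kPi; }
  else if (h.fam == 2) { h.dlo = -1.0; h.dhi = 1.0; }
  else                 { h.dlo = 0.0;  h.dhi = 1.0; }
}

// ---------------------------------------------------------------------------
// Built-in right-hand sides. Model ids:
//   0 R function rhs(t, x, xlag_matrix)
//   1 hopfield: pars (a, b, a12, a21, I1, I2); delays (tau_s, tau12, tau21)
//   2 rossler:  pars (a, b, c); no delay
//   3 bistable scalar: x' = x(t - tau) - x^3
//   4 linear scalar:   x' = -x(t - tau) + d; pars (d)
//   5 shifted double well (ODE): x' = (x - m) - (x - m)^3; pars (m)
//   6 rossler + transverse variation: pars (a, b, c, eps); one delay tau
//   7 linear msf: xi' = -xi - eps xi(t - tau); pars (eps)
//   8 rossler network: pars (a, b, c, sigma); Laplacian lap (N x N),
//     x -> x delayed diffusive coupling; state node-major (x_i, y_i, z_i)
struct Sys {
  int id = 0, s = 1, nd = 0, N = 0;
  const double* p = nullptr;
  const double* lap = nullptr;
  Function* rfun = nullptr;
  // optional CSR view of the Laplacian (network model)
  std::vector<int> row_ptr, col_idx;
  std::vector<double> nz_val;

  void build_sparse() {
    row_ptr.assign(N + 1, 0);
    col_idx.clear(); nz_val.clear();
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        double v = lap[i + (size_t)j * N];
        if (v != 0.0) { col_idx.push_back(j); nz_val.push_back(v); }
      }
      row_ptr[i + 1] = (int)col_idx.size();
    }
  }

  void rhs(double t, const double* x, const double* const* xl, double* out) {
    switch (id) {
    case 1: {
      double a = p[0], b = p[1], a12 = p[2], a21 = p[3], I1 = p[4], I2 = p[5];
      out[0] = -b * x[0] + a * std::tanh(xl[0][0]) + a12 * std::tanh(xl[1][1]) + I1;
      out[1] = -b * x[1] + a * std::tanh(xl[0][1]) + a21 * std::tanh(xl[2][0]) + I2;
      break; }
    case 2: {
      double a = p[0], b = p[1], c = p[2];
      out[0] = -x[1] - x[2];
      out[1] = x[0] + a * x[1];
      out[2] = b + x[2] * (x[0] - c);
      break; }
    case 3:
      out[0] = xl[0][0] - x[0] * x[0] * x[0];
      break;
    case 4:
      out[0] = -xl[0][0] + p[0];
      break;
    case 5: {
      double u = x[0] - p[0];
      out[0] = u - u * u * u;
      break; }
    case 6: {
      // pars: a, b, c, ci (instantaneous), cl (delayed), cs (orbit feedback),
      //       comp (0/1/2: E = projector on that component; 3: E = identity)
      // xi' = DF(s) xi - ci E xi(t) - cl E xi(t-tau)
      // s'  = F(s) + cs E [s(t-tau) - s(t)]
      double a = p[0], b = p[1], c = p[2], ci = p[3], cl = p[4], cs = p[5];
      int comp = (int)p[6];
      out[0] = -x[1] - x[2];
      out[1] = x[0] + a * x[1];
      out[2] = b + x[2] * (x[0] - c);
      out[3] = -x[4] - x[5];
      out[4] = x[3] + a * x[4];
      out[5] = x[2] * x[3] + (x[0] - c) * x[5];
      for (int j = 0; j < 3; ++j) {
        if (comp == j || comp == 3) {
          out[j] += cs * (xl[0][j] - x[j]);
          out[3 + j] += -ci * x[3 + j] - cl * xl[0][3 + j];
        }
      }
      break; }
    case 7:
      out[0] = -x[0] - p[0] * xl[0][0];
      break;
    case 8: {
      double a = p[0], b = p[1], c = p[2], sig = p[3];
      const double* xd = xl[0];
      for (int i = 0; i < N; ++i) {
        const double* xi = x + 3 * i;
        double* oi = out + 3 * i;
        double cp = 0.0;
        if (!row_ptr.empty()) {
          for (int q = row_ptr[i]; q < row_ptr[i + 1]; ++q)
            cp += nz_val[q] * xd[3 * col_idx[q]];
        } else {
          for (int j = 0; j < N; ++j) cp += lap[i + (size_t)j * N] * xd[3 * j];
        }
        oi[0] = -xi[1] - xi[2] - sig * cp;
        oi[1] = xi[0] + a * xi[1];
        oi[2] = b + xi[2] * (xi[0] - c);
      }
      break; }
    default: {
      NumericVector xx(s);
      for (int j = 0; j < s; ++j) xx[j] = x[j];
      NumericMatrix xlm(s, std::max(nd, 1));
      for (int d = 0; d < nd; ++d)
        for (int j = 0; j < s; ++j) xlm(j, d) = xl[d][j];
      NumericVector v = (*rfun)(t, xx, xlm);
      for (int j = 0; j < s; ++j) out[j] = v[j];
    }
    }
  }
};

// ---------------------------------------------------------------------------
// RK4 method-of-steps engine. Solution stored at the full uniform grid
// (state X and derivative F, time-major) so delayed lookups use cubic
// Hermite interpolation; requires dt <= min positive delay so all stage
// lookups lie in the completed past.
struct Engine {
  Sys* sys;
  History* hist;
  int s, nd, K;
  double dt, div_bound;
  std::vector<double> delays;
  std::vector<double> X, F;                  // (K+1) * s
  std::vector<double> lagbuf, k1, k2, k3, k4, xs;
  std::vector<const double*> xlp;
  int last = 0;
  bool diverged = false;

  void setup(Sys* sy, History* h, const std::vector<double>& del,
             double dt_, int K_, double bound) {
    sys = sy; hist = h; s = sy->s; nd = (int)del.size();
    delays = del; dt = dt_; K = K_; div_bound = bound;
    X.assign((size_t)(K + 1) * s, 0.0);
    F.assign((size_t)(K + 1) * s, 0.0);
    lagbuf.assign((size_t)std::max(nd, 1) * s, 0.0);
    k1.assign(s, 0.0); k2.assign(s, 0.0); k3.assign(s, 0.0); k4.assign(s, 0.0);
    xs.assign(s, 0.0);
    xlp.assign(std::max(nd, 1), nullptr);
  }

  void reset() {
    last = 0; diverged = false;
    hist->eval(0.0, &X[0]);
  }

  // value of the solution (or history) at tq <= current time
  void lag_at(double tq, double* out) {
    if (tq <= 0.0) { hist->eval(tq, out); return; }
    double u = tq / dt;
    double ru = std::floor(u + 0.5);
    if (std::fabs(u - ru) < 1e-9) {   // on-grid query
      int k = (int)ru;
      if (k > last) k = last;
      const double* xk = &X[(size_t)k * s];
      for (int j = 0; j < s; ++j) out[j] = xk[j];
      return;
    }
    int k = (int)std::floor(u);
    if (k > last - 1) k = last - 1;
    if (k < 0) k = 0;
    double a = u - k;
    double a2 = a * a, a3 = a2 * a;
    double h00 = 2 * a3 - 3 * a2 + 1, h10 = a3 - 2 * a2 + a;
    double h01 = -2 * a3 + 3 * a2,    h11 = a3 - a2;
    const double* x0 = &X[(size_t)k * s];
    const double* x1 = &X[(size_t)(k + 1) * s];
    const double* f0 = &F[(size_t)k * s];
    const double* f1 = &F[(size_t)(k + 1) * s];
    for (int j = 0; j < s; ++j)
      out[j] = h00 * x0[j] + h10 * dt * f0[j] + h01 * x1[j] + h11 * dt * f1[j];
  }

  void eval_stage(double ts, const double* xst, double* kout) {
    for (int d = 0; d < nd; ++d) {
      if (delays[d] == 0.0) {
        xlp[d] = xst;
      } else {
        lag_at(ts - delays[d], &lagbuf[(size_t)d * s]);
        xlp[d] = &lagbuf[(size_t)d * s];
      }
    }
    sys->rhs(ts, xst, xlp.data(), kout);
  }

  // one RK4 step from index `last`; returns false on divergence
  bool step() {
    double t = last * dt;
    const double* x = &X[(size_t)last * s];
    eval_stage(t, x, k1.data());
    std::copy(k1.begin(), k1.end(), F.begin() + (size_t)last * s);
    for (int j = 0; j < s; ++j) xs[j] = x[j] + 0.5 * dt * k1[j];
    eval_stage(t + 0.5 * dt, xs.data(), k2.data());
    for (int j = 0; j < s; ++j) xs[j] = x[j] + 0.5 * dt * k2[j];
    eval_stage(t + 0.5 * dt, xs.data(), k3.data());
    for (int j = 0; j < s; ++j) xs[j] = x[j] + dt * k3[j];
    eval_stage(t + dt, xs.data(), k4.data());
    double* xn = &X[(size_t)(last + 1) * s];
    bool ok = true;
    for (int j = 0; j < s; ++j) {
      xn[j] = x[j] + dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
      if (!std::isfinite(xn[j]) || std::fabs(xn[j]) > div_bound) ok = false;
    }
    ++last;
    if (!ok) diverged = true;
    return ok;
  }

  void finish_derivative() {
    // derivative at the final stored point, for Hermite queries near t_end
    double t = last * dt;
    eval_stage(t, &X[(size_t)last * s], k1.data());
    std::copy(k1.begin(), k1.end(), F.begin() + (size_t)last * s);
  }
};

static std::vector<double> as_std(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

static Sys make_sys(int model, const NumericVector& pars,
                    const NumericMatrix& lap, int s, int nd,
                    Function* rfun) {
  Sys sy;
  sy.id = model; sy.s = s; sy.nd = nd;
  sy.p = pars.size() ? &pars[0] : nullptr;
  if (lap.nrow() > 0) { sy.lap = &lap[0]; sy.N = lap.nrow(); }
  sy.rfun = rfun;
  return sy;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_integrate(int model, NumericVector pars, NumericMatrix lap,
                   int s, NumericVector delays,
                   int hist_type, NumericVector hist_const,
                   int hist_fam, NumericMatrix hist_coef, double hist_tau,
                   SEXP hist_rfun, SEXP rhs_rfun,
                   double t_end, double dt, double div_bound,
                   int keep_every) {
  // hist_rfun / rhs_rfun are always R closures (the R wrapper passes a
  // dummy when unused), so construction is safe.
  History h;
  h.s = s; h.tau = hist_tau; h.type = hist_type;
  if (hist_type == 0) h.cvec = hist_const.size() ? &hist_const[0] : nullptr;
  if (hist_type == 1) {
    h.fam = hist_fam; h.n = hist_coef.ncol();
    h.coef = &hist_coef[0];
    if (hist_const.size() == s) h.offset = &hist_const[0];
    set_domain(h);
  }
  Function hfun(hist_rfun);
  if (hist_type == 2) h.rf = &hfun;
  h.prepare();

  Function rfun2(rhs_rfun);
  Sys sy = make_sys(model, pars, lap, s, delays.size(),
                    model == 0 ? &rfun2 : nullptr);

  int K = (int)std::lround(t_end / dt);
  Engine eng;
  std::vector<double> del = as_std(delays);
  eng.setup(&sy, &h, del, dt, K, div_bound);
  eng.reset();
  int done = 0;
  for (int k = 0; k < K; ++k) {
    if (!eng.step()) break;
    ++done;
  }
  if (!eng.diverged) eng.finish_derivative();
  int kept_last = eng.last;
  std::vector<int> keep;
  for (int k = 0; k < kept_last; k += keep_every) keep.push_back(k);
  keep.push_back(kept_last);  // always include the final point
  int nkeep = (int)keep.size();
  NumericVector tout(nkeep);
  NumericMatrix xout(nkeep, s), fout(nkeep, s);
  for (int i = 0; i < nkeep; ++i) {
    int k = keep[i];
    tout[i] = k * dt;
    for (int j = 0; j < s; ++j) {
      xout(i, j) = eng.X[(size_t)k * s + j];
      fout(i, j) = eng.F[(size_t)k * s + j];
    }
  }
  return List::create(_["t"] = tout, _["x"] = xout, _["f"] = fout,
                      _["diverged"] = eng.diverged,
                      _["t_last"] = kept_last * dt);
}

// ---------------------------------------------------------------------------
// Batch basin-stability sampling: integrate each history (one column of
// coef_all = vec of the s x n coefficient matrix), classify to the attractor
// whose sup-norm distance stays < delta throughout the final `window`
// time units; optional early exit once a trajectory has stayed within
// delta/2 of one attractor for a full window.
// [[Rcpp::export]]
List cpp_bs_batch(int model, NumericVector pars, NumericMatrix lap,
                  int s, NumericVector delays,
                  int fam, int n, NumericMatrix coef_all, double tau_span,
                  double t_end, double dt,
                  NumericMatrix attractors, double delta, double window,
                  bool early_exit, double div_bound) {
  int T = coef_all.ncol();
  int Ka = attractors.nrow();
  History h;
  h.type = 1; h.s = s; h.fam = fam; h.n = n; h.tau = tau_span;
  set_domain(h);
  h.prepare();
  Sys sy = make_sys(model, pars, lap, s, delays.size(), nullptr);
  int K = (int)std::lround(t_end / dt);
  Engine eng;
  std::vector<double> del = as_std(delays);
  eng.setup(&sy, &h, del, dt, K, div_bound);

  IntegerVector labels(T);
  LogicalVector diverged(T);
  std::vector<double> cnt(Ka), wmax(Ka);
  int wsteps = (int)std::lround(window / dt);

  for (int tIdx = 0; tIdx < T; ++tIdx) {
    h.coef = &coef_all[(size_t)tIdx * (size_t)s * n];
    eng.reset();
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(wmax.begin(), wmax.end(), 0.0);
    int label = 0;
    bool done = false;
    for (int k = 0; k < K && !done; ++k) {
      if (!eng.step()) break;
      const double* x = &eng.X[(size_t)eng.last * s];
      bool in_window = (eng.last >= K - wsteps);
      for (int a = 0; a < Ka; ++a) {
        double d = 0.0;
        for (int j = 0; j < s; ++j)
          d = std::max(d, std::fabs(x[j] - attractors(a, j)));
        if (in_window && d > wmax[a]) wmax[a] = d;
        if (early_exit) {
          if (d < 0.5 * delta) {
            cnt[a] += dt;
            if (cnt[a] >= window) { label = a + 1; done = true; }
          } else cnt[a] = 0.0;
        }
      }
    }
    if (eng.diverged) {
      labels[tIdx] = 0; diverged[tIdx] = true;
      continue;
    }
    if (!done) {
      int hits = 0;
      for (int a = 0; a < Ka; ++a)
        if (wmax[a] < delta) { ++hits; label = a + 1; }
      if (hits != 1) label = 0;
    }
    labels[tIdx] = label;
    diverged[tIdx] = false;
  }
  return List::create(_["label"] = labels, _["diverged"] = diverged);
}

// ---------------------------------------------------------------------------
// Largest transverse Lyapunov exponent of the delayed variational equation
// (master stability function), Benettin-style: the variational state --
// the whole discretized history segment -- is renormalized at fixed
// intervals and the log norms are averaged.  node: 2 = Rossler (pars a,b,c),
// 1 = linear scalar F(x) = -x.
// [[Rcpp::export]]
List cpp_msf_lyap(int node, NumericVector pars, double ci, double cl,
                  double cs, double tau, int comp,
                  double dt, double t_pre, double t_disc, double t_avg,
                  double renorm_dt, NumericVector s0, NumericVector xi0) {
  int sdim = (node == 2) ? 3 : 0;
  int vdim = (node == 2) ? 3 : 1;
  int s = sdim + vdim;

  // 1) bring the node onto its attractor (plain RK4 ODE run)
  std::vector<double> satt(std::max(sdim, 1), 0.0);
  if (node == 2) {
    NumericVector np(3); np[0] = pars[0]; np[1] = pars[1]; np[2] = pars[2];
    Sys nodesys = make_sys(2, np, NumericMatrix(0, 0), 3, 0, nullptr);
    History hc; hc.type = 0; hc.s = 3; hc.cvec = &s0[0]; hc.tau = 1.0;
    hc.prepare();
    int Kp = (int)std::lround(t_pre / dt);
    Engine pre;
    std::vector<double> nodel;
    pre.setup(&nodesys, &hc, nodel, dt, Kp, 1e9);
    pre.reset();
    for (int k = 0; k < Kp; ++k) if (!pre.step()) break;
    for (int j = 0; j < 3; ++j) satt[j] = pre.X[(size_t)pre.last * 3 + j];
    if (pre.diverged)
      return List::create(_["lambda"] = NA_REAL, _["ok"] = false);
  }

  // 2) joint run of node + transverse variation with delayed coupling
  NumericVector jp;
  int model;
  if (node == 2) {
    jp = NumericVector::create(pars[0], pars[1], pars[2], ci, cl, cs,
                               (double)comp);
    model = 6;
  } else {
    jp = NumericVector::create(cl);
    model = 7;
  }
  Sys sy = make_sys(model, jp, NumericMatrix(0, 0), s, 1, nullptr);
  std::vector<double> init(s);
  double nrm0 = 0.0;
  for (int j = 0; j < vdim; ++j) nrm0 += xi0[j] * xi0[j];
  nrm0 = std::sqrt(nrm0);
  for (int j = 0; j < sdim; ++j) init[j] = satt[j];
  for (int j = 0; j < vdim; ++j) init[sdim + j] = xi0[j] / nrm0;

  History h; h.type = 0; h.s = s; h.cvec = init.data();
  h.tau = (tau > 0 ? tau : dt);
  h.prepare();

  double t_total = t_disc + t_avg;
  int K = (int)std::lround(t_total / dt);
  Engine eng;
  std::vector<double> del(1, tau);
  eng.setup(&sy, &h, del, dt, K, 1e12);
  eng.reset();

  int rsteps = std::max(1, (int)std::lround(renorm_dt / dt));
  int Ltau = (int)std::ceil(tau / dt) + 2;
  double logsum = 0.0, t_acc = 0.0;
  std::vector<double> running;
  bool ok = true;
  for (int k = 0; k < K; ++k) {
    if (!eng.step()) { ok = false; break; }
    if (eng.last % rsteps == 0) {
      const double* x = &eng.X[(size_t)eng.last * s];
      double nrm = 0.0;
      for (int j = 0; j < vdim; ++j) nrm += x[sdim + j] * x[sdim + j];
      nrm = std::sqrt(nrm);
      if (!(nrm > 0.0) || !std::isfinite(nrm)) { ok = false; break; }
      double t_now = eng.last * dt;
      if (t_now > t_disc) {
        logsum += std::log(nrm);
        t_acc += rsteps * dt;
        running.push_back(logsum / t_acc);
      }
      // rescale the variational part of the stored history window
      int k0 = std::max(0, eng.last - Ltau);
      for (int kk = k0; kk <= eng.last; ++kk) {
        for (int j = 0; j < vdim; ++j) {
          eng.X[(size_t)kk * s + sdim + j] /= nrm;
          eng.F[(size_t)kk * s + sdim + j] /= nrm;
        }
      }
    }
  }
  double lambda = t_acc > 0 ? logsum / t_acc : NA_REAL;
  // fluctuation of the running estimate over its last half
  double fluct = NA_REAL;
  if (running.size() >= 4) {
    fluct = 0.0;
    for (size_t i = running.size() / 2; i < running.size(); ++i)
      fluct = std::max(fluct, std::fabs(running[i] - lambda));
  }
  return List::create(_["lambda"] = lambda, _["ok"] = ok,
                      _["fluct"] = fluct, _["t_avg"] = t_acc);
}

// ---------------------------------------------------------------------------
// Batch synchronization check for the delay-coupled Rossler network.
// Each sample's node histories are the synchronous constant s0 plus a
// basis-expanded perturbation (coef_all column = vec of (3N) x n matrix).
// Synchronized <=> max pairwise node distance (Euclidean, R^3) stays below
// delta_sync over the final win_frac fraction of the run.
// [[Rcpp::export]]
List cpp_network_bs(NumericMatrix lap, NumericVector pars, double sigma,
                    double tau, int fam, int n, NumericMatrix coef_all,
                    NumericVector s0rep, double t_end, double dt,
                    double win_frac, double delta_sync, double div_bound) {
  int N = lap.nrow();
  int s = 3 * N;
  int T = coef_all.ncol();
  NumericVector jp = NumericVector::create(pars[0], pars[1], pars[2], sigma);
  Sys sy = make_sys(8, jp, lap, s, 1, nullptr);
  sy.build_sparse();
  History h;
  h.type = 1; h.s = s; h.fam = fam; h.n = n; h.tau = tau;
  h.offset = &s0rep[0];
  set_domain(h);
  h.prepare();
  int K = (int)std::lround(t_end / dt);
  int kwin = (int)std::lround((1.0 - win_frac) * K);
  Engine eng;
  std::vector<double> del(1, tau);
  eng.setup(&sy, &h, del, dt, K, div_bound);

  LogicalVector sync(T), diverged(T);
  NumericVector maxdev(T);
  for (int tIdx = 0; tIdx < T; ++tIdx) {
    h.coef = &coef_all[(size_t)tIdx * (size_t)s * n];
    eng.reset();
    double wdev = 0.0;
    bool failed = false;
    for (int k = 0; k < K; ++k) {
      if (!eng.step()) break;
      if (eng.last >= kwin) {
        const double* x = &eng.X[(size_t)eng.last * s];
        double mx = 0.0;
        for (int i = 0; i < N && mx < div_bound; ++i) {
          for (int j = i + 1; j < N; ++j) {
            double d0 = x[3 * i] - x[3 * j];
            double d1 = x[3 * i + 1] - x[3 * j + 1];
            double d2 = x[3 * i + 2] - x[3 * j + 2];
            double d = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
            if (d > mx) mx = d;
          }
        }
        if (mx > wdev) wdev = mx;
        if (wdev >= delta_sync) { failed = true; break; }  // cannot sync now
      }
    }
    diverged[tIdx] = eng.diverged;
    maxdev[tIdx] = wdev;
    sync[tIdx] = !eng.diverged && !failed && eng.last == K && wdev < delta_sync;
  }
  return List::create(_["sync"] = sync, _["diverged"] = diverged,
                      _["max_dev"] = maxdev);
}
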