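// Compiled core for mpqtl: fixed-step RK4 integration of the coupled
// juvenile-phase Lotka-Volterra system, biphasic mean-curve evaluation,
// SAD(1) covariance construction, the two profile objectives (weighted
// least-squares curve fit given Sigma; SAD fit given curves), a classical
// Nelder-Mead simplex minimizer with configurable initial simplex size
// (small simplices make warm-started M-steps cheap), and a batched
// per-marker LR scan.
//
// Parameter order used throughout (one genotype, 12 values):
//   0 alpha_H  1 K_H1  2 beta_H_from_D  3 alpha_D  4 K_D1  5 beta_D_from_H
//   6 K_H2     7 p_H   8 q_H            9 K_D2    10 p_D  11 q_D
// Unconstrained scale: log for alpha/K entries, identity for beta/p/q.
// SAD order (5 values): phi_1, phi_2, gamma_1, gamma_2, rho
// Unconstrained scale: atanh for phi/rho, log for gamma.

#include <RcppArmadillo.h>

using namespace Rcpp;

static const double BIG = 1e10;

static inline bool is_log_par(int r) {
  return r == 0 || r == 1 || r == 3 || r == 4 || r == 6 || r == 9;
}

// [[Rcpp::export]]
arma::vec cpp_nge_untransform(const arma::vec& tpar) {
  arma::vec out(12);
  for (int r = 0; r < 12; ++r)
    // clamp the log-scale entries so positive parameters stay positive in
    // double precision even when the optimizer wanders far out
    out[r] = is_log_par(r)
      ? std::exp(std::min(std::max(tpar[r], -60.0), 60.0))
      : tpar[r];
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_nge_transform(const arma::vec& par) {
  arma::vec out(12);
  for (int r = 0; r < 12; ++r)
    out[r] = is_log_par(r) ? std::log(par[r]) : par[r];
  return out;
}

// ---------------------------------------------------------------------------
// Nelder-Mead simplex minimizer (reflection 1, expansion 2, contraction 1/2,
// shrink 1/2).  `init_step` scales the initial simplex about the start
// point; `maxit` caps function evaluations; convergence when the simplex
// function-value spread falls below reltol * (|f_best| + reltol).
// ---------------------------------------------------------------------------

typedef double (*objfn)(int, const double*, void*);

static int nelder_mead(int n, double* x, double* fmin, objfn fn, void* ex,
                       double init_step, double reltol, int maxit) {
  const int np = n + 1;
  std::vector<double> P((size_t)np * n), F(np);
  std::vector<double> cen(n), xr(n), xe(n), xc(n);
  for (int j = 0; j < n; ++j) P[j] = x[j];
  F[0] = fn(n, x, ex);
  int neval = 1;
  for (int i = 1; i < np; ++i) {
    double* Pi = &P[(size_t)i * n];
    for (int j = 0; j < n; ++j) Pi[j] = x[j];
    double h = init_step * std::max(std::fabs(x[i - 1]), 0.25);
    Pi[i - 1] += h;
    F[i] = fn(n, Pi, ex);
    ++neval;
  }
  while (neval < maxit) {
    // locate best, worst, second-worst
    int ib = 0, iw = 0, isw = 0;
    for (int i = 1; i < np; ++i) {
      if (F[i] < F[ib]) ib = i;
      if (F[i] > F[iw]) iw = i;
    }
    isw = (iw == 0) ? 1 : 0;
    for (int i = 0; i < np; ++i)
      if (i != iw && F[i] > F[isw]) isw = i;
    if (F[iw] - F[ib] <= reltol * (std::fabs(F[ib]) + reltol)) break;
    for (int j = 0; j < n; ++j) cen[j] = 0.0;
    for (int i = 0; i < np; ++i) {
      if (i == iw) continue;
      const double* Pi = &P[(size_t)i * n];
      for (int j = 0; j < n; ++j) cen[j] += Pi[j];
    }
    for (int j = 0; j < n; ++j) cen[j] /= n;
    double* Pw = &P[(size_t)iw * n];
    for (int j = 0; j < n; ++j) xr[j] = cen[j] + (cen[j] - Pw[j]);
    double fr = fn(n, xr.data(), ex); ++neval;
    if (fr < F[ib]) {
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - Pw[j]);
      double fe = fn(n, xe.data(), ex); ++neval;
      if (fe < fr) { std::copy(xe.begin(), xe.end(), Pw); F[iw] = fe; }
      else         { std::copy(xr.begin(), xr.end(), Pw); F[iw] = fr; }
    } else if (fr < F[isw]) {
      std::copy(xr.begin(), xr.end(), Pw); F[iw] = fr;
    } else {
      bool outside = fr < F[iw];
      for (int j = 0; j < n; ++j)
        xc[j] = outside ? cen[j] + 0.5 * (cen[j] - Pw[j])
                        : cen[j] - 0.5 * (cen[j] - Pw[j]);
      double fc = fn(n, xc.data(), ex); ++neval;
      if (fc < std::min(fr, F[iw])) {
        std::copy(xc.begin(), xc.end(), Pw); F[iw] = fc;
      } else {
        const double* Pb = &P[(size_t)ib * n];
        for (int i = 0; i < np; ++i) {
          if (i == ib) continue;
          double* Pi = &P[(size_t)i * n];
          for (int j = 0; j < n; ++j)
            Pi[j] = Pb[j] + 0.5 * (Pi[j] - Pb[j]);
          F[i] = fn(n, Pi, ex); ++neval;
        }
      }
    }
  }
  int ib = 0;
  for (int i = 1; i < np; ++i) if (F[i] < F[ib]) ib = i;
  const double* Pb = &P[(size_t)ib * n];
  for (int j = 0; j < n; ++j) x[j] = Pb[j];
  *fmin = F[ib];
  return neval;
}

// generic R objective hookup for testing the minimizer itself
struct RFunEx { Function* f; };
static double rfun_obj(int n, const double* par, void* ex_) {
  RFunEx* ex = static_cast<RFunEx*>(ex_);
  NumericVector x(par, par + n);
  return as<double>((*ex->f)(x));
}

// [[Rcpp::export]]
List cpp_nelder_mead(NumericVector par0, Function fn, double init_step,
                     double reltol, int maxit) {
  RFunEx ex{&fn};
  std::vector<double> x(par0.begin(), par0.end());
  double fmin = 0.0;
  int ne = nelder_mead((int)x.size(), x.data(), &fmin, rfun_obj, &ex,
                       init_step, reltol, maxit);
  return List::create(_["par"] = NumericVector(x.begin(), x.end()),
                      _["value"] = fmin, _["fncount"] = ne);
}

// right-hand side of the juvenile-phase coupled logistic (LV) system
static inline void lv_rhs(const double* s, double* ds, const double* p) {
  const double H = s[0], D = s[1];
  ds[0] = p[0] * (1.0 - H / p[1]) * H + p[0] * p[2] * H * D;
  ds[1] = p[3] * (1.0 - D / p[4]) * D + p[3] * p[5] * D * H;
}

// Classical RK4 from t = 0, state (h0, d0), fixed step `step`, sampled by
// linear interpolation at `times` (nondecreasing, >= 0).  Returns the time
// of failure if the state goes non-finite, otherwise -1.
static double lv_integrate(const double* p, double h0, double d0,
                           const double* times, int nt, double step,
                           double* H, double* D) {
  double t = 0.0, s[2] = {h0, d0};
  const double tmax = times[nt - 1];
  int k = 0;
  while (k < nt && times[k] <= t + 1e-12) { H[k] = s[0]; D[k] = s[1]; ++k; }
  double k1[2], k2[2], k3[2], k4[2], tmp[2], prev[2];
  while (t < tmax - 1e-12) {
    const double h = std::min(step, tmax - t);
    const double tprev = t;
    prev[0] = s[0]; prev[1] = s[1];
    lv_rhs(s, k1, p);
    tmp[0] = s[0] + 0.5 * h * k1[0]; tmp[1] = s[1] + 0.5 * h * k1[1];
    lv_rhs(tmp, k2, p);
    tmp[0] = s[0] + 0.5 * h * k2[0]; tmp[1] = s[1] + 0.5 * h * k2[1];
    lv_rhs(tmp, k3, p);
    tmp[0] = s[0] + h * k3[0]; tmp[1] = s[1] + h * k3[1];
    lv_rhs(tmp, k4, p);
    s[0] += h / 6.0 * (k1[0] + 2.0 * k2[0] + 2.0 * k3[0] + k4[0]);
    s[1] += h / 6.0 * (k1[1] + 2.0 * k2[1] + 2.0 * k3[1] + k4[1]);
    t += h;
    if (!std::isfinite(s[0]) || !std::isfinite(s[1])) return t;
    while (k < nt && times[k] <= t + 1e-12) {
      const double w = (times[k] - tprev) / (t - tprev);
      H[k] = prev[0] + w * (s[0] - prev[0]);
      D[k] = prev[1] + w * (s[1] - prev[1]);
      ++k;
    }
  }
  return -1.0;
}

// [[Rcpp::export]]
List cpp_solve_phase1(const arma::vec& par, const arma::vec& times,
                      double step, double h0, double d0) {
  const int nt = (int)times.n_elem;
  arma::vec H(nt), D(nt);
  double fail = lv_integrate(par.memptr(), h0, d0, times.memptr(), nt,
                             step, H.memptr(), D.memptr());
  return List::create(_["H1"] = H, _["D1"] = D, _["t_fail"] = fail);
}

// total mean vector (height years then diameter years)
static double nge_mu(const double* th, const double* times, int T,
                     double step, double eps, double* mu) {
  std::vector<double> H(T), D(T);
  double fail = lv_integrate(th, eps, eps, times, T, step, H.data(),
                             D.data());
  if (fail >= 0.0) return fail;
  for (int i = 0; i < T; ++i) {
    mu[i]     = H[i] + th[6] * std::exp(-std::exp(th[7]  - th[8]  * times[i]));
    mu[T + i] = D[i] + th[9] * std::exp(-std::exp(th[10] - th[11] * times[i]));
  }
  return -1.0;
}

// [[Rcpp::export]]
arma::vec cpp_nge_mu(const arma::vec& par, const arma::vec& times,
                     double step, double eps) {
  const int T = (int)times.n_elem;
  arma::vec mu(2 * T);
  double fail = nge_mu(par.memptr(), times.memptr(), T, step, eps,
                       mu.memptr());
  if (fail >= 0.0) mu.fill(arma::datum::nan);
  return mu;
}

// in-place forward substitution z = L^{-1} r for lower-triangular L
static inline void fsolve(const double* L, int d, double* r) {
  for (int i = 0; i < d; ++i) {
    double s = r[i];
    const double* Li = L + (size_t)i;   // column-major: L[i + d*j]
    for (int j = 0; j < i; ++j) s -= L[i + (size_t)d * j] * r[j];
    (void)Li;
    r[i] = s / L[i + (size_t)d * i];
  }
}

// ---------------------------------------------------------------------------
// curve-fit profile objective:
//   0.5 * sum_j w_j * (mu(theta_j) - ybar_j)' Sigma^-1 (mu(theta_j) - ybar_j)
// theta_j assembled from a flat unconstrained vector through an index matrix
// (12 x J, 0-based), so genotype-shared blocks are expressed by repeating
// indices.  L is the lower Cholesky factor of Sigma; when absent the
// identity weight is used (ordinary least squares).
// ---------------------------------------------------------------------------

struct CurveEx {
  const arma::imat* idx;
  const arma::mat*  ybar;
  const arma::vec*  w;
  const arma::mat*  L;     // nullptr => identity
  const arma::vec*  times;
  double step, eps;
  const arma::vec* lo;     // nullptr => unbounded (natural scale)
  const arma::vec* hi;
  std::vector<double> mu, r;  // scratch
};

static double curve_obj(int npar, const double* par, void* ex_) {
  (void)npar;
  CurveEx* ex = static_cast<CurveEx*>(ex_);
  const int J = (int)ex->ybar->n_cols, T2 = (int)ex->ybar->n_rows;
  const int T = T2 / 2;
  double th[12];
  double val = 0.0;
  for (int j = 0; j < J; ++j) {
    for (int r = 0; r < 12; ++r) {
      double v = par[(*ex->idx)(r, j)];
      if (is_log_par(r)) {
        if (v > 60.0) return BIG;  // exp() overflow guard
        th[r] = std::exp(v);
      } else {
        th[r] = v;
      }
      // generous biological box: keeps the search off the unidentified
      // ridges (asymptote/interaction tradeoffs) far outside the data
      if (ex->lo && (th[r] < (*ex->lo)[r] || th[r] > (*ex->hi)[r]))
        return BIG;
    }
    if (nge_mu(th, ex->times->memptr(), T, ex->step, ex->eps,
               ex->mu.data()) >= 0.0)
      return BIG;
    const double* yb = ex->ybar->colptr(j);
    for (int i = 0; i < T2; ++i) ex->r[i] = ex->mu[i] - yb[i];
    double q = 0.0;
    if (ex->L) {
      fsolve(ex->L->memptr(), T2, ex->r.data());
      for (int i = 0; i < T2; ++i) q += ex->r[i] * ex->r[i];
    } else {
      for (int i = 0; i < T2; ++i) q += ex->r[i] * ex->r[i];
    }
    val += 0.5 * (*ex->w)(j) * q;
  }
  return std::isfinite(val) ? val : BIG;
}

// [[Rcpp::export]]
double cpp_curve_objective(const arma::vec& tpar, const arma::imat& idx,
                           const arma::mat& ybar, const arma::vec& w,
                           Nullable<NumericMatrix> L_, const arma::vec& times,
                           double step, double eps) {
  arma::mat L;
  CurveEx ex{&idx, &ybar, &w, nullptr, &times, step, eps,
             nullptr, nullptr,
             std::vector<double>(ybar.n_rows),
             std::vector<double>(ybar.n_rows)};
  if (L_.isNotNull()) { L = as<arma::mat>(L_.get()); ex.L = &L; }
  return curve_obj((int)tpar.n_elem, tpar.memptr(), &ex);
}

// [[Rcpp::export]]
List cpp_fit_curves(const arma::vec& tpar0, const arma::imat& idx,
                    const arma::mat& ybar, const arma::vec& w,
                    Nullable<NumericMatrix> L_, const arma::vec& times,
                    double step, double eps, int maxit, double reltol,
                    double init_step = 0.1,
                    Nullable<NumericVector> lo_ = R_NilValue,
                    Nullable<NumericVector> hi_ = R_NilValue) {
  arma::mat L;
  arma::vec lo, hi;
  CurveEx ex{&idx, &ybar, &w, nullptr, &times, step, eps,
             nullptr, nullptr,
             std::vector<double>(ybar.n_rows),
             std::vector<double>(ybar.n_rows)};
  if (L_.isNotNull()) { L = as<arma::mat>(L_.get()); ex.L = &L; }
  if (lo_.isNotNull() && hi_.isNotNull()) {
    lo = as<arma::vec>(lo_.get());
    hi = as<arma::vec>(hi_.get());
    ex.lo = &lo; ex.hi = &hi;
  }
  const int n = (int)tpar0.n_elem;
  std::vector<double> x(tpar0.begin(), tpar0.end());
  double fmin = 0.0;
  int ne = nelder_mead(n, x.data(), &fmin, curve_obj, &ex, init_step,
                       reltol, maxit);
  return List::create(_["par"] = arma::vec(x.data(), n),
                      _["value"] = fmin, _["fncount"] = ne);
}

// ---------------------------------------------------------------------------
// SAD(1) covariance over the 2T grid (trait-1 rows first, time index 1..T):
//   Var_k(t)          = gamma_k^2 (1 - phi_k^{2t}) / (1 - phi_k^2)
//   Cov_k(t1, t2)     = phi_k^{t2 - t1} Var_k(t1),              t2 > t1
//   Cov(e1 t1, e2 t2) = (phi2^{t2-t1} - phi1^{t1} phi2^{t2})
//                        / (1 - phi1 phi2) * rho gamma1 gamma2,  t2 >= t1
// and the phi-swapped mirror for t1 > t2 (equivalently: the covariance of
// the generating process e_k(t) = phi_k e_k(t-1) + eps_k(t), e_k(0) = 0,
// Corr(eps_1(t), eps_2(t)) = rho, which these formulas reproduce exactly).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_sad_cov(double phi1, double phi2, double g1, double g2,
                      double rho, int T) {
  arma::vec pw1(T + 1), pw2(T + 1);
  pw1[0] = 1.0; pw2[0] = 1.0;
  for (int t = 1; t <= T; ++t) {
    pw1[t] = pw1[t - 1] * phi1;
    pw2[t] = pw2[t - 1] * phi2;
  }
  const double d1 = 1.0 - phi1 * phi1, d2 = 1.0 - phi2 * phi2;
  arma::vec v1(T), v2(T);
  for (int t = 1; t <= T; ++t) {
    v1[t - 1] = (phi1 == 0.0) ? g1 * g1
              : g1 * g1 * (1.0 - pw1[t] * pw1[t]) / d1;
    v2[t - 1] = (phi2 == 0.0) ? g2 * g2
              : g2 * g2 * (1.0 - pw2[t] * pw2[t]) / d2;
  }
  arma::mat S(2 * T, 2 * T);
  const double cxd = 1.0 - phi1 * phi2;
  const double cg = rho * g1 * g2;
  for (int i = 0; i < T; ++i) {
    for (int j = 0; j < T; ++j) {
      const int t1 = i + 1, t2 = j + 1;
      if (t2 >= t1) {
        S(i, j) = pw1[t2 - t1] * v1[t1 - 1];
        S(T + i, T + j) = pw2[t2 - t1] * v2[t1 - 1];
      } else {
        S(i, j) = pw1[t1 - t2] * v1[t2 - 1];
        S(T + i, T + j) = pw2[t1 - t2] * v2[t2 - 1];
      }
      double c;
      if (t2 >= t1) c = (pw2[t2 - t1] - pw1[t1] * pw2[t2]) / cxd * cg;
      else          c = (pw1[t1 - t2] - pw1[t1] * pw2[t2]) / cxd * cg;
      S(i, T + j) = c;
      S(T + j, i) = c;
    }
  }
  return S;
}

// negative Gaussian log-likelihood profile in the SAD parameters:
//   n/2 log|Sigma| + 1/2 tr(Sigma^-1 S) + n T log(2 pi)
// where S is the (responsibility-weighted) residual scatter matrix.
struct SadEx {
  const arma::mat* S;
  double n;
  int T;
};

static double sad_obj(int npar, const double* par, void* ex_) {
  (void)npar;
  SadEx* ex = static_cast<SadEx*>(ex_);
  const double phi1 = std::tanh(par[0]), phi2 = std::tanh(par[1]);
  if (par[2] > 60.0 || par[3] > 60.0) return BIG;
  const double g1 = std::exp(par[2]), g2 = std::exp(par[3]);
  const double rho = std::tanh(par[4]);
  arma::mat Sig = cpp_sad_cov(phi1, phi2, g1, g2, rho, ex->T);
  arma::mat L;
  if (!arma::chol(L, Sig, "lower")) return BIG;
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  arma::mat W, V;
  if (!arma::solve(W, arma::trimatl(L), *(ex->S),
                   arma::solve_opts::no_approx)) return BIG;
  if (!arma::solve(V, arma::trimatl(L), W.t(),
                   arma::solve_opts::no_approx)) return BIG;
  double tr = arma::trace(V);
  double val = 0.5 * ex->n * logdet + 0.5 * tr +
               ex->n * ex->T * std::log(2.0 * M_PI);
  return std::isfinite(val) ? val : BIG;
}

// [[Rcpp::export]]
double cpp_sad_objective(const arma::vec& tpar, const arma::mat& S,
                         double n, int T) {
  SadEx ex{&S, n, T};
  return sad_obj((int)tpar.n_elem, tpar.memptr(), &ex);
}

// [[Rcpp::export]]
List cpp_fit_sad(const arma::vec& tpar0, const arma::mat& S, double n,
                 int T, int maxit, double reltol, double init_step = 0.1) {
  SadEx ex{&S, n, T};
  const int np = (int)tpar0.n_elem;
  std::vector<double> x(tpar0.begin(), tpar0.end());
  double fmin = 0.0;
  int ne = nelder_mead(np, x.data(), &fmin, sad_obj, &ex, init_step,
                       reltol, maxit);
  return List::create(_["par"] = arma::vec(x.data(), np),
                      _["value"] = fmin, _["fncount"] = ne);
}

// ---------------------------------------------------------------------------
// batched per-marker LR scan with the covariance fixed at the null fit.
// With Sigma fixed and genotypes fully observed,
//   LR = B + 2 V0 - 2 sum_j V_j
// where B = sum_j n_j (ybar_j - ybar)' Sigma^-1 (ybar_j - ybar), V0 is the
// null weighted-LS curve objective 0.5 n q0, and V_j is genotype j's
// objective after a warm-started Nelder-Mead refinement from the null
// parameters; identical to the grouped alternative fit, minus the per-
// marker container overhead.  G: M x n integer codes (1..J; 0 = missing ->
// marker skipped here).  Returns NA for markers with < 2 classes or a
// class with < 2 members.
// ---------------------------------------------------------------------------

// Markers whose quick-pass LR exceeds `refine_above` are refitted with the
// larger `maxit_refine` budget, so detection decisions near a threshold
// use fully converged fits while clearly null markers stay cheap.
// [[Rcpp::export]]
arma::vec cpp_scan_lrs(const arma::mat& Y, const arma::imat& G,
                       const arma::mat& L, const arma::vec& tpar0,
                       double V0, const arma::vec& times, double step,
                       double eps, int maxit, double reltol,
                       double init_step = 0.02,
                       double refine_above = 1e300,
                       int maxit_refine = 2500,
                       Nullable<NumericVector> lo_ = R_NilValue,
                       Nullable<NumericVector> hi_ = R_NilValue) {
  const int n = (int)Y.n_rows, T2 = (int)Y.n_cols, M = (int)G.n_rows;
  arma::vec ybar = arma::mean(Y, 0).t();
  arma::imat idx1(12, 1);
  for (int r = 0; r < 12; ++r) idx1(r, 0) = r;
  arma::vec out(M);
  out.fill(arma::datum::nan);
  arma::vec w1(1);
  arma::vec lo, hi;
  CurveEx ex{&idx1, nullptr, &w1, &L, &times, step, eps,
             nullptr, nullptr,
             std::vector<double>(T2), std::vector<double>(T2)};
  if (lo_.isNotNull() && hi_.isNotNull()) {
    lo = as<arma::vec>(lo_.get());
    hi = as<arma::vec>(hi_.get());
    ex.lo = &lo; ex.hi = &hi;
  }
  std::vector<double> z(T2);
  for (int m = 0; m < M; ++m) {
    int J = 0;
    for (int i = 0; i < n; ++i) J = std::max(J, (int)G(m, i));
    if (J < 2 || J > 3) continue;
    arma::mat gm(T2, J, arma::fill::zeros);
    arma::vec nj(J, arma::fill::zeros);
    bool missing = false;
    for (int i = 0; i < n; ++i) {
      int g = G(m, i);
      if (g < 1) { missing = true; break; }
      nj[g - 1] += 1.0;
      gm.col(g - 1) += Y.row(i).t();
    }
    if (missing) continue;
    if (nj.min() < 2) continue;
    double B = 0.0;
    for (int j = 0; j < J; ++j) {
      gm.col(j) /= nj[j];
      for (int i = 0; i < T2; ++i) z[i] = gm(i, j) - ybar[i];
      fsolve(L.memptr(), T2, z.data());
      double q = 0.0;
      for (int i = 0; i < T2; ++i) q += z[i] * z[i];
      B += nj[j] * q;
    }
    double Vsum = 0.0;
    for (int j = 0; j < J; ++j) {
      arma::mat yb = gm.col(j);
      w1[0] = nj[j];
      ex.ybar = &yb;
      std::vector<double> x(tpar0.begin(), tpar0.end());
      double fmin = 0.0;
      nelder_mead(12, x.data(), &fmin, curve_obj, &ex, init_step, reltol,
                  maxit);
      Vsum += fmin;
    }
    double lr = B + 2.0 * V0 - 2.0 * Vsum;
    if (lr > refine_above && maxit_refine > maxit) {
      Vsum = 0.0;
      for (int j = 0; j < J; ++j) {
        arma::mat yb = gm.col(j);
        w1[0] = nj[j];
        ex.ybar = &yb;
        std::vector<double> x(tpar0.begin(), tpar0.end());
        double fmin = 0.0;
        nelder_mead(12, x.data(), &fmin, curve_obj, &ex, 0.05, reltol,
                    maxit_refine);
        Vsum += fmin;
      }
      lr = B + 2.0 * V0 - 2.0 * Vsum;
    }
    out[m] = lr > 0.0 ? lr : 0.0;
  }
  return out;
}
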