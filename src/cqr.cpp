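// Quantile regression core: Frisch-Newton interior-point solver.
//
// The check-loss problem  min_b sum_i m_i * rho_tau(y_i - x_i' b)  (m_i =
// observation multiplicities, 1 for a plain fit) is solved through its
// bounded-variable LP dual
//     min  y'a   s.t.  X'a = tau * X'm,   0 <= a <= m,
// whose equality multiplier at the optimum is exactly b-hat.  A Mehrotra
// predictor-corrector primal-dual iteration converges in 10-20 steps
// independent of n; each step costs O(n p^2) for the normal-equations
// matrix X' D X (p is a handful of covariates).  The bootstrap loop lives
// here too: per replicate, rows are compacted and multiplicities become
// dual upper bounds, and the full-data solution seeds the barrier start.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Cholesky of symmetric p x p (column-major, lower triangle); false if
// not positive definite.
static bool chol_factor(std::vector<double> &A, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) {
      double l = A[k * p + j];
      d -= l * l;
    }
    if (d <= 0.0 || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    A[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[j * p + i];
      for (int k = 0; k < j; ++k) s -= A[k * p + i] * A[k * p + j];
      A[j * p + i] = s / d;
    }
  }
  return true;
}

static void chol_solve(const std::vector<double> &L, double *b, int p) {
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[k * p + i] * b[k];
    b[i] = s / L[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < p; ++k) s -= L[i * p + k] * b[k];
    b[i] = s / L[i * p + i];
  }
}

struct QrWork {
  std::vector<double> x, s, z, w, xinv, sinv, zinv, winv, dx, dz, dw, rhsv,
      dinv, xlam, t1, t2, tmp, M, rhs;
  void resize(int n, int p) {
    x.resize(n); s.resize(n); z.resize(n); w.resize(n);
    xinv.resize(n); sinv.resize(n); zinv.resize(n); winv.resize(n);
    dx.resize(n); dz.resize(n); dw.resize(n);
    rhsv.resize(n); dinv.resize(n); xlam.resize(n);
    t1.resize(n); t2.resize(n); tmp.resize(n);
    M.resize(p * p); rhs.resize(p);
  }
};

// x' * lam over columns of Xc (stride n), accumulated into out[n]
static inline void mat_vec(const double *Xc, const double *lam, int n, int p,
                           double *out) {
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  for (int j = 0; j < p; ++j) {
    const double bj = lam[j];
    const double *xj = Xc + (size_t)j * n;
    for (int i = 0; i < n; ++i) out[i] += bj * xj[i];
  }
}

// Solve one quantile fit.  Xc: n x p column-major; m: multiplicities
// (NULL = all ones); lam0: optional coefficient start used to centre the
// initial dual slacks (NULL = weighted least squares).  Returns iterations
// used, or -1 on a degenerate design, -2 on non-convergence.
static int qr_ip_fit(const double *Xc, const double *y, const double *m,
                     int n, int p, double tau, double tol, int max_iter,
                     const double *lam0, double *lam, QrWork &wk) {
  wk.resize(n, p);
  std::vector<double> &x = wk.x, &s = wk.s, &z = wk.z, &w = wk.w,
      &xinv = wk.xinv, &sinv = wk.sinv, &zinv = wk.zinv, &winv = wk.winv,
      &dx = wk.dx, &dz = wk.dz, &dw = wk.dw, &rhsv = wk.rhsv,
      &dinv = wk.dinv, &xlam = wk.xlam, &t1 = wk.t1, &t2 = wk.t2,
      &tmp = wk.tmp, &M = wk.M, &rhs = wk.rhs;

  // primal start x = tau*m keeps X'x = tau*X'm exactly feasible
  for (int i = 0; i < n; ++i) {
    double ui = m ? m[i] : 1.0;
    x[i] = tau * ui;
    s[i] = (1.0 - tau) * ui;
  }

  if (lam0) {
    for (int j = 0; j < p; ++j) lam[j] = lam0[j];
  } else {
    // (weighted) least-squares start
    std::fill(M.begin(), M.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double *xj = Xc + (size_t)j * n;
      for (int k = j; k < p; ++k) {
        const double *xk = Xc + (size_t)k * n;
        double sv = 0.0;
        if (m) for (int i = 0; i < n; ++i) sv += m[i] * xj[i] * xk[i];
        else   for (int i = 0; i < n; ++i) sv += xj[i] * xk[i];
        M[j * p + k] = sv;
      }
      double sy = 0.0;
      if (m) for (int i = 0; i < n; ++i) sy += m[i] * xj[i] * y[i];
      else   for (int i = 0; i < n; ++i) sy += xj[i] * y[i];
      rhs[j] = sy;
    }
    for (int j = 0; j < p; ++j) M[j * p + j] *= (1.0 + 1e-12);
    if (!chol_factor(M, p)) return -1;
    chol_solve(M, rhs.data(), p);
    for (int j = 0; j < p; ++j) lam[j] = rhs[j];
  }

  // dual slacks z - w = y - X*lam, both strictly positive
  mat_vec(Xc, lam, n, p, xlam.data());
  double absr = 0.0, absy = 0.0;
  for (int i = 0; i < n; ++i) {
    absr += std::fabs(y[i] - xlam[i]);
    absy += std::fabs(y[i]) * x[i];
  }
  const double delta = 0.1 * (absr / n) + 1e-6;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - xlam[i];
    z[i] = (r > 0.0 ? r : 0.0) + delta;
    w[i] = (r < 0.0 ? -r : 0.0) + delta;
  }
  const double gap_tol = tol * (1.0 + absy);

  for (int it = 1; it <= max_iter; ++it) {
    double gap = 0.0;
    for (int i = 0; i < n; ++i) gap += x[i] * z[i] + s[i] * w[i];
    if (gap < gap_tol) return it;

    mat_vec(Xc, lam, n, p, xlam.data());
    for (int i = 0; i < n; ++i) {
      xinv[i] = 1.0 / x[i];
      sinv[i] = 1.0 / s[i];
      zinv[i] = 1.0 / z[i];
      winv[i] = 1.0 / w[i];
      dinv[i] = 1.0 / (z[i] * xinv[i] + w[i] * sinv[i]);
    }
    // normal-equations matrix X' D X, factored once per iteration
    std::fill(M.begin(), M.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double *xj = Xc + (size_t)j * n;
      for (int k = j; k < p; ++k) {
        const double *xk = Xc + (size_t)k * n;
        double sv = 0.0;
        for (int i = 0; i < n; ++i) sv += xj[i] * xk[i] * dinv[i];
        M[j * p + k] = sv;
      }
    }
    for (int j = 0; j < p; ++j) M[j * p + j] *= (1.0 + 1e-12);
    if (!chol_factor(M, p)) return -1;

    const double mu = gap / (2.0 * n);

    // --- predictor (affine) step ------------------------------------
    // dual residual rc = y - X lam - z + w; rhsv = rc + z - w = y - X lam
    for (int i = 0; i < n; ++i) {
      rhsv[i] = y[i] - xlam[i];
      tmp[i] = rhsv[i] * dinv[i];
    }
    for (int j = 0; j < p; ++j) {
      const double *xj = Xc + (size_t)j * n;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) sv += xj[i] * tmp[i];
      rhs[j] = sv;
    }
    chol_solve(M, rhs.data(), p);  // rhs = dlam_affine
    mat_vec(Xc, rhs.data(), n, p, dx.data());  // reuse dx as X*dlam
    // branchless ratio tests: alpha = 1/max(-step * reciprocal)
    double mp = 0.0, md = 0.0;
    for (int i = 0; i < n; ++i) {
      double dxi = (dx[i] - rhsv[i]) * dinv[i];
      dx[i] = dxi;
      dz[i] = -z[i] * (1.0 + dxi * xinv[i]);
      dw[i] = -w[i] * (1.0 - dxi * sinv[i]);
      mp = std::max(mp, std::max(-dxi * xinv[i], dxi * sinv[i]));
      md = std::max(md, std::max(-dz[i] * zinv[i], -dw[i] * winv[i]));
    }
    double ap = mp > 1.0 ? 1.0 / mp : 1.0;
    double ad = md > 1.0 ? 1.0 / md : 1.0;
    double mu_aff = 0.0;
    for (int i = 0; i < n; ++i)
      mu_aff += (x[i] + ap * dx[i]) * (z[i] + ad * dz[i]) +
                (s[i] - ap * dx[i]) * (w[i] + ad * dw[i]);
    mu_aff /= 2.0 * n;
    double sigma = mu_aff / mu;
    sigma = sigma * sigma * sigma;
    if (sigma > 1.0) sigma = 1.0;
    const double smu = sigma * mu;

    // --- corrector step (same factorisation) ------------------------
    for (int i = 0; i < n; ++i) {
      t1[i] = smu - dx[i] * dz[i];
      t2[i] = smu + dx[i] * dw[i];  // ds = -dx
      rhsv[i] = (y[i] - xlam[i]) - t1[i] * xinv[i] + t2[i] * sinv[i];
      tmp[i] = rhsv[i] * dinv[i];
    }
    for (int j = 0; j < p; ++j) {
      const double *xj = Xc + (size_t)j * n;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) sv += xj[i] * tmp[i];
      rhs[j] = sv;
    }
    chol_solve(M, rhs.data(), p);
    mat_vec(Xc, rhs.data(), n, p, dx.data());
    mp = 0.0; md = 0.0;
    for (int i = 0; i < n; ++i) {
      double dxi = (dx[i] - rhsv[i]) * dinv[i];
      dx[i] = dxi;
      dz[i] = (t1[i] - z[i] * dxi) * xinv[i] - z[i];
      dw[i] = (t2[i] + w[i] * dxi) * sinv[i] - w[i];
      mp = std::max(mp, std::max(-dxi * xinv[i], dxi * sinv[i]));
      md = std::max(md, std::max(-dz[i] * zinv[i], -dw[i] * winv[i]));
    }
    const double eta = 0.9995;
    ap = mp > eta ? eta / mp : 1.0;
    ad = md > eta ? eta / md : 1.0;
    for (int i = 0; i < n; ++i) {
      x[i] += ap * dx[i]; s[i] -= ap * dx[i];
      z[i] += ad * dz[i]; w[i] += ad * dw[i];
    }
    for (int j = 0; j < p; ++j) lam[j] += ad * rhs[j];
  }
  return -2;
}

// [[Rcpp::export(name = ".cqr_fit_cpp")]]
NumericMatrix cqr_fit_cpp(NumericMatrix X, NumericVector y, NumericVector taus,
                          double tol = 1e-8, int max_iter = 100) {
  const int n = X.nrow(), p = X.ncol(), K = taus.size();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n <= p) stop("need more observations than parameters");
  QrWork wk;
  NumericMatrix out(p, K);
  std::vector<double> lam(p);
  for (int k = 0; k < K; ++k) {
    double tau = taus[k];
    if (!(tau > 0.0 && tau < 1.0)) stop("quantiles must lie in (0, 1)");
    int it = qr_ip_fit(REAL(X), REAL(y), nullptr, n, p, tau, tol, max_iter,
                       nullptr, lam.data(), wk);
    if (it == -1) stop("degenerate design in quantile regression fit");
    if (it == -2)
      warning("interior-point iteration limit reached at tau = %f", tau);
    for (int j = 0; j < p; ++j) out(j, k) = lam[j];
  }
  return out;
}

// Pair (x, y) nonparametric bootstrap.  Resampling uses R's RNG, so
// results are reproducible under set.seed().  Rows with multiplicity zero
// are compacted out of each replicate; the remaining multiplicities enter
// as observation weights (dual upper bounds), and the full-data solution
// at each quantile seeds the replicate's barrier start.
// [[Rcpp::export(name = ".cqr_boot_cpp")]]
List cqr_boot_cpp(NumericMatrix X, NumericVector y, NumericVector taus,
                  int n_boot, double tol = 1e-8, double boot_tol = 1e-3,
                  int max_iter = 100) {
  const int n = X.nrow(), p = X.ncol(), K = taus.size();
  if (n_boot < 0) stop("n_boot must be non-negative");
  NumericMatrix coef = cqr_fit_cpp(X, y, taus, tol, max_iter);
  NumericMatrix se(p, K);
  IntegerVector nb_ok(K);
  std::fill(se.begin(), se.end(), NA_REAL);
  if (n_boot > 0) {
    QrWork wk;
    std::vector<double> sum(p * K, 0.0), ssq(p * K, 0.0), lam(p), start(p);
    std::vector<int> cnt(K, 0), mult(n);
    std::vector<double> Xb((size_t)n * p), yb(n), mb(n);
    const double *Xp = REAL(X);
    RNGScope scope;
    for (int b = 0; b < n_boot; ++b) {
      std::fill(mult.begin(), mult.end(), 0);
      for (int i = 0; i < n; ++i) {
        int idx = (int)(n * unif_rand());
        if (idx == n) idx = n - 1;
        mult[idx] += 1;
      }
      int nb = 0;
      for (int i = 0; i < n; ++i)
        if (mult[i] > 0) {
          yb[nb] = y[i];
          mb[nb] = (double)mult[i];
          for (int j = 0; j < p; ++j)
            Xb[(size_t)j * n + nb] = Xp[(size_t)j * n + i];
          ++nb;
        }
      for (int j = 1; j < p; ++j)      // compact columns to stride nb
        for (int i = 0; i < nb; ++i)
          Xb[(size_t)j * nb + i] = Xb[(size_t)j * n + i];
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < p; ++j) start[j] = coef(j, k);
        int it = qr_ip_fit(Xb.data(), yb.data(), mb.data(), nb, p, taus[k],
                           boot_tol, max_iter, start.data(), lam.data(), wk);
        if (it == -1) continue;  // degenerate resample: skip
        cnt[k] += 1;
        for (int j = 0; j < p; ++j) {
          sum[j + k * p] += lam[j];
          ssq[j + k * p] += lam[j] * lam[j];
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      nb_ok[k] = cnt[k];
      for (int j = 0; j < p; ++j) {
        if (cnt[k] > 1) {
          double mmean = sum[j + k * p] / cnt[k];
          double v = (ssq[j + k * p] - cnt[k] * mmean * mmean) / (cnt[k] - 1);
          se(j, k) = v > 0.0 ? std::sqrt(v) : 0.0;
        }
      }
    }
  }
  return List::create(_["coef"] = coef, _["se"] = se, _["n_boot_ok"] = nb_ok);
}
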