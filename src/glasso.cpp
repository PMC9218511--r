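#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// L1-penalised sparse inverse covariance estimation (graphical lasso)
// along a decreasing penalty path, by block coordinate descent: each
// column update solves a lasso problem in the current covariance
// estimate W by coordinate descent (active-set strategy with an
// incrementally maintained fitted vector), with W and the regression
// coefficients B warm-started from the previous penalty value. The
// diagonal is not penalised (diag(W) stays diag(S)), matching the
// convention of estimating from a correlation matrix.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// one coordinate pass over `idx`; c = W * B(,j) (full p-vector, includes
// the k term, excludes j by construction since B(j,j) = 0)
static double coord_pass(const double* S, double* W, double* B, double* c,
                         int p, int j, double lam,
                         const std::vector<int>& idx) {
  double max_db = 0.0;
  for (int ii = (int) idx.size() - 1; ii >= 0; --ii) {
    int k = idx[ii];
    double bk = B[j * p + k];
    double r = S[j * p + k] - (c[k] - W[k * p + k] * bk);
    double bnew = soft(r, lam) / W[k * p + k];
    double db = bnew - bk;
    if (db != 0.0) {
      double adb = std::fabs(db);
      if (adb > max_db) max_db = adb;
      B[j * p + k] = bnew;
      const double* wk = W + k * p;  // column k of symmetric W
      for (int l = 0; l < p; ++l) c[l] += db * wk[l];
    }
  }
  return max_db;
}

// [[Rcpp::export]]
List glasso_path_cpp(NumericMatrix S_, NumericVector lambdas,
                     double tol = 1e-4, int maxit = 200,
                     int inner_maxit = 500) {
  int p = S_.nrow();
  int nl = lambdas.size();
  NumericMatrix Sm(clone(S_));
  NumericMatrix Wm(clone(S_));
  NumericMatrix Bm(p, p);  // B(k, j): coefficient of variable k, column j
  double* S = Sm.begin();
  double* W = Wm.begin();
  double* B = Bm.begin();

  NumericVector thetas(Dimension(p, p, nl));
  LogicalVector conv(nl);
  IntegerVector iters(nl);

  // convergence scale: mean absolute off-diagonal of S
  double off = 0.0;
  int noff = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { off += std::fabs(S[j * p + i]); ++noff; }
  double sbar = noff > 0 ? off / noff : 0.0;
  if (sbar <= 0) sbar = 1.0;
  double thr = tol * sbar;
  double inner_thr = 0.1 * thr;

  std::vector<double> c(p);
  std::vector<int> all_idx, active;
  for (int k = 0; k < p; ++k) all_idx.push_back(k);

  for (int li = 0; li < nl; ++li) {
    double lam = lambdas[li];
    bool ok = true;
    int it = 0;
    for (it = 0; it < maxit; ++it) {
      double max_dw = 0.0;
      for (int j = 0; j < p; ++j) {
        if (W[j * p + j] <= 0) { ok = false; break; }
        // c = W * B(,j) over all rows (B(j,j) = 0)
        for (int l = 0; l < p; ++l) c[l] = 0.0;
        for (int k = 0; k < p; ++k) {
          double bk = B[j * p + k];
          if (bk != 0.0) {
            const double* wk = W + k * p;
            for (int l = 0; l < p; ++l) c[l] += bk * wk[l];
          }
        }
        std::vector<int> idx;
        idx.reserve(p - 1);
        for (int k = 0; k < p; ++k) if (k != j) idx.push_back(k);
        // full pass, then iterate on the active set until stable,
        // finishing with a full KKT pass
        for (int inner = 0; inner < inner_maxit; ++inner) {
          double d_full = coord_pass(S, W, B, c.data(), p, j, lam, idx);
          if (d_full < inner_thr) break;
          active.clear();
          for (int k = 0; k < p; ++k)
            if (k != j && B[j * p + k] != 0.0) active.push_back(k);
          for (int a = 0; a < inner_maxit; ++a) {
            if (coord_pass(S, W, B, c.data(), p, j, lam, active) < inner_thr)
              break;
          }
        }
        // w12 = W11 beta; B(j,j) = 0 so c already excludes column j
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double wkj = c[k];
          double dw = std::fabs(wkj - W[j * p + k]);
          if (dw > max_dw) max_dw = dw;
          W[j * p + k] = wkj;
          W[k * p + j] = wkj;
        }
      }
      if (!ok) break;
      if (max_dw < thr) { ++it; break; }
    }
    iters[li] = it;
    if (it >= maxit) ok = false;

    // back out the precision matrix from (W, B)
    if (ok) {
      for (int j = 0; j < p && ok; ++j) {
        double denom = W[j * p + j];
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          denom -= W[j * p + k] * B[j * p + k];
        }
        if (!(denom > 0) || !std::isfinite(denom)) { ok = false; break; }
        double tjj = 1.0 / denom;
        thetas[li * p * p + j * p + j] = tjj;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          thetas[li * p * p + j * p + k] = -B[j * p + k] * tjj;
        }
      }
      if (ok) {
        // symmetrise; keep hard zeros hard so edge counts are exact
        for (int j = 0; j < p; ++j) {
          for (int k = j + 1; k < p; ++k) {
            double a = thetas[li * p * p + j * p + k];
            double b = thetas[li * p * p + k * p + j];
            double m = (a == 0.0 || b == 0.0) ? 0.0 : 0.5 * (a + b);
            thetas[li * p * p + j * p + k] = m;
            thetas[li * p * p + k * p + j] = m;
          }
        }
      }
    }
    conv[li] = ok;
    if (!ok) {
      // reset the warm start so later penalties are not poisoned
      for (int i = 0; i < p * p; ++i) { W[i] = S[i]; B[i] = 0.0; }
    }
  }

  thetas.attr("dim") = Dimension(p, p, nl);
  return List::create(_["theta"] = thetas, _["converged"] = conv,
                      _["iterations"] = iters);
}
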