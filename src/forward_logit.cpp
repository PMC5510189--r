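// Hot path for bootstrap stability selection: IRLS logistic fits and
// ROC metrics for the forward model-building loop. The R implementations
// in R/roc.R and R/select.R define the reference semantics; tests assert
// agreement between the two routes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mann-Whitney AUC of scores s against 0/1 labels y (ties counted 1/2).
static double auc_mw(const vec& s, const vec& y) {
  const uword n = s.n_elem;
  uvec ord = sort_index(s, "ascend");
  vec r(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && s(ord(j + 1)) == s(ord(i))) ++j;
    double midrank = 0.5 * ((i + 1) + (j + 1));
    for (uword k = i; k <= j; ++k) r(ord(k)) = midrank;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  double sum1 = accu(r % y);
  return (sum1 - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

// Partial AUC over fpr in [0, fmax] of the tie-corrected empirical ROC,
// linearly interpolated at the boundary; unnormalized (max value fmax).
static double pauc_mw(const vec& s, const vec& y, double fmax) {
  const uword n = s.n_elem;
  uvec ord = sort_index(s, "descend");
  double n1 = accu(y), n0 = n - n1;
  double tp = 0, fp = 0, prev_fpr = 0, prev_tpr = 0, area = 0;
  uword i = 0;
  while (i < n) {
    uword j = i;
    double val = s(ord(i));
    while (j < n && s(ord(j)) == val) {
      if (y(ord(j)) > 0.5) tp += 1; else fp += 1;
      ++j;
    }
    double fpr = fp / n0, tpr = tp / n1;
    if (prev_fpr < fmax && fpr > prev_fpr) {
      double f2c = std::min(fpr, fmax);
      double t2c = prev_tpr + (tpr - prev_tpr) * (f2c - prev_fpr) / (fpr - prev_fpr);
      area += (f2c - prev_fpr) * (prev_tpr + t2c) / 2.0;
    }
    prev_fpr = fpr; prev_tpr = tpr;
    i = j;
  }
  return area;
}

// IRLS logistic fit; returns false on rank deficiency, non-convergence or
// separation (callers skip such candidates). Convergence: relative deviance
// change below tol.
static bool irls(const mat& X, const vec& y, vec beta, int max_iter, double tol,
                 vec& beta_out, double& dev_out, vec& fitted_out, mat& info_out) {
  double dev_old = datum::inf;
  bool conv = false;
  mat XtWX;
  for (int it = 0; it < max_iter; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, 1.0);
    vec zw = w % eta + (y - mu);
    XtWX = X.t() * (X.each_col() % w);
    vec bn;
    if (!solve(bn, XtWX, X.t() * zw, solve_opts::no_approx)) return false;
    beta = bn;
    if (abs(beta).max() > 30.0) return false; // diverging: separation
    eta = X * beta;
    mu = clamp(1.0 / (1.0 + exp(-eta)), 1e-12, 1.0 - 1e-12);
    double dev = -2.0 * accu(y % log(mu) + (1.0 - y) % log(1.0 - mu));
    if (dev < 1e-6) return false; // perfect separation
    if (std::isfinite(dev) && std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) {
      conv = true;
      dev_old = dev;
      break;
    }
    dev_old = dev;
  }
  if (!conv) return false;
  beta_out = beta;
  dev_out = dev_old;
  fitted_out = 1.0 / (1.0 + exp(-(X * beta)));
  info_out = XtWX;
  return true;
}

// Forward selection over a base design. E: candidates x samples; base:
// samples x k; criterion: 0 = auc, 1 = pauc, 2 = wald. Returns 1-based
// candidate indices in selection order plus per-step metrics.
// [[Rcpp::export(name = ".forward_select_cpp")]]
Rcpp::List forward_select_cpp(const arma::mat& E, const arma::mat& base,
                              const arma::vec& y, int criterion,
                              double min_auc_gain, double min_pauc_gain,
                              double max_wald_p, int max_panel_size,
                              double fmax) {
  const uword n = y.n_elem;
  // centre covariates: identical fits and metrics, but keeps coefficients on
  // a scale where the divergence-based separation check is honest
  mat baseC = base;
  for (uword j = 0; j < baseC.n_cols; ++j) baseC.col(j) -= mean(baseC.col(j));
  mat EC = E;
  for (uword i = 0; i < EC.n_rows; ++i) EC.row(i) -= mean(EC.row(i));

  mat X(n, baseC.n_cols + 1);
  X.col(0).ones();
  if (baseC.n_cols > 0) X.cols(1, baseC.n_cols) = baseC;

  vec beta_cur, fitted, dummy_fitted;
  double dev;
  mat info;
  vec beta0(X.n_cols, fill::zeros);
  bool base_ok = irls(X, y, beta0, 50, 1e-8, beta_cur, dev, fitted, info);
  if (!base_ok) {
    return Rcpp::List::create(Rcpp::Named("base_ok") = false);
  }
  double base_auc = auc_mw(fitted, y);
  double base_pauc = pauc_mw(fitted, y, fmax);
  double cur_metric = (criterion == 0) ? base_auc
                    : (criterion == 1) ? base_pauc : 0.0;

  std::vector<uword> panel;
  std::vector<double> metrics, gains, wald_ps;
  std::vector<bool> used(E.n_rows, false);

  while ((int)panel.size() < max_panel_size) {
    int best_j = -1;
    double best_value = (criterion == 2) ? datum::inf : -datum::inf;
    vec best_beta;
    for (uword j = 0; j < E.n_rows; ++j) {
      if (used[j]) continue;
      mat Xc(n, X.n_cols + 1);
      Xc.cols(0, X.n_cols - 1) = X;
      Xc.col(X.n_cols) = EC.row(j).t();
      vec bs(Xc.n_cols, fill::zeros);
      bs.head(beta_cur.n_elem) = beta_cur;
      vec beta_j, fitted_j;
      double dev_j;
      mat info_j;
      if (!irls(Xc, y, bs, 30, 1e-6, beta_j, dev_j, fitted_j, info_j)) continue;
      if (criterion == 2) {
        mat cov;
        if (!inv_sympd(cov, info_j)) continue;
        double se = std::sqrt(std::max(cov(cov.n_rows - 1, cov.n_cols - 1), 0.0));
        if (se <= 0) continue;
        double z = std::abs(beta_j(beta_j.n_elem - 1)) / se;
        double p = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
        if (p < best_value) { best_value = p; best_j = j; best_beta = beta_j; }
      } else {
        double v = (criterion == 0) ? auc_mw(fitted_j, y) : pauc_mw(fitted_j, y, fmax);
        if (v > best_value) { best_value = v; best_j = j; best_beta = beta_j; }
      }
    }
    if (best_j < 0) break; // every remaining candidate fit failed
    double gain = NA_REAL;
    if (criterion == 2) {
      if (best_value > max_wald_p) break;
    } else {
      gain = best_value - cur_metric;
      double thr = (criterion == 0) ? min_auc_gain : min_pauc_gain;
      if (gain < thr) break;
      cur_metric = best_value;
    }
    panel.push_back(best_j + 1);
    metrics.push_back(criterion == 2 ? NA_REAL : best_value);
    gains.push_back(gain);
    wald_ps.push_back(criterion == 2 ? best_value : NA_REAL);
    used[best_j] = true;
    mat Xn(n, X.n_cols + 1);
    Xn.cols(0, X.n_cols - 1) = X;
    Xn.col(X.n_cols) = EC.row(best_j).t();
    X = Xn;
    beta_cur = best_beta;
  }

  return Rcpp::List::create(
    Rcpp::Named("base_ok") = true,
    Rcpp::Named("panel") = Rcpp::IntegerVector(panel.begin(), panel.end()),
    Rcpp::Named("metric") = Rcpp::NumericVector(metrics.begin(), metrics.end()),
    Rcpp::Named("gain") = Rcpp::NumericVector(gains.begin(), gains.end()),
    Rcpp::Named("wald_p") = Rcpp::NumericVector(wald_ps.begin(), wald_ps.end()),
    Rcpp::Named("base_auc") = base_auc,
    Rcpp::Named("base_pauc") = base_pauc);
}
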