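#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

// generalized Kullback-Leibler divergence D(V || WH)
static double gkl_div(const mat& V, const mat& WH) {
  const double* v = V.memptr();
  const double* w = WH.memptr();
  const uword n = V.n_elem;
  double d = 0.0;
  for (uword i = 0; i < n; ++i) {
    double wi = w[i] < EPS ? EPS : w[i];
    if (v[i] > 0.0) d += v[i] * std::log(v[i] / wi) - v[i] + wi;
    else d += wi;
  }
  return d;
}

// R = V / max(WH, EPS), written into preallocated R
static void safe_ratio(const mat& V, const mat& WH, mat& R) {
  const double* v = V.memptr();
  const double* w = WH.memptr();
  double* r = R.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    double wi = w[i] < EPS ? EPS : w[i];
    r[i] = v[i] / wi;
  }
}

// Multiplicative-update NMF under generalized KL divergence.
// Stops when the relative objective change between successive checks
// (every check_every iterations) falls below tol, or at max_iter.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every) {
  const uword m = V.n_rows, n = V.n_cols, k = W.n_cols;
  mat R(m, n), WH(m, n), Hnum(k, n), Wnum(m, k);
  std::vector<double> trace;
  WH = W * H;
  double obj = gkl_div(V, WH);
  trace.push_back(obj);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update
    safe_ratio(V, WH, R);
    Hnum = W.t() * R;
    for (uword j = 0; j < k; ++j) {
      double ws = accu(W.col(j));
      if (ws < EPS) ws = EPS;
      double* hr = H.memptr();
      double* nr = Hnum.memptr();
      for (uword c = 0; c < n; ++c) {
        hr[j + c * k] *= nr[j + c * k] / ws;
      }
    }
    WH = W * H;
    // W update
    safe_ratio(V, WH, R);
    Wnum = R * H.t();
    for (uword j = 0; j < k; ++j) {
      double hs = accu(H.row(j));
      if (hs < EPS) hs = EPS;
      double* wc = W.colptr(j);
      const double* nc = Wnum.colptr(j);
      for (uword r = 0; r < m; ++r) wc[r] *= nc[r] / hs;
    }
    WH = W * H;
    if (it % check_every == 0 || it == max_iter) {
      double newobj = gkl_div(V, WH);
      trace.push_back(newobj);
      double denom = std::abs(obj) > EPS ? std::abs(obj) : EPS;
      bool conv = std::abs(obj - newobj) / denom < tol;
      obj = newobj;
      if (conv) break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
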