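#include <Rcpp.h>
using namespace Rcpp;

// Plug-in (empirical) mutual information, in nats, between a discrete column
// and a discrete reference vector. Inputs are 0-based codes; any code outside
// [0, bins) is a caller bug and is guarded by the R wrappers.
// logs of the integer counts 0..n are precomputed once per kernel call:
// I = (1/n) * sum_c c * (log c + log n - log mx - log my)
static double mi_from_counts(const std::vector<int>& joint, int bx, int by,
                             int n, const std::vector<double>& logt) {
  std::vector<int> mx(bx, 0), my(by, 0);
  for (int a = 0; a < bx; ++a)
    for (int b = 0; b < by; ++b) {
      int c = joint[a * by + b];
      mx[a] += c;
      my[b] += c;
    }
  double acc = 0.0;
  const double logn = logt[n];
  for (int a = 0; a < bx; ++a) {
    if (mx[a] == 0) continue;
    const double la = logt[mx[a]];
    for (int b = 0; b < by; ++b) {
      int c = joint[a * by + b];
      if (c == 0) continue;
      acc += c * (logt[c] + logn - la - logt[my[b]]);
    }
  }
  double mi = acc / n;
  return mi > 0.0 ? mi : 0.0;  // clamp -0 / rounding dust
}

static std::vector<double> log_table(int n) {
  std::vector<double> logt(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) logt[i] = std::log((double)i);
  return logt;
}

// [[Rcpp::export(name = ".mi_columns_ref")]]
NumericVector mi_columns_ref(IntegerMatrix D, IntegerVector ref,
                             int dbins, int rbins) {
  const int n = D.nrow(), d = D.ncol();
  if (ref.size() != n) stop("reference length must equal row count");
  NumericVector out(d);
  std::vector<int> joint((size_t)dbins * rbins);
  std::vector<double> logt = log_table(n);
  std::vector<int> refc(n);
  for (int i = 0; i < n; ++i) refc[i] = ref[i];
  for (int j = 0; j < d; ++j) {
    std::fill(joint.begin(), joint.end(), 0);
    const int* col = &D(0, j);
    for (int i = 0; i < n; ++i) joint[(size_t)col[i] * rbins + refc[i]]++;
    out[j] = mi_from_counts(joint, dbins, rbins, n, logt);
  }
  return out;
}

// Equal-width discretization of every column into `bins` codes 0..bins-1;
// constant columns map to all zeros (same convention as discretize() in R).
// [[Rcpp::export(name = ".discretize_matrix")]]
IntegerMatrix discretize_matrix(NumericMatrix X, int bins) {
  const int n = X.nrow(), d = X.ncol();
  IntegerMatrix D(n, d);
  for (int j = 0; j < d; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    double w = hi - lo;
    if (w <= 0.0) {
      for (int i = 0; i < n; ++i) D(i, j) = 0;
      continue;
    }
    for (int i = 0; i < n; ++i) {
      int b = (int)std::floor((X(i, j) - lo) / w * bins);
      if (b >= bins) b = bins - 1;
      if (b < 0) b = 0;
      D(i, j) = b;
    }
  }
  return D;
}
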