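#include <Rcpp.h>
using namespace Rcpp;

// Dependent (joint-channel) dynamic time warping.
// Local cost between frame i of A and frame j of B is the Euclidean
// distance between the two C-dimensional frame vectors; the DP runs over
// the full L x L grid with steps (i-1,j), (i,j-1), (i-1,j-1) and no
// warping band. Series are L x C matrices (column-major from R); they
// are repacked row-major so each frame vector is contiguous.

static void pack_rowmajor(const NumericMatrix& m, std::vector<double>& out) {
  const int L = m.nrow(), C = m.ncol();
  out.resize((size_t)L * C);
  for (int i = 0; i < L; ++i)
    for (int c = 0; c < C; ++c)
      out[(size_t)i * C + c] = m(i, c);
}

static double dtw_packed(const double* a, int n, const double* b, int m,
                         int C, std::vector<double>& prev,
                         std::vector<double>& cur) {
  prev.resize(m);
  cur.resize(m);
  auto cost = [C](const double* x, const double* y) {
    double s = 0.0;
    for (int c = 0; c < C; ++c) {
      const double d = x[c] - y[c];
      s += d * d;
    }
    return std::sqrt(s);
  };
  prev[0] = cost(a, b);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + cost(a, b + (size_t)j * C);
  for (int i = 1; i < n; ++i) {
    const double* ai = a + (size_t)i * C;
    cur[0] = prev[0] + cost(ai, b);
    for (int j = 1; j < m; ++j) {
      double best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      if (prev[j - 1] < best) best = prev[j - 1];
      cur[j] = best + cost(ai, b + (size_t)j * C);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export(name = ".dtw_pair_cpp")]]
double dtw_pair_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.ncol() != b.ncol()) stop("series have different channel counts");
  std::vector<double> pa, pb, prev, cur;
  pack_rowmajor(a, pa);
  pack_rowmajor(b, pb);
  return dtw_packed(pa.data(), a.nrow(), pb.data(), b.nrow(), a.ncol(),
                    prev, cur);
}

// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(List series) {
  const int n = series.size();
  std::vector<std::vector<double>> s(n);
  std::vector<int> len(n);
  int C = -1;
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = as<NumericMatrix>(series[i]);
    if (C < 0) C = m.ncol();
    else if (m.ncol() != C) stop("series have different channel counts");
    len[i] = m.nrow();
    pack_rowmajor(m, s[i]);
  }
  NumericMatrix d(n, n);
  std::vector<double> prev, cur;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double v = dtw_packed(s[i].data(), len[i], s[j].data(), len[j],
                                  C, prev, cur);
      d(i, j) = v;
      d(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return d;
}
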