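#include <Rcpp.h>
using namespace Rcpp;

// log(exp(a) + exp(b)) without overflow; -Inf is the additive identity.
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + log1p(exp(((a > b) ? b : a) - m));
}

// Triangle of log unsigned Stirling numbers of the first kind, rows 1..nmax.
// Row n is stored at offset n*(n-1)/2 with entries k = 1..n.
static std::vector<double> log_stirling_triangle(int nmax) {
  std::vector<double> tri((size_t)nmax * (nmax + 1) / 2);
  tri[0] = 0.0; // s(1,1) = 1
  for (int n = 2; n <= nmax; ++n) {
    size_t prev = (size_t)(n - 1) * (n - 2) / 2;
    size_t cur  = (size_t)n * (n - 1) / 2;
    double lnm1 = log((double)(n - 1));
    // s(n,k) = (n-1) s(n-1,k) + s(n-1,k-1)
    tri[cur] = lnm1 + tri[prev];                 // k = 1
    for (int k = 2; k < n; ++k)
      tri[cur + k - 1] = logadd(lnm1 + tri[prev + k - 1], tri[prev + k - 2]);
    tri[cur + n - 1] = 0.0;                      // s(n,n) = 1
  }
  return tri;
}

// Log ancestry coefficients K(D,A) of Etienne's (2005) sampling formula for
// abundance vector D = counts (all > 0), returned for A = S..J.
// Per species: c_n(a) = s(n,a) * (a-1)! / (n-1)!, a = 1..n; K is the
// coefficient-wise product over species, i.e. a convolution in A, done in
// log space with stable log-sum-exp accumulation.
//' @noRd
// [[Rcpp::export(name = ".log_kda")]]
NumericVector log_kda(IntegerVector counts) {
  int S = counts.size();
  int J = 0, nmax = 1;
  for (int i = 0; i < S; ++i) {
    if (counts[i] <= 0) stop("counts must be positive");
    J += counts[i];
    if (counts[i] > nmax) nmax = counts[i];
  }
  std::vector<double> tri = log_stirling_triangle(nmax);

  // running convolution; cur[a - n_done_species] corresponds to total A
  std::vector<double> cur(1, 0.0); // single empty product
  int s_done = 0;
  for (int i = 0; i < S; ++i) {
    int n = counts[i];
    size_t row = (size_t)n * (n - 1) / 2;
    std::vector<double> c(n);
    for (int a = 1; a <= n; ++a)
      c[a - 1] = tri[row + a - 1] + lgamma((double)a) - lgamma((double)n);
    std::vector<double> out(cur.size() + n - 1, R_NegInf);
    for (size_t x = 0; x < cur.size(); ++x) {
      if (cur[x] == R_NegInf) continue;
      for (int y = 0; y < n; ++y)
        out[x + y] = logadd(out[x + y], cur[x] + c[y]);
    }
    cur.swap(out);
    ++s_done;
  }
  // cur index x corresponds to A = S + x, x = 0..(J-S)
  return NumericVector(cur.begin(), cur.end());
}
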