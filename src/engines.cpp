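#include <Rcpp.h>
using namespace Rcpp;

// Draw a species index (0-based) from the metacommunity, given the cumulative
// relative-abundance vector. Uses R's RNG so set.seed() governs everything.
static inline int draw_meta(const NumericVector& cum) {
  double u = unif_rand() * cum[cum.size() - 1];
  NumericVector::const_iterator it =
    std::upper_bound(cum.begin(), cum.end(), u);
  int idx = it - cum.begin();
  if (idx >= cum.size()) idx = cum.size() - 1;
  return idx;
}

static inline int rand_int(int n) { // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static IntegerMatrix count_state(const IntegerMatrix& ind, int n_species) {
  int J = ind.nrow(), n_plots = ind.ncol();
  IntegerMatrix counts(n_plots, n_species);
  for (int p = 0; p < n_plots; ++p)
    for (int i = 0; i < J; ++i)
      counts(p, ind(i, p))++;
  return counts;
}

//' @noRd
// [[Rcpp::export(name = ".sim_implicit_engine")]]
List sim_implicit_engine(NumericVector cum, int n_plots, int J, double m,
                         double events_per_plot,
                         Nullable<IntegerMatrix> init) {
  IntegerMatrix ind(J, n_plots);
  if (init.isNotNull()) {
    IntegerMatrix ini(init);
    if (ini.nrow() != J || ini.ncol() != n_plots)
      stop("init state has wrong dimensions");
    for (int p = 0; p < n_plots; ++p)
      for (int i = 0; i < J; ++i) ind(i, p) = ini(i, p);
  } else {
    for (int p = 0; p < n_plots; ++p)
      for (int i = 0; i < J; ++i) ind(i, p) = draw_meta(cum);
  }
  long n_meta = 0, n_local = 0;
  long long ev = (long long)events_per_plot;
  for (int p = 0; p < n_plots; ++p) {
    for (long long e = 0; e < ev; ++e) {
      int dead = rand_int(J);
      int sp;
      if (unif_rand() < m) {
        sp = draw_meta(cum); ++n_meta;
      } else {
        // parent drawn uniformly from the remaining J-1 individuals
        int r = rand_int(J - 1);
        if (r >= dead) ++r;
        sp = ind(r, p); ++n_local;
      }
      ind(dead, p) = sp;
    }
  }
  return List::create(_["state"] = ind,
                      _["counts"] = count_state(ind, cum.size()),
                      _["sources"] = NumericVector::create(
                        _["local"] = (double)n_local,
                        _["meta"] = (double)n_meta));
}

//' @noRd
// [[Rcpp::export(name = ".sim_lattice_engine")]]
List sim_lattice_engine(NumericVector cum, IntegerMatrix neighbors,
                        IntegerVector n_neighbors, int J,
                        double m_adj, double m_meta,
                        double sweeps, Nullable<IntegerMatrix> init) {
  int n_plots = neighbors.ncol();
  IntegerMatrix ind(J, n_plots);
  if (init.isNotNull()) {
    IntegerMatrix ini(init);
    if (ini.nrow() != J || ini.ncol() != n_plots)
      stop("init state has wrong dimensions");
    for (int p = 0; p < n_plots; ++p)
      for (int i = 0; i < J; ++i) ind(i, p) = ini(i, p);
  } else {
    for (int p = 0; p < n_plots; ++p)
      for (int i = 0; i < J; ++i) ind(i, p) = draw_meta(cum);
  }
  long n_meta = 0, n_adj = 0, n_local = 0;
  long long nsw = (long long)sweeps;
  for (long long s = 0; s < nsw; ++s) {
    // one death per plot per sweep
    for (int p = 0; p < n_plots; ++p) {
      int dead = rand_int(J);
      double u = unif_rand();
      int sp;
      if (u < m_adj) {
        int nb = neighbors(rand_int(n_neighbors[p]), p);
        sp = ind(rand_int(J), nb); ++n_adj;
      } else if (u < m_adj + m_meta) {
        sp = draw_meta(cum); ++n_meta;
      } else {
        int r = rand_int(J - 1);
        if (r >= dead) ++r;
        sp = ind(r, p); ++n_local;
      }
      ind(dead, p) = sp;
    }
  }
  return List::create(_["state"] = ind,
                      _["counts"] = count_state(ind, cum.size()),
                      _["sources"] = NumericVector::create(
                        _["local"] = (double)n_local,
                        _["adjacent"] = (double)n_adj,
                        _["meta"] = (double)n_meta));
}
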