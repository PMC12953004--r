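#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Abundance-weighted beta mean-nearest-taxon distance between two
// communities, evaluated on a (possibly label-permuted) distance matrix.
//
//   0.5 * [ sum_i fA_i * min_{j in B} d(i,j) + sum_j fB_j * min_{i in A} d(i,j) ]
//
// ia/ib: 0-based row indices of taxa present in each community; wa/wb their
// relative abundances (sum to 1). perm (0-based) maps each taxon index to its
// shuffled position on the tree; NULL means identity.
static double pair_bmntd(const double *d, const size_t nrow,
                         const std::vector<int> &ia,
                         const std::vector<double> &wa,
                         const std::vector<int> &ib,
                         const std::vector<double> &wb,
                         const int *perm) {
  const size_t na = ia.size(), nb = ib.size();
  std::vector<int> pa(na), pb(nb);
  for (size_t i = 0; i < na; ++i) pa[i] = perm ? perm[ia[i]] : ia[i];
  for (size_t j = 0; j < nb; ++j) pb[j] = perm ? perm[ib[j]] : ib[j];

  double sa = 0.0;
  std::vector<double> minb(nb, R_PosInf);
  for (size_t i = 0; i < na; ++i) {
    const double *col = d + nrow * pa[i];  // column pa[i]; d symmetric
    double m = R_PosInf;
    for (size_t j = 0; j < nb; ++j) {
      double v = col[pb[j]];
      if (v < m) m = v;
      if (v < minb[j]) minb[j] = v;
    }
    sa += wa[i] * m;
  }
  double sb = 0.0;
  for (size_t j = 0; j < nb; ++j) sb += wb[j] * minb[j];
  return 0.5 * (sa + sb);
}

static void community_lists(const NumericMatrix &w,
                            std::vector<std::vector<int> > &idx,
                            std::vector<std::vector<double> > &wt) {
  const int nt = w.nrow(), ns = w.ncol();
  idx.assign(ns, std::vector<int>());
  wt.assign(ns, std::vector<double>());
  for (int s = 0; s < ns; ++s) {
    double tot = 0.0;
    for (int t = 0; t < nt; ++t) tot += w(t, s);
    for (int t = 0; t < nt; ++t) {
      if (w(t, s) > 0) {
        idx[s].push_back(t);
        wt[s].push_back(w(t, s) / tot);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector bmntd_obs_cpp(NumericMatrix dist, NumericMatrix w,
                            IntegerMatrix pairs) {
  std::vector<std::vector<int> > idx;
  std::vector<std::vector<double> > wt;
  community_lists(w, idx, wt);
  const int np = pairs.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
    out[p] = pair_bmntd(dist.begin(), dist.nrow(), idx[a], wt[a], idx[b], wt[b], NULL);
  }
  return out;
}

// One tip-label permutation per null replicate (row of `perms`, 1-based),
// applied to every sample pair: the standard matrix-shuffle null.
// [[Rcpp::export]]
NumericMatrix bmntd_null_cpp(NumericMatrix dist, NumericMatrix w,
                             IntegerMatrix pairs, IntegerMatrix perms) {
  std::vector<std::vector<int> > idx;
  std::vector<std::vector<double> > wt;
  community_lists(w, idx, wt);
  const int np = pairs.nrow(), nn = perms.nrow(), nt = perms.ncol();
  NumericMatrix out(np, nn);
  std::vector<int> perm(nt);
  for (int r = 0; r < nn; ++r) {
    for (int t = 0; t < nt; ++t) perm[t] = perms(r, t) - 1;
    for (int p = 0; p < np; ++p) {
      int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
      out(p, r) = pair_bmntd(dist.begin(), dist.nrow(), idx[a], wt[a], idx[b], wt[b], perm.data());
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
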