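#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning log-likelihoods for a batch of alignment columns.
//
// edge:        postorder edge matrix (1-based ape node ids), child partials
//              are always complete before their parent edge is processed.
// scaled_len:  branch length * branch scale, one per edge.
// U, lambda, Uinv: eigendecomposition of the (reversible) rate matrix Q,
//              so P(t) = U diag(exp(lambda t)) Uinv.
// X:           integer matrix, n_tip x n_col; codes 1..4 = A,C,G,T and
//              0 = gap/missing (partial-likelihood vector of ones).
//
// Returns one log-likelihood per column. Per-column rescaling guards
// against underflow on large trees.
// [[Rcpp::export]]
NumericVector pruning_loglik(IntegerMatrix edge,
                             int n_node_total,
                             int n_tip,
                             NumericVector scaled_len,
                             NumericMatrix U,
                             NumericVector lambda,
                             NumericMatrix Uinv,
                             NumericVector pi,
                             IntegerMatrix X) {
  const int n_edge = edge.nrow();
  const int n_col  = X.ncol();
  if (X.nrow() != n_tip) stop("X must have one row per tip");

  // P(t) per edge
  std::vector<std::array<double, 16> > P(n_edge);
  for (int e = 0; e < n_edge; ++e) {
    double ex[4];
    for (int k = 0; k < 4; ++k) ex[k] = std::exp(lambda[k] * scaled_len[e]);
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k) s += U(i, k) * ex[k] * Uinv(k, j);
        P[e][i * 4 + j] = s < 0.0 ? 0.0 : s;
      }
    }
  }

  const int root = edge(n_edge - 1, 0) - 1;  // last postorder edge leaves the root
  std::vector<double> part(4 * n_node_total);
  NumericVector out(n_col);

  for (int c = 0; c < n_col; ++c) {
    std::fill(part.begin(), part.end(), 1.0);
    double logscale = 0.0;
    for (int e = 0; e < n_edge; ++e) {
      const int par = edge(e, 0) - 1;
      const int ch  = edge(e, 1) - 1;
      const double* Pe = P[e].data();
      double v[4];
      if (ch < n_tip) {
        const int s = X(ch, c);
        if (s == 0) {
          v[0] = v[1] = v[2] = v[3] = 1.0;
        } else {
          const int j = s - 1;
          for (int i = 0; i < 4; ++i) v[i] = Pe[i * 4 + j];
        }
      } else {
        const double* L = &part[4 * ch];
        for (int i = 0; i < 4; ++i) {
          v[i] = Pe[i * 4 + 0] * L[0] + Pe[i * 4 + 1] * L[1]
               + Pe[i * 4 + 2] * L[2] + Pe[i * 4 + 3] * L[3];
        }
      }
      double* Lp = &part[4 * par];
      double mx = 0.0;
      for (int i = 0; i < 4; ++i) {
        Lp[i] *= v[i];
        if (Lp[i] > mx) mx = Lp[i];
      }
      if (mx > 0.0 && mx < 1e-200) {
        for (int i = 0; i < 4; ++i) Lp[i] /= mx;
        logscale += std::log(mx);
      }
    }
    const double* Lr = &part[4 * root];
    double lik = 0.0;
    for (int i = 0; i < 4; ++i) lik += pi[i] * Lr[i];
    out[c] = std::log(lik) + logscale;
  }
  return out;
}
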