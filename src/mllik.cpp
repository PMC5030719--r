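#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning log-likelihood for a rooted/trifurcated tree whose
// edge matrix is in postorder (children before parents). P(t) comes from
// the eigendecomposition of the HKY rate matrix:
// P = right * diag(exp(vals * t)) * left. Partial likelihoods are kept in
// flat buffers; underflow protection rescales a pattern only when its
// partial drops below 1e-120 (branch lengths and tree depths here keep
// values far from the double floor in the common case).

// [[Rcpp::export(name = ".tree_loglik_cpp")]]
double tree_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                       int ntip, IntegerMatrix states, NumericVector weights,
                       NumericVector freqs, NumericVector vals,
                       NumericMatrix right, NumericMatrix left) {
  const int nedge = edge.nrow();
  const int npat = states.ncol();
  const int ntaxa = states.nrow();
  int nnode = 0;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));

  const int *st = states.begin();
  const double *w = weights.begin();
  std::vector<double> partial((size_t)(nnode + 1) * 4 * npat);
  std::vector<signed char> started(nnode + 1, 0);
  std::vector<double> msg(4 * npat);
  double scalelog = 0.0;
  double P[16];

  for (int e = 0; e < nedge; ++e) {
    const int child = edge(e, 1), parent = edge(e, 0);
    const double t = edge_length[e];
    double expv[4];
    for (int i = 0; i < 4; ++i) expv[i] = std::exp(vals[i] * t);
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) {
        double acc = 0.0;
        for (int k = 0; k < 4; ++k) acc += right(i, k) * expv[k] * left(k, j);
        P[4 * i + j] = acc > 0 ? acc : 0.0;
      }
    }
    double *m = msg.data();
    if (child <= ntip) {
      const int row = child - 1;
      double rowsum[4];
      for (int i = 0; i < 4; ++i)
        rowsum[i] = P[4 * i] + P[4 * i + 1] + P[4 * i + 2] + P[4 * i + 3];
      for (int s = 0; s < npat; ++s) {
        const int sv = st[row + (size_t)ntaxa * s];
        if (sv == 0) {
          m[4 * s] = rowsum[0]; m[4 * s + 1] = rowsum[1];
          m[4 * s + 2] = rowsum[2]; m[4 * s + 3] = rowsum[3];
        } else {
          const int j = sv - 1;
          m[4 * s] = P[j]; m[4 * s + 1] = P[4 + j];
          m[4 * s + 2] = P[8 + j]; m[4 * s + 3] = P[12 + j];
        }
      }
    } else {
      const double *cp = &partial[(size_t)child * 4 * npat];
      for (int s = 0; s < npat; ++s) {
        const double c0 = cp[4 * s], c1 = cp[4 * s + 1], c2 = cp[4 * s + 2],
                     c3 = cp[4 * s + 3];
        m[4 * s] = P[0] * c0 + P[1] * c1 + P[2] * c2 + P[3] * c3;
        m[4 * s + 1] = P[4] * c0 + P[5] * c1 + P[6] * c2 + P[7] * c3;
        m[4 * s + 2] = P[8] * c0 + P[9] * c1 + P[10] * c2 + P[11] * c3;
        m[4 * s + 3] = P[12] * c0 + P[13] * c1 + P[14] * c2 + P[15] * c3;
      }
    }
    double *pp = &partial[(size_t)parent * 4 * npat];
    if (!started[parent]) {
      std::copy(msg.begin(), msg.end(), pp);
      started[parent] = 1;
    } else {
      for (int k = 0; k < 4 * npat; ++k) pp[k] *= m[k];
      // rescale only patterns that have drifted toward underflow
      for (int s = 0; s < npat; ++s) {
        double mx = pp[4 * s];
        for (int i = 1; i < 4; ++i) mx = std::max(mx, pp[4 * s + i]);
        if (mx > 0 && mx < 1e-120) {
          for (int i = 0; i < 4; ++i) pp[4 * s + i] /= mx;
          scalelog += w[s] * std::log(mx);
        }
      }
    }
  }
  const int root = edge(nedge - 1, 0);
  const double *rp = &partial[(size_t)root * 4 * npat];
  double ll = scalelog;
  for (int s = 0; s < npat; ++s) {
    double site = freqs[0] * rp[4 * s] + freqs[1] * rp[4 * s + 1] +
                  freqs[2] * rp[4 * s + 2] + freqs[3] * rp[4 * s + 3];
    ll += w[s] * std::log(site);
  }
  return ll;
}
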