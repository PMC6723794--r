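#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted least-squares co-occurrence embedding fit with AdaGrad.
// Pairs (ii, jj, xx) are the nonzero upper-triangle entries (0-based ids);
// each visit updates both orderings (i as focus / j as context and vice
// versa). Initialization and per-epoch shuffling use R's RNG, so runs are
// reproducible under set.seed() and the epochs = 0 case returns the seeded
// random initialization.
// [[Rcpp::export]]
List cpp_fit_glove(IntegerVector ii, IntegerVector jj, NumericVector xx,
                   int n, int dim, double x_max, double alpha,
                   int epochs, double lr) {
  int m = ii.size();
  NumericMatrix W(n, dim), Wt(n, dim);
  NumericVector b(n), bt(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < dim; ++d) {
      W(i, d) = (unif_rand() - 0.5) / dim;
      Wt(i, d) = (unif_rand() - 0.5) / dim;
    }
    b[i] = (unif_rand() - 0.5) / dim;
    bt[i] = (unif_rand() - 0.5) / dim;
  }
  NumericMatrix gW(n, dim), gWt(n, dim);
  NumericVector gb(n), gbt(n);
  std::fill(gW.begin(), gW.end(), 1.0);
  std::fill(gWt.begin(), gWt.end(), 1.0);
  std::fill(gb.begin(), gb.end(), 1.0);
  std::fill(gbt.begin(), gbt.end(), 1.0);

  std::vector<double> logx(m), fwt(m);
  for (int k = 0; k < m; ++k) {
    logx[k] = std::log(xx[k]);
    double f = std::pow(xx[k] / x_max, alpha);
    fwt[k] = f > 1.0 ? 1.0 : f;
  }

  std::vector<int> order(m);
  for (int k = 0; k < m; ++k) order[k] = k;
  NumericVector loss(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with R's RNG
    for (int k = m - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(order[k], order[r]);
    }
    double cost = 0.0;
    for (int kk = 0; kk < m; ++kk) {
      int k = order[kk];
      for (int dir = 0; dir < 2; ++dir) {
        int i = dir == 0 ? ii[k] : jj[k];
        int j = dir == 0 ? jj[k] : ii[k];
        double diff = b[i] + bt[j] - logx[k];
        for (int d = 0; d < dim; ++d) diff += W(i, d) * Wt(j, d);
        double f = fwt[k];
        cost += 0.5 * f * diff * diff;
        double fd = f * diff;
        for (int d = 0; d < dim; ++d) {
          double gi = fd * Wt(j, d);
          double gj = fd * W(i, d);
          W(i, d) -= lr * gi / std::sqrt(gW(i, d));
          Wt(j, d) -= lr * gj / std::sqrt(gWt(j, d));
          gW(i, d) += gi * gi;
          gWt(j, d) += gj * gj;
        }
        b[i] -= lr * fd / std::sqrt(gb[i]);
        bt[j] -= lr * fd / std::sqrt(gbt[j]);
        gb[i] += fd * fd;
        gbt[j] += fd * fd;
      }
    }
    loss[ep] = cost / (2.0 * m);
  }
  return List::create(_["w"] = W, _["w_context"] = Wt,
                      _["b"] = b, _["b_context"] = bt, _["loss"] = loss);
}
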