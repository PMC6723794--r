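#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Adjacency is CSR over 0-based node indices: neighbors of v are
// nbr[off[v] .. off[v+1]-1], sorted ascending, with parallel edge weights.

static inline bool is_adjacent(const IntegerVector& off,
                               const IntegerVector& nbr,
                               int v, int x) {
  const int* first = &nbr[0] + off[v];
  const int* last = &nbr[0] + off[v + 1];
  return std::binary_search(first, last, x);
}

// Sample an index in [0, n) proportional to w, using R's RNG.
static inline int sample_weighted(const std::vector<double>& w, int n) {
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += w[i];
  double u = unif_rand() * total;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

// Biased second-order random walks (return parameter p, in-out parameter q).
// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector off, IntegerVector nbr,
                        NumericVector wts, int n_nodes,
                        int walks_per_node, int walk_length,
                        double p, double q) {
  List walks(n_nodes * walks_per_node);
  std::vector<double> buf;
  int k = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int s = 0; s < n_nodes; ++s) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      int prev = -1, curr = s;
      while ((int)walk.size() < walk_length) {
        int deg = off[curr + 1] - off[curr];
        if (deg == 0) break;  // dead end
        buf.resize(deg);
        for (int i = 0; i < deg; ++i) {
          int x = nbr[off[curr] + i];
          double w = wts[off[curr] + i];
          double alpha;
          if (prev < 0) alpha = 1.0;                       // first step
          else if (x == prev) alpha = 1.0 / p;             // return
          else if (is_adjacent(off, nbr, prev, x)) alpha = 1.0;
          else alpha = 1.0 / q;                            // outward
          buf[i] = w * alpha;
        }
        int pick = sample_weighted(buf, deg);
        int nxt = nbr[off[curr] + pick];
        walk.push_back(nxt);
        prev = curr;
        curr = nxt;
      }
      IntegerVector w1(walk.size());
      for (size_t i = 0; i < walk.size(); ++i) w1[i] = walk[i] + 1;  // 1-based
      walks[k++] = w1;
    }
  }
  return walks;
}

static inline double sigmoid(double x) {
  if (x > 20.0) return 1.0;
  if (x < -20.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus.
// walks: list of 1-based integer vectors. Returns input ("in") and output
// ("out") matrices, n_nodes x dim. Initialization uses R's RNG, so the
// epochs = 0 case returns a seed-reproducible random state. Vectors are
// held node-major so one node's embedding is contiguous in memory.
// [[Rcpp::export]]
List cpp_train_skipgram(List walks, int n_nodes, int dim, int window,
                        int negative, int epochs, double lr_init) {
  std::vector<double> win((size_t)n_nodes * dim), wout((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < win.size(); ++i)
    win[i] = (unif_rand() - 0.5) / dim;

  // unigram^0.75 negative-sampling table (cumulative)
  std::vector<double> counts(n_nodes, 0.0);
  long long n_tokens = 0;
  int n_walks = walks.size();
  for (int w = 0; w < n_walks; ++w) {
    IntegerVector walk = walks[w];
    for (int t = 0; t < walk.size(); ++t) counts[walk[t] - 1] += 1.0;
    n_tokens += walk.size();
  }
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }
  if (tot <= 0.0) stop("empty walk corpus");

  double total_steps = (double)epochs * (double)n_tokens + 1.0;
  double processed = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      IntegerVector walk = walks[w];
      int L = walk.size();
      for (int t = 0; t < L; ++t) {
        processed += 1.0;
        double lr = lr_init * std::max(1.0 - processed / total_steps, 1e-4);
        int center = walk[t] - 1;
        int lo = std::max(0, t - window), hi = std::min(L - 1, t + window);
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          int ctx = walk[c] - 1;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              double u = unif_rand() * tot;
              target = (int)(std::upper_bound(cum.begin(), cum.end(), u) -
                             cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* wc = &win[(size_t)center * dim];
            double* wt = &wout[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += wc[d] * wt[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * wt[d];
              wt[d] += g * wc[d];
            }
          }
          double* wc = &win[(size_t)center * dim];
          for (int d = 0; d < dim; ++d) wc[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix Win(n_nodes, dim), Wout(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) {
      Win(i, d) = win[(size_t)i * dim + d];
      Wout(i, d) = wout[(size_t)i * dim + d];
    }
  return List::create(_["in"] = Win, _["out"] = Wout);
}
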