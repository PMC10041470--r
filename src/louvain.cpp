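// Greedy generalized-Louvain maximization of a dense modularity quality
// matrix B (supra-node representation of a multilayer network).  The
// objective is sum_{ij} B(i,j) * [g_i == g_j] / twomu; B already contains
// the per-layer null model and the interlayer coupling terms, so the same
// engine serves single- and multilayer problems.
//
// Determinism: node visit order is reshuffled each pass with an explicit
// mt19937 stream seeded from R, so identical seeds give identical labels on
// every platform.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>
#include <algorithm>

using namespace Rcpp;

namespace {

// One Louvain level: greedy node moves until no move improves the summed
// same-community weight by more than tol.  Ties (including "no better than
// current") keep the current community.  Returns true if any move was made.
bool one_level(const std::vector<double> &B, int n, std::vector<int> &g,
               std::mt19937 &rng, double tol, int max_pass) {
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  std::vector<double> gain(n, 0.0);
  std::vector<int> touched;
  touched.reserve(n);
  bool any_move = false;
  for (int pass = 0; pass < max_pass; ++pass) {
    std::shuffle(order.begin(), order.end(), rng);
    bool moved = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      touched.clear();
      const double *row = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double w = row[j];
        if (w == 0.0) continue;
        int c = g[j];
        if (gain[c] == 0.0) touched.push_back(c);
        gain[c] += w;
      }
      int cur = g[i];
      double cur_gain = gain[cur];
      int best = cur;
      double best_gain = cur_gain;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (gain[c] > best_gain + tol) {
          best = c;
          best_gain = gain[c];
        }
        gain[c] = 0.0;           // reset for next node
      }
      gain[cur] = 0.0;
      // detaching into a fresh singleton community has gain 0; take it when
      // every alternative (including staying) is strictly worse
      if (best_gain < -tol) {
        int fresh = -1;
        for (int c = 0; c < n; ++c) {
          bool used = false;
          for (int j = 0; j < n; ++j) if (g[j] == c) { used = true; break; }
          if (!used) { fresh = c; break; }
        }
        if (fresh >= 0 && 0.0 > best_gain + tol) {
          best = fresh;
          best_gain = 0.0;
        }
      }
      if (best != cur) {
        g[i] = best;
        moved = true;
        any_move = true;
      }
    }
    if (!moved) break;
  }
  return any_move;
}

// Relabel communities to 0..C-1 preserving first-appearance order.
int compress_labels(std::vector<int> &g) {
  std::vector<int> map(g.size(), -1);
  int next = 0;
  for (size_t i = 0; i < g.size(); ++i) {
    if (map[g[i]] < 0) map[g[i]] = next++;
    g[i] = map[g[i]];
  }
  return next;
}

} // namespace

// [[Rcpp::export(name = ".louvain_dense")]]
List louvain_dense(NumericMatrix B_, double twomu, int seed,
                   double tol = 1e-10, int max_pass = 100,
                   bool random_init = false) {
  int n0 = B_.nrow();
  if (n0 != B_.ncol()) stop("B must be square");
  if (twomu <= 0) stop("twomu must be positive");

  std::vector<double> B0(B_.begin(), B_.end()); // symmetric: col-major == row-major
  std::mt19937 rng(static_cast<unsigned>(seed));

  // One complete hierarchical run; returns the final labels and Q.
  auto run_once = [&](bool rand_start, std::vector<int> &labels_out) {
    std::vector<double> B = B0;
    int n = n0;
    std::vector<int> node2comm(n0);
    std::iota(node2comm.begin(), node2comm.end(), 0);
    for (int level = 0; level < 64; ++level) {
      std::vector<int> g(n);
      std::iota(g.begin(), g.end(), 0);
      if (rand_start && level == 0 && n > 1) {
        // restart diversification: seed the greedy phase from a random
        // partition so independent restarts explore different basins
        std::uniform_int_distribution<int> ng(2, n);
        int groups = ng(rng);
        std::uniform_int_distribution<int> pick(0, groups - 1);
        for (int i = 0; i < n; ++i) g[i] = pick(rng);
        compress_labels(g);
      }
      bool moved = one_level(B, n, g, rng, tol, max_pass);
      if (!moved && !(rand_start && level == 0)) break;
      int C = compress_labels(g);
      for (int i = 0; i < n0; ++i) node2comm[i] = g[node2comm[i]];
      // aggregate B into C x C (diagonal keeps internal weight)
      std::vector<double> Bagg((size_t)C * C, 0.0);
      for (int i = 0; i < n; ++i) {
        const double *row = &B[(size_t)i * n];
        int ci = g[i];
        for (int j = 0; j < n; ++j) {
          double w = row[j];
          if (w != 0.0) Bagg[(size_t)ci * C + g[j]] += w;
        }
      }
      B.swap(Bagg);
      n = C;
      if (C == 1) break;
    }
    double qsum = 0.0;
    for (int c = 0; c < n; ++c) qsum += B[(size_t)c * n + c];
    labels_out = node2comm;
    return qsum / twomu;
  };

  std::vector<int> labels_a;
  double q = run_once(false, labels_a);
  if (random_init) {
    // a random-start pass can escape basins the singleton start cannot;
    // keep whichever hierarchy scores higher
    std::vector<int> labels_b;
    double qb = run_once(true, labels_b);
    if (qb > q + tol) { q = qb; labels_a.swap(labels_b); }
  }

  IntegerVector labels(n0);
  for (int i = 0; i < n0; ++i) labels[i] = labels_a[i] + 1; // 1-based
  return List::create(_["labels"] = labels, _["Q"] = q);
}

// Same-community weight sum of a labeling (used by the R-side modularity
// evaluation on large supra matrices).
// [[Rcpp::export(name = ".partition_weight")]]
double partition_weight(NumericMatrix B_, IntegerVector labels) {
  int n = B_.nrow();
  if (labels.size() != n) stop("labels must cover every supra node");
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (labels[i] == labels[j]) s += B_(i, j);
  return s;
}
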