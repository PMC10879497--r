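// Weighted Louvain community detection with a resolution parameter and a
// single-node fine-tuning pass, operating on dense symmetric matrices with
// zero diagonal (the scale of interest is ~10^2 nodes, so dense is right).
//
// Quality function:
//   Q(gamma) = (1/2m) * sum_ij [ W_ij - gamma * k_i * k_j / (2m) ] delta(c_i, c_j)
// with the i == j null term included (W_ii is zero on input graphs; aggregated
// graphs carry self-loops).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static double quality(const std::vector<double>& W, int n,
                      const std::vector<double>& self_w,
                      const std::vector<int>& comm,
                      const std::vector<double>& k,
                      double two_m, double gamma) {
  // sum over communities: (in-weight)/2m - gamma * (tot/2m)^2
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, comm[i] + 1);
  std::vector<double> w_in(nc, 0.0), tot(nc, 0.0);
  for (int i = 0; i < n; ++i) {
    tot[comm[i]] += k[i];
    w_in[comm[i]] += self_w[i];
    const double* wi = &W[(size_t)i * n];
    for (int j = 0; j < n; ++j)
      if (comm[j] == comm[i]) w_in[comm[i]] += wi[j];
  }
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += w_in[c] / two_m - gamma * (tot[c] / two_m) * (tot[c] / two_m);
  return q;
}

// one full local-moving phase; returns true if any node moved.
// order: node visiting order. comm modified in place (labels 0..n-1, possibly
// with gaps).
static bool local_move(const std::vector<double>& W, int n,
                       const std::vector<double>& self_w,
                       std::vector<int>& comm,
                       const std::vector<double>& k,
                       double two_m, double gamma,
                       const std::vector<int>& order) {
  std::vector<double> tot(n, 0.0);
  std::vector<int> csize(n, 0);
  for (int i = 0; i < n; ++i) { tot[comm[i]] += k[i]; csize[comm[i]] += 1; }
  std::vector<double> link(n, 0.0);   // weight from node to community
  std::vector<int> touched;
  touched.reserve(n);
  bool any_move = false;
  bool improved = true;
  const double eps = 1e-12;
  while (improved) {
    improved = false;
    for (int idx = 0; idx < n; ++idx) {
      int i = order[idx];
      int ci = comm[i];
      const double* wi = &W[(size_t)i * n];
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i || wi[j] == 0.0) continue;
        int cj = comm[j];
        if (link[cj] == 0.0) touched.push_back(cj);
        link[cj] += wi[j];
      }
      // remove i from its community
      tot[ci] -= k[i];
      csize[ci] -= 1;
      double base = link[ci] - gamma * k[i] * tot[ci] / two_m; // gain of staying
      double best_gain = base;
      int best_c = ci;
      for (int t = 0; t < (int)touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double gain = link[c] - gamma * k[i] * tot[c] / two_m;
        if (gain > best_gain + eps) { best_gain = gain; best_c = c; }
      }
      // splitting out into an empty community has gain 0
      if (0.0 > best_gain + eps && csize[ci] > 0) {
        for (int c = 0; c < n; ++c) {
          if (csize[c] == 0) { best_gain = 0.0; best_c = c; break; }
        }
      }
      comm[i] = best_c;
      tot[best_c] += k[i];
      csize[best_c] += 1;
      if (best_c != ci) { improved = true; any_move = true; }
      for (int t = 0; t < (int)touched.size(); ++t) link[touched[t]] = 0.0;
    }
  }
  return any_move;
}

static void relabel_contiguous(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
}

// full Louvain: local moving + aggregation until stable, seeded sweep order;
// `init` (labels on the original nodes, 0-based contiguous) seeds the first
// level, so a previously fine-tuned partition can be improved further
static std::vector<int> louvain_core(const std::vector<double>& W0, int n0,
                                     double gamma, std::mt19937& rng,
                                     const std::vector<int>* init = nullptr) {
  std::vector<double> W = W0;
  int n = n0;
  std::vector<double> self_w(n, 0.0);
  std::vector<int> node_of(n0);              // current level community of each original node
  for (int i = 0; i < n0; ++i) node_of[i] = i;

  double two_m = 0.0;
  for (size_t t = 0; t < W.size(); ++t) two_m += W[t];
  if (two_m <= 0.0) stop("empty graph: matrix has no positive edge weight");

  bool first_level = true;
  while (true) {
    std::vector<double> k(n, 0.0);
    for (int i = 0; i < n; ++i) {
      const double* wi = &W[(size_t)i * n];
      double s = self_w[i];
      for (int j = 0; j < n; ++j) s += wi[j];
      k[i] = s;
    }
    std::vector<int> comm(n);
    if (first_level && init != nullptr) {
      comm = *init;
    } else {
      for (int i = 0; i < n; ++i) comm[i] = i;
    }
    first_level = false;
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::shuffle(order.begin(), order.end(), rng);

    bool moved = local_move(W, n, self_w, comm, k, two_m, gamma, order);
    relabel_contiguous(comm);
    int nc = *std::max_element(comm.begin(), comm.end()) + 1;
    for (int i = 0; i < n0; ++i) node_of[i] = comm[node_of[i]];
    if (!moved || nc == n) break;

    // aggregate: community graph with self-loops
    std::vector<double> Wa((size_t)nc * nc, 0.0);
    std::vector<double> self_a(nc, 0.0);
    for (int i = 0; i < n; ++i) {
      self_a[comm[i]] += self_w[i];
      const double* wi = &W[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (wi[j] == 0.0) continue;
        if (comm[i] == comm[j]) {
          if (i < j) self_a[comm[i]] += 2.0 * wi[j]; // both directions
        } else {
          Wa[(size_t)comm[i] * nc + comm[j]] += wi[j];
        }
      }
    }
    W.swap(Wa);
    self_w.swap(self_a);
    n = nc;
  }
  relabel_contiguous(node_of);
  return node_of;
}

// deterministic single-node fine-tuning on the original graph
static void finetune_core(const std::vector<double>& W, int n,
                          std::vector<int>& comm, double gamma, double two_m) {
  std::vector<double> self_w(n, 0.0);
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double* wi = &W[(size_t)i * n];
    for (int j = 0; j < n; ++j) k[i] += wi[j];
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  local_move(W, n, self_w, comm, k, two_m, gamma, order);
  relabel_contiguous(comm);
}

// one repetition of the full procedure: Louvain, then alternate fine-tuning
// and re-aggregation from the fine-tuned partition until Q stops improving
static std::vector<int> louvain_rep(const std::vector<double>& Wv, int n,
                                    double gamma, std::mt19937& rng,
                                    double two_m, bool finetune,
                                    const std::vector<int>* init = nullptr) {
  std::vector<int> comm = louvain_core(Wv, n, gamma, rng, init);
  if (!finetune) return comm;
  std::vector<double> self_w(n, 0.0);
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += Wv[(size_t)i * n + j];
  for (int iter = 0; iter < 100; ++iter) {
    finetune_core(Wv, n, comm, gamma, two_m);
    double q_f = quality(Wv, n, self_w, comm, k, two_m, gamma);
    std::vector<int> comm2 = comm;
    comm2 = louvain_core(Wv, n, gamma, rng, &comm);
    double q2 = quality(Wv, n, self_w, comm2, k, two_m, gamma);
    if (q2 > q_f + 1e-12) {
      comm = comm2;
    } else {
      break;
    }
  }
  return comm;
}

static std::vector<double> as_vec(const NumericMatrix& W) {
  int n = W.nrow();
  std::vector<double> v((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      v[(size_t)i * n + j] = W(i, j);
  return v;
}

static double total_weight(const std::vector<double>& W) {
  double s = 0.0;
  for (size_t t = 0; t < W.size(); ++t) s += W[t];
  return s;
}

// [[Rcpp::export(name = ".louvain_cpp")]]
List louvain_cpp(NumericMatrix W, double gamma, int seed, bool finetune = true,
                 Rcpp::Nullable<IntegerVector> init = R_NilValue) {
  int n = W.nrow();
  std::vector<double> Wv = as_vec(W);
  double two_m = total_weight(Wv);
  if (two_m <= 0.0) stop("empty graph: matrix has no positive edge weight");
  std::mt19937 rng((unsigned)seed);
  std::vector<int> comm;
  if (init.isNotNull()) {
    IntegerVector iv(init);
    if ((int)iv.size() != n) stop("init: wrong length");
    std::vector<int> c0(n);
    for (int i = 0; i < n; ++i) c0[i] = iv[i] - 1;
    relabel_contiguous(c0);
    comm = louvain_rep(Wv, n, gamma, rng, two_m, finetune, &c0);
  } else {
    comm = louvain_rep(Wv, n, gamma, rng, two_m, finetune);
  }
  std::vector<double> self_w(n, 0.0);
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += Wv[(size_t)i * n + j];
  double q = quality(Wv, n, self_w, comm, k, two_m, gamma);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = comm[i] + 1;
  return List::create(_["labels"] = labels, _["q"] = q);
}

// [[Rcpp::export(name = ".finetune_cpp")]]
List finetune_cpp(NumericMatrix W, IntegerVector labels0, double gamma) {
  int n = W.nrow();
  std::vector<double> Wv = as_vec(W);
  double two_m = total_weight(Wv);
  if (two_m <= 0.0) stop("empty graph: matrix has no positive edge weight");
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = labels0[i] - 1;
  relabel_contiguous(comm);
  finetune_core(Wv, n, comm, gamma, two_m);
  std::vector<double> self_w(n, 0.0);
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += Wv[(size_t)i * n + j];
  double q = quality(Wv, n, self_w, comm, k, two_m, gamma);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = comm[i] + 1;
  return List::create(_["labels"] = labels, _["q"] = q);
}

// [[Rcpp::export(name = ".modularity_q_cpp")]]
double modularity_q_cpp(NumericMatrix W, IntegerVector labels, double gamma) {
  int n = W.nrow();
  std::vector<double> Wv = as_vec(W);
  double two_m = total_weight(Wv);
  if (two_m <= 0.0) stop("empty graph: matrix has no positive edge weight");
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = labels[i] - 1;
  relabel_contiguous(comm);
  std::vector<double> self_w(n, 0.0);
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += Wv[(size_t)i * n + j];
  return quality(Wv, n, self_w, comm, k, two_m, gamma);
}

// many independent seeded runs; rows of the result are repetitions
// [[Rcpp::export(name = ".repeated_louvain_cpp")]]
List repeated_louvain_cpp(NumericMatrix W, double gamma, IntegerVector seeds) {
  int n = W.nrow();
  int r = seeds.size();
  std::vector<double> Wv = as_vec(W);
  double two_m = total_weight(Wv);
  if (two_m <= 0.0) stop("empty graph: matrix has no positive edge weight");
  std::vector<double> self_w(n, 0.0);
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += Wv[(size_t)i * n + j];
  IntegerMatrix labels(r, n);
  NumericVector qs(r);
  for (int rep = 0; rep < r; ++rep) {
    std::mt19937 rng((unsigned)seeds[rep]);
    std::vector<int> comm = louvain_rep(Wv, n, gamma, rng, two_m, true);
    qs[rep] = quality(Wv, n, self_w, comm, k, two_m, gamma);
    for (int i = 0; i < n; ++i) labels(rep, i) = comm[i] + 1;
  }
  return List::create(_["labels"] = labels, _["q"] = qs);
}

// co-assignment fractions over repetitions (rows of `labels`)
// [[Rcpp::export(name = ".agreement_cpp")]]
NumericMatrix agreement_cpp(IntegerMatrix labels) {
  int r = labels.nrow(), n = labels.ncol();
  NumericMatrix D(n, n);
  for (int rep = 0; rep < r; ++rep) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (labels(rep, i) == labels(rep, j)) { D(i, j) += 1.0; D(j, i) += 1.0; }
  }
  for (int i = 0; i < n; ++i) {
    D(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) { D(i, j) /= r; D(j, i) /= r; }
  }
  return D;
}
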