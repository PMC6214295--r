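#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Hyperbolic law of cosines between precomputed node terms.
static inline double hdist(double chi, double shi, double ci, double si,
                           double chj, double shj, double cj, double sj) {
  double arg = chi * chj - shi * shj * (ci * cj + si * sj);
  if (arg < 1.0) arg = 1.0;
  return std::acosh(arg);
}

static inline double fermi(double x, double R, double T) {
  if (T == 0.0) return x < R ? 1.0 : (x > R ? 0.0 : 0.5);
  return 1.0 / (1.0 + std::exp((x - R) / (2.0 * T)));
}

struct NodeTerms {
  std::vector<double> ch, sh, c, s;
  NodeTerms(const NumericVector& r, const NumericVector& theta) {
    int n = r.size();
    ch.resize(n); sh.resize(n); c.resize(n); s.resize(n);
    for (int i = 0; i < n; ++i) {
      ch[i] = std::cosh(r[i]);
      sh[i] = std::sinh(r[i]);
      c[i] = std::cos(theta[i]);
      s[i] = std::sin(theta[i]);
    }
  }
};

// [[Rcpp::export]]
NumericVector cpp_expected_degrees(NumericVector r, NumericVector theta,
                                   double R, double T) {
  int n = r.size();
  NodeTerms t(r, theta);
  NumericVector k(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double x = hdist(t.ch[i], t.sh[i], t.c[i], t.s[i],
                       t.ch[j], t.sh[j], t.c[j], t.s[j]);
      double p = fermi(x, R, T);
      k[i] += p;
      k[j] += p;
    }
  }
  return k;
}

// [[Rcpp::export]]
double cpp_mean_expected_degree(NumericVector r, NumericVector theta,
                                double R, double T) {
  int n = r.size();
  NodeTerms t(r, theta);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double x = hdist(t.ch[i], t.sh[i], t.c[i], t.s[i],
                       t.ch[j], t.sh[j], t.c[j], t.s[j]);
      acc += fermi(x, R, T);
    }
  }
  return 2.0 * acc / n;
}

// Bernoulli edge sampling of the static model; uses R's RNG so results are
// reproducible from set.seed(). Returns a 2-column matrix of 1-based ids.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_psm_edges(NumericVector r, NumericVector theta,
                                   double R, double T) {
  int n = r.size();
  NodeTerms t(r, theta);
  std::vector<int> ea, eb;
  ea.reserve(16 * n);
  eb.reserve(16 * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double x = hdist(t.ch[i], t.sh[i], t.c[i], t.s[i],
                       t.ch[j], t.sh[j], t.c[j], t.s[j]);
      double p = fermi(x, R, T);
      if (unif_rand() < p) {
        ea.push_back(i + 1);
        eb.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ea.size(), 2);
  for (size_t e = 0; e < ea.size(); ++e) {
    out(e, 0) = ea[e];
    out(e, 1) = eb[e];
  }
  return out;
}

// Pairwise hyperbolic distances binned into equal-width windows, with the
// fraction of connected pairs per window. adjacency given in CSR form
// (0-based). Two O(N^2) passes: range, then histogram.
// [[Rcpp::export]]
List cpp_connection_bins(NumericVector r, NumericVector theta,
                         IntegerVector ptr, IntegerVector idx, int n_bins) {
  int n = r.size();
  NodeTerms t(r, theta);
  // adjacency membership test via sorted neighbour lists
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    for (int k = ptr[i]; k < ptr[i + 1]; ++k) nb[i].push_back(idx[k]);
    std::sort(nb[i].begin(), nb[i].end());
  }
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double x = hdist(t.ch[i], t.sh[i], t.c[i], t.s[i],
                       t.ch[j], t.sh[j], t.c[j], t.s[j]);
      if (x < lo) lo = x;
      if (x > hi) hi = x;
    }
  }
  double width = (hi - lo) / n_bins;
  if (width <= 0.0) width = 1.0;
  NumericVector total(n_bins), conn(n_bins);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double x = hdist(t.ch[i], t.sh[i], t.c[i], t.s[i],
                       t.ch[j], t.sh[j], t.c[j], t.s[j]);
      int b = (int)((x - lo) / width);
      if (b >= n_bins) b = n_bins - 1;
      if (b < 0) b = 0;
      total[b] += 1.0;
      bool linked = std::binary_search(nb[i].begin(), nb[i].end(), j);
      if (linked) conn[b] += 1.0;
    }
  }
  return List::create(_["min"] = lo, _["max"] = hi,
                      _["total"] = total, _["connected"] = conn);
}

// Greedy routing of many source-target pairs. Each node forwards to the
// neighbour hyperbolically closest to the target (ties to the lowest vertex
// index); forwarding to a visited or faulty node fails the routing.
// Returns per-pair success flag and greedy hop count (NA on failure).
// [[Rcpp::export]]
List cpp_route_batch(IntegerVector ptr, IntegerVector idx,
                     NumericVector r, NumericVector theta,
                     IntegerVector sources, IntegerVector targets,
                     LogicalVector faulty) {
  int n = r.size();
  int m = sources.size();
  NodeTerms t(r, theta);
  std::vector<int> stamp(n, -1);
  LogicalVector success(m);
  IntegerVector hops(m);
  for (int q = 0; q < m; ++q) {
    int src = sources[q], tgt = targets[q];
    int u = src;
    stamp[u] = q;
    int h = 0;
    bool ok = false;
    while (true) {
      // best neighbour of u by distance to target
      int best = -1;
      double bestd = R_PosInf;
      for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
        int v = idx[k];
        double d;
        if (v == tgt) {
          d = 0.0;
        } else {
          d = hdist(t.ch[v], t.sh[v], t.c[v], t.s[v],
                    t.ch[tgt], t.sh[tgt], t.c[tgt], t.s[tgt]);
        }
        if (d < bestd) {
          bestd = d;
          best = v;
        }
      }
      if (best < 0) break;               // isolated node: failure
      ++h;
      if (best == tgt) { ok = true; break; }
      if (faulty[best]) break;           // dropped by a faulty relay
      if (stamp[best] == q) break;       // loop: revisited node
      stamp[best] = q;
      u = best;
      if (h > n) break;                  // defensive; cannot trigger
    }
    success[q] = ok;
    hops[q] = ok ? h : NA_INTEGER;
  }
  return List::create(_["success"] = success, _["hops"] = hops);
}

// Unweighted shortest-path lengths for a list of pairs (BFS with early exit).
// [[Rcpp::export]]
IntegerVector cpp_bfs_pairs(IntegerVector ptr, IntegerVector idx,
                            IntegerVector sources, IntegerVector targets) {
  int n = ptr.size() - 1;
  int m = sources.size();
  IntegerVector out(m);
  std::vector<int> dist(n), stamp(n, -1);
  std::vector<int> queue(n);
  for (int q = 0; q < m; ++q) {
    int src = sources[q], tgt = targets[q];
    if (src == tgt) { out[q] = 0; continue; }
    int head = 0, tail = 0;
    queue[tail++] = src;
    stamp[src] = q;
    dist[src] = 0;
    int found = NA_INTEGER;
    while (head < tail) {
      int u = queue[head++];
      for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
        int v = idx[k];
        if (stamp[v] == q) continue;
        stamp[v] = q;
        dist[v] = dist[u] + 1;
        if (v == tgt) { found = dist[v]; head = tail; break; }
        queue[tail++] = v;
      }
    }
    out[q] = found;
  }
  return out;
}
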