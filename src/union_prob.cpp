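#include <Rcpp.h>
#include <cstdint>
#include <functional>
#include <map>
#include <vector>

using namespace Rcpp;

// Exact probability of a union of path events by Shannon expansion.
// Each path event is a conjunction of independent Bernoulli edge variables;
// edges are shared across paths. Sets are bitsets over the involved edges.

typedef std::vector<uint64_t> bits;

static inline bool bits_empty(const bits &b) {
  for (uint64_t w : b) if (w) return false;
  return true;
}

static double prod_prob(const bits &b, const std::vector<double> &p, int m) {
  double out = 1.0;
  for (int e = 0; e < m; ++e) {
    if (b[e >> 6] & (uint64_t(1) << (e & 63))) out *= p[e];
  }
  return out;
}

static double rec(std::vector<bits> sets, const std::vector<double> &p,
                  int m) {
  size_t n = sets.size();
  if (n == 0) return 0.0;
  for (const bits &s : sets) {
    if (bits_empty(s)) return 1.0;  // empty conjunction: certain event
  }
  if (n == 1) return prod_prob(sets[0], p, m);
  // edge usage counts
  std::vector<int> count(m, 0);
  for (const bits &s : sets) {
    for (int e = 0; e < m; ++e) {
      if (s[e >> 6] & (uint64_t(1) << (e & 63))) ++count[e];
    }
  }
  int pivot = 0, best = 0;
  for (int e = 0; e < m; ++e) {
    if (count[e] > best) { best = count[e]; pivot = e; }
  }
  if (best <= 1) {
    // pairwise edge-disjoint events: independence closed form
    double q = 1.0;
    for (const bits &s : sets) q *= 1.0 - prod_prob(s, p, m);
    return 1.0 - q;
  }
  if (n == 2) {
    double p1 = prod_prob(sets[0], p, m);
    double p2 = prod_prob(sets[1], p, m);
    bits u(sets[0]);
    for (size_t w = 0; w < u.size(); ++w) u[w] |= sets[1][w];
    return p1 + p2 - prod_prob(u, p, m);
  }
  const size_t word = pivot >> 6;
  const uint64_t mask = uint64_t(1) << (pivot & 63);
  std::vector<bits> present;
  std::vector<bits> absent;
  present.reserve(n);
  absent.reserve(n);
  for (const bits &s : sets) {
    if (s[word] & mask) {
      bits t(s);
      t[word] &= ~mask;
      present.push_back(std::move(t));
    } else {
      present.push_back(s);
      absent.push_back(s);
    }
  }
  double pe = p[pivot];
  return pe * rec(std::move(present), p, m) +
         (1.0 - pe) * rec(std::move(absent), p, m);
}

// [[Rcpp::export(name = ".union_prob_shannon")]]
double union_prob_shannon(List sets, NumericVector probs) {
  int n = sets.size();
  if (n == 0) return 0.0;
  // compact the involved edges
  std::vector<int> edges;
  std::vector<std::vector<int>> idx(n);
  std::map<int, int> remap;
  for (int i = 0; i < n; ++i) {
    IntegerVector s = sets[i];
    if (s.size() == 0) return 1.0;
    idx[i].reserve(s.size());
    for (int j = 0; j < s.size(); ++j) {
      int e = s[j];
      auto it = remap.find(e);
      int c;
      if (it == remap.end()) {
        c = (int)edges.size();
        remap[e] = c;
        edges.push_back(e);
      } else {
        c = it->second;
      }
      idx[i].push_back(c);
    }
  }
  int m = (int)edges.size();
  if (m > 4096) stop("union computation refused: %d involved edges", m);
  std::vector<double> p(m);
  for (int e = 0; e < m; ++e) {
    double pe = probs[edges[e] - 1];
    if (ISNAN(pe) || pe < 0.0 || pe > 1.0)
      stop("edge probability out of [0, 1]");
    p[e] = pe;
  }
  int words = (m + 63) / 64;
  std::vector<bits> bsets(n, bits(words, 0));
  for (int i = 0; i < n; ++i) {
    for (int c : idx[i]) bsets[i][c >> 6] |= uint64_t(1) << (c & 63);
  }
  // edge-disjoint groups of paths are independent factors: split into
  // connected components (union-find over path indices, linked via the
  // first carrier of each edge)
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  std::vector<int> first_seen(m, -1);
  for (int i = 0; i < n; ++i) {
    for (int c : idx[i]) {
      if (first_seen[c] < 0) {
        first_seen[c] = i;
      } else {
        int ra = find(first_seen[c]), rb = find(i);
        if (ra != rb) parent[rb] = ra;
      }
    }
  }
  std::map<int, std::vector<bits>> groups;
  for (int i = 0; i < n; ++i) {
    groups[find(i)].push_back(std::move(bsets[i]));
  }
  double q = 1.0;
  for (auto &kv : groups) {
    q *= 1.0 - rec(std::move(kv.second), p, m);
  }
  return 1.0 - q;
}
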