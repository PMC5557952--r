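#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// Self-contained RNG (splitmix64-seeded xorshift-star family) so that
// cascade estimates are bit-reproducible across platforms and independent
// of R's global RNG state. Each (master seed, node id) pair gets its own
// stream, making per-node coverage independent of evaluation order.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t fnv1a(const std::string &s) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (unsigned char c : s) {
    h ^= c;
    h *= 0x100000001B3ULL;
  }
  return h;
}

struct Stream {
  uint64_t s;
  explicit Stream(uint64_t seed) : s(seed) {
    for (int i = 0; i < 4; ++i) splitmix64(s); // warm up
  }
  double unif() {
    // 53-bit uniform in [0, 1)
    return (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
  }
};

static uint64_t stream_seed(double master_seed, const std::string &node_id) {
  uint64_t s = static_cast<uint64_t>(static_cast<int64_t>(master_seed));
  return s ^ (fnv1a(node_id) * 0x9E3779B97F4A7C15ULL);
}

// Independent Cascade realizations seeded at `seed_idx` (0-based).
// Returns c(mean coverage, sample variance) over n_sim replicates.
// Each newly activated node attempts each out-edge once; attempts into
// already-active targets are skipped.
// [[Rcpp::export]]
Rcpp::NumericVector ic_coverage_stats(Rcpp::IntegerVector src,
                                      Rcpp::IntegerVector dst,
                                      Rcpp::NumericVector w,
                                      int n_nodes, int seed_idx, int n_sim,
                                      double master_seed,
                                      std::string node_id) {
  const int m = src.size();
  // CSR-style out-adjacency
  std::vector<int> head(n_nodes + 1, 0), adj(m), eidx(m);
  for (int e = 0; e < m; ++e) head[src[e] + 1]++;
  for (int v = 0; v < n_nodes; ++v) head[v + 1] += head[v];
  {
    std::vector<int> pos(head.begin(), head.end() - 1);
    for (int e = 0; e < m; ++e) {
      adj[pos[src[e]]] = dst[e];
      eidx[pos[src[e]]++] = e;
    }
  }
  Stream rng(stream_seed(master_seed, node_id));
  std::vector<uint8_t> active(n_nodes);
  std::vector<int> frontier;
  frontier.reserve(n_nodes);
  double sum = 0.0, sumsq = 0.0;
  for (int rep = 0; rep < n_sim; ++rep) {
    std::fill(active.begin(), active.end(), 0);
    active[seed_idx] = 1;
    frontier.clear();
    frontier.push_back(seed_idx);
    int covered = 0;
    for (size_t f = 0; f < frontier.size(); ++f) { // FIFO breadth order
      int v = frontier[f];
      for (int k = head[v]; k < head[v + 1]; ++k) {
        int u = adj[k];
        if (active[u]) continue;
        if (rng.unif() < w[eidx[k]]) {
          active[u] = 1;
          ++covered;
          frontier.push_back(u);
        }
      }
    }
    sum += covered;
    sumsq += static_cast<double>(covered) * covered;
  }
  double mean = sum / n_sim;
  double var = n_sim > 1 ? (sumsq - n_sim * mean * mean) / (n_sim - 1) : 0.0;
  if (var < 0) var = 0;
  return Rcpp::NumericVector::create(mean, var);
}
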