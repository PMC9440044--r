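#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-independent PRNG for update schedules.
// splitmix64: passes BigCrush for this use (shuffling), trivial state.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Unbiased bounded draw (Lemire with rejection); exact, no libc dependence.
static inline uint64_t bounded(uint64_t &state, uint64_t n) {
  uint64_t threshold = (-n) % n;
  for (;;) {
    uint64_t r = splitmix64(state);
    __uint128_t m = (__uint128_t)r * (__uint128_t)n;
    uint64_t lo = (uint64_t)m;
    if (lo >= threshold) return (uint64_t)(m >> 64);
  }
}

static inline void shuffle_vec(std::vector<int> &v, uint64_t &state) {
  for (size_t i = v.size(); i > 1; --i) {
    size_t j = (size_t)bounded(state, (uint64_t)i);
    std::swap(v[i - 1], v[j]);
  }
}

// Compressed adjacency built once per network.
struct Adj {
  std::vector<int> ptr;  // n + 1
  std::vector<int> nbr;  // 2 * m
};

static Adj build_adj(int n, const IntegerMatrix &edges) {
  Adj a;
  int m = edges.nrow();
  a.ptr.assign(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    a.ptr[edges(e, 0) + 1]++;
    a.ptr[edges(e, 1) + 1]++;
  }
  for (int i = 0; i < n; ++i) a.ptr[i + 1] += a.ptr[i];
  a.nbr.assign(a.ptr[n], 0);
  std::vector<int> fill(a.ptr.begin(), a.ptr.end() - 1);
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    a.nbr[fill[u]++] = v;
    a.nbr[fill[v]++] = u;
  }
  return a;
}

// One asynchronous cascade to its fixed point.
// labels: in/out, seeds pre-set according to the input pattern and clamped
// (never examined).  Sweeps visit the still-unlabelled non-seed nodes in a
// fresh random permutation, labelling immediately; stops when a full sweep
// labels nothing.  Returns number of sweeps performed.
static int run_sweeps(const Adj &adj, const NumericVector &phi,
                      const LogicalVector &antag,
                      std::vector<uint8_t> &labels,
                      std::vector<int> &lcount,
                      std::vector<int> &active, uint64_t &rng,
                      std::vector<int> *trace_sweep,
                      std::vector<int> *trace_node) {
  int sweeps = 0;
  bool changed = true;
  while (changed && !active.empty()) {
    ++sweeps;
    changed = false;
    shuffle_vec(active, rng);
    size_t keep = 0;
    for (size_t idx = 0; idx < active.size(); ++idx) {
      int u = active[idx];
      int deg = adj.ptr[u + 1] - adj.ptr[u];
      double frac = deg > 0 ? (double)lcount[u] / (double)deg : 0.0;
      bool fire = antag[u] ? (frac < phi[u]) : (frac >= phi[u]);
      if (fire) {
        labels[u] = 1;
        for (int j = adj.ptr[u]; j < adj.ptr[u + 1]; ++j) lcount[adj.nbr[j]]++;
        if (trace_sweep) {
          trace_sweep->push_back(sweeps);
          trace_node->push_back(u);
        }
        changed = true;
      } else {
        active[keep++] = u;
      }
    }
    active.resize(keep);
  }
  return sweeps;
}

static void init_state(const Adj &adj, int n, const IntegerVector &seeds,
                       const LogicalVector &pattern,
                       std::vector<uint8_t> &labels, std::vector<int> &lcount,
                       std::vector<int> &active) {
  labels.assign(n, 0);
  lcount.assign(n, 0);
  std::vector<uint8_t> is_seed(n, 0);
  for (int i = 0; i < seeds.size(); ++i) is_seed[seeds[i]] = 1;
  for (int i = 0; i < seeds.size(); ++i) {
    if (pattern[i]) {
      int s = seeds[i];
      labels[s] = 1;
      for (int j = adj.ptr[s]; j < adj.ptr[s + 1]; ++j) lcount[adj.nbr[j]]++;
    }
  }
  active.clear();
  for (int u = 0; u < n; ++u)
    if (!is_seed[u]) active.push_back(u);
}

// [[Rcpp::export]]
List cascade_run_cpp(int n, IntegerMatrix edges, NumericVector phi,
                     LogicalVector antag, IntegerVector seeds,
                     LogicalVector pattern, double order_seed,
                     bool trace = false) {
  Adj adj = build_adj(n, edges);
  std::vector<uint8_t> labels;
  std::vector<int> lcount, active;
  init_state(adj, n, seeds, pattern, labels, lcount, active);
  uint64_t rng = (uint64_t)order_seed;
  std::vector<int> ts, tn;
  int sweeps = run_sweeps(adj, phi, antag, labels, lcount, active, rng,
                          trace ? &ts : nullptr, trace ? &tn : nullptr);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = labels[i] != 0;
  List res = List::create(_["labels"] = out, _["sweeps"] = sweeps);
  if (trace) {
    res["trace_sweep"] = IntegerVector(ts.begin(), ts.end());
    res["trace_node"] = IntegerVector(tn.begin(), tn.end());
  }
  return res;
}

// Run all 2^k input patterns against a frozen network and assemble, per
// node, the truth-table id of the Boolean function it computes.  Pattern x
// assigns seed i (i = 0 first) the bit (x >> (k-1-i)) & 1, i.e. the first
// seed is the most significant bit; the id packs outputs most significant
// row first so AND = 1, XOR = 6, NAND = 14 for k = 2.
// [[Rcpp::export]]
IntegerVector extract_functions_cpp(int n, IntegerMatrix edges,
                                    NumericVector phi, LogicalVector antag,
                                    IntegerVector seeds, int k,
                                    double order_seed) {
  Adj adj = build_adj(n, edges);
  int npat = 1 << k;
  std::vector<int> ids(n, 0);
  std::vector<uint8_t> labels;
  std::vector<int> lcount, active;
  uint64_t base = (uint64_t)order_seed;
  for (int x = 0; x < npat; ++x) {
    LogicalVector pattern(k);
    for (int i = 0; i < k; ++i) pattern[i] = (x >> (k - 1 - i)) & 1;
    init_state(adj, n, seeds, pattern, labels, lcount, active);
    // independent schedule stream per pattern
    uint64_t rng = base;
    for (int burn = 0; burn <= x; ++burn) splitmix64(rng);
    run_sweeps(adj, phi, antag, labels, lcount, active, rng, nullptr,
               nullptr);
    int bit = npat - 1 - x;
    for (int u = 0; u < n; ++u)
      if (labels[u]) ids[u] |= (1 << bit);
  }
  IntegerVector out(n);
  for (int u = 0; u < n; ++u) out[u] = ids[u];
  for (int i = 0; i < seeds.size(); ++i) out[seeds[i]] = NA_INTEGER;
  return out;
}
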