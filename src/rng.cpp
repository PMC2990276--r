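// Deterministic, order-independent randomness for semantic spaces.
//
// Every elemental vector and every predicate permutation is a pure function of
// (owner name, global seed): a 64-bit FNV-1a hash of the name, mixed with the
// seed, initialises a splitmix64 stream. Vectors can therefore be regenerated
// at any time without being stored, and corpus traversal order cannot affect
// the space.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t fnv1a64(const std::string& s, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL;
  for (unsigned char c : s) {
    h ^= c;
    h *= 1099511628211ULL;
  }
  // decorrelate streams that share a name but differ in seed
  h ^= seed * 0x9E3779B97F4A7C15ULL;
  h ^= h >> 33;
  h *= 0xFF51AFD7ED558CCDULL;
  h ^= h >> 33;
  return h;
}

// Draw an integer in [0, n) without modulo bias.
static inline uint64_t bounded(uint64_t& state, uint64_t n) {
  uint64_t threshold = (~n + 1) % n;  // 2^64 mod n
  for (;;) {
    uint64_t r = splitmix64(state);
    if (r >= threshold) return r % n;
  }
}

//' @noRd
// [[Rcpp::export(name = ".elemental_coords")]]
List elemental_coords_cpp(CharacterVector names, int d, int s, double global_seed) {
  if (s > d) stop("seed_count (%d) exceeds dimension (%d): infeasible sparsity", s, d);
  if (s <= 0 || s % 2 != 0) stop("seed_count must be a positive even integer");
  int n = names.size();
  IntegerMatrix coords(s, n);
  IntegerMatrix signs(s, n);
  std::vector<char> used(d);
  uint64_t seed = (uint64_t)(int64_t)global_seed;
  for (int j = 0; j < n; ++j) {
    std::string nm = as<std::string>(names[j]);
    uint64_t state = fnv1a64("elemental:" + nm, seed);
    std::fill(used.begin(), used.end(), 0);
    for (int i = 0; i < s; ++i) {
      int idx;
      do {
        idx = (int)bounded(state, (uint64_t)d);
      } while (used[idx]);
      used[idx] = 1;
      coords(i, j) = idx + 1;                  // 1-based for R
      signs(i, j) = (i % 2 == 0) ? 1 : -1;     // s even: equal +1/-1 counts
    }
  }
  return List::create(_["coords"] = coords, _["signs"] = signs);
}

//' @noRd
// [[Rcpp::export(name = ".seeded_permutation")]]
IntegerVector seeded_permutation_cpp(std::string key, int d, double global_seed) {
  uint64_t state = fnv1a64("permutation:" + key, (uint64_t)(int64_t)global_seed);
  IntegerVector p(d);
  for (int i = 0; i < d; ++i) p[i] = i + 1;
  for (int i = d - 1; i > 0; --i) {  // Fisher-Yates
    int j = (int)bounded(state, (uint64_t)(i + 1));
    std::swap(p[i], p[j]);
  }
  return p;
}
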