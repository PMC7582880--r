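// MinHash signatures over k-mer sets and a streaming locality-sensitive
// clustering of noisy reads. Signatures are banded; band keys index a hash
// table of clusters; each read is assigned to the candidate cluster whose
// representative (first member) is closest in edit distance, provided the
// distance passes a verification threshold, otherwise it founds a new
// cluster. Single-linkage merging across buckets is deliberately avoided:
// at the error rates this package targets, transitive merging through
// false bucket collisions chains unrelated clusters together.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include "rng.h"

using namespace Rcpp;

namespace {

inline int base_code2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// distinct k-mer codes of a read (2 bits per base); k <= 31
void kmer_codes(const std::string& s, int k, std::vector<uint64_t>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code2(s[i]);
    if (c < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++valid >= k) out.push_back(cur);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// H minima of seeded hash functions over the k-mer set
void minhash_one(const std::vector<uint64_t>& kmers,
                 const std::vector<uint64_t>& salts,
                 std::vector<uint64_t>& sig) {
  int H = (int)salts.size();
  sig.assign(H, ~0ULL);
  for (uint64_t km : kmers) {
    uint64_t g = mix64(km + 0x9E3779B97F4A7C15ULL);
    for (int h = 0; h < H; ++h) {
      uint64_t v = g * salts[h];
      v ^= v >> 29;
      if (v < sig[h]) sig[h] = v;
    }
  }
}

std::vector<uint64_t> make_salts(int H, uint64_t seed) {
  SplitMix64 rng(mix64(seed + 0xA5A5A5A55A5A5A5AULL));
  std::vector<uint64_t> salts(H);
  for (int h = 0; h < H; ++h) salts[h] = rng.next() | 1ULL; // odd multipliers
  return salts;
}

int myers_dist_cl(const std::string& a, const std::string& b); // fwd

// local copy of the bit-parallel distance (kept static per translation unit)
int myers_dist_cl(const std::string& a, const std::string& b) {
  int m = (int)a.size();
  if (m == 0) return (int)b.size();
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) {
    int c = base_code2(a[i]);
    Peq[c < 0 ? 0 : c] |= 1ULL << i;
  }
  uint64_t Pv = ~0ULL, Mv = 0;
  int score = m;
  uint64_t last = 1ULL << (m - 1);
  for (char ch : b) {
    int c = base_code2(ch);
    uint64_t Eq = Peq[c < 0 ? 0 : c];
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & last) ++score;
    else if (Mh & last) --score;
    Ph = (Ph << 1) | 1ULL;
    Mh <<= 1;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
  }
  return score;
}

} // namespace

// MinHash signature matrix (reads x H). Values are the 64-bit minima folded
// to 53 bits so they remain exact in R doubles. Reads shorter than k yield
// a row of NA (empty-signature sentinel).
// [[Rcpp::export]]
NumericMatrix cpp_minhash(CharacterVector reads, int k, int H, double seed) {
  int n = reads.size();
  NumericMatrix out(n, H);
  std::vector<uint64_t> salts = make_salts(H, (uint64_t)seed);
  std::vector<uint64_t> kmers, sig;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    kmer_codes(s, k, kmers);
    if (kmers.empty()) {
      for (int h = 0; h < H; ++h) out(i, h) = NA_REAL;
      continue;
    }
    minhash_one(kmers, salts, sig);
    for (int h = 0; h < H; ++h) out(i, h) = (double)(sig[h] >> 11);
  }
  return out;
}

// For each query sequence, the index (1-based) of the closest target
// sequence by edit distance, or NA when the best distance exceeds
// max_dist. Ties -> lower index. Used to attach small cluster fragments to
// the representative of a larger cluster of the same source oligo.
// [[Rcpp::export]]
IntegerVector cpp_nearest_rep(CharacterVector queries, CharacterVector targets,
                              int max_dist) {
  int nq = queries.size(), nt = targets.size();
  std::vector<std::string> ts(nt);
  for (int j = 0; j < nt; ++j) ts[j] = as<std::string>(targets[j]);
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int best = -1, best_d = max_dist + 1;
    for (int j = 0; j < nt; ++j) {
      int d = myers_dist_cl(q, ts[j]);
      if (d < best_d) {
        best_d = d;
        best = j;
      }
    }
    out[i] = best >= 0 ? best + 1 : NA_INTEGER;
  }
  return out;
}

// Streaming LSH clustering. Returns 1-based cluster ids; NA for reads
// shorter than k (discard bin). max_candidates caps the number of distinct
// clusters verified per read (bands are scanned in order).
// [[Rcpp::export]]
IntegerVector cpp_lsh_cluster(CharacterVector reads, int k, int H,
                              int bands, int rows_per_band, double seed,
                              int max_dist, int max_candidates) {
  if (bands * rows_per_band != H)
    stop("bands * rows_per_band must equal H");
  int n = reads.size();
  IntegerVector out(n);
  std::vector<uint64_t> salts = make_salts(H, (uint64_t)seed);
  std::unordered_map<uint64_t, int> key2cluster;
  key2cluster.reserve((size_t)n * bands / 2);
  std::vector<std::string> reps; // representative read per cluster
  std::vector<uint64_t> kmers, sig, keys((size_t)bands);
  std::vector<int> cand;
  cand.reserve(max_candidates);

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    kmer_codes(s, k, kmers);
    if (kmers.empty()) {
      out[i] = NA_INTEGER;
      continue;
    }
    minhash_one(kmers, salts, sig);
    for (int b = 0; b < bands; ++b) {
      uint64_t key = 0xCBF29CE484222325ULL ^ (uint64_t)b;
      for (int r = 0; r < rows_per_band; ++r) {
        key ^= sig[b * rows_per_band + r];
        key *= 0x100000001B3ULL;
      }
      keys[b] = mix64(key);
    }
    // candidate clusters, in band order, de-duplicated
    cand.clear();
    for (int b = 0; b < bands && (int)cand.size() < max_candidates; ++b) {
      auto it = key2cluster.find(keys[b]);
      if (it == key2cluster.end()) continue;
      int c = it->second;
      bool seen = false;
      for (int cc : cand)
        if (cc == c) { seen = true; break; }
      if (!seen) cand.push_back(c);
    }
    int best = -1, best_d = max_dist + 1;
    for (int c : cand) {
      int d = myers_dist_cl(s, reps[c]);
      if (d < best_d || (d == best_d && best >= 0 && c < best)) {
        best_d = d;
        best = c;
      }
    }
    int assigned;
    if (best >= 0 && best_d <= max_dist) {
      assigned = best;
    } else {
      assigned = (int)reps.size();
      reps.push_back(s);
    }
    out[i] = assigned + 1;
    // first binding wins: keys already mapped keep their cluster
    for (int b = 0; b < bands; ++b) key2cluster.emplace(keys[b], assigned);
  }
  return out;
}
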