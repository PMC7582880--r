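// Monte-Carlo read corruption for the light-directed synthesis channel:
// per-sequence Poisson counts of deletions, substitutions and insertions at
// uniform positions, a single 3' T linker appended during synthesis, and a
// C-rich (C:T) library-preparation tail filling the fixed sequencing
// window. Fully deterministic for a fixed seed; read i uses its own
// substream so results are independent of chunking.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

inline int bcode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return 0;
  }
}

// d distinct positions in [0, len), descending order
void draw_positions(SplitMix64& rng, int d, int len, std::vector<int>& pos) {
  pos.clear();
  if (d >= len) {
    for (int i = len - 1; i >= 0; --i) pos.push_back(i);
    return;
  }
  std::vector<int> idx(len);
  for (int i = 0; i < len; ++i) idx[i] = i;
  for (int i = 0; i < d; ++i) {
    int j = i + (int)rng.below(len - i);
    std::swap(idx[i], idx[j]);
  }
  pos.assign(idx.begin(), idx.begin() + d);
  std::sort(pos.begin(), pos.end(), std::greater<int>());
}

std::string corrupt_one(const std::string& oligo, SplitMix64& rng,
                        double lam_del, double lam_sub, double lam_ins,
                        double tail_c_frac, bool append_t, bool tail,
                        int window) {
  std::string s = oligo;
  std::vector<int> pos;

  // deletions
  int d = std::min(rng.poisson(lam_del), (int)s.size());
  draw_positions(rng, d, (int)s.size(), pos);
  for (int p : pos) s.erase(s.begin() + p);

  // substitutions: to a uniformly chosen *different* base
  int ns = std::min(rng.poisson(lam_sub), (int)s.size());
  draw_positions(rng, ns, (int)s.size(), pos);
  for (int p : pos) {
    int old = bcode(s[p]);
    s[p] = BASES[(old + 1 + (int)rng.below(3)) & 3];
  }

  // insertions of a uniform base at a uniform position, applied sequentially
  int ni = rng.poisson(lam_ins);
  for (int t = 0; t < ni; ++t) {
    int p = (int)rng.below(s.size() + 1);
    s.insert(s.begin() + p, BASES[rng.below(4)]);
  }

  if (append_t) s.push_back('T');

  if (window > 0) {
    if (tail)
      while ((int)s.size() < window)
        s.push_back(rng.unif() < tail_c_frac ? 'C' : 'T');
    if ((int)s.size() > window) s.resize(window);
  }
  return s;
}

} // namespace

// `sources` gives the oligo (string) for each read to generate; `ordinals`
// gives the global read ordinal used to key the per-read substream.
// window < 0 means no tail fill and no truncation (unbounded window).
// [[Rcpp::export]]
CharacterVector cpp_corrupt_reads(CharacterVector sources, IntegerVector ordinals,
                                  double lam_del, double lam_sub, double lam_ins,
                                  double tail_c_frac, bool append_t, bool tail,
                                  int window, double seed) {
  int n = sources.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t init = mix64((uint64_t)seed * 0x2545F4914F6CDD1DULL ^
                          mix64((uint64_t)(uint32_t)ordinals[i] + 0x6A09E667F3BCC909ULL));
    SplitMix64 rng(init);
    out[i] = corrupt_one(as<std::string>(sources[i]), rng, lam_del, lam_sub,
                         lam_ins, tail_c_frac, append_t, tail, window);
  }
  return out;
}
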