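// Pairwise alignment primitives: Myers bit-parallel edit distance (reads
// here are at most 64 nt, so one machine word suffices), Needleman-Wunsch
// global alignment with the fixed scoring match=+1 / mismatch=-1 / gap=-1
// and deterministic tie-breaking, center-star progressive multiple
// alignment, and unit-cost error classification against a reference.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <map>
#include <algorithm>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 0;
  }
}

// Myers (1999) bit-parallel Levenshtein distance, pattern length <= 64
int myers_dist(const std::string& a, const std::string& b) {
  int m = (int)a.size();
  if (m == 0) return (int)b.size();
  if (m > 64) Rcpp::stop("myers_dist: pattern longer than 64");
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) Peq[base_code(a[i])] |= 1ULL << i;
  uint64_t Pv = ~0ULL, Mv = 0;
  int score = m;
  uint64_t last = 1ULL << (m - 1);
  for (char c : b) {
    uint64_t Eq = Peq[base_code(c)];
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

// Global alignment, match +1 / mismatch -1 / gap -1 (linear).
// Traceback preference at equal score: diagonal, then up (gap in b),
// then left (gap in a).
void nw_align(const std::string& a, const std::string& b,
              std::string& out_a, std::string& out_b,
              int s_match = 1, int s_mismatch = -1, int s_gap = -1) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> dp((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) dp[at(i, 0)] = i * s_gap;
  for (int j = 0; j <= m; ++j) dp[at(0, j)] = j * s_gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = dp[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? s_match : s_mismatch);
      int u = dp[at(i - 1, j)] + s_gap;
      int l = dp[at(i, j - 1)] + s_gap;
      int best = s >= u ? (s >= l ? s : l) : (u >= l ? u : l);
      dp[at(i, j)] = best;
    }
  }
  out_a.clear();
  out_b.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        dp[at(i, j)] == dp[at(i - 1, j - 1)] +
          (a[i - 1] == b[j - 1] ? s_match : s_mismatch)) {
      out_a.push_back(a[i - 1]);
      out_b.push_back(b[j - 1]);
      --i; --j;
    } else if (i > 0 && dp[at(i, j)] == dp[at(i - 1, j)] + s_gap) {
      out_a.push_back(a[i - 1]);
      out_b.push_back('-');
      --i;
    } else {
      out_a.push_back('-');
      out_b.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_edit_dist(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = myers_dist(sa, sb);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b) {
  std::string ga, gb;
  nw_align(a, b, ga, gb);
  int score = 0;
  for (size_t i = 0; i < ga.size(); ++i) {
    if (ga[i] == '-' || gb[i] == '-') score -= 1;
    else score += (ga[i] == gb[i]) ? 1 : -1;
  }
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = score);
}

namespace {

// Star alignment of `rs` against an explicit (ungapped) center string:
// every read is pairwise-aligned to the center and merged into the master
// alignment under "once a gap, always a gap". `center_row` receives the
// gapped center; the returned rows follow the input order of `rs`.
std::vector<std::string> star_align(const std::string& center,
                                    const std::vector<std::string>& rs,
                                    std::string& center_row,
                                    int s_match = 1, int s_mismatch = -1,
                                    int s_gap = -1) {
  int n = (int)rs.size();
  std::vector<std::string> rows(n);
  std::string master = center; // center with accumulated gaps
  std::vector<int> done;

  for (int idx = 0; idx < n; ++idx) {
    std::string gc, gr;
    nw_align(center, rs[idx], gc, gr, s_match, s_mismatch, s_gap);
    std::string new_master, new_row;
    std::vector<std::string> new_rows(done.size());
    size_t i = 0, j = 0;
    while (i < master.size() || j < gc.size()) {
      bool mg = i < master.size() && master[i] == '-';
      bool pg = j < gc.size() && gc[j] == '-';
      if (i < master.size() && j < gc.size() && !mg && !pg) {
        new_master.push_back(master[i]);
        for (size_t t = 0; t < done.size(); ++t) new_rows[t].push_back(rows[done[t]][i]);
        new_row.push_back(gr[j]);
        ++i; ++j;
      } else if (mg && pg) {
        new_master.push_back('-');
        for (size_t t = 0; t < done.size(); ++t) new_rows[t].push_back(rows[done[t]][i]);
        new_row.push_back(gr[j]);
        ++i; ++j;
      } else if (mg) {
        new_master.push_back('-');
        for (size_t t = 0; t < done.size(); ++t) new_rows[t].push_back(rows[done[t]][i]);
        new_row.push_back('-');
        ++i;
      } else { // pg (or master exhausted)
        new_master.push_back('-');
        for (size_t t = 0; t < done.size(); ++t) new_rows[t].push_back('-');
        new_row.push_back(gr[j]);
        ++j;
      }
    }
    master = new_master;
    for (size_t t = 0; t < done.size(); ++t) rows[done[t]] = new_rows[t];
    rows[idx] = new_row;
    done.push_back(idx);
  }
  center_row = master;
  return rows;
}

} // namespace

// Center-star progressive MSA: the center is the read minimizing the total
// edit distance to all others (ties -> first in input order); every other
// read is pairwise-aligned to the ungapped center and merged into the master
// alignment under "once a gap, always a gap". Row order follows the input.
// [[Rcpp::export]]
CharacterVector cpp_center_star(CharacterVector reads) {
  int n = reads.size();
  std::vector<std::string> rs(n);
  for (int i = 0; i < n; ++i) rs[i] = as<std::string>(reads[i]);
  if (n == 1) return reads;

  // choose center
  std::vector<long> tot(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = myers_dist(rs[i], rs[j]);
      tot[i] += d;
      tot[j] += d;
    }
  int center = 0;
  for (int i = 1; i < n; ++i)
    if (tot[i] < tot[center]) center = i;

  // align the non-center reads against the center read; the center aligns
  // to itself trivially and is re-inserted at its input position
  std::vector<std::string> others;
  others.reserve(n - 1);
  for (int i = 0; i < n; ++i)
    if (i != center) others.push_back(rs[i]);
  std::string center_row;
  std::vector<std::string> rows = star_align(rs[center], others, center_row);

  CharacterVector out(n);
  int t = 0;
  for (int i = 0; i < n; ++i) {
    if (i == center) out[i] = center_row;
    else out[i] = rows[t++];
  }
  return out;
}

// Star MSA of reads against a given reference/consensus string. The first
// element of the result is the gapped center row, followed by the aligned
// reads in input order. Used for iterative consensus refinement:
// re-aligning a cluster against its current consensus makes insertion
// columns coalesce, which a noisy read center cannot do, and the center row
// marks which columns are insertions relative to the consensus.
// [[Rcpp::export]]
CharacterVector cpp_star_msa(std::string center, CharacterVector reads) {
  int n = reads.size();
  std::vector<std::string> rs(n);
  for (int i = 0; i < n; ++i) rs[i] = as<std::string>(reads[i]);
  std::string center_row;
  std::vector<std::string> rows = star_align(center, rs, center_row);
  CharacterVector out(n + 1);
  out[0] = center_row;
  for (int i = 0; i < n; ++i) out[i + 1] = rows[i];
  return out;
}

namespace {

// Myers distance of full `pattern` against the best-matching *prefix* of
// `text` (free trailing gaps on the text side). Used as the consensus-
// polishing objective: a clipped read must fit inside the consensus, but
// the consensus may extend beyond the read's reach.
int myers_semiglobal(const std::string& pattern, const std::string& text) {
  int m = (int)pattern.size();
  if (m == 0) return 0;
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) Peq[base_code(pattern[i])] |= 1ULL << i;
  uint64_t Pv = ~0ULL, Mv = 0;
  int score = m, best = m;
  uint64_t last = 1ULL << (m - 1);
  for (char c : text) {
    uint64_t Eq = Peq[base_code(c)];
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & last) ++score;
    else if (Mh & last) --score;
    if (score < best) best = score;
    Ph = (Ph << 1) | 1ULL;
    Mh <<= 1;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
  }
  return best;
}

// Clip the C/T library-prep tail of a read: remove the maximal trailing
// run of C/T characters (the synthesis linker T and the C:T fill are both
// drawn from {C, T}), capped at `max_clip`. Genuine trailing C/T bases of
// the source are clipped too; the extension stage recovers them.
std::string clip_tail(const std::string& read, int max_clip) {
  int keep = (int)read.size();
  int clipped = 0;
  while (keep > 0 && clipped < max_clip) {
    char c = read[keep - 1];
    if (c == 'C' || c == 'T') {
      --keep;
      ++clipped;
    } else {
      break;
    }
  }
  return read.substr(0, keep);
}

struct VoteResult {
  std::string cons;
};

// One consensus vote round: star-align (clipped) reads around the center,
// then per column: columns where the center has a base use the weighted
// rule (base beats gap when count >= gap_weight * gaps); insertion columns
// (center gap) require a strict majority of that column's voters. Bases
// beyond a read's clipped extent vote neither base nor gap.
// One consensus vote round with slot-pooled insertions. Columns where the
// center has a base use the weighted rule (the plurality base is emitted
// when its count >= gap_weight * gap votes; deletions are the dominant
// error, so gaps are discounted). Insertions are voted per *slot* (a
// maximal run of center-gap columns): reads frequently place the same
// inserted base in different columns of one gap run, so per-column counts
// split while the slot-level count does not. The most common non-empty
// inserted string of a slot is emitted when its support satisfies the same
// asymmetric rule against the reads that insert nothing there. Bases
// beyond a read's last aligned base vote neither base nor gap.
// A borderline indel decision of a vote round, recorded so that candidate
// *variants* can be emitted: `pos` is the position in the emitted
// consensus, `add` the string whose insertion toggles the decision (empty
// when the toggle is the removal of `remove_len` characters), `margin` the
// distance of the vote from the decision boundary (smaller = more
// contested).
struct VoteDecision {
  int pos;
  std::string add;
  int remove_len;
  double margin;
};

std::string vote_round(const std::string& center,
                       const std::vector<std::string>& reads,
                       double gap_weight,
                       int s_match = 1, int s_mismatch = -1, int s_gap = -1,
                       std::vector<VoteDecision>* decisions = nullptr) {
  std::string center_row;
  std::vector<std::string> rows = star_align(center, reads, center_row,
                                             s_match, s_mismatch, s_gap);
  int nc = (int)center_row.size();
  int n = (int)reads.size();
  // mark no-coverage trailing regions: everything after a read's last base
  std::vector<int> last_base(n, -1);
  for (int i = 0; i < n; ++i)
    for (int c = nc - 1; c >= 0; --c)
      if (rows[i][c] != '-') { last_base[i] = c; break; }

  std::string out;
  out.reserve(nc);
  int c = 0;
  while (c < nc) {
    if (center_row[c] == '-') {
      // slot: maximal run of center-gap columns
      int c2 = c;
      while (c2 < nc && center_row[c2] == '-') ++c2;
      std::map<std::string, int> ins;
      int none = 0;
      for (int i = 0; i < n; ++i) {
        if (c > last_base[i]) continue; // no coverage in this slot
        std::string s;
        for (int t = c; t < c2; ++t)
          if (rows[i][t] != '-') s.push_back(rows[i][t]);
        if (s.empty()) ++none;
        else ++ins[s];
      }
      if (!ins.empty()) {
        auto best = ins.begin();
        for (auto it = ins.begin(); it != ins.end(); ++it)
          if (it->second > best->second) best = it; // ties -> lexicographic first
        double margin = (double)best->second - gap_weight * (double)none;
        bool emit = best->second >= 2 && margin >= 0.0;
        if (decisions) {
          if (emit)
            decisions->push_back({(int)out.size(), std::string(), (int)best->first.size(), margin});
          else if (best->second >= 1)
            decisions->push_back({(int)out.size(), best->first, 0, -margin});
        }
        if (emit) out += best->first;
      }
      c = c2;
    } else {
      int cnt[4] = {0, 0, 0, 0};
      int gaps = 0;
      for (int i = 0; i < n; ++i) {
        if (c > last_base[i]) continue;
        char ch = rows[i][c];
        if (ch == '-') ++gaps;
        else ++cnt[base_code(ch)];
      }
      int best = 0;
      for (int b = 1; b < 4; ++b)
        if (cnt[b] > cnt[best]) best = b;
      double margin = (double)cnt[best] - gap_weight * (double)gaps;
      bool emit = cnt[best] >= 1 && margin >= 0.0;
      if (decisions && gaps >= 1 && cnt[best] >= 1) {
        if (emit)
          decisions->push_back({(int)out.size(), std::string(), 1, margin});
        else
          decisions->push_back({(int)out.size(), std::string(1, "ACGT"[best]), 0, -margin});
      }
      if (emit) out.push_back("ACGT"[best]);
      ++c;
    }
  }
  return out;
}

// Positional majority extension of a core consensus towards the 3' end
// using the unclipped reads: each read's unaligned suffix past the core is
// voted position by position until no base wins an absolute majority of
// the reads still extending. The C-rich tail makes the extension overshoot
// the design length with C's; the caller trims to the target length.
std::string extend_suffix(const std::string& core,
                          const std::vector<std::string>& reads,
                          int max_extend) {
  int n = (int)reads.size();
  std::vector<std::string> suf(n);
  for (int i = 0; i < n; ++i) {
    std::string gc, gr;
    nw_align(core, reads[i], gc, gr);
    // suffix = read bases after the column of the core's last base
    int lastc = -1;
    for (int c = (int)gc.size() - 1; c >= 0; --c)
      if (gc[c] != '-') { lastc = c; break; }
    std::string s;
    for (int c = lastc + 1; c < (int)gr.size(); ++c)
      if (gr[c] != '-') s.push_back(gr[c]);
    suf[i] = s;
  }
  std::string out = core;
  for (int t = 0; t < max_extend; ++t) {
    int cnt[4] = {0, 0, 0, 0};
    int covering = 0;
    for (int i = 0; i < n; ++i) {
      if ((int)suf[i].size() > t) {
        ++covering;
        ++cnt[base_code(suf[i][(size_t)t])];
      }
    }
    int best = 0;
    for (int b = 1; b < 4; ++b)
      if (cnt[b] > cnt[best]) best = b;
    if (covering == 0 || 2 * cnt[best] <= covering) break;
    out.push_back("ACGT"[best]);
  }
  return out;
}

} // namespace

namespace {

// medoid = read minimizing the total edit distance to the others
int medoid_index(const std::vector<std::string>& rs) {
  int n = (int)rs.size();
  std::vector<long> tot(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = myers_dist(rs[i], rs[j]);
      tot[i] += d;
      tot[j] += d;
    }
  int med = 0;
  for (int i = 1; i < n; ++i)
    if (tot[i] < tot[med]) med = i;
  return med;
}

} // namespace

// Semi-global distance of `pattern` against the best prefix of `text`
// (the consensus-polishing objective); exported for diagnostics/tests.
// [[Rcpp::export]]
IntegerVector cpp_edit_semiglobal(CharacterVector pattern, CharacterVector text) {
  R_xlen_t n = std::max(pattern.size(), text.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = myers_semiglobal(as<std::string>(pattern[i % pattern.size()]),
                              as<std::string>(text[i % text.size()]));
  return out;
}

// Full consensus of one cluster/subset. Stages: (1) C/T tail clipping of
// every read (the tails of deletion-shortened reads otherwise vote,
// consistently, for spurious C's near the 3' end); (2) medoid-centred,
// slot-pooled weighted vote rounds on the clipped reads until the
// consensus is stable (core consensus); (3) positional majority extension
// with the unclipped reads, restoring genuine trailing C/T bases clipped
// in (1); overshoot past the design length is the caller's trim. Returns
// the raw consensus string.
// [[Rcpp::export]]
std::string cpp_refine_consensus(CharacterVector reads, double gap_weight,
                                 int vote_iters, int max_clip,
                                 bool extend, int max_extend,
                                 int s_match, int s_mismatch, int s_gap) {
  int n = reads.size();
  std::vector<std::string> rs(n);
  for (int i = 0; i < n; ++i) rs[i] = as<std::string>(reads[i]);
  if (n == 1) return rs[0];
  std::vector<std::string> clipped(n);
  for (int i = 0; i < n; ++i) clipped[i] = clip_tail(rs[i], max_clip);

  std::string cons = clipped[medoid_index(clipped)];
  for (int it = 0; it < vote_iters; ++it) {
    std::string nxt = vote_round(cons, clipped, gap_weight,
                                 s_match, s_mismatch, s_gap);
    if (nxt.empty()) break;
    bool same = (nxt == cons);
    cons = nxt;
    if (same) break;
  }
  if (cons.empty()) return cons;
  if (extend) cons = extend_suffix(cons, rs, max_extend);
  return cons;
}

// Consensus with borderline-decision variants: returns the primary
// consensus first, followed by variants obtained by toggling up to
// `max_decisions` of the most contested indel decisions of the final vote
// round (all combinations). Wrong variants are cheap: they are frameshifted
// relative to the inner code and almost always rejected downstream, while a
// correct variant rescues a cluster whose majority vote picked the wrong
// side of a near-tie.
// [[Rcpp::export]]
CharacterVector cpp_refine_consensus_variants(CharacterVector reads,
                                              double gap_weight,
                                              int vote_iters, int max_clip,
                                              int max_extend,
                                              int max_decisions,
                                              int s_match, int s_mismatch,
                                              int s_gap) {
  int n = reads.size();
  std::vector<std::string> rs(n);
  for (int i = 0; i < n; ++i) rs[i] = as<std::string>(reads[i]);
  if (n == 1) return CharacterVector::create(rs[0]);
  std::vector<std::string> clipped(n);
  for (int i = 0; i < n; ++i) clipped[i] = clip_tail(rs[i], max_clip);

  std::string cons = clipped[medoid_index(clipped)];
  for (int it = 0; it < vote_iters; ++it) {
    std::string nxt = vote_round(cons, clipped, gap_weight,
                                 s_match, s_mismatch, s_gap);
    if (nxt.empty()) break;
    bool same = (nxt == cons);
    cons = nxt;
    if (same) break;
  }
  if (cons.empty()) return CharacterVector::create(cons);

  // one recording pass around the stable core
  std::vector<VoteDecision> dec;
  std::string rec = vote_round(cons, clipped, gap_weight,
                               s_match, s_mismatch, s_gap, &dec);
  if (!rec.empty()) cons = rec;
  std::sort(dec.begin(), dec.end(),
            [](const VoteDecision& a, const VoteDecision& b) {
              if (a.margin != b.margin) return a.margin < b.margin;
              return a.pos < b.pos;
            });
  if ((int)dec.size() > max_decisions) dec.resize(max_decisions);
  // apply toggles from the right so positions stay valid
  std::sort(dec.begin(), dec.end(),
            [](const VoteDecision& a, const VoteDecision& b) {
              return a.pos > b.pos;
            });
  int nd = (int)dec.size();
  std::vector<std::string> variants;
  for (int mask = 0; mask < (1 << nd); ++mask) {
    std::string v = cons;
    bool ok = true;
    for (int t = 0; t < nd; ++t) {
      if (!(mask & (1 << t))) continue;
      const VoteDecision& d = dec[t];
      if (d.remove_len > 0) {
        if (d.pos + d.remove_len > (int)v.size()) { ok = false; break; }
        v.erase(d.pos, d.remove_len);
      } else {
        if (d.pos > (int)v.size()) { ok = false; break; }
        v.insert(d.pos, d.add);
      }
    }
    if (ok) variants.push_back(v);
  }
  CharacterVector out(variants.size());
  for (size_t i = 0; i < variants.size(); ++i)
    out[i] = extend_suffix(variants[i], rs, max_extend);
  return out;
}

// Edit alignment of a read against its 60-nt reference; each alignment
// column is classified as substitution / deletion / insertion. A
// substitution costs 2, an indel 1: at unit costs, a deletion and an
// insertion a few bases apart are parsimoniously collapsed into a shorter
// run of "substitutions", which systematically inflates the substitution
// rate and deflates the indel rates on an indel-dominated channel. With
// the 2:1 ratio only the genuinely indistinguishable case (deletion and
// insertion at adjacent positions, one mismatched base) remains ambiguous.
// Canonical traceback prefers a substitution over an indel pair at equal
// cost (diagonal first), then deletion, then insertion. Positions are
// 1-based reference coordinates; an insertion is attributed to the
// reference position in front of which it occurs (clipped to ref length).
// Types: 1 = sub, 2 = del, 3 = ins.
// [[Rcpp::export]]
IntegerMatrix cpp_classify_errors(std::string read, std::string ref) {
  int n = (int)ref.size(), m = (int)read.size();
  std::vector<int> dp((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) dp[at(i, 0)] = i;
  for (int j = 0; j <= m; ++j) dp[at(0, j)] = j;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int s = dp[at(i - 1, j - 1)] + (ref[i - 1] == read[j - 1] ? 0 : 2);
      int d = dp[at(i - 1, j)] + 1;     // ref base missing from read
      int ins = dp[at(i, j - 1)] + 1;   // extra base in read
      dp[at(i, j)] = std::min(s, std::min(d, ins));
    }
  std::vector<std::pair<int, int>> ev; // (position, type)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        dp[at(i, j)] == dp[at(i - 1, j - 1)] + (ref[i - 1] == read[j - 1] ? 0 : 2)) {
      if (ref[i - 1] != read[j - 1]) ev.push_back({i, 1});
      --i; --j;
    } else if (i > 0 && dp[at(i, j)] == dp[at(i - 1, j)] + 1) {
      ev.push_back({i, 2});
      --i;
    } else {
      ev.push_back({std::min(i + 1, n), 3});
      --j;
    }
  }
  std::reverse(ev.begin(), ev.end());
  IntegerMatrix out((int)ev.size(), 2);
  for (size_t t = 0; t < ev.size(); ++t) {
    out(t, 0) = ev[t].first;
    out(t, 1) = ev[t].second;
  }
  colnames(out) = CharacterVector::create("position", "type");
  return out;
}
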