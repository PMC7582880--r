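---
title: "Storing files in high-error synthetic DNA: the oligostore model and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing files in high-error synthetic DNA: the oligostore model and pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Light-directed (photolithographic) array synthesis produces DNA far more
cheaply than conventional phosphoramidite deposition, at the price of very
high sequence error rates when the photodeprotection step is run fast:
deletion rates above 10% per base, with substantial insertion and
substitution rates on top. `oligostore` implements a complete storage
system built for that regime: it encodes arbitrary binary files into pools
of short 60-nt oligonucleotides carrying no primer sequences at all, and
recovers the file from noisy sequencing reads through clustering, multiple
alignment, weighted-majority consensus calling and concatenated
Reed–Solomon errors-and-erasures decoding.

## The code construction

The default layout stores a file in `N` = 16,383 oligos of 60 nt, of which
`K` = 10,977 carry information; the remaining 5,406 are redundancy. Each
sequence holds 120 bits (2 bits per nucleotide):

* **84 payload bits**, read as six 14-bit symbols. Symbol *j* of sequence
  *r* is message symbol *r* of outer Reed–Solomon codeword *j*: six
  independent RS(16383, 10977) codes over GF(2^14) run *across* the pool.
  Because the outer code works on whole sequences, a missing sequence is an
  *erasure* in all six codewords (cost: one redundancy symbol each) and a
  wrongly reconstructed sequence is an *error* (cost: two). Decoding
  succeeds whenever each codeword satisfies 2·errors + erasures ≤ N − K;
  with no errors, up to 1 − K/N ≈ 33% of the sequences may be missing.
* **24 index bits**, the sequence's address, XOR-masked with a fixed
  constant. Only indices below 2^14 are used at this scale, so the top ten
  index bits are constant; the mask is chosen so they render the 5-nt
  prefix `ACAAC`. The index occupies nt 40–51 — mid-sequence, because both
  sequence ends see elevated error rates.
* **12 inner parity bits**: the 108 data bits (13 payload symbols, 4 index
  symbols, 1 payload symbol of 6 bits each) are extended to 20 six-bit
  symbols by an inner RS(20, 18) code over GF(2^6), which corrects one
  symbol error per sequence and rejects most frameshifted candidates.

Payload bits are XORed with a per-row pseudo-random keystream before outer
encoding ("randomization"). This is invertible, breaks up homopolymers,
balances GC content near 0.5 and makes distinct sequences near-orthogonal —
which is what makes reference-free read clustering work. No constrained
coding (GC/homopolymer avoidance) is used; rare bad motifs are left to the
error-correcting code. Files larger than one block are split into
independent RS(N, K) blocks with block-offset indices; net information
density is K·84 / (N·60) = 0.938 bits/nt.

The engine is a single table-driven GF(2^m) Reed–Solomon implementation
(systematic generator-polynomial encoder; Berlekamp–Massey decoder with
erasure-locator initialisation, Chien search and Forney values),
parameterised by field and code length, so the inner (m = 6) and outer
(m = 14, including shortened lengths such as N = 1023) codes share one
code path. The decoder re-checks all syndromes after correction and
returns an explicit failure rather than a silently corrupted message;
beyond the design radius a bounded-distance decoder can still miscorrect
onto a *different valid codeword* — unavoidable in principle — but it will
never return an inconsistent word as success. Primitive polynomials are
x^6+x+1 and x^14+x^10+x^6+x+1 with first consecutive root α^1; any
primitive choice is self-consistent between encoder and decoder, and
bit-compatibility with other implementations is not a goal.

## The channel model

`channel_params()` reproduces the error structure of speed-optimised
photolithographic synthesis followed by single-strand library preparation
and sequencing in a fixed window:

* per-sequence error counts are Poisson with means λ_del = 7, λ_sub = 2,
  λ_ins = 3 over the 60-nt design length — per-base rates of 11.7%, 3.3%
  and 5.0%. Positions are uniform; substitutions go to a uniformly chosen
  different base; the operations are applied deletions → substitutions →
  insertions with positions re-drawn on the current sequence (order
  effects are second-order at these rates);
* one 3′ T is appended (the synthesis linker), then a C:T = 5:1 tail
  (library preparation) fills the sequence up to the 60-nt window, and the
  read is truncated to the window.

The per-position error rates of the *model* are flat. The apparent 3′
increase in substitution/insertion rates seen in windowed reads is an
emergent artifact: deletions shorten the synthesized oligo, the C-rich
tail slides into the window, and a fixed-window comparison against the
design misreads tail bases as substitutions. The simulator injects nothing
position-dependent; the analytics module demonstrates that the artifact
emerges on its own (and therefore estimates channel rates on the 5′ half
of the window only).

Per-oligo read counts are negative binomial with mean `coverage` and size
`dispersion` (default 4). Array synthesis yields strongly inhomogeneous
coverage — spatial effects on the chip leave some oligos nearly unread —
and size 4 gives a realistically heavy left tail (a few percent of oligos
below the 5-read consensus cutoff at mean 30) without modelling the
spatial structure itself, which is out of scope. All randomness is
deterministic given an integer seed; each read draws from its own
substream, so results do not depend on chunking.

## Reconstruction pipeline

1. **Trim** reads longer than 60 nt at the 3′ end.
2. **Cluster** reads by source oligo without a reference. The naive method
   keys on the exact first 16 nt; it is linear-time and its clusters are
   pure, but at a 20% per-base error rate a prefix is error-free with
   probability ≈ 0.8^16 ≈ 3%, so almost no cluster reaches the 5-read
   cutoff at moderate coverage. The MinHash method computes 128 hash
   minima over each read's 7-mer set, groups them into 64 bands of 2, and
   streams the reads through a band-key table: a read joins the verified
   nearest cluster (bit-parallel edit distance to the cluster's founding
   read, threshold 23) among those sharing any band key, else founds a new
   cluster. Verified nearest-cluster assignment, rather than
   single-linkage merging of bucket collisions, prevents false collisions
   from chaining unrelated clusters. Two fragment-merge passes then
   re-attach small clusters to the nearest larger one at a stricter
   threshold (21), recovering reads that fragmented before their oligo's
   band keys had accumulated. The thresholds come from the distance
   distributions at the default channel: same-oligo read pairs centre near
   edit distance 20, unrelated pairs near 31 with under 0.1% below 23.
3. **Consensus.** Clusters with fewer than 5 reads are discarded; clusters
   of 5–15 reads are aligned whole; larger clusters contribute five random
   subsets of 15. The exposed building blocks follow the design exactly:
   center-star multiple alignment (the read minimising total edit distance
   to the rest is the star center; "once a gap, always a gap" merging) and
   per-column weighted majority voting with base weight 1 and gap weight
   0.4 — deletions dominate this channel, so a base should win a column
   even against twice as many gaps. The candidate extractor iterates this
   vote: reads are first clipped of their trailing C/T run (the tail of a
   deletion-shortened read otherwise votes, *consistently*, for spurious
   C's near the 3′ end), re-aligned in a star around the running consensus
   (which lets insertion columns that smear around a noisy read center
   coalesce), and re-voted until stable; insertions relative to the
   running consensus are pooled per gap run and accepted against the same
   0.4 rule, genuine trailing bases are restored by a positional majority
   extension with the unclipped reads, and overshoot past 60 nt is
   trimmed. Because the remaining consensus mistakes are single indels at
   near-tie columns, the extractor also emits *variant* candidates —
   all toggles of the three most contested indel decisions. A wrong
   variant is frameshifted and almost always rejected by the inner code;
   a right one rescues the cluster.
4. **Inner decode and collate.** Every candidate maps back to 20 six-bit
   symbols and is decoded (≤ 1 symbol corrected), its index unmasked and
   bounds-checked. Conflicting rows at one index are ranked by the fewest
   inner corrections first (a true candidate is an exact codeword; a
   frameshifted one that happens to decode almost always needs a
   correction), then by support; corrected rows with single-candidate
   support are dropped entirely, since converting a probably-wrong row
   into an erasure halves its cost to the outer code.
5. **Outer decode** with errors and erasures per block, unscramble,
   unframe. Failure is explicit, with per-codeword diagnostics; no partial
   file is emitted.

## What the tests do and do not show

The simulator is the test bed for the whole pipeline; it reproduces the
error *structure* of the channel (Poisson indel/substitution counts, tail
intrusion, window truncation, overdispersed coverage) but not everything
about real data: no spatial correlation of errors across the chip, no
PCR/sequencing-specific biases, no quality scores, constant per-base
rates within a sequence, and an idealised C:T tail composition.
Recovery demonstrated here therefore shows the algorithms behave correctly
under the stated error model at the stated scale — not a guarantee for any
particular instrument run. Real-data statistics reported for this class of
experiment (overall 2.6/6.2/5.7% rates, hundreds of thousands of
candidates from tens of millions of reads) depend on the deposited
sequencing data and are deliberately not asserted by the test suite.

Problem sizes were chosen so the whole suite runs comfortably on one CPU:
unit tests use shortened blocks (N = 255 or 1023 at the design rate
K/N ≈ 0.67), the system-level suite exercises the full N = 16,383 code for
the noiseless round-trip (a 99,103-byte file) and the 33%-erasure bound,
and end-to-end noisy-channel recovery runs on two N = 1023 blocks holding
a 10-kB file at mean coverage 30 (~62,000 simulated reads). Full-scale
noisy recovery at tens of millions of reads is a cluster-scale
computation and is substituted by the scaled run plus the invariant
suites.

## Numerical and design choices worth knowing

* **Keystream.** A 64-bit mix/splitmix generator keyed by
  (scramble seed, row index); "multiplication of a pseudorandom sequence"
  over GF(2) is XOR, and XOR is self-inverting. The seed is part of the
  code definition.
* **Index mask** 0x106A5D: any 24-bit constant whose top ten bits render
  `ACAAC` reproduces the designed composition peak; the decoded index is
  mask-independent as long as both sides agree.
* **Framing.** A 64-bit big-endian length header precedes the file bytes
  in row 0; trailing pad bits are zero before randomization.
* **Alignment scores.** `pairwise_align()` uses match +1 / mismatch −1 /
  gap −1 with deterministic tie-breaking (diagonal, up, left) — ties occur
  constantly on 60-nt noisy reads, and the star-merge step requires
  reproducible placements. The error *classifier* instead prices a
  substitution at twice an indel: at equal costs, a deletion–insertion
  pair a few bases apart is parsimoniously collapsed into "substitutions",
  which would bias rate estimation on an indel-dominated channel; with the
  2:1 ratio only the genuinely indistinguishable adjacent case remains,
  and the profile recovers the simulator's deletion/substitution rates
  within a percentage point or two on the 5′ half of the window.
* **Consensus tie-breaks.** Per column: bases A < C < G < T, and a base
  beats the gap at equal weighted score. Candidates shorter than 60 nt are
  rejected rather than padded (the inner code needs exactly 120 bits);
  longer ones keep their first 60 nt.
* **MSA engine.** A center-star aligner replaces a general-purpose MSA
  tool: the contribution being exercised is the voting scheme and the
  surrounding code, not the aligner, and an in-package aligner keeps the
  pipeline dependency-free and deterministic.
* **Degenerate inputs.** Empty files frame to an all-zero payload and
  round-trip; empty read sets yield an all-erasure table and a clean
  failure; reads shorter than the k-mer size go to an explicit discard
  bin.

## Known limitations

* Cross-decodability with other implementations of the same construction
  is not attempted: primitive polynomials, root offsets, keystream, index
  mask and framing are all internally consistent choices that a different
  implementation would have made differently.
* The LSH clustering is a streaming approximation tuned for the default
  channel; at error rates far above the design point its distance
  thresholds would need re-deriving.
* Decoding assumes the read pool fits in memory; streaming operation at
  the scale of tens of millions of reads is out of scope.
* The consensus stage knows the C/T composition of the library-prep tail;
  a different preparation chemistry would need a different clip rule.
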