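# Turn clusters of noisy reads into 60-nt candidate sequences: filter small
# clusters, subsample large ones, center-star multiple alignment, weighted
# majority voting with down-weighted gaps.

#' Global pairwise alignment
#'
#' Needleman-Wunsch with match = +1, mismatch = -1, gap = -1 (linear gap
#' cost) and deterministic tie-breaking (prefer diagonal, then up, then
#' left).
#'
#' @param a,b Sequences to align.
#' @return List with gapped strings `a` and `b` and the alignment `score`.
#' @export
#' @examples
#' pairwise_align("ACGT", "AGT")
pairwise_align <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  cpp_nw_align(a, b)
}

#' Subsample a cluster for multiple alignment
#'
#' Clusters with fewer than `min_reads` members are discarded (too small to
#' vote down ~20% per-base error); clusters of `min_reads` to `max_reads`
#' are aligned whole; larger clusters contribute `n_subsets` random subsets
#' of exactly `max_reads` reads each (multiple alignment cost grows steeply
#' with the number of sequences, and alignments beyond 15 reads stop
#' improving the consensus).
#'
#' @param members Vector of read ids in the cluster.
#' @param min_reads,max_reads,n_subsets Filtering and subsampling rule.
#' @param seed Integer seed for the random subsets.
#' @return List of read-id vectors (possibly empty).
#' @export
subsample_cluster <- function(members, min_reads = 5L, max_reads = 15L,
                              n_subsets = 5L, seed = 1L) {
  n <- length(members)
  if (n < min_reads) return(list())
  if (n <= max_reads) return(list(members))
  withr::with_seed(seed, {
    lapply(seq_len(n_subsets), function(i) sample(members, max_reads))
  })
}

#' Center-star multiple sequence alignment
#'
#' The center is the read minimising the total edit distance to all others;
#' every other read is pairwise-aligned to the center and merged under
#' "once a gap, always a gap". Row order matches the input, and removing
#' the gaps from row i restores read i exactly.
#'
#' @param reads Character vector of reads (intended for 5-15 sequences).
#' @return Character matrix of aligned rows (one row per read, columns =
#'   alignment columns) of class `alignment_matrix`.
#' @export
center_star_msa <- function(reads) {
  stopifnot(length(reads) >= 1)
  aligned <- cpp_center_star(reads)
  mat <- matrix(unlist(strsplit(aligned, "", fixed = TRUE), use.names = FALSE),
                nrow = length(aligned), byrow = TRUE)
  class(mat) <- c("alignment_matrix", class(mat))
  mat
}

#' Weighted majority consensus of an alignment
#'
#' Per alignment column, each base A/C/G/T scores `base_weight` times its
#' count and a gap scores `gap_weight` times its count. The argmax is
#' emitted; if the gap wins, the column is dropped (it represents an
#' insertion in some reads relative to the source). The gap weight of 0.4
#' encodes that deletions are far more likely than substitutions or
#' insertions on this channel: a base can win a column even when gaps
#' outnumber it 2:1. Ties are resolved deterministically (A < C < G < T;
#' at equal score a base beats the gap). Consensus longer than the target
#' length is trimmed to the first `target_len` nt; shorter consensus is
#' rejected (`NA`) because the inner code needs exactly 120 bits.
#'
#' @param alignment An `alignment_matrix` from [center_star_msa()] (or any
#'   character matrix over A,C,G,T,-).
#' @param base_weight,gap_weight Voting weights.
#' @param target_len Required candidate length (default 60). `NA` disables
#'   the trim/reject step and returns the raw consensus.
#' @return A single candidate string, or `NA_character_` if rejected.
#' @export
#' @examples
#' m <- center_star_msa(c("ACGTACGT", "ACGTACGT", "ACGACGT"))
#' weighted_majority(m, target_len = 8)
weighted_majority <- function(alignment, base_weight = 1, gap_weight = 0.4,
                              target_len = 60L) {
  stopifnot(is.matrix(alignment), nrow(alignment) >= 1)
  counts <- vapply(BASE_ALPHABET, function(b) colSums(alignment == b),
                   numeric(ncol(alignment)))
  if (ncol(alignment) == 1) counts <- matrix(counts, nrow = 1)
  gap_score <- gap_weight * colSums(alignment == "-")
  base_score <- counts * base_weight
  best_base <- max.col(base_score, ties.method = "first")
  best_score <- base_score[cbind(seq_len(nrow(base_score)), best_base)]
  keep <- best_score >= gap_score  # base wins ties against the gap
  cons <- paste(BASE_ALPHABET[best_base[keep]], collapse = "")
  if (is.na(target_len)) return(cons)
  if (nchar(cons) < target_len) return(NA_character_)
  substr(cons, 1L, target_len)
}

# Refined consensus of one read subset (see cpp_refine_consensus): C/T
# tail clipping, medoid start, slot-pooled weighted vote rounds to
# stability, positional 3' extension with the unclipped reads, trim to the
# target length. `variants = TRUE` additionally toggles the most contested
# indel decisions of the final vote round and returns all combinations
# (primary consensus first).
consensus_one <- function(sub_seqs, base_weight, gap_weight, target_len,
                          refine_iters, variants = FALSE,
                          max_variant_decisions = 3L) {
  gw <- gap_weight / base_weight
  if (variants) {
    cons <- cpp_refine_consensus_variants(sub_seqs, gw,
                                          vote_iters = as.integer(refine_iters),
                                          max_clip = 14L, max_extend = 20L,
                                          max_decisions = as.integer(max_variant_decisions),
                                          s_match = 1L, s_mismatch = -1L,
                                          s_gap = -1L)
    cons <- unique(cons[nchar(cons) >= target_len])
    if (length(cons) == 0) return(character(0))
    return(substr(cons, 1L, target_len))
  }
  cons <- cpp_refine_consensus(sub_seqs, gw,
                               vote_iters = as.integer(refine_iters),
                               max_clip = 14L, extend = TRUE,
                               max_extend = 20L,
                               s_match = 1L, s_mismatch = -1L, s_gap = -1L)
  if (nchar(cons) < target_len) return(NA_character_)
  substr(cons, 1L, target_len)
}

#' Extract consensus candidates from clusters
#'
#' Applies the subsample / align / vote pipeline to every cluster: clusters
#' with fewer than `min_reads` reads are dropped, clusters up to `max_reads`
#' are aligned whole, larger clusters contribute `n_subsets` subsets of
#' `max_reads` reads, and each alignment is voted into one candidate.
#'
#' The vote is refined iteratively: reads are first clipped of their
#' trailing C/T run (the library-prep tail of a deletion-shortened read
#' otherwise votes, consistently, for spurious C's near the 3' end), then
#' re-aligned in a star around the running consensus and re-voted
#' (`refine_iters` rounds, or until stable). With a noisy read as
#' alignment center, reads place their insertions inconsistently and the
#' votes smear across columns; centering on the consensus and pooling
#' insertion votes per gap run lets them coalesce, which raises the
#' fraction of error-free candidates several-fold at high deletion rates.
#' Genuine trailing bases are restored by a positional majority extension
#' with the unclipped reads, and overshoot past `target_len` is trimmed.
#'
#' @param reads A `read_set` tibble (or character vector).
#' @param clusters Tibble `read_id`, `cluster` from a clustering function.
#' @param min_reads,max_reads,n_subsets See [subsample_cluster()].
#' @param base_weight,gap_weight See [weighted_majority()].
#' @param target_len Candidate length (default 60).
#' @param refine_iters Maximum consensus vote rounds.
#' @param variants Also emit alternative candidates obtained by toggling
#'   the most contested indel decisions of the vote (at most
#'   `max_variant_decisions` of them, all combinations). Wrong variants are
#'   frameshifted relative to the inner code and almost always rejected
#'   downstream; a correct variant rescues a cluster whose majority vote
#'   picked the wrong side of a near-tie.
#' @param max_variant_decisions Number of contested decisions to toggle.
#' @param seed Integer seed for the cluster subsampling.
#' @return Tibble `cluster`, `subsample`, `variant`, `n_reads`, `sequence`
#'   (one row per accepted candidate; the primary consensus of a subset is
#'   `variant == 1`).
#' @export
consensus_candidates <- function(reads, clusters, min_reads = 5L,
                                 max_reads = 15L, n_subsets = 5L,
                                 base_weight = 1, gap_weight = 0.4,
                                 target_len = 60L, refine_iters = 6L,
                                 variants = TRUE,
                                 max_variant_decisions = 3L,
                                 seed = 1L) {
  seqs <- read_sequences(reads)
  names(seqs) <- as.character(read_ids(reads))
  keep <- !is.na(clusters$cluster)
  by_cluster <- split(clusters$read_id[keep], clusters$cluster[keep])
  sizes <- lengths(by_cluster)
  by_cluster <- by_cluster[sizes >= min_reads]
  if (length(by_cluster) == 0) {
    return(tibble::tibble(cluster = integer(0), subsample = integer(0),
                          variant = integer(0), n_reads = integer(0),
                          sequence = character(0)))
  }

  cluster_ids <- as.integer(names(by_cluster))
  cap <- length(by_cluster) * n_subsets *
    (if (variants) 2L^max_variant_decisions else 1L)
  out_cluster <- integer(cap)
  out_sub <- integer(cap)
  out_var <- integer(cap)
  out_n <- integer(cap)
  out_seq <- character(cap)
  m <- 0L
  for (i in seq_along(by_cluster)) {
    members <- by_cluster[[i]]
    subsets <- subsample_cluster(members, min_reads, max_reads, n_subsets,
                                 seed = seed + cluster_ids[i])
    for (s in seq_along(subsets)) {
      sub_seqs <- seqs[as.character(subsets[[s]])]
      sub_seqs <- sub_seqs[nchar(sub_seqs) > 0]
      if (length(sub_seqs) < min_reads) next
      cand <- consensus_one(unname(sub_seqs), base_weight, gap_weight,
                            target_len, refine_iters, variants = variants,
                            max_variant_decisions = max_variant_decisions)
      cand <- cand[!is.na(cand)]
      for (v in seq_along(cand)) {
        m <- m + 1L
        out_cluster[m] <- cluster_ids[i]
        out_sub[m] <- s
        out_var[m] <- v
        out_n[m] <- length(sub_seqs)
        out_seq[m] <- cand[v]
      }
    }
  }
  keep_rows <- seq_len(m)
  tibble::tibble(cluster = out_cluster[keep_rows], subsample = out_sub[keep_rows],
                 variant = out_var[keep_rows], n_reads = out_n[keep_rows],
                 sequence = out_seq[keep_rows])
}
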