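# Group noisy reads by their (unknown) source oligo: exact 16-nt-prefix
# hashing, and MinHash locality-sensitive hashing with edit-distance
# verification.

#' Cluster reads by exact sequence prefix
#'
#' The naive method: reads sharing their first `prefix_len` nucleotides
#' exactly fall into one cluster. Linear time, and effective because the
#' randomised payload makes designed sequences pairwise near-orthogonal —
#' but a single synthesis error inside the prefix sends a read to its own
#' (wrong) cluster, so completeness degrades quickly at high error rates.
#'
#' @param reads A `read_set` tibble (columns `read_id`, `sequence`), or a
#'   character vector.
#' @param prefix_len Prefix length in nt (16 performs best at these error
#'   rates).
#' @return Tibble `read_id`, `cluster` (integer; `NA` = discard bin for
#'   reads shorter than the prefix), `key` (the prefix string).
#' @export
cluster_by_prefix <- function(reads, prefix_len = 16L) {
  stopifnot(prefix_len >= 1)
  seqs <- read_sequences(reads)
  ids <- read_ids(reads)
  long_enough <- nchar(seqs) >= prefix_len
  key <- ifelse(long_enough, substr(seqs, 1L, prefix_len), NA_character_)
  cluster <- match(key, unique(key[long_enough]))
  tibble::tibble(read_id = ids, cluster = cluster, key = key)
}

#' MinHash signature of a read's k-mer set
#'
#' `H` minima of independently seeded hash functions over the set of
#' distinct k-mers of the read. Identical reads give identical signatures,
#' and the expected fraction of matching components between two signatures
#' equals the Jaccard similarity of the two k-mer sets.
#'
#' @param reads Character vector (or `read_set` tibble).
#' @param k K-mer size.
#' @param H Number of hash functions.
#' @param seed Integer seed of the hash family.
#' @return Numeric matrix (reads x H); a read shorter than `k` yields a row
#'   of `NA` (empty-signature sentinel, routed to the discard bin by
#'   [cluster_lsh()]).
#' @export
minhash_signature <- function(reads, k = 6L, H = 128L, seed = 1L) {
  cpp_minhash(read_sequences(reads), as.integer(k), as.integer(H),
              as.double(seed))
}

#' Cluster reads by MinHash locality-sensitive hashing
#'
#' Signatures are split into `bands` bands of `rows_per_band` hashes; a
#' band's values are combined into one bucket key. Reads are processed in
#' input order: each read looks up its band keys among the keys of already
#' formed clusters, verifies the candidate clusters by bit-parallel edit
#' distance to the cluster representative (its first read), joins the
#' closest candidate within `max_dist`, and otherwise founds a new cluster.
#' All of the read's band keys are then registered for its cluster, so
#' recall grows as clusters accumulate members. Assigning each read to
#' exactly one verified cluster (rather than single-linkage merging of
#' bucket co-occurrences) keeps false bucket collisions from chaining
#' unrelated clusters together at high error rates.
#'
#' @param reads A `read_set` tibble or character vector.
#' @param k K-mer size for the signatures. At ~20% total per-base error,
#'   short k-mers are the only ones with usable survival probability; the
#'   default 7 balances k-mer survival in noisy reads against random
#'   background key collisions, which grow with the read count.
#' @param H Number of hash functions (`bands * rows_per_band`).
#' @param bands,rows_per_band Banding layout; fewer rows per band makes
#'   collisions more permissive (edit-distance verification then removes
#'   false positives).
#' @param seed Integer seed.
#' @param max_dist Edit-distance acceptance threshold to the cluster
#'   representative. Same-oligo read pairs at the default channel rates sit
#'   around distance 20 (90% below 26) on a 60-nt window while unrelated
#'   pairs concentrate near 31 (under 0.1% below 23); 23 accepts most true
#'   members and almost no impostors even when thousands of wrong
#'   representatives are in play.
#' @param max_candidates Cap on distinct candidate clusters verified per
#'   read.
#' @param merge_fragments Run a second pass that re-attaches small clusters
#'   (fewer than `fragment_size` reads) to the nearest large cluster within
#'   `merge_dist` of its representative. Reads of the same oligo that
#'   founded separate clusters early (before the oligo's band keys had
#'   accumulated) are recovered this way, which raises cluster completeness
#'   substantially at high error rates.
#' @param fragment_size Clusters below this size are merge candidates.
#' @param merge_dist Acceptance threshold of the merge pass; stricter than
#'   `max_dist` because both representatives are noisy reads and, with
#'   thousands of clusters, some wrong representative is otherwise always
#'   within reach.
#' @return Tibble `read_id`, `cluster` (integer id, `NA` for reads shorter
#'   than `k`).
#' @export
cluster_lsh <- function(reads, k = 7L, H = 128L, bands = 64L,
                        rows_per_band = 2L, seed = 1L, max_dist = 23L,
                        max_candidates = 64L, merge_fragments = TRUE,
                        fragment_size = 5L, merge_dist = max_dist - 2L) {
  if (bands * rows_per_band != H) stop("bands * rows_per_band must equal H")
  seqs <- read_sequences(reads)
  ids <- read_ids(reads)
  cl <- cpp_lsh_cluster(seqs, as.integer(k), as.integer(H), as.integer(bands),
                        as.integer(rows_per_band), as.double(seed),
                        as.integer(max_dist), as.integer(max_candidates))
  if (merge_fragments && any(!is.na(cl))) {
    # round 1: 1-2 read shards onto mid-size clusters, so that an oligo
    # whose reads fragmented early can still assemble a >= fragment_size
    # cluster; round 2: remaining small clusters onto full-size ones
    cl <- merge_fragment_pass(cl, seqs, target_min = 3L,
                              source_max = 3L, merge_dist = merge_dist)
    cl <- merge_fragment_pass(cl, seqs, target_min = fragment_size,
                              source_max = fragment_size,
                              merge_dist = merge_dist)
  }
  tibble::tibble(read_id = ids, cluster = cl)
}

# attach clusters with fewer than source_max reads to the nearest cluster
# with at least target_min reads (representative = founding read) within
# merge_dist
merge_fragment_pass <- function(cl, seqs, target_min, source_max, merge_dist) {
  first_idx <- which(!is.na(cl) & !duplicated(cl))
  rep_cluster <- cl[first_idx]
  rep_seq <- seqs[first_idx]
  sizes <- table(cl)
  src <- rep_cluster[sizes[as.character(rep_cluster)] < source_max]
  tgt <- rep_cluster[sizes[as.character(rep_cluster)] >= target_min]
  tgt <- setdiff(tgt, src)
  if (length(src) == 0 || length(tgt) == 0) return(cl)
  hit <- cpp_nearest_rep(rep_seq[match(src, rep_cluster)],
                         rep_seq[match(tgt, rep_cluster)],
                         as.integer(merge_dist))
  remap <- stats::setNames(tgt[hit[!is.na(hit)]], src[!is.na(hit)])
  moved <- as.character(cl) %in% names(remap)
  cl[moved] <- unname(remap[as.character(cl[moved])])
  cl
}

#' Summarise clustering quality against known provenance
#'
#' For simulated reads whose source oligo is known, reports cluster purity
#' (weighted majority-provenance fraction), completeness (fraction of a
#' source's reads captured by its largest cluster) and the fraction of
#' oligos owning at least one cluster with `min_reads`+ members whose
#' majority provenance is that oligo — the quantity that decides whether a
#' consensus candidate can be produced for the oligo.
#'
#' @param clusters Tibble from [cluster_by_prefix()] or [cluster_lsh()].
#' @param reads The `read_set` the clustering was computed on (must carry
#'   `source` provenance).
#' @param n_oligos Total number of designed oligos (defaults to the number
#'   of distinct sources observed).
#' @param min_reads Cluster size cutoff used downstream.
#' @return One-row tibble: `purity`, `completeness`, `frac_recoverable`,
#'   `n_clusters`, `n_clusters_ge_min`.
#' @export
cluster_quality <- function(clusters, reads, n_oligos = NULL, min_reads = 5L) {
  stopifnot("source" %in% names(reads))
  df <- dplyr::inner_join(clusters, reads[, c("read_id", "source")],
                          by = "read_id")
  df <- df[!is.na(df$cluster), , drop = FALSE]
  if (is.null(n_oligos)) n_oligos <- dplyr::n_distinct(reads$source)

  per_cluster <- df |>
    dplyr::count(.data$cluster, .data$source) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = sum(.data$n),
                     top = max(.data$n),
                     major = .data$source[which.max(.data$n)],
                     .groups = "drop")

  completeness <- df |>
    dplyr::count(.data$source, .data$cluster) |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(frac = max(.data$n) / sum(.data$n), .groups = "drop")

  recoverable <- per_cluster |>
    dplyr::filter(.data$size >= min_reads, .data$top > .data$size / 2)

  tibble::tibble(
    purity = sum(per_cluster$top) / sum(per_cluster$size),
    completeness = mean(completeness$frac),
    frac_recoverable = dplyr::n_distinct(recoverable$major) / n_oligos,
    n_clusters = nrow(per_cluster),
    n_clusters_ge_min = sum(per_cluster$size >= min_reads)
  )
}

read_sequences <- function(reads) {
  if (is.character(reads)) reads
  else if (is.data.frame(reads) && "sequence" %in% names(reads)) reads$sequence
  else stop("expected a character vector or a tibble with a `sequence` column")
}

read_ids <- function(reads) {
  if (is.data.frame(reads) && "read_id" %in% names(reads)) reads$read_id
  else seq_len(if (is.data.frame(reads)) nrow(reads) else length(reads))
}
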