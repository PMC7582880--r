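# End-to-end reconstruction: trim -> cluster -> consensus -> inner decode ->
# collation -> outer errors-and-erasures decode, with stagewise reporting.

#' Trim reads to the sequencing window
#'
#' Reads longer than `window` nt are truncated at the 3' end (errors
#' concentrate there); shorter reads pass through unchanged. Read counts
#' are conserved.
#'
#' @param reads A `read_set` tibble or character vector.
#' @param window Window length in nt.
#' @return Object of the same shape with trimmed sequences.
#' @export
trim_reads <- function(reads, window = 60L) {
  if (is.character(reads)) {
    return(ifelse(nchar(reads) > window, substr(reads, 1L, window), reads))
  }
  reads$sequence <- ifelse(nchar(reads$sequence) > window,
                           substr(reads$sequence, 1L, window), reads$sequence)
  reads
}

#' Collate inner-decoded candidates into an index table
#'
#' Inner-decodes every candidate, drops rejects, and resolves conflicts per
#' index. A candidate sequence that is exactly a designed codeword decodes
#' with zero inner corrections, while a frameshifted (wrong) candidate that
#' happens to decode almost always needs a correction; rows are therefore
#' ranked by their best supporting candidate's inner correction count
#' first, then by plurality over identical payload rows, then
#' lexicographically. Corrected rows supported by fewer than
#' `min_support_corrected` candidates are dropped entirely: turning a
#' probably-wrong row into an erasure halves its cost to the outer code
#' (an erasure consumes one redundancy symbol, an undetected error two).
#' Indices with no surviving candidate become erasures; surviving wrong
#' rows are the symbol errors the outer code must correct.
#'
#' @param candidates Tibble with a `sequence` column (from
#'   [consensus_candidates()]), or a character vector.
#' @param params A [code_params()] object.
#' @param min_support_corrected Minimum number of supporting candidates for
#'   a row whose inner decode needed a correction.
#' @return List with `rows` (tibble `index`, `row`, `support`), and `stats`
#'   (one-row tibble: `n_candidates`, `n_inner_ok`, `n_indices`,
#'   `n_erasures`).
#' @export
collate_candidates <- function(candidates, params = code_params(),
                               min_support_corrected = 2L) {
  seqs <- if (is.character(candidates)) candidates else candidates$sequence
  dec <- inner_decode(seqs, params)
  ok <- dec[dec$ok, c("index", "row", "n_corrected")]
  total <- params$blocks * params$N
  if (nrow(ok) == 0) {
    return(list(
      rows = tibble::tibble(index = integer(0), row = character(0),
                            support = integer(0)),
      stats = tibble::tibble(n_candidates = length(seqs), n_inner_ok = 0L,
                             n_indices = 0L, n_erasures = total)))
  }
  rows <- ok |>
    dplyr::group_by(.data$index, .data$row) |>
    dplyr::summarise(support = dplyr::n(),
                     best_corr = min(.data$n_corrected), .groups = "drop") |>
    dplyr::group_by(.data$index) |>
    dplyr::arrange(.data$best_corr, dplyr::desc(.data$support), .data$row,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$best_corr == 0L |
                    .data$support >= min_support_corrected) |>
    dplyr::select("index", "row", "support")
  list(rows = rows,
       stats = tibble::tibble(n_candidates = length(seqs),
                              n_inner_ok = sum(dec$ok),
                              n_indices = nrow(rows),
                              n_erasures = total - nrow(rows)))
}

#' Reconstruct a file from noisy reads
#'
#' The full decoding pipeline: trim to the 60-nt window, cluster (MinHash
#' LSH by default, or the 16-nt-prefix method), extract weighted-majority
#' consensus candidates from clusters of five or more reads, inner-decode
#' and collate candidates by index, and outer-decode with errors and
#' erasures. Deterministic for fixed seeds. On outer-decode failure no
#' partial file is emitted; the report carries per-stage diagnostics either
#' way.
#'
#' @param reads A `read_set` tibble or character vector of reads.
#' @param params A [code_params()] object (must match the encoder's).
#' @param cluster_method `"lsh"` or `"prefix"`.
#' @param truth Optional `oligo_set` of the designed sequences; when given,
#'   the report includes the fraction of error-free candidates.
#' @param seed Integer seed for clustering and subsampling.
#' @param min_reads,max_reads,n_subsets,gap_weight Consensus stage controls,
#'   see [consensus_candidates()].
#' @param ... Further arguments passed to the clustering function.
#' @return A `reconstruction` object: list with `ok`, `bytes` (raw vector or
#'   `NULL`), and `report` (a `decode_report` tibble of stage statistics).
#' @export
#' @examples
#' p <- code_params(N = 255, K = 171)
#' oligos <- encode_file(as.raw(0:199), p)
#' reads <- sample_reads(oligos, channel_params(coverage = 12), seed = 3)
#' rec <- reconstruct(reads, p, seed = 3)
#' rec$ok
reconstruct <- function(reads, params = code_params(),
                        cluster_method = c("lsh", "prefix"), truth = NULL,
                        seed = 1L, min_reads = 5L, max_reads = 15L,
                        n_subsets = 5L, gap_weight = 0.4, ...) {
  cluster_method <- match.arg(cluster_method)
  seqs_in <- read_sequences(reads)
  n_reads <- length(seqs_in)
  n_long <- sum(nchar(seqs_in) > params$oligo_len)
  trimmed <- trim_reads(seqs_in, params$oligo_len)
  reads_tbl <- tibble::tibble(read_id = read_ids(reads), sequence = trimmed)

  clusters <- switch(cluster_method,
    lsh = cluster_lsh(reads_tbl, seed = seed, ...),
    prefix = cluster_by_prefix(reads_tbl, ...)
  )
  cl_sizes <- table(clusters$cluster)

  candidates <- consensus_candidates(reads_tbl, clusters,
                                     min_reads = min_reads,
                                     max_reads = max_reads,
                                     n_subsets = n_subsets,
                                     gap_weight = gap_weight,
                                     target_len = params$oligo_len,
                                     seed = seed)
  frac_ef <- if (!is.null(truth) && nrow(candidates) > 0) {
    mean(candidates$sequence %in% truth$sequence)
  } else {
    NA_real_
  }

  coll <- collate_candidates(candidates, params)
  res <- outer_decode(coll$rows, params)

  report <- tibble::new_tibble(list(
    n_reads = n_reads,
    n_trimmed = n_long,
    n_clusters = length(cl_sizes),
    n_clusters_ge5 = sum(cl_sizes >= min_reads),
    n_candidates = coll$stats$n_candidates,
    n_inner_ok = coll$stats$n_inner_ok,
    frac_candidates_error_free = frac_ef,
    n_indices_recovered = coll$stats$n_indices,
    n_erasures = coll$stats$n_erasures,
    n_outer_errors_corrected = res$n_errors_corrected,
    success = res$ok
  ), class = "decode_report", nrow = 1L)

  structure(list(ok = res$ok, bytes = res$bytes, report = report,
                 codewords = res$codewords),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction>", if (x$ok) "success" else "FAILED", "\n")
  r <- x$report
  cat(sprintf("  %d reads -> %d clusters (%d with >= 5 reads) -> %d candidates\n",
              r$n_reads, r$n_clusters, r$n_clusters_ge5, r$n_candidates))
  cat(sprintf("  indices recovered %d, erasures %d, outer errors corrected %s\n",
              r$n_indices_recovered, r$n_erasures,
              format(r$n_outer_errors_corrected)))
  if (x$ok) cat(sprintf("  decoded %d bytes\n", length(x$bytes)))
  invisible(x)
}

#' Tidy methods for reconstruction results
#'
#' `tidy()` returns the stagewise statistics in long form (one row per
#' statistic); `glance()` returns the one-row report.
#'
#' @param x A `reconstruction` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.reconstruction <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(as.data.frame(x$report),
                  success = as.numeric(.data$success)),
    dplyr::everything(),
    names_to = "statistic", values_to = "value")
}

#' @rdname tidy.reconstruction
#' @export
glance.reconstruction <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
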