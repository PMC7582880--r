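# Read-characterisation analytics: per-position error probabilities against
# the designed sequences, per-position base composition, read length and GC
# summaries.

#' Classify the errors of one read against its reference
#'
#' Optimal unit-cost edit alignment between the read and its 60-nt designed
#' reference; every alignment column is classified as substitution,
#' deletion or insertion. Ambiguity is resolved by canonical traceback
#' (substitution preferred over an indel pair at equal cost, then deletion,
#' then insertion); at the heavily eroded 3' end of a windowed read the
#' insertion/substitution distinction is intrinsically ambiguous.
#'
#' @param read A read string.
#' @param reference The designed sequence it originates from.
#' @return Tibble `position` (1-based reference coordinate), `type`
#'   (factor: sub/del/ins).
#' @export
#' @examples
#' classify_errors("ACGTCGT", "ACGTACGT")  # one deletion
classify_errors <- function(read, reference) {
  ev <- cpp_classify_errors(read, reference)
  tibble::tibble(
    position = unname(ev[, 1]),
    type = factor(c("sub", "del", "ins")[unname(ev[, 2])],
                  levels = c("sub", "del", "ins"))
  )
}

#' Assign reads to their closest designed sequence
#'
#' Brute-force nearest reference by bit-parallel edit distance over the
#' whole oligo set: O(reads x references), intended for provenance-free
#' pools of moderate size (simulated read sets carry provenance and do not
#' need it).
#'
#' @param reads A `read_set` tibble or character vector.
#' @param references An `oligo_set` (columns `index`, `sequence`).
#' @param max_dist Assignments above this distance become `NA`.
#' @return Integer vector of reference indices (same order as `reads`).
#' @export
assign_reads <- function(reads, references, max_dist = 45L) {
  seqs <- read_sequences(reads)
  hit <- cpp_nearest_rep(seqs, references$sequence, as.integer(max_dist))
  references$index[hit]
}

#' Per-position error profile of a read pool
#'
#' Aligns each read to its assigned reference and tallies substitution,
#' deletion and insertion rates per reference position (errors at the
#' position divided by reads covering it). With the simulator's flat
#' per-base error rates, the apparent rates still rise towards the 3' end
#' of the fixed window — deletions pull the C-rich tail into view — which
#' is why rate estimation should be read off the 5' half.
#'
#' @param reads A `read_set` tibble or character vector.
#' @param references An `oligo_set` (or tibble with `index`, `sequence`)
#'   holding the designed sequences.
#' @param assignment Integer vector mapping each read to a reference
#'   `index`; defaults to the `source` provenance column of `reads`.
#' @param window Analysis window (reads are trimmed to it first).
#' @return An `error_profile` tibble: `position`, `n_covering`, and
#'   per-type rates `sub`, `del`, `ins`; overall rates and the number of
#'   reads used are attached as attributes `overall` and `n_reads_used`.
#' @export
error_profile <- function(reads, references, assignment = NULL, window = 60L) {
  seqs <- trim_reads(read_sequences(reads), window)
  if (is.null(assignment)) {
    if (!is.data.frame(reads) || !"source" %in% names(reads)) {
      stop("supply `assignment` (e.g. via assign_reads()) or a read_set ",
           "with provenance (`source`)")
    }
    assignment <- reads$source
  }
  ref_seq <- references$sequence[match(assignment, references$index)]
  usable <- !is.na(ref_seq) & nchar(seqs) > 0
  seqs <- seqs[usable]
  ref_seq <- ref_seq[usable]
  n_pos <- window
  if (length(seqs) == 0) {
    prof <- tibble::new_tibble(
      list(position = seq_len(n_pos), n_covering = rep(0L, n_pos),
           sub = rep(NA_real_, n_pos), del = rep(NA_real_, n_pos),
           ins = rep(NA_real_, n_pos)),
      class = "error_profile", nrow = n_pos)
    attr(prof, "overall") <- c(sub = NA_real_, del = NA_real_, ins = NA_real_)
    attr(prof, "n_reads_used") <- 0L
    return(prof)
  }
  counts <- matrix(0, nrow = n_pos, ncol = 3,
                   dimnames = list(NULL, c("sub", "del", "ins")))
  for (i in seq_along(seqs)) {
    ev <- cpp_classify_errors(seqs[i], ref_seq[i])
    if (nrow(ev) == 0) next
    for (t in 1:3) {
      pos <- ev[ev[, 2] == t, 1]
      if (length(pos)) {
        tab <- tabulate(pos, nbins = n_pos)
        counts[, t] <- counts[, t] + tab
      }
    }
  }
  n_reads <- length(seqs)
  rates <- counts / n_reads
  prof <- tibble::new_tibble(
    list(position = seq_len(n_pos), n_covering = rep(n_reads, n_pos),
         sub = rates[, "sub"], del = rates[, "del"], ins = rates[, "ins"]),
    class = "error_profile", nrow = n_pos)
  attr(prof, "overall") <- colMeans(rates)
  attr(prof, "n_reads_used") <- n_reads
  prof
}

#' Per-position base composition
#'
#' Relative A/C/G/T frequencies at each position over a set of sequences;
#' shorter sequences contribute only to the positions they cover. On the
#' designed oligos the constant ten index bits produce the A and C peaks at
#' positions 40-51; on noisy reads the peak shifts left and washes out as
#' deletions shuffle positions, and C rises at the 3' end where the
#' library-preparation tail enters the window.
#'
#' @param reads A `read_set` tibble, `oligo_set`, or character vector.
#' @param window Number of positions to tabulate.
#' @return Tibble `position`, `base`, `freq`; at every covered position the
#'   four frequencies sum to 1.
#' @export
base_composition <- function(reads, window = 60L) {
  seqs <- read_sequences(reads)
  seqs <- seqs[nchar(seqs) > 0]
  mat <- matrix(NA_character_, nrow = length(seqs), ncol = window)
  for (i in seq_along(seqs)) {
    ch <- strsplit(substr(seqs[i], 1L, window), "", fixed = TRUE)[[1]]
    mat[i, seq_along(ch)] <- ch
  }
  res <- lapply(seq_len(window), function(p) {
    col <- mat[, p]
    col <- col[!is.na(col)]
    n <- length(col)
    tibble::tibble(position = p, base = BASE_ALPHABET,
                   freq = if (n == 0) rep(NA_real_, 4)
                          else as.numeric(table(factor(col, BASE_ALPHABET))) / n)
  })
  dplyr::bind_rows(res)
}

#' Read length distribution
#'
#' @param reads A `read_set` tibble or character vector.
#' @return Tibble `length`, `n`.
#' @export
read_length_hist <- function(reads) {
  seqs <- read_sequences(reads)
  if (length(seqs) == 0) return(tibble::tibble(length = integer(0), n = integer(0)))
  tab <- table(nchar(seqs))
  tibble::tibble(length = as.integer(names(tab)), n = as.integer(tab))
}

#' Per-read GC content
#'
#' @param reads A `read_set` tibble or character vector.
#' @return Numeric vector of per-read GC fractions.
#' @export
gc_content <- function(reads) {
  seqs <- read_sequences(reads)
  n <- nchar(seqs)
  gc <- nchar(gsub("[^GCgc]", "", seqs))
  ifelse(n > 0, gc / n, NA_real_)
}

#' Plot an error profile
#'
#' Per-position substitution, deletion and insertion rates along the read
#' window.
#'
#' @param object An `error_profile` from [error_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("sub", "del", "ins"),
                            names_to = "type", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$rate,
                                   colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (5' to 3', nt)", y = "error probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-position base composition
#'
#' @param composition Tibble from [base_composition()].
#' @return A ggplot object.
#' @export
plot_base_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(.data$position, .data$freq,
                               colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (5' to 3', nt)", y = "relative frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
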