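# Monte-Carlo model of the synthesis + library-prep + sequencing channel.

#' Channel parameters for the synthesis error model
#'
#' Per-sequence error counts are Poisson: on average `lambda_del` deletions,
#' `lambda_sub` substitutions and `lambda_ins` insertions per 60-nt
#' sequence (defaults 7, 2 and 3 — the rates of light-directed maskless
#' synthesis run at speed-optimised exposure, equivalent to per-base
#' probabilities of 11.7%, 3.3% and 5.0%). After corruption one T is
#' appended (the synthesis linker), then a C-rich library-preparation tail
#' at C:T ratio `tail_ct` fills the sequence up to the fixed sequencing
#' window of `window` nt, and the read is truncated to the window. Deletions
#' shorten the synthesized oligo, so the tail intrudes into the window and
#' the apparent error rate rises towards the 3' end — an emergent property,
#' not an injected one: the per-position error rates themselves are flat.
#'
#' @param lambda_del,lambda_sub,lambda_ins Mean deletions / substitutions /
#'   insertions per sequence.
#' @param tail_ct Length-2 numeric, the C:T ratio of the tail (default
#'   `c(5, 1)`).
#' @param append_t Append the 3' T synthesis linker?
#' @param tail Append the C/T library-preparation tail?
#' @param window Sequencing window in nt; `Inf` disables both tail fill and
#'   truncation (useful to observe raw synthesized lengths).
#' @param coverage Mean reads per oligo.
#' @param dispersion Negative-binomial size parameter of the per-oligo read
#'   count distribution (smaller = stronger coverage inhomogeneity).
#' @return A `channel_params` object.
#' @export
channel_params <- function(lambda_del = 7, lambda_sub = 2, lambda_ins = 3,
                           tail_ct = c(5, 1), append_t = TRUE, tail = TRUE,
                           window = 60, coverage = 30, dispersion = 4) {
  stopifnot(lambda_del >= 0, lambda_sub >= 0, lambda_ins >= 0,
            length(tail_ct) == 2, all(tail_ct >= 0), sum(tail_ct) > 0,
            coverage >= 0, dispersion > 0)
  structure(list(lambda_del = lambda_del, lambda_sub = lambda_sub,
                 lambda_ins = lambda_ins, tail_ct = tail_ct,
                 append_t = isTRUE(append_t), tail = isTRUE(tail),
                 window = window, coverage = coverage,
                 dispersion = dispersion),
            class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  r <- expected_error_rates(x)
  cat(sprintf(
    "<channel_params> lambda (del/sub/ins) = %.3g/%.3g/%.3g per 60 nt\n",
    x$lambda_del, x$lambda_sub, x$lambda_ins))
  cat(sprintf("  per-base rates %.1f%%/%.1f%%/%.1f%%; tail C:T %g:%g; window %s nt\n",
              100 * r[["p_del"]], 100 * r[["p_sub"]], 100 * r[["p_ins"]],
              x$tail_ct[1], x$tail_ct[2], format(x$window)))
  invisible(x)
}

#' Expected per-base error probabilities
#'
#' Converts the per-sequence Poisson means into per-base probabilities over
#' the 60-nt design length: \eqn{\lambda / 60}. The defaults give 11.7%
#' deletions, 3.3% substitutions and 5.0% insertions.
#'
#' @param params A [channel_params()] object.
#' @return Named numeric vector `(p_del, p_sub, p_ins)`.
#' @export
#' @examples
#' expected_error_rates(channel_params())
expected_error_rates <- function(params) {
  c(p_del = params$lambda_del / 60,
    p_sub = params$lambda_sub / 60,
    p_ins = params$lambda_ins / 60)
}

#' Corrupt oligos through the synthesis/sequencing channel
#'
#' Applies Poisson-distributed deletions, substitutions and insertions at
#' uniform random positions (in that order, positions re-drawn on the
#' current sequence), appends the 3' T linker, fills with the C:T tail up to
#' the window and truncates to the window. Deterministic for a fixed seed;
#' read `i` uses its own random substream.
#'
#' @param oligos Character vector of source sequences (one read generated
#'   per element).
#' @param params A [channel_params()] object.
#' @param seed Integer seed.
#' @param ordinals Optional integer substream ids (defaults to
#'   `seq_along(oligos) - 1`); [sample_reads()] uses global read ordinals so
#'   that results do not depend on how reads are grouped by oligo.
#' @return Character vector of reads.
#' @export
#' @examples
#' corrupt_read(strrep("ACGT", 15), channel_params(), seed = 1)
corrupt_read <- function(oligos, params = channel_params(), seed = 1L,
                         ordinals = NULL) {
  if (length(oligos) == 0) return(character(0))
  if (is.null(ordinals)) ordinals <- seq_along(oligos) - 1L
  tail_c_frac <- params$tail_ct[1] / sum(params$tail_ct)
  window <- if (is.finite(params$window)) as.integer(params$window) else -1L
  cpp_corrupt_reads(oligos, as.integer(ordinals),
                    params$lambda_del, params$lambda_sub, params$lambda_ins,
                    tail_c_frac, params$append_t, params$tail,
                    window, as.double(seed))
}

#' Sample a synthetic read pool from an oligo set
#'
#' Draws a read count for every oligo from a negative-binomial coverage
#' model (mean `params$coverage`, size `params$dispersion`; zero-coverage
#' oligos occur naturally), then pushes each copy through [corrupt_read()].
#' Deterministic under `seed`.
#'
#' @param oligos An `oligo_set` tibble (columns `index`, `sequence`), or any
#'   tibble with a `sequence` column.
#' @param params A [channel_params()] object.
#' @param seed Integer seed.
#' @param n_reads Optional total read count; when given, read sources are
#'   drawn from the per-oligo negative-binomial weights so that exactly
#'   `n_reads` reads are returned.
#' @return A `read_set` tibble: `read_id`, `sequence`, and provenance
#'   `source` (the 0-based index of the originating oligo).
#' @export
#' @examples
#' p <- code_params(N = 255, K = 171)
#' oligos <- encode_file(as.raw(0:99), p)
#' reads <- sample_reads(oligos, channel_params(coverage = 5), seed = 1)
sample_reads <- function(oligos, params = channel_params(), seed = 1L,
                         n_reads = NULL) {
  n_oligo <- nrow(oligos)
  src_index <- if ("index" %in% names(oligos)) oligos$index
               else seq_len(n_oligo) - 1L
  if (n_oligo == 0 || params$coverage == 0 && is.null(n_reads)) {
    return(tibble::new_tibble(
      list(read_id = integer(0), sequence = character(0), source = integer(0)),
      class = "read_set", nrow = 0L))
  }
  counts <- withr::with_seed(seed, {
    cnt <- stats::rnbinom(n_oligo, mu = params$coverage,
                          size = params$dispersion)
    if (!is.null(n_reads)) {
      n_reads <- as.integer(n_reads)
      if (n_reads == 0) {
        cnt <- integer(n_oligo)
      } else {
        w <- cnt + 1e-9
        cnt <- as.integer(stats::rmultinom(1, n_reads, prob = w / sum(w)))
      }
    }
    cnt
  })
  src <- rep.int(seq_len(n_oligo), counts)
  seqs <- corrupt_read(oligos$sequence[src], params, seed = seed,
                       ordinals = seq_along(src) - 1L)
  tibble::new_tibble(
    list(read_id = seq_along(src),
         sequence = seqs,
         source = as.integer(src_index[src])),
    class = "read_set", nrow = length(src))
}
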