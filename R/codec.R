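# File <-> oligo transformation: framing, pseudo-randomization, outer
# RS(16383,10977) encoding across 6 interleaved codewords over GF(2^14),
# 24-bit mid-sequence index, inner RS(20,18) over GF(2^6), and the
# 2-bit-per-base map 00->A, 01->C, 10->G, 11->T.

#' Invertible payload randomisation
#'
#' XORs a bit vector with a deterministic pseudo-random keystream keyed by
#' `(seed, stream)`. Applying the same call twice restores the input. The
#' codec scrambles each information row with its own stream (the row index)
#' before outer encoding, which breaks up homopolymers, balances GC content
#' and makes distinct sequences near-orthogonal without any constrained
#' coding.
#'
#' @param bits Integer 0/1 vector.
#' @param seed Integer keystream seed.
#' @param stream Stream id (the codec uses the 0-based payload row index).
#' @return Scrambled bit vector of the same length.
#' @export
#' @examples
#' b <- sample(0:1, 84, replace = TRUE)
#' identical(scramble_bits(scramble_bits(b, 1), 1), b)
scramble_bits <- function(bits, seed, stream = 0L) {
  bits <- as.integer(bits)
  if (length(bits) == 0) return(bits)
  ks <- cpp_keystream_matrix(as.double(seed), as.integer(stream), length(bits))
  bitwXor(bits, ks[1, ])
}

scramble_rows <- function(rows, seed) {
  if (nrow(rows) == 0) return(rows)
  ks <- cpp_keystream_matrix(as.double(seed), seq_len(nrow(rows)) - 1L,
                             ncol(rows))
  out <- bitwXor(rows, ks)  # bitwXor drops dim attributes
  dim(out) <- dim(rows)
  out
}

#' Frame a file into fixed-width payload rows
#'
#' Lays the file out as `blocks * K` rows of 84 bits: a 64-bit big-endian
#' length header, then the file bytes MSB-first, then zero padding. The
#' frame is the unscrambled payload; [encode_file()] randomises it before
#' encoding.
#'
#' @param bytes Raw vector (file content).
#' @param params A [code_params()] object.
#' @return A `payload_frame`: list with `rows` (bit matrix `blocks*K` x 84)
#'   and `n_bytes`.
#' @export
frame_payload <- function(bytes, params) {
  stopifnot(is.raw(bytes))
  total_rows <- params$blocks * params$K
  capacity_bits <- total_rows * params$payload_bits
  need_bits <- 64 + 8 * length(bytes)
  if (need_bits > capacity_bits) {
    stop(sprintf(paste0(
      "file of %d bytes exceeds payload capacity: K*84 payload bound is ",
      "%d bits (%d bytes usable; raw 2 bits/nt upper bound %s bytes)"),
      length(bytes), capacity_bits, payload_capacity_bytes(params),
      format(raw_capacity_bytes(params), big.mark = ",")))
  }
  bits <- integer(capacity_bits)
  bits[1:64] <- length_to_bits(length(bytes))
  if (length(bytes) > 0) {
    bits[64 + seq_len(8 * length(bytes))] <- bytes_to_bits(bytes)
  }
  structure(list(rows = matrix(bits, ncol = params$payload_bits, byrow = TRUE),
                 n_bytes = length(bytes)),
            class = "payload_frame")
}

#' @rdname frame_payload
#' @param frame A `payload_frame`.
#' @export
unframe_payload <- function(frame) {
  bits <- as.integer(t(frame$rows))
  n <- bits_to_length(bits[1:64])
  if (64 + 8 * n > length(bits)) stop("corrupt frame: length header too large")
  bits_to_bytes(bits[64 + seq_len(8 * n)])
}

#' Outer Reed-Solomon encoding across sequences
#'
#' Each 84-bit payload row is read as six 14-bit symbols; symbol `j` of row
#' `r` is message symbol `r` of outer codeword `j`. Six independent
#' systematic RS(N, K) encodings over GF(2^14) extend the `K` information
#' rows of each block to `N` rows; rows `K..N-1` are the redundancy
#' sequences.
#'
#' @param frame A `payload_frame` (rows already scrambled by the caller when
#'   used inside the codec).
#' @param params A [code_params()] object.
#' @return Bit matrix with `blocks * N` rows and 84 columns.
#' @export
outer_encode <- function(frame, params) {
  rows <- frame$rows
  stopifnot(nrow(rows) == params$blocks * params$K)
  rs <- outer_rs(params)
  out <- matrix(0L, nrow = params$blocks * params$N, ncol = params$payload_bits)
  for (b in seq_len(params$blocks) - 1L) {
    block_rows <- rows[b * params$K + seq_len(params$K), , drop = FALSE]
    msg_sym <- bits_to_symbols(block_rows, params$outer_symbol_bits) # K x 6
    cw <- rs_encode(t(msg_sym), rs)                                  # 6 x N
    out[b * params$N + seq_len(params$N), ] <-
      symbols_to_bits(t(cw), params$outer_symbol_bits)
  }
  out
}

# data-symbol layout of one sequence: payload symbols 1..13, four index
# symbols (24 bits of index XOR index_mask, big-endian), payload symbol 14
assemble_symbols <- function(rows, indices, params) {
  n <- nrow(rows)
  sym <- matrix(0L, nrow = n, ncol = params$inner_k)
  sym[, 1:13] <- bits_to_symbols(rows[, 1:78, drop = FALSE], params$symbol_bits)
  masked <- bitwXor(as.integer(indices), params$index_mask)
  sym[, 14:17] <- bits_to_symbols(int_to_bits(masked, params$index_bits),
                                  params$symbol_bits)
  sym[, 18] <- bits_to_int(rows[, 79:84, drop = FALSE])
  sym
}

#' Assemble a 60-nt sequence from a payload row and its index
#'
#' Builds the 18 data symbols (13 payload symbols, 4 index symbols carrying
#' the 24-bit masked index, 1 payload symbol), appends two inner RS(20, 18)
#' parity symbols and maps the 120 bits to 60 nt. The index occupies nt
#' 40-51, away from the error-prone sequence ends, and its mask is chosen so
#' that the ten index bits that are constant for any index below \eqn{2^{14}}
#' render the 5-nt prefix `ACAAC`.
#'
#' @param row_bits 84-bit integer vector, or a matrix with 84 columns.
#' @param index Integer index (0-based), one per row; must be below
#'   \eqn{2^{24}}.
#' @param params A [code_params()] object.
#' @return Character vector of 60-nt sequences.
#' @export
#' @examples
#' p <- code_params(N = 255, K = 171)
#' s <- assemble_sequence(rep(0L, 84), 0L, p)
#' substr(s, 40, 44)  # constant index prefix
assemble_sequence <- function(row_bits, index, params) {
  rows <- if (is.null(dim(row_bits))) matrix(as.integer(row_bits), nrow = 1)
          else row_bits
  stopifnot(ncol(rows) == params$payload_bits)
  index <- as.integer(index)
  if (any(index < 0L) || any(index >= bitwShiftL(1L, params$index_bits))) {
    stop("index must lie in [0, 2^24)")
  }
  sym <- assemble_symbols(rows, index, params)
  cw <- rs_encode(sym, inner_rs(params))
  bits_to_dna(symbols_to_bits(cw, params$symbol_bits))
}

#' Encode a file into an oligo set
#'
#' Full encoder: frame, per-row pseudo-randomisation, outer RS encoding
#' across sequences, index attachment, inner RS encoding within each
#' sequence, base mapping. Deterministic for a fixed
#' `params$scramble_seed`.
#'
#' @param input A file path or a raw vector.
#' @param params A [code_params()] object.
#' @return An `oligo_set`: tibble with `index` (0-based, block-offset) and
#'   `sequence` (60 nt), one row per designed oligo, with the parameters
#'   attached as attribute `code_params`.
#' @export
#' @examples
#' p <- code_params(N = 255, K = 171)
#' oligos <- encode_file(as.raw(sample(0:255, 100, replace = TRUE)), p)
#' nrow(oligos)            # N sequences
#' unique(nchar(oligos$sequence))
encode_file <- function(input, params = code_params()) {
  bytes <- if (is.raw(input)) input
           else readBin(input, what = "raw", n = file.size(input))
  frame <- frame_payload(bytes, params)
  frame$rows <- scramble_rows(frame$rows, params$scramble_seed)
  all_rows <- outer_encode(frame, params)
  indices <- global_indices(params)
  tibble::new_tibble(
    list(index = indices,
         sequence = assemble_sequence(all_rows, indices, params)),
    class = "oligo_set", code_params = params, nrow = length(indices)
  )
}

# global index of the oligo at position p (0-based) of block b is b*N + p
global_indices <- function(params) {
  as.integer(rep(seq_len(params$blocks) - 1L, each = params$N) * params$N +
               rep(seq_len(params$N) - 1L, times = params$blocks))
}

#' Inner-decode candidate sequences
#'
#' Maps each 60-nt candidate back to 20 six-bit symbols, applies the inner
#' RS(20, 18) errors-only decoder (corrects at most one symbol error),
#' unmasks the 24-bit index and extracts the 84-bit payload row. Candidates
#' that fail the inner decode, or whose index falls outside the designed
#' range, are rejected; rejection is a normal, counted outcome.
#'
#' @param candidates Character vector of candidate sequences (only 60-nt
#'   A/C/G/T strings can decode; anything else is rejected).
#' @param params A [code_params()] object.
#' @return Tibble with one row per candidate: `candidate` (input), `ok`,
#'   `index` (0-based, NA when rejected), `row` (84-character bit string),
#'   `n_corrected` (inner symbol corrections).
#' @export
inner_decode <- function(candidates, params = code_params()) {
  n <- length(candidates)
  out <- tibble::tibble(
    candidate = as.character(candidates),
    ok = logical(n),
    index = rep(NA_integer_, n),
    row = rep(NA_character_, n),
    n_corrected = rep(NA_integer_, n)
  )
  usable <- !is.na(candidates) & nchar(candidates) == params$oligo_len &
    !grepl("[^ACGT]", candidates)
  if (!any(usable)) return(out)
  seqs <- candidates[usable]
  sym <- bits_to_symbols(dna_to_bits(seqs), params$symbol_bits)  # m x 20
  dec <- cpp_rs_decode_many(sym, params$inner_m, params$inner_poly,
                            params$inner_n, params$inner_k, params$fcr)
  ok <- dec$ok
  idx <- rep(NA_integer_, length(seqs))
  rowstr <- rep(NA_character_, length(seqs))
  if (any(ok)) {
    cw <- dec$codeword[ok, , drop = FALSE]
    index_bits <- symbols_to_bits(cw[, 14:17, drop = FALSE], params$symbol_bits)
    idx_ok <- bitwXor(bits_to_int(index_bits), params$index_mask)
    in_range <- idx_ok >= 0L & idx_ok < params$blocks * params$N
    rows <- cbind(symbols_to_bits(cw[, 1:13, drop = FALSE], params$symbol_bits),
                  int_to_bits(cw[, 18], params$symbol_bits))
    idx[ok] <- ifelse(in_range, idx_ok, NA_integer_)
    rowstr[ok] <- ifelse(in_range, bits_to_strings(rows), NA_character_)
    ok[ok] <- in_range
  }
  out$ok[usable] <- ok
  out$index[usable] <- idx
  out$row[usable] <- rowstr
  out$n_corrected[usable] <- ifelse(ok, dec$n_errors, NA_integer_)
  out
}

#' Outer Reed-Solomon decoding from a collated index table
#'
#' Takes at most one 84-bit payload row per index (as produced by
#' [collate_candidates()]), treats missing indices as erasures in all six
#' outer codewords of their block and present-but-wrong rows as symbol
#' errors, and decodes each codeword with the errors-and-erasures decoder.
#' Succeeds whenever every codeword satisfies \eqn{2e + \epsilon \le N - K};
#' any codeword beyond the radius yields an explicit failure with
#' per-codeword diagnostics, never a silently corrupted file.
#'
#' @param rows Tibble with columns `index` (0-based, unique) and `row`
#'   (84-character bit strings).
#' @param params A [code_params()] object.
#' @return List with `ok`, `bytes` (raw vector on success, `NULL`
#'   otherwise), `n_erasures`, `n_errors_corrected`, and `codewords`
#'   (per-codeword diagnostic tibble).
#' @export
outer_decode <- function(rows, params = code_params()) {
  stopifnot(all(c("index", "row") %in% names(rows)))
  if (anyDuplicated(rows$index)) stop("collated table must have unique indices")
  total <- params$blocks * params$N
  keep <- !is.na(rows$index) & rows$index >= 0L & rows$index < total
  rows <- rows[keep, , drop = FALSE]

  rs <- outer_rs(params)
  diag <- vector("list", params$blocks * params$n_outer)
  message_rows <- matrix(0L, nrow = params$blocks * params$K,
                         ncol = params$payload_bits)
  all_ok <- TRUE
  n_eras_total <- 0L
  n_err_total <- 0L

  for (b in seq_len(params$blocks) - 1L) {
    in_block <- rows$index %/% params$N == b
    pos <- rows$index[in_block] %% params$N            # 0-based within block
    sym <- matrix(NA_integer_, nrow = params$N, ncol = params$n_outer)
    if (any(in_block)) {
      sym[pos + 1L, ] <- bits_to_symbols(strings_to_bits(rows$row[in_block]),
                                         params$outer_symbol_bits)
    }
    dec <- cpp_rs_decode_many(t(sym), params$outer_m, params$outer_poly,
                              params$N, params$K, params$fcr)
    for (j in seq_len(params$n_outer)) {
      diag[[b * params$n_outer + j]] <- tibble::tibble(
        block = b, codeword = j, ok = dec$ok[j],
        n_errors = dec$n_errors[j], n_erasures = dec$n_erasures[j])
    }
    if (!all(dec$ok)) {
      all_ok <- FALSE
      next
    }
    n_eras_total <- n_eras_total + sum(dec$n_erasures)
    n_err_total <- n_err_total + sum(dec$n_errors)
    msg_sym <- t(dec$codeword[, seq_len(params$K), drop = FALSE])  # K x 6
    message_rows[b * params$K + seq_len(params$K), ] <-
      symbols_to_bits(msg_sym, params$outer_symbol_bits)
  }

  diagnostics <- dplyr::bind_rows(diag)
  if (!all_ok) {
    return(list(ok = FALSE, bytes = NULL,
                n_erasures = total - nrow(rows),
                n_errors_corrected = NA_integer_,
                codewords = diagnostics))
  }
  frame <- structure(
    list(rows = scramble_rows(message_rows, params$scramble_seed),
         n_bytes = NA_integer_),
    class = "payload_frame")
  bytes <- tryCatch(unframe_payload(frame), error = function(e) NULL)
  list(ok = !is.null(bytes), bytes = bytes,
       n_erasures = as.integer(n_eras_total / params$n_outer),
       n_errors_corrected = n_err_total,
       codewords = diagnostics)
}

#' Noiseless decode of a full oligo set
#'
#' Convenience inverse of [encode_file()] for sequences that have not passed
#' through a channel: inner-decodes every sequence, collates by index and
#' outer-decodes.
#'
#' @param oligos An `oligo_set` tibble (or any tibble with `sequence`).
#' @param params A [code_params()] object.
#' @return Raw vector of file bytes.
#' @export
decode_oligos <- function(oligos, params = code_params()) {
  dec <- inner_decode(oligos$sequence, params)
  dec <- dec[dec$ok, c("index", "row")]
  dec <- dec[!duplicated(dec$index), , drop = FALSE]
  res <- outer_decode(dec, params)
  if (!res$ok) stop("outer decoding failed")
  res$bytes
}
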