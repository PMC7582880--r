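#' Code-layout parameters for the oligo codec
#'
#' Collects every dimension of the concatenated code and the sequence
#' layout. The defaults are the full-scale design: `N = 16383` oligos of 60
#' nt per outer block, of which `K = 10977` carry information, an 84-bit
#' payload per sequence (six 14-bit symbols of the outer Reed-Solomon code),
#' a 24-bit mid-sequence index, and an inner RS(20, 18) code over
#' \eqn{GF(2^6)} whose 20 six-bit symbols map to the 120 bits (= 60 nt) of
#' one oligo. Files too large for one outer block are split across
#' `blocks` independent RS(N, K) blocks with block-offset indices.
#'
#' @param N Oligos per outer block (outer codeword length); at most
#'   `2^14 - 1`.
#' @param K Information oligos per block (outer message length).
#' @param blocks Number of independent outer blocks.
#' @param scramble_seed Integer seed of the payload randomisation keystream;
#'   part of the code definition (encoder and decoder must agree).
#' @return A `code_params` object.
#' @export
#' @examples
#' p <- code_params()
#' p$N - p$K            # outer redundancy sequences
#' code_params(N = 1023, K = 685)  # scaled-down block, same rate
code_params <- function(N = 16383L, K = 10977L, blocks = 1L,
                        scramble_seed = 7L) {
  N <- as.integer(N); K <- as.integer(K); blocks <- as.integer(blocks)
  p <- structure(list(
    N = N, K = K, blocks = blocks,
    scramble_seed = as.integer(scramble_seed),
    payload_bits = 84L, index_bits = 24L,
    inner_n = 20L, inner_k = 18L, symbol_bits = 6L,
    oligo_len = 60L, n_outer = 6L, outer_symbol_bits = 14L,
    outer_m = 14L, outer_poly = 0x4443L,
    inner_m = 6L, inner_poly = 0x43L,
    index_mask = 0x106A5DL, fcr = 1L
  ), class = "code_params")
  validate_code_params(p)
  p
}

validate_code_params <- function(p) {
  stopifnot(
    p$inner_n * p$symbol_bits == 2L * p$oligo_len,
    p$index_bits + p$payload_bits == p$inner_k * p$symbol_bits,
    p$payload_bits == p$n_outer * p$outer_symbol_bits,
    p$blocks >= 1L
  )
  if (!(1L <= p$K && p$K < p$N && p$N <= bitwShiftL(1L, p$outer_m) - 1L)) {
    stop("need 1 <= K < N <= 2^14 - 1 per outer block")
  }
  invisible(p)
}

#' @export
print.code_params <- function(x, ...) {
  cat(sprintf(
    "<code_params> %d block(s) of RS(%d, %d) over GF(2^14); inner RS(%d, %d) over GF(2^6)\n",
    x$blocks, x$N, x$K, x$inner_n, x$inner_k))
  cat(sprintf("  %d x %d nt oligos, %d-bit payload + %d-bit index per sequence\n",
              x$blocks * x$N, x$oligo_len, x$payload_bits, x$index_bits))
  cat(sprintf("  capacity %s bytes, net density %.3f bits/nt\n",
              format(payload_capacity_bytes(x), big.mark = ","),
              net_density(x)))
  invisible(x)
}

#' Arithmetic summaries of a code layout
#'
#' `payload_capacity_bytes()` is the usable file capacity (information rows
#' times 84 bits, minus the 64-bit length header); `raw_capacity_bytes()`
#' the information-theoretic bound of 2 bits/nt over all oligos;
#' `net_density()` the net information density K*84 / (N*60) in bits per
#' nucleotide; `outer_redundancy()` the number of redundancy-only sequences
#' per block; `erasure_bound()` the largest tolerable fraction of missing
#' sequences, `1 - K/N`.
#'
#' @param params A `code_params` object.
#' @return A single number.
#' @export
payload_capacity_bytes <- function(params) {
  (params$blocks * params$K * params$payload_bits - 64) %/% 8
}

#' @rdname payload_capacity_bytes
#' @export
raw_capacity_bytes <- function(params) {
  params$blocks * params$N * params$oligo_len * 2 / 8
}

#' @rdname payload_capacity_bytes
#' @export
net_density <- function(params) {
  (params$K * params$payload_bits) / (params$N * params$oligo_len)
}

#' @rdname payload_capacity_bytes
#' @export
outer_redundancy <- function(params) {
  params$N - params$K
}

#' @rdname payload_capacity_bytes
#' @export
erasure_bound <- function(params) {
  1 - params$K / params$N
}

outer_rs <- function(params) {
  rs_params(gf_field(params$outer_m, params$outer_poly),
            n = params$N, k = params$K, fcr = params$fcr)
}

inner_rs <- function(params) {
  rs_params(gf_field(params$inner_m, params$inner_poly),
            n = params$inner_n, k = params$inner_k, fcr = params$fcr)
}
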