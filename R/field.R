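#' Construct a binary extension field GF(2^m)
#'
#' Builds the exponential and logarithm tables for table-driven arithmetic in
#' \eqn{GF(2^m)} under a primitive polynomial, the symbol alphabet of both
#' Reed-Solomon codes used by the codec: the inner code works over
#' \eqn{GF(2^6)} (one symbol = 3 nt), the outer code over \eqn{GF(2^{14})}
#' (one symbol = one 14-bit block of a sequence payload).
#'
#' @param m Extension degree; symbols take values in `0:(2^m - 1)`.
#' @param primitive_poly Integer bit mask of the primitive polynomial,
#'   including the leading term (e.g. `0x43` is \eqn{x^6 + x + 1}). Defaults
#'   are provided for `m` in 3, 4, 6, 8, 14. The polynomial is checked for
#'   primitivity (the generated cycle must enumerate all nonzero elements).
#' @return An object of class `gf_field` with components `m`, `order`,
#'   `primitive_poly`, `exp` (length `2^m - 1`, `exp[i]` = \eqn{\alpha^{i-1}})
#'   and `log` (position `a + 1` holds \eqn{\log_\alpha a}).
#' @export
#' @examples
#' f <- gf_field(6)
#' gf_mul(5L, 7L, f)
gf_field <- function(m, primitive_poly = NULL) {
  defaults <- c(`3` = 0xB, `4` = 0x13, `6` = 0x43, `8` = 0x11D, `14` = 0x4443)
  if (is.null(primitive_poly)) {
    key <- as.character(m)
    if (!key %in% names(defaults)) {
      stop("no default primitive polynomial for m = ", m,
           "; supply `primitive_poly`")
    }
    primitive_poly <- defaults[[key]]
  }
  primitive_poly <- as.integer(primitive_poly)
  if (bitwShiftR(primitive_poly, m) != 1L) {
    stop("primitive polynomial must have degree exactly m")
  }
  tab <- cpp_gf_tables(m, primitive_poly)
  if (anyDuplicated(tab$exp) > 0L) {
    stop(sprintf("0x%X is not primitive for GF(2^%d)", primitive_poly, m))
  }
  structure(
    list(m = as.integer(m), order = bitwShiftL(1L, m),
         primitive_poly = primitive_poly, exp = tab$exp, log = tab$log),
    class = "gf_field"
  )
}

#' @export
print.gf_field <- function(x, ...) {
  cat(sprintf("<gf_field> GF(2^%d), primitive polynomial 0x%X\n",
              x$m, x$primitive_poly))
  invisible(x)
}

check_elements <- function(a, field) {
  a <- as.integer(a)
  if (any(a < 0L | a >= field$order)) {
    stop("field elements must lie in [0, 2^m)")
  }
  a
}

#' Finite-field arithmetic
#'
#' Vectorised multiplication, addition (XOR) and inversion in a field built
#' by [gf_field()].
#'
#' @param a,b Integer vectors of field elements (recycled).
#' @param field A `gf_field` object.
#' @return Integer vector of field elements.
#' @export
gf_mul <- function(a, b, field) {
  a <- check_elements(a, field)
  b <- check_elements(b, field)
  cpp_gf_mul(a, b, field$m, field$primitive_poly)
}

#' @rdname gf_mul
#' @export
gf_add <- function(a, b, field) {
  a <- check_elements(a, field)
  b <- check_elements(b, field)
  bitwXor(a, b)
}

#' @rdname gf_mul
#' @export
gf_inv <- function(a, field) {
  a <- check_elements(a, field)
  if (any(a == 0L)) stop("0 has no multiplicative inverse")
  field$exp[((field$order - 1L - field$log[a + 1L]) %% (field$order - 1L)) + 1L]
}

#' Parameterise a Reed-Solomon code
#'
#' @param field A `gf_field` from [gf_field()].
#' @param n Codeword length in symbols, `n <= 2^m - 1` (smaller `n` gives a
#'   shortened code).
#' @param k Message length in symbols, `1 <= k < n`.
#' @param fcr First consecutive root: the generator polynomial has roots
#'   \eqn{\alpha^{fcr}, \ldots, \alpha^{fcr + n - k - 1}}. Default 1
#'   (narrow-sense).
#' @return An `rs_params` object.
#' @export
#' @examples
#' inner <- rs_params(gf_field(6), n = 20, k = 18)
rs_params <- function(field, n, k, fcr = 1L) {
  stopifnot(inherits(field, "gf_field"))
  n <- as.integer(n); k <- as.integer(k)
  if (!(1L <= k && k < n && n <= field$order - 1L)) {
    stop("need 1 <= k < n <= 2^m - 1")
  }
  structure(list(field = field, n = n, k = k, fcr = as.integer(fcr)),
            class = "rs_params")
}

#' @export
print.rs_params <- function(x, ...) {
  cat(sprintf("<rs_params> RS(%d, %d) over GF(2^%d), t = %d, fcr = %d\n",
              x$n, x$k, x$field$m, (x$n - x$k) %/% 2L, x$fcr))
  invisible(x)
}

#' Systematic Reed-Solomon encoding
#'
#' Appends `n - k` parity symbols (the remainder of \eqn{x^{n-k} m(x)} modulo
#' the generator polynomial) to the message.
#'
#' @param message Integer vector of `k` field elements, or a matrix with `k`
#'   columns to encode many messages at once.
#' @param params An `rs_params` object.
#' @return Codeword(s) in the same shape: vector of `n` symbols or matrix
#'   with `n` columns.
#' @export
rs_encode <- function(message, params) {
  vec <- is.null(dim(message))
  msg <- if (vec) matrix(as.integer(message), nrow = 1)
         else matrix(as.integer(message), nrow = nrow(message))
  if (ncol(msg) != params$k) stop("message must have k = ", params$k, " symbols")
  check_elements(msg, params$field)
  out <- cpp_rs_encode_many(msg, params$field$m, params$field$primitive_poly,
                            params$n, params$k, params$fcr)
  if (vec) as.integer(out[1, ]) else out
}

#' Errors-and-erasures Reed-Solomon decoding
#'
#' Decodes a received word, correcting up to \eqn{e} symbol errors and
#' \eqn{\epsilon} erasures whenever \eqn{2e + \epsilon \le n - k}
#' (Berlekamp-Massey with erasure-locator initialisation, Chien search,
#' Forney error values). The decoder re-checks all syndromes after
#' correction and reports failure rather than returning a corrupted
#' message.
#'
#' @param received Integer vector of `n` symbols; `NA` marks an erasure.
#' @param params An `rs_params` object.
#' @param erasures Optional integer vector of additional erasure positions
#'   (1-based) whose values are ignored.
#' @return A list with `ok` (logical), `message` (first `k` symbols of the
#'   corrected codeword, `NULL` on failure), `codeword`, `n_errors`
#'   (errors corrected outside erasures) and `n_erasures` (erasures filled).
#' @export
rs_decode <- function(received, params, erasures = integer(0)) {
  received <- as.integer(received)
  if (length(received) != params$n) stop("received word must have n symbols")
  if (length(erasures)) {
    erasures <- as.integer(erasures)
    stopifnot(all(erasures >= 1L), all(erasures <= params$n),
              !anyDuplicated(erasures))
    received[erasures] <- NA_integer_
  }
  n_eras <- sum(is.na(received))
  if (n_eras > params$n - params$k) {
    return(list(ok = FALSE, message = NULL, codeword = NULL,
                n_errors = 0L, n_erasures = n_eras))
  }
  check_elements(received[!is.na(received)], params$field)
  res <- cpp_rs_decode_many(matrix(received, nrow = 1),
                            params$field$m, params$field$primitive_poly,
                            params$n, params$k, params$fcr)
  ok <- res$ok[1]
  cw <- as.integer(res$codeword[1, ])
  list(ok = ok,
       message = if (ok) cw[seq_len(params$k)] else NULL,
       codeword = if (ok) cw else NULL,
       n_errors = res$n_errors[1],
       n_erasures = res$n_erasures[1])
}

rs_generator_poly <- function(params) {
  cpp_rs_genpoly(params$field$m, params$field$primitive_poly,
                 params$n, params$k, params$fcr)
}
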