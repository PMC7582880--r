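# Internal bit plumbing. Bits travel as integer 0/1 vectors or matrices;
# all packing is big-endian (most significant bit first), both within bytes
# and within code symbols.

int_to_bits <- function(x, nbits) {
  x <- as.integer(x)
  out <- matrix(0L, nrow = length(x), ncol = nbits)
  for (j in seq_len(nbits)) {
    out[, j] <- bitwAnd(bitwShiftR(x, nbits - j), 1L)
  }
  out
}

bits_to_int <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  nbits <- ncol(bits)
  out <- integer(nrow(bits))
  for (j in seq_len(nbits)) {
    out <- bitwOr(bitwShiftL(out, 1L), as.integer(bits[, j]))
  }
  out
}

bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0) return(integer(0))
  as.integer(t(int_to_bits(as.integer(bytes), 8L)))
}

bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8 == 0)
  if (length(bits) == 0) return(raw(0))
  as.raw(bits_to_int(matrix(bits, ncol = 8L, byrow = TRUE)))
}

# 64-bit big-endian length header (stored as two 32-bit halves to stay
# within R's integer range; file sizes here are far below 2^31)
length_to_bits <- function(n) {
  c(integer(32), as.integer(int_to_bits(as.integer(n), 32L)))
}

bits_to_length <- function(bits) {
  stopifnot(length(bits) == 64)
  hi <- bits_to_int(matrix(bits[1:32], nrow = 1))
  if (hi != 0L) stop("length header exceeds supported range")
  bits_to_int(matrix(bits[33:64], nrow = 1))
}

BASE_ALPHABET <- c("A", "C", "G", "T")

# bit matrix (n x 2L) -> vector of sequences, pairs read left to right:
# 00 -> A, 01 -> C, 10 -> G, 11 -> T
bits_to_dna <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  n <- nrow(bits)
  L <- ncol(bits) %/% 2L
  idx <- 2L * bits[, seq(1L, 2L * L, by = 2L), drop = FALSE] +
    bits[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  chars <- matrix(BASE_ALPHABET[idx + 1L], nrow = n)
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

dna_to_bits <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  idx <- matrix(match(chars, BASE_ALPHABET) - 1L, nrow = n)
  if (anyNA(idx)) stop("sequences must be over {A,C,G,T}")
  bits <- matrix(0L, nrow = n, ncol = 2L * L)
  bits[, seq(1L, 2L * L, by = 2L)] <- bitwShiftR(idx, 1L)
  bits[, seq(2L, 2L * L, by = 2L)] <- bitwAnd(idx, 1L)
  bits
}

# rows of a bit matrix as "0"/"1" strings (collation keys)
bits_to_strings <- function(bits) {
  chars <- matrix(as.character(bits), nrow = nrow(bits))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

strings_to_bits <- function(strs) {
  n <- length(strs)
  chars <- matrix(unlist(strsplit(strs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  matrix(as.integer(chars == "1"), nrow = n)
}

# split a bit matrix into s-bit symbols: (n x s*w) -> (n x w) integers
bits_to_symbols <- function(bits, s) {
  w <- ncol(bits) %/% s
  out <- matrix(0L, nrow = nrow(bits), ncol = w)
  for (jj in seq_len(w)) {
    block <- bits[, ((jj - 1L) * s + 1L):(jj * s), drop = FALSE]
    out[, jj] <- bits_to_int(block)
  }
  out
}

symbols_to_bits <- function(sym, s) {
  n <- nrow(sym)
  w <- ncol(sym)
  out <- matrix(0L, nrow = n, ncol = w * s)
  for (jj in seq_len(w)) {
    out[, ((jj - 1L) * s + 1L):(jj * s)] <- int_to_bits(sym[, jj], s)
  }
  out
}

max_homopolymer <- function(seqs) {
  vapply(seqs, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}
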