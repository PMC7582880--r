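# Reading and writing the standard sequence formats (via Biostrings) and
# plain one-read-per-line text.

#' Read sequencing reads from FASTA, FASTQ or plain text
#'
#' Format is chosen by file extension: `.fa`/`.fasta` and `.fq`/`.fastq`
#' are parsed with Biostrings (multi-line records and CRLF tolerated);
#' anything else is read as one sequence per line.
#'
#' @param path Input file.
#' @return A `read_set` tibble (`read_id`, `sequence`).
#' @export
read_reads <- function(path) {
  ext <- tolower(tools::file_ext(path))
  seqs <- if (ext %in% c("fa", "fasta")) {
    as.character(Biostrings::readDNAStringSet(path))
  } else if (ext %in% c("fq", "fastq")) {
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    lines <- readLines(path)
    lines <- gsub("\r$", "", lines)
    lines[nzchar(lines)]
  }
  tibble::new_tibble(
    list(read_id = seq_along(seqs), sequence = unname(toupper(seqs))),
    class = "read_set", nrow = length(seqs))
}

#' Write an oligo set as single-line FASTA
#'
#' Record ids are the decimal sequence indices.
#'
#' @param oligos An `oligo_set` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_oligos_fasta <- function(oligos, path) {
  x <- Biostrings::DNAStringSet(oligos$sequence)
  names(x) <- as.character(oligos$index)
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' Read a designed oligo set from FASTA
#'
#' Record ids are interpreted as decimal indices (as written by
#' [write_oligos_fasta()]); unparsable ids fall back to 0-based record
#' order.
#'
#' @param path Input FASTA.
#' @return An `oligo_set` tibble (`index`, `sequence`).
#' @export
read_oligos_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  idx <- suppressWarnings(as.integer(sub("\\s.*$", "", names(x))))
  if (anyNA(idx)) idx <- seq_along(x) - 1L
  tibble::new_tibble(
    list(index = idx, sequence = unname(as.character(x))),
    class = "oligo_set", nrow = length(x))
}

#' Write reads as plain text or FASTQ
#'
#' FASTQ output (extension `.fq`/`.fastq`) uses a constant quality of "I";
#' any other extension writes one read per line.
#'
#' @param reads A `read_set` tibble or character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  seqs <- read_sequences(reads)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fq", "fastq")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(c(paste0("@read", i), seqs[i], "+",
                   strrep("I", nchar(seqs[i]))), con)
    }
  } else {
    writeLines(seqs, path)
  }
  invisible(path)
}
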