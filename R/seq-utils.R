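# Nucleotide plumbing shared by the alignment and sequence-simulation code.
# All sequences are handled in DNA space: U is mapped to T on input so RNA
# and DNA inputs align in a single alphabet.

.BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and maps U to T. Any other character is an error that names
#' the first offending position.
#'
#' @param x single character string
#' @param what label used in error messages
#' @return normalized string over A/C/G/T
#' @export
normalize_seq <- function(x, what = "sequence") {
  .check(is.character(x) && length(x) == 1L && !is.na(x),
         sprintf("%s must be a single character string", what))
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% .BASES)
  .check(length(bad) == 0L,
         sprintf("illegal character '%s' in %s at position %d",
                 if (length(bad)) ch[bad[1]] else "", what,
                 if (length(bad)) bad[1] else 0L))
  x
}

# integer encoding: A=1 C=2 G=3 T=4; 0 is reserved for masked positions
.encode <- function(x) match(strsplit(x, "", fixed = TRUE)[[1]], .BASES)

.decode <- function(v) {
  out <- c("-", .BASES)[v + 1L]  # 0 -> "-"
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character string over A/C/G/T (U accepted)
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  x <- normalize_seq(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

.complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Read a FASTA file into a named character vector (DNA space)
#' @param path FASTA file path
#' @return named character vector of sequences, U mapped to T
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(ss), function(s) normalize_seq(s), character(1))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write named sequences to a FASTA file
#' @param seqs named character vector
#' @param path output path
#' @return invisibly, the path
#' @export
write_fasta_seqs <- function(seqs, path) {
  .check(!is.null(names(seqs)) && all(nzchar(names(seqs))),
         "sequences must be named")
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}
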