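# Reference genome handling. A reference is represented as a named list of
# character vectors (one single-character vector per contig) plus the raw
# sequences; built either from a FASTA file or directly from strings.

#' Build a reference object from sequences
#'
#' @param seqs named character vector of contig sequences
#' @return an object of class `reference`
#' @export
reference_from_seqs <- function(seqs) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]])
  structure(list(seqs = vapply(seqs, toupper, character(1)),
                 chars = chars,
                 lengths = vapply(chars, length, integer(1))),
            class = "reference")
}

#' Load a reference from a FASTA file
#'
#' @param path FASTA file (uncompressed or gzip)
#' @return a `reference` object
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  reference_from_seqs(seqs)
}

contig_length <- function(ref, contig) {
  if (!contig %in% names(ref$chars))
    stop("unknown contig: ", contig)
  ref$lengths[[contig]]
}

# Reference bases over [start, end) (0-based half-open), as a character vector.
ref_chars <- function(ref, contig, start, end) {
  ref$chars[[contig]][(start + 1L):end]
}

ref_base_at <- function(ref, contig, pos0) {
  ref$chars[[contig]][pos0 + 1L]
}

#' Write a reference to FASTA (and index it)
#'
#' @param ref a `reference` object
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(ss, path)
  Rsamtools::indexFa(path)
  invisible(path)
}
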