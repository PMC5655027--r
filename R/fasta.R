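#' Read contigs from a FASTA file
#'
#' Loads every record, normalizes lowercase to uppercase, and enforces the
#' contig-set invariants: unique ids, non-empty sequences, and an alphabet
#' restricted to A/C/G/T/N. The record id is the first whitespace-delimited
#' token of the header.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of uppercase sequences, one per record.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("FASTA ", path, ": duplicate record id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  as_contig_set(seqs, what = paste0("FASTA ", path))
}

#' Write contigs to a FASTA file
#'
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  contigs <- as_contig_set(contigs)
  set <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
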