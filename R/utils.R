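# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators have no side
#' effects on the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# standard genetic code, DNA codons -> one-letter amino acids ("*" = stop)
codon_table <- function() Biostrings::GENETIC_CODE

#' Translate DNA codons to amino acids
#'
#' Codons containing characters outside A/C/G/T (e.g. N) translate to NA.
#' @noRd
translate_codons <- function(codons) {
  aa <- unname(codon_table()[codons])
  aa
}

#' Reverse-complement character sequences
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

BASES <- c("A", "C", "G", "T")

# map ASCII byte -> base code 1..4 (A,C,G,T); anything else (incl. N) -> 0
base_code_lookup <- local({
  lk <- integer(256)
  lk[utf8ToInt("A")] <- 1L
  lk[utf8ToInt("C")] <- 2L
  lk[utf8ToInt("G")] <- 3L
  lk[utf8ToInt("T")] <- 4L
  lk
})

encode_bases <- function(seq) base_code_lookup[utf8ToInt(seq)]

# complement in code space: A<->T, C<->G
COMP_CODE <- c(4L, 3L, 2L, 1L)

#' Validate a contig set
#'
#' A contig set is a named character vector of uppercase A/C/G/T/N sequences
#' with unique non-empty ids and positive lengths.
#' @noRd
as_contig_set <- function(x, what = "contig set") {
  if (!is.character(x) || is.null(names(x))) {
    stop(what, ": expected a named character vector of sequences", call. = FALSE)
  }
  ids <- names(x)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(what, ": empty or missing contig id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(what, ": duplicate contig id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  x <- toupper(x)
  empty <- !nzchar(x)
  if (any(empty)) {
    stop(what, ": empty sequence for contig(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, ": characters outside {A,C,G,T,N} in contig(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  x
}

contig_lengths <- function(contigs) {
  stats::setNames(nchar(contigs), names(contigs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
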