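# Per-position base pileups from read alignments. The pileup is the
# substrate of SNV calling: a 4 x L count matrix (A/C/G/T) per contig.
# Positions inside read insertions contribute no base to any reference
# column; deletions consume reference positions without adding a base; N
# bases never count toward any allele or toward coverage.

# Long-format aligned bases per contig: for each contig a data.frame with
# read index, reference position and base code (1..4). N and non-ACGT bases
# are dropped here, once, for all downstream consumers.
alignment_base_pairs <- function(alignments, contigs) {
  contigs <- as_contig_set(contigs)
  out <- list()
  for (cn in unique(alignments$contig_id)) {
    rows <- which(alignments$contig_id == cn)
    refs <- vector("list", length(rows))
    codes <- vector("list", length(rows))
    rdix <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      cig <- alignments$cigar[i]
      if (grepl("^[0-9]+M$", cig)) {  # fast path: gapless
        len <- as.integer(sub("M$", "", cig))
        ref <- alignments$pos[i]:(alignments$pos[i] + len - 1L)
        code <- encode_bases(alignments$seq[i])
      } else {
        ap <- aligned_pairs(alignments$pos[i], cig)
        ref <- ap$ref
        code <- encode_bases(alignments$seq[i])[ap$read]
      }
      keep <- code > 0L
      refs[[k]] <- ref[keep]
      codes[[k]] <- code[keep]
      rdix[[k]] <- rep.int(k, sum(keep))
    }
    out[[cn]] <- data.frame(read = unlist(rdix), pos = unlist(refs),
                            code = unlist(codes))
  }
  out
}

#' Build a base pileup from alignments
#'
#' @param alignments Data.frame of alignment records (see [read_sam()] or
#'   [mix_and_sequence()]).
#' @param contigs Named character vector of reference sequences; all contigs
#'   given are represented in the pileup (a contig with no reads has an
#'   all-zero count matrix).
#' @return An object of class `"pileup"`: a list of 4 x L integer count
#'   matrices (rows A, C, G, T), one per contig, with a `lengths` attribute.
#' @export
build_pileup <- function(alignments, contigs) {
  contigs <- as_contig_set(contigs)
  lens <- contig_lengths(contigs)
  unknown <- setdiff(unique(alignments$contig_id), names(lens))
  if (length(unknown) > 0L) {
    stop("alignments reference unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pairs <- alignment_base_pairs(alignments, contigs)
  mats <- lapply(names(lens), function(cn) {
    len <- lens[[cn]]
    p <- pairs[[cn]]
    cnt <- if (is.null(p) || nrow(p) == 0L) {
      integer(4L * len)
    } else {
      tabulate((p$pos - 1L) * 4L + p$code, nbins = 4L * len)
    }
    matrix(cnt, nrow = 4L, dimnames = list(BASES, NULL))
  })
  names(mats) <- names(lens)
  structure(mats, lengths = lens, class = "pileup")
}

#' Pileup columns as a data.frame
#'
#' One row per reference position covered by at least one read.
#'
#' @param pileup A [build_pileup()] object.
#' @return Data.frame with `contig_id`, `position`, `A`, `C`, `G`, `T`,
#'   `coverage`.
#' @export
pileup_columns <- function(pileup) {
  stopifnot(inherits(pileup, "pileup"))
  rows <- lapply(names(pileup), function(cn) {
    m <- pileup[[cn]]
    cov <- colSums(m)
    at <- which(cov > 0L)
    if (length(at) == 0L) return(NULL)
    data.frame(contig_id = cn, position = at, A = m[1L, at], C = m[2L, at],
               G = m[3L, at], T = m[4L, at], coverage = cov[at],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), position = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), coverage = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Coverage statistics of a pileup
#'
#' Mean coverage over the total reference length (matching genome-wide mean
#' depth) and over covered positions only.
#'
#' @param pileup A [build_pileup()] object.
#' @return List with `total_length`, `covered_length`, `mean_coverage`,
#'   `mean_coverage_covered`.
#' @export
coverage_stats <- function(pileup) {
  stopifnot(inherits(pileup, "pileup"))
  total_len <- sum(attr(pileup, "lengths"))
  base_total <- sum(vapply(pileup, sum, numeric(1)))
  covered <- sum(vapply(pileup, function(m) sum(colSums(m) > 0L), numeric(1)))
  list(total_length = total_len, covered_length = covered,
       mean_coverage = base_total / total_len,
       mean_coverage_covered = if (covered > 0) base_total / covered else 0)
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup> ", length(x), " contig(s), total length ",
      sum(attr(x, "lengths")), " bp\n", sep = "")
  invisible(x)
}
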