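# Minimal SAM reader/writer. The subset understood here is what short-read
# pileup profiling needs: @SQ header lines, the unmapped/secondary flag bits,
# POS, CIGAR (M/=/X/I/D/N/S/H), and SEQ. BAM, supplementary alignments and
# paired-end rescue logic are deliberately out of scope.

SAM_FLAG_UNMAPPED <- 4L
SAM_FLAG_SECONDARY <- 256L

#' Parse a CIGAR string into operations
#'
#' @param cigar A single CIGAR string, e.g. `"2S3M1D4M"`.
#' @return A data.frame with columns `len` (integer) and `op` (character).
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L || paste(toks, collapse = "") != cigar) {
    stop("invalid CIGAR string: ", cigar, call. = FALSE)
  }
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = substr(toks, nchar(toks), nchar(toks)),
    stringsAsFactors = FALSE
  )
}

#' Reference footprint length of a CIGAR
#'
#' Number of reference bases consumed: the sum of M, =, X, D and N operation
#' lengths.
#'
#' @param cigar A CIGAR string.
#' @return Integer footprint length.
#' @export
cigar_reference_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

# read bases consumed by a CIGAR (must equal nchar(SEQ))
cigar_read_span <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
}

#' Aligned (reference position, read position) pairs for one alignment
#'
#' Expands a CIGAR into the matched pairs: insertions and soft clips consume
#' read bases but contribute no pair; deletions/skips consume reference bases
#' but contribute no pair.
#' @noRd
aligned_pairs <- function(pos, cigar) {
  ops <- parse_cigar(cigar)
  ref <- integer(0)
  rd <- integer(0)
  rcur <- pos
  qcur <- 1L
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      ref <- c(ref, rcur:(rcur + len - 1L))
      rd <- c(rd, qcur:(qcur + len - 1L))
      rcur <- rcur + len
      qcur <- qcur + len
    } else if (op %in% c("D", "N")) {
      rcur <- rcur + len
    } else if (op %in% c("I", "S")) {
      qcur <- qcur + len
    }
    # H and P consume neither
  }
  list(ref = ref, read = rd)
}

#' Read alignments from a SAM file
#'
#' Parses a minimal SAM subset and validates it against a contig set:
#' `@SQ` lengths must match, every reference name must be a known contig and
#' every alignment footprint must lie within its contig. Unmapped (flag 0x4)
#' and secondary (flag 0x100) records are skipped.
#'
#' @param path Path to a SAM text file.
#' @param contigs Named character vector of reference sequences
#'   (see [read_fasta()]).
#' @return A data.frame with columns `read_id`, `contig_id`, `pos`, `flag`,
#'   `mapq`, `cigar`, `seq`.
#' @export
read_sam <- function(path, contigs) {
  contigs <- as_contig_set(contigs)
  lens <- contig_lengths(contigs)
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  for (h in lines[hdr]) {
    if (startsWith(h, "@SQ")) {
      f <- strsplit(h, "\t", fixed = TRUE)[[1]]
      sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
      ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
      if (is.na(sn) || !(sn %in% names(lens))) {
        stop("SAM header references unknown contig: ", sn, call. = FALSE)
      }
      if (!is.na(ln) && ln != lens[[sn]]) {
        stop("SAM header length for ", sn, " (", ln,
             ") does not match contig length (", lens[[sn]], ")", call. = FALSE)
      }
    }
  }
  body <- lines[!hdr & nzchar(lines)]
  if (length(body) == 0L) {
    return(data.frame(read_id = character(0), contig_id = character(0),
                      pos = integer(0), flag = integer(0), mapq = integer(0),
                      cigar = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("SAM record with fewer than 11 fields at line ",
         which(!hdr & nzchar(lines))[which(nf < 11L)[1]], call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  rec <- data.frame(
    read_id = get(1), flag = as.integer(get(2)), contig_id = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    seq = toupper(get(10)), stringsAsFactors = FALSE
  )
  keep <- bitwAnd(rec$flag, SAM_FLAG_UNMAPPED) == 0L &
    bitwAnd(rec$flag, SAM_FLAG_SECONDARY) == 0L
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    rownames(rec) <- NULL
    return(rec[, c("read_id", "contig_id", "pos", "flag", "mapq", "cigar", "seq")])
  }
  unknown <- setdiff(unique(rec$contig_id), names(lens))
  if (length(unknown) > 0L) {
    stop("SAM references contig(s) absent from the contig set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  span <- vapply(rec$cigar, cigar_reference_span, integer(1), USE.NAMES = FALSE)
  off <- rec$pos < 1L | (rec$pos + span - 1L) > lens[rec$contig_id]
  if (any(off)) {
    stop("alignment footprint outside contig bounds for read(s): ",
         paste(utils::head(rec$read_id[off], 5L), collapse = ", "),
         call. = FALSE)
  }
  has_seq <- rec$seq != "*"
  qspan <- vapply(rec$cigar[has_seq],
                  function(c) cigar_read_span(parse_cigar(c)), numeric(1),
                  USE.NAMES = FALSE)
  bad <- which(has_seq)[qspan != nchar(rec$seq[has_seq])]
  if (length(bad) > 0L) {
    stop("CIGAR/SEQ length mismatch for read(s): ",
         paste(utils::head(rec$read_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  rownames(rec) <- NULL
  rec[, c("read_id", "contig_id", "pos", "flag", "mapq", "cigar", "seq")]
}

#' Write alignments to a SAM file
#'
#' @param alignments Data.frame as returned by [read_sam()].
#' @param contigs Named character vector of reference sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  contigs <- as_contig_set(contigs)
  lens <- contig_lengths(contigs)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  flag <- alignments$flag %||% rep(0L, nrow(alignments))
  mapq <- alignments$mapq %||% rep(60L, nrow(alignments))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  alignments$read_id, flag, alignments$contig_id,
                  alignments$pos, mapq, alignments$cigar, alignments$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}
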