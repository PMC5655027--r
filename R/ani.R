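# Fragment-based average nucleotide identity (ANIb-style): chop the query
# genome into fixed 1020 nt windows, find each fragment's best local
# alignment in the subject (k-mer seeds + diagonal voting to locate the
# candidate region, dynamic-programming extension to score it), and average
# the identities of fragments whose best hit passes the identity and
# coverage acceptance cutoffs. Both directions are computed; their mean is
# the headline value.

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `fragment_length` per contig; a terminal
#' remainder shorter than the window is discarded.
#'
#' @param contigs Named character vector of sequences.
#' @param fragment_length Window size in bp (>= 100; default 1020).
#' @return Data.frame with `fragment_id`, `contig_id`, `start`, `end`, `seq`.
#' @export
fragment_genome <- function(contigs, fragment_length = 1020L) {
  contigs <- as_contig_set(contigs)
  if (fragment_length < 100L) stop("fragment_length must be >= 100", call. = FALSE)
  rows <- lapply(names(contigs), function(cn) {
    len <- nchar(contigs[[cn]])
    n <- len %/% fragment_length
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1L) * fragment_length + 1L
    end <- start + fragment_length - 1L
    data.frame(fragment_id = sprintf("%s:%d-%d", cn, start, end),
               contig_id = cn, start = start, end = end,
               seq = substring(contigs[[cn]], start, end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fragment_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0), seq = character(0))
  }
  rownames(out) <- NULL
  out
}

# k-mer index over both strands of a subject genome. Sequences are stored
# per (contig, strand); minus-strand coordinates are on the reverse
# complement, which is all the aligner needs (identity is strand-symmetric).
build_subject_index <- function(subject, k = 15L) {
  subject <- as_contig_set(subject)
  seqs <- character(0)
  for (cn in names(subject)) {
    seqs[paste0(cn, "/+")] <- subject[[cn]]
    seqs[paste0(cn, "/-")] <- revcomp(subject[[cn]])
  }
  kmers <- list()
  for (sn in names(seqs)) {
    s <- seqs[[sn]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    kmers[[sn]] <- split(seq_len(n), km)
  }
  structure(list(seqs = seqs, kmers = kmers, k = k), class = "subject_index")
}

#' Align one fragment against a subject genome
#'
#' Seeds with exact shared k-mers on both strands, votes on banded
#' diagonals to pick the best candidate region, then computes a local
#' alignment (match 2, mismatch -3, gap open 5, gap extend 2) of the
#' fragment against that region. Returns the best hit or "no hit" when no
#' diagonal gathers at least `min_seeds` seeds.
#'
#' @param fragment A single sequence string.
#' @param subject Named character vector of subject sequences, or a
#'   prebuilt index from `build_subject_index()`.
#' @param k Seed k-mer length.
#' @param min_seeds Minimum seed count on the best diagonal band.
#' @param band Diagonal band width used to pool seeds.
#' @return List with `hit` (logical) and, for hits, `identity` (fraction of
#'   identical bases over aligned columns), `coverage` (aligned fragment
#'   fraction), `score`, `subject_name`.
#' @export
align_fragment <- function(fragment, subject, k = 15L, min_seeds = 2L,
                           band = 16L) {
  idx <- if (inherits(subject, "subject_index")) subject else {
    build_subject_index(subject, k)
  }
  k <- idx$k
  nf <- nchar(fragment) - k + 1L
  if (nf < 1L) return(list(hit = FALSE))
  fkm <- substring(fragment, seq_len(nf), seq_len(nf) + k - 1L)
  best <- NULL
  for (sn in names(idx$kmers)) {
    tab <- idx$kmers[[sn]]
    hits_q <- which(fkm %in% names(tab))
    if (length(hits_q) == 0L) next
    diag_votes <- integer(0)
    qpos <- integer(0)
    spos <- integer(0)
    for (q in hits_q) {
      sp <- tab[[fkm[q]]]
      qpos <- c(qpos, rep.int(q, length(sp)))
      spos <- c(spos, sp)
    }
    dband <- (spos - qpos) %/% band
    votes <- table(dband)
    top <- names(votes)[which.max(votes)]
    if (votes[[top]] < min_seeds) next
    sel <- dband == as.integer(top)
    d <- stats::median(spos[sel] - qpos[sel])
    cand <- list(subject_name = sn, diag = d, votes = votes[[top]])
    if (is.null(best) || cand$votes > best$votes) best <- cand
  }
  if (is.null(best)) return(list(hit = FALSE))
  sseq <- idx$seqs[[best$subject_name]]
  margin <- 60L
  s_from <- max(1L, best$diag + 1L - margin)
  s_to <- min(nchar(sseq), best$diag + nchar(fragment) + margin)
  window <- substr(sseq, s_from, s_to)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(fragment),
    subject = Biostrings::DNAString(window),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  ncols <- Biostrings::nchar(aln)
  if (ncols == 0L) return(list(hit = FALSE))
  identity <- Biostrings::nmatch(aln) / ncols
  pat <- Biostrings::pattern(aln)  # aligned range on the original fragment
  cov <- (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) /
    nchar(fragment)
  list(hit = TRUE, identity = unname(identity), coverage = unname(cov),
       score = Biostrings::score(aln), subject_name = best$subject_name)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' @param genome_a,genome_b Named character vectors of sequences.
#' @param fragment_length Fragment window size (1020 bp by convention).
#' @param min_identity Acceptance cutoff on per-fragment identity (fraction).
#' @param min_fragment_coverage Acceptance cutoff on aligned fragment
#'   fraction.
#' @param k Seed k-mer length.
#' @return Object of class `"ani_result"` with per-direction identities and
#'   acceptance counts, `ani_ab` and `ani_ba` (percent mean identity over
#'   accepted fragments in each direction), and `mean_of_directions` (the
#'   headline ANI, percent). Directions with no accepted fragment give `NA`
#'   and are flagged in `undefined`.
#' @export
compute_ani <- function(genome_a, genome_b, fragment_length = 1020L,
                        min_identity = 0.7, min_fragment_coverage = 0.7,
                        k = 15L) {
  genome_a <- as_contig_set(genome_a)
  genome_b <- as_contig_set(genome_b)
  if (length(genome_a) == 0L || length(genome_b) == 0L) {
    stop("both genomes must be non-empty", call. = FALSE)
  }
  direction <- function(query, subject) {
    frags <- fragment_genome(query, fragment_length)
    idx <- build_subject_index(subject, k)
    ids <- rep(NA_real_, nrow(frags))
    accepted <- logical(nrow(frags))
    for (i in seq_len(nrow(frags))) {
      h <- align_fragment(frags$seq[i], idx, k = k)
      if (h$hit) {
        ids[i] <- h$identity
        accepted[i] <- h$identity >= min_identity &&
          h$coverage >= min_fragment_coverage
      }
    }
    list(identities = ids[accepted], fragments_total = nrow(frags),
         fragments_aligned = sum(accepted))
  }
  ab <- direction(genome_a, genome_b)
  ba <- direction(genome_b, genome_a)
  ani_ab <- if (ab$fragments_aligned > 0L) 100 * mean(ab$identities) else NA_real_
  ani_ba <- if (ba$fragments_aligned > 0L) 100 * mean(ba$identities) else NA_real_
  mean_dir <- mean(c(ani_ab, ani_ba), na.rm = TRUE)
  structure(list(
    forward = ab, reverse = ba, ani_ab = ani_ab, ani_ba = ani_ba,
    mean_of_directions = if (is.nan(mean_dir)) NA_real_ else mean_dir,
    undefined = is.na(ani_ab) && is.na(ani_ba)
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ANI> mean of directions: %s (A->B %s, B->A %s); %d/%d and %d/%d fragments accepted\n",
              format(round(x$mean_of_directions, 2)),
              format(round(x$ani_ab, 2)), format(round(x$ani_ba, 2)),
              x$forward$fragments_aligned, x$forward$fragments_total,
              x$reverse$fragments_aligned, x$reverse$fragments_total))
  invisible(x)
}

#' Pairwise ANI matrix over a set of genomes
#'
#' @param genomes Named list of genomes (each a named character vector).
#' @param ... Passed to [compute_ani()].
#' @return Symmetric numeric matrix of headline ANI values (percent), 100 on
#'   the diagonal.
#' @export
ani_matrix <- function(genomes, ...) {
  n <- length(genomes)
  stopifnot(n >= 2L, !is.null(names(genomes)))
  m <- matrix(100, n, n, dimnames = list(names(genomes), names(genomes)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- compute_ani(genomes[[i]], genomes[[j]], ...)
      m[i, j] <- m[j, i] <- r$mean_of_directions
    }
  }
  m
}
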