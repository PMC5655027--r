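# Codon-aware single-amino-acid variant (SAAV) calling. For each codon of
# each ORF, only reads that map to all three codon positions contribute: the
# in-frame 3-mer of each spanning read is translated (reverse-complemented
# for minus-strand ORFs) and amino acids are tallied. This preserves the
# physical linkage of the three bases within a read and avoids the inflation
# a per-position caller would produce from partial codon mappings. Stop
# codons are tallied as the distinct symbol "*".

#' Call single-amino-acid variants
#'
#' A codon is a SAAV iff its spanning coverage (reads aligned at all three
#' codon positions with called bases) is at least `min_spanning_coverage` and
#' the amino-acid departure from consensus is at least `min_departure`. The
#' departure/coverage defaults mirror the SNV thresholds.
#'
#' @param alignments Alignment data.frame (see [read_sam()]).
#' @param contigs Named character vector of reference sequences.
#' @param orfs ORF table (1-based inclusive coordinates, length divisible
#'   by 3).
#' @param min_spanning_coverage Minimum number of codon-spanning reads.
#' @param min_departure Minimum amino-acid departure from consensus.
#' @return Data.frame with one row per SAAV: `orf_id`, `codon_index`,
#'   `consensus_aa`, `aa_counts` (e.g. `"K=7;E=3"`), `spanning_coverage`,
#'   `departure_from_consensus_aa`, `n_aa_observed`. Ties for the consensus
#'   amino acid break lexicographically.
#' @export
call_saavs <- function(alignments, contigs, orfs, min_spanning_coverage = 10L,
                       min_departure = 0.05) {
  contigs <- as_contig_set(contigs)
  orfs <- validate_orfs(orfs, contigs)
  pairs <- alignment_base_pairs(alignments, contigs)
  letters4 <- BASES
  rows <- list()
  n_out <- 0L
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    p <- pairs[[o$contig_id]]
    if (is.null(p) || nrow(p) == 0L) next
    sel <- p$pos >= o$start & p$pos <= o$end
    if (!any(sel)) next
    sub <- p[sel, ]
    if (o$strand == "+") {
      off <- sub$pos - o$start
      code <- sub$code
    } else {
      off <- o$end - sub$pos
      code <- COMP_CODE[sub$code]
    }
    codon <- off %/% 3L + 1L
    slot <- off %% 3L
    n_codons <- (o$end - o$start + 1L) %/% 3L
    # each (read, codon) key accumulates one base per slot in radix-5 digits
    key <- as.numeric(sub$read) * (n_codons + 1) + codon
    contrib <- code * 5^slot
    acc <- rowsum(contrib, key)
    codon_of_key <- as.numeric(rownames(acc)) %% (n_codons + 1)
    b0 <- acc[, 1] %% 5
    b1 <- (acc[, 1] %/% 5) %% 5
    b2 <- (acc[, 1] %/% 25) %% 5
    spans <- b0 > 0 & b1 > 0 & b2 > 0
    if (!any(spans)) next
    cdn <- codon_of_key[spans]
    aa <- translate_codons(paste0(letters4[b0[spans]], letters4[b1[spans]],
                                  letters4[b2[spans]]))
    for (cd in unique(cdn)) {
      counts <- sort(table(aa[cdn == cd]), decreasing = TRUE)
      covg <- sum(counts)
      if (covg < min_spanning_coverage) next
      # consensus: highest count, lexicographic tie-break
      top <- max(counts)
      cons <- sort(names(counts)[counts == top])[1]
      dep <- 1 - counts[[cons]] / covg
      if (dep < min_departure) next
      n_out <- n_out + 1L
      rows[[n_out]] <- data.frame(
        orf_id = o$orf_id, codon_index = as.integer(cd), consensus_aa = cons,
        aa_counts = paste(names(counts), counts, sep = "=", collapse = ";"),
        spanning_coverage = as.integer(covg),
        departure_from_consensus_aa = dep,
        n_aa_observed = length(counts), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(orf_id = character(0), codon_index = integer(0),
                      consensus_aa = character(0), aa_counts = character(0),
                      spanning_coverage = integer(0),
                      departure_from_consensus_aa = numeric(0),
                      n_aa_observed = integer(0))
  }
  rownames(out) <- NULL
  out
}
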