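#' Summarize variant statistics for one MAG
#'
#' Produces the per-MAG row of the standard summary table: SNV density per
#' kbp, mean majority allele frequency over SNV positions, SAAV/SNV ratio
#' (a pN/pS-like selection proxy), mean coverage and coverage normalized per
#' 100 million metagenome reads.
#'
#' @param snvs SNV data.frame from [call_snvs()].
#' @param saavs SAAV data.frame from [call_saavs()].
#' @param pileup Pileup for the MAG's contigs (for coverage and length).
#' @param mag_id MAG identifier.
#' @param total_reads Total reads in the source metagenome (for normalized
#'   coverage); `NA` leaves normalized coverage `NA`.
#' @param denominator `"total"` (default; density over total MAG length,
#'   matching the conventional SNVs/kbp unit) or `"covered"` (density over
#'   positions with any coverage).
#' @param maf_over `"snv"` (default; mean majority allele frequency over SNV
#'   positions only) or `"all"` (over every covered position).
#' @return One-row data.frame with the columns of [write_summary_tsv()].
#'   With zero SNVs, `saav_snv_ratio` and `mean_majority_allele_frequency`
#'   are `NA` (undefined), never 0.
#' @export
summarize_mag <- function(snvs, saavs, pileup, mag_id,
                          total_reads = NA_real_,
                          denominator = c("total", "covered"),
                          maf_over = c("snv", "all")) {
  denominator <- match.arg(denominator)
  maf_over <- match.arg(maf_over)
  cs <- coverage_stats(pileup)
  len <- if (denominator == "total") cs$total_length else cs$covered_length
  snv_count <- nrow(snvs)
  saav_count <- nrow(saavs)
  maf <- if (maf_over == "snv") {
    if (snv_count > 0L) mean(snvs$majority_allele_frequency) else NA_real_
  } else {
    cols <- pileup_columns(pileup)
    if (nrow(cols) == 0L) NA_real_ else {
      m <- as.matrix(cols[, c("A", "C", "G", "T")])
      mean(apply(m, 1L, max) / cols$coverage)
    }
  }
  data.frame(
    mag_id = mag_id,
    total_length = cs$total_length,
    mean_coverage = cs$mean_coverage,
    normalized_coverage = if (is.na(total_reads)) NA_real_ else {
      cs$mean_coverage / (total_reads / 1e8)
    },
    snv_count = snv_count,
    snvs_per_kbp = 1000 * snv_count / len,
    mean_majority_allele_frequency = maf,
    saav_count = saav_count,
    saav_snv_ratio = if (snv_count == 0L) NA_real_ else saav_count / snv_count,
    fraction_biallelic = if (snv_count == 0L) NA_real_ else {
      mean(snvs$n_alleles_observed == 2L)
    },
    stringsAsFactors = FALSE
  )
}

#' Distribution of majority allele frequencies across SNVs
#'
#' Bins the per-SNV majority allele frequency (support `[0.25, 1]`: with four
#' bases the majority allele carries at least a quarter of the reads) and
#' reports the mean and modal bin midpoint. Note the documented bias of the
#' statistic: at a perfectly even 50/50 strain mixture the *majority* count
#' of a symmetric binomial exceeds half, so the mean sits slightly above 0.5.
#'
#' @param snvs SNV data.frame from [call_snvs()] (at least one row).
#' @param bin_width Histogram bin width on `[0, 1]`.
#' @return List of class `"allele_freq_dist"`: `breaks`, `mids`, `counts`,
#'   `density`, `mean`, `mode` (midpoint of the fullest bin).
#' @export
allele_frequency_distribution <- function(snvs, bin_width = 0.05) {
  if (!is.data.frame(snvs) || nrow(snvs) == 0L) {
    stop("allele_frequency_distribution requires at least one SNV", call. = FALSE)
  }
  f <- snvs$majority_allele_frequency
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(f, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 density = h$density, mean = mean(f),
                 mode = h$mids[which.max(h$counts)]),
            class = "allele_freq_dist")
}

#' @export
print.allele_freq_dist <- function(x, ...) {
  cat("<allele frequency distribution> n =", sum(x$counts),
      " mean =", round(x$mean, 4), " mode bin =", x$mode, "\n")
  invisible(x)
}
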