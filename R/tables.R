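# TSV-backed tables: bin membership + MAG metadata, ORF tables, and the
# per-MAG variant summary in the Table-2-style column layout.

#' Validate an ORF table
#'
#' Enforces: `end >= start`, ORF length divisible by 3, strand in `+`/`-`,
#' and (when contigs are supplied) ORF coordinates within contig bounds.
#' Coordinates are 1-based inclusive.
#'
#' @param orfs Data.frame with columns `orf_id`, `contig_id`, `start`, `end`,
#'   `strand`, and optionally `cog_category` and `cluster_id`.
#' @param contigs Optional named character vector of contig sequences.
#' @return The validated data.frame.
#' @export
validate_orfs <- function(orfs, contigs = NULL) {
  need <- c("orf_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(orfs))
  if (length(miss) > 0L) {
    stop("ORF table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(orfs$orf_id)) stop("duplicate orf_id in ORF table", call. = FALSE)
  if (any(orfs$end < orfs$start)) {
    stop("ORF table: end < start for ",
         paste(orfs$orf_id[orfs$end < orfs$start], collapse = ", "), call. = FALSE)
  }
  len <- orfs$end - orfs$start + 1L
  if (any(len %% 3L != 0L)) {
    stop("ORF length not divisible by 3 for: ",
         paste(orfs$orf_id[len %% 3L != 0L], collapse = ", "), call. = FALSE)
  }
  if (!all(orfs$strand %in% c("+", "-"))) {
    stop("ORF strand must be '+' or '-'", call. = FALSE)
  }
  if (!is.null(contigs)) {
    contigs <- as_contig_set(contigs)
    lens <- contig_lengths(contigs)
    unknown <- setdiff(unique(orfs$contig_id), names(lens))
    if (length(unknown) > 0L) {
      stop("ORF table references unknown contig(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- orfs$start < 1L | orfs$end > lens[orfs$contig_id]
    if (any(out)) {
      stop("ORF outside contig bounds: ",
           paste(orfs$orf_id[out], collapse = ", "), call. = FALSE)
    }
  }
  orfs
}

#' Read an ORF table from TSV
#'
#' @inheritParams validate_orfs
#' @param path TSV path with a header line.
#' @export
read_orf_table <- function(path, contigs = NULL) {
  orfs <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_orfs(orfs, contigs)
}

#' Write an ORF table to TSV
#' @param orfs ORF data.frame.
#' @param path Output path.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter MAGs on completeness and redundancy
#'
#' Retains MAGs with completeness strictly above `min_completeness` and
#' redundancy strictly below `max_redundancy` (defaults 70% and 10%, the
#' conventional quality gate for calling a bin a MAG). Both inequalities are
#' strict, so a bin at exactly 10% redundancy is dropped.
#'
#' @param mags Data.frame of per-MAG metadata with at least `mag_id`,
#'   `completeness`, `redundancy` (both in percent, 0-100).
#' @param min_completeness Completeness threshold (percent).
#' @param max_redundancy Redundancy threshold (percent).
#' @return The retained rows of `mags`.
#' @export
filter_mags <- function(mags, min_completeness = 70, max_redundancy = 10) {
  need <- c("mag_id", "completeness", "redundancy")
  miss <- setdiff(need, names(mags))
  if (length(miss) > 0L) {
    stop("MAG metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(mags$completeness) | is.na(mags$redundancy)
  if (any(bad)) {
    stop("missing completeness/redundancy for MAG(s): ",
         paste(mags$mag_id[bad], collapse = ", "), call. = FALSE)
  }
  rng <- mags$completeness < 0 | mags$completeness > 100 |
    mags$redundancy < 0 | mags$redundancy > 100
  if (any(rng)) {
    stop("completeness/redundancy outside [0,100] for MAG(s): ",
         paste(mags$mag_id[rng], collapse = ", "), call. = FALSE)
  }
  keep <- mags$completeness > min_completeness & mags$redundancy < max_redundancy
  out <- mags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a contig-to-MAG membership table
#'
#' @param path TSV with columns `contig_id`, `mag_id`.
#' @export
read_bin_membership <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "mag_id")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L) {
    stop("bin membership missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$contig_id)) {
    stop("contig assigned to more than one MAG: ",
         paste(unique(m$contig_id[duplicated(m$contig_id)]), collapse = ", "),
         call. = FALSE)
  }
  m
}

# column order and printed precision of the per-MAG summary table
SUMMARY_COLUMNS <- c(
  mag_id = NA, total_length = 0, mean_coverage = 2, normalized_coverage = 2,
  snv_count = 0, snvs_per_kbp = 2, mean_majority_allele_frequency = 4,
  saav_count = 0, saav_snv_ratio = 4, fraction_biallelic = 4
)

#' Write per-MAG variant summaries to TSV
#'
#' One header line; fixed column order (`mag_id`, `total_length`,
#' `mean_coverage`, `normalized_coverage`, `snv_count`, `snvs_per_kbp`,
#' `mean_majority_allele_frequency`, `saav_count`, `saav_snv_ratio`,
#' `fraction_biallelic`); frequencies/ratios at 4 decimals, coverages and
#' densities at 2. The file re-reads losslessly at that precision via
#' [read_summary_tsv()]. An undefined SAAV/SNV ratio (zero SNVs) is written
#' as `NA`, never as 0.
#'
#' @param rows Data.frame of [summarize_mag()] rows.
#' @param path Output path.
#' @export
write_summary_tsv <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("summary rows must be a non-empty data.frame", call. = FALSE)
  }
  cols <- names(SUMMARY_COLUMNS)
  miss <- setdiff(cols, names(rows))
  if (length(miss) > 0L) {
    stop("summary rows missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- rows[, cols, drop = FALSE]
  for (cn in cols) {
    dg <- SUMMARY_COLUMNS[[cn]]
    if (!is.na(dg) && dg > 0) {
      out[[cn]] <- ifelse(is.na(out[[cn]]), NA_character_,
                          sprintf(paste0("%.", dg, "f"), out[[cn]]))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open summary output path: ", path, call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-MAG variant summary TSV
#' @param path Path written by [write_summary_tsv()].
#' @export
read_summary_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
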