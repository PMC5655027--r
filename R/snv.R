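# SNV calling. A reference position is a single-nucleotide variant iff its
# coverage is at least `min_coverage` and the departure from consensus --
# the fraction of mapped bases not matching the majority base -- is at
# least `min_departure`. The fixed defaults (coverage 10, departure 0.05)
# are the study conditions; a coverage-dependent baseline can be plugged in
# through `threshold_fun` for callers that scale the departure floor with
# depth.

#' Call single-nucleotide variants from a pileup
#'
#' @param pileup A [build_pileup()] object.
#' @param min_coverage Minimum coverage for a position to be evaluated.
#' @param min_departure Minimum departure from consensus
#'   (1 - majority allele frequency).
#' @param threshold_fun Optional function of coverage returning the minimum
#'   departure at that coverage; overrides `min_departure` when given.
#' @return Data.frame with one row per SNV: `contig_id`, `position`,
#'   `consensus`, per-base counts `A`/`C`/`G`/`T`, `coverage`,
#'   `departure_from_consensus`, `majority_allele_frequency`,
#'   `n_alleles_observed`. Ties for the majority base break on the fixed
#'   order A < C < G < T.
#' @export
call_snvs <- function(pileup, min_coverage = 10L, min_departure = 0.05,
                      threshold_fun = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  if (min_coverage < 1L) stop("min_coverage must be >= 1", call. = FALSE)
  if (min_departure < 0 || min_departure > 1) {
    stop("min_departure must be in [0, 1]", call. = FALSE)
  }
  rows <- lapply(names(pileup), function(cn) {
    m <- pileup[[cn]]
    cov <- colSums(m)
    cand <- which(cov >= min_coverage)
    if (length(cand) == 0L) return(NULL)
    sub <- m[, cand, drop = FALSE]
    maj_idx <- max.col(t(sub), ties.method = "first")  # A<C<G<T tie-break
    maj_cnt <- sub[cbind(maj_idx, seq_along(cand))]
    maf <- maj_cnt / cov[cand]
    dep <- 1 - maf
    floor_dep <- if (is.null(threshold_fun)) min_departure else {
      threshold_fun(cov[cand])
    }
    is_snv <- dep >= floor_dep
    if (!any(is_snv)) return(NULL)
    at <- cand[is_snv]
    sub <- sub[, is_snv, drop = FALSE]
    data.frame(
      contig_id = cn, position = at, consensus = BASES[maj_idx[is_snv]],
      A = sub[1L, ], C = sub[2L, ], G = sub[3L, ], T = sub[4L, ],
      coverage = cov[at],
      departure_from_consensus = dep[is_snv],
      majority_allele_frequency = maf[is_snv],
      n_alleles_observed = colSums(sub > 0L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), position = integer(0),
                      consensus = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), coverage = integer(0),
                      departure_from_consensus = numeric(0),
                      majority_allele_frequency = numeric(0),
                      n_alleles_observed = integer(0))
  }
  rownames(out) <- NULL
  out
}
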