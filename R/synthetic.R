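# Synthetic strain-community generator. Emulates the data the pipeline sees
# in a real study -- a reference genome with ORFs, strain variants carrying
# substitutions at a controlled density and nonsynonymous fraction, strains
# mixed at controlled proportions and sequenced as ~170 bp single-end reads
# with known alignments -- together with full ground truth, so variant calls,
# ANI and pangenome statistics can be checked against planted values.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Generate a random reference genome with annotated ORFs
#'
#' Contigs are uniform random A/C/G/T. ORFs are written into the sequence as
#' ATG + sense codons + stop codon (reverse-complemented for minus-strand
#' ORFs), non-overlapping, on both strands, until roughly `orf_density` of
#' the genome is coding. Deterministic given `seed`.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (>= 1000).
#' @param orf_density Target fraction of coding bases, in `[0, 0.85]`.
#' @param seed Integer seed.
#' @return A list with `contigs` (named character vector) and `orfs`
#'   (ORF table data.frame).
#' @export
generate_reference <- function(n_contigs = 1L, contig_length = 10000L,
                               orf_density = 0.7, seed) {
  if (contig_length < 1000L) stop("contig_length must be >= 1000", call. = FALSE)
  if (orf_density < 0 || orf_density > 0.85) {
    stop("orf_density infeasible: must be in [0, 0.85]", call. = FALSE)
  }
  sense <- setdiff(all_codons(), STOP_CODONS)
  with_seed(seed, {
    contigs <- character(n_contigs)
    names(contigs) <- sprintf("contig_%02d", seq_len(n_contigs))
    orf_rows <- list()
    orf_n <- 0L
    for (ci in seq_len(n_contigs)) {
      seq_chars <- sample(BASES, contig_length, replace = TRUE)
      coding <- 0L
      pos <- sample(10:60, 1L)
      while (coding < orf_density * contig_length) {
        n_codons <- sample(60:220, 1L)
        orf_len <- 3L * n_codons
        if (pos + orf_len - 1L > contig_length - 10L) break
        body <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
                  sample(STOP_CODONS, 1L))
        orf_seq <- paste(body, collapse = "")
        strand <- sample(c("+", "-"), 1L)
        placed <- if (strand == "+") orf_seq else revcomp(orf_seq)
        seq_chars[pos:(pos + orf_len - 1L)] <-
          strsplit(placed, "", fixed = TRUE)[[1]]
        orf_n <- orf_n + 1L
        orf_rows[[orf_n]] <- data.frame(
          orf_id = sprintf("%s_orf_%03d", names(contigs)[ci], orf_n),
          contig_id = names(contigs)[ci], start = pos,
          end = pos + orf_len - 1L, strand = strand, stringsAsFactors = FALSE
        )
        coding <- coding + orf_len
        pos <- pos + orf_len + sample(20:120, 1L)
      }
      if (orf_density > 0 && coding < 0.5 * orf_density * contig_length) {
        stop("orf_density infeasible for contig_length ", contig_length,
             call. = FALSE)
      }
      contigs[ci] <- paste(seq_chars, collapse = "")
    }
    orfs <- if (orf_n == 0L) {
      data.frame(orf_id = character(0), contig_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    } else do.call(rbind, orf_rows)
    list(contigs = as_contig_set(contigs), orfs = orfs)
  })
}

# Per-base coding map: one row per coding position with its ORF, codon index
# (1-based within the ORF, in coding orientation) and codon slot (0..2).
coding_map <- function(contigs, orfs) {
  if (nrow(orfs) == 0L) {
    return(data.frame(contig_id = character(0), pos = integer(0),
                      orf_id = character(0), codon = integer(0),
                      slot = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    pos <- o$start:o$end
    off <- if (o$strand == "+") pos - o$start else o$end - pos
    data.frame(contig_id = o$contig_id, pos = pos, orf_id = o$orf_id,
               codon = off %/% 3L + 1L, slot = off %% 3L, strand = o$strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Effect of substituting `alt` at a coding position: TRUE if the encoded
# amino acid changes. `codon_seq` is the reference codon in coding
# orientation; `slot` the 0-based position within it; for minus-strand ORFs
# the substituted base enters the codon complemented.
substitution_changes_aa <- function(codon_seq, slot, alt, strand) {
  base_in_codon <- if (strand == "+") alt else BASES[COMP_CODE[match(alt, BASES)]]
  mutated <- codon_seq
  substr(mutated, slot + 1L, slot + 1L) <- base_in_codon
  isTRUE(translate_codons(mutated) != translate_codons(codon_seq))
}

# reference codon (coding orientation) for an ORF row and codon index
reference_codon <- function(contigs, orf, codon_idx) {
  if (orf$strand == "+") {
    s <- orf$start + 3L * (codon_idx - 1L)
    substr(contigs[[orf$contig_id]], s, s + 2L)
  } else {
    e <- orf$end - 3L * (codon_idx - 1L)
    revcomp(substr(contigs[[orf$contig_id]], e - 2L, e))
  }
}

#' Inject substitutions into a genome to create a strain variant
#'
#' Places exactly `n_snvs` single-base substitutions; the realized number of
#' amino-acid-changing (nonsynonymous) substitutions equals
#' `round(nonsyn_fraction * n_snvs)`, achieved by classifying candidate
#' substitutions with the standard codon table. Synonymous quota is filled
#' from noncoding positions and synonymous coding changes. By default at most
#' one variant is placed per codon and variants are at least 3 bp apart, so
#' one codon carries at most one variant.
#'
#' @param contigs Reference genome (named character vector).
#' @param orfs ORF table for the reference.
#' @param n_snvs Number of substitutions to place.
#' @param nonsyn_fraction Target nonsynonymous fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param min_spacing Minimum distance between placed variants (bp).
#' @param exclude Optional data.frame (`contig_id`, `pos`) of positions to
#'   avoid (e.g. variants already used by another strain).
#' @return A list with `contigs` (the mutated genome) and `truth`, a
#'   data.frame with one row per injected variant: `contig_id`, `pos`,
#'   `ref`, `alt`, `is_nonsynonymous`, `orf_id`, `codon_index`.
#' @export
mutate_strain <- function(contigs, orfs, n_snvs, nonsyn_fraction, seed,
                          min_spacing = 3L, exclude = NULL) {
  contigs <- as_contig_set(contigs)
  validate_orfs(orfs, contigs)
  if (nonsyn_fraction < 0 || nonsyn_fraction > 1) {
    stop("nonsyn_fraction must be in [0, 1]", call. = FALSE)
  }
  n_nonsyn <- round(nonsyn_fraction * n_snvs)
  n_syn <- n_snvs - n_nonsyn
  cmap <- coding_map(contigs, orfs)
  ckey <- paste(cmap$contig_id, cmap$pos)
  with_seed(seed, {
    # candidate pool: every (contig, pos)
    lens <- contig_lengths(contigs)
    used <- new.env(hash = TRUE, parent = emptyenv())  # blocked positions
    block <- function(contig, pos) {
      for (p in (pos - min_spacing + 1L):(pos + min_spacing - 1L)) {
        assign(paste(contig, p), TRUE, envir = used)
      }
    }
    if (!is.null(exclude) && nrow(exclude) > 0L) {
      for (i in seq_len(nrow(exclude))) block(exclude$contig_id[i], exclude$pos[i])
    }
    blocked <- function(contig, pos) {
      exists(paste(contig, pos), envir = used, inherits = FALSE)
    }
    orf_by_id <- split(orfs, orfs$orf_id)
    pick_sites <- function(n_needed, want_nonsyn) {
      out <- vector("list", n_needed)
      got <- 0L
      # iterate candidate positions in a random order
      all_pos <- do.call(rbind, lapply(names(lens), function(cn) {
        data.frame(contig_id = cn, pos = seq_len(lens[[cn]]),
                   stringsAsFactors = FALSE)
      }))
      ord <- sample.int(nrow(all_pos))
      map_idx <- match(paste(all_pos$contig_id, all_pos$pos), ckey)
      for (j in ord) {
        if (got == n_needed) break
        contig <- all_pos$contig_id[j]
        pos <- all_pos$pos[j]
        if (blocked(contig, pos)) next
        mi <- map_idx[j]
        in_orf <- !is.na(mi)
        ref <- substr(contigs[[contig]], pos, pos)
        if (!ref %in% BASES) next
        alts <- setdiff(BASES, ref)
        if (in_orf) {
          orf <- orf_by_id[[cmap$orf_id[mi]]]
          codon <- reference_codon(contigs, orf, cmap$codon[mi])
          changes <- vapply(alts, substitution_changes_aa, logical(1),
                            codon_seq = codon, slot = cmap$slot[mi],
                            strand = orf$strand)
          alts <- if (want_nonsyn) alts[changes] else alts[!changes]
          if (length(alts) == 0L) next
        } else if (want_nonsyn) {
          next  # noncoding positions cannot be nonsynonymous
        }
        alt <- if (length(alts) == 1L) alts else sample(alts, 1L)
        got <- got + 1L
        out[[got]] <- data.frame(
          contig_id = contig, pos = pos, ref = ref, alt = alt,
          is_nonsynonymous = want_nonsyn,
          orf_id = if (in_orf) cmap$orf_id[mi] else NA_character_,
          codon_index = if (in_orf) cmap$codon[mi] else NA_integer_,
          stringsAsFactors = FALSE
        )
        block(contig, pos)
      }
      if (got < n_needed) {
        stop("target nonsynonymous fraction unreachable: only ", got, " of ",
             n_needed, if (want_nonsyn) " nonsynonymous" else " synonymous",
             " sites available", call. = FALSE)
      }
      do.call(rbind, out)
    }
    truth <- rbind(
      if (n_nonsyn > 0L) pick_sites(n_nonsyn, TRUE),
      if (n_syn > 0L) pick_sites(n_syn, FALSE)
    )
    if (is.null(truth)) {
      truth <- data.frame(contig_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          is_nonsynonymous = logical(0),
                          orf_id = character(0), codon_index = integer(0),
                          stringsAsFactors = FALSE)
    }
    mutated <- contigs
    if (nrow(truth) > 0L) {
      for (cn in unique(truth$contig_id)) {
        s <- mutated[[cn]]
        rows <- truth[truth$contig_id == cn, ]
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[rows$pos] <- rows$alt
        mutated[[cn]] <- paste(ch, collapse = "")
      }
    }
    rownames(truth) <- NULL
    list(contigs = mutated, truth = truth)
  })
}

#' Sequence a mixture of strains into reads with known alignments
#'
#' Reads are drawn per contig to the requested depth, assigned to strains
#' multinomially by mixing proportion, started uniformly along the contig,
#' and (optionally) corrupted with independent substitution errors. Because
#' strains differ from the reference only by substitutions, the true
#' placement is the alignment, so no external mapper is needed: the expected
#' alternate-allele frequency at an injected biallelic site equals the summed
#' proportion of the carrying strains.
#'
#' @param strains List of genomes (named character vectors with identical
#'   contig names and lengths); the first is conventionally the reference.
#' @param proportions Mixing proportions, summing to 1.
#' @param read_length Read length in bp (the study conditions use 170 bp
#'   single-end fragments).
#' @param depth Target mean coverage depth.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param sam_path,fasta_path Optional output paths; when given, a SAM file
#'   with the true alignments and/or a reads FASTA are written.
#' @return A list with `alignments` (data.frame usable by [build_pileup()]),
#'   `reads` (named character vector), and `truth` (data.frame with per-read
#'   `strain` index and `n_errors`).
#' @export
mix_and_sequence <- function(strains, proportions, read_length = 170L,
                             depth = 50, error_rate = 0, seed,
                             sam_path = NULL, fasta_path = NULL) {
  stopifnot(length(strains) >= 1L, length(proportions) == length(strains))
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("strain proportions must sum to 1", call. = FALSE)
  }
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  strains <- lapply(strains, as_contig_set)
  lens <- contig_lengths(strains[[1]])
  for (s in strains[-1]) {
    if (!identical(contig_lengths(s), lens)) {
      stop("all strains must share contig names and lengths", call. = FALSE)
    }
  }
  if (any(read_length > lens)) {
    stop("read_length exceeds contig length", call. = FALSE)
  }
  with_seed(seed, {
    aln <- list()
    truth <- list()
    for (cn in names(lens)) {
      len <- lens[[cn]]
      n_reads <- round(depth * len / read_length)
      if (n_reads == 0L) next
      strain_idx <- sample.int(length(strains), n_reads, replace = TRUE,
                               prob = proportions)
      starts <- sample.int(len - read_length + 1L, n_reads, replace = TRUE)
      strain_seqs <- vapply(strains, `[[`, character(1), cn)
      seqs <- substring(strain_seqs[strain_idx], starts,
                        starts + read_length - 1L)
      n_err <- if (error_rate > 0) {
        stats::rbinom(n_reads, read_length, error_rate)
      } else integer(n_reads)
      for (i in which(n_err > 0L)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- sample.int(read_length, n_err[i])
        ch[at] <- vapply(ch[at], function(b) sample(setdiff(BASES, b), 1L), "")
        seqs[i] <- paste(ch, collapse = "")
      }
      ids <- sprintf("%s_read_%06d", cn, seq_len(n_reads))
      aln[[cn]] <- data.frame(
        read_id = ids, contig_id = cn, pos = starts, flag = 0L, mapq = 60L,
        cigar = sprintf("%dM", read_length), seq = seqs,
        stringsAsFactors = FALSE
      )
      truth[[cn]] <- data.frame(read_id = ids, contig_id = cn,
                                strain = strain_idx, n_errors = n_err,
                                stringsAsFactors = FALSE)
    }
    alignments <- do.call(rbind, aln)
    rownames(alignments) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    reads <- stats::setNames(alignments$seq, alignments$read_id)
    if (!is.null(sam_path)) write_sam(alignments, strains[[1]], sam_path)
    if (!is.null(fasta_path)) {
      writeLines(paste0(">", names(reads), "\n", reads), fasta_path)
    }
    list(alignments = alignments, reads = reads, truth = truth)
  })
}

#' Simulate a full strain community with ground truth
#'
#' Convenience wrapper composing [generate_reference()], [mutate_strain()]
#' (one mutated strain per non-reference proportion, with variant positions
#' disjoint across strains) and [mix_and_sequence()]. Strain 1 is the
#' unmutated reference.
#'
#' @param n_contigs,contig_length,orf_density Passed to [generate_reference()].
#' @param proportions Mixing proportions (first = reference strain).
#' @param n_snvs Substitutions per mutated strain (recycled).
#' @param nonsyn_fraction Nonsynonymous fraction per mutated strain (recycled).
#' @param depth,read_length,error_rate Passed to [mix_and_sequence()].
#' @param seed Integer seed; stage seeds are derived from it.
#' @return List with `reference` (contigs + orfs), `strains`,
#'   `alignments`, `reads`, and `truth`. `truth$variants` carries an
#'   `expected_freq` column (the proportion of the carrying strain);
#'   `truth$snv_density_per_kbp` and `truth$saav_snv_fraction` are the
#'   planted population-level values.
#' @export
simulate_strain_community <- function(n_contigs = 1L, contig_length = 20000L,
                                      orf_density = 0.7,
                                      proportions = c(0.7, 0.3),
                                      n_snvs = 100L, nonsyn_fraction = 0.3,
                                      depth = 200, read_length = 170L,
                                      error_rate = 0, seed) {
  if (contig_length < 1000L) stop("contig_length must be >= 1000", call. = FALSE)
  n_strains <- length(proportions)
  if (n_strains < 2L) stop("need at least two strains", call. = FALSE)
  n_snvs <- rep_len(n_snvs, n_strains - 1L)
  nonsyn_fraction <- rep_len(nonsyn_fraction, n_strains - 1L)
  ref <- generate_reference(n_contigs, contig_length, orf_density,
                            seed = seed)
  strains <- list(ref$contigs)
  variants <- list()
  exclude <- NULL
  for (i in seq_len(n_strains - 1L)) {
    mut <- mutate_strain(ref$contigs, ref$orfs, n_snvs[i], nonsyn_fraction[i],
                         seed = seed + 1000L * i, exclude = exclude)
    strains[[i + 1L]] <- mut$contigs
    v <- mut$truth
    v$strain <- i + 1L
    v$expected_freq <- proportions[i + 1L]
    variants[[i]] <- v
    exclude <- rbind(exclude, v[, c("contig_id", "pos")])
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL
  seqd <- mix_and_sequence(strains, proportions, read_length = read_length,
                           depth = depth, error_rate = error_rate,
                           seed = seed + 777L)
  total_len <- sum(contig_lengths(ref$contigs))
  list(
    reference = ref, strains = strains,
    alignments = seqd$alignments, reads = seqd$reads,
    truth = list(
      variants = variants, read_origins = seqd$truth,
      snv_density_per_kbp = 1000 * nrow(variants) / total_len,
      saav_snv_fraction = mean(variants$is_nonsynonymous),
      proportions = proportions
    )
  )
}

#' Generate a genome pair at a controlled divergence
#'
#' The second genome differs from the first by independent substitutions at
#' per-site rate `divergence`, supporting ANI recovery tests (expected ANI
#' is about `100 * (1 - divergence)`).
#'
#' @param contigs Source genome.
#' @param divergence Per-site substitution probability in `[0, 0.25]`.
#' @param seed Integer seed.
#' @return List with `genome_a`, `genome_b` and `truth`
#'   (`divergence`, `n_substitutions`).
#' @export
generate_divergent_pair <- function(contigs, divergence, seed) {
  contigs <- as_contig_set(contigs)
  if (divergence < 0 || divergence > 0.25) {
    stop("divergence must be in [0, 0.25]", call. = FALSE)
  }
  with_seed(seed, {
    b <- contigs
    n_sub <- 0L
    for (cn in names(b)) {
      ch <- strsplit(b[[cn]], "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(ch)) < divergence & ch %in% BASES)
      if (length(hit) > 0L) {
        ch[hit] <- vapply(ch[hit], function(x) sample(setdiff(BASES, x), 1L), "")
        b[[cn]] <- paste(ch, collapse = "")
      }
      n_sub <- n_sub + length(hit)
    }
    list(genome_a = contigs, genome_b = b,
         truth = list(divergence = divergence, n_substitutions = n_sub))
  })
}

# canonical one-letter COG functional categories
COG_LETTERS <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                 "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X",
                 "Y", "Z")

#' Generate a planted pangenome with COG labels
#'
#' Builds a gene-cluster-by-MAG presence/absence matrix with `n_core`
#' clusters present in every MAG, `n_accessory` private clusters per MAG,
#' and `focal_pair_unique` clusters present in exactly the first two MAGs
#' (the focal pair) and absent elsewhere. Each cluster gets one COG letter:
#' the enriched category at frequency `enrichment_strength` within the
#' focal-pair-unique clusters and `background_frequency` elsewhere, the
#' remaining mass spread uniformly over the other letters.
#'
#' @param n_mags Number of MAGs (>= 3 so "all others" is non-empty).
#' @param n_core Core cluster count.
#' @param n_accessory Private accessory clusters per MAG.
#' @param focal_pair_unique Clusters unique to the focal pair.
#' @param enriched_category COG letter planted in the unique clusters.
#' @param enrichment_strength Frequency of the category among unique
#'   clusters.
#' @param background_frequency Frequency of the category elsewhere.
#' @param seed Integer seed.
#' @param categories Pool of COG letters to draw from.
#' @return List with `matrix` (binary, clusters x MAGs), `cog_labels`
#'   (named character vector, cluster -> letter) and `truth`.
#' @export
generate_pangenome <- function(n_mags = 9L, n_core = 1500L, n_accessory = 50L,
                               focal_pair_unique = 310L,
                               enriched_category = "M",
                               enrichment_strength = 0.5,
                               background_frequency = 0.1, seed,
                               categories = c("C", "E", "F", "G", "H", "I",
                                              "J", "K", "L", "M", "N", "O",
                                              "P", "R", "S", "T", "U", "V")) {
  if (n_mags < 3L) {
    stop("focal pair undefined: need n_mags >= 3", call. = FALSE)
  }
  if (n_core < 0L || n_accessory < 0L || focal_pair_unique < 0L) {
    stop("cluster counts must be >= 0", call. = FALSE)
  }
  if (!(enriched_category %in% COG_LETTERS)) {
    stop("enriched_category must be a valid COG letter", call. = FALSE)
  }
  if (!(enriched_category %in% categories)) {
    categories <- c(categories, enriched_category)
  }
  mags <- sprintf("MAG_%02d", seq_len(n_mags))
  focal <- mags[1:2]
  cl_core <- if (n_core > 0L) sprintf("core_%04d", seq_len(n_core)) else character(0)
  cl_uni <- if (focal_pair_unique > 0L) {
    sprintf("unique_%04d", seq_len(focal_pair_unique))
  } else character(0)
  cl_acc <- character(0)
  acc_owner <- character(0)
  if (n_accessory > 0L) {
    cl_acc <- as.vector(vapply(seq_len(n_mags), function(m) {
      sprintf("acc_%s_%04d", mags[m], seq_len(n_accessory))
    }, character(n_accessory)))
    acc_owner <- rep(mags, each = n_accessory)
  }
  clusters <- c(cl_core, cl_uni, cl_acc)
  pa <- matrix(0L, nrow = length(clusters), ncol = n_mags,
               dimnames = list(clusters, mags))
  pa[cl_core, ] <- 1L
  pa[cl_uni, focal] <- 1L
  if (length(cl_acc) > 0L) pa[cbind(cl_acc, acc_owner)] <- 1L
  draw <- function(n, p_enriched) {
    other <- setdiff(categories, enriched_category)
    probs <- c(p_enriched, rep((1 - p_enriched) / length(other), length(other)))
    sample(c(enriched_category, other), n, replace = TRUE, prob = probs)
  }
  labels <- with_seed(seed, {
    lab <- character(length(clusters))
    names(lab) <- clusters
    bg <- c(cl_core, cl_acc)
    if (length(bg) > 0L) lab[bg] <- draw(length(bg), background_frequency)
    if (length(cl_uni) > 0L) lab[cl_uni] <- draw(length(cl_uni), enrichment_strength)
    lab
  })
  list(
    matrix = pa, cog_labels = labels,
    truth = list(
      focal_mags = focal, unique_clusters = cl_uni,
      enriched_category = enriched_category,
      enrichment_strength = enrichment_strength,
      background_frequency = background_frequency,
      enrichment_planted = enrichment_strength > background_frequency
    )
  )
}
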