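# Pileups, SNV calling, SAAV calling and MAG summaries.

test_that("pileup counts follow CIGAR semantics", {
  contigs <- c(c1 = "ACGTACGTAC")
  aln <- make_alignments(
    list("r1", "c1", 1, "4M", "ACGT"),
    list("r2", "c1", 1, "4M", "ACGT"),
    list("r3", "c1", 1, "4M", "ACGT")
  )
  pu <- build_pileup(aln, contigs)
  cols <- pileup_columns(pu)
  expect_equal(nrow(cols), 4)
  expect_equal(cols$coverage, rep(3, 4))
  expect_equal(cols$A, c(3, 0, 0, 0))

  # a 1-bp deletion removes the read from that column only
  aln2 <- make_alignments(
    list("r1", "c1", 1, "6M", "ACGTAC"),
    list("r2", "c1", 1, "2M1D3M", "ACACG")  # deletes position 3
  )
  pu2 <- build_pileup(aln2, contigs)
  cov2 <- pileup_columns(pu2)
  expect_equal(cov2$coverage[cov2$position == 3], 1)
  expect_equal(cov2$coverage[cov2$position == 2], 2)
  # insertions contribute no base to any reference column
  aln3 <- make_alignments(list("r1", "c1", 1, "2M2I2M", "ACGGGT"))
  cols3 <- pileup_columns(build_pileup(aln3, contigs))
  expect_equal(cols3$position, 1:4)
  expect_equal(cols3$coverage, rep(1, 4))

  # N bases count toward neither allele nor coverage
  aln4 <- make_alignments(list("r1", "c1", 1, "4M", "ANGT"))
  cols4 <- pileup_columns(build_pileup(aln4, contigs))
  expect_false(2 %in% cols4$position)

  empty <- build_pileup(aln[0, ], contigs)
  expect_equal(nrow(pileup_columns(empty)), 0)
})

test_that("call_snvs applies coverage and departure thresholds with fixed tie-break", {
  mk_pileup <- function(counts, len = ncol(counts)) {
    structure(list(c1 = counts), lengths = c(c1 = len), class = "pileup")
  }
  # counts {A:11, C:1}: SNV with departure 1/12
  m <- matrix(0L, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[1, 1] <- 11L; m[2, 1] <- 1L
  s <- call_snvs(mk_pileup(m))
  expect_equal(nrow(s), 1)
  expect_equal(s$departure_from_consensus, 1 / 12)
  expect_equal(s$majority_allele_frequency, 11 / 12)
  expect_equal(s$consensus, "A")
  expect_equal(s$n_alleles_observed, 2)

  # below min coverage: {A:8, C:1}
  m2 <- m; m2[1, 1] <- 8L
  expect_equal(nrow(call_snvs(mk_pileup(m2))), 0)
  # no departure: {A:12}
  m3 <- m; m3[2, 1] <- 0L; m3[1, 1] <- 12L
  expect_equal(nrow(call_snvs(mk_pileup(m3))), 0)
  # tie 6/6 between C and G: consensus is C (A<C<G<T order)
  m4 <- matrix(c(0L, 6L, 6L, 0L), 4, 1,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  s4 <- call_snvs(mk_pileup(m4))
  expect_equal(s4$consensus, "C")
  expect_equal(s4$majority_allele_frequency, 0.5)
})

test_that("SNV invariants: departure identity, threshold monotonicity, order invariance", {
  sim <- simulate_strain_community(contig_length = 5000, n_snvs = 30,
                                   depth = 60, seed = 21)
  pu <- build_pileup(sim$alignments, sim$reference$contigs)
  s <- call_snvs(pu)
  expect_gt(nrow(s), 0)
  expect_equal(s$departure_from_consensus + s$majority_allele_frequency,
               rep(1, nrow(s)))
  expect_true(all(s$majority_allele_frequency >= 0.25))
  expect_true(all(s$coverage >= 10))

  # raising either threshold never increases the call count
  n_base <- nrow(call_snvs(pu, 10, 0.05))
  for (cov in c(15, 25, 40)) {
    expect_lte(nrow(call_snvs(pu, cov, 0.05)), n_base)
  }
  for (dep in c(0.1, 0.2, 0.35)) {
    expect_lte(nrow(call_snvs(pu, 10, dep)), n_base)
  }

  # shuffling read input order changes nothing
  shuffled <- sim$alignments[sample(nrow(sim$alignments)), ]
  expect_identical(call_snvs(build_pileup(shuffled, sim$reference$contigs)),
                   s)
})

test_that("call_saavs tallies codon-spanning reads only and translates in context", {
  # ORF at positions 1-9 on the forward strand; codon 2 = positions 4-6
  contigs <- c(c1 = "ATGAAAGGCTAAGG")
  orfs <- data.frame(orf_id = "o1", contig_id = "c1", start = 1L, end = 12L,
                     strand = "+")
  spanning <- function(n, codon_seq) {
    lapply(seq_len(n), function(i) {
      list(paste0("r", codon_seq, i), "c1", 4, "3M", codon_seq)
    })
  }
  # 7x AAA (K) + 3x GAA (E): departure 0.3 -> SAAV
  aln <- do.call(make_alignments, c(spanning(7, "AAA"), spanning(3, "GAA")))
  s <- call_saavs(aln, contigs, orfs)
  expect_equal(nrow(s), 1)
  expect_equal(s$codon_index, 2)
  expect_equal(s$consensus_aa, "K")
  expect_equal(s$departure_from_consensus_aa, 0.3)
  expect_equal(s$aa_counts, "K=7;E=3")

  # 7x AAA + 3x AAG: both lysine -> synonymous, no SAAV
  aln2 <- do.call(make_alignments, c(spanning(7, "AAA"), spanning(3, "AAG")))
  expect_equal(nrow(call_saavs(aln2, contigs, orfs)), 0)

  # 9 spanning reads: below spanning coverage, not evaluated
  aln3 <- do.call(make_alignments, c(spanning(6, "AAA"), spanning(3, "GAA")))
  expect_equal(nrow(call_saavs(aln3, contigs, orfs)), 0)

  # a read covering only 2 of 3 codon positions does not contribute
  aln4 <- do.call(make_alignments, c(spanning(7, "AAA"), spanning(3, "GAA"),
                                     list(list("rp", "c1", 5, "2M", "AA"))))
  s4 <- call_saavs(aln4, contigs, orfs)
  expect_equal(s4$spanning_coverage, 10)
})

test_that("minus-strand ORFs are translated from the reverse complement", {
  # forward 1..9 reverse-complements to an ORF: ATG GCA TAA
  contigs <- c(c1 = "TTATGCCATGCG")
  orfs <- data.frame(orf_id = "o1", contig_id = "c1", start = 1L, end = 9L,
                     strand = "-")
  # codon 2 (GCA, alanine) sits at forward positions 4-6 (TGC)
  reads <- c(rep("TGC", 7), rep("TGG", 5))  # TGG revcomps to CCA -> proline
  aln <- do.call(make_alignments, lapply(seq_along(reads), function(i) {
    list(paste0("r", i), "c1", 4, "3M", reads[i])
  }))
  s <- call_saavs(aln, contigs, orfs)
  expect_equal(nrow(s), 1)
  expect_equal(s$codon_index, 2)
  expect_equal(s$consensus_aa, "A")
  expect_match(s$aa_counts, "A=7")
  expect_match(s$aa_counts, "P=5")
})

test_that("stop-codon variants are tallied as a distinct symbol", {
  contigs <- c(c1 = "ATGAAAGGCTAAGG")
  orfs <- data.frame(orf_id = "o1", contig_id = "c1", start = 1L, end = 12L,
                     strand = "+")
  reads <- c(rep("AAA", 7), rep("TAA", 4))
  aln <- do.call(make_alignments, lapply(seq_along(reads), function(i) {
    list(paste0("r", i), "c1", 4, "3M", reads[i])
  }))
  s <- call_saavs(aln, contigs, orfs)
  expect_match(s$aa_counts, "\\*=4")
})

test_that("summarize_mag computes Table-2-style statistics", {
  sim <- simulate_strain_community(contig_length = 5000, n_snvs = 30,
                                   nonsyn_fraction = 0.3, depth = 60, seed = 22)
  pu <- build_pileup(sim$alignments, sim$reference$contigs)
  snvs <- call_snvs(pu)
  saavs <- call_saavs(sim$alignments, sim$reference$contigs, sim$reference$orfs)
  s <- summarize_mag(snvs, saavs, pu, "POP", total_reads = 5e7)
  expect_equal(s$snvs_per_kbp, 1000 * s$snv_count / 5000)
  expect_equal(s$saav_snv_ratio, s$saav_count / s$snv_count)
  expect_equal(s$mean_majority_allele_frequency,
               mean(snvs$majority_allele_frequency))
  # normalized coverage: mean coverage 60ish for a 50M-read metagenome -> x2
  expect_equal(s$normalized_coverage, s$mean_coverage / 0.5)

  # zero SNVs: ratio is NA (undefined), never 0
  s0 <- summarize_mag(snvs[0, ], saavs[0, ], pu, "POP")
  expect_true(is.na(s0$saav_snv_ratio))
  expect_true(is.na(s0$mean_majority_allele_frequency))
})

test_that("saav_count never exceeds snv_count on clean spanning data", {
  for (seed in c(31, 32, 33)) {
    sim <- simulate_strain_community(contig_length = 5000, n_snvs = 40,
                                     nonsyn_fraction = 0.5, depth = 80,
                                     seed = seed)
    pu <- build_pileup(sim$alignments, sim$reference$contigs)
    n_snv <- nrow(call_snvs(pu))
    n_saav <- nrow(call_saavs(sim$alignments, sim$reference$contigs,
                              sim$reference$orfs))
    expect_lte(n_saav, n_snv)
  }
})

test_that("allele frequency distribution summarizes SNV majority frequencies", {
  snvs <- data.frame(majority_allele_frequency = rep(11 / 12, 5))
  d <- allele_frequency_distribution(snvs)
  expect_equal(d$mean, 11 / 12)
  expect_equal(sum(d$counts), 5)
  expect_equal(d$mode, 0.925, tolerance = 1e-9)
  expect_error(allele_frequency_distribution(snvs[0, , drop = FALSE]),
               "at least one")
})
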