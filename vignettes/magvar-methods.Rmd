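---
title: "Methods: population-genomic variant profiling for MAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic variant profiling for MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magvar)
```

## What the package models

A metagenome-assembled genome (MAG) is a draft genome binned out of an
environmental assembly. The reads that map back to a MAG come from a
*population* of closely related strains, not a single clone, and the pattern
of disagreement between those reads and the assembled consensus is a window
into the population's evolutionary state:

* **SNV density (SNVs/kbp)** — how much standing nucleotide diversity the
  population carries. Few SNVs plus high coverage suggests a recent clonal
  expansion or selective sweep; many SNVs suggests an older, diverse
  population.
* **Majority allele frequency** — the fraction of mapped reads carrying the
  most common base at a variant site. Values near 0.5 indicate evenly mixed
  strains; values near 0.8–1.0 indicate one dominant variant.
* **SAAV/SNV ratio** — the fraction of nucleotide variants that change the
  encoded amino acid. Like pN/pS, it separates purifying selection (low
  values: nonsynonymous variants are purged) from relaxed or positive
  selection (high values).
* **Normalized coverage** — mean depth divided by (total metagenome reads /
  10^8), making abundance comparable across metagenomes of different size.

Around this core the package provides fragment-based average nucleotide
identity (ANI) for species-level comparisons, pangenome construction
(similarity graph → Markov clustering → presence/absence matrix →
dendrogram), detection of gene clusters uniquely shared by a focal pair of
MAGs, and a resampling test for COG-category enrichment in such gene sets.

## Variant calling

**SNVs.** `build_pileup()` turns alignments into per-position A/C/G/T
counts. A read insertion contributes no base to any reference column, a
deletion removes the read from the deleted columns, and N bases count
toward neither allele nor coverage. `call_snvs()` then flags a position as
an SNV iff coverage ≥ `min_coverage` (default 10) and departure from
consensus — the fraction of bases not matching the majority base — is
≥ `min_departure` (default 0.05). Some profilers scale the departure floor
with depth to suppress sequencing error at high coverage; because no single
published curve is canonical, the package uses the two fixed thresholds as
defaults and accepts any depth-dependent rule through `threshold_fun`.
Ties for the consensus base break on the fixed order A < C < G < T, so
calls are deterministic and independent of read input order. One SNV is
reported per position regardless of allele count; `n_alleles_observed`
makes the (empirically dominant) biallelic case checkable.

**SAAVs.** `call_saavs()` works per codon and uses only reads that align
to *all three* codon positions, keeping the physical linkage of bases
within a read; 3-mers are reverse-complemented for minus-strand ORFs,
translated with the standard genetic code, and tallied as amino acids
(stop = `*`). The amino-acid departure threshold is not independently
standardized, so the SNV values (spanning coverage ≥ 10, departure ≥ 0.05)
are reused — a deliberate design choice, exposed as parameters.

**Summaries.** `summarize_mag()` uses total MAG length as the SNV-density
denominator (matching the conventional SNVs/kbp unit); a covered-length
denominator is available via `denominator = "covered"`. The mean majority
allele frequency averages over SNV positions only (option `maf_over =
"all"` for all covered positions). A MAG with zero SNVs gets an `NA`
SAAV/SNV ratio — undefined, never zero.

## The synthetic community generator

Every downstream stage is validated against planted truth rather than
external data. `generate_reference()` writes ORFs (ATG + sense codons +
stop, both strands) into random contigs; `mutate_strain()` places an exact
number of substitutions with an exact nonsynonymous count
(`round(fraction × n)`), classifying each candidate substitution with the
codon table; `mix_and_sequence()` draws single-end reads multinomially by
strain proportion with uniform starts and optional independent substitution
errors, emitting the true alignments directly so no mapper is involved.

Default conditions mirror the target study: ~170 bp single-end reads (the
study's merged overlapping pairs), contigs ≥ 1000 bp, a two-strain 0.7/0.3
mixture with 100 injected SNVs at nonsynonymous fraction 0.30, and 200×
depth for recovery tests. Variants are placed at least one codon apart so a
codon carries at most one variant, which makes the planted SAAV/SNV
fraction exactly the nonsynonymous fraction. The error model is
substitution-only (no indels — indel handling in pileups is exercised by
hand-written SAM fixtures instead); there are no quality scores, GC bias,
or chimeras. Consequences for interpretation: passing recovery tests show
the *estimators* are correct under the stated sampling model; they do not
certify behavior under mapping artifacts, strain-specific gene content, or
correlated sequencing error, which real data can exhibit.

A documented statistical bias worth knowing: at a perfectly even 50/50
mixture the majority-allele frequency is the maximum of a symmetric
binomial pair, so its mean sits slightly above 0.5 even when the truth is
0.5.

## ANI

`compute_ani()` follows the fragment-based (ANIb-style) definition: the
query genome is cut into consecutive 1020 nt windows (terminal remainders
dropped), each fragment is aligned to the subject, and ANI is the mean
identity over fragments whose best hit reaches 70% identity and 70%
fragment coverage. The aligner is a k-mer seed (default k = 15, both
strands) with diagonal voting to locate the candidate region, followed by a
local dynamic-programming alignment (match 2, mismatch −3, gap open 5,
gap extend 2). ANIb is direction-dependent; both directions and their mean
are reported, with the mean as the headline value. Genomes more than ~98%
identical are conventionally read as the same species.

## Pangenome

`build_maxbit_graph()` normalizes pairwise ORF scores by the smaller
self-score (`maxbit`), keeping edges at weight ≥ 0.3. `mcl_cluster()`
implements Markov clustering with inflation 2: self-loops at each node's
maximum incident edge weight (isolated nodes: 1), column-stochastic
normalization, alternating expansion and inflation, pruning below 1e-6,
convergence when the largest entry change drops below 1e-8 (cap 200
iterations, error on non-convergence). Clusters are read off attractor
rows; a node supported by several attractors is assigned to the one with
the largest weight (lexicographic tie-break), so the output is always a
partition. `cluster_dendrogram()` uses Euclidean distance on binary
gene-content profiles and complete linkage — the `dist`/`hclust`
defaults — and emits Newick.

`cog_enrichment()` draws `sample_size` genes (default 200) from the
background pool without replacement for each of `repetitions` (default 500)
resamples and compares the focal set's per-category proportion against the
null quantiles at the 90/93/99% levels; the achieved confidence is the
fraction of null draws strictly below the observed proportion. Sampling is
without replacement and proportions (not counts) are compared, so focal
sets of any size are handled. Because null proportions live on a lattice
(multiples of 1/`sample_size`), the strict comparison makes the test
slightly conservative: its false-positive rate sits at or just below
1 − level, which the calibration test verifies.

`generate_pangenome()` takes `enrichment_strength` together with an
explicit `background_frequency` (default 0.10): a planted enrichment is
only well-defined relative to a stated background rate.

## Numerical and design choices

* Coordinates are 1-based inclusive in all files (SAM/ORF convention);
  conversions happen only at parse boundaries.
* The standard genetic code is used throughout (the relevant taxa are
  bacteria and archaea; code variants are out of scope).
* Welch's t-test is computed from the closed-form statistic and
  Satterthwaite degrees of freedom, two-sided; with zero variance in both
  groups and equal means, p = 1 by convention. Ratio comparisons are run on
  natural logs (this choice reproduces the Sulfurovum-scale test result
  from the bundled printed table).
* The Shannon–Wiener index is the natural-log form −Σ p log p. Recomputed
  16S diversity values for individual samples in the bundled table do not
  match the standard definition at per-sample level (their published scale
  is not derivable from the printed data); only the printed columns' means
  are treated as reproducible quantities.
* MAG quality filtering is strict on both sides: completeness > 70 and
  redundancy < 10 (a bin at exactly 10% redundancy is dropped).

## Problem sizes

The bundled demo scenario and the test suite run on deliberately small
instances — single contigs of 3–20 kbp, depths of 40–200×, pangenomes of a
few thousand clusters, 20-node clustering instances — chosen so the full
suite and the reproduction script each complete in well under a minute
while still exercising every code path at depths where the binomial
tolerances are tight. The algorithms themselves are vectorized per contig
and scale to real MAG sizes linearly in genome length and read count,
except `score_orf_similarities()`, which is quadratic in ORF count and
intended for synthetic-scale pangenomes (real datasets should supply
precomputed scores).

## Known limitations

* No indel variant calling, haplotype phasing, or strain deconvolution.
* The SAM reader covers the minimal subset the pipeline needs (no
  supplementary alignments, mate rescue, or BAM).
* The internal fragment aligner is built for the ANI use case (high-identity
  hits); it is not a general homology search and reports no alignment
  statistics beyond identity, coverage and score.
* Enrichment confidence levels are per category; no multiplicity correction
  across categories is applied.
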