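Package: magvar
Title: Population-Genomic Variant Profiling for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study intra-population genomic variation in microbial
    communities through metagenome-assembled genomes (MAGs): per-position
    pileups from read alignments, single-nucleotide variant (SNV) calling with
    coverage and departure-from-consensus thresholds, codon-aware
    single-amino-acid variant (SAAV) calling restricted to reads spanning the
    full codon, per-MAG summary statistics (SNV density, majority allele
    frequency, SAAV/SNV ratio as a pN/pS-like selection proxy, normalized
    coverage), fragment-based average nucleotide identity (ANI), pangenome
    construction via maxbit similarity graphs and Markov clustering,
    gene-cluster presence/absence dendrograms, uniquely-shared-cluster
    detection, resampling-based COG-category enrichment, Shannon-Wiener
    diversity, and Welch two-sample tests. A seeded synthetic strain-community
    generator with full ground truth makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
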