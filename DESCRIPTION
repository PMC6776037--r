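Package: phagediv
Title: Prophage Diversity, Uptake Signal Sequence Profiling, and
    Phage-Host Coevolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for temperate phage diversity in naturally
    competent Pasteurellaceae hosts (Aggregatibacter, Haemophilus).
    Implements prophage inclusion filtering from completeness scores and
    ORF counts, MinHash sketching with Mash distances and fragment-based
    average nucleotide identity for genome clustering, per-megabase
    profiling of DNA uptake signal sequence (USS) motifs in both
    orientations with a frequency-cutoff classifier for
    Pasteurellaceae-lysogenizing phages, marker-protein screening of
    metagenome contigs with a coverage-times-identity score, prevalence
    and rarefaction statistics (Fisher's exact test with Bonferroni
    correction, one-way ANOVA with Tukey HSD, Wilson intervals), and a
    Bray-Curtis / non-metric multidimensional scaling ordination of
    delta-GC and USS frequencies. A seeded synthetic-data generator
    emulates genomes with controlled GC content and planted motifs,
    diverged phage families, lysogeny tables, and fragmented metagenome
    contigs, so every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
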