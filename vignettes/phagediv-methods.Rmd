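---
title: "Methods: prophage diversity, USS profiling, and phage-host coevolution"
author: "phagediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prophage diversity, USS profiling, and phage-host coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and scientific background

`phagediv` implements an analysis workflow for temperate phage (prophage)
diversity in human-associated *Aggregatibacter* and *Haemophilus* species,
and for the signal those phages carry of long-term coevolution with their
naturally competent *Pasteurellaceae* hosts. The workflow has five
computational pillars:

1. a prophage inclusion filter over upstream prediction scores and ORF
   counts, with automated deduplication;
2. genome comparison by MinHash/Mash distance and a simplified fragment-based
   average nucleotide identity (ANI), followed by threshold clustering into
   genus-like clusters and subfamily-like superclusters;
3. per-megabase profiling of DNA uptake signal sequences (USSs) in both
   orientations, with a frequency-cutoff classifier for phages that
   lysogenize *Pasteurellaceae*;
4. marker-protein screening of metagenome contigs with a
   coverage-times-identity retention score and per-site prevalence
   profiling; and
5. prevalence/richness statistics (Fisher, Bonferroni, ANOVA/Tukey, Wilson
   intervals, rarefaction) and a Bray-Curtis / non-metric multidimensional
   scaling (nMDS) ordination of delta-GC and USS frequencies.

Real inputs (public genome assemblies, oral metagenome assemblies) are not
bundled; a seeded synthetic-data module generates inputs with the same
statistical structure so that every stage is testable at desk scale. The
numbered scripts under `analysis/` run the whole study over the bundled
configuration and narrate each stage.

## The USS statistic

Naturally competent *Pasteurellaceae* take up environmental DNA
preferentially when it carries a short uptake signal sequence. Two dialect
cores exist: the *H. influenzae*-like (Hin-USS) and the
*A. pleuropneumoniae*-like (Apl-USS) 9-mer. Because uptake-biased
recombination slowly enriches these motifs, the genomic USS density of a
phage is a molecular clock of its association with such hosts. The package
defaults to the canonical literature cores `AAGTGCGGT` (Hin) and
`ACAAGCGGT` (Apl); both are configurable, and a core that equals its own
reverse complement is rejected because both-orientation counting assumes
the strands are distinguishable.

Counting rules (`count_motif`): occurrences of the core plus occurrences of
its reverse complement, overlaps allowed; windows containing a non-ACGT
character are excluded from the count, and the per-Mb denominator is the
number of A/C/G/T bases only, so N-padding can neither create nor deflate
density. The single-mismatch profile (Hamming distance at most 1 to either
orientation, counted per window so a window close to both orientations is
counted once) includes the exact matches, guaranteeing the superset
invariant; it is reported alongside the exact profile, never instead of it.
A background rate of chance hits is expected and accepted rather than
suppressed: a random genome yields about `2 L / 4^9` spurious 9-mer windows
per orientation pair, i.e. roughly 7.6 per Mb, which is far below the
classifier cutoff.

The classifier (`classify_lysogenizer`) calls a phage
*Pasteurellaceae*-lysogenizing when either exact USS frequency reaches the
cutoff, 100 per Mb by default, with an inclusive boundary (a profile at
exactly 100 is positive); the source analysis states only the cutoff value,
so the boundary rule is fixed here as a design decision.

## Prophage filtering and deduplication

The inclusion filter keeps annotations with completeness score strictly
greater than 90 ("score > 90") and at least 40 ORFs ("at least 40"), the
asymmetry being deliberate. Duplicate screening, a manual step in the
original analysis, is automated with a reproducible proxy: records at Mash
distance at most 0.001 whose host species metadata agree are grouped
transitively, and all but the first record in identifier sort order are
flagged. The subjective criteria for pseudoreplication (same patient,
colony variants) are out of scope; only the distance-plus-species rule is
implemented.

## Genome distance, ANI, and clustering

`minhash_sketch` hashes canonical k-mers (minimum of a k-mer and its
reverse complement on a 2-bit encoding) with splitmix64 under a fixed,
documented seed and keeps the bottom 1000 distinct values (k = 21). Hash
values are truncated to 53 bits so they are exactly representable as R
numerics. Bit-compatibility with external sketching tools is not a goal;
the estimator contract is, and tests calibrate the sketch Jaccard against
the exact k-mer Jaccard computed over the full canonical sets. The Mash
distance is `d = -(1/k) log(2j / (1 + j))`, with `j = 0` reported as
`d = 1`.

`fragment_ani` is a deliberately simplified fragment ANI: consecutive
1020-nt fragments, best ungapped offset on the other genome located by
exact 12-mer seed voting, reciprocal best fragment pairing, and a 35%
identity qualifying rule (full-fragment ungapped placement makes fragment
coverage all-or-none, so the 35% coverage rule is subsumed). Unrelated
genomes produce no qualifying pair and the ANI is flagged undefined rather
than forced to zero.

Cluster definitions in the source analysis combined phylogenomic trees,
dotplots, and curation; here they are replaced by explicit single-linkage
connected components: Mash distance at most 0.09 defines clusters (informed
by within-cluster distances observed up to about 0.08) and at most 0.25
defines superclusters. Components are computed by union-find rather than a
dendrogram cut so the "at or below threshold" semantics are exact at the
boundary; nesting of clusters within superclusters holds by construction.
The dotplot (`dotplot_matrix`) is exact forward-strand word matching at
word length 10, with reverse-strand matches behind an off-by-default flag;
the assignment of clusters to the three gene-content-based main groups
(transposable, P2-like, lambda-like) is metadata, not computed.

## Marker screen

`search_markers` translates all six reading frames (plain codon
translation, stops as `*`, partial codons dropped) in a single vectorized
call and aligns each marker protein to each frame with a plain affine-gap
Smith-Waterman (BLOSUM62, NCBI-style gap cost `11 + L`). A score-only
rolling-row pass selects the best frame and gates on E-value before the
traceback alignment runs; the compiled aligner is verified against
`Biostrings::pairwiseAlignment` in the test suite. E-values use the
Karlin-Altschul form `K m n exp(-lambda S)` with fixed constants
(`K = 0.041`, `lambda = 0.267`) and are explicitly approximate; hit
retention therefore leans on the identity score. Only the best-scoring hit
per (marker, contig) pair is kept, a choice the source analysis leaves
open.

The identity score is read as the *fraction* of the query covered times the
percent identity, giving a 0-100 scale on which the canonical threshold of
95 is meaningful; the literal product of two percentages (0-10000) is
rejected as inconsistent with that threshold. Retention is inclusive at
exactly 95 and at the E-value cutoff (1e-80 by default). Prevalence is
computed per body site at the sample level, with supercluster prevalence
the union over member clusters; raising either cutoff can only remove
positives, a monotonicity property the tests enforce. Externally produced
12/13-column tabular hits can be ingested in place of the built-in aligner
and feed the identical score and filters.

One interaction worth knowing: with the approximate E-value constants, a
fully identical hit of a 120-residue marker scores near 1e-77 and would
fail the 1e-80 cutoff. Real marker proteins are longer; the synthetic study
uses 160-residue markers, for which full-length hits pass with orders of
magnitude to spare.

## Statistics

* `fisher_exact_2x2` enumerates the hypergeometric support directly and
  sums point probabilities at most `(1 + 1e-7)` times the observed one (the
  conventional guard against floating-point ties). The suite verifies it
  exhaustively against an independent log-binomial enumeration for all 2x2
  tables with margins up to 30 and against `stats::fisher.test` on random
  tables, and checks its conservatism under the null.
* `bonferroni` multiplies by an explicit family size (the number of tests
  in one analysis panel, clusters times group comparisons) and caps at 1;
  `#` marks results significant only before correction.
* `anova_tukey` wraps `stats::aov` and `TukeyHSD`.
* `rarefy` uses nested (prefix) subsampling without replacement: each
  replicate is one random permutation of the genomes, and the richness at n
  is the number of distinct clusters among the first n. This makes every
  replicate curve non-decreasing by construction — the natural reading of a
  per-replicate monotone rarefaction — while each prefix is still a uniform
  random subset. Ten replicates by default with a t-based 95% CI across
  replicates (the original spreadsheet's interval method is unspecified;
  t-quantiles are the safer small-sample choice, and the same choice is
  made for per-genome count CIs). The analytic expectation
  `E[S_n] = sum_i (1 - C(G - g_i, n) / C(G, n))` is exposed as
  `rarefaction_expectation` and matches `vegan::specaccum(method = "exact")`
  to numerical precision.
* `prevalence_summary` uses Wilson score intervals
  (`prop.test(correct = FALSE)`).

## Coevolution ordination

`build_features` aggregates profiles to entity means (phage clusters enter
as the mean of their members), forms delta-GC as the entity mean GC minus
the dataset minimum, and rescales each of the three variables so its
maximum is 100. The per-variable reading of "standardized by maximum" is
chosen over a shared maximum because the variable vectors are fitted
separately; a column whose maximum is 0 is left all-zero and flagged
instead of divided. The standardization is idempotent. Bray-Curtis is the
classical `sum |x - y| / sum (x + y)` with the all-zero pair defined as 0.

`nmds` minimizes Kruskal stress-1 with isotonic regression
(`stats::isoreg`) under the primary approach to ties (tied input
dissimilarities are ordered by current configuration distance, leaving them
free) alternating with Guttman majorization updates. A step-halving
safeguard accepts only non-increasing stress, which makes the recorded
stress trace monotone by construction and doubles as a convergence
criterion. The first restart starts from classical metric scaling, the
remaining 19 from seeded random configurations, and the best restart is
returned; coordinates are centered, rotated to principal axes, and
sign-canonicalized so runs are comparable. Defaults: 2 dimensions, 20
restarts, 300 iterations, tolerance 1e-7, explicit seed. `vegan::monoMDS`
serves as an independent cross-check in the tests, never as the
implementation, because the acceptance properties require the per-iteration
stress trace.

A caveat on nearest-neighbour readings of the embedding: stress-1 weights
absolute residuals, so rank inversions among very small dissimilarities
(e.g. a phage cluster sitting almost on top of two similar clades) can
survive at near-zero stress. Host-proximity fractions quoted from the
embedding are therefore slightly noisier than the same fractions computed
in feature space, where the synthetic benchmark recovers hosts essentially
always.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of their spec, including the seed; no
function touches the global RNG stream. Background sequence is i.i.d. at a
target GC; motif planting overwrites background bases at uniformly chosen
non-overlapping positions (rejection sampling, capped at 10^4 retries) in a
random orientation, so the genome length and per-Mb denominators stay
exact. Families derive members from one ancestor by i.i.d.
Jukes-Cantor-like substitution, giving the closed-form expected pairwise
identity `(1 - r)^2 + r^2/3` recorded in the truth table. Lysogeny tables
are Bernoulli draws from a clade-by-cluster prevalence matrix. Metagenome
contigs are uniform substrings of phage genomes sampled proportionally to
abundance, with truth labels marking contigs that overlap a marker interval
by at least half the marker length.

The bundled study configuration (`inst/extdata/default_config.yaml`) fixes
the emulated conditions: four host clades (genome stand-ins of 150 kb; USS
densities around 750/600/500 per Mb for the Hin-dialect clades, with one
Apl-dialect clade near 550 per Mb, matching the observed saturation scale
of roughly 750 per Mb and the dialect split), six phage clusters of four
40-kb members each (the observed mean prophage size is near 39 kb) in three
superclusters, within-cluster divergence 3% and cluster-to-supercluster
divergence 8% (placing within-cluster Mash distances near 0.06 and
within-supercluster distances near 0.16, inside the respective thresholds),
prophage USS densities at roughly 60% of host levels (accumulation still in
progress), a lysogeny design with one strongly enriched cluster per clade,
and a three-site, nine-sample metagenome with 160-residue markers. Problem
sizes throughout the tests (10-kb sequences for the counting oracle, 1-Mb
genomes for density recovery, 200 + 2000 genomes for the classifier
benchmark, 100 family pairs for MinHash calibration, 30 pairs spanning
pairwise divergence 0-12% for the Mash-ANI coherence check, 50 x 20 tables
at 1000 replicates for rarefaction) were chosen as the smallest scales at
which the binomial/Poisson tolerances of the assertions are meaningful.

Deliberately not modelled: gene content and codon structure, genome
mosaicism and recombination, read-level sequencing error and assembly
artifacts, uptake machinery mechanics, and calibrated E-value statistics.
Passing tests therefore demonstrate the correctness and calibration of the
implemented statistics under the stated generative model, not performance
on real assemblies.

## Degenerate inputs and numerical conventions

* Sequences with ambiguity codes are retained; each module defines its own
  handling (skipped k-mers, excluded windows, `-4` substitution score).
* A motif longer than its sequence counts zero; a profile over a sequence
  with no A/C/G/T bases is an error.
* Jaccard 0 maps to Mash distance 1 (capped); fragment ANI without
  qualifying pairs is `NA` with a zero pair count.
* Fisher tables must be non-negative with a positive total; degenerate
  margins give p = 1 through the enumeration itself.
* The nMDS input must be symmetric with a zero diagonal; zero configuration
  distances are floored at 1e-12 before forming Guttman ratios.
* All pipeline TSV/JSON outputs are written with stable formatting so a
  rerun under the same configuration is byte-identical.
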