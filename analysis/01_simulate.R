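# Stage 1: synthesize the study inputs.
#
# Generates the emulated dataset: four host clades of naturally competent
# bacteria with dialect-specific uptake-signal-sequence (USS) densities and
# GC content, six phage clusters (three superclusters) of diverged 40-kb
# genomes with planted USS and an embedded marker protein each, a prophage
# annotation funnel including low-score/low-ORF decoys and duplicated
# entries, a lysogeny presence table with clade-specific enrichment, and a
# fragmented three-site oral metagenome.

source("analysis/00_common.R")

man <- run_stage("simulate")
s <- man$stages$simulate

cat(sprintf("Simulated %d bacterial genomes across %d clades.\n",
            s$bacterial_genomes, length(study_config()$synthetic$clades)))
cat(sprintf("Simulated %d phage genomes in %d clusters; %d annotation rows\n",
            s$phage_genomes, length(study_config()$synthetic$clusters),
            s$prophage_annotations))
cat(sprintf("  (including decoys and duplicates for the intactness filter).\n"))
cat(sprintf("Lysogeny table: %d genomes; metagenome: %d contigs in %d samples.\n",
            s$lysogeny_genomes, s$metagenome_contigs, s$metagenome_samples))
cat(sprintf("Outputs written under %s/\n", run_dir))
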