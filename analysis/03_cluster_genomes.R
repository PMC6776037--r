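# Stage 3: genome-distance clustering.
#
# Sketches every kept prophage genome (MinHash, k = 21, sketch 1000),
# computes all pairwise Mash distances and simplified fragment ANI, and
# groups genomes by single-linkage threshold clustering into genus-like
# clusters (Mash <= 0.09) nested in subfamily-like superclusters
# (Mash <= 0.25). Also reports the Pearson correlation between Mash
# distance and 1 - ANI as a coherence check between the k-mer and
# fragment-alignment views of distance.

source("analysis/00_common.R")

man <- run_stage("cluster")
cl <- man$stages$cluster

cat(sprintf("Clustered %d genomes into %d clusters within %d superclusters.\n",
            cl$genomes_clustered, cl$n_clusters, cl$n_superclusters))
cat(sprintf("Pearson r between Mash distance and 1 - ANI: %.3f\n",
            cl$mash_ani_pearson_r))

pairs <- tsv("distance_pairs.tsv")
within <- pairs[pairs$mash_distance <= 0.09, ]
cat(sprintf("Within-cluster Mash distances span %.3f-%.3f; within-cluster ANI %.3f-%.3f\n",
            min(within$mash_distance), max(within$mash_distance),
            min(within$ani, na.rm = TRUE), max(within$ani, na.rm = TRUE)))
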