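# Stage 7: phage-host coevolution ordination.
#
# Builds the three-variable feature matrix over bacterial clades and phage
# clusters (delta-GC, Hin-USS and Apl-USS frequencies, each standardized to
# maximum 100), computes Bray-Curtis dissimilarities, embeds the entities in
# two dimensions by non-metric multidimensional scaling (best of 20
# restarts), and fits variable vectors from the Pearson correlations of each
# variable with the ordination axes.

source("analysis/00_common.R")

man <- run_stage("ordinate")
o <- man$stages$ordinate

cat(sprintf("Ordinated %d entities; 2D stress-1 = %.4f\n", o$entities, o$stress))
coords <- tsv("ordination_coordinates.tsv")
print(coords, row.names = FALSE)
vec <- tsv("ordination_vectors.tsv")
cat("Fitted variable vectors (axis correlations, multiple R):\n")
print(vec, row.names = FALSE)

# nearest bacterial clade for each phage cluster in the embedding
cfg <- study_config()
clades <- vapply(cfg$synthetic$clades, function(x) x$name, character(1))
hosts <- setNames(vapply(cfg$synthetic$clusters, function(x) x$host_clade,
                         character(1)),
                  vapply(cfg$synthetic$clusters, function(x) x$name, character(1)))
rownames(coords) <- coords$entity
cat("\nNearest clade per phage cluster (designed host in parentheses):\n")
for (cl in names(hosts)) {
  dd <- sqrt((coords[clades, "axis1"] - coords[cl, "axis1"])^2 +
               (coords[clades, "axis2"] - coords[cl, "axis2"])^2)
  cat(sprintf("  %s -> %s (%s)\n", cl, clades[which.min(dd)], hosts[[cl]]))
}
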