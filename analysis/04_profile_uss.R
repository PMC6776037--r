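# Stage 4: USS / GC profiling.
#
# Counts Hin-USS and Apl-USS motifs (exact and single-mismatch, both
# orientations) per megabase of every bacterial and phage genome, computes
# GC%, and classifies each phage as Pasteurellaceae-lysogenizing when either
# exact USS frequency reaches 100 per Mb.

source("analysis/00_common.R")

man <- run_stage("profile_uss")
p <- man$stages$profile_uss

prof <- tsv("uss_profiles.tsv")
bact <- prof[prof$kind == "bacterium", ]
phage <- prof[prof$kind == "phage", ]

cat(sprintf("Profiled %d genomes (%d bacterial, %d phage).\n",
            p$profiles, nrow(bact), nrow(phage)))
cat(sprintf("Phages classified USS-positive at the 100/Mb cutoff: %d of %d\n",
            p$phages_classified_positive, nrow(phage)))
agg <- aggregate(cbind(gc_percent, hin_per_mb, apl_per_mb) ~ entity,
                 data = prof, FUN = function(x) round(mean(x), 1))
cat("Per-entity means (clades and clusters):\n")
print(agg, row.names = FALSE)
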