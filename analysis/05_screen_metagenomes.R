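# Stage 5: marker-protein metagenome screen.
#
# Searches each cluster's marker protein against the six reading frames of
# every metagenome contig (BLOSUM62 local alignment), keeps hits with
# approximate E-value <= 1e-80 and identity score (query coverage fraction
# times percent identity) >= 95, and profiles phage cluster and supercluster
# prevalence per body site.

source("analysis/00_common.R")

man <- run_stage("screen")
s <- man$stages$screen

cat(sprintf("Raw hits: %d; retained after E-value and identity-score filters: %d\n",
            s$hits, s$retained_hits))
prev <- tsv("site_prevalence.tsv")
cl <- prev[prev$level == "cluster" & prev$n_positive > 0, ]
cat("Detected cluster prevalence by body site:\n")
print(cl[order(cl$body_site, -cl$prevalence),
         c("body_site", "label", "n_positive", "n_samples", "prevalence")],
      row.names = FALSE)
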