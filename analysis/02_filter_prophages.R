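# Stage 2: prophage inclusion filter.
#
# Applies the intactness criteria to the annotation table: completeness
# score strictly above 90, at least 40 predicted ORFs, and automatic
# deduplication (Mash distance <= 0.001 within the same host species, first
# record by id kept). This reproduces the funnel from raw phage-like
# elements down to the non-redundant intact prophage set.

source("analysis/00_common.R")

man <- run_stage("filter")
f <- man$stages$filter

cat(sprintf("Annotations in: %d\n", f$annotations_in))
cat(sprintf("Flagged as duplicates: %d\n", f$flagged_duplicates))
cat(sprintf("Intact, non-duplicated prophages kept: %d\n", f$prophages_kept))

kept <- tsv("prophages_kept.tsv")
cat(sprintf("Score range among kept: %d-%d; ORF range: %d-%d\n",
            min(kept$completeness_score), max(kept$completeness_score),
            min(kept$orf_count), max(kept$orf_count)))
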