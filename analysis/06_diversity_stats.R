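# Stage 6: prevalence and richness statistics.
#
# On the lysogeny presence table: per-cluster two-sided Fisher tests of
# clade association with Bonferroni correction over the panel, per-genome
# prophage count comparison across clades by one-way ANOVA with Tukey HSD,
# prevalence summaries with Wilson 95% intervals, and rarefaction of phage
# cluster richness (10 replicates, nested subsampling).

source("analysis/00_common.R")

man <- run_stage("stats")
st <- man$stages$stats

cat(sprintf("Fisher tests run: %d; significant after Bonferroni: %d\n",
            st$fisher_tests, st$significant_after_bonferroni))
tests <- tsv("prevalence_tests.tsv")
sig <- tests[tests$p_adjusted < 0.05, ]
cat("Clade-enriched (or depleted) clusters after correction:\n")
print(sig[, c("group", "cluster", "carriers_in", "noncarriers_in",
              "p_value", "p_adjusted", "significance")], row.names = FALSE)

cat(sprintf("\nANOVA on prophage counts per genome across clades: p = %.4g\n",
            st$anova_p))
tk <- tsv("tukey.tsv")
print(tk[tk$p_adjusted < 0.05, ], row.names = FALSE)

rar <- tsv("rarefaction.tsv")
cat(sprintf("\nRarefaction: richness %.1f at n = %d genomes (95%% CI %.1f-%.1f)\n",
            rar$mean_richness[nrow(rar)], nrow(rar),
            rar$ci_lower[nrow(rar)], rar$ci_upper[nrow(rar)]))
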