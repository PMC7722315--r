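#!/usr/bin/env Rscript
# Stage 2: consensus circRNA catalog and exon categorization.
#
# Junctions supported by >= 2 BSJ reads in both callers form the catalog;
# caller A supplies expression. The top 1% by BSJ reads defines the
# high-confidence set. Exons of circRNA genes are categorized as BSJ
# circ-exons (boundary-matched), circ-exons (internal to a circle), or
# non-circ-exons.

suppressMessages(library(circscreen))

sim <- read_simulation("results/simulation")
dir.create("results/catalog", showWarnings = FALSE, recursive = TRUE)

me <- gene_merged_exons(sim$annotation$models)
catalog <- consensus_catalog(sim$circs$calls_a, sim$circs$calls_b)
catalog <- assign_host_gene(catalog, me)
catalog$relative_ratio <- relative_ratio(catalog$bsj_reads,
                                         catalog$linear_reads)
top <- top_percentile(catalog, 0.01)
et <- categorize_exons(me, catalog)

write.table(catalog, "results/catalog/catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(et, "results/catalog/exon_categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("consensus circRNAs: %d (from %d + %d caller calls)\n",
            nrow(catalog), nrow(sim$circs$calls_a),
            nrow(sim$circs$calls_b)))
cat(sprintf("top 1%% set: %d circRNA(s); highest support %d reads\n",
            nrow(top), max(top$bsj_reads)))
cat(sprintf("circular junction more abundant than linear for %.0f%%\n",
            100 * mean(catalog$relative_ratio > 0.5, na.rm = TRUE)))
print(table(et$category))
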