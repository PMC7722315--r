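#!/usr/bin/env Rscript
# Stage 5: eCLIP reads across backsplice junctions.
#
# Builds the exhaustive junction reference (last 30 bp of every donor exon
# pasted to the first 30 bp of every not-downstream acceptor exon, per
# transcript), maps the short eCLIP reads with <= 2 mismatches and a 5 bp
# span floor, removes PCR duplicates by barcode and position, and calls
# junctions with >= 10 reads in both IP replicates and log2FC >= 3 over
# the input.

suppressMessages(library(circscreen))

sim <- read_simulation("results/simulation")
dir.create("results/bsj", showWarnings = FALSE, recursive = TRUE)

refs <- build_bsj_reference(sim$annotation$models, sim$annotation$genome,
                            k = 30)
hits <- map_reads(sim$reads_sim$reads, refs)
dedup <- dedup_reads(hits)
counts <- count_junction_reads(dedup)
calls <- call_junction_sites(counts)
write.table(calls, "results/bsj/junction_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("junction references: %d (%d after sequence collapsing)\n",
            nrow(refs$junctions), nrow(refs$references)))
cat(sprintf("reads: %d   mapped hits: %d   after dedup: %d\n",
            nrow(sim$reads_sim$reads), nrow(hits), nrow(dedup)))
cat(sprintf("junctions with any coverage: %d; called: %d\n",
            nrow(counts), sum(calls$called)))
cat("called junctions:",
    paste(calls$junction_id[calls$called], collapse = ", "), "\n")
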