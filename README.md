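# circscreen

Transcriptome-wide screening of circular RNA (circRNA) and RNA-binding
protein (RBP) interactions.

CircRNAs form when a downstream splice donor backsplices to an upstream
acceptor; the resulting closed transcripts are stable, often abundant,
and untranslated — ideal binding platforms, potentially sponges, for
RBPs. Given backsplice-junction (BSJ) call tables from two circRNA
callers, eCLIP peak tables with size-matched input controls, a gene
annotation, gene expression values, Alu repeat positions,
knockdown/control count matrices, and raw junction-spanning reads,
circscreen answers three questions:

1. **Are circularizing exons enriched with RBP binding sites?**
   Peaks become binding sites after filtering (≥ 10 IP reads,
   log2 fold change ≥ 3 — an 8-fold linear enrichment — and ≥ 4 bp).
   Coverage of a feature is the percent of its exonic bases under the
   union of sites. BSJ circ-exons (exons whose boundary coincides with a
   backsplice coordinate) are compared to internal non-circularizing
   exons three ways: within host genes (pseudocount ratio
   `(cov + 1)/(mean cov + 1)`), per RBP (Wilcoxon rank-sum, BH-adjusted,
   FDR < 0.1), and against expression-matched draws from genes without
   circRNAs (100 expression bins, 100 iterations, add-one empirical
   p-value).
2. **Do specific RBPs sit in the introns flanking circRNAs?** 10 kb
   windows on each side are intersected with purely intronic bases;
   both-flank binding presence is tested circRNAs-vs-exons by
   Yates-corrected chi-square, inverted-Alu pairs (opposite-strand Alus
   across the two flanks) the same way, and the knockdown effect on the
   flanked circRNA subset is a Welch t-test on per-sample RPM totals.
3. **Does any RBP bind the backsplice junction itself?** An exhaustive
   junction reference (last 30 bp of each donor exon + first 30 bp of
   each not-downstream acceptor exon, per transcript; n(n+1)/2 per
   n-exon transcript) is scanned with ungapped ≤ 2-mismatch alignment of
   the short eCLIP reads, requiring ≥ 5 bp on each side of the junction,
   with PCR deduplication by barcode and position; junctions are called
   at ≥ 10 reads per IP replicate and per-replicate log2 fold change ≥ 3
   over input.

A synthetic-data generator (`simulate_screen()`) emulates every input
with planted ground truth — enriched RBPs, a flank-binding RBP with a
15% knockdown effect on its targets, callable junctions, an enriched GO
term — so the whole screen runs end-to-end with no external data.

## Worked example

```r
library(circscreen)

sim <- simulate_screen(simulation_config(seed = 7))
res <- run_screen(sim, screen_config(seed = 7))
res
#> circscreen run:
#>   n_consensus_circrnas             27
#>   n_top_circrnas                   1
#>   median_relative_ratio            0.5435
#>   mean_circ_rbp_coverage           57.62
#>   resample_observed_mean           59.35
#>   resample_empirical_p             0.009901
#>   n_rbps_differentially_bound      5
#>   kd_flanked_relative_change       -0.1781
#>   kd_flanked_p                     0.003317
#>   kd_complement_p                  0.06299
#>   n_junctions_called               6
#>   colocalization_pct               100
#>   top_go_term                      GO:PLANTED regulation of mRNA stability
#>   top_go_fold                      2
#>   top_go_p                         0.0303
```

Reading the output: 27 junctions survive the two-caller ≥ 2-read
consensus; the median circular-to-linear ratio above 0.5 means most
catalog circles out-express their linear counterparts at the junction.
Merged RBP sites cover 58% of the average circRNA's exonic bases, and
the mean coverage of BSJ circ-exons (59%) exceeds all 100
expression-matched resamples (empirical p = 1/101, the floor of the
add-one estimator, reported as p < 0.01). The knockdown of the
flank-binding RBP lowers expression of its both-flank target circRNAs by
18% (planted: 15%) at p = 0.003 while the complement stays
non-significant, and the six called junctions are exactly the planted
ones (three references, each shared by two isoforms). The planted GO
term tops the enrichment table.

`res$flank_enrichment`, `res$circ_coverage` (the per-circRNA table with
host-gene enrichment ratios), `res$differential_binding`, and
`res$junction_calls` hold the per-feature tables behind these summaries.

The `analysis/` directory holds the same workflow as numbered stage
scripts (`01_simulate.R` … `06_go_colocalization.R`); each writes its
tables under `results/` and prints what it found.

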