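# One seed of the expression-matched resampling analysis: generate a
# coordinate-only screen, measure mean merged-RBP coverage of internal BSJ
# circ-exons, and compare against expression-matched draws of internal
# non-circ-exons from genes without circRNAs.
measure_resample_p <- function(seed, circ_multiplier = 3,
                               iterations = 100L, n_bins = 100L) {
  cfg <- simulation_config(seed = seed, circ_multiplier = circ_multiplier)
  sim <- simulate_screen(cfg, stages = character(0), sequence = FALSE)
  me <- gene_merged_exons(sim$annotation$models)
  catalog <- sim$peaks_sim$catalog
  et <- categorize_exons(me, catalog)
  sites <- sites_granges(filter_sites(sim$peaks_sim$peaks))
  bins <- expression_bins(sim$annotation$models$genes, n_bins)
  cgenes <- unique(stats::na.omit(catalog$host_gene))
  cbins <- bins$bin[match(cgenes, bins$gene_id)]
  cbins <- cbins[!is.na(cbins)]
  obs <- et[et$category == "bsj_circ_exon" & et$gene_id %in% cgenes &
              !et$is_first & !et$is_last, ]
  pool <- et[!(et$gene_id %in% cgenes) & !et$is_first & !et$is_last, ]
  pool$bin <- bins$bin[match(pool$gene_id, bins$gene_id)]
  pool <- pool[!is.na(pool$bin), ]
  oc <- exon_coverage(gintervals(obs$chrom, obs$start, obs$end), sites)
  pc <- exon_coverage(gintervals(pool$chrom, pool$start, pool$end), sites)
  rs <- matched_resample(mean(oc), cbins, pool$bin, pc,
                         iterations = iterations)
  list(p = rs$empirical_p, obs_mean = mean(oc),
       obs_exons = oc, pool_exons = pc)
}

# One seed of the flanking-intron enrichment for the flank RBP
measure_flank_khsrp <- function(seed) {
  cfg <- simulation_config(seed = seed)
  sim <- simulate_screen(cfg, stages = character(0), sequence = FALSE)
  introns <- intronic_regions(sim$annotation$models)
  me <- gene_merged_exons(sim$annotation$models)
  catalog <- sim$peaks_sim$catalog
  et <- categorize_exons(me, catalog)
  sites <- sites_granges(filter_sites(sim$peaks_sim$peaks))
  k_sites <- sites[sites$rbp == cfg$flank_rbp]
  cgenes <- unique(stats::na.omit(catalog$host_gene))
  nc <- et[et$gene_id %in% cgenes & et$category == "non_circ_exon" &
             !et$is_first & !et$is_last, ]
  circ_fl <- flank_pairs(catalog_granges(catalog), introns)
  nc_fl <- flank_pairs(gintervals(nc$chrom, nc$start, nc$end), introns)
  flank_enrichment_test(both_flank_presence_all(circ_fl, k_sites),
                        both_flank_presence_all(nc_fl, k_sites))
}
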