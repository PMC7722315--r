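test_that("merged-site coverage matches the per-base oracle", {
  # exon (1,100); sites (11,40) and (31,60) cover 50 bases = 50%
  exon <- gintervals("chr1", 1, 100)
  sites <- gintervals("chr1", c(11, 31), c(40, 60), rbp = c("A", "B"))
  cv <- rbp_coverage(exon, sites)
  expect_equal(cv$covered_bp, 50)
  expect_equal(cv$coverage_pct, 50)
  expect_equal(rbp_coverage(exon, sites[0])$coverage_pct, 0)
  expect_equal(rbp_coverage(exon, gintervals("chr1", 1, 200,
                                             rbp = "A"))$coverage_pct, 100)
  expect_error(rbp_coverage(GenomicRanges::GRanges(), sites), "no exonic")
  # per-RBP rows when not merging
  byr <- rbp_coverage(exon, sites, merge_rbps = FALSE)
  expect_equal(byr$rbp, c("A", "B"))
  expect_equal(byr$coverage_pct, c(30, 30))
})

test_that("coverage is invariant to site splitting and ordering", {
  set.seed(41)
  exon <- gr_from_df(data.frame(start = 1, end = 500))
  for (i in 1:20) {
    df <- rand_intervals(8, 600)
    sites <- gr_from_df(df)
    base <- rbp_coverage(exon, sites)$coverage_pct
    expect_equal(base, oracle_coverage_pct(data.frame(start = 1, end = 500),
                                           df))
    # split every site at its midpoint
    mid <- pmin(df$end, df$start + pmax(0, (df$end - df$start) %/% 2))
    split_df <- rbind(data.frame(start = df$start, end = mid),
                      data.frame(start = pmin(mid + 1, df$end),
                                 end = df$end))
    split_df <- split_df[split_df$start <= split_df$end, ]
    expect_equal(rbp_coverage(exon, gr_from_df(split_df))$coverage_pct, base)
    # permuting input order changes nothing; adding sites never decreases
    expect_equal(rbp_coverage(exon,
                              sites[sample(length(sites))])$coverage_pct,
                 base)
    expect_gte(rbp_coverage(exon, c(sites, gr_from_df(
      rand_intervals(2, 600))))$coverage_pct, base)
  }
})

test_that("per-exon coverage vector matches single-feature coverage", {
  set.seed(42)
  exons <- gr_from_df(data.frame(start = c(1, 201, 401),
                                 end = c(100, 300, 500)))
  sites <- gr_from_df(rand_intervals(10, 600))
  vec <- exon_coverage(exons, sites)
  for (i in 1:3) {
    expect_equal(vec[i], rbp_coverage(exons[i], sites)$coverage_pct)
  }
})

test_that("host-gene enrichment applies the add-one pseudocount", {
  # circCDYL-like inputs: 93% circ coverage, 7% mean non-circ coverage
  e <- host_gene_enrichment(93, c(7, 7))
  expect_equal(e$ratio, 94 / 8)
  # fully covered circle over a site-free internal exon
  expect_equal(host_gene_enrichment(100, 0)$ratio, 101)
  # no internal non-circ exons in the host gene
  expect_true(is.na(host_gene_enrichment(50, numeric())$ratio))
})

test_that("expression bins are deterministic equal-size quantiles", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      fpkm = sample(seq(0.1, 1000, length.out = 200)))
  b <- expression_bins(genes, 100)
  expect_true(all(table(b$bin) == 2))
  expect_equal(b$bin[which.max(b$fpkm)], 100)
  # identical fpkm split into adjacent bins by gene id
  ties <- data.frame(gene_id = c("gB", "gA", "gC", "gD"), fpkm = 5)
  bt <- expression_bins(ties, 2)
  expect_equal(bt$gene_id, c("gA", "gB", "gC", "gD"))
  expect_equal(bt$bin, c(1L, 1L, 2L, 2L))
  expect_error(expression_bins(genes[1:50, ], 100), "expressed genes")
  # zero-expression genes are dropped before binning
  genes$fpkm[1] <- 0
  expect_false("g001" %in% expression_bins(genes, 100)$gene_id)
})

test_that("matched resampling preserves the bin histogram semantics", {
  set.seed(43)
  pool_bins <- rep(1:5, each = 20)
  pool_values <- rnorm(100, mean = 10 * pool_bins)  # strong bin effect
  circ_bins <- c(1, 1, 5)
  rs <- matched_resample(0, circ_bins, pool_bins, pool_values,
                         iterations = 200)
  # every resampled mean is a mean of two bin-1 draws and one bin-5 draw
  lo <- range(pool_values[pool_bins == 1])
  hi <- range(pool_values[pool_bins == 5])
  expect_true(all(rs$resampled_means >= (2 * lo[1] + hi[1]) / 3))
  expect_true(all(rs$resampled_means <= (2 * lo[2] + hi[2]) / 3))
  expect_false(rs$replacement_used)
  expect_false(rs$bin_fallback_used)
  # observed above all resamples gives the add-one floor
  rs2 <- matched_resample(1e6, circ_bins, pool_bins, pool_values,
                          iterations = 100)
  expect_equal(rs2$empirical_p, 1 / 101)
  # constant pool makes ties count and p = 1
  rs3 <- matched_resample(7, circ_bins, pool_bins, rep(7, 100),
                          iterations = 100)
  expect_equal(rs3$empirical_p, 1)
  # small pool bins flag replacement; absent bins fall back to nearest
  rs4 <- matched_resample(0, c(2, 2, 2), c(2, 2), rnorm(2), iterations = 10)
  expect_true(rs4$replacement_used)
  rs5 <- matched_resample(0, 3, c(1, 5), rnorm(2), iterations = 10)
  expect_true(rs5$bin_fallback_used)
})

test_that("per-RBP differential binding applies floors and BH", {
  # geometry: 3 BSJ circ-exons fully covered by RBP "hot", 3 internal
  # non-circ exons uncovered; RBP "rare" has too few sites to qualify
  et <- data.frame(
    gene_id = "g1", chrom = "chr1",
    start = c(1, 201, 401, 601, 801, 1001, 1201, 1401),
    end = c(100, 300, 500, 700, 900, 1100, 1300, 1500),
    strand = "+", exon_rank = 1:8,
    is_first = c(TRUE, rep(FALSE, 7)),
    is_last = c(rep(FALSE, 7), TRUE),
    category = c("non_circ_exon", "bsj_circ_exon", "bsj_circ_exon",
                 "bsj_circ_exon", "non_circ_exon", "non_circ_exon",
                 "non_circ_exon", "non_circ_exon"))
  et$in_any_circ <- et$category != "non_circ_exon"
  hot <- gintervals("chr1", seq(201, 700, by = 25), seq(210, 709, by = 25),
                    rbp = "hot")
  rare <- gintervals("chr1", c(801, 851), c(810, 860), rbp = "rare")
  out <- per_rbp_differential_binding(et, c(hot, rare), min_sites = 20)
  expect_equal(out$rbp, "hot")          # under-threshold RBP excluded
  expect_equal(out$n_bsj, 3)
  expect_equal(out$n_noncirc, 3)        # first/last exons dropped
  expect_gt(out$mean_cov_bsj, out$mean_cov_noncirc)
  expect_equal(out$p, wilcoxon_rank_sum(
    exon_coverage(gintervals(et$chrom[2:4], et$start[2:4], et$end[2:4]),
                  hot),
    exon_coverage(gintervals(et$chrom[5:7], et$start[5:7], et$end[5:7]),
                  hot)))
  expect_equal(out$fdr, out$p)          # single test: BH is identity
})
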