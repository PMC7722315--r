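test_that("flank windows intersect intronic bases only", {
  # feature (50001,52000) inside a sea of intron
  introns <- gintervals("chr1", 1, 100000)
  pair <- flank_pair(gintervals("chr1", 50001, 52000), introns)
  expect_equal(df_from_gr(pair$upstream),
               data.frame(start = 40001L, end = 50000L))
  expect_equal(df_from_gr(pair$downstream),
               data.frame(start = 52001L, end = 62000L))
  expect_equal(interval_bases(pair$upstream), 10000L)
  # an exon inside the upstream window is excluded
  introns2 <- interval_subtract(introns, gintervals("chr1", 45001, 46000))
  pair2 <- flank_pair(gintervals("chr1", 50001, 52000), introns2)
  expect_equal(interval_bases(pair2$upstream), 9000L)
  # features at the chromosome start have a clipped upstream window
  pair3 <- flank_pair(gintervals("chr1", 3001, 4000), introns)
  expect_equal(df_from_gr(pair3$upstream),
               data.frame(start = 1L, end = 3000L))
})

test_that("vectorized flank pairs agree with the single-feature version", {
  set.seed(51)
  introns <- merge_intervals(gr_from_df(rand_intervals(30, 5000)))
  feats <- gr_from_df(data.frame(start = c(500, 1500, 4000),
                                 end = c(700, 1600, 4400)))
  fp <- flank_pairs(feats, introns, width = 300)
  for (i in 1:3) {
    single <- flank_pair(feats[i], introns, width = 300)
    multi <- flank_pair_at(fp, i)
    expect_equal(df_from_gr(multi$upstream), df_from_gr(single$upstream))
    expect_equal(df_from_gr(multi$downstream),
                 df_from_gr(single$downstream))
  }
})

test_that("both-flank presence requires a site on each side", {
  introns <- gintervals("chr1", 1, 100000)
  feat <- gintervals("chr1", 50001, 52000)
  pair <- flank_pair(feat, introns)
  up <- gintervals("chr1", 45000, 45040, rbp = "K")
  dn <- gintervals("chr1", 55000, 55040, rbp = "K")
  expect_true(both_flank_presence(pair, c(up, dn)))
  expect_false(both_flank_presence(pair, up))
  expect_false(both_flank_presence(pair, dn))
  # a site straddling the feature boundary counts for that flank
  straddle <- gintervals("chr1", 51990, 52010, rbp = "K")
  expect_true(both_flank_presence(pair, c(up, straddle)))
  fp <- flank_pairs(feat, introns)
  expect_equal(both_flank_presence_all(fp, c(up, dn)), TRUE)
  expect_equal(both_flank_presence_all(fp, up), FALSE)
})

test_that("inverted Alu pairs need opposite strands across the flanks", {
  introns <- gintervals("chr1", 1, 100000)
  pair <- flank_pair(gintervals("chr1", 50001, 52000), introns)
  up_p <- gintervals("chr1", 45000, 45300, strand = "+")
  dn_m <- gintervals("chr1", 55000, 55300, strand = "-")
  dn_p <- gintervals("chr1", 55000, 55300, strand = "+")
  expect_true(iralu_both_flanks(pair, c(up_p, dn_m)))
  expect_false(iralu_both_flanks(pair, c(up_p, dn_p)))
  expect_false(iralu_both_flanks(pair, up_p))
  # symmetric under swapping every strand
  swap <- function(gr) {
    s <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(s == "+", "-", "+")
    gr
  }
  set.seed(52)
  for (i in 1:20) {
    alus <- gr_from_df(rand_intervals(6, 100000), chrom = "chr1")
    GenomicRanges::strand(alus) <- sample(c("+", "-"), 6, replace = TRUE)
    expect_equal(iralu_both_flanks(pair, alus),
                 iralu_both_flanks(pair, swap(alus)))
  }
})

test_that("flank enrichment chi-square and fold behave as specified", {
  r0 <- flank_enrichment_test(rep(c(TRUE, FALSE), each = 10),
                              rep(c(TRUE, FALSE), each = 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r1 <- flank_enrichment_test(rep(c(TRUE, FALSE), c(30, 70)),
                              rep(c(TRUE, FALSE), c(10, 90)))
  expect_equal(r1$statistic, 11.28125)
  expect_equal(r1$fold, 3)
  # proportions 20% vs 8% give fold 2.5
  r2 <- flank_enrichment_test(rep(c(TRUE, FALSE), c(20, 80)),
                              rep(c(TRUE, FALSE), c(8, 92)))
  expect_equal(r2$fold, 2.5)
  # a zero margin leaves the test undefined
  r3 <- flank_enrichment_test(rep(FALSE, 10), rep(FALSE, 10))
  expect_true(is.na(r3$p))
})

test_that("RPM normalization scales counts by library size", {
  m <- matrix(c(5, 0, 10, 2), 2, dimnames = list(c("c1", "c2"), NULL))
  rpm <- rpm_normalize(m, c(1e6, 2e6))
  expect_equal(unname(rpm[1, 1]), 5)
  expect_equal(unname(rpm[2, 1]), 0)
  expect_equal(unname(rpm[1, 2]), 5)  # doubled library halves RPM
  expect_error(rpm_normalize(m, c(0, 1)), "positive")
  expect_error(rpm_normalize(-m, c(1, 1)), "non-negative")
})

test_that("knockdown comparison recovers constructed effects", {
  rpm <- matrix(c(85, 85, 85, 100, 100, 100), 1,
                dimnames = list("c1", NULL))
  cond <- rep(c("KD", "control"), each = 3)
  # exact 0.85x construction gives a -15% relative change
  out <- kd_group_compare(rpm + rbind(c(1, 2, 3, 1, 2, 3) * 1e-9), cond,
                          "c1")
  expect_equal(out$relative_change, -0.15, tolerance = 1e-6)
  # identical groups: no change, rank-sum p = 1
  rpm2 <- matrix(rep(c(3, 4, 5), 2), 1, dimnames = list("c1", NULL))
  out2 <- kd_group_compare(rpm2, cond, "c1", test = "wilcoxon")
  expect_equal(out2$relative_change, 0)
  expect_equal(out2$p, 1)
  expect_error(kd_group_compare(rpm2, cond, character()), "empty")
  expect_error(kd_group_compare(rpm2, cond, "nope"), "absent")
})
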