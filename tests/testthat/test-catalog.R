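make_calls <- function(starts, bsj, linear = 0L, chrom = "chr1",
                       width = 100L) {
  circ_calls(data.frame(
    chrom = chrom, start = starts, end = starts + width - 1L,
    strand = "+", bsj_reads = bsj, linear_reads = linear,
    stringsAsFactors = FALSE))
}

test_that("consensus keeps junctions with >= 2 reads in both callers", {
  a <- make_calls(c(100, 200, 300, 400), bsj = c(5, 5, 1, 4))
  b <- make_calls(c(100, 200, 300), bsj = c(3, 1, 1))
  out <- consensus_catalog(a, b)
  expect_equal(out$start, 100)     # (5,3) kept; (5,1), (1,1) dropped;
  expect_equal(out$bsj_reads_b, 3) # 400 absent from caller B
})

test_that("coordinate-convention mismatch between callers errors", {
  a <- make_calls(100, 5)
  b <- make_calls(100, 5)
  attr(b, "coords") <- NULL
  expect_error(consensus_catalog(a, b), "coordinate convention")
})

test_that("caller dialects normalize to identical junctions", {
  dir <- withr::local_tempdir()
  df1 <- data.frame(chrom = "chr1", start = 101, end = 200, strand = "+",
                    bsj_reads = 5, linear_reads = 0)
  df0 <- transform(df1, start = 100)  # same junction, BED-style start
  write.table(df1, file.path(dir, "a.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(df0, file.path(dir, "b.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  a <- read_circ_calls(file.path(dir, "a.tsv"), "one_based_closed")
  b <- read_circ_calls(file.path(dir, "b.tsv"), "zero_based_half_open")
  expect_identical(a$circ_id, b$circ_id)
})

test_that("top percentile selects ceiling(fraction * N) by caller-A reads", {
  set.seed(11)
  for (n in c(1, 7, 100, 1234)) {
    cat_n <- make_calls(seq_len(n) * 1000L, bsj = sample(2:10000, n,
                                                         replace = TRUE))
    k <- ceiling(0.01 * n)
    sel <- top_percentile(cat_n, 0.01)
    expect_equal(nrow(sel), k)
    expect_gte(min(sel$bsj_reads),
               max(cat_n$bsj_reads[!(cat_n$circ_id %in% sel$circ_id)], 0))
  }
  expect_error(top_percentile(make_calls(1, 5), 0), "proportion")
  expect_error(top_percentile(make_calls(1, 5), 1.5), "proportion")
})

test_that("boundary ties break lexicographically by circ_id", {
  cat_t <- make_calls(c(300, 100, 200), bsj = c(10, 5, 5))
  sel <- top_percentile(cat_t, 2 / 3)
  expect_equal(sel$start, c(300, 100))  # chr1:100- sorts before chr1:200-
})

test_that("relative circular-to-linear ratio follows the doubling rule", {
  expect_equal(relative_ratio(10, 20), 0.5)
  expect_equal(relative_ratio(0, 7), 0)
  expect_equal(relative_ratio(5163, 0), 1)  # fully circular junction
  expect_true(is.na(relative_ratio(0, 0)))
  # monotone in each argument
  expect_true(all(diff(relative_ratio(1:50, 10)) > 0))
  expect_true(all(diff(relative_ratio(10, 1:50)) < 0))
  expect_error(relative_ratio(-1, 5), "non-negative")
})

test_that("host gene is the strand-matched gene with most exon overlap", {
  me <- gene_merged_exons(toy_models())
  cat1 <- make_calls(301, bsj = 10, width = 300)  # overlaps gA exons
  expect_equal(assign_host_gene(cat1, me)$host_gene, "gA")
  # minus-strand circRNA on chr2 matches gB
  cat2 <- circ_calls(data.frame(chrom = "chr2", start = 2001, end = 3200,
                                strand = "-", bsj_reads = 5,
                                linear_reads = 0))
  expect_equal(assign_host_gene(cat2, me)$host_gene, "gB")
  # strand-mismatched circRNA gets no host
  cat3 <- circ_calls(data.frame(chrom = "chr2", start = 2001, end = 3200,
                                strand = "+", bsj_reads = 5,
                                linear_reads = 0))
  expect_true(is.na(assign_host_gene(cat3, me)$host_gene))
})

test_that("exonic parts are the circ span intersected with host exons", {
  # merged exons (101,200),(301,400),(601,700); span (101,500)
  exons <- gintervals("chr1", c(101, 301, 601), c(200, 400, 700),
                      strand = "+", gene_id = "g1",
                      transcript_id = "t1")
  me <- gene_merged_exons(gene_models(exons))
  cat1 <- assign_host_gene(
    circ_calls(data.frame(chrom = "chr1", start = 101, end = 500,
                          strand = "+", bsj_reads = 9, linear_reads = 0)),
    me)
  parts <- circ_exonic_parts(cat1, me)
  expect_equal(parts$summary$exonic_length, 200L)
  expect_equal(parts$summary$n_exons, 2L)
  expect_true(parts$summary$has_exons)
  # intergenic span is flagged
  cat2 <- assign_host_gene(
    circ_calls(data.frame(chrom = "chr1", start = 5000, end = 5400,
                          strand = "+", bsj_reads = 9, linear_reads = 0)),
    me)
  p2 <- circ_exonic_parts(cat2, me)
  expect_false(p2$summary$has_exons)
  expect_equal(p2$summary$exonic_length, 0L)
})

test_that("exon categories follow the boundary-precedence rule", {
  exons <- gintervals("chr1", c(101, 251, 401, 601), c(200, 300, 500, 700),
                      strand = "+", gene_id = "g1",
                      transcript_id = "t1")
  me <- gene_merged_exons(gene_models(exons))
  cat1 <- assign_host_gene(
    circ_calls(data.frame(chrom = "chr1", start = 101, end = 500,
                          strand = "+", bsj_reads = 9, linear_reads = 0)),
    me)
  et <- categorize_exons(me, cat1)
  expect_equal(et$category,
               c("bsj_circ_exon",  # boundary match at 101
                 "circ_exon",      # inside span, no boundary
                 "bsj_circ_exon",  # boundary match at 500
                 "non_circ_exon"))
  expect_equal(et$in_any_circ, c(TRUE, TRUE, TRUE, FALSE))
  # an exon internal to circle X but boundary exon of circle Y is BSJ
  two <- assign_host_gene(
    circ_calls(data.frame(chrom = "chr1", start = c(101, 251),
                          end = c(500, 300), strand = "+",
                          bsj_reads = c(9, 9), linear_reads = 0)),
    me)
  et2 <- categorize_exons(me, two)
  expect_equal(et2$category[2], "bsj_circ_exon")
  # removing a circRNA never promotes a non-circ exon
  et3 <- categorize_exons(me, two[1, , drop = FALSE])
  was_non <- et2$category == "non_circ_exon"
  expect_true(all(et3$category[was_non] == "non_circ_exon"))
})
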