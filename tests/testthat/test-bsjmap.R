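# deterministic two-gene annotation with a known genome for junction tests
bsj_fixture <- function(seed = 61) {
  set.seed(seed)
  genome_str <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                      collapse = "")
  genome <- Biostrings::DNAStringSet(genome_str)
  names(genome) <- "chrF"
  exons <- gintervals(
    "chrF",
    start = c(101, 301, 601, 1501, 1901, 2401),
    end = c(200, 380, 700, 1580, 2000, 2480),
    strand = c(rep("+", 3), rep("-", 3)),
    gene_id = c(rep("gP", 3), rep("gM", 3)),
    transcript_id = c(rep("gP.T1", 3), rep("gM.T1", 3)))
  list(models = gene_models(exons), genome = genome,
       genome_str = genome_str)
}

test_that("every exon pair yields one junction reference", {
  fx <- bsj_fixture()
  refs <- build_bsj_reference(fx$models, fx$genome, k = 30)
  per_tx <- table(refs$junctions$transcript_id)
  expect_equal(unname(per_tx[["gP.T1"]]), 6)  # n(n+1)/2 for n = 3
  expect_equal(unname(per_tx[["gM.T1"]]), 6)
  expect_true(all(nchar(refs$junctions$sequence) == 60))
  expect_false(any(refs$junctions$truncated))
  # plus strand, donor exon 2 to acceptor exon 1: last 30 of exon 2
  # followed by first 30 of exon 1, read off the genome directly
  j21 <- refs$junctions[refs$junctions$junction_id == "gP.T1:2:1", ]
  expect_equal(j21$sequence,
               paste0(substr(fx$genome_str, 351, 380),
                      substr(fx$genome_str, 101, 130)))
  # single-exon circle junction i = j
  j11 <- refs$junctions[refs$junctions$junction_id == "gP.T1:1:1", ]
  expect_equal(j11$sequence,
               paste0(substr(fx$genome_str, 171, 200),
                      substr(fx$genome_str, 101, 130)))
  # minus strand: transcript order is reversed and sequences are
  # reverse-complemented
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  jm <- refs$junctions[refs$junctions$junction_id == "gM.T1:2:1", ]
  donor <- rc(substr(fx$genome_str, 1901, 2000))  # exon 2 in tx order
  acceptor <- rc(substr(fx$genome_str, 2401, 2480))  # exon 1 in tx order
  expect_equal(jm$sequence,
               paste0(substr(donor, 71, 100), substr(acceptor, 1, 30)))
})

test_that("short exons truncate their junction arm without padding", {
  set.seed(62)
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""))
  names(genome) <- "chrF"
  exons <- gintervals("chrF", c(101, 301), c(120, 400), strand = "+",
                      gene_id = "g", transcript_id = "g.T1")
  refs <- build_bsj_reference(gene_models(exons), genome, k = 30)
  j <- refs$junctions[refs$junctions$junction_id == "g.T1:2:1", ]
  expect_equal(j$acceptor_len, 20)  # 20 bp exon contributes all its bases
  expect_true(j$truncated)
  expect_equal(nchar(j$sequence), 50)
})

test_that("junction hits require span and respect the mismatch budget", {
  fx <- bsj_fixture()
  refs <- build_bsj_reference(fx$models, fx$genome, k = 30)
  ref1 <- refs$references[1, ]
  mk <- function(seq, id = "r1") {
    data.frame(read_id = id, barcode = "AACCGGTTAA", sequence = seq,
               sample = "IP_rep1", stringsAsFactors = FALSE)
  }
  # 20 bp read copied from positions 21-40: 10 bp on each side
  hit <- map_reads(mk(substr(ref1$sequence, 21, 40)), refs)
  expect_true(ref1$ref_id %in% hit$ref_id)
  expect_true(any(hit$offset == 21 & hit$ref_id == ref1$ref_id))
  # placed at 27-46: only 4 bp on the donor side
  expect_equal(nrow(map_reads(mk(substr(ref1$sequence, 27, 46)), refs)), 0)
  # three substitutions exceed the budget
  bad <- substr(ref1$sequence, 21, 40)
  substr(bad, 2, 2) <- if (substr(bad, 2, 2) == "A") "C" else "A"
  substr(bad, 9, 9) <- if (substr(bad, 9, 9) == "A") "C" else "A"
  substr(bad, 17, 17) <- if (substr(bad, 17, 17) == "A") "C" else "A"
  expect_equal(nrow(map_reads(mk(bad), refs)), 0)
  # reverse-complement orientation is searched
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref1$sequence, 21, 40))))
  hit_rc <- map_reads(mk(rc), refs)
  expect_true(any(hit_rc$orientation == "-" & hit_rc$ref_id == ref1$ref_id))
  # reads shorter than twice the span floor are skipped with a warning
  expect_warning(out <- map_reads(mk("ACGTACGT"), refs), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("mapping equals a brute-force Hamming scan on random instances", {
  set.seed(63)
  for (rep in 1:3) {
    refs <- list(references = data.frame(
      ref_id = sprintf("R%02d", 1:40),
      sequence = vapply(1:40, function(i) {
        paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
              collapse = "")
      }, character(1)),
      junction_offset = 30L,
      stringsAsFactors = FALSE))
    refs$references$junction_ids <- refs$references$ref_id
    reads <- do.call(rbind, lapply(1:12, function(i) {
      src <- sample(40, 1)
      st <- sample(12:35, 1)
      len <- sample(20:25, 1)
      sq <- substr(refs$references$sequence[src], st, st + len - 1)
      nmm <- sample(0:3, 1)
      if (nmm > 0) {
        ch <- strsplit(sq, "")[[1]]
        for (p in sample(len, nmm)) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        }
        sq <- paste(ch, collapse = "")
      }
      data.frame(read_id = sprintf("r%02d", i), barcode = "AAAA",
                 sequence = sq, sample = "IP_rep1",
                 stringsAsFactors = FALSE)
    }))
    got <- map_reads(reads, refs)
    for (i in seq_len(nrow(reads))) {
      want <- oracle_map_read(reads$sequence[i], refs$references)
      have <- got[got$read_id == reads$read_id[i],
                  c("ref_id", "offset", "orientation")]
      rownames(have) <- NULL
      expect_equal(have[order(have$ref_id, have$offset, have$orientation), ],
                   want[order(want$ref_id, want$offset, want$orientation), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("deduplication keeps one read per barcode/junction/offset", {
  hits <- data.frame(
    read_id = c("r2", "r1", "r3", "r4", "r5"),
    barcode = c("A", "A", "B", "A", "A"),
    sample = "IP_rep1",
    junction_id = "j1", ref_id = "R1",
    offset = c(100, 100, 100, 100, 120),
    orientation = "+")
  out <- dedup_reads(hits)
  expect_equal(nrow(out), 3)  # (A,100), (B,100), (A,120)
  expect_true("r1" %in% out$read_id)   # first by read id wins
  expect_false("r2" %in% out$read_id)
  # idempotent and order-insensitive in output size
  expect_identical(dedup_reads(out), out)
  expect_equal(nrow(dedup_reads(hits[sample(5), ])), 3)
  expect_equal(nrow(dedup_reads(hits[0, ])), 0)
})

test_that("junction calling enforces per-replicate floors and fold change", {
  counts <- data.frame(
    junction_id = c("j1", "j2", "j3"),
    IP_rep1 = c(15, 15, 100),
    IP_rep2 = c(15, 9, 100),
    input = c(1, 0, 40))
  out <- call_junction_sites(counts)
  expect_equal(out$called, c(TRUE, FALSE, FALSE))
  expect_equal(out$log2fc_rep1, log2(c(16 / 2, 16 / 1, 101 / 41)))
  expect_error(call_junction_sites(counts[, 1:3]), "columns")
})

test_that("FASTQ round-trip preserves reads and barcodes", {
  reads <- data.frame(read_id = c("a1", "a2"),
                      barcode = c("ACGTACGTAC", "TTTTGGGGCC"),
                      sequence = c("ACGTACGTACGTACGTACGT",
                                   "GGGGTTTTCCCCAAAAGGGG"),
                      sample = "IP_rep1", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_eclip_fastq(reads, path)
  back <- read_eclip_reads(path, sample = "IP_rep1")
  expect_equal(back$barcode, reads$barcode)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$sample, reads$sample)
})
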