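# Independent brute-force oracles. Everything here works on explicit
# per-base sets or exhaustive enumeration and never calls the package's
# interval or statistics code paths.

# intervals as data frames of 1-based closed start/end on one chromosome
bases_of <- function(df) {
  if (nrow(df) == 0L) return(integer())
  sort(unique(unlist(mapply(seq.int, df$start, df$end, SIMPLIFY = FALSE))))
}

set_to_intervals <- function(bases) {
  if (length(bases) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  bases <- sort(unique(bases))
  brk <- c(0L, which(diff(bases) > 1L), length(bases))
  data.frame(start = bases[brk[-length(brk)] + 1L],
             end = bases[brk[-1L]])
}

bf_merge <- function(df) set_to_intervals(bases_of(df))
bf_intersect <- function(a, b) {
  set_to_intervals(intersect(bases_of(a), bases_of(b)))
}
bf_subtract <- function(a, b) {
  set_to_intervals(setdiff(bases_of(a), bases_of(b)))
}

rand_intervals <- function(n, max_coord = 1000L) {
  s <- sample.int(max_coord - 1L, n, replace = TRUE)
  w <- sample.int(50L, n, replace = TRUE)
  data.frame(start = s, end = pmin(max_coord, s + w - 1L))
}

gr_from_df <- function(df, chrom = "chrT") {
  gintervals(rep(chrom, nrow(df)), df$start, df$end)
}

df_from_gr <- function(gr) {
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

# exhaustive hypergeometric tail for a 2x2 table, direction "greater" on
# the top-left cell at fixed margins
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # col 1 total
  n <- a + b + c + d
  lo <- max(0L, k - (n - m))
  hi <- min(m, k)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n - m, k - x) / choose(n, k)
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcox_two_sided <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  p
}

# Yates-corrected chi-square statistic from the definition
oracle_chi2 <- function(tbl, yates = TRUE) {
  e <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  d <- abs(tbl - e)
  if (yates) d <- pmax(d - 0.5, 0)
  sum(d^2 / e)
}

# step-up BH from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# per-base coverage oracle: percent of feature bases hit by any site
oracle_coverage_pct <- function(feature_df, site_df) {
  fb <- bases_of(feature_df)
  100 * length(intersect(fb, bases_of(site_df))) / length(fb)
}

# all-offsets Hamming scan of a read against references (both strands)
oracle_map_read <- function(seq, refs, max_mm = 2L, min_span = 5L) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits <- list()
  for (ori in c("+", "-")) {
    pat <- if (ori == "+") seq else revcomp(seq)
    pv <- strsplit(pat, "")[[1]]
    len <- length(pv)
    for (i in seq_len(nrow(refs))) {
      rv <- strsplit(refs$sequence[i], "")[[1]]
      off <- refs$junction_offset[i]
      if (length(rv) < len) next
      for (st in seq_len(length(rv) - len + 1L)) {
        mm <- sum(pv != rv[st:(st + len - 1L)])
        left <- off - st + 1L
        right <- (st + len - 1L) - off
        if (mm <= max_mm && left >= min_span && right >= min_span) {
          hits[[length(hits) + 1L]] <- data.frame(
            ref_id = refs$ref_id[i], offset = st, orientation = ori,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(ref_id = character(), offset = integer(),
                      orientation = character()))
  }
  unique(do.call(rbind, hits))
}

# tiny deterministic gene models fixture: two genes, two chromosomes
toy_models <- function() {
  exons <- gintervals(
    chrom = c(rep("chr1", 5), rep("chr2", 3)),
    start = c(101, 301, 501, 101, 501, 1001, 2001, 3001),
    end   = c(200, 400, 600, 220, 600, 1200, 2200, 3200),
    strand = c(rep("+", 5), rep("-", 3)),
    gene_id = c(rep("gA", 5), rep("gB", 3)),
    transcript_id = c(rep("gA.T1", 3), rep("gA.T2", 2),
                      rep("gB.T1", 3))
  )
  gene_models(exons, expression = data.frame(gene_id = c("gA", "gB"),
                                             fpkm = c(5, 50)))
}
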