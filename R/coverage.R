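#' Fraction of a feature's exonic bases covered by RBP binding sites
#'
#' Merges the supplied binding sites (union across RBPs when `merge_rbps`)
#' and intersects them with the feature's exonic intervals. Coverage is the
#' percentage of exonic bases overlapped by at least one site.
#'
#' @param feature_exonic `GRanges` of the feature's exonic parts (e.g. one
#'   element of [circ_exonic_parts()]). Must be non-empty: features without
#'   annotated exons are excluded upstream.
#' @param sites `GRanges` of filtered binding sites with an `rbp` column.
#' @param merge_rbps Union sites across all RBPs before intersecting
#'   (default `TRUE`). With `FALSE` a row per RBP is returned.
#' @return Data frame with `rbp` (`"all"` when merged), `exonic_length`,
#'   `covered_bp`, `coverage_pct`.
#' @export
rbp_coverage <- function(feature_exonic, sites, merge_rbps = TRUE) {
  len <- interval_bases(feature_exonic)
  if (len == 0L) stop("feature has no exonic bases; exclude it upstream")
  one <- function(s, label) {
    cov <- if (length(s) == 0L) 0L else {
      interval_bases(interval_intersect(feature_exonic, s))
    }
    data.frame(rbp = label, exonic_length = len, covered_bp = cov,
               coverage_pct = 100 * cov / len, stringsAsFactors = FALSE)
  }
  if (merge_rbps) {
    one(sites, "all")
  } else {
    out <- do.call(rbind, lapply(sort(unique(sites$rbp)), function(r) {
      one(sites[sites$rbp == r], r)
    }))
    rownames(out) <- NULL
    out
  }
}

#' Per-exon merged binding-site coverage
#'
#' Vectorized coverage of many exons by the union of binding sites.
#'
#' @param exons `GRanges` of exons.
#' @param sites `GRanges` of binding sites (merged internally).
#' @return Numeric vector of coverage percentages, parallel to `exons`.
#' @export
exon_coverage <- function(exons, sites) {
  n <- length(exons)
  covered <- numeric(n)
  if (length(sites) > 0L && n > 0L) {
    red <- merge_intervals(sites)
    hits <- GenomicRanges::findOverlaps(exons, red, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(exons)[S4Vectors::queryHits(hits)],
        IRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
      covered[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  100 * covered / IRanges::width(exons)
}

#' Host-gene RBP-coverage enrichment ratio of a circRNA
#'
#' Divides the circRNA's merged RBP coverage by the mean coverage of the
#' internal (not first/last) non-circularizing exons of its host gene. A
#' pseudocount of 1 is added to numerator and denominator so circRNAs and
#' exons without any binding site stay in the analysis; the ratio is
#' therefore bounded to \[1/101, 101\]. `NA` when the host gene has no
#' internal non-circ-exons.
#'
#' @param circ_coverage_pct CircRNA coverage percentage (scalar).
#' @param noncirc_coverage_pct Numeric vector of coverage percentages of the
#'   host gene's internal non-circ-exons (possibly empty).
#' @return List with `ratio`, `circ_coverage_pct`,
#'   `mean_noncirc_coverage_pct`, `n_noncirc_exons`.
#' @export
host_gene_enrichment <- function(circ_coverage_pct, noncirc_coverage_pct) {
  n <- length(noncirc_coverage_pct)
  m <- if (n == 0L) NA_real_ else mean(noncirc_coverage_pct)
  list(
    ratio = if (n == 0L) NA_real_ else (circ_coverage_pct + 1) / (m + 1),
    circ_coverage_pct = circ_coverage_pct,
    mean_noncirc_coverage_pct = m,
    n_noncirc_exons = n
  )
}

#' Assign expressed genes to expression quantile bins
#'
#' Sorts genes with positive expression by FPKM (ties broken by gene id so
#' the assignment is deterministic) and splits them into `n_bins` bins of
#' equal size up to the remainder; the highest-expressed gene always lands
#' in the top bin.
#'
#' @param genes Data frame with columns `gene_id` and `fpkm`.
#' @param n_bins Number of bins (default 100).
#' @return Data frame `gene_id`, `fpkm`, `bin` (integer 1..n_bins),
#'   restricted to genes with `fpkm > 0`.
#' @export
expression_bins <- function(genes, n_bins = 100L) {
  expressed <- genes[!is.na(genes$fpkm) & genes$fpkm > 0, , drop = FALSE]
  n <- nrow(expressed)
  if (n < n_bins) {
    stop(sprintf("only %d expressed genes for %d bins", n, n_bins))
  }
  ord <- order(expressed$fpkm, expressed$gene_id)
  out <- expressed[ord, c("gene_id", "fpkm"), drop = FALSE]
  out$bin <- as.integer(floor((seq_len(n) - 1L) * n_bins / n) + 1L)
  rownames(out) <- NULL
  out
}

#' Expression-matched resampling of non-circularizing exons
#'
#' Compares the observed mean merged-RBP coverage of circularizing exons to
#' a null distribution of means obtained by repeatedly drawing internal
#' non-circ-exons from genes not producing circRNAs, matching the
#' expression-bin histogram of the circRNA-producing genes: each iteration
#' draws, per bin, as many pool exons as circRNA genes occupy that bin.
#' Draws are without replacement within a bin when the pool suffices, with
#' replacement (flagged) otherwise; a bin with no pool exons at all falls
#' back to the nearest populated bin (flagged). The empirical p-value uses
#' the add-one estimator ([empirical_p()]), so 100 iterations floor it at
#' 1/101.
#'
#' @param observed_mean Observed mean coverage of the circularizing exons.
#' @param circ_gene_bins Integer vector: the expression bin of each
#'   circRNA-producing gene (a multiset; repeated bins draw repeatedly).
#' @param pool_bins,pool_values Parallel vectors giving each pool exon's
#'   gene expression bin and its coverage percentage.
#' @param iterations Number of resampling repetitions (default 100).
#' @return List with `observed_mean`, `resampled_means`, `empirical_p`,
#'   `replacement_used`, `bin_fallback_used`.
#' @export
matched_resample <- function(observed_mean, circ_gene_bins,
                             pool_bins, pool_values, iterations = 100L) {
  stopifnot(length(pool_bins) == length(pool_values),
            length(pool_bins) > 0L, length(circ_gene_bins) > 0L)
  pool_by_bin <- split(pool_values, pool_bins)
  avail_bins <- as.integer(names(pool_by_bin))
  need <- table(circ_gene_bins)
  need_bins <- as.integer(names(need))
  need_n <- as.integer(need)
  src_bin <- vapply(need_bins, function(b) {
    avail_bins[which.min(abs(avail_bins - b))]
  }, integer(1))
  fallback <- any(src_bin != need_bins)
  replacement <- any(need_n > vapply(
    as.character(src_bin), function(b) length(pool_by_bin[[b]]), integer(1)))
  means <- vapply(seq_len(iterations), function(i) {
    draw <- unlist(lapply(seq_along(need_bins), function(j) {
      vals <- pool_by_bin[[as.character(src_bin[j])]]
      k <- need_n[j]
      if (k <= length(vals)) {
        vals[sample.int(length(vals), k)]
      } else {
        vals[sample.int(length(vals), k, replace = TRUE)]
      }
    }), use.names = FALSE)
    mean(draw)
  }, numeric(1))
  list(
    observed_mean = observed_mean,
    resampled_means = means,
    empirical_p = empirical_p(observed_mean, means),
    replacement_used = replacement,
    bin_fallback_used = fallback
  )
}

#' Per-RBP differential binding between exon categories
#'
#' For each RBP with at least `min_sites` distinct filtered binding sites,
#' compares per-exon coverage of BSJ circ-exons against internal
#' non-circ-exons of circRNA-producing genes with a two-sided Wilcoxon
#' rank-sum test, followed by Benjamini-Hochberg adjustment. RBPs whose
#' comparison has fewer than two exons in either category are skipped with
#' a warning.
#'
#' @param exon_table Exon category table from [categorize_exons()],
#'   restricted by the caller to the genes of interest. First and last
#'   exons are excluded here.
#' @param sites `GRanges` of filtered binding sites with an `rbp` column.
#' @param min_sites Minimum distinct binding sites per RBP (default 20).
#' @param fdr_threshold Significance threshold on the adjusted p (default
#'   0.1).
#' @return Data frame per tested RBP: `rbp`, `n_sites`, `n_bsj`,
#'   `n_noncirc`, `mean_cov_bsj`, `mean_cov_noncirc`, `p`, `fdr`,
#'   `significant`, ordered by `p`.
#' @export
per_rbp_differential_binding <- function(exon_table, sites, min_sites = 20L,
                                         fdr_threshold = 0.1) {
  circ_genes <- unique(exon_table$gene_id[exon_table$in_any_circ])
  keep <- exon_table$gene_id %in% circ_genes &
    !exon_table$is_first & !exon_table$is_last &
    exon_table$category %in% c("bsj_circ_exon", "non_circ_exon")
  et <- exon_table[keep, , drop = FALSE]
  exons_gr <- gintervals(et$chrom, et$start, et$end)
  site_counts <- table(sites$rbp)
  rbps <- sort(names(site_counts)[site_counts >= min_sites])
  res <- lapply(rbps, function(r) {
    cov <- exon_coverage(exons_gr, sites[sites$rbp == r])
    a <- cov[et$category == "bsj_circ_exon"]
    b <- cov[et$category == "non_circ_exon"]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("RBP %s skipped: fewer than 2 exons in a category", r))
      return(NULL)
    }
    data.frame(rbp = r, n_sites = as.integer(site_counts[[r]]),
               n_bsj = length(a), n_noncirc = length(b),
               mean_cov_bsj = mean(a), mean_cov_noncirc = mean(b),
               p = wilcoxon_rank_sum(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(rbp = character(), n_sites = integer(),
                      n_bsj = integer(), n_noncirc = integer(),
                      mean_cov_bsj = numeric(), mean_cov_noncirc = numeric(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  }
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p, out$rbp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
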