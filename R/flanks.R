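#' Intronic flanking regions of a feature
#'
#' Intersects fixed-width windows upstream and downstream of a feature with
#' purely intronic bases. Windows are clipped at position 1; they are not
#' truncated at neighbouring genes, only restricted to intronic bases.
#'
#' @param feature A length-1 `GRanges` (a circRNA span or an exon).
#' @param introns `GRanges` of purely intronic regions
#'   ([intronic_regions()]).
#' @param width Flank window width in bp (default 10000).
#' @return List with `upstream` and `downstream` `GRanges` (genomic left
#'   and right of the feature, irrespective of strand).
#' @export
flank_pair <- function(feature, introns, width = 10000L) {
  stopifnot(length(feature) == 1L)
  fp <- flank_pairs(feature, introns, width)
  flank_pair_at(fp, 1L)
}

#' Intronic flanking regions for many features at once
#'
#' Vectorized counterpart of [flank_pair()]: one overlap query computes the
#' intronic content of every upstream and downstream window.
#'
#' @param features `GRanges` of features.
#' @param introns `GRanges` of purely intronic regions.
#' @param width Flank window width in bp (default 10000).
#' @return An object of class `flank_pairs`: list with `upstream` and
#'   `downstream` `GRanges` (each carrying a `feature` index column) and
#'   `n`, the number of features. Extract one feature's pair with
#'   [flank_pair_at()].
#' @export
flank_pairs <- function(features, introns, width = 10000L) {
  n <- length(features)
  chrom <- as.character(GenomicRanges::seqnames(features))
  s <- GenomicRanges::start(features)
  e <- GenomicRanges::end(features)
  clip <- function(lo, hi) {
    lo <- pmax(1L, lo)
    keep <- which(hi >= lo)
    if (!length(keep)) {
      gr <- GenomicRanges::GRanges()
      gr$feature <- integer()
      return(gr)
    }
    win <- gintervals(chrom[keep], lo[keep], hi[keep])
    hits <- GenomicRanges::findOverlaps(win, introns, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    pieces <- GenomicRanges::pintersect(
      GenomicRanges::granges(win)[qi],
      GenomicRanges::granges(introns)[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE)
    pieces$hit <- NULL
    pieces$feature <- keep[qi]
    pieces
  }
  structure(list(upstream = clip(s - width, s - 1L),
                 downstream = clip(e + 1L, e + width),
                 n = n),
            class = "flank_pairs")
}

#' Extract one feature's flank pair
#'
#' @param pairs A `flank_pairs` object.
#' @param i Feature index.
#' @return List with `upstream` and `downstream` `GRanges`.
#' @export
flank_pair_at <- function(pairs, i) {
  pick <- function(gr) {
    out <- gr[gr$feature == i]
    out$feature <- NULL
    merge_intervals(out)
  }
  list(upstream = pick(pairs$upstream), downstream = pick(pairs$downstream))
}

#' Binding-site presence in both flanking introns
#'
#' `TRUE` iff at least one site overlaps the intronic upstream flank and at
#' least one site overlaps the intronic downstream flank (any overlap of
#' >= 1 bp counts, so a site straddling the feature boundary into a flank
#' counts for that flank).
#'
#' @param pair Flank pair from [flank_pair()].
#' @param sites `GRanges` of one RBP's filtered binding sites.
#' @return Logical flag.
#' @export
both_flank_presence <- function(pair, sites) {
  if (length(sites) == 0L) return(FALSE)
  has <- function(flank) {
    length(flank) > 0L &&
      length(GenomicRanges::findOverlaps(flank, sites,
                                         ignore.strand = TRUE)) > 0L
  }
  has(pair$upstream) && has(pair$downstream)
}

#' Inverted Alu pair across the two flanking introns
#'
#' `TRUE` iff some Alu element overlaps the upstream flank and some Alu
#' overlaps the downstream flank on the opposite strand (the inverted
#' orientation that allows the two repeats to base-pair across the feature
#' and promote circularization).
#'
#' @param pair Flank pair from [flank_pair()].
#' @param alus Stranded `GRanges` of Alu repeat positions.
#' @return Logical flag.
#' @export
iralu_both_flanks <- function(pair, alus) {
  if (length(alus) == 0L) return(FALSE)
  strands_in <- function(flank) {
    if (length(flank) == 0L) return(character())
    hits <- GenomicRanges::findOverlaps(flank, alus, ignore.strand = TRUE)
    unique(as.character(
      GenomicRanges::strand(alus)[S4Vectors::subjectHits(hits)]))
  }
  up <- strands_in(pair$upstream)
  dn <- strands_in(pair$downstream)
  ("+" %in% up && "-" %in% dn) || ("-" %in% up && "+" %in% dn)
}

#' Vectorized both-flank binding-site presence
#'
#' @param pairs A `flank_pairs` object.
#' @param sites `GRanges` of one RBP's binding sites.
#' @return Logical vector, one flag per feature.
#' @export
both_flank_presence_all <- function(pairs, sites) {
  hit_features <- function(flank) {
    if (length(flank) == 0L || length(sites) == 0L) return(integer())
    hits <- GenomicRanges::findOverlaps(flank, sites, ignore.strand = TRUE)
    unique(flank$feature[S4Vectors::queryHits(hits)])
  }
  out <- logical(pairs$n)
  both <- intersect(hit_features(pairs$upstream),
                    hit_features(pairs$downstream))
  out[both] <- TRUE
  out
}

#' Vectorized inverted-Alu detection across flank pairs
#'
#' @param pairs A `flank_pairs` object.
#' @param alus Stranded `GRanges` of Alu repeats.
#' @return Logical vector, one flag per feature.
#' @export
iralu_both_flanks_all <- function(pairs, alus) {
  strand_hits <- function(flank, st) {
    sel <- alus[as.character(GenomicRanges::strand(alus)) == st]
    if (length(flank) == 0L || length(sel) == 0L) return(integer())
    hits <- GenomicRanges::findOverlaps(flank, sel, ignore.strand = TRUE)
    unique(flank$feature[S4Vectors::queryHits(hits)])
  }
  up_p <- strand_hits(pairs$upstream, "+")
  up_m <- strand_hits(pairs$upstream, "-")
  dn_p <- strand_hits(pairs$downstream, "+")
  dn_m <- strand_hits(pairs$downstream, "-")
  out <- logical(pairs$n)
  out[union(intersect(up_p, dn_m), intersect(up_m, dn_p))] <- TRUE
  out
}

#' Chi-square enrichment of a flag between two feature groups
#'
#' Compares the fraction of flagged features (e.g. both-flank binding-site
#' presence) between circRNAs and internal non-circularizing exons with a
#' Yates-corrected 2x2 chi-square test, and reports the fold change of
#' proportions.
#'
#' @param group_a_flags,group_b_flags Logical vectors (group A is typically
#'   circRNAs, group B non-circ-exons).
#' @return List with `fold` (`prop_a / prop_b`), `prop_a`, `prop_b`,
#'   `statistic`, `p` (`NA` when a table margin is zero).
#' @export
flank_enrichment_test <- function(group_a_flags, group_b_flags) {
  a <- sum(group_a_flags); na <- length(group_a_flags)
  b <- sum(group_b_flags); nb <- length(group_b_flags)
  stopifnot(na > 0L, nb > 0L)
  tbl <- matrix(c(a, na - a, b, nb - b), nrow = 2, byrow = TRUE)
  ht <- chi_square_2x2(tbl, yates = TRUE)
  prop_a <- a / na
  prop_b <- b / nb
  list(fold = if (prop_b > 0) prop_a / prop_b else NA_real_,
       prop_a = prop_a, prop_b = prop_b,
       statistic = ht$statistic, p = ht$p)
}

#' Reads-per-million normalization of a count matrix
#'
#' @param counts Numeric matrix (features x samples) of non-negative read
#'   counts.
#' @param library_sizes Numeric vector of total mapped reads per sample
#'   (all > 0), parallel to the columns of `counts`.
#' @return Matrix of the same shape in reads per million.
#' @export
rpm_normalize <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  stopifnot(length(library_sizes) == ncol(counts))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  sweep(counts, 2, library_sizes, function(x, l) x * 1e6 / l)
}

#' Knockdown versus control comparison of circRNA expression
#'
#' Sums RPM over a subset of circRNAs per sample (total subset expression,
#' the per-sample statistic compared between conditions) and tests
#' knockdown against control samples with a Welch t-test or Wilcoxon
#' rank-sum test. The per-circRNA mean RPM per condition is also returned.
#'
#' @param rpm Matrix of RPM values (circRNAs x samples) with rownames.
#' @param condition Character vector per sample, `"KD"` or `"control"`.
#' @param subset_ids CircRNA rownames to aggregate (non-empty).
#' @param test `"t"` (Welch, default) or `"wilcoxon"`.
#' @return List with `mean_kd`, `mean_control` (means across samples of the
#'   per-sample subset totals), `relative_change`
#'   (`(mean_kd - mean_control) / mean_control`), `p`, `per_sample_totals`.
#' @export
kd_group_compare <- function(rpm, condition, subset_ids,
                             test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(length(condition) == ncol(rpm))
  if (length(subset_ids) == 0L) stop("subset is empty")
  missing_ids <- setdiff(subset_ids, rownames(rpm))
  if (length(missing_ids)) {
    stop("subset ids absent from matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  sub <- rpm[subset_ids, , drop = FALSE]
  totals <- colSums(sub)
  kd <- totals[condition == "KD"]
  ctrl <- totals[condition == "control"]
  p <- if (test == "t") {
    if (length(kd) < 2L || length(ctrl) < 2L) {
      stop("t-test requires >= 2 samples per condition")
    }
    welch_t_test(kd, ctrl)$p
  } else {
    wilcoxon_rank_sum(kd, ctrl)
  }
  mean_kd <- mean(kd)
  mean_ctrl <- mean(ctrl)
  list(
    mean_kd = mean_kd,
    mean_control = mean_ctrl,
    relative_change = (mean_kd - mean_ctrl) / mean_ctrl,
    p = p,
    per_sample_totals = totals
  )
}
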