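#' Read an eCLIP peak table
#'
#' Reads a BED6+ style tab-delimited peak table with columns `chrom`,
#' `start`, `end`, `rbp`, `score`, `strand` and any of `ip_reads`,
#' `input_reads`, `log2fc`. On-disk coordinates are BED-style 0-based
#' half-open and are converted to 1-based closed.
#'
#' @param path Path to the TSV file (header required).
#' @return Data frame of peaks with 1-based closed coordinates and a
#'   `width` column.
#' @export
read_binding_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "rbp", "strand")
  if (!all(req %in% names(df))) {
    stop("peak table must have columns: ", paste(req, collapse = ", "))
  }
  df$start <- df$start + 1L
  df$width <- df$end - df$start + 1L
  df
}

#' log2 fold change of IP over size-matched input
#'
#' `log2((ip + pseudocount) / (input + pseudocount))`. When library sizes
#' are supplied, counts are first scaled to reads per million; otherwise raw
#' counts are compared directly.
#'
#' @param ip_reads,input_reads Non-negative count vectors.
#' @param pseudocount Added to both counts before the ratio (default 1), so
#'   the fold change is defined when the input count is zero.
#' @param ip_library,input_library Optional library sizes (total mapped
#'   reads) used to scale counts to reads per million before the ratio.
#' @return Numeric vector of log2 fold changes.
#' @export
compute_log2fc <- function(ip_reads, input_reads, pseudocount = 1,
                           ip_library = NULL, input_library = NULL) {
  if (any(ip_reads < 0, na.rm = TRUE) || any(input_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  if (!is.null(ip_library) && !is.null(input_library)) {
    ip_reads <- ip_reads * 1e6 / ip_library
    input_reads <- input_reads * 1e6 / input_library
  }
  log2((ip_reads + pseudocount) / (input_reads + pseudocount))
}

#' Filter eCLIP peaks into high-confidence binding sites
#'
#' Applies the three independent binding-site filters: minimum IP read
#' support, minimum log2 fold change over the size-matched input, and
#' minimum site width. A precomputed `log2fc` column is trusted when
#' present; otherwise the fold change is computed from `ip_reads` /
#' `input_reads` with pseudocount 1. The default `min_log2fc = 3`
#' corresponds to an 8-fold linear IP enrichment.
#'
#' @param peaks Peak data frame from [read_binding_sites()].
#' @param min_ip Minimum IP reads (default 10).
#' @param min_log2fc Minimum log2 fold change (default 3).
#' @param min_width Minimum site width in bp (default 4).
#' @return The retained peaks, with a `log2fc` column filled in.
#' @export
filter_sites <- function(peaks, min_ip = 10, min_log2fc = 3, min_width = 4) {
  has_fc <- !is.null(peaks$log2fc)
  has_counts <- !is.null(peaks$ip_reads) && !is.null(peaks$input_reads)
  if (!has_fc && !has_counts) {
    stop("peaks must carry either log2fc or ip_reads/input_reads")
  }
  if (!has_fc) {
    peaks$log2fc <- compute_log2fc(peaks$ip_reads, peaks$input_reads)
  }
  if (is.null(peaks$width)) peaks$width <- peaks$end - peaks$start + 1L
  keep <- peaks$width >= min_width & peaks$log2fc >= min_log2fc
  if (!is.null(peaks$ip_reads)) keep <- keep & peaks$ip_reads >= min_ip
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GRanges view of a peak table
#'
#' @param peaks Peak data frame (1-based closed coordinates).
#' @return `GRanges` with `rbp` (and `log2fc` when present) metadata.
#' @export
sites_granges <- function(peaks) {
  gr <- gintervals(peaks$chrom, peaks$start, peaks$end,
                   strand = ifelse(peaks$strand %in% c("+", "-"),
                                   peaks$strand, "*"))
  gr$rbp <- peaks$rbp
  if (!is.null(peaks$log2fc)) gr$log2fc <- peaks$log2fc
  gr
}

#' Overlaps between binding sites and features above a minimum length
#'
#' One row per (site, feature) pair whose base-level overlap is at least
#' `min_overlap` bp; shorter chance overlaps are disregarded.
#'
#' @param sites `GRanges` of filtered binding sites.
#' @param features `GRanges` of target features.
#' @param min_overlap Minimum overlap in bp (default 4).
#' @return Data frame with `site_idx`, `feature_idx`, `overlap_bp`.
#' @export
site_feature_overlaps <- function(sites, features, min_overlap = 4) {
  hits <- GenomicRanges::findOverlaps(sites, features, ignore.strand = TRUE,
                                      minoverlap = as.integer(min_overlap))
  data.frame(
    site_idx = S4Vectors::queryHits(hits),
    feature_idx = S4Vectors::subjectHits(hits),
    overlap_bp = IRanges::width(IRanges::pintersect(
      IRanges::ranges(sites)[S4Vectors::queryHits(hits)],
      IRanges::ranges(features)[S4Vectors::subjectHits(hits)]))
  )
}

#' Classify binding-site locations relative to gene structure
#'
#' A site is `exonic` when it overlaps merged exons but no purely intronic
#' bases, `intronic` when the reverse holds, `exon_intron_boundary` when it
#' overlaps both base classes, and `other` when it lies entirely outside
#' annotated genes.
#'
#' @param sites `GRanges` of binding sites.
#' @param exons `GRanges` of merged exons (e.g. [gene_merged_exons()]).
#' @param introns `GRanges` of purely intronic regions
#'   (e.g. [intronic_regions()]).
#' @return Character vector (one class per site).
#' @export
classify_site_location <- function(sites, exons, introns) {
  n <- length(sites)
  count_bp <- function(target) {
    out <- integer(n)
    if (length(target) == 0L) return(out)
    red <- merge_intervals(target)
    hits <- GenomicRanges::findOverlaps(sites, red, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(sites)[S4Vectors::queryHits(hits)],
      IRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
    out
  }
  ex_bp <- count_bp(exons)
  int_bp <- count_bp(introns)
  ifelse(ex_bp > 0L & int_bp > 0L, "exon_intron_boundary",
         ifelse(ex_bp > 0L, "exonic",
                ifelse(int_bp > 0L, "intronic", "other")))
}
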