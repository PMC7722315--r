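#' Read a circRNA caller output table
#'
#' Reads a tab-delimited backsplice-junction (BSJ) call table with columns
#' `chrom`, `start`, `end`, `strand`, `bsj_reads`, `linear_reads` and an
#' optional `gene_id`. Caller dialects differ in coordinate convention; the
#' `coords` flag declares the on-disk convention and the table is normalized
#' to 1-based closed coordinates in memory.
#'
#' @param path Path to the TSV file (header line required).
#' @param coords `"one_based_closed"` (CIRI2-style, default) or
#'   `"zero_based_half_open"` (BED-style).
#' @return A data frame of calls with a `circ_id` column (`chrom:start-end`
#'   after normalization) and a `coords` attribute recording the
#'   normalization.
#' @export
read_circ_calls <- function(path, coords = c("one_based_closed",
                                             "zero_based_half_open")) {
  coords <- match.arg(coords)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "strand", "bsj_reads", "linear_reads")
  if (!all(req %in% names(df))) {
    stop("circRNA call table must have columns: ", paste(req, collapse = ", "))
  }
  if (coords == "zero_based_half_open") {
    df$start <- df$start + 1L
  }
  circ_calls(df)
}

#' Construct a normalized circRNA call table
#'
#' @param df Data frame with 1-based closed `start`/`end` and the columns
#'   listed in [read_circ_calls()].
#' @return The validated data frame with `circ_id` added and
#'   `attr(, "coords") == "one_based_closed"`.
#' @export
circ_calls <- function(df) {
  stopifnot(is.data.frame(df))
  if (any(df$start > df$end)) stop("invalid circRNA span: start > end")
  if (any(df$bsj_reads < 0) || any(df$linear_reads < 0)) {
    stop("read counts must be non-negative")
  }
  df$circ_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  attr(df, "coords") <- "one_based_closed"
  df
}

#' Consensus circRNA catalog from two callers
#'
#' Retains backsplice junctions called with at least `min_reads` junction
#' reads by both callers. Junctions are matched on exact
#' (chrom, start, end) coordinates; expression fields (`bsj_reads`,
#' `linear_reads`, `strand`, `gene_id` if present) are taken from caller A,
#' whose counts drive all downstream expression ranking. Caller B
#' contributes only its read count (kept as `bsj_reads_b`).
#'
#' @param calls_a,calls_b Call tables from [read_circ_calls()] /
#'   [circ_calls()]. Both must carry the same coordinate normalization;
#'   a mismatch is an error.
#' @param min_reads Minimum BSJ reads required in each caller (default 2).
#' @return Data frame of consensus calls ordered by `circ_id`, with
#'   `bsj_reads` (caller A) and `bsj_reads_b` (caller B).
#' @export
consensus_catalog <- function(calls_a, calls_b, min_reads = 2L) {
  ca <- attr(calls_a, "coords")
  cb <- attr(calls_b, "coords")
  if (is.null(ca) || is.null(cb) || !identical(ca, cb)) {
    stop("caller tables disagree on coordinate convention; ",
         "normalize both with read_circ_calls()/circ_calls()")
  }
  key_a <- calls_a$circ_id
  key_b <- calls_b$circ_id
  idx <- match(key_a, key_b)
  keep <- !is.na(idx) &
    calls_a$bsj_reads >= min_reads &
    calls_b$bsj_reads[idx] >= min_reads
  out <- calls_a[keep, , drop = FALSE]
  out$bsj_reads_b <- calls_b$bsj_reads[idx[keep]]
  out <- out[order(out$circ_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coords") <- "one_based_closed"
  out
}

#' Select the top expression percentile of a circRNA catalog
#'
#' Picks the `ceiling(fraction * N)` circRNAs with the highest caller-A BSJ
#' read counts. Ties at the boundary are broken deterministically by
#' lexicographic `circ_id` order.
#'
#' @param catalog Consensus catalog data frame.
#' @param fraction Proportion in (0, 1] to select (default 0.01).
#' @return The selected rows, ordered by decreasing `bsj_reads` then
#'   `circ_id`.
#' @export
top_percentile <- function(catalog, fraction = 0.01) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("'fraction' must be a single proportion in (0, 1]")
  }
  n <- nrow(catalog)
  if (n == 0L) stop("catalog is empty")
  k <- as.integer(ceiling(fraction * n))
  ord <- order(-catalog$bsj_reads, catalog$circ_id)
  out <- catalog[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative circular-to-linear expression ratio
#'
#' Computes `(2 * circ) / (2 * circ + linear)`: a BSJ read is generated from
#' the two ends of a circular junction but counted once, while linear reads
#' across the same positions come from one end, so circular reads are
#' doubled before forming the proportion.
#'
#' @param bsj_reads,linear_reads Non-negative count vectors (recycled).
#' @return Numeric vector in \[0, 1\]; `NA` where both counts are zero.
#' @export
relative_ratio <- function(bsj_reads, linear_reads) {
  if (any(bsj_reads < 0, na.rm = TRUE) || any(linear_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  denom <- 2 * bsj_reads + linear_reads
  ifelse(denom == 0, NA_real_, 2 * bsj_reads / denom)
}

#' GRanges view of a circRNA call table
#'
#' @param catalog Call table with 1-based closed coordinates.
#' @return `GRanges` with `circ_id`, `bsj_reads`, and `host_gene` (if
#'   assigned) metadata columns.
#' @export
catalog_granges <- function(catalog) {
  gr <- gintervals(catalog$chrom, catalog$start, catalog$end,
                   strand = ifelse(catalog$strand %in% c("+", "-"),
                                   catalog$strand, "*"))
  gr$circ_id <- catalog$circ_id
  gr$bsj_reads <- catalog$bsj_reads
  if (!is.null(catalog$host_gene)) gr$host_gene <- catalog$host_gene
  gr
}

#' Assign host genes to circRNAs
#'
#' The host gene is the gene whose merged exons overlap the circRNA span by
#' the most bases, considering only genes on the circRNA's strand when that
#' strand is known (`+`/`-`); ties break by lexicographic `gene_id`.
#' CircRNAs overlapping no exon of any (strand-compatible) gene get
#' `host_gene = NA`.
#'
#' @param catalog Call table (1-based closed coordinates).
#' @param merged_exons Merged exons from [gene_merged_exons()].
#' @return `catalog` with a `host_gene` column.
#' @export
assign_host_gene <- function(catalog, merged_exons) {
  gr <- catalog_granges(catalog)
  hits <- GenomicRanges::findOverlaps(gr, merged_exons, ignore.strand = TRUE)
  host <- rep(NA_character_, nrow(catalog))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    circ_strand <- as.character(GenomicRanges::strand(gr))[qi]
    exon_strand <- as.character(GenomicRanges::strand(merged_exons))[si]
    ok <- circ_strand == "*" | circ_strand == exon_strand
    qi <- qi[ok]; si <- si[ok]
    if (length(qi)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gr)[qi], IRanges::ranges(merged_exons)[si]))
      key <- paste(qi, merged_exons$gene_id[si], sep = "\r")
      bases <- tapply(ov, key, sum)
      parts <- strsplit(names(bases), "\r", fixed = TRUE)
      q <- as.integer(vapply(parts, `[`, "", 1L))
      g <- vapply(parts, `[`, "", 2L)
      ord <- order(q, -as.numeric(bases), g)
      first <- !duplicated(q[ord])
      host[q[ord][first]] <- g[ord][first]
    }
  }
  catalog$host_gene <- host
  catalog
}

#' Exonic parts of each circRNA
#'
#' Intersects each circRNA span with the merged exons of its host gene.
#' CircRNAs without an assigned host gene or whose span overlaps no
#' annotated exon are flagged (`has_exons = FALSE`) and carry
#' `exonic_length = 0`; such circRNAs are excluded from coverage analyses.
#'
#' @param catalog Call table with a `host_gene` column
#'   (see [assign_host_gene()]).
#' @param merged_exons Merged exons from [gene_merged_exons()].
#' @return A list with
#'   \describe{
#'     \item{parts}{`GRangesList`, one element per catalog row, of exonic
#'       sub-intervals.}
#'     \item{summary}{data frame `circ_id`, `exonic_length`, `n_exons`,
#'       `has_exons`.}
#'   }
#' @export
circ_exonic_parts <- function(catalog, merged_exons) {
  if (is.null(catalog$host_gene)) {
    stop("catalog lacks host_gene; run assign_host_gene() first")
  }
  gr <- catalog_granges(catalog)
  hits <- GenomicRanges::findOverlaps(gr, merged_exons, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same_gene <- !is.na(catalog$host_gene[qi]) &
    merged_exons$gene_id[si] == catalog$host_gene[qi]
  qi <- qi[same_gene]; si <- si[same_gene]
  pieces <- GenomicRanges::pintersect(
    GenomicRanges::granges(gr)[qi], GenomicRanges::granges(merged_exons)[si],
    ignore.strand = TRUE)
  pieces$hit <- NULL
  fac <- factor(qi, levels = seq_len(nrow(catalog)))
  parts <- GenomicRanges::split(pieces, fac)
  names(parts) <- catalog$circ_id
  # pieces of one circRNA are disjoint (merged exons are), so widths sum
  lens <- integer(nrow(catalog))
  agg <- tapply(IRanges::width(pieces), qi, sum)
  lens[as.integer(names(agg))] <- as.integer(agg)
  nex <- S4Vectors::elementNROWS(parts)
  summary <- data.frame(
    circ_id = catalog$circ_id,
    exonic_length = lens,
    n_exons = as.integer(nex),
    has_exons = lens > 0L,
    stringsAsFactors = FALSE
  )
  list(parts = parts, summary = summary)
}

#' Categorize merged exons relative to a circRNA catalog
#'
#' Each merged exon of a gene producing circRNAs is classified as
#' `bsj_circ_exon` when either of its boundaries coincides exactly with a
#' backsplice coordinate of any same-gene catalog circRNA (an exon that is
#' internal in one circle but a boundary exon of another is a BSJ
#' circ-exon: boundary matching takes precedence), `circ_exon` when it lies
#' fully inside some same-gene circRNA span without a boundary match, and
#' `non_circ_exon` otherwise.
#'
#' @param merged_exons Merged exons from [gene_merged_exons()].
#' @param catalog Call table with `host_gene` assigned.
#' @return Data frame with one row per merged exon: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `exon_rank`, `is_first`, `is_last`,
#'   `category`, `in_any_circ`.
#' @export
categorize_exons <- function(merged_exons, catalog) {
  if (is.null(catalog$host_gene)) {
    stop("catalog lacks host_gene; run assign_host_gene() first")
  }
  ex <- data.frame(
    gene_id = merged_exons$gene_id,
    chrom = as.character(GenomicRanges::seqnames(merged_exons)),
    start = GenomicRanges::start(merged_exons),
    end = GenomicRanges::end(merged_exons),
    strand = as.character(GenomicRanges::strand(merged_exons)),
    exon_rank = merged_exons$exon_rank,
    is_first = merged_exons$is_first,
    is_last = merged_exons$is_last,
    stringsAsFactors = FALSE
  )
  ex$category <- "non_circ_exon"
  calls <- catalog[!is.na(catalog$host_gene), , drop = FALSE]
  by_gene <- split(calls, calls$host_gene)
  for (g in names(by_gene)) {
    rows <- which(ex$gene_id == g)
    if (!length(rows)) next
    cc <- by_gene[[g]]
    for (i in rows) {
      bsj <- any(ex$start[i] == cc$start | ex$end[i] == cc$end)
      inside <- any(ex$start[i] >= cc$start & ex$end[i] <= cc$end)
      if (bsj) {
        ex$category[i] <- "bsj_circ_exon"
      } else if (inside) {
        ex$category[i] <- "circ_exon"
      }
    }
  }
  ex$in_any_circ <- ex$category %in% c("bsj_circ_exon", "circ_exon")
  ex
}
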