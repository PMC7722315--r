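#' Construct a validated set of genomic intervals
#'
#' Builds a [GenomicRanges::GRanges] from parallel coordinate vectors, using
#' the 1-based closed convention of GRanges. All interval algebra in the
#' package goes through GRanges; on-disk BED (0-based half-open) is converted
#' at the I/O boundary by [read_bed()] / [write_bed()].
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based closed; `start <= end` and
#'   `start >= 1` are enforced.
#' @param strand Strand characters among `"+"`, `"-"`, `"*"` (default `"*"`).
#' @param ... Further metadata columns, recycled as in `data.frame()`.
#' @return A `GRanges` object.
#' @examples
#' gintervals("chr1", c(11, 31), c(40, 60))
#' @export
gintervals <- function(chrom, start, end, strand = "*", ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be non-missing integers")
  }
  if (any(start < 1L)) stop("interval start must be >= 1 (1-based closed)")
  if (any(start > end)) stop("invalid interval: start > end")
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    ...
  )
}

.assert_gr <- function(x, arg = deparse(substitute(x))) {
  if (!methods::is(x, "GRanges")) {
    stop(sprintf("'%s' must be a GRanges object", arg))
  }
  if (any(IRanges::width(x) < 1L)) {
    stop(sprintf("'%s' contains zero- or negative-width intervals", arg))
  }
  invisible(x)
}

#' Merge overlapping and bookended intervals
#'
#' Collapses a set of intervals into disjoint, sorted intervals covering the
#' same bases. Touching (bookended) intervals merge at distance 0, and strand
#' is ignored, matching `bedtools merge` defaults.
#'
#' @param x A `GRanges`.
#' @return A `GRanges` of disjoint, sorted, strand-`*` intervals whose union
#'   of bases equals that of `x`.
#' @examples
#' merge_intervals(gintervals("chr1", c(11, 31), c(40, 60)))
#' @export
merge_intervals <- function(x) {
  .assert_gr(x)
  GenomicRanges::reduce(x, ignore.strand = TRUE, min.gapwidth = 1L)
}

#' Base-level intersection of two interval sets
#'
#' @param a,b `GRanges` objects; strand is ignored.
#' @return Merged `GRanges` covering exactly the bases present in both sets.
#' @export
interval_intersect <- function(a, b) {
  .assert_gr(a)
  .assert_gr(b)
  GenomicRanges::intersect(merge_intervals(a), merge_intervals(b),
                           ignore.strand = TRUE)
}

#' Base-level subtraction of two interval sets
#'
#' @param a,b `GRanges` objects; strand is ignored.
#' @return Merged `GRanges` covering the bases of `a` not present in `b`.
#' @export
interval_subtract <- function(a, b) {
  .assert_gr(a)
  if (length(b) == 0L) return(merge_intervals(a))
  .assert_gr(b)
  GenomicRanges::setdiff(merge_intervals(a), merge_intervals(b),
                         ignore.strand = TRUE)
}

#' Total number of bases in an interval set
#'
#' @param x A `GRanges`; overlapping intervals are merged first so each base
#'   counts once.
#' @return Integer base count.
#' @export
interval_bases <- function(x) {
  if (length(x) == 0L) return(0L)
  sum(IRanges::width(merge_intervals(x)))
}

#' Read / write BED6 interval files
#'
#' Thin wrappers over [rtracklayer::import.bed()] / `export.bed()`, which
#' perform the 0-based half-open (on disk) to 1-based closed (in memory)
#' conversion. `name` and `score` columns are preserved when present.
#'
#' @param path File path.
#' @param x A `GRanges` to write.
#' @return `read_bed()` returns a `GRanges`; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  .assert_gr(x)
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
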