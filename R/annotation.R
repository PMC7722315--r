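#' Read gene models from a GTF annotation
#'
#' Imports exon features from a GTF file (1-based closed on disk, converted
#' by rtracklayer) and assembles per-gene transcript models. Genes whose
#' exons span several chromosomes or strands are rejected: downstream region
#' algebra is per-gene and assumes a single chromosome and strand.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on `exon` features.
#' @param expression Optional data frame with columns `gene_id` and `fpkm`;
#'   genes absent from the table get `fpkm = NA`.
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{exons}{`GRanges` of exons with `gene_id`, `transcript_id`.}
#'     \item{genes}{data frame with `gene_id`, `chrom`, `strand`, `fpkm`.}
#'   }
#' @export
read_gene_models <- function(path, expression = NULL) {
  gtf <- rtracklayer::import(path, format = "GTF")
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in GTF: ", path)
  if (is.null(ex$gene_id) || is.null(ex$transcript_id) ||
      anyNA(ex$gene_id) || anyNA(ex$transcript_id)) {
    stop("GTF exon features must carry gene_id and transcript_id attributes")
  }
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id)
  )
  gene_models(ex, expression = expression)
}

#' Assemble gene models from an exon GRanges
#'
#' @param exons `GRanges` with metadata columns `gene_id` and
#'   `transcript_id`.
#' @param expression Optional data frame with `gene_id` and `fpkm` columns.
#' @return A `gene_models` object (see [read_gene_models()]).
#' @export
gene_models <- function(exons, expression = NULL) {
  .assert_gr(exons)
  if (is.null(exons$gene_id) || is.null(exons$transcript_id)) {
    stop("exons must carry gene_id and transcript_id metadata columns")
  }
  chrom <- as.character(GenomicRanges::seqnames(exons))
  strand <- as.character(GenomicRanges::strand(exons))
  per_gene_chrom <- tapply(chrom, exons$gene_id, function(v) length(unique(v)))
  per_gene_strand <- tapply(strand, exons$gene_id, function(v) length(unique(v)))
  bad <- names(per_gene_chrom)[per_gene_chrom > 1L | per_gene_strand > 1L]
  if (length(bad)) {
    stop("gene(s) on multiple chromosomes or strands: ",
         paste(bad, collapse = ", "))
  }
  first <- !duplicated(exons$gene_id)
  genes <- data.frame(
    gene_id = exons$gene_id[first],
    chrom = chrom[first],
    strand = strand[first],
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes$fpkm <- NA_real_
  if (!is.null(expression)) {
    stopifnot(all(c("gene_id", "fpkm") %in% names(expression)))
    idx <- match(genes$gene_id, expression$gene_id)
    genes$fpkm <- as.numeric(expression$fpkm[idx])
  }
  structure(list(exons = exons, genes = genes), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d exon records\n",
              nrow(x$genes), length(unique(x$exons$transcript_id)),
              length(x$exons)))
  invisible(x)
}

#' Merged exons per gene with first/last flags
#'
#' Merges exons across all transcript isoforms of each gene into one genomic
#' interval per exon per gene, then flags the 5'-most merged exon of each
#' gene `is_first` and the 3'-most `is_last` (orientation follows the gene
#' strand, so on the minus strand the genomically last merged exon is the
#' first exon). First/last status is decided on the merged list, after
#' isoform merging.
#'
#' @param models A `gene_models` object.
#' @return `GRanges` sorted by gene then start, with metadata columns
#'   `gene_id`, `exon_rank` (genomic order), `is_first`, `is_last`.
#' @export
gene_merged_exons <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  grl <- GenomicRanges::split(ex, ex$gene_id)
  merged <- GenomicRanges::reduce(grl)  # per-gene merge keeps gene strand
  n <- S4Vectors::elementNROWS(merged)
  out <- unlist(merged, use.names = FALSE)
  gene_id <- rep(names(merged), n)
  rank_genomic <- unlist(lapply(n, seq_len), use.names = FALSE)
  minus <- as.character(GenomicRanges::strand(out)) == "-"
  is_first <- ifelse(minus, rank_genomic == rep(n, n), rank_genomic == 1L)
  is_last <- ifelse(minus, rank_genomic == 1L, rank_genomic == rep(n, n))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gene_id, exon_rank = rank_genomic,
    is_first = is_first, is_last = is_last
  )
  out
}

#' Purely intronic regions per gene
#'
#' Returns, for each gene, the bases of the merged exon hull (the span from
#' the first to the last exonic base across all isoforms) that are not exonic
#' in any isoform. Bases that are intronic in one isoform but exonic in
#' another are therefore excluded.
#'
#' @param models A `gene_models` object.
#' @return `GRanges` with a `gene_id` metadata column; empty for
#'   single-exon genes.
#' @export
intronic_regions <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  grl <- GenomicRanges::split(ex, ex$gene_id)
  merged <- GenomicRanges::reduce(grl)
  hull <- unlist(range(merged), use.names = FALSE)
  introns <- GenomicRanges::psetdiff(hull, merged)
  n <- S4Vectors::elementNROWS(introns)
  out <- unlist(introns, use.names = FALSE)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = rep(names(merged), n)
  )
  out
}
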