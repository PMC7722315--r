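#' Build the exhaustive backsplice-junction reference set
#'
#' For every transcript and every exon pair (acceptor index i <= donor
#' index j in transcript order, including i = j, the single-exon circle),
#' constructs the putative backsplice sequence: the last `k` bases of the
#' donor exon j followed by the first `k` bases of the acceptor exon i, in
#' transcript orientation (minus-strand exons are reverse-complemented).
#' Exons shorter than `k` contribute their full length (no padding into
#' introns) and are flagged truncated. Junctions with identical sequences
#' are collapsed into one reference retaining all source junction ids.
#'
#' @param models A `gene_models` object.
#' @param genome Named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param k Bases taken from each side of the junction (default 30).
#' @return List with
#'   \describe{
#'     \item{junctions}{data frame `junction_id`
#'       (`transcript:donor_index:acceptor_index`), `transcript_id`,
#'       `donor_index`, `acceptor_index`, `donor_len`, `acceptor_len`,
#'       `truncated`, `sequence`, `ref_id`.}
#'     \item{references}{data frame `ref_id`, `sequence`,
#'       `junction_offset` (position where the donor side ends),
#'       `junction_ids` (comma-separated sources).}
#'   }
#' @export
build_bsj_reference <- function(models, genome, k = 30L) {
  stopifnot(inherits(models, "gene_models"),
            methods::is(genome, "DNAStringSet"))
  ex <- models$exons
  chrom <- as.character(GenomicRanges::seqnames(ex))
  if (!all(unique(chrom) %in% names(genome))) {
    stop("genome is missing chromosome(s): ",
         paste(setdiff(unique(chrom), names(genome)), collapse = ", "))
  }
  strand_chr <- as.character(GenomicRanges::strand(ex))
  exon_seq <- character(length(ex))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    exon_seq[i] <- as.character(Biostrings::Views(
      genome[[ch]], GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i]))
  }
  minus <- strand_chr == "-"
  if (any(minus)) {
    exon_seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(exon_seq[minus])))
  }
  tx_of <- ex$transcript_id
  parts <- lapply(split(seq_along(ex), tx_of), function(idx) {
    ord <- order(GenomicRanges::start(ex)[idx],
                 decreasing = strand_chr[idx[1]] == "-")
    idx <- idx[ord]  # transcript order 5' -> 3'
    n <- length(idx)
    j <- rep(seq_len(n), seq_len(n))
    i <- sequence(seq_len(n))
    seqs <- exon_seq[idx]
    lens <- nchar(seqs)
    dl <- pmin(k, lens[j])
    al <- pmin(k, lens[i])
    data.frame(
      junction_id = sprintf("%s:%d:%d", tx_of[idx[1]], j, i),
      transcript_id = tx_of[idx[1]], donor_index = j, acceptor_index = i,
      donor_len = dl, acceptor_len = al,
      truncated = dl < k | al < k,
      sequence = paste0(substr(seqs[j], lens[j] - dl + 1L, lens[j]),
                        substr(seqs[i], 1L, al)),
      stringsAsFactors = FALSE
    )
  })
  junctions <- do.call(rbind, parts)
  rownames(junctions) <- NULL
  uniq <- !duplicated(junctions$sequence)
  ref_seq <- junctions$sequence[uniq]
  ref_id <- sprintf("BSJREF%05d", seq_along(ref_seq))
  junctions$ref_id <- ref_id[match(junctions$sequence, ref_seq)]
  grouped <- split(junctions$junction_id,
                   factor(junctions$ref_id, levels = ref_id))
  references <- data.frame(
    ref_id = ref_id,
    sequence = ref_seq,
    junction_offset = junctions$donor_len[uniq],
    junction_ids = vapply(grouped, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(references) <- NULL
  list(junctions = junctions, references = references)
}

#' Write backsplice-junction references as FASTA
#'
#' @param refs Reference list from [build_bsj_reference()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_bsj_fasta <- function(refs, path) {
  s <- Biostrings::DNAStringSet(refs$references$sequence)
  names(s) <- refs$references$ref_id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Map short reads onto backsplice-junction references
#'
#' Ungapped alignment of each full read against every reference (both
#' orientations) with at most `max_mismatches` substitutions; a hit must
#' cover at least `min_span` bases on each side of the junction, so every
#' counted read genuinely crosses the backsplice. Reads shorter than
#' `2 * min_span` cannot qualify and are skipped with a warning. A read
#' matching a collapsed reference is reported once per distinct source
#' junction id.
#'
#' @param reads Data frame with columns `read_id`, `barcode`, `sequence`,
#'   and `sample` (e.g. `IP_rep1`, `IP_rep2`, `input`).
#' @param refs Reference list from [build_bsj_reference()].
#' @param max_mismatches Substitution budget (default 2); indels are not
#'   allowed.
#' @param min_span Minimum bases on each side of the junction (default 5).
#' @return Data frame of hits: `read_id`, `barcode`, `sample`,
#'   `junction_id`, `ref_id`, `offset` (1-based alignment start in the
#'   reference), `orientation` (`+`/`-`).
#' @export
map_reads <- function(reads, refs, max_mismatches = 2L, min_span = 5L) {
  offsets <- refs$references$junction_offset
  empty <- data.frame(read_id = character(), barcode = character(),
                      sample = character(), junction_id = character(),
                      ref_id = character(), offset = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  short <- nchar(reads$sequence) < 2L * min_span
  if (any(short)) {
    warning(sprintf("%d read(s) shorter than 2*min_span skipped", sum(short)))
    reads <- reads[!short, , drop = FALSE]
  }
  if (nrow(reads) == 0L) return(empty)
  # scan one concatenated subject (references separated by N runs longer
  # than any read, so cross-boundary windows are discarded by the bounds
  # check below); one C-level search per read and orientation
  ref_len <- nchar(refs$references$sequence)
  sep <- max(nchar(reads$sequence)) + 5L
  ref_start <- cumsum(c(1L, utils::head(ref_len + sep, -1L)))
  subject <- Biostrings::DNAString(
    paste(refs$references$sequence, collapse = strrep("N", sep)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$sequence)))
  out <- list()
  for (r in seq_len(nrow(reads))) {
    len <- nchar(reads$sequence[r])
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") reads$sequence[r] else rc[r]
      m <- Biostrings::matchPattern(pat, subject,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
      pos <- IRanges::start(m)
      if (!length(pos)) next
      hit_ref <- findInterval(pos, ref_start)
      st <- pos - ref_start[hit_ref] + 1L
      ok <- st >= 1L & st + len - 1L <= ref_len[hit_ref]
      st <- st[ok]; hit_ref <- hit_ref[ok]
      if (!length(hit_ref)) next
      left <- offsets[hit_ref] - st + 1L
      right <- (st + len - 1L) - offsets[hit_ref]
      ok <- left >= min_span & right >= min_span
      st <- st[ok]; hit_ref <- hit_ref[ok]
      if (!length(hit_ref)) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = reads$read_id[r], barcode = reads$barcode[r],
        sample = reads$sample[r],
        ref_id = refs$references$ref_id[hit_ref],
        offset = st, orientation = ori, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  jids <- strsplit(refs$references$junction_ids[
    match(hits$ref_id, refs$references$ref_id)], ",", fixed = TRUE)
  n_j <- lengths(jids)
  hits <- hits[rep(seq_len(nrow(hits)), n_j), , drop = FALSE]
  hits$junction_id <- unlist(jids, use.names = FALSE)
  hits <- unique(hits[, c("read_id", "barcode", "sample", "junction_id",
                          "ref_id", "offset", "orientation")])
  hits <- hits[order(hits$read_id, hits$junction_id, hits$offset), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Remove PCR duplicates among junction hits
#'
#' Among hits sharing the same sample, barcode, junction and alignment
#' offset, exactly one representative is retained (the first by read id
#' order). The operation is idempotent and its output size does not depend
#' on input order.
#'
#' @param hits Hit table from [map_reads()].
#' @return The deduplicated hit table.
#' @export
dedup_reads <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$sample, hits$barcode, hits$junction_id, hits$offset,
               hits$read_id)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$sample, hits$barcode, hits$junction_id, hits$offset,
               sep = "\r")
  out <- hits[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count deduplicated junction-spanning reads per sample
#'
#' @param hits Deduplicated hit table from [dedup_reads()]. Each read
#'   counts once per distinct junction it maps to, even when it aligns at
#'   several offsets.
#' @param samples Sample names to tabulate (columns of the result).
#' @return Data frame with `junction_id` and one count column per sample.
#' @export
count_junction_reads <- function(hits,
                                 samples = c("IP_rep1", "IP_rep2", "input")) {
  uniq <- unique(hits[, c("read_id", "sample", "junction_id"), drop = FALSE])
  jids <- sort(unique(uniq$junction_id))
  out <- data.frame(junction_id = jids, stringsAsFactors = FALSE)
  for (s in samples) {
    cnt <- table(uniq$junction_id[uniq$sample == s])
    out[[s]] <- as.integer(cnt[match(jids, names(cnt))])
    out[[s]][is.na(out[[s]])] <- 0L
  }
  out
}

#' Call RBP binding at backsplice junctions
#'
#' A junction is called when it is supported by at least `min_reads`
#' deduplicated reads in each IP replicate and the log2 fold change of each
#' IP replicate over the input, with a pseudocount of 1, is at least
#' `min_log2fc`.
#'
#' @param counts Data frame from [count_junction_reads()] with columns
#'   `junction_id`, `IP_rep1`, `IP_rep2`, `input`.
#' @param min_reads Per-replicate read floor (default 10).
#' @param min_log2fc Per-replicate log2 fold-change floor (default 3).
#' @param pseudocount Added to IP and input counts (default 1).
#' @return `counts` with `log2fc_rep1`, `log2fc_rep2`, and a logical
#'   `called` column.
#' @export
call_junction_sites <- function(counts, min_reads = 10L, min_log2fc = 3,
                                pseudocount = 1) {
  req <- c("junction_id", "IP_rep1", "IP_rep2", "input")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns: ", paste(req, collapse = ", "))
  }
  counts$log2fc_rep1 <- compute_log2fc(counts$IP_rep1, counts$input,
                                       pseudocount)
  counts$log2fc_rep2 <- compute_log2fc(counts$IP_rep2, counts$input,
                                       pseudocount)
  counts$called <- counts$IP_rep1 >= min_reads &
    counts$IP_rep2 >= min_reads &
    counts$log2fc_rep1 >= min_log2fc &
    counts$log2fc_rep2 >= min_log2fc
  counts
}

#' Read short eCLIP reads from FASTQ or TSV
#'
#' FASTQ read names carry the randomer barcode after the last `":"`. The
#' TSV dialect has columns `read_id`, `barcode`, `sequence` (and
#' optionally `sample`).
#'
#' @param path Input path; format inferred from the extension
#'   (`.fastq`/`.fq` vs anything else = TSV).
#' @param sample Sample label attached to all reads (ignored when the TSV
#'   already has a `sample` column).
#' @return Data frame `read_id`, `barcode`, `sequence`, `sample`.
#' @export
read_eclip_reads <- function(path, sample = NA_character_) {
  if (grepl("\\.(fastq|fq)$", path)) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq")
    ids <- names(s)
    df <- data.frame(
      read_id = ids,
      barcode = sub(".*:", "", ids),
      sequence = as.character(s),
      sample = sample,
      stringsAsFactors = FALSE
    )
    rownames(df) <- NULL
    df
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("read_id", "barcode", "sequence")
    if (!all(req %in% names(df))) {
      stop("read TSV must have columns: ", paste(req, collapse = ", "))
    }
    if (is.null(df$sample)) df$sample <- sample
    df
  }
}

#' Write eCLIP reads as FASTQ
#'
#' Read names are `read_id:barcode` so the barcode can be recovered by
#' [read_eclip_reads()]; constant dummy qualities are emitted.
#'
#' @param reads Data frame with `read_id`, `barcode`, `sequence`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_eclip_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- paste(reads$read_id, reads$barcode, sep = ":")
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = qual)
  invisible(path)
}
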