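#' Configuration for the synthetic screen generator
#'
#' Collects every parameter of the synthetic-data generator with defaults
#' chosen to emulate a desk-scale version of a circRNA-RBP screen: a few
#' hundred genes, tens of circRNA-producing genes, a dozen RBPs with a
#' planted subset whose binding-site density is multiplied on circularizing
#' exons, one RBP (KHSRP) with planted binding in both introns flanking a
#' target circRNA subset plus a matching 15% knockdown decrease, planted
#' inverted-Alu pairs, planted junction-spanning eCLIP reads, and one
#' planted enriched GO term.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_genes,n_chroms Number of genes and chromosomes.
#' @param exons_per_gene,exon_length,intron_length,intergenic_length
#'   Two-element ranges (uniform integer draws).
#' @param isoform2_prob Probability that a gene with >= 4 exons gets a
#'   second, exon-skipping isoform.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal expression parameters
#'   (the default sd spans > 4 orders of magnitude).
#' @param n_circ_genes Number of circRNA-producing genes (among genes with
#'   >= 4 exons, so circles avoid first/last exons).
#' @param circ_exon_weights Sampling weights for circRNAs spanning 1, 2, or
#'   3 exons.
#' @param bsj_mean,bsj_size Negative-binomial BSJ read counts (caller A).
#' @param top_multiplier Count multiplier for the planted top-percentile
#'   circRNAs.
#' @param consensus_fail_frac Fraction of true circRNAs failing the 2-read
#'   consensus in exactly one caller.
#' @param n_rbps Total RBPs including the flank RBP.
#' @param n_enriched_rbps RBPs with the planted circ-exon density
#'   multiplier.
#' @param flank_rbp Name of the flanking-intron RBP.
#' @param exonic_site_density,intronic_site_density Baseline binding sites
#'   per kb per RBP on exonic / intronic bases.
#' @param circ_multiplier Density multiplier on circularizing exons for
#'   enriched RBPs (default 3).
#' @param site_width Range of binding-site widths (bp).
#' @param peak_fail_frac Extra peaks, as a fraction of baseline, generated
#'   to fail exactly one filter threshold.
#' @param flank_target_frac Fraction of consensus circRNAs receiving
#'   planted both-flank sites of `flank_rbp`.
#' @param flank_site_prob Probability of a planted site per flank per
#'   target circRNA.
#' @param iralu_frac Fraction of circRNAs with a planted inverted-Alu pair.
#' @param alu_density Background Alu density per kb of intron.
#' @param kd_effect Multiplicative knockdown effect on circRNAs with
#'   both-flank sites of `flank_rbp` (default 0.85, a 15% decrease).
#' @param kd_samples Samples per condition.
#' @param kd_mu_meanlog,kd_mu_sdlog,kd_size Count model for the
#'   knockdown matrix (negative binomial around log-normal means).
#' @param read_length Range of eCLIP read lengths (bp).
#' @param n_planted_junctions Junctions planted with calling-level read
#'   support.
#' @param junction_read_count Deduplicated reads per IP replicate for
#'   planted junctions.
#' @param duplicate_rate Expected PCR duplicates per unique read.
#' @param read_min_side Minimum bases a simulated read keeps on each side
#'   of the junction.
#' @param n_go_terms Number of GO terms in the annotation table (one of
#'   which is planted as enriched in the circ-binding RBP subset).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 300L,
                              n_chroms = 2L,
                              exons_per_gene = c(3L, 8L),
                              exon_length = c(80L, 400L),
                              intron_length = c(3000L, 8000L),
                              intergenic_length = c(500L, 3000L),
                              isoform2_prob = 0.5,
                              fpkm_meanlog = 1,
                              fpkm_sdlog = 2.5,
                              n_circ_genes = 30L,
                              circ_exon_weights = c(0.5, 0.3, 0.2),
                              bsj_mean = 30,
                              bsj_size = 5,
                              top_multiplier = 100,
                              consensus_fail_frac = 0.1,
                              n_rbps = 12L,
                              n_enriched_rbps = 4L,
                              flank_rbp = "KHSRP",
                              exonic_site_density = 1.2,
                              intronic_site_density = 0.03,
                              circ_multiplier = 3,
                              site_width = c(20L, 80L),
                              peak_fail_frac = 0.1,
                              flank_target_frac = 0.5,
                              flank_site_prob = 0.95,
                              iralu_frac = 0.3,
                              alu_density = 0.02,
                              kd_effect = 0.85,
                              kd_samples = 3L,
                              kd_mu_meanlog = log(150),
                              kd_mu_sdlog = 0.4,
                              kd_size = 500,
                              read_length = c(20L, 25L),
                              n_planted_junctions = 3L,
                              junction_read_count = 15L,
                              duplicate_rate = 0.3,
                              read_min_side = 8L,
                              n_go_terms = 8L) {
  cfg <- as.list(environment())
  stopifnot(cfg$circ_multiplier > 0, cfg$kd_effect > 0, cfg$kd_effect <= 1,
            cfg$n_enriched_rbps < cfg$n_rbps)
  class(cfg) <- "sim_config"
  cfg
}

.runif_int <- function(n, range) {
  sample.int(range[2] - range[1] + 1L, n, replace = TRUE) + range[1] - 1L
}

.rand_dna <- function(len) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, len,
                                                     replace = TRUE)])
}

#' Simulate a gene annotation, genome, and expression table
#'
#' Lays non-overlapping multi-isoform genes along the chromosomes (second
#' isoforms skip one internal exon), draws log-normal FPKM values, and
#' optionally generates a random genome sequence covering the annotation.
#' Called inside [simulate_screen()]'s seeded stream; set a seed first when
#' calling directly.
#'
#' @param config A [simulation_config()].
#' @param sequence Generate the genome sequence (default `TRUE`; skip for
#'   coordinate-only analyses).
#' @return List with `models` (a `gene_models` with FPKM), `expression`
#'   (data frame `gene_id`, `fpkm`), and `genome`
#'   ([Biostrings::DNAStringSet] or `NULL`).
#' @export
simulate_annotation <- function(config, sequence = TRUE) {
  chroms <- sprintf("chrS%d", seq_len(config$n_chroms))
  cursor <- stats::setNames(rep(1L, config$n_chroms), chroms)
  acc <- list(gene = list(), tx = list(), chrom = list(),
              start = list(), end = list(), strand = list())
  push <- function(gene, tx, chrom, start, end, strand) {
    k <- length(acc$gene) + 1L
    acc$gene[[k]] <<- rep(gene, length(start))
    acc$tx[[k]] <<- rep(tx, length(start))
    acc$chrom[[k]] <<- rep(chrom, length(start))
    acc$start[[k]] <<- start
    acc$end[[k]] <<- end
    acc$strand[[k]] <<- rep(strand, length(start))
  }
  for (g in seq_len(config$n_genes)) {
    chrom <- chroms[(g - 1L) %% config$n_chroms + 1L]
    n_ex <- .runif_int(1L, config$exons_per_gene)
    ex_len <- .runif_int(n_ex, config$exon_length)
    in_len <- if (n_ex > 1L) .runif_int(n_ex - 1L, config$intron_length)
              else integer()
    gap <- .runif_int(1L, config$intergenic_length)
    start <- cursor[[chrom]] + gap
    ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("G%04d", g)
    push(gene_id, sprintf("%s.T1", gene_id), chrom, ex_start, ex_end, strand)
    if (n_ex >= 4L && stats::runif(1) < config$isoform2_prob) {
      skip <- sample(2:(n_ex - 1L), 1L)
      push(gene_id, sprintf("%s.T2", gene_id), chrom, ex_start[-skip],
           ex_end[-skip], strand)
    }
    cursor[[chrom]] <- ex_end[n_ex] + 1L
  }
  ex <- data.frame(
    gene_id = unlist(acc$gene), transcript_id = unlist(acc$tx),
    chrom = unlist(acc$chrom), start = unlist(acc$start),
    end = unlist(acc$end), strand = unlist(acc$strand),
    stringsAsFactors = FALSE)
  expression <- data.frame(
    gene_id = sprintf("G%04d", seq_len(config$n_genes)),
    fpkm = stats::rlnorm(config$n_genes, config$fpkm_meanlog,
                         config$fpkm_sdlog),
    stringsAsFactors = FALSE)
  exons <- gintervals(ex$chrom, ex$start, ex$end, strand = ex$strand,
                      gene_id = ex$gene_id, transcript_id = ex$transcript_id)
  models <- gene_models(exons, expression = expression)
  genome <- NULL
  if (sequence) {
    lens <- cursor + 1000L
    genome <- Biostrings::DNAStringSet(vapply(lens, .rand_dna, character(1)))
    names(genome) <- chroms
  }
  list(models = models, expression = expression, genome = genome)
}

#' Simulate two circRNA caller tables with ground truth
#'
#' Places circRNAs on internal exon boundaries of circRNA-producing genes,
#' draws caller-A BSJ counts (negative binomial, with a planted
#' top-percentile subset boosted by `top_multiplier`), correlated caller-B
#' counts, and linear junction reads. A configurable fraction of true
#' circRNAs fails the 2-read consensus in exactly one caller, and a few
#' caller-specific junk calls are added.
#'
#' @param config A [simulation_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return List with `calls_a`, `calls_b` (normalized call tables) and
#'   `truth`: `circ_genes`, `consensus_ids`, `planted_top_ids`,
#'   `circ_table` (circ_id, gene_id, consensus flag).
#' @export
simulate_circ_calls <- function(config, ann, me = NULL) {
  if (is.null(me)) me <- gene_merged_exons(ann$models)
  n_per_gene <- table(me$gene_id)
  eligible <- names(n_per_gene)[n_per_gene >= 4L]
  if (length(eligible) < config$n_circ_genes) {
    stop("too few genes with >= 4 exons for n_circ_genes")
  }
  circ_genes <- sort(sample(eligible, config$n_circ_genes))
  rows <- lapply(circ_genes, function(g) {
    exg <- me[me$gene_id == g]
    exg <- exg[order(GenomicRanges::start(exg))]
    n_ex <- length(exg)
    span <- sample(seq_along(config$circ_exon_weights), 1L,
                   prob = config$circ_exon_weights)
    span <- min(span, n_ex - 2L)
    a <- sample(2:(n_ex - span), 1L)
    d <- a + span - 1L
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(exg))[1],
      start = GenomicRanges::start(exg)[a],
      end = GenomicRanges::end(exg)[d],
      strand = as.character(GenomicRanges::strand(exg))[1],
      gene_id = g, stringsAsFactors = FALSE)
  })
  circ <- do.call(rbind, rows)
  n <- nrow(circ)
  bsj <- as.integer(pmax(2L, stats::rnbinom(n, mu = config$bsj_mean,
                                            size = config$bsj_size)))
  n_top <- max(1L, ceiling(0.01 * n))
  top_idx <- sample.int(n, n_top)
  bsj[top_idx] <- as.integer(round(bsj[top_idx] * config$top_multiplier) +
                               max(bsj) + 1L)
  fail_idx <- sample.int(n, round(config$consensus_fail_frac * n))
  bsj_b <- as.integer(pmax(2L, round(bsj * stats::runif(n, 0.7, 1.3))))
  bsj_b[fail_idx] <- 1L
  linear <- as.integer(stats::rnbinom(n, mu = 2 * config$bsj_mean,
                                      size = config$bsj_size))
  calls_a <- circ_calls(data.frame(
    chrom = circ$chrom, start = circ$start, end = circ$end,
    strand = circ$strand, bsj_reads = bsj, linear_reads = linear,
    gene_id = circ$gene_id, stringsAsFactors = FALSE))
  # caller-specific junk on exon boundaries of non-circ genes
  junk_pool <- me[!(me$gene_id %in% circ_genes)]
  junk_idx <- sample.int(length(junk_pool), 10L)  # disjoint between callers
  junk <- function(i) {
    circ_calls(data.frame(
      chrom = as.character(GenomicRanges::seqnames(junk_pool))[i],
      start = GenomicRanges::start(junk_pool)[i],
      end = GenomicRanges::end(junk_pool)[i],
      strand = as.character(GenomicRanges::strand(junk_pool))[i],
      bsj_reads = sample(2:5, length(i), replace = TRUE),
      linear_reads = sample(0:20, length(i), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  calls_b <- circ_calls(data.frame(
    chrom = circ$chrom, start = circ$start, end = circ$end,
    strand = circ$strand, bsj_reads = bsj_b,
    linear_reads = as.integer(stats::rnbinom(n, mu = 2 * config$bsj_mean,
                                             size = config$bsj_size)),
    stringsAsFactors = FALSE))
  ja <- junk(junk_idx[1:5])
  jb <- junk(junk_idx[6:10])
  ja$gene_id <- NA_character_
  calls_a <- circ_calls(rbind(calls_a, ja))
  calls_b <- circ_calls(rbind(calls_b, jb))
  consensus <- calls_a$circ_id[seq_len(n)][bsj >= 2L & bsj_b >= 2L]
  truth <- list(
    circ_genes = circ_genes,
    consensus_ids = sort(consensus),
    planted_top_ids = calls_a$circ_id[top_idx],
    circ_table = data.frame(
      circ_id = calls_a$circ_id[seq_len(n)], gene_id = circ$gene_id,
      consensus = calls_a$circ_id[seq_len(n)] %in% consensus,
      stringsAsFactors = FALSE)
  )
  list(calls_a = calls_a, calls_b = calls_b, truth = truth)
}

.place_sites <- function(region, n, width_range) {
  if (n <= 0L || length(region) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  w <- IRanges::width(region)
  iv <- sample.int(length(region), n, replace = TRUE, prob = w)
  pos <- GenomicRanges::start(region)[iv] +
    floor(stats::runif(n) * w[iv])
  sw <- .runif_int(n, width_range)
  data.frame(chrom = as.character(GenomicRanges::seqnames(region))[iv],
             start = as.integer(pos), end = as.integer(pos + sw - 1L),
             stringsAsFactors = FALSE)
}

.passing_counts <- function(n) {
  ip <- stats::rpois(n, 30) + 10L
  fc <- stats::runif(n, 3.2, 6)
  input <- pmax(0L, as.integer(floor((ip + 1) / 2^fc - 1)))
  data.frame(ip_reads = ip, input_reads = input)
}

#' Simulate eCLIP peaks with planted circ-exon and flank enrichment
#'
#' Places binding sites as a width-weighted uniform process at baseline
#' density on exonic and intronic bases for every RBP; enriched RBPs get
#' `circ_multiplier` times the exonic density on circularizing exons; the
#' flank RBP gets planted sites in both intronic flanks of a target circRNA
#' subset. IP/input counts are drawn so these sites pass the default
#' filters; an extra `peak_fail_frac` of peaks fails exactly one filter.
#' Background and planted inverted-Alu positions are generated alongside.
#'
#' @param config A [simulation_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param circs Caller simulation from [simulate_circ_calls()].
#' @param flank_width Flank window width used for planting (default 10000).
#' @param me,introns Optional precomputed [gene_merged_exons()] /
#'   [intronic_regions()] results (recomputed when `NULL`).
#' @return List with `peaks` (data frame, 1-based closed), `alus`
#'   (stranded `GRanges`), and `truth`: `enriched_rbps`, `flank_rbp`,
#'   `planted_flank_ids`, `planted_iralu_ids`.
#' @export
simulate_eclip_peaks <- function(config, ann, circs, flank_width = 10000L,
                                 me = NULL, introns = NULL) {
  if (is.null(me)) me <- gene_merged_exons(ann$models)
  if (is.null(introns)) introns <- intronic_regions(ann$models)
  catalog <- consensus_catalog(circs$calls_a, circs$calls_b)
  catalog <- assign_host_gene(catalog, me)
  parts <- circ_exonic_parts(catalog, me)
  circ_exonic <- merge_intervals(unlist(parts$parts))
  rbp_names <- c(sprintf("RBP%02d", seq_len(config$n_rbps - 1L)),
                 config$flank_rbp)
  enriched <- rbp_names[seq_len(config$n_enriched_rbps)]
  kb <- function(gr) interval_bases(gr) / 1000
  fp <- flank_pairs(catalog_granges(catalog), introns, width = flank_width)
  # flank pieces are already disjoint (per-gene introns are), so skip the
  # per-feature canonical merge when extracting placement regions
  flank_side <- function(id, side) {
    i <- match(id, catalog$circ_id)
    gr <- fp[[side]]
    gr[gr$feature == i]
  }
  target_ids <- sort(sample(catalog$circ_id,
                            round(config$flank_target_frac * nrow(catalog))))
  peak_rows <- list()
  add <- function(df, rbp) {
    if (nrow(df) == 0L) return()
    df$rbp <- rbp
    peak_rows[[length(peak_rows) + 1L]] <<- df
  }
  for (r in rbp_names) {
    add(.place_sites(me, stats::rpois(1, config$exonic_site_density * kb(me)),
                     config$site_width), r)
    add(.place_sites(introns,
                     stats::rpois(1, config$intronic_site_density *
                                    kb(introns)),
                     config$site_width), r)
    if (r %in% enriched) {
      extra <- (config$circ_multiplier - 1) * config$exonic_site_density *
        kb(circ_exonic)
      add(.place_sites(circ_exonic, stats::rpois(1, extra),
                       config$site_width), r)
    }
    if (r == config$flank_rbp) {
      for (id in target_ids) {
        for (side in c("upstream", "downstream")) {
          fl <- flank_side(id, side)
          if (length(fl) > 0L && stats::runif(1) < config$flank_site_prob) {
            add(.place_sites(fl, 1L, config$site_width), r)
          }
        }
      }
    }
  }
  peaks <- do.call(rbind, peak_rows)
  cc <- .passing_counts(nrow(peaks))
  peaks <- cbind(peaks, cc)
  # extra peaks each failing exactly one filter
  n_fail <- round(config$peak_fail_frac * nrow(peaks))
  if (n_fail > 0L) {
    fail <- .place_sites(me, n_fail, config$site_width)
    fc <- cbind(fail, .passing_counts(n_fail))
    fc$rbp <- sample(rbp_names, n_fail, replace = TRUE)
    mode <- sample.int(3L, n_fail, replace = TRUE)
    fc$ip_reads[mode == 1L] <- sample(1:9, sum(mode == 1L), replace = TRUE)
    fc$input_reads[mode == 2L] <- fc$ip_reads[mode == 2L]  # log2fc ~ 0
    short <- mode == 3L
    fc$end[short] <- fc$start[short] + sample(1:2, sum(short),
                                              replace = TRUE)
    peaks <- rbind(peaks, fc[, names(peaks)])
  }
  peaks$strand <- "*"
  peaks$score <- 0L
  peaks$width <- peaks$end - peaks$start + 1L
  peaks$log2fc <- compute_log2fc(peaks$ip_reads, peaks$input_reads)
  rownames(peaks) <- NULL
  # Alu repeats: background plus planted inverted pairs across the flanks
  alu_bg <- .place_sites(introns,
                         stats::rpois(1, config$alu_density * kb(introns)),
                         c(250L, 350L))
  alu_bg$strand <- sample(c("+", "-"), nrow(alu_bg), replace = TRUE)
  iralu_ids <- sort(sample(catalog$circ_id,
                           round(config$iralu_frac * nrow(catalog))))
  alu_pl <- list()
  for (id in iralu_ids) {
    fl_up <- flank_side(id, "upstream")
    fl_dn <- flank_side(id, "downstream")
    if (length(fl_up) == 0L || length(fl_dn) == 0L) next
    up <- .place_sites(fl_up, 1L, c(250L, 350L))
    dn <- .place_sites(fl_dn, 1L, c(250L, 350L))
    s <- sample(c("+", "-"), 1L)
    up$strand <- s
    dn$strand <- if (s == "+") "-" else "+"
    alu_pl[[length(alu_pl) + 1L]] <- rbind(up, dn)
  }
  alu <- rbind(alu_bg, do.call(rbind, alu_pl))
  alus <- gintervals(alu$chrom, alu$start, alu$end, strand = alu$strand)
  list(
    peaks = peaks,
    alus = alus,
    catalog = catalog,
    truth = list(enriched_rbps = enriched, flank_rbp = config$flank_rbp,
                 planted_flank_ids = target_ids,
                 planted_iralu_ids = iralu_ids)
  )
}

#' Simulate knockdown/control circRNA count matrices
#'
#' Negative-binomial BSJ read counts for every circRNA across knockdown and
#' control samples; circRNAs in `effect_ids` have their mean multiplied by
#' `kd_effect` in knockdown samples only.
#'
#' @param config A [simulation_config()].
#' @param circ_ids Character vector of circRNA ids (matrix rows).
#' @param effect_ids Subset of `circ_ids` receiving the knockdown effect.
#' @return List with `counts` (matrix circRNAs x samples), `condition`
#'   (per-sample `"KD"`/`"control"`), `library_sizes`.
#' @export
simulate_kd_counts <- function(config, circ_ids, effect_ids) {
  n <- length(circ_ids)
  k <- config$kd_samples
  condition <- rep(c("KD", "control"), each = k)
  mu <- stats::rlnorm(n, config$kd_mu_meanlog, config$kd_mu_sdlog)
  library_sizes <- as.integer(round(stats::runif(2L * k, 1.8e7, 2.2e7)))
  counts <- matrix(0L, n, 2L * k,
                   dimnames = list(circ_ids,
                                   paste0(condition, c(seq_len(k),
                                                       seq_len(k)))))
  scale <- matrix(1, n, 2L * k)
  scale[circ_ids %in% effect_ids, condition == "KD"] <- config$kd_effect
  # control columns are drawn first so they are identical across values of
  # the effect parameter under the same seed
  for (j in c(which(condition == "control"), which(condition == "KD"))) {
    # expected counts scale with sequencing depth; RPM undoes it exactly
    depth <- library_sizes[j] / 2e7
    counts[, j] <- as.integer(stats::rnbinom(n, mu = mu * scale[, j] * depth,
                                             size = config$kd_size))
  }
  list(counts = counts, condition = condition,
       library_sizes = library_sizes)
}

#' Simulate junction-spanning eCLIP reads
#'
#' Samples error-free reads across planted junctions so they pass the
#' calling thresholds (per-replicate read floor and fold change over
#' input), plus decoy junctions that miss exactly one threshold, PCR
#' duplicates, and a few reads carrying three substitutions that must not
#' map. Reads keep at least `read_min_side` bases on each side of the
#' junction.
#'
#' @param config A [simulation_config()].
#' @param refs Reference set from [build_bsj_reference()].
#' @return List with `reads` (data frame `read_id`, `barcode`, `sequence`,
#'   `sample`) and `truth`: `called_junctions`, `decoy_junctions`,
#'   `error_read_ids`.
#' @export
simulate_bsj_reads <- function(config, refs) {
  full <- refs$references[!grepl("N", refs$references$sequence) &
                            nchar(refs$references$sequence) ==
                            2L * refs$references$junction_offset, ,
                          drop = FALSE]
  n_pick <- config$n_planted_junctions + 2L
  if (nrow(full) < n_pick) stop("too few full-length references")
  pick <- full[sample.int(nrow(full), n_pick), , drop = FALSE]
  planted <- pick[seq_len(config$n_planted_junctions), , drop = FALSE]
  decoys <- pick[-seq_len(config$n_planted_junctions), , drop = FALSE]
  counter <- 0L
  make_reads <- function(ref_row, n, sample_name, errors = 0L) {
    if (n <= 0L) return(NULL)
    seq <- ref_row$sequence
    off <- ref_row$junction_offset
    out <- lapply(seq_len(n), function(i) {
      len <- .runif_int(1L, config$read_length)
      lo <- off + 1L + config$read_min_side - len
      hi <- off + 1L - config$read_min_side
      st <- sample(lo:hi, 1L)
      rd <- substr(seq, st, st + len - 1L)
      if (errors > 0L) {
        pos <- sample.int(len, errors)
        ch <- strsplit(rd, "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1L)
        rd <- paste(ch, collapse = "")
      }
      counter <<- counter + 1L
      data.frame(read_id = sprintf("read%05d", counter),
                 barcode = .rand_dna(10L), sequence = rd,
                 sample = sample_name, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  reads <- list()
  for (i in seq_len(nrow(planted))) {
    reads[[length(reads) + 1L]] <-
      make_reads(planted[i, ], config$junction_read_count, "IP_rep1")
    reads[[length(reads) + 1L]] <-
      make_reads(planted[i, ], config$junction_read_count, "IP_rep2")
    reads[[length(reads) + 1L]] <- make_reads(planted[i, ], 1L, "input")
  }
  # decoy 1 fails the per-replicate read floor; decoy 2 fails fold change
  reads[[length(reads) + 1L]] <-
    make_reads(decoys[1, ], config$junction_read_count, "IP_rep1")
  reads[[length(reads) + 1L]] <- make_reads(decoys[1, ], 5L, "IP_rep2")
  reads[[length(reads) + 1L]] <- make_reads(decoys[1, ], 1L, "input")
  reads[[length(reads) + 1L]] <-
    make_reads(decoys[2, ], config$junction_read_count, "IP_rep1")
  reads[[length(reads) + 1L]] <-
    make_reads(decoys[2, ], config$junction_read_count, "IP_rep2")
  reads[[length(reads) + 1L]] <-
    make_reads(decoys[2, ], config$junction_read_count, "input")
  reads <- do.call(rbind, reads)
  # PCR duplicates: copies with identical barcode and position
  n_dup <- stats::rpois(1, config$duplicate_rate * nrow(reads))
  if (n_dup > 0L) {
    src <- reads[sample.int(nrow(reads), n_dup, replace = TRUE), ,
                 drop = FALSE]
    src$read_id <- sprintf("dup%05d", seq_len(n_dup))
    reads <- rbind(reads, src)
  }
  err <- make_reads(planted[1, ], 3L, "IP_rep1", errors = 3L)
  reads <- rbind(reads, err)
  rownames(reads) <- NULL
  expand_ids <- function(rows) {
    sort(unique(unlist(strsplit(rows$junction_ids, ",", fixed = TRUE))))
  }
  list(reads = reads,
       truth = list(called_junctions = expand_ids(planted),
                    decoy_junctions = expand_ids(decoys),
                    error_read_ids = err$read_id))
}

#' Simulate a GO annotation table with one planted enriched term
#'
#' The planted term annotates every enriched RBP plus two background RBPs;
#' the remaining terms annotate random RBP subsets.
#'
#' @param config A [simulation_config()].
#' @param rbp_names All RBP names.
#' @param enriched_rbps The planted circ-exon-enriched RBPs.
#' @return List with `go` (data frame `rbp`, `term`, `domain`) and
#'   `truth$planted_term`.
#' @export
simulate_go_table <- function(config, rbp_names, enriched_rbps) {
  planted_term <- "GO:PLANTED regulation of mRNA stability"
  others <- setdiff(rbp_names, enriched_rbps)
  rows <- list(data.frame(
    rbp = c(enriched_rbps, sample(others, 2L)),
    term = planted_term, domain = "BP", stringsAsFactors = FALSE))
  for (i in seq_len(config$n_go_terms - 1L)) {
    k <- sample(2:5, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      rbp = sample(rbp_names, k),
      term = sprintf("GO:%07d synthetic term %d", i, i),
      domain = sample(c("BP", "CC", "MF"), 1L),
      stringsAsFactors = FALSE)
  }
  list(go = do.call(rbind, rows), truth = list(planted_term = planted_term))
}

#' Simulate subcellular localization tables
#'
#' CircRNAs are always cytoplasmic, a subset also nuclear; RBPs occupy
#' both compartments, only the cytoplasm, or only the nucleus.
#'
#' @param circ_ids CircRNA identifiers.
#' @param rbp_names RBP names.
#' @return List of data frames `circ` (`circ_id`, `compartment`) and `rbp`
#'   (`rbp`, `compartment`).
#' @export
simulate_localization <- function(circ_ids, rbp_names) {
  circ_rows <- lapply(circ_ids, function(id) {
    comp <- if (stats::runif(1) < 0.6) c("cytoplasm", "nucleus")
            else "cytoplasm"
    data.frame(circ_id = id, compartment = comp, stringsAsFactors = FALSE)
  })
  rbp_rows <- lapply(rbp_names, function(r) {
    u <- stats::runif(1)
    comp <- if (u < 0.6) c("cytoplasm", "nucleus")
            else if (u < 0.8) "cytoplasm" else "nucleus"
    data.frame(rbp = r, compartment = comp, stringsAsFactors = FALSE)
  })
  list(circ = do.call(rbind, circ_rows), rbp = do.call(rbind, rbp_rows))
}

#' Run the full synthetic-data generator
#'
#' Generates every input of the screen under one seeded random stream:
#' annotation + genome + expression, two circRNA caller tables, eCLIP
#' peaks and Alu positions with planted effects, knockdown count matrices
#' (effect applied to the circRNAs that actually carry both-flank sites of
#' the flank RBP), backsplice-junction references and junction-spanning
#' reads, a GO table, and localization tables. Rerunning with the same
#' config reproduces identical outputs.
#'
#' @param config A [simulation_config()].
#' @param stages Character subset of
#'   `c("kd", "reads", "go", "localization")` to generate beyond the core
#'   annotation/circ/peak stages (default all).
#' @param sequence Generate the genome sequence (required for `"reads"`).
#' @return A list of class `circ_simulation` with components `config`,
#'   `annotation`, `circs`, `peaks_sim`, `kd`, `bsj`, `reads_sim`, `go`,
#'   `localization`, and `truth` (merged ground-truth records, including
#'   `flanked_ids`, the circRNAs with measured both-flank sites of the
#'   flank RBP).
#' @export
simulate_screen <- function(config = simulation_config(),
                            stages = c("kd", "reads", "go", "localization"),
                            sequence = TRUE) {
  set.seed(config$seed)
  if ("reads" %in% stages && !sequence) {
    stop("stage 'reads' requires sequence = TRUE")
  }
  ann <- simulate_annotation(config, sequence = sequence)
  me <- gene_merged_exons(ann$models)
  introns <- intronic_regions(ann$models)
  circs <- simulate_circ_calls(config, ann, me = me)
  peaks_sim <- simulate_eclip_peaks(config, ann, circs, me = me,
                                    introns = introns)
  truth <- c(circs$truth, peaks_sim$truth)
  sim <- list(config = config, annotation = ann, circs = circs,
              peaks_sim = peaks_sim)
  # circRNAs whose measured flanks both carry flank-RBP sites; the KD
  # effect is applied to exactly this subset
  catalog <- peaks_sim$catalog
  fsites <- sites_granges(
    filter_sites(peaks_sim$peaks[peaks_sim$peaks$rbp == config$flank_rbp, ,
                                 drop = FALSE]))
  cg <- catalog_granges(catalog)
  flagged <- both_flank_presence_all(flank_pairs(cg, introns), fsites)
  truth$flanked_ids <- catalog$circ_id[flagged]
  if ("kd" %in% stages) {
    sim$kd <- simulate_kd_counts(config, catalog$circ_id, truth$flanked_ids)
  }
  if ("reads" %in% stages) {
    refs <- build_bsj_reference(ann$models, ann$genome, k = 30L)
    sim$bsj <- refs
    sim$reads_sim <- simulate_bsj_reads(config, refs)
    truth <- c(truth, sim$reads_sim$truth)
  }
  rbp_names <- sort(unique(peaks_sim$peaks$rbp))
  if ("go" %in% stages) {
    go_sim <- simulate_go_table(config, rbp_names, truth$enriched_rbps)
    sim$go <- go_sim$go
    truth <- c(truth, go_sim$truth)
  }
  if ("localization" %in% stages) {
    sim$localization <- simulate_localization(catalog$circ_id, rbp_names)
  }
  sim$catalog <- catalog
  sim$truth <- truth
  class(sim) <- "circ_simulation"
  sim
}

#' Write a simulation to disk in standard formats
#'
#' Emits the exact formats the package readers consume: genome FASTA, GTF
#' annotation, expression TSV, two caller TSVs (1-based closed), a BED6+
#' peak TSV (0-based half-open starts, as in BED), an Alu BED6 file,
#' knockdown count and library-size TSVs, per-sample FASTQ read files, GO
#' and localization TSVs, and a ground-truth JSON.
#'
#' @param sim A `circ_simulation` from [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sim$annotation$genome)) {
    Biostrings::writeXStringSet(sim$annotation$genome, p("genome.fa"))
  }
  ex <- sim$annotation$models$exons
  gtf <- ex
  gtf$type <- "exon"
  gtf$source <- "circscreen_sim"
  rtracklayer::export(gtf, p("annotation.gtf"), format = "GTF")
  tsv(sim$annotation$expression, p("expression.tsv"))
  drop_id <- function(df) df[, setdiff(names(df), "circ_id"), drop = FALSE]
  tsv(drop_id(sim$circs$calls_a), p("circ_calls_a.tsv"))
  tsv(drop_id(sim$circs$calls_b), p("circ_calls_b.tsv"))
  pk <- sim$peaks_sim$peaks
  pk_out <- data.frame(chrom = pk$chrom, start = pk$start - 1L,
                       end = pk$end, rbp = pk$rbp, score = pk$score,
                       strand = pk$strand, ip_reads = pk$ip_reads,
                       input_reads = pk$input_reads,
                       stringsAsFactors = FALSE)
  tsv(pk_out, p("eclip_peaks.tsv"))
  write_bed(sim$peaks_sim$alus, p("alu.bed"))
  if (!is.null(sim$kd)) {
    cnt <- data.frame(circ_id = rownames(sim$kd$counts), sim$kd$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    tsv(cnt, p("kd_counts.tsv"))
    tsv(data.frame(sample = colnames(sim$kd$counts),
                   condition = sim$kd$condition,
                   library_size = sim$kd$library_sizes),
        p("kd_library_sizes.tsv"))
  }
  if (!is.null(sim$reads_sim)) {
    for (s in unique(sim$reads_sim$reads$sample)) {
      write_eclip_fastq(
        sim$reads_sim$reads[sim$reads_sim$reads$sample == s, , drop = FALSE],
        p(sprintf("eclip_reads_%s.fastq", s)))
    }
  }
  if (!is.null(sim$bsj)) write_bsj_fasta(sim$bsj, p("bsj_reference.fa"))
  if (!is.null(sim$go)) tsv(sim$go, p("go_annotations.tsv"))
  if (!is.null(sim$localization)) {
    tsv(sim$localization$circ, p("localization_circ.tsv"))
    tsv(sim$localization$rbp, p("localization_rbp.tsv"))
  }
  jsonlite::write_json(sim$truth, p("ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
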