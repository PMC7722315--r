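#' Screen configuration with the published default thresholds
#'
#' Collects every tunable threshold of the screen. Defaults: consensus at
#' 2 BSJ reads per caller, top 1% expression set, binding-site filters of
#' 10 IP reads / log2 fold change 3 (an 8-fold linear enrichment) / 4 bp
#' width and 4 bp minimum overlap, 10 kb flank windows, 100 expression
#' bins, 100 resampling iterations, 30 bp junction arms, 2 mismatches and
#' a 5 bp span floor for junction reads, 20 binding sites per RBP for the
#' differential-binding test, and FDR < 0.1 significance.
#'
#' @param consensus_min_reads,top_fraction,min_ip_reads,min_log2fc
#'   Catalog and peak-filter thresholds.
#' @param min_site_width,min_overlap,flank_width,n_bins,iterations
#'   Coverage and flank parameters.
#' @param bsj_k,max_mismatches,min_span Junction-mapping parameters.
#' @param min_rbp_sites,fdr_threshold Differential-binding parameters.
#' @param flank_rbp RBP tested in the flanking-intron analysis.
#' @param resample_circ_set `"all"` (default) compares exons of every
#'   consensus circRNA gene; `"top"` restricts to genes of the top
#'   expression percentile.
#' @param seed Seed for the resampling stage.
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(consensus_min_reads = 2L,
                          top_fraction = 0.01,
                          min_ip_reads = 10L,
                          min_log2fc = 3,
                          min_site_width = 4L,
                          min_overlap = 4L,
                          flank_width = 10000L,
                          n_bins = 100L,
                          iterations = 100L,
                          bsj_k = 30L,
                          max_mismatches = 2L,
                          min_span = 5L,
                          min_rbp_sites = 20L,
                          fdr_threshold = 0.1,
                          flank_rbp = "KHSRP",
                          resample_circ_set = c("all", "top"),
                          seed = 1L) {
  resample_circ_set <- match.arg(resample_circ_set)
  cfg <- as.list(environment())
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  if (cfg$iterations < 1L || cfg$n_bins < 1L || cfg$flank_width < 1L ||
      cfg$consensus_min_reads < 0L || cfg$min_span < 1L ||
      cfg$bsj_k < 1L || cfg$max_mismatches < 0L) {
    stop("invalid screen_config threshold")
  }
  class(cfg) <- "screen_config"
  cfg
}

.schema_version <- "1"

#' Run the circRNA-RBP screen on a simulation or input directory
#'
#' Executes every analysis stage in order: consensus catalog and top
#' percentile, exon categorization, per-circRNA merged RBP coverage with
#' host-gene enrichment ratios, per-RBP differential binding,
#' expression-matched resampling, flanking-intron RBP and inverted-Alu
#' enrichment, knockdown comparison in RPM, backsplice-junction read
#' mapping and calling, GO enrichment of the circ-binding RBP subset, and
#' co-localization. Results are returned as a list and, when `out_dir` is
#' given, written as tab-delimited tables plus a JSON summary and a
#' manifest recording config, seed, input checksums, and package version;
#' reruns with identical inputs are byte-identical.
#'
#' @param sim Either a `circ_simulation` from [simulate_screen()] or a
#'   directory written by [write_simulation()].
#' @param config A [screen_config()].
#' @param out_dir Optional output directory.
#' @return A list of stage results (class `circ_screen`).
#' @export
run_screen <- function(sim, config = screen_config(), out_dir = NULL) {
  input_files <- character()
  if (is.character(sim)) {
    input_files <- sort(list.files(sim, full.names = TRUE))
    sim <- read_simulation(sim)
  }
  ann <- sim$annotation
  res <- list(config = config)

  # --- catalog -------------------------------------------------------
  me <- gene_merged_exons(ann$models)
  introns <- intronic_regions(ann$models)
  catalog <- consensus_catalog(sim$circs$calls_a, sim$circs$calls_b,
                               min_reads = config$consensus_min_reads)
  catalog <- assign_host_gene(catalog, me)
  catalog$relative_ratio <- relative_ratio(catalog$bsj_reads,
                                           catalog$linear_reads)
  top <- top_percentile(catalog, config$top_fraction)
  exon_table <- categorize_exons(me, catalog)
  parts <- circ_exonic_parts(catalog, me)
  res$catalog <- catalog
  res$top <- top
  res$exon_table <- exon_table

  # --- binding sites and coverage ------------------------------------
  sites <- filter_sites(sim$peaks_sim$peaks,
                        min_ip = config$min_ip_reads,
                        min_log2fc = config$min_log2fc,
                        min_width = config$min_site_width)
  sites_gr <- sites_granges(sites)
  res$site_location <- table(classify_site_location(sites_gr, me, introns))
  cov_tab <- catalog[, c("circ_id", "host_gene", "bsj_reads",
                         "linear_reads", "relative_ratio")]
  cov_tab$exonic_length <- parts$summary$exonic_length
  cov_tab$n_exons <- parts$summary$n_exons
  cov_tab$rbp_overlap_bp <- NA_integer_
  cov_tab$rbp_coverage <- NA_real_
  cov_tab$n_rbps <- NA_integer_
  cov_tab$n_non_circ_exons_host <- NA_integer_
  cov_tab$mean_rbp_coverage_non_circ_exons <- NA_real_
  cov_tab$ratio_rbp_coverage <- NA_real_
  internal_noncirc <- exon_table[!exon_table$is_first &
                                   !exon_table$is_last &
                                   exon_table$category == "non_circ_exon", ]
  for (i in seq_len(nrow(cov_tab))) {
    if (!parts$summary$has_exons[i]) next
    fe <- parts$parts[[i]]
    ov <- site_feature_overlaps(sites_gr, fe,
                                min_overlap = config$min_overlap)
    use <- sites_gr[unique(ov$site_idx)]
    cv <- rbp_coverage(fe, use, merge_rbps = TRUE)
    cov_tab$rbp_overlap_bp[i] <- cv$covered_bp
    cov_tab$rbp_coverage[i] <- cv$coverage_pct
    cov_tab$n_rbps[i] <- length(unique(use$rbp))
    host <- cov_tab$host_gene[i]
    if (!is.na(host)) {
      hx <- internal_noncirc[internal_noncirc$gene_id == host, ]
      nc_cov <- if (nrow(hx)) {
        exon_coverage(gintervals(hx$chrom, hx$start, hx$end), sites_gr)
      } else numeric()
      enr <- host_gene_enrichment(cov_tab$rbp_coverage[i], nc_cov)
      cov_tab$n_non_circ_exons_host[i] <- enr$n_noncirc_exons
      cov_tab$mean_rbp_coverage_non_circ_exons[i] <-
        enr$mean_noncirc_coverage_pct
      cov_tab$ratio_rbp_coverage[i] <- enr$ratio
    }
  }
  res$circ_coverage <- cov_tab
  res$differential_binding <- per_rbp_differential_binding(
    exon_table, sites_gr, min_sites = config$min_rbp_sites,
    fdr_threshold = config$fdr_threshold)

  # --- expression-matched resampling ---------------------------------
  set.seed(config$seed)
  genes <- ann$models$genes
  bins <- expression_bins(genes, n_bins = config$n_bins)
  circ_set <- if (config$resample_circ_set == "top") top else catalog
  circ_genes <- unique(stats::na.omit(circ_set$host_gene))
  all_circ_genes <- unique(stats::na.omit(catalog$host_gene))
  circ_bins <- bins$bin[match(circ_genes, bins$gene_id)]
  circ_bins <- circ_bins[!is.na(circ_bins)]
  obs_ex <- exon_table[exon_table$category == "bsj_circ_exon" &
                         exon_table$gene_id %in% circ_genes &
                         !exon_table$is_first & !exon_table$is_last, ]
  pool_ex <- exon_table[!(exon_table$gene_id %in% all_circ_genes) &
                          !exon_table$is_first & !exon_table$is_last, ]
  pool_ex$bin <- bins$bin[match(pool_ex$gene_id, bins$gene_id)]
  pool_ex <- pool_ex[!is.na(pool_ex$bin), ]
  obs_cov <- exon_coverage(gintervals(obs_ex$chrom, obs_ex$start,
                                      obs_ex$end), sites_gr)
  pool_cov <- exon_coverage(gintervals(pool_ex$chrom, pool_ex$start,
                                       pool_ex$end), sites_gr)
  res$resample <- matched_resample(mean(obs_cov), circ_bins,
                                   pool_ex$bin, pool_cov,
                                   iterations = config$iterations)
  res$resample$n_observed_exons <- length(obs_cov)

  # --- flanking introns ----------------------------------------------
  cg <- catalog_granges(catalog)
  circ_flanks <- flank_pairs(cg, introns, width = config$flank_width)
  nc <- internal_noncirc[internal_noncirc$gene_id %in% all_circ_genes, ]
  nc_gr <- gintervals(nc$chrom, nc$start, nc$end)
  nc_flanks <- flank_pairs(nc_gr, introns, width = config$flank_width)
  flank_tab <- do.call(rbind, lapply(sort(unique(sites$rbp)), function(r) {
    sr <- sites_gr[sites_gr$rbp == r]
    fa <- both_flank_presence_all(circ_flanks, sr)
    fb <- both_flank_presence_all(nc_flanks, sr)
    ft <- flank_enrichment_test(fa, fb)
    data.frame(rbp = r, n_circ = length(fa), n_noncirc_exons = length(fb),
               prop_circ = ft$prop_a, prop_noncirc = ft$prop_b,
               fold = ft$fold, statistic = ft$statistic, p = ft$p,
               stringsAsFactors = FALSE)
  }))
  rownames(flank_tab) <- NULL
  res$flank_enrichment <- flank_tab
  ir_circ <- iralu_both_flanks_all(circ_flanks, sim$peaks_sim$alus)
  ir_nc <- iralu_both_flanks_all(nc_flanks, sim$peaks_sim$alus)
  ir <- flank_enrichment_test(ir_circ, ir_nc)
  res$iralu <- data.frame(prop_circ = ir$prop_a, prop_noncirc = ir$prop_b,
                          fold = ir$fold, statistic = ir$statistic,
                          p = ir$p)
  fr_sites <- sites_gr[sites_gr$rbp == config$flank_rbp]
  flanked <- both_flank_presence_all(circ_flanks, fr_sites)
  res$flanked_ids <- catalog$circ_id[flanked]

  # --- knockdown comparison ------------------------------------------
  if (!is.null(sim$kd)) {
    rpm <- rpm_normalize(sim$kd$counts, sim$kd$library_sizes)
    have <- intersect(res$flanked_ids, rownames(rpm))
    comp <- intersect(setdiff(catalog$circ_id, res$flanked_ids),
                      rownames(rpm))
    res$kd_flanked <- kd_group_compare(rpm, sim$kd$condition, have,
                                       test = "t")
    res$kd_complement <- kd_group_compare(rpm, sim$kd$condition, comp,
                                          test = "t")
  }

  # --- junction-spanning reads ---------------------------------------
  if (!is.null(sim$reads_sim)) {
    refs <- if (!is.null(sim$bsj)) sim$bsj else {
      build_bsj_reference(ann$models, ann$genome, k = config$bsj_k)
    }
    hits <- map_reads(sim$reads_sim$reads, refs,
                      max_mismatches = config$max_mismatches,
                      min_span = config$min_span)
    dedup <- dedup_reads(hits)
    counts <- count_junction_reads(dedup)
    res$junction_calls <- call_junction_sites(
      counts, min_reads = config$min_ip_reads,
      min_log2fc = config$min_log2fc)
    # report: called junctions that coincide with a catalogued BSJ
    res$junctions_matching_catalog <- character(0)
  }

  # --- GO and co-localization ----------------------------------------
  if (!is.null(sim$go)) {
    db <- res$differential_binding
    subset_rbps <- db$rbp[db$significant &
                            db$mean_cov_bsj > db$mean_cov_noncirc]
    all_rbps <- sort(unique(sim$peaks_sim$peaks$rbp))
    res$go_subset <- subset_rbps
    res$go_enrichment <- if (length(subset_rbps) >= 1L) {
      go_enrichment(subset_rbps, all_rbps, sim$go)
    } else NULL
  }
  if (!is.null(sim$localization)) {
    topg <- catalog_granges(top)
    ov <- site_feature_overlaps(sites_gr, topg,
                                min_overlap = config$min_overlap)
    inter <- unique(data.frame(
      circ_id = top$circ_id[ov$feature_idx],
      rbp = sites_gr$rbp[ov$site_idx], stringsAsFactors = FALSE))
    res$interactions <- inter
    res$colocalization <- colocalization_fraction(
      inter, sim$localization$circ, sim$localization$rbp)
  }

  class(res) <- "circ_screen"
  if (!is.null(out_dir)) {
    write_screen(res, out_dir, input_files = input_files)
  }
  res
}

#' Read a simulation directory back into memory
#'
#' Counterpart of [write_simulation()]: reads the annotation, expression,
#' caller tables, peaks, Alus, knockdown matrices, reads, GO and
#' localization tables with the package's format readers.
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list shaped like a `circ_simulation` (without ground truth).
#' @export
read_simulation <- function(dir) {
  p <- function(...) {
    f <- file.path(dir, ...)
    if (!file.exists(f)) stop("missing input file: ", f)
    f
  }
  opt <- function(...) {
    f <- file.path(dir, ...)
    if (file.exists(f)) f else NULL
  }
  expression <- utils::read.delim(p("expression.tsv"),
                                  stringsAsFactors = FALSE)
  models <- read_gene_models(p("annotation.gtf"), expression = expression)
  genome <- if (!is.null(opt("genome.fa"))) {
    Biostrings::readDNAStringSet(opt("genome.fa"))
  } else NULL
  if (!is.null(genome)) names(genome) <- sub(" .*", "", names(genome))
  sim <- list(
    annotation = list(models = models, expression = expression,
                      genome = genome),
    circs = list(
      calls_a = read_circ_calls(p("circ_calls_a.tsv")),
      calls_b = read_circ_calls(p("circ_calls_b.tsv"))),
    peaks_sim = list(
      peaks = read_binding_sites(p("eclip_peaks.tsv")),
      alus = read_bed(p("alu.bed")))
  )
  if (!is.null(opt("kd_counts.tsv"))) {
    cnt <- utils::read.delim(opt("kd_counts.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
    mat <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(mat) <- cnt$circ_id
    libs <- utils::read.delim(opt("kd_library_sizes.tsv"),
                              stringsAsFactors = FALSE)
    libs <- libs[match(colnames(mat), libs$sample), ]
    sim$kd <- list(counts = mat, condition = libs$condition,
                   library_sizes = libs$library_size)
  }
  fq <- list.files(dir, pattern = "^eclip_reads_.*\\.fastq$")
  if (length(fq)) {
    reads <- do.call(rbind, lapply(fq, function(f) {
      read_eclip_reads(file.path(dir, f),
                       sample = sub("^eclip_reads_(.*)\\.fastq$", "\\1", f))
    }))
    sim$reads_sim <- list(reads = reads)
  }
  if (!is.null(opt("go_annotations.tsv"))) {
    sim$go <- utils::read.delim(opt("go_annotations.tsv"),
                                stringsAsFactors = FALSE)
  }
  if (!is.null(opt("localization_circ.tsv"))) {
    sim$localization <- list(
      circ = utils::read.delim(opt("localization_circ.tsv"),
                               stringsAsFactors = FALSE),
      rbp = utils::read.delim(opt("localization_rbp.tsv"),
                              stringsAsFactors = FALSE))
  }
  sim
}

#' Write screen results with a reproducibility manifest
#'
#' @param res A `circ_screen` result list.
#' @param out_dir Output directory (created if needed).
#' @param input_files Input paths checksummed into the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_screen <- function(res, out_dir, input_files = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(res$catalog, p("catalog.tsv"))
  tsv(res$top, p("top_catalog.tsv"))
  tsv(res$circ_coverage, p("circ_rbp_coverage.tsv"))
  tsv(res$exon_table, p("exon_categories.tsv"))
  tsv(res$differential_binding, p("rbp_differential_binding.tsv"))
  tsv(data.frame(iteration = seq_along(res$resample$resampled_means),
                 mean_coverage = res$resample$resampled_means),
      p("resample_distribution.tsv"))
  tsv(res$flank_enrichment, p("flank_enrichment.tsv"))
  if (!is.null(res$go_enrichment)) {
    tsv(res$go_enrichment, p("go_enrichment.tsv"))
  }
  if (!is.null(res$junction_calls)) {
    tsv(res$junction_calls, p("bsj_junction_calls.tsv"))
  }
  summary <- screen_summary(res)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    schema_version = .schema_version,
    package = "circscreen",
    version = as.character(utils::packageVersion("circscreen")),
    seed = res$config$seed,
    config = unclass(res$config),
    input_checksums = if (length(input_files)) {
      ck <- tools::md5sum(input_files)
      names(ck) <- basename(input_files)
      as.list(ck)
    } else list()
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Headline numbers of a screen run
#'
#' @param res A `circ_screen` result list.
#' @return A named list of scalar summaries.
#' @export
screen_summary <- function(res) {
  out <- list(
    n_consensus_circrnas = nrow(res$catalog),
    n_top_circrnas = nrow(res$top),
    median_relative_ratio = stats::median(res$catalog$relative_ratio,
                                          na.rm = TRUE),
    mean_circ_rbp_coverage = mean(res$circ_coverage$rbp_coverage,
                                  na.rm = TRUE),
    resample_observed_mean = res$resample$observed_mean,
    resample_empirical_p = res$resample$empirical_p,
    n_rbps_differentially_bound = sum(res$differential_binding$significant)
  )
  if (!is.null(res$kd_flanked)) {
    out$kd_flanked_relative_change <- res$kd_flanked$relative_change
    out$kd_flanked_p <- res$kd_flanked$p
    out$kd_complement_p <- res$kd_complement$p
  }
  if (!is.null(res$junction_calls)) {
    out$n_junctions_called <- sum(res$junction_calls$called)
  }
  if (!is.null(res$colocalization)) {
    out$colocalization_pct <- res$colocalization$percent
  }
  if (!is.null(res$go_enrichment) && nrow(res$go_enrichment)) {
    out$top_go_term <- res$go_enrichment$term[1]
    out$top_go_fold <- res$go_enrichment$fold[1]
    out$top_go_p <- res$go_enrichment$p[1]
  }
  out
}

#' @export
print.circ_screen <- function(x, ...) {
  s <- screen_summary(x)
  cat("circscreen run:\n")
  for (nm in names(s)) {
    v <- s[[nm]]
    cat(sprintf("  %-32s %s\n", nm,
                if (is.numeric(v)) format(v, digits = 4) else v))
  }
  invisible(x)
}
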