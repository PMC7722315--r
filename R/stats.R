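#' Chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square with one degree of freedom. The Yates continuity
#' correction subtracts 0.5 from each |O - E| (capped at zero), the default
#' of R's `chisq.test()` for 2x2 tables.
#'
#' @param tbl 2x2 matrix of non-negative counts (rows = group,
#'   columns = outcome).
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return List with `statistic` and `p`; both `NA` when any table margin
#'   is zero.
#' @export
chi_square_2x2 <- function(tbl, yates = TRUE) {
  tbl <- as.matrix(tbl)
  stopifnot(identical(dim(tbl), c(2L, 2L)), all(tbl >= 0))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_))
  }
  ht <- suppressWarnings(stats::chisq.test(tbl, correct = yates))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' One-tailed Fisher's exact test for a 2x2 table
#'
#' Hypergeometric tail probability of tables at least as extreme as the
#' observed one in the stated direction, at fixed margins.
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @param direction `"greater"` (default) tests enrichment of the top-left
#'   cell; `"less"` tests depletion.
#' @return The one-tailed p-value.
#' @export
fisher_one_tailed <- function(tbl, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  tbl <- as.matrix(tbl)
  stopifnot(identical(dim(tbl), c(2L, 2L)), all(tbl >= 0))
  stats::fisher.test(tbl, alternative = direction)$p.value
}

#' Wilcoxon rank-sum test
#'
#' Exact when both samples are small and tie-free, otherwise the normal
#' approximation with tie and continuity corrections (the `wilcox.test()`
#' switch-over). Returns p = 1 when every value in both groups is
#' identical, where the ranking carries no information.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return The p-value.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, alternative = alternative)$p.value)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @return List with `t` and `p`; both `NA` (with a warning) when both
#'   groups have zero variance.
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("both groups have zero variance; t-test undefined")
    return(list(t = NA_real_, p = NA_real_))
  }
  ht <- stats::t.test(x, y)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and monotone in the
#' raw-p ranking.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Empirical p-value against a resampled null distribution
#'
#' Add-one tail estimator `(1 + #(null >= observed)) / (1 + length(null))`,
#' which can never return zero with finitely many resamples: with 100
#' resamples the floor is 1/101, reported as p < 0.01.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of resampled statistics.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null) {
  stopifnot(length(observed) == 1L, length(null) >= 1L)
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' GO term enrichment of an RBP subset
#'
#' For each GO term annotated to at least `min_rbps_per_term` background
#' RBPs, tests whether the subset is enriched for the term with a
#' one-tailed Fisher's exact test, and reports the fold enrichment
#' `(k/n) / (K/N)` (subset hit proportion over background hit proportion).
#'
#' @param subset_rbps Character vector, the RBPs of interest (must be a
#'   subset of `all_rbps`).
#' @param all_rbps Character vector of all background RBPs.
#' @param go_annotations Data frame with columns `rbp`, `term`, and
#'   optionally `domain`; annotations for RBPs outside `all_rbps` are
#'   ignored.
#' @param min_rbps_per_term Minimum distinct annotated RBPs for a term to be
#'   tested (default 2).
#' @return Data frame per qualifying term: `term`, `domain` (if supplied),
#'   `subset_hits`, `background_hits`, `fold`, `p`, ordered by `p`.
#' @export
go_enrichment <- function(subset_rbps, all_rbps, go_annotations,
                          min_rbps_per_term = 2L) {
  if (!all(subset_rbps %in% all_rbps)) {
    stop("subset_rbps must be contained in all_rbps")
  }
  ann <- go_annotations[go_annotations$rbp %in% all_rbps, , drop = FALSE]
  ann <- unique(ann[, intersect(c("rbp", "term", "domain"), names(ann)),
                    drop = FALSE])
  counts <- table(ann$term)
  terms <- names(counts)[counts >= min_rbps_per_term]
  n <- length(subset_rbps)
  N <- length(all_rbps)
  res <- lapply(terms, function(tm) {
    hit_rbps <- unique(ann$rbp[ann$term == tm])
    k <- sum(subset_rbps %in% hit_rbps)
    K <- length(hit_rbps)
    tbl <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
    data.frame(
      term = tm,
      domain = if ("domain" %in% names(ann)) {
        ann$domain[match(tm, ann$term)]
      } else NA_character_,
      subset_hits = k,
      background_hits = K,
      fold = (k / n) / (K / N),
      p = fisher_one_tailed(tbl, "greater"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(term = character(), domain = character(),
                      subset_hits = integer(), background_hits = integer(),
                      fold = numeric(), p = numeric())
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subcellular co-localization of predicted circRNA-RBP interactions
#'
#' An interaction is co-localized when the circRNA and the RBP share at
#' least one subcellular compartment. Pairs whose circRNA or RBP is missing
#' from the localization tables are excluded from the percentage and
#' counted as unresolved.
#'
#' @param interactions Data frame with columns `circ_id` and `rbp`.
#' @param circ_compartments Data frame with columns `circ_id`,
#'   `compartment` (one row per circRNA-compartment pair).
#' @param rbp_compartments Data frame with columns `rbp`, `compartment`.
#' @return List with `percent` (co-localized percentage of resolved pairs),
#'   `n_resolved`, `n_colocalized`, `n_unresolved`.
#' @export
colocalization_fraction <- function(interactions, circ_compartments,
                                    rbp_compartments) {
  circ_sets <- split(circ_compartments$compartment, circ_compartments$circ_id)
  rbp_sets <- split(rbp_compartments$compartment, rbp_compartments$rbp)
  resolved <- interactions$circ_id %in% names(circ_sets) &
    interactions$rbp %in% names(rbp_sets)
  pairs <- interactions[resolved, , drop = FALSE]
  coloc <- mapply(function(ci, rb) {
    length(intersect(circ_sets[[ci]], rbp_sets[[rb]])) > 0L
  }, pairs$circ_id, pairs$rbp, USE.NAMES = FALSE)
  n_res <- nrow(pairs)
  list(
    percent = if (n_res > 0L) 100 * sum(coloc) / n_res else NA_real_,
    n_resolved = n_res,
    n_colocalized = if (n_res > 0L) sum(coloc) else 0L,
    n_unresolved = sum(!resolved)
  )
}
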