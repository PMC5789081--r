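#' Per-cluster transcription-factor enrichment
#'
#' For every (cluster, TF) pair, tests over-representation of the TF's target
#' genes inside the cluster with the one-sided Fisher test
#' ([fisher_overrep()]). The background defaults to the union of all
#' clustered genes. TFs with no target in the background are skipped. As in
#' the enrichment rule used for cascade construction, significance is an
#' uncorrected `p < alpha` (pathway over-representation, by contrast, is
#' FDR-corrected: see [pathway_ora()]).
#'
#' @param clustering A `gene_clustering`.
#' @param kb A `tf_kb`.
#' @param background Background gene set; must contain every clustered gene.
#' @param alpha Per-test enrichment threshold (default 0.05).
#' @return A `tf_enrichment`: data frame with columns `cluster`, `tf`,
#'   `k_overlap`, `m_targets`, `n_cluster`, `p`, `enriched`.
#' @export
tf_enrichment_per_cluster <- function(clustering, kb, background = NULL,
                                      alpha = 0.05) {
  genes <- names(clustering$assignment)
  if (is.null(background)) background <- genes
  if (!all(genes %in% background))
    stop("background must contain every clustered gene")
  background <- unique(background)
  N <- length(background)
  tsets <- kb_target_sets(kb)
  tsets <- lapply(tsets, intersect, background)
  skipped <- names(tsets)[lengths(tsets) == 0]
  if (length(skipped))
    message(length(skipped), " TF(s) with no target in background skipped")
  tsets <- tsets[lengths(tsets) > 0]
  rows <- list()
  for (k in seq_len(clustering$K)) {
    members <- genes[clustering$assignment == k]
    n <- length(members)
    for (f in names(tsets)) {
      kk <- length(intersect(tsets[[f]], members))
      m <- length(tsets[[f]])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, tf = f, k_overlap = kk, m_targets = m, n_cluster = n,
        p = fisher_overrep(kk, m, n, N), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # alpha >= 1 is the degenerate "flag everything tested" setting
  out$enriched <- out$p < alpha | alpha >= 1
  attr(out, "alpha") <- alpha
  class(out) <- c("tf_enrichment", "data.frame")
  out
}

#' Pathway over-representation analysis (ORA)
#'
#' Hypergeometric over-representation of a gene list in each set of a
#' collection (e.g. KEGG pathways from a GMT), BH-adjusted across the sets of
#' the collection; significance at `adj_p < fdr`.
#'
#' @param gene_list Character vector of genes (must be a subset of
#'   `background`).
#' @param collection A [gene_set_collection()] (already size-filtered).
#' @param background Character vector: the gene universe for the test.
#' @param fdr FDR threshold (default 0.05).
#' @return An `ora_result`: data frame with columns `set`, `k`, `m`,
#'   `n_list`, `p`, `adj_p`, `significant`, ordered by p.
#' @export
pathway_ora <- function(gene_list, collection, background, fdr = 0.05) {
  gene_list <- unique(gene_list)
  if (length(gene_list) == 0) stop("empty gene list")
  background <- unique(background)
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("gene list not contained in background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], background)
    if (length(s) == 0) return(NULL)
    k <- length(intersect(s, gene_list))
    data.frame(set = nm, k = k, m = length(s), n_list = n,
               p = fisher_overrep(k, length(s), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no collection set overlaps the background")
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < fdr
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Overlap of DE sets with curated signatures
#'
#' For every (condition, signature) pair, reports the percentage of the
#' signature's genes that are DE in the condition and the hypergeometric
#' overlap p-value at a fixed symbol universe (default 41220 approved
#' symbols). Signatures should be pre-filtered to a minimum size (the
#' collection's `min_size`, conventionally 30).
#'
#' @param de_sets_by_condition Named list: condition -> DE gene set.
#' @param signatures A [gene_set_collection()].
#' @param universe_size Symbol universe size.
#' @param alpha Significance mark threshold on the raw p (default 0.05).
#' @return Data frame with columns `condition`, `signature`, `sig_size`,
#'   `k`, `percent`, `p`, `significant`.
#' @export
signature_overlap <- function(de_sets_by_condition, signatures,
                              universe_size = 41220, alpha = 0.05) {
  rows <- list()
  for (cond in names(de_sets_by_condition)) {
    de <- unique(de_sets_by_condition[[cond]])
    for (nm in names(signatures)) {
      sig <- signatures[[nm]]
      res <- hypergeom_overlap_test(sig, de, universe_size)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, signature = nm, sig_size = length(sig),
        k = res$k, percent = res$percent, p = res$p,
        significant = res$p < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Directional test of clusters against an external contrast
#'
#' For each cluster, asks whether its member genes rank high ("up") or low
#' ("down") among the log2 fold changes of an external contrast (e.g. an
#' insulin-resistance model), using [mean_rank_gene_set_test()] with both
#' one-sided alternatives. The reported direction is the smaller one-sided
#' p-value; both p-values are retained. Genes without an external statistic
#' are dropped; at least 80% of clustered genes must be covered, and clusters
#' with fewer than `min_covered` covered genes are flagged untested.
#'
#' @param clustering A `gene_clustering`.
#' @param external_stats Named numeric vector of per-gene log2 fold changes.
#' @param min_covered Minimum covered genes for a cluster to be tested.
#' @param min_coverage Minimum overall coverage fraction (default 0.8).
#' @return Data frame with columns `cluster`, `n_members`, `n_covered`,
#'   `p_up`, `p_down`, `direction`, `tested`.
#' @export
cluster_direction_test <- function(clustering, external_stats,
                                   min_covered = 5, min_coverage = 0.8) {
  if (is.null(names(external_stats)))
    stop("external_stats must be a named numeric vector")
  genes <- names(clustering$assignment)
  covered <- intersect(genes, names(external_stats))
  if (length(covered) / length(genes) < min_coverage)
    stop("external statistics cover only ",
         round(100 * length(covered) / length(genes)), "% of clustered genes ",
         "(need >= ", round(100 * min_coverage), "%)")
  dropped <- length(genes) - length(covered)
  if (dropped > 0)
    message(dropped, " clustered gene(s) without external statistic dropped")
  rows <- lapply(seq_len(clustering$K), function(k) {
    members <- intersect(genes[clustering$assignment == k], names(external_stats))
    if (length(members) < min_covered ||
        length(members) >= length(external_stats)) {
      return(data.frame(cluster = k, n_members = clustering$sizes[k],
                        n_covered = length(members), p_up = NA_real_,
                        p_down = NA_real_, direction = NA_character_,
                        tested = FALSE, stringsAsFactors = FALSE))
    }
    p_up <- mean_rank_gene_set_test(external_stats, members, "up")
    p_down <- mean_rank_gene_set_test(external_stats, members, "down")
    data.frame(cluster = k, n_members = clustering$sizes[k],
               n_covered = length(members), p_up = p_up, p_down = p_down,
               direction = if (p_up <= p_down) "up" else "down",
               tested = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
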