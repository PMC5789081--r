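#' Standardised temporal log2 fold-change profiles
#'
#' Builds the gene-by-time matrix of log2 fold changes for a set of genes and
#' z-standardises each row (mean 0, unit variance across timepoints), so
#' clustering responds to profile shape rather than magnitude. Rows that are
#' constant across time become all-zero.
#'
#' @param det A `de_table` for a single condition containing every requested
#'   gene at every timepoint.
#' @param genes Genes to profile; default the DE union of `det`.
#' @return A `profile_matrix`: list with `values` (gene x time matrix),
#'   `times` (ordered timepoints) and `genes`.
#' @export
build_profiles <- function(det, genes = NULL) {
  if (length(unique(det$condition)) > 1)
    stop("profiles are built from a single condition's DE table")
  if (is.null(genes)) genes <- unique(det$gene[det$is_de])
  if (length(genes) == 0) stop("no genes to profile")
  times <- sort(unique(det$time_h))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(times),
              dimnames = list(genes, as.character(times)))
  for (i in seq_along(times)) {
    sub <- det[det$time_h == times[i], ]
    idx <- match(genes, sub$gene)
    if (any(is.na(idx)))
      stop("gene(s) missing at ", times[i], " h: ",
           paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
    m[, i] <- sub$log2FC[idx]
  }
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdev == 0, 1, sdev)
  z[sdev == 0, ] <- 0
  structure(list(values = z, times = times, genes = genes),
            class = "profile_matrix")
}

new_clustering <- function(assignment, values) {
  K <- max(assignment)
  if (any(tabulate(assignment, K) == 0)) stop("empty cluster in assignment")
  centers <- do.call(rbind, lapply(seq_len(K), function(k) {
    colMeans(values[assignment == k, , drop = FALSE])
  }))
  rownames(centers) <- seq_len(K)
  structure(list(K = K,
                 assignment = assignment,
                 centers = centers,
                 sizes = tabulate(assignment, K)),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat("gene_clustering: K =", x$K, "clusters over", length(x$assignment),
      "genes\nsizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of temporal profiles
#'
#' Agglomerative clustering with Euclidean distance and Ward's
#' squared-distance linkage (`ward.D2`), cut to exactly `K` groups. Each gene
#' receives a single cluster membership; the result is deterministic.
#'
#' @param profiles A [build_profiles()] result.
#' @param K Number of clusters (2 <= K <= number of genes).
#' @return A `gene_clustering`: list with `K`, named `assignment` (gene ->
#'   cluster id), `centers` (mean standardised profile per cluster) and
#'   `sizes`.
#' @export
hierarchical_clusters <- function(profiles, K) {
  n <- nrow(profiles$values)
  if (K < 1 || K > n) stop("K must lie between 1 and the gene count (", n, ")")
  hc <- stats::hclust(stats::dist(profiles$values, method = "euclidean"),
                      method = "ward.D2")
  assignment <- stats::cutree(hc, k = K)
  new_clustering(assignment, profiles$values)
}

cluster_with_method <- function(profiles, K, method, seed = NULL) {
  if (method == "hierarchical") return(hierarchical_clusters(profiles, K))
  if (!is.null(seed)) set.seed(seed)
  if (method == "kmeans") {
    km <- stats::kmeans(profiles$values, centers = K, nstart = 10,
                        iter.max = 50)
    assignment <- km$cluster
  } else if (method == "cmeans") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("the 'e1071' package is required for fuzzy c-means")
    cm <- e1071::cmeans(profiles$values, centers = K, iter.max = 100)
    assignment <- apply(cm$membership, 1, which.max)
    names(assignment) <- rownames(profiles$values)
  } else stop("unknown clustering method: ", method)
  # guard against empty clusters from degenerate runs
  used <- sort(unique(assignment))
  assignment <- match(assignment, used)
  names(assignment) <- rownames(profiles$values)
  new_clustering(assignment, profiles$values)
}

#' Knowledge-based enrichment score of a clustering
#'
#' Scores how well known TF target sets co-cluster. For each cluster, every
#' TF with at least one target in the background is tested for
#' over-representation of its targets in the cluster (one-sided Fisher test,
#' background = the clustered genes). Two raw scores are available:
#' `"neglogp"` (default) is the mean over clusters of the strongest
#' enrichment, `-log10(min p)`, counting clusters with no TF below `alpha`
#' as 0; `"fraction"` is the fraction of clusters containing at least one TF
#' set enriched at `p < alpha`.
#'
#' @param clustering A `gene_clustering`.
#' @param kb A `tf_kb`.
#' @param alpha Enrichment threshold (default 0.05).
#' @param score_type `"neglogp"` or `"fraction"`.
#' @param background Background gene set; default the clustered genes.
#' @return Raw score (non-negative; 0 when no cluster shows enrichment).
#' @export
cluster_enrichment_score <- function(clustering, kb, alpha = 0.05,
                                     score_type = c("neglogp", "fraction"),
                                     background = NULL) {
  score_type <- match.arg(score_type)
  if (length(clustering$assignment) == 0) stop("empty clustering")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(background)) background <- names(clustering$assignment)
  N <- length(background)
  tsets <- kb_target_sets(kb)
  tsets <- lapply(tsets, intersect, background)
  tsets <- tsets[lengths(tsets) > 0]
  per_cluster_min_p <- vapply(seq_len(clustering$K), function(k) {
    members <- names(clustering$assignment)[clustering$assignment == k]
    members <- intersect(members, background)
    if (length(tsets) == 0 || length(members) == 0) return(1)
    p <- vapply(tsets, function(tg) {
      fisher_overrep(length(intersect(tg, members)), length(tg),
                     length(members), N)
    }, numeric(1))
    min(p)
  }, numeric(1))
  if (score_type == "fraction") {
    mean(per_cluster_min_p < alpha)
  } else {
    mean(ifelse(per_cluster_min_p < alpha, -log10(per_cluster_min_p), 0))
  }
}

#' Select the number of clusters by knowledge-base enrichment
#'
#' Clusters the profiles at every candidate K (and with every requested
#' method), scores each partition with [cluster_enrichment_score()], and
#' normalises the scores by their maximum so the best configuration scores
#' exactly 1. Hierarchical clustering is deterministic; k-means and c-means
#' are re-seeded deterministically from `seed` for each K.
#'
#' @param profiles A [build_profiles()] result.
#' @param kb A `tf_kb`.
#' @param k_range Candidate cluster numbers.
#' @param methods Subset of `c("hierarchical", "kmeans", "cmeans")`.
#' @param alpha Enrichment threshold.
#' @param seed Seed for stochastic methods.
#' @param score_type Passed to [cluster_enrichment_score()].
#' @return List with `curve` (data frame `method, k, raw_score,
#'   normalized_score`), `best_k`, `best_method` and `clustering` (the best
#'   partition). If no candidate shows any knowledge-base signal, a warning
#'   is raised and K falls back to the heuristic `sqrt(n/2)` (clipped to
#'   `k_range`), clustered hierarchically.
#' @export
select_optimal_k <- function(profiles, kb, k_range = 2:12,
                             methods = "hierarchical", alpha = 0.05,
                             seed = 1L, score_type = c("neglogp", "fraction")) {
  score_type <- match.arg(score_type)
  if (length(k_range) == 0) stop("k_range is empty")
  methods <- match.arg(methods, c("hierarchical", "kmeans", "cmeans"),
                       several.ok = TRUE)
  grid <- expand.grid(method = methods, k = sort(k_range),
                      stringsAsFactors = FALSE)
  clusterings <- vector("list", nrow(grid))
  raw <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cl <- cluster_with_method(profiles, grid$k[i], grid$method[i],
                              seed = seed + grid$k[i])
    clusterings[[i]] <- cl
    raw[i] <- cluster_enrichment_score(cl, kb, alpha = alpha,
                                       score_type = score_type)
  }
  if (max(raw) == 0) {
    warning("no knowledge-base enrichment signal at any K; ",
            "falling back to the sqrt(n/2) heuristic")
    k_fallback <- round(sqrt(nrow(profiles$values) / 2))
    k_fallback <- min(max(k_fallback, min(k_range)), max(k_range))
    best_cl <- hierarchical_clusters(profiles, k_fallback)
    curve <- data.frame(grid, raw_score = raw, normalized_score = raw)
    return(list(curve = curve, best_k = k_fallback,
                best_method = "hierarchical", clustering = best_cl,
                fallback = TRUE))
  }
  normalized <- raw / max(raw)
  # ties: prefer the first listed method, then the smallest K
  best <- which(normalized == 1)[1]
  curve <- data.frame(grid, raw_score = raw, normalized_score = normalized)
  names(curve)[1:2] <- c("method", "k")
  list(curve = curve, best_k = grid$k[best], best_method = grid$method[best],
       clustering = clusterings[[best]], fallback = FALSE)
}

#' Write cluster membership to TSV (`gene, cluster`)
#' @param clustering A `gene_clustering`.
#' @param path Output path.
#' @export
write_clusters <- function(clustering, path) {
  df <- data.frame(gene = names(clustering$assignment),
                   cluster = unname(clustering$assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
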