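#' Built-in temporal profile templates
#'
#' Unit-scale log2 fold-change shapes over the default timepoints
#' (2, 4, 8, 24 h). The first eight are distinct non-constant shapes used for
#' planted clusters; `flat_up` / `flat_down` plant a constant fold change at
#' every timepoint (useful for pure DE benchmarks, not for clustering).
#'
#' @param times Timepoints the templates are defined over (must be length 4).
#' @return Numeric matrix, templates x timepoints.
#' @export
profile_templates <- function(times = c(2, 4, 8, 24)) {
  if (length(times) != 4) stop("built-in templates are defined over 4 timepoints")
  m <- rbind(
    early_up       = c(1.00, 0.60, 0.25, 0.05),
    transient_up   = c(0.20, 1.00, 0.50, 0.05),
    late_up        = c(0.05, 0.15, 0.45, 1.00),
    early_down     = -c(1.00, 0.60, 0.25, 0.05),
    transient_down = -c(0.20, 1.00, 0.50, 0.05),
    late_down      = -c(0.05, 0.15, 0.45, 1.00),
    sustained_up   = c(0.55, 0.75, 0.90, 1.00),
    down_recover   = c(-1.00, -0.60, -0.20, 0.10),
    flat_up        = c(1, 1, 1, 1),
    flat_down      = -c(1, 1, 1, 1))
  colnames(m) <- as.character(times)
  m
}

#' Simulation configuration
#'
#' Defines the study design emulated by the generator: 2 replicates of each
#' of 4 timepoints (2, 4, 8, 24 h) under conditions control / drugA / drugB /
#' both, with the transcriptional response concentrated in the combined
#' condition (effect multipliers 0 / 0.3 / 0.3 / 1). Planted genes fall into
#' `k_true` temporal clusters of `cluster_size` genes, each following one
#' profile template scaled by `effect_size` (log2 units), on top of a
#' gene-specific baseline and Gaussian noise on the log2 scale.
#'
#' @param n_genes Total genes (planted + background).
#' @param n_tfs Total TFs in the knowledge base (cascade drivers + decoys).
#' @param targets_per_tf Range (min, max) of decoy target-set sizes.
#' @param k_true Number of planted clusters (<= number of templates used).
#' @param templates Template matrix as from [profile_templates()]; rows beyond
#'   `k_true` are unused.
#' @param effect_size Peak |log2FC| per cluster; scalar or length `k_true`.
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param n_replicates Replicates per condition-timepoint.
#' @param times Timepoints in hours.
#' @param conditions Named vector of effect multipliers in \[0, 1\]; must
#'   include a zero-multiplier control.
#' @param cluster_size Genes per planted cluster.
#' @param reversal_fraction Fraction of planted genes whose effect an
#'   anti-oxidant co-treatment abolishes (used by [simulate_reversal()]).
#' @param noise_family `"gaussian"` (default) or `"t"` (heavier-tailed,
#'   scaled Student t with 3 df).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, n_tfs = 50, targets_per_tf = c(20, 60),
                       k_true = 6, templates = profile_templates(),
                       effect_size = 2, noise_sd = 0.25, n_replicates = 2,
                       times = c(2, 4, 8, 24),
                       conditions = c(control = 0, drugA = 0.3, drugB = 0.3,
                                      both = 1),
                       cluster_size = 40, reversal_fraction = 0.5,
                       noise_family = c("gaussian", "t"), seed = 1L) {
  noise_family <- match.arg(noise_family)
  if (noise_sd <= 0) stop("noise_sd must be positive (zero noise degenerates ",
                          "the t-statistics)")
  if (k_true > nrow(templates))
    stop("k_true exceeds the number of profile templates")
  if (any(conditions < 0) || any(conditions > 1))
    stop("condition effect multipliers must lie in [0, 1]")
  if (!any(conditions == 0))
    stop("at least one condition must be a zero-multiplier control")
  if (n_tfs < k_true + 1)
    stop("need at least k_true + 1 TFs (cascade drivers plus a terminal TF)")
  if (max(targets_per_tf) > n_genes)
    stop("targets_per_tf exceeds the gene count")
  n_planted <- k_true * cluster_size
  n_decoys <- n_tfs - (k_true + 1)
  if (n_genes < n_planted + 1 + n_decoys + max(targets_per_tf))
    stop("n_genes too small for the requested planted structure")
  if (length(effect_size) == 1) effect_size <- rep(effect_size, k_true)
  if (length(effect_size) != k_true)
    stop("effect_size must be scalar or length k_true")
  if (reversal_fraction < 0 || reversal_fraction > 1)
    stop("reversal_fraction must lie in [0, 1]")
  structure(list(n_genes = n_genes, n_tfs = n_tfs,
                 targets_per_tf = targets_per_tf, k_true = k_true,
                 templates = templates[, as.character(times), drop = FALSE],
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_replicates = n_replicates, times = times,
                 conditions = conditions, cluster_size = cluster_size,
                 reversal_fraction = reversal_fraction,
                 noise_family = noise_family, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a TF-target knowledge base with a planted cascade
#'
#' Each planted cluster c is the exact rank-1 target set of one driver TF
#' D_c. Drivers are chained: for c >= 2, D_c is itself a member gene of
#' cluster c-1 (so it is DE with cluster c-1's profile and a target of
#' D_(c-1)), planting the connector D_c: cluster (c-1) -> cluster c. D_1 is a
#' background (non-DE) gene, emulating an upstream-only regulator controlled
#' post-translationally. One member of the last cluster is additionally
#' annotated as a TF with a small random target set, so the terminal driver
#' also regulates a TF. Remaining TFs are decoys with random target sets at
#' mixed evidence ranks 1-3.
#'
#' @param config A [sim_config()].
#' @return List with `kb` (a `tf_kb` including rank-3 decoy edges; filter
#'   with [tf_kb()] or [read_tf_kb()] as desired) and `truth` (planted
#'   assignment, drivers, upstream TF-cluster pairs, connectors, TF genes).
#' @export
simulate_kb <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$k_true; cs <- config$cluster_size
  genes <- sim_gene_ids(config$n_genes)
  clusters <- lapply(seq_len(k), function(c)
    genes[((c - 1) * cs + 1):(c * cs)])
  planted <- unlist(clusters)
  background <- setdiff(genes, planted)
  root <- background[1]
  drivers <- c(root, vapply(seq_len(k - 1), function(c) clusters[[c]][1],
                            character(1)))
  terminal_tf <- clusters[[k]][1]
  n_decoys <- config$n_tfs - (k + 1)
  decoys <- background[seq_len(n_decoys) + 1]
  edges <- list()
  for (c in seq_len(k)) {
    edges[[length(edges) + 1L]] <- data.frame(
      tf = drivers[c], tg = clusters[[c]], rank = 1L, stringsAsFactors = FALSE)
  }
  edges[[length(edges) + 1L]] <- data.frame(
    tf = terminal_tf, tg = sample(background[-seq_len(n_decoys + 1)], 10),
    rank = 1L, stringsAsFactors = FALSE)
  for (d in decoys) {
    lo <- config$targets_per_tf[1]; hi <- config$targets_per_tf[2]
    size <- if (lo == hi) lo else sample(seq(lo, hi), 1)
    edges[[length(edges) + 1L]] <- data.frame(
      tf = d, tg = sample(genes, size),
      rank = sample(1:3, size, replace = TRUE), stringsAsFactors = FALSE)
  }
  kb <- tf_kb(do.call(rbind, edges))
  assignment <- stats::setNames(rep(seq_len(k), each = cs), planted)
  connectors <- if (k >= 2) data.frame(
    tf = drivers[-1], from_cluster = seq_len(k - 1),
    to_cluster = 2:k, stringsAsFactors = FALSE
  ) else data.frame(tf = character(), from_cluster = integer(),
                    to_cluster = integer())
  truth <- list(assignment = assignment,
                drivers = stats::setNames(drivers, seq_len(k)),
                terminal_tf = terminal_tf,
                upstream = data.frame(tf = drivers, cluster = seq_len(k),
                                      stringsAsFactors = FALSE),
                connectors = connectors,
                tf_genes = c(drivers, terminal_tf, decoys))
  list(kb = kb, truth = truth)
}

sim_noise <- function(n, sd, family) {
  if (family == "gaussian") stats::rnorm(n, 0, sd)
  else sd * stats::rt(n, df = 3) / sqrt(3)
}

# Assemble an expression matrix from per-condition true-lfc matrices.
sim_expression <- function(genes, baseline, lfc_by_condition, times,
                           n_replicates, noise_sd, noise_family) {
  conds <- names(lfc_by_condition)
  n <- length(genes)
  cols <- list(); ids <- character(); meta <- list()
  for (cond in conds) {
    lfc <- lfc_by_condition[[cond]]
    for (ti in seq_along(times)) {
      for (r in seq_len(n_replicates)) {
        cols[[length(cols) + 1L]] <- baseline + lfc[, ti] +
          sim_noise(n, noise_sd, noise_family)
        ids <- c(ids, sprintf("%s_t%02d_r%d", cond, times[ti], r))
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = ids[length(ids)], condition = cond,
          time_h = times[ti], replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(genes, ids)
  expression_matrix(values, do.call(rbind, meta))
}

#' Simulate a multi-condition time-course expression matrix
#'
#' Expression = baseline + multiplier x effect_size x template(time) for
#' planted genes, plus noise everywhere; controls have multiplier 0. The
#' planted structure (including the cascade drivers, which are members of the
#' preceding cluster) comes from [simulate_kb()].
#'
#' @param sim Result of [simulate_kb()] (provides the planted structure).
#' @param config The same [sim_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth`, the
#'   `sim$truth` extended with `true_lfc` (per condition, gene x time matrix
#'   of planted log2 fold changes vs control).
#' @export
simulate_timecourse <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- sim_gene_ids(config$n_genes)
  baseline <- stats::runif(config$n_genes, 6, 10)
  k <- config$k_true
  tmpl <- config$templates[seq_len(k), , drop = FALSE]
  base_lfc <- matrix(0, nrow = config$n_genes, ncol = length(config$times),
                     dimnames = list(genes, as.character(config$times)))
  for (c in seq_len(k)) {
    members <- names(sim$truth$assignment)[sim$truth$assignment == c]
    base_lfc[members, ] <- matrix(config$effect_size[c] * tmpl[c, ],
                                  nrow = length(members),
                                  ncol = length(config$times), byrow = TRUE)
  }
  lfc_by_condition <- lapply(config$conditions, function(mult) mult * base_lfc)
  expr <- sim_expression(genes, baseline, lfc_by_condition, config$times,
                         config$n_replicates, config$noise_sd,
                         config$noise_family)
  truth <- sim$truth
  truth$true_lfc <- lfc_by_condition
  list(expr = expr, truth = truth)
}

#' Simulate knowledge base and expression in one call
#'
#' @param config A [sim_config()].
#' @return List with `kb`, `expr` and `truth`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_kb(config)
  tc <- simulate_timecourse(sim, config)
  list(kb = sim$kb, expr = tc$expr, truth = tc$truth)
}

#' Simulate an anti-oxidant reversal experiment
#'
#' Three conditions: control, a perturbation model (full planted effect), and
#' the model co-treated with an anti-oxidant (AO) that abolishes the effect
#' of a random `reversal_fraction` of the planted genes (their expression
#' returns to control level, so the model+AO vs model contrast is DE in the
#' opposite direction); non-reversed genes keep the full model effect.
#'
#' @param config A [sim_config()] (uses `reversal_fraction`).
#' @return List with `expr`, `truth` (including `reversed` genes and
#'   per-condition `true_lfc` where `model_AO` is expressed vs control).
#' @export
simulate_reversal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_kb(config)
  set.seed(config$seed + 2L)
  genes <- sim_gene_ids(config$n_genes)
  baseline <- stats::runif(config$n_genes, 6, 10)
  k <- config$k_true
  tmpl <- config$templates[seq_len(k), , drop = FALSE]
  model_lfc <- matrix(0, nrow = config$n_genes, ncol = length(config$times),
                      dimnames = list(genes, as.character(config$times)))
  for (c in seq_len(k)) {
    members <- names(sim$truth$assignment)[sim$truth$assignment == c]
    model_lfc[members, ] <- matrix(config$effect_size[c] * tmpl[c, ],
                                   nrow = length(members),
                                   ncol = length(config$times), byrow = TRUE)
  }
  planted <- names(sim$truth$assignment)
  reversed <- sample(planted, round(config$reversal_fraction * length(planted)))
  ao_lfc <- model_lfc
  ao_lfc[reversed, ] <- 0
  lfc_by_condition <- list(control = model_lfc * 0, model = model_lfc,
                           model_AO = ao_lfc)
  expr <- sim_expression(genes, baseline, lfc_by_condition, config$times,
                         config$n_replicates, config$noise_sd,
                         config$noise_family)
  truth <- sim$truth
  truth$true_lfc <- lfc_by_condition
  truth$reversed <- reversed
  list(expr = expr, truth = truth)
}

#' Recovery metrics against simulation truth
#'
#' Dispatches on the predicted object:
#' * `de_table`: per-timepoint precision, recall and empirical FDR of the DE
#'   calls against the planted fold changes (a gene is truly DE at a
#'   timepoint when its planted |log2FC| exceeds `lfc_threshold`).
#' * `gene_clustering`: adjusted Rand index against the planted assignment
#'   (over planted genes present in the clustering).
#' * `cascade_graph`: connector precision and recall; predicted cluster ids
#'   are mapped to planted clusters by majority overlap (pass the clustering
#'   used to build the graph).
#'
#' @param predicted A `de_table`, `gene_clustering` or `cascade_graph`.
#' @param truth A simulation `truth` list.
#' @param ... Method-specific arguments (`lfc_threshold` for DE tables;
#'   `clustering` for cascade graphs).
#' @return A data frame or list of metrics; see the methods.
#' @export
evaluate_recovery <- function(predicted, truth, ...) {
  UseMethod("evaluate_recovery")
}

#' @rdname evaluate_recovery
#' @export
evaluate_recovery.de_table <- function(predicted, truth,
                                       lfc_threshold = 0.5, ...) {
  cond <- unique(predicted$condition)
  if (length(cond) != 1) stop("DE recovery is evaluated per condition")
  true_lfc <- truth$true_lfc[[cond]]
  if (is.null(true_lfc)) stop("condition absent from truth: ", cond)
  times <- sort(unique(predicted$time_h))
  rows <- lapply(times, function(t_h) {
    sub <- predicted[predicted$time_h == t_h, ]
    idx <- match(rownames(true_lfc), sub$gene)
    if (any(is.na(idx))) stop("gene universe mismatch with truth")
    pred <- sub$is_de[idx]
    truly <- abs(true_lfc[, as.character(t_h)]) > lfc_threshold
    tp <- sum(pred & truly); fp <- sum(pred & !truly); fn <- sum(!pred & truly)
    data.frame(time_h = t_h, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fdr = fp / max(1, tp + fp))
  })
  do.call(rbind, rows)
}

map_clusters_to_truth <- function(clustering, truth) {
  vapply(seq_len(clustering$K), function(k) {
    members <- names(clustering$assignment)[clustering$assignment == k]
    lab <- truth$assignment[intersect(members, names(truth$assignment))]
    if (length(lab) == 0) return(NA_integer_)
    as.integer(names(which.max(table(lab))))
  }, integer(1))
}

#' @rdname evaluate_recovery
#' @export
evaluate_recovery.gene_clustering <- function(predicted, truth, ...) {
  common <- intersect(names(predicted$assignment), names(truth$assignment))
  if (length(common) == 0) stop("no planted genes in the clustering")
  list(ari = adjusted_rand_index(predicted$assignment[common],
                                 truth$assignment[common]),
       n_common = length(common),
       coverage = length(common) / length(truth$assignment))
}

#' @rdname evaluate_recovery
#' @export
evaluate_recovery.cascade_graph <- function(predicted, truth,
                                            clustering = NULL, ...) {
  if (is.null(clustering))
    stop("pass the clustering used to build the cascade graph")
  cmap <- map_clusters_to_truth(clustering, truth)
  conn <- predicted$connectors
  conn <- conn[!conn$self, , drop = FALSE]
  pred_keys <- if (nrow(conn)) paste(conn$tf, cmap[conn$from_cluster],
                                     cmap[conn$to_cluster]) else character()
  true_keys <- paste(truth$connectors$tf, truth$connectors$from_cluster,
                     truth$connectors$to_cluster)
  overlap <- length(intersect(unique(pred_keys), unique(true_keys)))
  list(n_predicted = length(unique(pred_keys)),
       n_true = length(unique(true_keys)),
       precision = if (length(pred_keys)) overlap / length(unique(pred_keys))
                   else NA_real_,
       recall = if (length(true_keys)) overlap / length(unique(true_keys))
                else NA_real_)
}
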