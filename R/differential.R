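#' Differential-expression configuration
#'
#' Thresholds and time-period definitions used throughout the pipeline. A
#' gene is differentially expressed (DE) at a timepoint when its absolute
#' log2 fold change exceeds `lfc_threshold` AND its BH-adjusted p-value is
#' below `fdr_threshold`. "Early" and "late" are unions over the listed
#' timepoints.
#'
#' @param lfc_threshold Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_threshold Adjusted p-value threshold (default 0.05).
#' @param early_times Timepoints (h) defining the early response.
#' @param late_times Timepoints (h) defining the late response.
#' @return A `de_config`.
#' @export
de_config <- function(lfc_threshold = 0.5, fdr_threshold = 0.05,
                      early_times = c(2, 4, 8), late_times = 24) {
  if (lfc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  if (length(intersect(early_times, late_times)))
    stop("early and late time sets must be disjoint")
  structure(list(lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
                 early_times = early_times, late_times = late_times),
            class = "de_config")
}

#' Per-timepoint differential expression against time-matched controls
#'
#' At each timepoint, the treatment replicates are contrasted with the
#' time-matched control replicates using the moderated t-test
#' ([moderated_t_test()]); each contrast estimates its own variance prior
#' across all genes and is BH-adjusted within itself. DE flags are set per
#' [de_config()].
#'
#' @param expr An [expression_matrix()].
#' @param treatment,control Condition labels from the sample sheet.
#' @param config A [de_config()].
#' @param times Timepoints (h) to test; default all timepoints at which the
#'   treatment condition is present.
#' @param prior Optional fixed `variance_prior` applied to every contrast
#'   (mainly for simulation studies); default estimates one per contrast.
#' @return A `de_table`: data frame with one row per (gene, time_h) and
#'   columns `gene`, `condition`, `time_h`, `log2FC`, `t`, `df_total`, `p`,
#'   `adj_p`, `is_de`.
#' @export
run_de_timecourse <- function(expr, treatment, control, config = de_config(),
                              times = NULL, prior = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  sheet <- expr$samples
  if (!treatment %in% sheet$condition)
    stop("condition not in sample sheet: ", treatment)
  if (!control %in% sheet$condition)
    stop("condition not in sample sheet: ", control)
  if (is.null(times))
    times <- sort(unique(sheet$time_h[sheet$condition == treatment]))
  out <- vector("list", length(times))
  for (i in seq_along(times)) {
    t_h <- times[i]
    ia <- which(sheet$condition == treatment & sheet$time_h == t_h)
    ib <- which(sheet$condition == control & sheet$time_h == t_h)
    if (length(ia) == 0 || length(ib) == 0)
      stop("no samples for time ", t_h, " h in condition ",
           if (length(ia) == 0) treatment else control)
    if (length(ia) < 2 || length(ib) < 2)
      stop("need >= 2 replicates per group at ", t_h, " h")
    res <- moderated_t_test(expr$values[, ia, drop = FALSE],
                            expr$values[, ib, drop = FALSE], prior = prior)
    res$condition <- treatment
    res$time_h <- t_h
    out[[i]] <- res
  }
  det <- do.call(rbind, out)
  det$is_de <- abs(det$log2FC) > config$lfc_threshold &
    det$adj_p < config$fdr_threshold
  det <- det[, c("gene", "condition", "time_h", "log2FC", "t", "df_total",
                 "p", "adj_p", "is_de")]
  attr(det, "config") <- config
  class(det) <- c("de_table", "data.frame")
  det
}

#' DE gene sets by timepoint and time period
#'
#' @param det A `de_table` (one condition).
#' @param config A [de_config()]; defines early/late membership.
#' @return List with `per_time` (named list of DE sets, one per timepoint),
#'   `union` (DE at any timepoint), `early` (DE at any early timepoint) and
#'   `late` (DE at any late timepoint). Early and late may overlap.
#' @export
de_sets <- function(det, config = de_config()) {
  times <- sort(unique(det$time_h))
  per_time <- lapply(times, function(t_h)
    unique(det$gene[det$time_h == t_h & det$is_de]))
  names(per_time) <- as.character(times)
  need <- c(config$early_times, config$late_times)
  absent <- setdiff(need, times)
  if (length(absent))
    stop("requested time(s) absent from DE table: ",
         paste(absent, collapse = ", "), " h")
  pick <- function(ts) unique(unlist(per_time[as.character(ts)], use.names = FALSE))
  list(per_time = per_time,
       union = unique(unlist(per_time, use.names = FALSE)),
       early = pick(config$early_times),
       late = pick(config$late_times))
}

#' Cross-condition DE overlap and proportion tests
#'
#' At one timepoint, computes Venn-style counts of DE-set intersections
#' across conditions and tests each pair of conditions for a difference in
#' DE-gene frequency with the Yates-corrected chi-squared test
#' ([yates_chi_squared()]; cells are DE / not-DE counts over the shared gene
#' universe).
#'
#' @param tables Named list of `de_table`s (names default to each table's
#'   condition); all must share the same gene universe.
#' @param time_h Timepoint at which to compare.
#' @return List with `venn` (data frame: `conditions` label of each region in
#'   "a&b" notation, `n` genes DE in exactly those conditions) and `pairwise`
#'   (data frame with `cond_a`, `cond_b`, DE counts, `chi2`, `p`).
#' @export
condition_overlap <- function(tables, time_h) {
  if (length(tables) < 2) stop("need at least 2 conditions to compare")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(x) x$condition[1], character(1))
  universes <- lapply(tables, function(x) sort(unique(x$gene)))
  if (!all(vapply(universes, identical, logical(1), y = universes[[1]])))
    stop("DE tables have mismatched gene universes")
  genes <- universes[[1]]
  n_universe <- length(genes)
  sets <- lapply(tables, function(x)
    unique(x$gene[x$time_h == time_h & x$is_de]))
  conds <- names(tables)
  member <- vapply(sets, function(s) genes %in% s, logical(n_universe))
  # Venn regions: every non-empty subset of conditions
  subsets <- unlist(lapply(seq_along(conds), function(k)
    utils::combn(conds, k, simplify = FALSE)), recursive = FALSE)
  venn <- data.frame(
    conditions = vapply(subsets, paste, character(1), collapse = "&"),
    n = vapply(subsets, function(ss) {
      inside <- rowSums(member[, ss, drop = FALSE]) == length(ss)
      outside <- rowSums(member[, setdiff(conds, ss), drop = FALSE]) == 0
      sum(inside & outside)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    na <- length(sets[[pr[1]]]); nb <- length(sets[[pr[2]]])
    # a zero margin (e.g. no DE genes in either condition) is untestable
    ct <- tryCatch(yates_chi_squared(na, n_universe - na, nb, n_universe - nb),
                   error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(cond_a = pr[1], cond_b = pr[2], de_a = na, de_b = nb,
               chi2 = ct$chi2, p = ct$p, stringsAsFactors = FALSE)
  }))
  list(venn = venn, pairwise = pairwise)
}

#' Anti-oxidant reversal analysis
#'
#' Counts how many genes DE in a perturbation model (model vs control) are
#' significantly changed in the opposite direction when an anti-oxidant (AO)
#' is added (model+AO vs model). A gene is "reversed" when, at some timepoint
#' at which it is DE in the model contrast, the AO contrast shows a fold
#' change of opposite sign that itself passes the full DE definition (both
#' thresholds); set `require_significance = FALSE` to count sign opposition
#' alone.
#'
#' @param de_model_vs_ctrl `de_table` for model vs control.
#' @param de_modelAO_vs_model `de_table` for model+AO vs model.
#' @param config A [de_config()] (used when `require_significance = FALSE`
#'   only for bookkeeping; DE flags are taken from the tables).
#' @param de_modelAO_vs_ctrl Optional `de_table` for model+AO vs control;
#'   when supplied, the Jaccard index of the DE sets with and without AO
#'   (both against control) is reported, otherwise `ji` is `NA`.
#' @param require_significance Whether reversal requires the AO contrast to
#'   pass the full DE definition (default) or only sign opposition.
#' @return A `reversal_summary`: list with `n_de_model`, `n_reversed`,
#'   `percent_reversed` and `ji`.
#' @export
reversal_analysis <- function(de_model_vs_ctrl, de_modelAO_vs_model,
                              config = de_config(),
                              de_modelAO_vs_ctrl = NULL,
                              require_significance = TRUE) {
  if (!setequal(unique(de_model_vs_ctrl$gene), unique(de_modelAO_vs_model$gene)))
    stop("DE tables have mismatched gene universes")
  key <- function(df) paste(df$gene, df$time_h)
  model <- de_model_vs_ctrl[de_model_vs_ctrl$is_de, , drop = FALSE]
  if (nrow(model) == 0) stop("model DE set is empty")
  ao <- de_modelAO_vs_model
  idx <- match(key(model), key(ao))
  if (any(is.na(idx)))
    stop("AO contrast missing gene/timepoint rows present in the model contrast")
  opposite <- sign(ao$log2FC[idx]) == -sign(model$log2FC) &
    model$log2FC != 0
  reversed <- if (require_significance) opposite & ao$is_de[idx] else opposite
  de_genes <- unique(model$gene)
  reversed_genes <- unique(model$gene[reversed])
  ji <- NA_real_
  if (!is.null(de_modelAO_vs_ctrl)) {
    ao_ctrl_set <- unique(de_modelAO_vs_ctrl$gene[de_modelAO_vs_ctrl$is_de])
    if (length(de_genes) + length(ao_ctrl_set) > 0)
      ji <- jaccard_index(de_genes, ao_ctrl_set)
  }
  structure(list(n_de_model = length(de_genes),
                 n_reversed = length(reversed_genes),
                 percent_reversed = 100 * length(reversed_genes) / length(de_genes),
                 ji = ji,
                 reversed_genes = reversed_genes),
            class = "reversal_summary")
}

#' Write / read a DE table as TSV
#'
#' Columns: `gene, condition, time_h, log2FC, t, df_total, p, adj_p, is_de`.
#'
#' @param det A `de_table`.
#' @param path File path.
#' @return `read_de_table()` returns a `de_table`.
#' @export
write_de_table <- function(det, path) {
  utils::write.table(as.data.frame(det), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  det <- utils::read.delim(path, stringsAsFactors = FALSE)
  det$is_de <- as.logical(det$is_de)
  class(det) <- c("de_table", "data.frame")
  det
}
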