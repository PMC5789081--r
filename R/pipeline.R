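#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Accepts
#' either a YAML file (flat keys, same names as the arguments) or arguments
#' directly. Required: `expression`, `sample_sheet`, `kb`, `out_dir`. All
#' referenced input paths must exist at validation time.
#'
#' @param path Optional YAML file; values in it are overridden by any
#'   argument supplied directly.
#' @param expression,sample_sheet,kb Input paths (TSV; see
#'   [read_expression()], [read_tf_kb()]).
#' @param out_dir Output directory (created if absent).
#' @param control Control condition label.
#' @param treatments Treatment conditions to contrast; default all non-control
#'   conditions in the sample sheet.
#' @param cluster_condition Condition whose DE union is clustered; default
#'   the last treatment.
#' @param gene_sets,signatures Optional GMT paths (pathway collection /
#'   curated signatures).
#' @param external_stats Optional TSV (`gene`, `log2FC`) for the cluster
#'   direction test.
#' @param lfc_threshold,fdr_threshold,early_times,late_times See [de_config()].
#' @param max_rank Knowledge-base evidence-rank cutoff.
#' @param min_set_size Minimum gene-set size for GMT collections.
#' @param universe_size Symbol universe for signature overlap.
#' @param k_range,alpha,score_type,methods See [select_optimal_k()].
#' @param tf_filter See [build_cascade()].
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic clustering method.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, expression = NULL, sample_sheet = NULL,
                            kb = NULL, out_dir = NULL, control = "control",
                            treatments = NULL, cluster_condition = NULL,
                            gene_sets = NULL, signatures = NULL,
                            external_stats = NULL, lfc_threshold = 0.5,
                            fdr_threshold = 0.05, early_times = c(2, 4, 8),
                            late_times = 24, max_rank = 2, min_set_size = 30,
                            universe_size = 41220, k_range = 2:12,
                            alpha = 0.05, score_type = "neglogp",
                            methods = "hierarchical", tf_filter = "strict",
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$path <- NULL
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    supplied <- names(as.list(match.call()))[-1]
    for (nm in names(file_cfg)) {
      if (!nm %in% supplied) cfg[[nm]] <- file_cfg[[nm]]
    }
  }
  for (req in c("expression", "sample_sheet", "kb", "out_dir")) {
    if (is.null(cfg[[req]])) stop("pipeline config is missing '", req, "'")
  }
  for (p in c("expression", "sample_sheet", "kb", "gene_sets", "signatures",
              "external_stats")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config path does not exist: ", p, " = ", cfg[[p]])
  }
  cfg$k_range <- as.integer(cfg$k_range)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, timings, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  assign("timings", timings, envir = parent.frame())
  res
}

#' Run the full analysis pipeline
#'
#' Sequences differential expression (each treatment vs time-matched
#' control), DE-set bookkeeping and cross-condition proportion tests,
#' knowledge-guided clustering with optimal-K selection, per-cluster TF
#' enrichment, optional pathway ORA / signature overlap / direction tests,
#' and cascade construction, writing every result as TSV plus a JSON manifest
#' (seed, configuration echo, per-stage timings). All outputs are pure
#' functions of the inputs and the seed; only the manifest's timing fields
#' differ between repeated runs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (written to stderr).
#' @return Invisibly, a list with the main in-memory results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[txcascade] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  set.seed(config$seed)
  dcfg <- de_config(config$lfc_threshold, config$fdr_threshold,
                    config$early_times, config$late_times)

  say("reading inputs")
  inputs <- stage("read_inputs", timings, function() {
    expr <- read_expression(config$expression, config$sample_sheet)
    kb <- read_tf_kb(config$kb, max_rank = config$max_rank)
    list(expr = expr, kb = kb)
  })
  expr <- inputs$expr; kb <- inputs$kb
  treatments <- config$treatments
  if (is.null(treatments))
    treatments <- setdiff(unique(expr$samples$condition), config$control)
  if (length(treatments) == 0) stop("no treatment conditions found")
  cluster_condition <- config$cluster_condition
  if (is.null(cluster_condition))
    cluster_condition <- treatments[length(treatments)]

  say("differential expression: ", paste(treatments, collapse = ", "))
  de_tables <- stage("differential_expression", timings, function() {
    tabs <- lapply(treatments, function(tr) {
      det <- run_de_timecourse(expr, tr, config$control, dcfg)
      write_de_table(det, file.path(config$out_dir,
                                    paste0("de_", tr, ".tsv")))
      det
    })
    names(tabs) <- treatments
    tabs
  })

  say("DE-set summaries")
  sets_by_cond <- stage("de_sets", timings, function() {
    sets <- lapply(de_tables, de_sets, config = dcfg)
    summ <- do.call(rbind, lapply(names(sets), function(cond) {
      s <- sets[[cond]]
      data.frame(condition = cond,
                 set = c(names(s$per_time), "union", "early", "late"),
                 n = c(lengths(s$per_time), length(s$union),
                       length(s$early), length(s$late)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(summ, file.path(config$out_dir, "de_set_sizes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sets
  })

  if (length(de_tables) >= 2) {
    say("cross-condition overlap tests")
    stage("condition_overlap", timings, function() {
      times <- sort(unique(de_tables[[1]]$time_h))
      venns <- list(); chis <- list()
      for (t_h in times) {
        ov <- condition_overlap(de_tables, t_h)
        ov$venn$time_h <- t_h; ov$pairwise$time_h <- t_h
        venns[[length(venns) + 1L]] <- ov$venn
        chis[[length(chis) + 1L]] <- ov$pairwise
      }
      utils::write.table(do.call(rbind, venns),
                         file.path(config$out_dir, "condition_venn.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(do.call(rbind, chis),
                         file.path(config$out_dir, "condition_chisq.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  say("clustering DE union of '", cluster_condition, "'")
  clust <- stage("clustering", timings, function() {
    det <- de_tables[[cluster_condition]]
    profiles <- build_profiles(det)
    sel <- select_optimal_k(profiles, kb, k_range = config$k_range,
                            methods = config$methods, alpha = config$alpha,
                            seed = config$seed, score_type = config$score_type)
    utils::write.table(sel$curve,
                       file.path(config$out_dir, "score_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_clusters(sel$clustering,
                   file.path(config$out_dir, "clusters.tsv"))
    sel
  })

  say("TF enrichment per cluster (K = ", clust$best_k, ")")
  enr <- stage("tf_enrichment", timings, function() {
    enr <- tf_enrichment_per_cluster(clust$clustering, kb,
                                     alpha = config$alpha)
    utils::write.table(as.data.frame(enr),
                       file.path(config$out_dir, "tf_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr
  })

  if (!is.null(config$gene_sets)) {
    say("pathway over-representation")
    stage("pathway_ora", timings, function() {
      collection <- read_gene_sets(config$gene_sets,
                                   min_size = config$min_set_size)
      background <- rownames(expr$values)
      s <- sets_by_cond[[cluster_condition]]
      res <- list()
      for (period in c("early", "late")) {
        gl <- intersect(s[[period]], background)
        if (length(gl) == 0) next
        r <- pathway_ora(gl, collection, background, fdr = config$fdr_threshold)
        r$gene_list <- period
        res[[period]] <- r
      }
      if (length(res))
        utils::write.table(do.call(rbind, res),
                           file.path(config$out_dir, "pathway_ora.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  if (!is.null(config$signatures)) {
    say("signature overlap")
    stage("signature_overlap", timings, function() {
      sigs <- read_gene_sets(config$signatures, min_size = config$min_set_size)
      de_union <- lapply(sets_by_cond, `[[`, "union")
      res <- signature_overlap(de_union, sigs,
                               universe_size = config$universe_size)
      utils::write.table(res,
                         file.path(config$out_dir, "signature_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  if (!is.null(config$external_stats)) {
    say("cluster direction tests")
    stage("direction_test", timings, function() {
      ext <- utils::read.delim(config$external_stats, stringsAsFactors = FALSE)
      stats_vec <- stats::setNames(ext$log2FC, ext$gene)
      res <- cluster_direction_test(clust$clustering, stats_vec)
      utils::write.table(res,
                         file.path(config$out_dir, "cluster_direction.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  say("cascade construction")
  graph <- stage("cascade", timings, function() {
    graph <- build_cascade(clust$clustering, de_tables[[cluster_condition]],
                           enr, kb, alpha = config$alpha,
                           tf_filter = config$tf_filter)
    export_cascade(graph, file.path(config$out_dir, "cascade"),
                   format = "edge-tsv")
    export_cascade(graph, file.path(config$out_dir, "cascade"),
                   format = "sif")
    graph
  })

  manifest <- list(
    package = "txcascade",
    version = as.character(utils::packageVersion("txcascade")),
    seed = config$seed,
    config = unclass(config),
    best_k = clust$best_k,
    timings_s = timings,
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  say("done; outputs in ", config$out_dir)
  invisible(list(de_tables = de_tables, de_sets = sets_by_cond,
                 selection = clust, tf_enrichment = enr, cascade = graph,
                 manifest = manifest))
}

#' Write a simulated dataset to pipeline-ready files
#'
#' Convenience wrapper: simulates a dataset with [simulate_dataset()] and
#' writes the expression matrix, sample sheet, knowledge base and truth files
#' in the formats consumed by [pipeline_config()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a named list of paths (plus the truth object).
#' @export
write_simulated_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                sample_sheet = file.path(dir, "sample_sheet.tsv"),
                kb = file.path(dir, "tf_kb.tsv"),
                truth_clusters = file.path(dir, "truth_clusters.tsv"),
                truth_connectors = file.path(dir, "truth_connectors.tsv"))
  write_expression(ds$expr, paths$expression, paths$sample_sheet)
  write_tf_kb(ds$kb, paths$kb)
  utils::write.table(
    data.frame(gene = names(ds$truth$assignment),
               cluster = unname(ds$truth$assignment)),
    paths$truth_clusters, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$connectors, paths$truth_connectors,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(truth = ds$truth)))
}
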