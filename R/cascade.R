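#' Assemble the transcriptional cascade graph
#'
#' Builds a typed graph from a clustering of DE genes, per-cluster TF
#' enrichment, and the TF-target knowledge base, following four rules:
#'
#' 1. *Upstream*: a TF enriched in a cluster (`p < alpha`) is placed upstream
#'    of that cluster (edge TF -> cluster), provided it passes the TF-TF
#'    participation filter (below).
#' 2. *Membership*: every DE TF assigned to a cluster receives a membership
#'    edge (cluster -> TF).
#' 3. *Connector*: a TF B is placed between clusters I and II when it is DE
#'    in cluster I, a known target of a TF upstream of cluster I, and
#'    enriched in cluster II. The supporting TF-TF edges (A -> B) are emitted
#'    as `regulatory` edges.
#' 4. *TF-TF filter*: a cascade requires one TF to regulate another, so an
#'    enriched TF enters the cascade only if it participates in a TF-TF
#'    relationship. Under the default `"strict"` rule a TF qualifies either
#'    outbound - at least one of its targets is a TF that is DE in a cluster
#'    in which the TF itself is enriched - or inbound - it is itself DE in a
#'    cluster and a target of a TF already upstream of that cluster (the
#'    inbound route is iterated to a fixpoint). `"permissive"` accepts any TF
#'    with a target that is a TF; `"none"` disables the filter.
#'
#' Enriched TFs that are not themselves clustered (regulated by other means,
#' e.g. post-translationally) are retained as upstream-only nodes.
#'
#' @param clustering A `gene_clustering` of the DE genes.
#' @param det The `de_table` the clustering was computed from.
#' @param enr A [tf_enrichment_per_cluster()] table computed on `clustering`
#'   with the same `kb`.
#' @param kb The `tf_kb` used for the enrichment.
#' @param alpha Enrichment threshold (default 0.05).
#' @param tf_filter `"strict"`, `"permissive"` or `"none"`.
#' @param allow_self_connectors Whether a TF may connect a cluster to itself
#'   (I = II); such connectors are annotated with `self = TRUE`.
#' @return A `cascade_graph`: list with `nodes` (data frame `node, type,
#'   cluster, size`), `edges` (data frame `from, type, to`) and `connectors`
#'   (data frame `tf, from_cluster, to_cluster, self`).
#' @export
build_cascade <- function(clustering, det, enr, kb, alpha = 0.05,
                          tf_filter = c("strict", "permissive", "none"),
                          allow_self_connectors = TRUE) {
  tf_filter <- match.arg(tf_filter)
  assignment <- clustering$assignment
  if (!all(names(assignment) %in% det$gene))
    stop("clustering and DE table have mismatched gene universes")
  tf_all <- kb_tfs(kb)
  targets <- kb_target_sets(kb)
  de_genes <- unique(det$gene[det$is_de])
  clustered_de_tfs <- intersect(tf_all, intersect(names(assignment), de_genes))

  epairs <- enr[enr$p < alpha, c("cluster", "tf"), drop = FALSE]
  enriched_in <- lapply(split(epairs$cluster, epairs$tf), unique)

  qualifies_outbound <- function(f) {
    tftg <- intersect(targets[[f]], tf_all)
    if (length(tftg) == 0) return(FALSE)
    if (tf_filter == "permissive") return(TRUE)
    cand <- tftg[tftg %in% de_genes & tftg %in% names(assignment)]
    if (length(cand) == 0) return(FALSE)
    any(assignment[cand] %in% enriched_in[[f]])
  }

  if (tf_filter == "none") {
    retained <- names(enriched_in)
  } else {
    retained <- names(enriched_in)[vapply(names(enriched_in),
                                          qualifies_outbound, logical(1))]
    # inbound closure: an enriched TF that is DE in a cluster and a target of
    # a TF already upstream of that cluster joins the cascade
    repeat {
      upstream_of <- function(cl) {
        retained[vapply(retained, function(f) cl %in% enriched_in[[f]],
                        logical(1))]
      }
      candidates <- setdiff(names(enriched_in), retained)
      candidates <- intersect(candidates, clustered_de_tfs)
      add <- candidates[vapply(candidates, function(b) {
        ups <- upstream_of(assignment[[b]])
        any(vapply(ups, function(a) b %in% targets[[a]], logical(1)))
      }, logical(1))]
      if (length(add) == 0) break
      retained <- c(retained, add)
    }
  }

  upstream <- do.call(rbind, lapply(retained, function(f) {
    data.frame(from = f, type = "upstream",
               to = paste0("C", enriched_in[[f]]), stringsAsFactors = FALSE)
  }))
  membership <- if (length(clustered_de_tfs)) data.frame(
    from = paste0("C", unname(assignment[clustered_de_tfs])),
    type = "membership", to = clustered_de_tfs, stringsAsFactors = FALSE
  ) else NULL

  connectors <- list(); regulatory <- list()
  upstream_tfs_of <- function(cl) {
    retained[vapply(retained, function(f) cl %in% enriched_in[[f]],
                    logical(1))]
  }
  for (b in intersect(clustered_de_tfs, retained)) {
    I <- assignment[[b]]
    regulators <- upstream_tfs_of(I)
    regulators <- regulators[vapply(regulators, function(a)
      b %in% targets[[a]], logical(1))]
    if (length(regulators) == 0) next
    for (II in enriched_in[[b]]) {
      if (II == I && !allow_self_connectors) next
      connectors[[length(connectors) + 1L]] <- data.frame(
        tf = b, from_cluster = I, to_cluster = II, self = II == I,
        stringsAsFactors = FALSE)
    }
    for (a in regulators) {
      regulatory[[length(regulatory) + 1L]] <- data.frame(
        from = a, type = "regulatory", to = b, stringsAsFactors = FALSE)
    }
  }
  connectors <- if (length(connectors)) unique(do.call(rbind, connectors))
                else data.frame(tf = character(), from_cluster = integer(),
                                to_cluster = integer(), self = logical())
  regulatory <- if (length(regulatory)) unique(do.call(rbind, regulatory))
                else NULL
  edges <- rbind(upstream, membership, regulatory)
  if (is.null(edges))
    edges <- data.frame(from = character(), type = character(),
                        to = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  rownames(connectors) <- NULL

  tf_nodes <- sort(unique(c(retained, clustered_de_tfs)))
  nodes <- rbind(
    data.frame(node = paste0("C", seq_len(clustering$K)), type = "cluster",
               cluster = seq_len(clustering$K), size = clustering$sizes,
               stringsAsFactors = FALSE),
    if (length(tf_nodes)) data.frame(
      node = tf_nodes, type = "tf",
      cluster = ifelse(tf_nodes %in% names(assignment),
                       unname(assignment[tf_nodes]), NA_integer_),
      size = NA_integer_, stringsAsFactors = FALSE) else NULL)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, connectors = connectors),
            class = "cascade_graph")
}

#' @export
print.cascade_graph <- function(x, ...) {
  cat("cascade_graph:", sum(x$nodes$type == "cluster"), "clusters,",
      sum(x$nodes$type == "tf"), "TFs,", nrow(x$edges), "edges,",
      nrow(x$connectors), "connectors\n")
  invisible(x)
}

#' Export a cascade graph
#'
#' Formats:
#' * `"edge-tsv"`: three TSVs (`<prefix>_nodes.tsv`, `<prefix>_edges.tsv`,
#'   `<prefix>_connectors.tsv`); round-trip safe via [read_cascade_tsv()].
#' * `"sif"`: `<prefix>.sif` with the edge type as the interaction label
#'   (isolated nodes listed alone), plus node-attribute and connector TSVs.
#' * `"graphml"`: `<prefix>.graphml` with typed node and edge attributes
#'   (requires the `igraph` package).
#'
#' @param graph A `cascade_graph`.
#' @param prefix Output path prefix (directory must exist).
#' @param format One of `"edge-tsv"`, `"sif"`, `"graphml"`.
#' @return Invisibly, the paths written.
#' @export
export_cascade <- function(graph, prefix,
                           format = c("edge-tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "cascade_graph"))
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (format == "edge-tsv") {
    paths <- c(wt(graph$nodes, paste0(prefix, "_nodes.tsv")),
               wt(graph$edges, paste0(prefix, "_edges.tsv")),
               wt(graph$connectors, paste0(prefix, "_connectors.tsv")))
    return(invisible(paths))
  }
  if (format == "sif") {
    lines <- if (nrow(graph$edges))
      paste(graph$edges$from, graph$edges$type, graph$edges$to, sep = "\t")
    else character()
    connected <- unique(c(graph$edges$from, graph$edges$to))
    isolated <- setdiff(graph$nodes$node, connected)
    sif <- paste0(prefix, ".sif")
    writeLines(c(lines, isolated), sif)
    paths <- c(sif, wt(graph$nodes, paste0(prefix, "_node_attrs.tsv")),
               wt(graph$connectors, paste0(prefix, "_connectors.tsv")))
    return(invisible(paths))
  }
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the 'igraph' package is required for GraphML export")
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "type")], directed = TRUE,
    vertices = graph$nodes)
  path <- paste0(prefix, ".graphml")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-read an edge-tsv cascade export
#'
#' @param prefix The prefix given to [export_cascade()] with
#'   `format = "edge-tsv"`.
#' @return A `cascade_graph` identical to the exported one.
#' @export
read_cascade_tsv <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "character"))
  connectors <- utils::read.delim(paste0(prefix, "_connectors.tsv"),
                                  stringsAsFactors = FALSE,
                                  colClasses = c("character", "integer",
                                                 "integer", "logical"))
  nodes$node <- as.character(nodes$node)
  structure(list(nodes = nodes, edges = edges, connectors = connectors),
            class = "cascade_graph")
}
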