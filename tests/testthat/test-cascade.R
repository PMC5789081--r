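# Worked two-cluster cascade: TF A regulates cluster C1 (which contains TF B);
# B's targets are cluster C2. All clustered genes DE.
worked_example <- function() {
  c1 <- c("B", "x1", "x2", "x3")
  c2 <- c("y1", "y2", "y3", "y4")
  assignment <- setNames(c(rep(1, 4), rep(2, 4)), c(c1, c2))
  cl <- manual_clustering(assignment)
  kb <- tf_kb(rbind(data.frame(tf = "A", tg = c1, rank = 1L),
                    data.frame(tf = "B", tg = c2, rank = 1L)))
  lfc <- matrix(1, 8, 2, dimnames = list(c(c1, c2), c(2, 24)))
  det <- manual_de_table(lfc, matrix(TRUE, 8, 2, dimnames = dimnames(lfc)))
  enr <- tf_enrichment_per_cluster(cl, kb)
  list(cl = cl, kb = kb, det = det, enr = enr)
}

test_that("the worked example yields all four edge types and the connector", {
  w <- worked_example()
  g <- build_cascade(w$cl, w$det, w$enr, w$kb)
  key <- with(g$edges, paste(from, type, to))
  expect_true("A upstream C1" %in% key)
  expect_true("B upstream C2" %in% key)
  expect_true("C1 membership B" %in% key)
  expect_true("A regulatory B" %in% key)
  expect_equal(nrow(g$connectors), 1)
  expect_equal(g$connectors$tf, "B")
  expect_equal(g$connectors$from_cluster, 1)
  expect_equal(g$connectors$to_cluster, 2)
  expect_false(g$connectors$self)
  # A is an upstream-only node (not clustered)
  expect_true(is.na(g$nodes$cluster[g$nodes$node == "A"]))
  expect_true(verify_connectors(g, w$cl, w$det, w$enr, w$kb))
})

test_that("no enriched TFs gives cluster nodes only", {
  w <- worked_example()
  enr0 <- w$enr
  enr0$p <- 1; enr0$enriched <- FALSE
  g <- build_cascade(w$cl, w$det, enr0, w$kb)
  expect_equal(nrow(g$edges[g$edges$type == "upstream", ]), 0)
  expect_equal(nrow(g$connectors), 0)
  expect_true(all(paste0("C", 1:2) %in% g$nodes$node))
})

test_that("an enriched TF that is no regulator's target gets no connector", {
  # A's targets exclude B, so nothing upstream of C1 regulates B; B still
  # passes the TF-TF filter outbound because its target z is a DE TF in C2
  c1 <- c("B", "x1", "x2", "x3", "x4")
  c2 <- c("y1", "y2", "y3", "z")
  assignment <- setNames(c(rep(1, 5), rep(2, 4)), c(c1, c2))
  cl <- manual_clustering(assignment)
  kb <- tf_kb(rbind(data.frame(tf = "A", tg = c("x1", "x2", "x3", "x4"), rank = 1L),
                    data.frame(tf = "B", tg = c2, rank = 1L),
                    data.frame(tf = "z", tg = c("w1", "w2"), rank = 1L)))
  lfc <- matrix(1, 9, 2, dimnames = list(c(c1, c2), c(2, 24)))
  det <- manual_de_table(lfc, matrix(TRUE, 9, 2, dimnames = dimnames(lfc)))
  enr <- suppressMessages(tf_enrichment_per_cluster(cl, kb))
  expect_true(enr$enriched[enr$tf == "B" & enr$cluster == 2])
  g <- build_cascade(cl, det, enr, kb)
  key <- with(g$edges, paste(from, type, to))
  expect_true("B upstream C2" %in% key)
  expect_true("C1 membership B" %in% key)
  # A fails the TF-TF filter (no TF among its targets): no upstream edge
  expect_false(any(g$edges$from == "A"))
  expect_equal(nrow(g$connectors), 0)
  expect_true(verify_connectors(g, cl, det, enr, kb))
})

test_that("permissive filter relaxes the strict in-cluster TG rule", {
  # B's only TF target sits outside any cluster: strict drops B, permissive keeps it
  c1 <- c("B", "x1", "x2", "x3")
  c2 <- c("y1", "y2", "y3", "y4")
  assignment <- setNames(c(rep(1, 4), rep(2, 4)), c(c1, c2))
  cl <- manual_clustering(assignment)
  kb <- tf_kb(rbind(data.frame(tf = "B", tg = c(c2, "ext_tf"), rank = 1L),
                    data.frame(tf = "ext_tf", tg = c("w1", "w2"), rank = 1L)))
  lfc <- matrix(1, 8, 2, dimnames = list(c(c1, c2), c(2, 24)))
  det <- manual_de_table(lfc, matrix(TRUE, 8, 2, dimnames = dimnames(lfc)))
  enr <- suppressMessages(tf_enrichment_per_cluster(cl, kb))
  g_strict <- build_cascade(cl, det, enr, kb, tf_filter = "strict")
  g_perm <- build_cascade(cl, det, enr, kb, tf_filter = "permissive")
  expect_false(any(g_strict$edges$type == "upstream"))
  expect_true(any(g_perm$edges$type == "upstream" & g_perm$edges$from == "B"))
  # relaxing the filter only ever adds nodes/edges
  expect_true(all(with(g_strict$edges, paste(from, type, to)) %in%
                  with(g_perm$edges, paste(from, type, to))))
})

test_that("cascade exports round-trip (edge-tsv) and emit SIF/GraphML", {
  w <- worked_example()
  g <- build_cascade(w$cl, w$det, w$enr, w$kb)
  prefix <- file.path(tempdir(), "casc")
  export_cascade(g, prefix, format = "edge-tsv")
  g2 <- read_cascade_tsv(prefix)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$connectors, g$connectors)
  expect_equal(g2$nodes$node, g$nodes$node)

  export_cascade(g, prefix, format = "sif")
  sif <- readLines(paste0(prefix, ".sif"))
  expect_true("A\tupstream\tC1" %in% sif)
  expect_length(sif, nrow(g$edges))  # no isolated nodes here

  # empty-edge graph lists isolated cluster nodes in the SIF
  enr0 <- w$enr; enr0$p <- 1; enr0$enriched <- FALSE
  g0 <- build_cascade(w$cl, w$det, enr0, w$kb)
  export_cascade(g0, paste0(prefix, "0"), format = "sif")
  sif0 <- readLines(paste0(prefix, "0.sif"))
  # C2 has no edges at all (membership edges keep C1 connected to B)
  expect_true("C2" %in% sif0)
  expect_true(any(grepl("^C1\t", sif0)))

  skip_if_not_installed("igraph")
  export_cascade(g, prefix, format = "graphml")
  ig <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::gsize(ig), nrow(g$edges))
  expect_setequal(igraph::vertex_attr(ig, "name"), g$nodes$node)
})

test_that("planted cascades are recovered on simulated data", {
  cfg <- sim_config(n_genes = 1200, n_tfs = 15, targets_per_tf = c(10, 20),
                    k_true = 4, cluster_size = 30, noise_sd = 0.1, seed = 53)
  ds <- simulate_dataset(cfg)
  det <- run_de_timecourse(ds$expr, "both", "control")
  prof <- build_profiles(det)
  cl <- hierarchical_clusters(prof, 4)
  enr <- suppressMessages(tf_enrichment_per_cluster(cl, ds$kb))
  g <- build_cascade(cl, det, enr, ds$kb)
  met <- evaluate_recovery(g, ds$truth, clustering = cl)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
  expect_true(verify_connectors(g, cl, det, enr, ds$kb))
})
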