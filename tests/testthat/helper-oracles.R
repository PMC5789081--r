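# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Hypergeometric upper tail by explicit combinatorial enumeration.
enum_hyper_tail <- function(k, m, n, N) {
  j <- seq(k, min(m, n))
  if (length(j) == 0 || k > min(m, n)) return(0)
  sum(exp(lchoose(m, j) + lchoose(N - m, n - j) - lchoose(N, n)))
}

# Benjamini-Hochberg by the literal min-over-thresholds step-up definition.
brute_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) t * n / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Ordinary pooled two-sample t-test (textbook formula), one gene at a time.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
}

# Yates chi-squared evaluated symbol-by-symbol from the formula.
hand_yates <- function(a, b, c, d) {
  N <- a + b + c + d
  corrected <- abs(a * d - b * c) - N / 2
  if (corrected < 0) corrected <- 0
  N * corrected^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive verification that every emitted connector (and no omitted
# triple) satisfies the three placement conditions, given the graph's own
# upstream edges, the enrichment table, the DE table and the knowledge base.
verify_connectors <- function(graph, clustering, det, enr, kb,
                              alpha = 0.05) {
  assignment <- clustering$assignment
  de_genes <- unique(det$gene[det$is_de])
  targets <- kb_target_sets(kb)
  up <- graph$edges[graph$edges$type == "upstream", , drop = FALSE]
  upstream_tfs <- function(cl) up$from[up$to == paste0("C", cl)]
  tfs <- unique(c(up$from, graph$nodes$node[graph$nodes$type == "tf"]))
  expected <- list()
  for (b in tfs) {
    if (!b %in% names(assignment) || !b %in% de_genes) next
    I <- assignment[[b]]
    regulators <- upstream_tfs(I)
    has_reg <- any(vapply(regulators, function(a) b %in% targets[[a]],
                          logical(1)))
    if (!has_reg) next
    enriched_in <- enr$cluster[enr$tf == b & enr$p < alpha]
    # connectors require b itself to be upstream (i.e. in the cascade)
    enriched_in <- enriched_in[paste0("C", enriched_in) %in% up$to[up$from == b]]
    for (II in enriched_in) {
      expected[[length(expected) + 1L]] <- paste(b, I, II)
    }
  }
  emitted <- with(graph$connectors, paste(tf, from_cluster, to_cluster))
  setequal(unlist(expected), emitted)
}
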