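# Small in-code fixtures.

# Expression matrix with two conditions x two timepoints x 2 replicates and
# user-supplied per-gene effects added to the treatment samples.
tiny_expression <- function(n_genes = 20, effects = NULL,
                            times = c(2, 24), noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  sheet <- expand.grid(replicate = 1:2, time_h = times,
                       condition = c("control", "treated"),
                       stringsAsFactors = FALSE)
  sheet$sample_id <- with(sheet, paste(condition, time_h, replicate, sep = "_"))
  sheet <- sheet[, c("sample_id", "condition", "time_h", "replicate")]
  vals <- matrix(stats::rnorm(n_genes * nrow(sheet), 8, noise_sd),
                 nrow = n_genes, dimnames = list(genes, sheet$sample_id))
  if (!is.null(effects)) {
    for (i in which(sheet$condition == "treated")) {
      vals[, i] <- vals[, i] + effects
    }
  }
  expression_matrix(vals, sheet)
}

# Hand-built de_table (single condition) from a gene x time matrix of lfc
# values and a logical DE matrix.
manual_de_table <- function(lfc, is_de, condition = "treated") {
  times <- as.numeric(colnames(lfc))
  rows <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(gene = rownames(lfc), condition = condition,
               time_h = times[i], log2FC = lfc[, i], t = lfc[, i],
               df_total = 10, p = ifelse(is_de[, i], 1e-6, 0.5),
               adj_p = ifelse(is_de[, i], 1e-5, 0.8),
               is_de = is_de[, i], stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("de_table", "data.frame")
  rows
}

# Clustering object from a named assignment vector (centers not needed by
# enrichment/cascade code paths).
manual_clustering <- function(assignment) {
  K <- max(assignment)
  structure(list(K = K, assignment = assignment,
                 centers = matrix(0, K, 2), sizes = tabulate(assignment, K)),
            class = "gene_clustering")
}
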