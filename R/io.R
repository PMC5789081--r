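#' Construct an expression matrix bound to a sample sheet
#'
#' The central expression container: a numeric gene-by-sample matrix of
#' log2-scale intensities together with the sample sheet describing each
#' column (condition, time in hours, replicate). Values are assumed already
#' background-corrected and normalised; no normalisation is performed by this
#' package.
#'
#' @param values Numeric matrix, genes in rows (unique symbols as rownames),
#'   samples in columns (sample ids as colnames). All values must be finite.
#' @param samples Data frame with columns `sample_id`, `condition`, `time_h`,
#'   `replicate`; rows in the same order as the matrix columns.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("'values' must have gene symbols as rownames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene symbols (", paste(utils::head(dup, 5), collapse = ", "),
         "); probe-level data must be collapsed with collapse_probes()")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  samples <- validate_sample_sheet(samples)
  if (ncol(values) != nrow(samples))
    stop("matrix has ", ncol(values), " columns but sample sheet has ",
         nrow(samples), " rows")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(samples$sample_id)))
    stop("matrix column names do not match sample sheet order")
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "condition", "time_h", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  if (!is.numeric(sheet$time_h) || any(!is.finite(sheet$time_h)) || any(sheet$time_h <= 0))
    stop("time_h must be positive and finite")
  if (any(sheet$replicate <= 0) || any(sheet$replicate != round(sheet$replicate)))
    stop("replicate must be a positive integer")
  sheet
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("times (h):", paste(sort(unique(x$samples$time_h)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene-level expression matrix and its sample sheet
#'
#' The expression file is TSV with a header; the first column must be named
#' `gene`, remaining columns are sample ids. The sample sheet is TSV with
#' columns `sample_id`, `condition`, `time_h`, `replicate`. Matrix columns
#' are reordered to sample-sheet order; gene (row) order is preserved.
#' Duplicate gene symbols are an error here: probe-level data must first go
#' through [collapse_probes()].
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  sheet <- validate_sample_sheet(sheet)
  raw <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(raw)[1] != "gene")
    stop("first column of the expression matrix must be named 'gene'")
  vals <- raw[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric values in expression column(s): ",
         paste(bad, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- raw$gene
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample columns in expression matrix")
  absent <- setdiff(sheet$sample_id, colnames(m))
  if (length(absent))
    stop("sample(s) in sheet but missing from matrix: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(colnames(m), sheet$sample_id)
  if (length(extra))
    stop("sample(s) in matrix but missing from sheet: ",
         paste(extra, collapse = ", "))
  m <- m[, sheet$sample_id, drop = FALSE]
  expression_matrix(m, sheet)
}

#' Write an expression matrix and sample sheet to TSV
#'
#' Inverse of [read_expression()]; the round trip preserves values exactly
#' (values are written with full precision).
#'
#' @param em An `expression_matrix`.
#' @param matrix_path,sample_sheet_path Output paths.
#' @export
write_expression <- function(em, matrix_path, sample_sheet_path) {
  stopifnot(inherits(em, "expression_matrix"))
  chr <- apply(em$values, 2, function(x) sprintf("%.17g", x))
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(em$values),
                                     dimnames = dimnames(em$values))
  df <- data.frame(gene = rownames(em$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Read a probe-level intensity matrix
#'
#' Like [read_expression()] but without a sample sheet and with duplicate row
#' identifiers allowed (first column must be named `probe`). Intended as input
#' to [collapse_probes()].
#'
#' @param path Path to a TSV with first column `probe`.
#' @return Numeric matrix with probe ids as rownames.
#' @export
read_probe_matrix <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "probe")
    stop("first column of a probe matrix must be named 'probe'")
  vals <- raw[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric values in probe column(s): ", paste(bad, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- raw$probe
  m
}

#' Collapse probe-level intensities to one row per gene
#'
#' Probes mapping to the same gene symbol are summarised to a single
#' representative row. The default (`per_sample_median`) takes, for each
#' sample, the median across that gene's probes, preserving sample-wise
#' temporal structure. The alternative (`median_average_probe`) picks the one
#' probe whose across-sample average is closest to the median of those
#' averages, i.e. a single representative probe. Single-probe genes pass
#' through unchanged under both methods.
#'
#' @param probe_matrix Numeric probe-by-sample matrix with probe rownames.
#' @param probe_to_gene Mapping of probe to gene symbol: either a named
#'   character vector (names are probes) or a data frame with columns
#'   `probe` and `gene`. Every probe in the matrix must be mapped.
#' @param samples Optional sample sheet; when supplied the result is a full
#'   [expression_matrix()], otherwise a plain matrix is returned.
#' @param method Collapsing rule, see Details.
#' @return An `expression_matrix` (if `samples` given) or a gene-by-sample
#'   matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene, samples = NULL,
                            method = c("per_sample_median", "median_average_probe")) {
  method <- match.arg(method)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe))
  } else {
    map <- probe_to_gene
  }
  probes <- rownames(probe_matrix)
  unmapped <- setdiff(probes, names(map))
  if (length(unmapped))
    stop("probe(s) absent from mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  genes <- unname(map[probes])
  idx <- split(seq_along(probes), genes)
  out <- matrix(NA_real_, nrow = length(idx), ncol = ncol(probe_matrix),
                dimnames = list(names(idx), colnames(probe_matrix)))
  for (g in names(idx)) {
    rows <- idx[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- probe_matrix[rows, ]
    } else if (method == "per_sample_median") {
      out[g, ] <- apply(probe_matrix[rows, , drop = FALSE], 2, stats::median)
    } else {
      avg <- rowMeans(probe_matrix[rows, , drop = FALSE])
      pick <- rows[which.min(abs(avg - stats::median(avg)))]
      out[g, ] <- probe_matrix[pick, ]
    }
  }
  # keep first-appearance gene order
  out <- out[unique(genes), , drop = FALSE]
  if (is.null(samples)) out else expression_matrix(out, samples)
}

#' Read a ranked TF-to-target knowledge base
#'
#' TSV with columns `tf`, `tg`, `rank` where rank is an integer evidence tier
#' (1 = strongest). Edges above `max_rank` are discarded; duplicate (tf, tg)
#' pairs keep the best (lowest) rank.
#'
#' @param path Path to the TSV.
#' @param max_rank Highest evidence tier retained (default 2, i.e. ranks 1-2).
#' @return A `tf_kb`: data frame with columns `tf`, `tg`, `rank`.
#' @export
read_tf_kb <- function(path, max_rank = 2) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  tf_kb(df, max_rank = max_rank)
}

#' Construct a TF knowledge base from an edge table
#'
#' @param edges Data frame with columns `tf`, `tg`, `rank`.
#' @param max_rank Highest evidence tier retained.
#' @return A `tf_kb` object (a filtered, deduplicated edge data frame).
#' @export
tf_kb <- function(edges, max_rank = Inf) {
  required <- c("tf", "tg", "rank")
  missing <- setdiff(required, names(edges))
  if (length(missing))
    stop("knowledge base is missing column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(edges$tf) | is.na(edges$tg) | is.na(edges$rank)) ||
      any(edges$tf == "" | edges$tg == ""))
    stop("malformed knowledge-base row(s): empty or missing fields")
  if (!is.numeric(edges$rank) || any(edges$rank != round(edges$rank)) ||
      any(edges$rank < 1))
    stop("rank must be a positive integer evidence tier")
  edges <- edges[edges$rank <= max_rank, required, drop = FALSE]
  if (nrow(edges) == 0L)
    stop("knowledge base is empty after filtering at max_rank = ", max_rank)
  o <- order(edges$tf, edges$tg, edges$rank)
  edges <- edges[o, , drop = FALSE]
  keep <- !duplicated(edges[, c("tf", "tg")])
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("tf_kb", "data.frame")
  edges
}

#' Write a TF knowledge base to TSV
#' @param kb A `tf_kb`.
#' @param path Output path.
#' @export
write_tf_kb <- function(kb, path) {
  utils::write.table(as.data.frame(kb), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Transcription factors and target sets of a knowledge base
#'
#' @param kb A `tf_kb`.
#' @return `kb_tfs()`: character vector of TF symbols. `kb_target_sets()`:
#'   named list mapping each TF to its unique target genes.
#' @export
kb_tfs <- function(kb) unique(kb$tf)

#' @rdname kb_tfs
#' @export
kb_target_sets <- function(kb) lapply(split(kb$tg, kb$tf), unique)

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Memberships are
#' deduplicated; sets with fewer than `min_size` unique members are dropped.
#'
#' @param gmt_path Path to the GMT file.
#' @param min_size Minimum retained set size (unique members).
#' @return A `gene_set_collection`: named list of character vectors, with the
#'   filter threshold stored in attribute `min_size`.
#' @export
read_gene_sets <- function(gmt_path, min_size = 1) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets, min_size = min_size)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param min_size Minimum retained set size after deduplication.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, min_size = 1) {
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) >= min_size]
  structure(sets, class = "gene_set_collection", min_size = min_size)
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_set_collection` or plain named list.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
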