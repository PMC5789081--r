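#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma, which is nearly linear; used by
#' [estimate_variance_prior()] to solve the moment equation for the prior
#' degrees of freedom.
#'
#' @param x Positive value; returns y with trigamma(y) = x.
#' @keywords internal
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) stop("trigamma_inverse requires x > 0")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate an empirical-Bayes variance prior
#'
#' Fits the scaled-F marginal model for per-gene sample variances: each
#' observed variance is s0_sq * F(df, d0) under the hierarchical model in
#' which true gene variances follow a scaled inverse chi-squared prior with
#' `d0` degrees of freedom and location `s0_sq`. Estimation is by moment
#' matching on log variances using digamma/trigamma identities. When the
#' empirical dispersion of the log variances is at or below the theoretical
#' sampling minimum (trigamma(df/2)), the prior is degenerate (`d0 = Inf`)
#' and only its location is estimated: from the geometric mean of the
#' variances when they are literally constant, otherwise from the
#' bias-corrected mean of the log variances (the chi-squared sampling bias
#' `digamma(df/2) - log(df/2)` is removed, as in limma's fitFDist).
#'
#' @param s_sq Numeric vector of per-gene sample variances (log2 units
#'   squared); at least 10 finite non-negative values required. Zeros are
#'   excluded from estimation with a warning.
#' @param df Residual degrees of freedom of each variance (scalar, >= 1).
#' @return A `variance_prior`: list with elements `d0` (prior degrees of
#'   freedom, possibly `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_variance_prior <- function(s_sq, df) {
  if (length(df) != 1L || !is.finite(df) || df < 1)
    stop("df must be a single value >= 1")
  s_sq <- s_sq[is.finite(s_sq)]
  if (any(s_sq < 0)) stop("sample variances must be non-negative")
  if (any(s_sq == 0)) {
    warning("zero variances excluded from prior estimation")
    s_sq <- s_sq[s_sq > 0]
  }
  if (length(s_sq) < 10L)
    stop("need at least 10 finite positive variances to estimate a prior (got ",
         length(s_sq), ")")
  z <- log(s_sq)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (stats::var(z) < 1e-12) {
    # variances are literally constant: point prior at the common value
    prior <- list(d0 = Inf, s0_sq = exp(mean(z)))
  } else if (evar <= 0) {
    # dispersion fully explained by chi-squared sampling noise: point prior,
    # with the log-scale sampling bias removed from the location estimate
    prior <- list(d0 = Inf, s0_sq = exp(mean(e)))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  structure(prior, class = "variance_prior")
}

#' Construct a variance prior directly
#' @param d0 Prior degrees of freedom (> 0, may be `Inf`).
#' @param s0_sq Prior variance (> 0). `d0 = 0` (no moderation) is allowed as
#'   a limiting case, in which `s0_sq` is ignored.
#' @return A `variance_prior`.
#' @export
variance_prior <- function(d0, s0_sq) {
  if (d0 < 0) stop("d0 must be >= 0")
  if (d0 > 0 && (!is.finite(s0_sq) || s0_sq <= 0))
    stop("s0_sq must be positive")
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' Moderated two-sample t-test with variance shrinkage
#'
#' For each gene, the pooled within-group variance is shrunk towards the
#' prior: `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)` with
#' `df = nA + nB - 2`, and the statistic is
#' `t = (meanA - meanB) / (s_tilde * sqrt(1/nA + 1/nB))`, referred to a t
#' distribution with `df + d0` degrees of freedom (standard normal when
#' `d0 = Inf`, the ordinary pooled t when `d0 = 0`). P-values are two-sided
#' and Benjamini-Hochberg adjusted across genes.
#'
#' @param groupA,groupB Numeric gene-by-replicate matrices with identical
#'   rownames and row order; at least 2 replicates each. The log2 fold change
#'   reported is `meanA - meanB` (treatment minus control).
#' @param prior A `variance_prior`, or `NULL` to estimate one from the pooled
#'   variances of this contrast via [estimate_variance_prior()].
#' @return Data frame with columns `gene`, `log2FC`, `t`, `df_total`, `p`,
#'   `adj_p`.
#' @export
moderated_t_test <- function(groupA, groupB, prior = NULL) {
  if (is.null(dim(groupA)) || is.null(dim(groupB)))
    stop("groupA and groupB must be matrices (genes x replicates)")
  if (nrow(groupA) != nrow(groupB) ||
      !identical(rownames(groupA), rownames(groupB)))
    stop("groupA and groupB must have identical gene order")
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2 || nB < 2)
    stop("at least 2 replicates required in each group (got ", nA, ", ", nB, ")")
  df <- nA + nB - 2
  meanA <- rowMeans(groupA); meanB <- rowMeans(groupB)
  ssA <- rowSums((groupA - meanA)^2)
  ssB <- rowSums((groupB - meanB)^2)
  s2 <- (ssA + ssB) / df
  if (is.null(prior)) prior <- estimate_variance_prior(s2, df)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  lfc <- meanA - meanB
  if (is.infinite(d0)) {
    s2_tilde <- rep.int(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_tilde <- s2
    df_total <- df
  } else {
    if (s0_sq == 0) stop("finite d0 with s0_sq = 0 is degenerate")
    s2_tilde <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  se <- sqrt(s2_tilde * (1 / nA + 1 / nB))
  if (any(se == 0 & lfc != 0))
    stop("zero residual variance with a non-zero fold change; ",
         "moderation prior cannot be degenerate here")
  t_mod <- ifelse(se == 0, 0, lfc / se)
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(gene = rownames(groupA), log2FC = lfc, t = t_mod,
             df_total = df_total, p = p, adj_p = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-sided Fisher over-representation p-value
#'
#' Probability of observing an overlap at least as large as `k` between a set
#' of size `m` and a draw of size `n` from a universe of size `N`, i.e. the
#' upper tail of the hypergeometric distribution (equivalently a one-sided
#' Fisher exact test for enrichment).
#'
#' @param k Observed overlap(s).
#' @param m Set size (e.g. a TF's targets within the background).
#' @param n Draw size (e.g. cluster size).
#' @param N Universe (background) size.
#' @return P(X >= k) with X ~ Hypergeometric(N, m, n). Vectorised.
#' @export
fisher_overrep <- function(k, m, n, N) {
  if (any(m > N) || any(n > N)) stop("set sizes cannot exceed the universe")
  if (any(k < 0) || any(k > pmin(m, n)))
    stop("overlap k inconsistent with margins")
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether two gene sets overlap more than expected for random sets of
#' the same sizes in a fixed symbol universe (default 41220 approved gene
#' symbols). The percentage reported is relative to `setA` (e.g. a curated
#' signature).
#'
#' @param setA,setB Character vectors of gene symbols.
#' @param universe_size Size of the symbol universe.
#' @return List with `k` (overlap), `percent` (100 * k / |setA|) and `p`
#'   (identical to [fisher_overrep()] at these margins).
#' @export
hypergeom_overlap_test <- function(setA, setB, universe_size = 41220) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(union(setA, setB)) > universe_size)
    stop("universe smaller than the union of the two sets")
  k <- length(intersect(setA, setB))
  p <- fisher_overrep(k, length(setA), length(setB), universe_size)
  percent <- if (length(setA) == 0) 0 else 100 * k / length(setA)
  list(k = k, percent = percent, p = p)
}

#' Yates continuity-corrected chi-squared test for a 2x2 table
#'
#' `chi2 = N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` with one
#' degree of freedom. The correction is clamped at zero, so perfectly equal
#' proportions give chi2 = 0 and p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `(a, b)` / `(c, d)`. Alternatively `a` may be a 2x2 matrix.
#' @return List with `chi2` and `p`.
#' @export
yates_chi_squared <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("table must be 2x2")
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  N <- sum(cells)
  if (N == 0) stop("empty contingency table")
  margins <- c("row1" = a + b, "row2" = c + d, "col1" = a + c, "col2" = b + d)
  zero <- names(margins)[margins == 0]
  if (length(zero))
    stop("zero margin in contingency table: ", paste(zero, collapse = ", "))
  corrected <- max(abs(a * d - b * c) - N / 2, 0)
  chi2 <- N * corrected^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Mean-rank gene-set (direction) test
#'
#' Ranks all genes by a per-gene statistic (log2 fold changes in typical use)
#' and asks whether the member genes of a set rank systematically high
#' (`alternative = "up"`), low (`"down"`), or extreme in absolute value
#' (`"mixed"`; genes are ranked by |statistic|). The p-value uses the normal
#' approximation to the rank sum:
#' `z = (meanRank_set - (N+1)/2) / sqrt((N - m)(N + 1) / (12 m))`,
#' with average ranks for ties.
#'
#' @param statistics Numeric vector of per-gene statistics, optionally named.
#' @param set_members Integer indices into `statistics`, or gene names when
#'   `statistics` is named. Must be a non-empty strict subset.
#' @param alternative One of `"up"`, `"down"`, `"mixed"`.
#' @return One-sided p-value (upper tail of |rank| for `"mixed"`).
#' @export
mean_rank_gene_set_test <- function(statistics,
                                    set_members,
                                    alternative = c("up", "down", "mixed")) {
  alternative <- match.arg(alternative)
  N <- length(statistics)
  if (N < 10) stop("need at least 10 genes to rank")
  if (is.character(set_members)) {
    if (is.null(names(statistics)))
      stop("statistics must be named to use gene-name set members")
    miss <- setdiff(set_members, names(statistics))
    if (length(miss))
      stop("set member(s) absent from statistics: ",
           paste(utils::head(miss, 5), collapse = ", "))
    set_members <- match(unique(set_members), names(statistics))
  }
  m <- length(set_members)
  if (m == 0) stop("gene set is empty")
  if (m >= N) stop("gene set must be a strict subset of all genes")
  r <- if (alternative == "mixed") rank(abs(statistics)) else rank(statistics)
  z <- (mean(r[set_members]) - (N + 1) / 2) /
    sqrt((N - m) * (N + 1) / (12 * m))
  switch(alternative,
         up    = stats::pnorm(z, lower.tail = FALSE),
         down  = stats::pnorm(z, lower.tail = TRUE),
         mixed = stats::pnorm(z, lower.tail = FALSE))
}

#' Jaccard index of two sets
#'
#' @param setA,setB Vectors (coerced to sets); at least one must be non-empty.
#' @return |intersection| / |union|.
#' @export
jaccard_index <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- union(setA, setB)
  if (length(u) == 0) stop("both sets are empty")
  length(intersect(setA, setB)) / length(u)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param x,y Vectors of cluster labels of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must have equal length")
  tab <- table(x, y)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / total
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
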