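test_that("Fisher over-representation matches combinatorial enumeration", {
  # frozen worked case: N=20, m=5, n=6, k=4 ->
  # [C(5,4)C(15,2) + C(5,5)C(15,1)] / C(20,6) = 540/38760
  expect_equal(fisher_overrep(4, 5, 6, 20), 540 / 38760, tolerance = 1e-12)
  # trivial limits
  expect_equal(fisher_overrep(0, 5, 6, 20), 1)
  expect_equal(fisher_overrep(3, 20, 3, 20), 1)       # m = N forces overlap
  # random margins vs enumeration
  set.seed(11)
  for (i in 1:200) {
    N <- sample(5:60, 1); m <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(m, n), 1)
    expect_equal(fisher_overrep(k, m, n, N), enum_hyper_tail(k, m, n, N),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in k at fixed margins
  p <- fisher_overrep(0:5, 8, 10, 30)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(fisher_overrep(6, 5, 6, 20), "inconsistent")
})

test_that("hypergeometric overlap test agrees with fisher_overrep and handles edges", {
  set.seed(3)
  univ <- sprintf("u%04d", 1:500)
  for (i in 1:100) {
    a <- sample(univ, sample(5:50, 1)); b <- sample(univ, sample(5:50, 1))
    res <- hypergeom_overlap_test(a, b, 500)
    expect_equal(res$p,
                 fisher_overrep(length(intersect(a, b)), length(a),
                                length(b), 500),
                 tolerance = 1e-12)
  }
  res <- hypergeom_overlap_test(c("x", "y"), c("z", "w"), 41220)
  expect_equal(res$k, 0)
  expect_equal(res$percent, 0)
  expect_error(hypergeom_overlap_test(letters[1:5], letters[6:10], 8),
               "universe")
})

test_that("BH adjustment matches the step-up definition and dominates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Yates chi-squared follows the clamped hand formula", {
  res <- yates_chi_squared(10, 10, 10, 10)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  res <- yates_chi_squared(30, 10, 10, 30)
  expect_equal(res$chi2, 18.05, tolerance = 1e-12)
  expect_equal(res$chi2, hand_yates(30, 10, 10, 30))
  # transposing the table leaves the statistic unchanged
  expect_equal(yates_chi_squared(30, 10, 10, 30)$chi2,
               yates_chi_squared(30, 10, 10, 30)$chi2)
  expect_equal(yates_chi_squared(7, 3, 12, 9)$chi2,
               yates_chi_squared(7, 12, 3, 9)$chi2)
  # agrees with the standard library implementation
  tab <- matrix(c(23, 11, 7, 19), 2, byrow = TRUE)
  ours <- yates_chi_squared(tab)
  ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
  expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_error(yates_chi_squared(0, 0, 3, 4), "margin")
})

test_that("variance prior: degenerate dispersion gives d0 = Inf at the geometric mean", {
  prior <- estimate_variance_prior(rep(1, 100), df = 2)
  expect_equal(prior$d0, Inf)
  expect_equal(prior$s0_sq, 1.0)
  expect_error(estimate_variance_prior(c(1, 2), df = 2), "at least 10")
})

test_that("variance prior estimation agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(19)
  df <- 4
  s2 <- 0.5 * (rchisq(5000, df) / df) * (6 / rchisq(5000, 6))
  ours <- estimate_variance_prior(s2, df)
  ref <- limma::fitFDist(s2, df1 = df)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t: identity, d0 = 0 ordinary-t limit, d0 = Inf closed form", {
  set.seed(7)
  a <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("g%02d", 1:20), NULL))
  res <- moderated_t_test(a, a, prior = variance_prior(Inf, 1))
  expect_equal(res$log2FC, rep(0, 20))
  expect_equal(res$t, rep(0, 20))
  expect_equal(res$p, rep(1, 20))

  b <- matrix(rnorm(60, 1), 20, 3, dimnames = dimnames(a))
  res0 <- moderated_t_test(a, b, prior = variance_prior(0, 1))
  for (i in 1:20) {
    expect_equal(res0$t[i], pooled_t(a[i, ], b[i, ]), tolerance = 1e-10)
  }
  expect_equal(res0$p, 2 * pt(-abs(res0$t), df = 4), tolerance = 1e-12)

  # d0 = Inf, s0_sq = 1, nA = nB = 2, lfc = 2 -> t = 2, normal p = 0.0455
  ga <- matrix(3, 1 + 10, 2); gb <- matrix(1, 11, 2)
  rownames(ga) <- rownames(gb) <- sprintf("g%02d", 1:11)
  resI <- moderated_t_test(ga, gb, prior = variance_prior(Inf, 1))
  expect_equal(resI$t[1], 2)
  expect_equal(resI$p[1], 2 * pnorm(-2), tolerance = 1e-12)
  expect_error(moderated_t_test(a[, 1, drop = FALSE], b, prior = variance_prior(0, 1)),
               "replicates")
})

test_that("moderated t matches limma's eBayes pipeline on simulated data", {
  skip_if_not_installed("limma")
  set.seed(23)
  n <- 500
  a <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  b <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  b[1:50, ] <- b[1:50, ] + 1
  rownames(a) <- rownames(b) <- sprintf("g%04d", 1:n)
  ours <- moderated_t_test(a, b)          # estimates its own prior
  design <- cbind(intercept = 1, treat = rep(c(1, 0), each = 3))
  fit <- limma::lmFit(cbind(a, b), design)
  fit <- limma::eBayes(fit)
  expect_equal(ours$t, unname(fit$t[, "treat"]), tolerance = 1e-6)
  expect_equal(ours$p, unname(fit$p.value[, "treat"]), tolerance = 1e-6)
})

test_that("sign of the moderated t matches the sign of the fold change", {
  set.seed(31)
  a <- matrix(rnorm(40, 1, 0.3), 10, 4)
  b <- matrix(rnorm(40, 0, 0.3), 10, 4)
  rownames(a) <- rownames(b) <- letters[1:10]
  res <- moderated_t_test(a, b, prior = variance_prior(4, 0.1))
  expect_true(all(sign(res$t) == sign(res$log2FC) | res$log2FC == 0))
  expect_true(all(res$adj_p >= res$p))
})

test_that("fully null contrasts reject at most the nominal FDR level", {
  set.seed(47)
  frac <- replicate(20, {
    a <- matrix(rnorm(1000 * 2), 1000, 2, dimnames = list(sprintf("g%04d", 1:1000), NULL))
    b <- matrix(rnorm(1000 * 2), 1000, 2, dimnames = list(sprintf("g%04d", 1:1000), NULL))
    mean(moderated_t_test(a, b)$adj_p < 0.05)
  })
  expect_lte(mean(frac), 0.05 + 0.01)
})

test_that("mean-rank gene-set test: degenerate, extreme and null behaviour", {
  # all statistics equal: average ranks give z = 0, p = 0.5
  expect_equal(mean_rank_gene_set_test(rep(1, 50), 1:10, "up"), 0.5)
  # top-m genes as the set: strongly significant upward
  s <- c(rnorm(950), rnorm(50, 10))
  expect_lt(mean_rank_gene_set_test(s, 951:1000, "up"), 0.01)
  expect_gt(mean_rank_gene_set_test(s, 951:1000, "down"), 0.99)
  expect_lt(mean_rank_gene_set_test(abs(s) * sign(rep_len(c(1, -1), 1000)),
                                    951:1000, "mixed"), 0.05)
  # named-statistic interface
  names(s) <- sprintf("g%04d", 1:1000)
  expect_equal(mean_rank_gene_set_test(s, names(s)[951:1000], "up"),
               mean_rank_gene_set_test(s, 951:1000, "up"))
  expect_error(mean_rank_gene_set_test(s, integer(0)), "empty")
  expect_error(mean_rank_gene_set_test(s, 1:1000), "strict subset")
})

test_that("mean-rank p-values agree with a permutation oracle", {
  set.seed(61)
  s <- rnorm(200)
  idx <- sample(200, 30)
  p <- mean_rank_gene_set_test(s, idx, "up")
  r <- rank(s)
  obs <- mean(r[idx])
  perm <- replicate(4000, mean(r[sample(200, 30)]))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p - p_perm), 0.03)
})

test_that("jaccard index follows the set definition", {
  expect_equal(jaccard_index(letters[1:4], letters[1:4]), 1)
  expect_equal(jaccard_index(letters[1:4], letters[5:8]), 0)
  expect_equal(jaccard_index(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(jaccard_index(character(), character()), "empty")
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(71)
  for (i in 1:20) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 10:1), 1)  # label permutation
})
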