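test_that("DE flags apply both thresholds, including large effects with weak p", {
  # gene 1: big, clean effect -> DE; gene 2: 0.4 lfc with tiny noise -> highly
  # significant but below the fold-change threshold -> not DE
  effects <- c(2, 0.4, rep(0, 18))
  em <- tiny_expression(n_genes = 20, effects = effects, noise_sd = 0.01,
                        seed = 9)
  det <- run_de_timecourse(em, "treated", "control",
                           config = de_config(early_times = 2, late_times = 24))
  g2 <- det[det$gene == "g002", ]
  expect_true(all(g2$adj_p < 1e-4))
  expect_false(any(g2$is_de))
  expect_true(all(det$is_de[det$gene == "g001"]))
  # stored flag always recomputable from stored columns
  expect_equal(det$is_de, abs(det$log2FC) > 0.5 & det$adj_p < 0.05)
})

test_that("a relabeled null contrast yields (almost) no DE calls", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:300)
  sheet <- expand.grid(replicate = 1:2, time_h = c(2, 24),
                       condition = c("a", "b"), stringsAsFactors = FALSE)
  sheet$sample_id <- with(sheet, paste(condition, time_h, replicate, sep = "_"))
  sheet <- sheet[, c("sample_id", "condition", "time_h", "replicate")]
  vals <- matrix(rnorm(300 * 8, 8, 0.3), 300,
                 dimnames = list(genes, sheet$sample_id))
  em <- expression_matrix(vals, sheet)
  det <- run_de_timecourse(em, "a", "b",
                           config = de_config(early_times = 2, late_times = 24))
  expect_lt(mean(det$is_de), 0.02)
})

test_that("de_sets implements union / early / late semantics", {
  lfc <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), c(2, 4, 8, 24)))
  de <- matrix(FALSE, 4, 4, dimnames = dimnames(lfc))
  de["g1", "24"] <- TRUE               # late only
  de["g2", c("4", "24")] <- TRUE       # early AND late
  de["g3", "2"] <- TRUE                # early only
  det <- manual_de_table(lfc, de)
  s <- de_sets(det)
  expect_setequal(s$union, c("g1", "g2", "g3"))
  expect_setequal(s$early, c("g2", "g3"))
  expect_setequal(s$late, c("g1", "g2"))
  expect_true("g2" %in% intersect(s$early, s$late))
  # union is exactly the union of per-timepoint sets
  expect_setequal(s$union, unique(unlist(s$per_time)))
  # empty DE table is fine
  s0 <- de_sets(manual_de_table(lfc, de & FALSE))
  expect_length(s0$union, 0)
  expect_error(de_sets(det, de_config(early_times = c(2, 4, 8, 12))), "12")
})

test_that("condition_overlap produces Venn regions and chi-squared calls", {
  lfc <- matrix(1, 100, 1, dimnames = list(sprintf("g%03d", 1:100), "2"))
  mk <- function(n_de, cond) {
    de <- matrix(FALSE, 100, 1, dimnames = dimnames(lfc))
    de[seq_len(n_de), 1] <- TRUE
    manual_de_table(lfc, de, condition = cond)
  }
  tabs <- list(a = mk(40, "a"), b = mk(40, "b"), c = mk(10, "c"))
  ov <- condition_overlap(tabs, 2)
  expect_equal(nrow(ov$venn), 7)      # 2^3 - 1 regions
  # identical a and b sets: all 40 in the a&b(&c) regions
  expect_equal(ov$venn$n[ov$venn$conditions == "a&b&c"], 10)
  expect_equal(ov$venn$n[ov$venn$conditions == "a&b"], 30)
  ab <- ov$pairwise[ov$pairwise$cond_a == "a" & ov$pairwise$cond_b == "b", ]
  expect_equal(ab$chi2, 0)            # equal proportions clamp to zero
  expect_equal(ab$p, 1)
  expect_error(condition_overlap(tabs[1], 2), "at least 2")
})

test_that("a dominant combined condition is detected by the proportion test", {
  cfg <- sim_config(n_genes = 3000, n_tfs = 8, targets_per_tf = c(10, 15),
                    k_true = 2, cluster_size = 100,
                    templates = profile_templates()[c("flat_up", "flat_down"), ],
                    noise_sd = 0.25, seed = 17)
  ds <- simulate_dataset(cfg)
  tabs <- lapply(c(drugA = "drugA", both = "both"), function(tr)
    run_de_timecourse(ds$expr, tr, "control"))
  ov <- condition_overlap(tabs, 24)
  row <- ov$pairwise[1, ]
  expect_gt(row$de_b, row$de_a)
  expect_lt(row$p, 0.001)
})

test_that("reversal analysis counts only significant opposite-direction changes", {
  lfc_model <- matrix(2, 10, 1, dimnames = list(paste0("g", 1:10), "2"))
  de_model <- matrix(TRUE, 10, 1, dimnames = dimnames(lfc_model))
  model <- manual_de_table(lfc_model, de_model, "model")

  # AO contrast: 4 genes significantly reversed, 2 significantly *further up*
  # (not reversed), rest unchanged
  lfc_ao <- matrix(0, 10, 1, dimnames = dimnames(lfc_model))
  de_ao <- matrix(FALSE, 10, 1, dimnames = dimnames(lfc_model))
  lfc_ao[1:4, 1] <- -2; de_ao[1:4, 1] <- TRUE
  lfc_ao[5:6, 1] <- 2;  de_ao[5:6, 1] <- TRUE
  ao <- manual_de_table(lfc_ao, de_ao, "model_AO")

  rs <- reversal_analysis(model, ao)
  expect_equal(rs$n_de_model, 10)
  expect_equal(rs$n_reversed, 4)
  expect_equal(rs$percent_reversed, 40)
  expect_true(is.na(rs$ji))

  # zero AO changes -> zero reversed
  rs0 <- reversal_analysis(model, manual_de_table(lfc_ao * 0, de_ao & FALSE))
  expect_equal(rs0$n_reversed, 0)
  expect_equal(rs0$percent_reversed, 0)

  # sign-only mode counts non-significant opposition too
  lfc_ao2 <- lfc_ao; lfc_ao2[7, 1] <- -0.1
  rs2 <- reversal_analysis(model, manual_de_table(lfc_ao2, de_ao),
                           require_significance = FALSE)
  expect_equal(rs2$n_reversed, 5)

  expect_error(reversal_analysis(manual_de_table(lfc_model, de_model & FALSE),
                                 ao), "empty")
})

test_that("planted anti-oxidant reversal is recovered quantitatively", {
  cfg <- sim_config(n_genes = 1500, n_tfs = 6, targets_per_tf = c(10, 15),
                    k_true = 2, cluster_size = 60,
                    templates = profile_templates()[c("flat_up", "flat_down"), ],
                    noise_sd = 0.2, reversal_fraction = 0.5, seed = 29)
  rev <- simulate_reversal(cfg)
  dm <- run_de_timecourse(rev$expr, "model", "control")
  da <- run_de_timecourse(rev$expr, "model_AO", "model")
  dac <- run_de_timecourse(rev$expr, "model_AO", "control")
  rs <- reversal_analysis(dm, da, de_modelAO_vs_ctrl = dac)
  expect_gt(rs$percent_reversed, 40)
  expect_lt(rs$percent_reversed, 60)
  # nearly all detected reversals are planted (the contrasts share the model
  # samples, so a rare extreme replicate can fake a reversal)
  expect_gte(mean(rs$reversed_genes %in% rev$truth$reversed), 0.9)
  # and nearly all planted reversals are detected
  expect_gte(mean(rev$truth$reversed %in% rs$reversed_genes), 0.9)
  expect_false(is.na(rs$ji))
  expect_lt(rs$ji, 0.7)               # AO removes about half the DE set
})

test_that("DE tables round-trip through TSV", {
  em <- tiny_expression(n_genes = 15, effects = c(rep(1, 5), rep(0, 10)),
                        seed = 33)
  det <- run_de_timecourse(em, "treated", "control",
                           config = de_config(early_times = 2, late_times = 24))
  path <- tempfile()
  write_de_table(det, path)
  det2 <- read_de_table(path)
  expect_equal(det2$is_de, det$is_de)
  expect_equal(det2$log2FC, det$log2FC, tolerance = 1e-12)
})
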