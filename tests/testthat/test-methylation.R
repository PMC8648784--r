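toy_probes <- function(delta, p_adj, pos, chrom = "chr1",
                       gene = "GENE1", region = "promoter") {
  n <- length(pos)
  list(probes = data.frame(probe_id = sprintf("P%02d", seq_len(n)),
                           delta_beta = delta, t = delta * 10,
                           p = p_adj / 2, p_adj = p_adj,
                           stringsAsFactors = FALSE),
       anno = data.frame(probe_id = sprintf("P%02d", seq_len(n)),
                         chrom = chrom, pos = pos, gene = gene,
                         region = region, stringsAsFactors = FALSE))
}

toy_betas <- function(n_probes, ids1, ids2, shift = 0) {
  b <- matrix(0.3, n_probes, length(c(ids1, ids2)),
              dimnames = list(sprintf("P%02d", seq_len(n_probes)),
                              c(ids1, ids2)))
  b[, ids1] <- b[, ids1] + shift
  b
}

test_that("probe tests: symmetry, identical groups, planted shifts", {
  set.seed(6)
  ids <- sprintf("s%02d", 1:40)
  labels <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = 20), ids)
  betas <- matrix(pmin(pmax(
    rbeta(100 * 40, 6, 14) , 0), 1), 100,
    dimnames = list(sprintf("P%03d", 1:100), ids))
  betas[1:5, 1:20] <- pmin(betas[1:5, 1:20] + 0.3, 1)   # planted shift
  res <- probe_tests(betas, labels)
  expect_true(all(res$p_adj[1:5] < 0.05))
  expect_true(all(res$delta_beta[1:5] > 0.2))
  swapped <- probe_tests(betas, labels, "APCmut_pos", "APCmut_neg")
  expect_equal(swapped$delta_beta, -res$delta_beta, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  # identical groups: duplicate the same samples under both labels
  dup <- cbind(betas[, 1:10], betas[, 1:10])
  colnames(dup) <- sprintf("d%02d", 1:20)
  labd <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = 10),
                   colnames(dup))
  resd <- probe_tests(dup, labd)
  expect_true(all(resd$p == 1))
  expect_error(probe_tests(betas[, 1:4],
                           labels[1:4]), ">= 3")
})

test_that("window merging follows gap, sign and size rules", {
  ids1 <- paste0("a", 1:5); ids2 <- paste0("b", 1:5)
  labels <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = 5),
                     c(ids1, ids2))
  # 5 adjacent significant probes, 200 bp apart -> one DMR with 5 probes
  tp <- toy_probes(rep(0.2, 5), rep(0.01, 5), pos = seq(100, 900, 200))
  betas <- toy_betas(5, ids1, ids2, 0.2)
  dmrs <- call_dmrs(tp$probes, tp$anno, betas, labels)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$n_probes, 5L)
  expect_equal(dmrs$start, 100L)
  expect_equal(dmrs$end, 901L)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$mean_beta_group1, 0.5, tolerance = 1e-12)
  expect_equal(dmrs$mean_beta_group2, 0.3, tolerance = 1e-12)
  # two clusters 5 kb apart -> two DMRs
  tp2 <- toy_probes(rep(0.2, 6), rep(0.01, 6),
                    pos = c(100, 300, 500, 5600, 5800, 6000))
  dmrs2 <- call_dmrs(tp2$probes, tp2$anno, toy_betas(6, ids1, ids2, 0.2),
                     labels)
  expect_equal(nrow(dmrs2), 2L)
  # opposite-sign probes never merge; min_probes filters singles
  tp3 <- toy_probes(c(0.2, 0.2, -0.2, 0.2, 0.2), rep(0.01, 5),
                    pos = seq(100, 900, 200))
  dmrs3 <- call_dmrs(tp3$probes, tp3$anno, toy_betas(5, ids1, ids2, 0.2),
                     labels, min_probes = 2)
  expect_equal(nrow(dmrs3), 2L)
  expect_true(all(dmrs3$direction == "hyper"))
  # a non-significant probe inside max_gap does not break the run
  tp4 <- toy_probes(rep(0.2, 5), c(0.01, 0.01, 0.5, 0.01, 0.01),
                    pos = seq(100, 900, 200))
  dmrs4 <- call_dmrs(tp4$probes, tp4$anno, toy_betas(5, ids1, ids2, 0.2),
                     labels, min_probes = 2)
  expect_equal(nrow(dmrs4), 1L)
  expect_equal(dmrs4$n_probes, 4L)
  # unsorted annotation is rejected
  bad_anno <- tp$anno
  bad_anno$pos <- rev(bad_anno$pos)
  expect_error(call_dmrs(tp$probes, bad_anno, betas, labels),
               "sorted")
})

test_that("multi-gene regions resolve to the most significant gene", {
  ids1 <- paste0("a", 1:5); ids2 <- paste0("b", 1:5)
  labels <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = 5),
                     c(ids1, ids2))
  tp <- toy_probes(rep(0.2, 4), c(0.02, 0.001, 0.02, 0.02),
                   pos = seq(100, 700, 200))
  tp$anno$gene <- c("GENEA", "GENEB", "GENEB", "GENEA")
  dmrs <- call_dmrs(tp$probes, tp$anno, toy_betas(4, ids1, ids2, 0.2),
                    labels)
  expect_equal(dmrs$gene, "GENEB")
})

test_that("dmr_summary counts by direction and region class", {
  res <- default_pipeline()
  summ <- res$dmr_summary
  expect_equal(sum(summ), nrow(res$dmrs))
  # planted promoter-heavy hypermethylation
  expect_gt(summ["hyper", "promoter"], summ["hypo", "promoter"])
  expect_gt(sum(summ["hyper", ]), sum(summ["hypo", ]))
  # empty input gives a zero table
  empty <- res$dmrs[0, ]
  expect_equal(sum(dmr_summary(empty)), 0L)
})

test_that("null cohorts yield essentially no DMRs", {
  n_null <- 0
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("s%02d", 1:30)
    labels <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = 15), ids)
    betas <- matrix(rbeta(800 * 30, 5, 10), 800,
                    dimnames = list(sprintf("P%03d", 1:800), ids))
    anno <- data.frame(probe_id = rownames(betas), chrom = "chr1",
                       pos = seq(0, by = 400, length.out = 800),
                       gene = "G", region = "body",
                       stringsAsFactors = FALSE)
    pr <- probe_tests(betas, labels)
    n_null <- n_null + nrow(call_dmrs(pr, anno, betas, labels))
  }
  expect_lte(n_null, 2)
})

test_that("planted AXIN2 DMR is recovered and anchors the correlation", {
  res <- default_pipeline()
  sim <- default_sim()
  planted <- sim$truth$dmrs
  ax_truth <- planted[planted$gene == "AXIN2", ]
  ax_called <- res$dmrs[res$dmrs$gene == "AXIN2", ]
  expect_equal(nrow(ax_called), 1L)
  expect_equal(ax_called$direction, "hyper")
  # boundaries within +/- 2 probes of the planted run (150 bp spacing)
  expect_lte(abs(ax_called$start - ax_truth$start), 2 * 150 + 1)
  expect_lte(abs(ax_called$end - ax_truth$end), 2 * 150 + 1)
  # AXIN2 ranks first by |r| against RNF43 expression, with negative r
  corr <- res$dmr_correlation$methylation
  expect_equal(corr$gene[1], "AXIN2")
  expect_lt(corr$r[1], 0)
})
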