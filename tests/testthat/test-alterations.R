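test_that("fisher_exact_2x2 equals enumeration and fisher.test", {
  set.seed(42)
  for (i in 1:300) {
    tab <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])$p
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(tab, 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_exact_2x2 handles degenerate and zero-cell tables", {
  res <- fisher_exact_2x2(0, 10, 0, 10)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  res2 <- fisher_exact_2x2(5, 0, 2, 8)
  expect_true(res2$zero_cell)
  expect_equal(res2$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4))
})

test_that("alteration matrix encodes mutations, CNAs and fusions", {
  sim <- small_sim()
  co <- classify_samples(sim$cohort)
  alt <- build_alteration_matrix(co)
  expect_true(all(alt$matrix %in% 0:1))
  # silent-only events never set the indicator
  sil <- co$mutations[co$mutations$variant_class == "silent", ]
  row1 <- sil[1, ]
  others <- co$mutations[co$mutations$sample_id == row1$sample_id &
                           co$mutations$gene == row1$gene &
                           co$mutations$variant_class != "silent", ]
  if (nrow(others) == 0 && row1$gene %in% rownames(alt$matrix))
    expect_equal(alt$matrix[row1$gene, row1$sample_id], 0L)
  # BRAF V600E carriers are flagged
  brf <- co$mutations$sample_id[co$mutations$protein_change == "V600E"]
  brf <- intersect(brf, colnames(alt$matrix))
  expect_true(all(alt$matrix["BRAF", brf] == 1L))
  # fusion pseudo-gene present and matches the fusion table
  expect_true("PTPRK-RSPO3" %in% rownames(alt$matrix))
  fus <- intersect(co$fusions$sample_id, colnames(alt$matrix))
  expect_equal(sum(alt$matrix["PTPRK-RSPO3", ]), length(fus))
})

test_that("enrichment scan ranks planted drivers and respects symmetry", {
  sim <- default_sim()
  co <- classify_samples(sim$cohort)
  alt <- build_alteration_matrix(co)
  scan <- enrichment_scan(alt, co$labels)
  expect_true(all(diff(scan$p) >= 0))
  expect_true(all(scan$p_adj >= scan$p - 1e-15))
  planted <- c("RNF43", "BRAF", "PTPRK-RSPO3")
  expect_true(all(planted %in% head(scan$gene, 5)))
  # swapping groups inverts odds ratios
  swapped <- enrichment_scan(alt, co$labels, group1 = "APCmut_pos",
                             group2 = "APCmut_neg")
  shared <- intersect(scan$gene[is.finite(scan$odds_ratio) &
                                  scan$odds_ratio > 0], swapped$gene)
  or1 <- setNames(scan$odds_ratio, scan$gene)[shared]
  or2 <- setNames(swapped$odds_ratio, swapped$gene)[shared]
  expect_equal(or2, 1 / or1, tolerance = 1e-12)
  # genes below min_altered are absent
  rare <- rownames(alt$matrix)[rowSums(alt$matrix) < 3]
  expect_length(intersect(rare, scan$gene), 0)
})

test_that("enrichment p-values are uniform under label permutation", {
  sim <- small_sim()
  co <- classify_samples(sim$cohort)
  alt <- build_alteration_matrix(co)
  set.seed(99)
  pvals <- unlist(lapply(1:50, function(i) {
    perm <- setNames(sample(co$labels), names(co$labels))
    enrichment_scan(alt, perm)$p
  }))
  # exact-test p-values are discrete and conservative under the null:
  # the empirical CDF must never exceed the uniform CDF beyond noise
  for (q in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(q * (1 - q) / length(pvals))
    expect_lt(mean(pvals <= q), q + 2.58 * se)
  }
})

test_that("clinical association reports Welch t and Fisher by level", {
  sim <- default_sim()
  co <- classify_samples(sim$cohort)
  rep <- clinical_association(co$clinical, co$labels)
  age <- rep[rep$feature == "age_at_diagnosis", ]
  expect_lt(age$mean1, age$mean2)          # younger onset in APCmut-
  expect_lt(age$p, 0.05)
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  # identical groups: continuous t = 0 -> p = 1, categorical p = 1
  labs <- co$labels
  half <- names(labs)[labs == "APCmut_pos"]
  clin2 <- co$clinical[co$clinical$sample_id %in% half, ]
  clin_dup <- rbind(clin2, transform(clin2,
                                     sample_id = paste0(sample_id, "_b")))
  labs2 <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = nrow(clin2)),
                    clin_dup$sample_id)
  rep2 <- clinical_association(clin_dup, labs2)
  expect_true(all(abs(rep2$p - 1) < 1e-9))
})

test_that("mutual exclusivity test matches the hypergeometric tail", {
  # 10-vs-10 disjoint alterations in 40 samples: P(overlap = 0) under the
  # independence null is dhyper(0, 10, 30, 10) ~ 0.0226
  mat <- matrix(0L, 2, 40,
                dimnames = list(c("GA", "GB"), sprintf("s%02d", 1:40)))
  mat["GA", 1:10] <- 1L
  mat["GB", 11:20] <- 1L
  res <- mutual_exclusivity(mat, c("GA", "GB"), n_perm = 10000, seed = 2)
  expect_equal(res$co_occurrence, 0)
  expect_lt(res$p_exclusive, 0.05)
  expect_equal(res$p_exclusive, dhyper(0, 10, 30, 10), tolerance = 0.3)
  # identical alteration vectors are maximally co-occurrent
  mat["GB", ] <- mat["GA", ]
  res2 <- mutual_exclusivity(mat, c("GA", "GB"), n_perm = 1000, seed = 2)
  expect_gt(res2$p_exclusive, 0.95)
  expect_error(mutual_exclusivity(mat, c("GA", "NOPE")), "absent")
})

test_that("dependency Welch t matches a hand-computed 3-vs-3 example", {
  # group1 = (1, 2, 3), group2 = (2, 4, 9): means 2 and 5, variances 1
  # and 13; t = -3 / sqrt(1/3 + 13/3) = -1.388730;
  # df = (14/3)^2 / ((1/9 + 169/9) / 2) = 2.306~ -> p = 0.2895
  dep <- rbind(g1 = c(1, 2, 3, 2, 4, 9))
  colnames(dep) <- sprintf("c%d", 1:6)
  labels <- setNames(rep(c("APCmut_neg", "APCmut_pos"), each = 3),
                     colnames(dep))
  res <- dependency_welch(dep, labels)
  expect_equal(res$t, -3 / sqrt(14 / 3), tolerance = 1e-12)
  tt <- t.test(c(1, 2, 3), c(2, 4, 9))
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-9)
  # identical groups: t = 0, p = 1
  dep2 <- rbind(g1 = c(5, 6, 7, 5, 6, 7))
  colnames(dep2) <- colnames(dep)
  res2 <- dependency_welch(dep2, labels)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("BH adjustment is monotone, bounded and matches the oracle", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
})
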