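toy_expr <- function() {
  mat <- rbind(RSPO3 = c(2, 4, 6), RNF43 = c(6, 4, 2),
               ZNRF3 = c(5, 4, 3), WNT3 = c(1, 2, 3))
  colnames(mat) <- c("s1", "s2", "s3")
  mat
}

test_that("wnt_ls matches the hand-computed three-sample example", {
  res <- wnt_ls(toy_expr(), wnt_genes = "WNT3")
  # raw score is perfectly linear across the three samples, so the outer
  # z-scoring gives (-1, 0, 1) under the sample-sd convention
  expect_equal(res$wnt_ls, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(mean(res$wnt_ls), 0, tolerance = 1e-12)
  expect_equal(sd(res$wnt_ls), 1, tolerance = 1e-12)
  expect_equal(res$max_wnt, c(1, 2, 3))
  expect_equal(res$rspo3_z, -res$rnf43_z, tolerance = 1e-12)
})

test_that("constant gene expression is rejected", {
  mat <- toy_expr()
  mat["ZNRF3", ] <- 4
  expect_error(wnt_ls(mat), "ZNRF3")
})

test_that("wnt_ls is invariant to per-gene affine rescaling", {
  sim <- small_sim()
  expr <- normalize_counts(sim$cohort$counts[
    filter_genes(sim$cohort$counts), ])
  a <- wnt_ls(expr)
  mat <- expr$logcpm
  mat["RSPO3", ] <- 7 * mat["RSPO3", ] - 3
  mat["RNF43", ] <- 0.2 * mat["RNF43", ] + 11
  b <- wnt_ls(mat)
  expect_equal(b$wnt_ls, a$wnt_ls, tolerance = 1e-9)
})

test_that("clustering recovers planted blocks and is order-invariant", {
  set.seed(5)
  n1 <- 8; n2 <- 7
  ids <- sprintf("s%02d", 1:(n1 + n2))
  mat <- matrix(rnorm(30 * (n1 + n2), 0, 0.3), 30,
                dimnames = list(sprintf("g%02d", 1:30), ids))
  mat[1:15, 1:n1] <- mat[1:15, 1:n1] + 3        # block structure
  wl_fake <- data.frame(sample_id = ids,
                        wnt_ls = c(rep(-1, n1), rep(1, n2)))
  sub <- cluster_apcneg(mat, ids, rownames(mat), wl_fake)
  expect_equal(unname(sub$cluster[1:n1]), rep("CL1", n1))
  expect_equal(unname(sub$cluster[(n1 + 1):(n1 + n2)]), rep("CL2", n2))
  # permuting sample order yields the identical partition
  perm <- sample(ids)
  sub2 <- cluster_apcneg(mat[, perm], perm, rownames(mat), wl_fake)
  expect_identical(sub2$cluster[ids], sub$cluster[ids])
  # a duplicated sample joins its twin
  mat2 <- cbind(mat, twin = mat[, 1])
  sub3 <- cluster_apcneg(mat2, c(ids, "twin"), rownames(mat), wl_fake)
  expect_equal(unname(sub3$cluster["twin"]), unname(sub3$cluster[ids[1]]))
  expect_error(cluster_apcneg(mat, ids, "g01", wl_fake), ">= 2 DE genes")
  # the dendrogram serializes to Newick
  expect_match(sub$newick, "^\\(")
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(31)
  for (i in 1:20) {
    x <- sample(1:3, 40, TRUE)
    y <- sample(1:4, 40, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2), c(2, 2, 1)), 1)
})

test_that("CL1/CL2 recovery on the default cohort reaches ARI >= 0.9", {
  res <- default_pipeline()
  sim <- default_sim()
  ari <- adjusted_rand_index(
    res$subtypes$cluster[names(sim$truth$cluster)], sim$truth$cluster)
  expect_gte(ari, 0.9)
})

test_that("group summary mirrors the planted WNT biology", {
  res <- default_pipeline()
  sim <- default_sim()
  summ <- res$wnt_summary
  get <- function(g, col) summ[summ$group == g, col]
  # fusion carriers have the highest WNT-LS of all groups
  expect_equal(summ$group[which.max(summ$mean_wnt_ls)],
               "PTPRK_RSPO3_fusion")
  # and the lowest WNT ligand expression
  expect_equal(summ$group[which.min(summ$mean_max_wnt)],
               "PTPRK_RSPO3_fusion")
  # CL2 groups sit above APCmut+; CL1 is comparable to APCmut+
  expect_gt(get("CL2_no_driver", "mean_wnt_ls"),
            get("APCmut_pos", "mean_wnt_ls"))
  expect_lt(abs(get("CL1", "mean_wnt_ls") -
                  get("APCmut_pos", "mean_wnt_ls")), 0.6)
  # empty groups are omitted with a warning
  warns <- capture_warnings(
    wnt_group_summary(res$wntls, res$labels, res$subtypes,
                      setNames(rep("none", 3),
                               names(res$subtypes$cluster)[1:3])))
  expect_true(any(grepl("empty group", warns)))
  # a single-member group reports its own values
  one <- res$wntls[1, ]
  drv1 <- setNames("rnf43_mut", one$sample_id)
  s1 <- suppressWarnings(
    wnt_group_summary(res$wntls, res$labels, res$subtypes, drv1))
  expect_equal(s1$mean_wnt_ls[s1$group == "RNF43_mut"], one$wnt_ls)
})

test_that("driver subgroups derived from tables match generator truth", {
  sim <- small_sim()
  co <- classify_samples(sim$cohort)
  drv <- driver_subgroups(co)
  expect_identical(drv[names(sim$truth$drivers)], sim$truth$drivers)
})
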