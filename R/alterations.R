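# Binary alteration matrix and group comparisons: two-tailed Fisher
# enrichment per gene, Table-1-style clinical associations, a
# frequency-preserving permutation test of pairwise mutual exclusivity,
# and Welch tests on dependency screens.

#' Build the binary alteration matrix
#'
#' One row per altered gene (plus fusion pseudo-genes named
#' `gene5-gene3`), one column per retained (non-excluded, tumor) sample.
#' An entry is 1 iff the sample carries a non-silent mutation, deep
#' deletion or amplification in the gene, or the fusion.
#'
#' @param cohort A classified `crc_cohort`.
#' @param nonsilent Variant classes counted as altering.
#' @return List with `matrix` (binary gene x sample), and `events`, a
#'   long-format data.frame (sample_id, gene, alteration_kind) suitable
#'   for oncoprint-style output.
#' @export
build_alteration_matrix <- function(cohort,
                                    nonsilent = nonsilent_classes()) {
  stopifnot(!is.null(cohort$labels))
  keep <- names(cohort$labels)[cohort$labels %in%
                                 c("APCmut_neg", "APCmut_pos")]
  mut <- cohort$mutations
  mut <- mut[mut$sample_id %in% keep &
               mut$variant_class %in% nonsilent, , drop = FALSE]
  cna <- cohort$cna
  cna <- cna[cna$sample_id %in% keep & cna$call != "neutral", , drop = FALSE]
  fus <- cohort$fusions
  fus <- fus[fus$sample_id %in% keep, , drop = FALSE]

  events <- rbind(
    data.frame(sample_id = mut$sample_id, gene = mut$gene,
               alteration_kind = "mutation", stringsAsFactors = FALSE),
    data.frame(sample_id = cna$sample_id, gene = cna$gene,
               alteration_kind = ifelse(cna$call == "deep_deletion",
                                        "deep_deletion", "amplification"),
               stringsAsFactors = FALSE),
    data.frame(sample_id = fus$sample_id,
               gene = paste0(fus$gene5, "-", fus$gene3),
               alteration_kind = "fusion", stringsAsFactors = FALSE))
  events <- events[!duplicated(events[c("sample_id", "gene",
                                        "alteration_kind")]), ]
  genes <- sort(unique(events$gene))
  mat <- matrix(0L, length(genes), length(keep),
                dimnames = list(genes, keep))
  mat[cbind(match(events$gene, genes), match(events$sample_id, keep))] <- 1L
  list(matrix = mat, events = events)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the probability-mass two-tailed
#' convention: the p-value is the sum, over all tables with the observed
#' margins, of probabilities no larger than the observed table's.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are groups
#'   (a + b = group 1), columns altered/unaltered.
#' @return List with `odds_ratio` (ad/bc; Inf or 0 with a `zero_cell`
#'   flag when a cell is empty) and `p` (two-tailed). A table with an
#'   all-zero margin returns p = 1 with `degenerate = TRUE`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0),
            all(c(a, b, c, d) == round(c(a, b, c, d))))
  m <- a + c; n <- b + d; k <- a + b
  zero_cell <- any(c(a, b, c, d) == 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0)
    return(list(odds_ratio = or, p = 1, zero_cell = zero_cell,
                degenerate = TRUE))
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  list(odds_ratio = or, p = p, zero_cell = zero_cell, degenerate = FALSE)
}

#' Per-gene alteration enrichment scan
#'
#' Two-tailed Fisher test of each gene's alteration frequency between two
#' label groups, ranked by ascending p with BH adjustment.
#'
#' @param alt Result of [build_alteration_matrix()] (or its `matrix`).
#' @param labels Named label vector.
#' @param group1,group2 Label values defining the two groups.
#' @param min_altered Minimum total altered samples for a gene to enter
#'   the scan.
#' @return data.frame (gene, a, b, c, d, odds_ratio, p, p_adj) sorted by
#'   ascending p; a/b are altered/unaltered in group1.
#' @export
enrichment_scan <- function(alt, labels, group1 = "APCmut_neg",
                            group2 = "APCmut_pos", min_altered = 3) {
  mat <- if (is.list(alt)) alt$matrix else alt
  g1 <- intersect(colnames(mat), names(labels)[labels == group1])
  g2 <- intersect(colnames(mat), names(labels)[labels == group2])
  if (!length(g1) || !length(g2)) stop2("both groups must be non-empty")
  keep <- rowSums(mat[, c(g1, g2), drop = FALSE]) >= min_altered
  mat <- mat[keep, , drop = FALSE]
  rows <- lapply(rownames(mat), function(g) {
    a <- sum(mat[g, g1]); b <- length(g1) - a
    c_ <- sum(mat[g, g2]); d <- length(g2) - c_
    f <- fisher_exact_2x2(a, b, c_, d)
    data.frame(gene = g, a = a, b = b, c = c_, d = d,
               odds_ratio = f$odds_ratio, p = f$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(gene = character(), a = integer(),
    b = integer(), c = integer(), d = integer(), odds_ratio = numeric(),
    p = numeric(), p_adj = numeric()))
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Clinical feature association report
#'
#' Compares clinical covariates between two label groups the way a
#' cohort-description table does: Welch two-tailed t for continuous
#' features, two-tailed Fisher per categorical level.
#'
#' @param clinical Clinical data.frame.
#' @param labels Named label vector.
#' @param group1,group2 Label values to compare.
#' @return data.frame (feature, level, type, mean1/mean2 or counts, p).
#' @export
clinical_association <- function(clinical, labels,
                                 group1 = "APCmut_neg",
                                 group2 = "APCmut_pos") {
  ids1 <- names(labels)[labels == group1]
  ids2 <- names(labels)[labels == group2]
  cl1 <- clinical[clinical$sample_id %in% ids1, ]
  cl2 <- clinical[clinical$sample_id %in% ids2, ]
  rows <- list()
  w <- welch_t(cl1$age_at_diagnosis, cl2$age_at_diagnosis)
  rows[[1]] <- data.frame(feature = "age_at_diagnosis", level = "",
                          type = "continuous",
                          mean1 = mean(cl1$age_at_diagnosis, na.rm = TRUE),
                          mean2 = mean(cl2$age_at_diagnosis, na.rm = TRUE),
                          n1_level = NA, n2_level = NA, p = w$p,
                          stringsAsFactors = FALSE)
  for (feat in c("sex", "race", "stage", "cimp")) {
    v1 <- cl1[[feat]]; v2 <- cl2[[feat]]
    ok1 <- !is.na(v1) & v1 != "unknown"; ok2 <- !is.na(v2) & v2 != "unknown"
    for (lev in sort(unique(c(v1[ok1], v2[ok2])))) {
      a <- sum(v1[ok1] == lev); b <- sum(ok1) - a
      c_ <- sum(v2[ok2] == lev); d <- sum(ok2) - c_
      f <- fisher_exact_2x2(a, b, c_, d)
      rows[[length(rows) + 1]] <- data.frame(
        feature = feat, level = lev, type = "categorical",
        mean1 = NA, mean2 = NA, n1_level = a, n2_level = c_, p = f$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise mutual exclusivity by permutation
#'
#' Null distribution of the co-occurrence count of two altered genes under
#' independent per-gene permutation of sample labels, which preserves each
#' gene's alteration frequency. The p-value is the lower-tail frequency of
#' permuted co-occurrence counts at or below the observed count, with a
#' +1 pseudocount.
#'
#' @param alt Result of [build_alteration_matrix()] (or its `matrix`).
#' @param gene_pair Character vector of two gene (or fusion pseudo-gene)
#'   names.
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @return List with `co_occurrence` (observed count) and `p_exclusive`.
#' @export
mutual_exclusivity <- function(alt, gene_pair, n_perm = 10000, seed = 1) {
  mat <- if (is.list(alt)) alt$matrix else alt
  stopifnot(length(gene_pair) == 2, n_perm >= 1000)
  missing <- setdiff(gene_pair, rownames(mat))
  if (length(missing))
    stop2("gene(s) absent from alteration matrix: ",
          paste(missing, collapse = ", "))
  x <- mat[gene_pair[1], ]; y <- mat[gene_pair[2], ]
  obs <- sum(x == 1 & y == 1)
  n <- length(x); kx <- sum(x); ky <- sum(y)
  set.seed(seed)
  null_co <- vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(n, kx); iy <- sample.int(n, ky)
    length(intersect(ix, iy))
  }, integer(1))
  p <- (1 + sum(null_co <= obs)) / (n_perm + 1)
  list(co_occurrence = obs, p_exclusive = p)
}

#' Welch t-test per gene on dependency scores
#'
#' Compares CRISPR dependency scores between two groups of cell lines,
#' gene by gene (Welch's unequal-variance t with Satterthwaite degrees of
#' freedom, two-tailed).
#'
#' @param dep_scores Numeric matrix, genes x cell lines.
#' @param labels Named label vector over cell lines.
#' @param group1,group2 Label values to compare.
#' @return data.frame (gene, delta, t, df, p, p_adj) sorted by p.
#' @export
dependency_welch <- function(dep_scores, labels,
                             group1 = "APCmut_neg",
                             group2 = "APCmut_pos") {
  idx1 <- which(colnames(dep_scores) %in% names(labels)[labels == group1])
  idx2 <- which(colnames(dep_scores) %in% names(labels)[labels == group2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop2("need >= 2 cell lines per group")
  res <- rowwise_welch(dep_scores, idx1, idx2)
  out <- data.frame(gene = rownames(dep_scores), delta = res$delta,
                    t = res$t, df = res$df, p = res$p,
                    p_adj = bh_adjust(res$p), stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
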