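# Simplified DMR analysis on beta values: per-probe Welch tests with BH
# adjustment, window-merge region calling over significant probes with
# consistent direction, region summaries, and DMR/expression correlation
# against an anchor gene.

#' Per-probe differential methylation tests
#'
#' Welch two-tailed t on beta values per probe between two label groups,
#' BH-adjusted across probes.
#'
#' @param betas Probes x samples beta matrix in \[0,1\].
#' @param labels Named label vector.
#' @param group1,group2 Label values; delta_beta = mean(group1) -
#'   mean(group2).
#' @return data.frame (probe_id, delta_beta, t, p, p_adj) in probe order.
#' @export
probe_tests <- function(betas, labels, group1 = "APCmut_neg",
                        group2 = "APCmut_pos") {
  idx1 <- which(colnames(betas) %in% names(labels)[labels == group1])
  idx2 <- which(colnames(betas) %in% names(labels)[labels == group2])
  if (length(idx1) < 3 || length(idx2) < 3)
    stop2("each group needs >= 3 samples")
  res <- rowwise_welch(betas, idx1, idx2)
  data.frame(probe_id = rownames(betas), delta_beta = res$delta,
             t = res$t, p = res$p, p_adj = bh_adjust(res$p),
             stringsAsFactors = FALSE)
}

#' Call differentially methylated regions by window merging
#'
#' Significant probes (p_adj below the cutoff) with a consistent
#' delta-beta sign are merged into regions whenever consecutive same-sign
#' significant probes on one chromosome are at most `max_gap` apart;
#' regions with fewer than `min_probes` members are dropped. Regions are
#' annotated to the gene among their member probes with the smallest
#' minimum p; per-group region methylation is the mean beta over the
#' region's significant probes. Coordinates are 0-based half-open
#' (`end` = last probe position + 1).
#'
#' @param probes Result of [probe_tests()].
#' @param probe_anno Probe annotation (probe_id, chrom, pos, gene,
#'   region), position-sorted within chromosome.
#' @param betas Beta matrix (for the per-group means).
#' @param labels,group1,group2 As in [probe_tests()].
#' @param p_adj_cut Significance cutoff on adjusted p (default 0.05).
#' @param max_gap Maximum within-region gap in bp (default 1000).
#' @param min_probes Minimum member probes per region (default 3).
#' @return data.frame (chrom, start, end, n_probes, gene, region,
#'   direction, mean_beta_group1, mean_beta_group2, min_p, probe_ids
#'   \[list column\]).
#' @export
call_dmrs <- function(probes, probe_anno, betas, labels,
                      group1 = "APCmut_neg", group2 = "APCmut_pos",
                      p_adj_cut = 0.05, max_gap = 1000, min_probes = 3) {
  anno <- probe_anno[match(probes$probe_id, probe_anno$probe_id), ]
  if (anyNA(anno$probe_id)) stop2("probes missing from annotation")
  for (ch in unique(anno$chrom)) {
    pos <- anno$pos[anno$chrom == ch]
    if (is.unsorted(pos)) stop2("annotation not position-sorted on ", ch)
  }
  sig <- probes$p_adj < p_adj_cut
  df <- cbind(anno, probes[c("delta_beta", "p", "p_adj")])[sig, ,
                                                           drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer(),
                      gene = character(), region = character(),
                      direction = character(), mean_beta_group1 = numeric(),
                      mean_beta_group2 = numeric(), min_p = numeric())
  empty$probe_ids <- list()
  if (!nrow(df)) return(empty)

  df <- df[order(df$chrom, df$pos), ]
  new_block <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                   diff(df$pos) > max_gap |
                   sign(df$delta_beta[-1]) != sign(df$delta_beta[-nrow(df)]))
  block <- cumsum(new_block)

  ids1 <- intersect(colnames(betas), names(labels)[labels == group1])
  ids2 <- intersect(colnames(betas), names(labels)[labels == group2])
  rows <- lapply(split(seq_len(nrow(df)), block), function(i) {
    b <- df[i, , drop = FALSE]
    if (nrow(b) < min_probes) return(NULL)
    gene_minp <- tapply(b$p, b$gene, min)
    gene <- names(gene_minp)[which.min(gene_minp)]
    out <- data.frame(
      chrom = b$chrom[1], start = min(b$pos), end = max(b$pos) + 1L,
      n_probes = nrow(b), gene = gene,
      region = b$region[which.min(b$p)],
      direction = if (b$delta_beta[1] > 0) "hyper" else "hypo",
      mean_beta_group1 = mean(betas[b$probe_id, ids1]),
      mean_beta_group2 = mean(betas[b$probe_id, ids2]),
      min_p = min(b$p), stringsAsFactors = FALSE)
    out$probe_ids <- list(b$probe_id)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res <- res[order(res$min_p), ]
  rownames(res) <- NULL
  res
}

#' Count DMRs by direction and genomic region class
#'
#' @param dmrs Result of [call_dmrs()].
#' @return Contingency table direction x region class (promoter / body /
#'   intergenic), zero-filled.
#' @export
dmr_summary <- function(dmrs) {
  table(factor(dmrs$direction, levels = c("hyper", "hypo")),
        factor(dmrs$region,
               levels = c("promoter", "body", "intergenic")))
}

#' Rank DMRs and their genes by correlation with an anchor gene
#'
#' Per DMR: the per-sample mean beta over its significant probes is
#' correlated (Pearson) with the anchor gene's expression; separately,
#' each DMR gene's own expression is correlated with the anchor's.
#' Constant DMRs are flagged with NA correlations.
#'
#' @param dmrs Result of [call_dmrs()].
#' @param betas Beta matrix.
#' @param expr An `expr_matrix` or logcpm matrix.
#' @param anchor_gene Anchor gene symbol (default "RNF43").
#' @param samples Optional sample subset (default: samples shared between
#'   betas and expression).
#' @return List with `methylation` (data.frame gene, chrom, start, end,
#'   r, p sorted by |r|) and `expression` (data.frame gene, r, p).
#' @export
dmr_expression_correlation <- function(dmrs, betas, expr,
                                       anchor_gene = "RNF43",
                                       samples = NULL) {
  mat <- if (inherits(expr, "expr_matrix")) expr$logcpm else expr
  if (!anchor_gene %in% rownames(mat))
    stop2("anchor gene absent from expression: ", anchor_gene)
  samples <- samples %||% intersect(colnames(betas), colnames(mat))
  if (length(samples) < 3) stop2("need >= 3 shared samples")
  anchor <- mat[anchor_gene, samples]
  cor_p <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(NA_real_, NA_real_))
    r <- stats::cor(x, y)
    tt <- r * sqrt((length(x) - 2) / (1 - r^2))
    c(r, 2 * stats::pt(-abs(tt), length(x) - 2))
  }
  meth_rows <- lapply(seq_len(nrow(dmrs)), function(k) {
    pid <- dmrs$probe_ids[[k]]
    mb <- colMeans(betas[pid, samples, drop = FALSE])
    rp <- cor_p(mb, anchor)
    data.frame(gene = dmrs$gene[k], chrom = dmrs$chrom[k],
               start = dmrs$start[k], end = dmrs$end[k],
               r = rp[1], p = rp[2], stringsAsFactors = FALSE)
  })
  meth <- do.call(rbind, meth_rows)
  meth <- meth[order(-abs(meth$r)), ]
  rownames(meth) <- NULL

  genes <- intersect(unique(dmrs$gene), rownames(mat))
  expr_rows <- lapply(genes, function(g) {
    rp <- cor_p(mat[g, samples], anchor)
    data.frame(gene = g, r = rp[1], p = rp[2], stringsAsFactors = FALSE)
  })
  expression <- do.call(rbind, expr_rows)
  if (!is.null(expression)) {
    expression <- expression[order(-abs(expression$r)), ]
    rownames(expression) <- NULL
  }
  list(methylation = meth, expression = expression)
}
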