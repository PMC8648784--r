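# Expression: CPM filtering, median-ratio normalized log2-CPM, and an
# empirical-Bayes moderated two-sample t with moment-matched
# hyperparameters.

#' Filter lowly expressed genes
#'
#' A gene is discarded iff it has less than one count per million in more
#' than half the samples (strict majority: a gene below 1 CPM in exactly
#' half of an even n is retained).
#'
#' @param counts Integer matrix, genes x samples.
#' @return Character vector of retained gene names.
#' @export
filter_genes <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  low <- rowSums(cpm < 1)
  rownames(counts)[low <= ncol(counts) / 2]
}

#' Normalize counts to log2 counts-per-million
#'
#' `logcpm = log2((count + prior) / effective_library_size * 1e6)` with
#' median-of-ratios scaled effective library sizes (DESeq-style size
#' factors rescaled to the mean raw library size), so composition shifts
#' in a few genes do not masquerade as global shifts.
#'
#' @param counts Filtered counts matrix.
#' @param prior_count Prior count added before the log (default 0.5).
#' @param method "median_ratio" (default) or "none" (raw library sizes).
#' @return List of class `expr_matrix`: `logcpm` (genes x samples),
#'   `library_sizes`, `effective_library_sizes`.
#' @export
normalize_counts <- function(counts, prior_count = 0.5,
                             method = c("median_ratio", "none")) {
  method <- match.arg(method)
  lib <- colSums(counts)
  eff <- lib
  if (method == "median_ratio") {
    logmeans <- rowMeans(log(counts + 0.5))
    sf <- apply(counts, 2, function(col)
      exp(stats::median(log(col + 0.5) - logmeans)))
    eff <- sf / mean(sf) * mean(lib)
  }
  logcpm <- log2(sweep(counts + prior_count, 2, eff, "/") * 1e6)
  structure(list(logcpm = logcpm, library_sizes = lib,
                 effective_library_sizes = eff),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$logcpm), "genes x", ncol(x$logcpm),
      "samples (log2 CPM)\n")
  invisible(x)
}

# Moment-matched scaled-F hyperparameters for the variance prior.
# Marginally s2 ~ s0^2 * F(d, d0); solves d0 and s0^2 from the first two
# moments of the observed s2 distribution. Returns d0 = Inf when the
# spread of s2 does not exceed what d residual df alone implies.
estimate_variance_prior <- function(s2, d) {
  m <- mean(s2); v <- stats::var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0)
    return(list(d0 = Inf, s02 = max(m, .Machine$double.eps)))
  r <- v / m^2
  if (r * d <= 2) return(list(d0 = Inf, s02 = m))
  d0 <- (2 * (d - 2) + 4 * r * d) / (r * d - 2)
  if (d0 <= 4) d0 <- 4.01   # moment solution valid only for d0 > 4
  s02 <- m * (d0 - 2) / d0
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t per gene
#'
#' Pooled-variance two-sample t with the gene-level residual variance
#' shrunk toward a prior: `s2_post = (d0 s0^2 + d s2) / (d0 + d)` with
#' `d = n1 + n2 - 2`, and `t_mod = log2fc / (s_post sqrt(1/n1 + 1/n2))`
#' referred to a t distribution on `d0 + d` degrees of freedom. When the
#' prior is not supplied, `d0` and `s0^2` are estimated by moment-matching
#' a scaled F marginal to the observed `s2` distribution. `d0 = 0` gives
#' the ordinary pooled t; `d0 = Inf` fixes every posterior variance at
#' `s0^2`.
#'
#' @param expr An `expr_matrix` (or a logcpm matrix).
#' @param labels Named label vector over samples.
#' @param group1,group2 Label values; log2fc = mean(group1) - mean(group2).
#' @param d0,s02 Optional prior degrees of freedom and prior variance.
#' @return data.frame (gene, log2fc, s2, s2_post, t_mod, df_total, p,
#'   p_adj) sorted by ascending p, with the estimated prior in
#'   attributes `d0` and `s02`.
#' @export
moderated_t <- function(expr, labels, group1 = "APCmut_neg",
                        group2 = "APCmut_pos", d0 = NULL, s02 = NULL) {
  mat <- if (inherits(expr, "expr_matrix")) expr$logcpm else expr
  idx1 <- which(colnames(mat) %in% names(labels)[labels == group1])
  idx2 <- which(colnames(mat) %in% names(labels)[labels == group2])
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2 || n2 < 2) stop2("each group needs >= 2 samples")

  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  ss1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  if (is.null(d0) || is.null(s02)) {
    prior <- estimate_variance_prior(s2, d)
    d0 <- d0 %||% prior$d0
    s02 <- s02 %||% prior$s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  t_mod <- ifelse(se == 0, 0, lfc / se)
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df_total)
  p[se == 0] <- 1

  out <- data.frame(gene = rownames(mat), log2fc = lfc, s2 = s2,
                    s2_post = s2_post, t_mod = t_mod,
                    df_total = df_total, p = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
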