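# Signature-based bulk deconvolution by non-negative least squares, the
# absolute immune score (coefficient sum), and correlation of cell-type
# scores with target quantities such as RSPO3 expression.

#' Deconvolve bulk expression against a cell-type signature
#'
#' Per sample, solves `min || S f - y ||` subject to `f >= 0` over the
#' genes shared between the signature matrix and the expression matrix,
#' on linear-scale expression (`2^logcpm`). The absolute score is the sum
#' of the fitted coefficients.
#'
#' @param expr An `expr_matrix` or logcpm matrix (log2 scale; un-logged
#'   internally) — or, with `linear = TRUE`, an already-linear matrix.
#' @param signature Non-negative genes x cell-types matrix.
#' @param linear Set TRUE if `expr` is already on the linear scale.
#' @return List of class `deconv_result`: `fractions` (cell-types x
#'   samples coefficients), `absolute_score`, `residual_norm` (both named
#'   per sample).
#' @export
deconvolve <- function(expr, signature, linear = FALSE) {
  mat <- if (inherits(expr, "expr_matrix")) expr$logcpm else expr
  genes <- intersect(rownames(signature), rownames(mat))
  if (!length(genes)) stop2("no signature genes present in expression")
  per_type <- colSums(signature[genes, , drop = FALSE] > 0)
  if (any(per_type == 0))
    stop2("cell type(s) without any present marker gene")
  s <- signature[genes, , drop = FALSE]
  y_all <- mat[genes, , drop = FALSE]
  if (!linear) y_all <- 2^y_all
  fit_one <- function(y) {
    f <- pracma::lsqnonneg(s, y)
    c(f$x, sqrt(max(f$resid.norm, 0)))
  }
  res <- apply(y_all, 2, fit_one)
  fractions <- res[seq_len(ncol(s)), , drop = FALSE]
  rownames(fractions) <- colnames(s)
  structure(list(fractions = fractions,
                 absolute_score = colSums(fractions),
                 residual_norm = res[ncol(s) + 1, ]),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("deconv_result:", nrow(x$fractions), "cell types x",
      ncol(x$fractions), "samples\n")
  cat("  absolute score: median",
      signif(stats::median(x$absolute_score), 3), "\n")
  invisible(x)
}

#' Correlate cell-type scores with target quantities
#'
#' Pearson correlation (with the two-tailed t approximation for p) between
#' every cell-type coefficient and every target vector over the shared
#' samples.
#'
#' @param deconv A `deconv_result`.
#' @param targets Named list of named numeric vectors (e.g. RSPO3
#'   expression per sample, mean AXIN2 beta per sample).
#' @return data.frame (cell_type, target, n, r, p), sorted within target
#'   by decreasing r.
#' @export
score_correlations <- function(deconv, targets) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  rows <- list()
  for (tn in names(targets)) {
    tv <- targets[[tn]]
    shared <- intersect(colnames(deconv$fractions), names(tv))
    if (length(shared) < 3) stop2("need >= 3 shared samples for ", tn)
    for (ct in rownames(deconv$fractions)) {
      x <- deconv$fractions[ct, shared]; y <- tv[shared]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(x, y)
        tt <- r * sqrt((length(shared) - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tt), length(shared) - 2)
      }
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, target = tn, n = length(shared), r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res[order(res$target, -res$r), ]
}

#' Absolute immune scores by group
#'
#' Per-group absolute score vectors plus the APCmut- vs APCmut+ Welch
#' two-tailed t-test. Empty groups are omitted with a warning.
#'
#' @param deconv A `deconv_result`.
#' @param labels Named classification labels.
#' @param subtypes Optional `subtype_labels` (or named CL1/CL2 vector)
#'   adding CL1/CL2 groups.
#' @return List with `groups` (named list of score vectors), `summary`
#'   (data.frame group, n, mean_score) and `neg_vs_pos` (t, df, p).
#' @export
group_absolute_scores <- function(deconv, labels, subtypes = NULL) {
  score <- deconv$absolute_score
  grp <- list(APCmut_neg = names(labels)[labels == "APCmut_neg"],
              APCmut_pos = names(labels)[labels == "APCmut_pos"],
              normal = names(labels)[labels == "normal"])
  if (!is.null(subtypes)) {
    cl <- if (inherits(subtypes, "subtype_labels")) subtypes$cluster else
      subtypes
    grp$CL1 <- names(cl)[cl == "CL1"]
    grp$CL2 <- names(cl)[cl == "CL2"]
  }
  groups <- list()
  for (g in names(grp)) {
    ids <- intersect(grp[[g]], names(score))
    if (!length(ids)) {
      warning("empty group omitted: ", g, call. = FALSE)
      next
    }
    groups[[g]] <- score[ids]
  }
  summary <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, n = length(groups[[g]]),
               mean_score = mean(groups[[g]]), stringsAsFactors = FALSE)))
  nvp <- if (!is.null(groups$APCmut_neg) && !is.null(groups$APCmut_pos) &&
             length(groups$APCmut_neg) >= 2 &&
             length(groups$APCmut_pos) >= 2)
    welch_t(groups$APCmut_neg, groups$APCmut_pos) else NULL
  list(groups = groups, summary = summary, neg_vs_pos = nvp)
}
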