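#' @keywords internal
"_PACKAGE"

# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector, as used for
#' every multiple-testing correction in the pipeline (differential
#' expression, alteration enrichment, probe tests, gene set enrichment,
#' onset scan).
#'
#' @param p Numeric vector of p-values in \[0, 1\]; NAs are propagated.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  stats::p.adjust(p, method = "BH")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to score recovery of planted subtype structure.
#'
#' @param x,y Vectors of cluster labels of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  n <- length(x)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Welch two-sample t with Satterthwaite df; returns t, df, two-tailed p.
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop2("welch_t requires >= 2 observations per group")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Row-wise Welch t on a matrix: group1/group2 are column index vectors.
# Returns data.frame(delta, t, p). Vectorized for probe/gene scale.
rowwise_welch <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- apply(mat[, idx1, drop = FALSE], 1, stats::var) / n1
  v2 <- apply(mat[, idx2, drop = FALSE], 1, stats::var) / n2
  se2 <- v1 + v2
  t <- ifelse(se2 == 0, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)))
  p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df))
  data.frame(delta = m1 - m2, t = t, df = df, p = p)
}
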