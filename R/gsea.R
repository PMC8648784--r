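# Preranked gene set enrichment: weighted Kolmogorov-Smirnov enrichment
# score with a gene-label permutation null, signed NES and tail p-values.

# ES from sorted hit positions without materializing the running sum:
# at hit j the running sum is H_j - (p_j - j)/(N - s); just before hit j
# it is H_{j-1} - (p_j - j)/(N - s). The signed extreme over those
# candidates is the ES (between-hit stretches are monotone).
es_from_positions <- function(pos, w_abs_exp, n_total) {
  s <- length(pos)
  nr <- sum(w_abs_exp)
  miss <- (pos - seq_len(s)) / (n_total - s)
  if (nr == 0) {              # all-zero weights: hits contribute nothing
    tops <- -miss
  } else {
    tops <- cumsum(w_abs_exp) / nr - miss
  }
  bottoms <- c(0, utils::head(cumsum(w_abs_exp), -1)) / max(nr, 1) - miss
  top <- max(tops); bottom <- min(bottoms)
  if (top >= -bottom) top else bottom
}

#' Weighted KS enrichment score of a gene set in a ranking
#'
#' Walks the ranked list; set members increment the running sum by
#' `|weight|^exponent` (normalized by the sum over members), non-members
#' decrement by `1/(N - Nh)`. The enrichment score is the signed maximal
#' deviation from zero.
#'
#' @param ranking Named numeric vector of ranking weights (e.g. DE t
#'   statistics); sorted internally by decreasing weight, ties broken by
#'   gene name.
#' @param gene_set Character vector of member genes; must intersect the
#'   ranking and must not cover it entirely.
#' @param exponent Weighting exponent (1 = classic weighted GSEA, 0 =
#'   unweighted KS).
#' @param return_profile If TRUE also return the full running-sum profile.
#' @return List with `es` and (optionally) `profile` (length-N numeric).
#' @export
enrichment_score <- function(ranking, gene_set, exponent = 1,
                             return_profile = FALSE) {
  ord <- order(-ranking, names(ranking))
  w <- ranking[ord]
  n <- length(w)
  hits <- which(names(w) %in% gene_set)
  if (!length(hits)) stop2("gene set does not intersect the ranking")
  if (length(hits) == n)
    stop2("gene set covers the whole ranking; miss increment undefined")
  wa <- abs(w[hits])^exponent
  es <- es_from_positions(hits, wa, n)
  out <- list(es = es)
  if (return_profile) {
    inc <- rep(-1 / (n - length(hits)), n)
    inc[hits] <- if (sum(wa) == 0) 0 else wa / sum(wa)
    out$profile <- cumsum(inc)
  }
  out
}

#' Preranked GSEA over a gene set collection
#'
#' For every set within the size bounds: enrichment score, a gene-label
#' permutation null (random same-size position sets in the fixed ranking),
#' NES = es / mean(|null es| of the matching sign), a signed tail p-value
#' with a +1 pseudocount (never exactly zero), and BH adjustment across
#' sets.
#'
#' @param ranking Named numeric weights with unique gene names.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param n_perm Permutations per set size (default 10000).
#' @param min_size,max_size Set size bounds after intersection with the
#'   ranking.
#' @param exponent Weighting exponent passed to [enrichment_score()].
#' @param seed Integer seed for the permutation null.
#' @return data.frame (set_name, size, es, nes, p, p_adj) sorted by p.
#' @export
gsea_preranked <- function(ranking, gene_sets, n_perm = 10000,
                           min_size = 15, max_size = 500, exponent = 1,
                           seed = 1) {
  if (anyDuplicated(names(ranking))) stop2("ranking gene names not unique")
  ord <- order(-ranking, names(ranking))
  w <- ranking[ord]
  n <- length(w)
  wa_all <- abs(w)^exponent
  sizes <- vapply(gene_sets, function(s)
    length(intersect(s, names(w))), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  gene_sets <- gene_sets[keep]; sizes <- sizes[keep]
  if (!length(gene_sets))
    return(data.frame(set_name = character(), size = integer(),
                      es = numeric(), nes = numeric(), p = numeric(),
                      p_adj = numeric()))
  set.seed(seed)
  # one shared null per distinct set size
  nulls <- lapply(sort(unique(sizes)), function(s)
    vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, s))
      es_from_positions(pos, wa_all[pos], n)
    }, numeric(1)))
  names(nulls) <- as.character(sort(unique(sizes)))

  rows <- lapply(seq_along(gene_sets), function(k) {
    hits <- which(names(w) %in% gene_sets[[k]])
    es <- es_from_positions(hits, wa_all[hits], n)
    null <- nulls[[as.character(sizes[k])]]
    if (es >= 0) {
      pos_null <- null[null >= 0]
      p <- (1 + sum(pos_null >= es)) / (1 + length(pos_null))
      nes <- if (length(pos_null)) es / mean(pos_null) else NA_real_
    } else {
      neg_null <- null[null < 0]
      p <- (1 + sum(neg_null <= es)) / (1 + length(neg_null))
      nes <- if (length(neg_null)) -es / mean(neg_null) else NA_real_
    }
    data.frame(set_name = names(gene_sets)[k], size = sizes[k], es = es,
               nes = nes, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  res
}
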