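# WNT ligand sensitivity score, max WNT ligand expression, CL1/CL2
# subtype clustering of APCmut- tumors, and group summaries.

#' Default WNT ligand gene list
#'
#' The 19 human WNT family gene symbols; callers typically intersect this
#' with the genes surviving the expression filter.
#'
#' @return Character vector of WNT gene symbols.
#' @export
wnt_ligand_genes <- function() WNT_LIGANDS

#' WNT ligand sensitivity score
#'
#' Per sample: z-score RSPO3, RNF43 and ZNRF3 expression over the scored
#' population (all tumors plus normals), form the raw score
#' `r = z(RSPO3) - (z(RNF43) + z(ZNRF3))`, and standardize it again over
#' the same population (`wnt_ls = (r - mean r) / sd r`). Also reports each
#' sample's maximum expression over the WNT ligand gene list. z-scores use
#' the sample (n-1) standard deviation.
#'
#' @param expr An `expr_matrix` (or logcpm matrix) covering the scored
#'   samples.
#' @param samples Optional sample subset defining the z population
#'   (default: all columns).
#' @param wnt_genes WNT ligand gene list; silently intersected with the
#'   expression matrix rows.
#' @return data.frame (sample_id, rspo3_z, rnf43_z, znrf3_z, wnt_ls,
#'   max_wnt).
#' @export
wnt_ls <- function(expr, samples = NULL, wnt_genes = wnt_ligand_genes()) {
  mat <- if (inherits(expr, "expr_matrix")) expr$logcpm else expr
  samples <- samples %||% colnames(mat)
  if (length(samples) < 2) stop2("z population needs >= 2 samples")
  mat <- mat[, samples, drop = FALSE]
  need <- c("RSPO3", "RNF43", "ZNRF3")
  missing <- setdiff(need, rownames(mat))
  if (length(missing))
    stop2("missing gene(s): ", paste(missing, collapse = ", "))
  zrow <- function(g) {
    v <- mat[g, ]
    s <- stats::sd(v)
    if (s == 0) stop2("constant expression for ", g, "; z undefined")
    (v - mean(v)) / s
  }
  r <- zrow("RSPO3") - (zrow("RNF43") + zrow("ZNRF3"))
  s_r <- stats::sd(r)
  if (s_r == 0) stop2("raw score constant; cannot standardize")
  wnt <- intersect(wnt_genes, rownames(mat))
  max_wnt <- if (length(wnt))
    apply(mat[wnt, , drop = FALSE], 2, max) else rep(NA_real_, ncol(mat))
  data.frame(sample_id = samples,
             rspo3_z = unname(zrow("RSPO3")),
             rnf43_z = unname(zrow("RNF43")),
             znrf3_z = unname(zrow("ZNRF3")),
             wnt_ls = unname((r - mean(r)) / s_r),
             max_wnt = unname(max_wnt),
             stringsAsFactors = FALSE)
}

#' Cluster APCmut- tumors into CL1/CL2
#'
#' Agglomerative hierarchical clustering of the APCmut- samples on the
#' differentially expressed genes, with distance 1 - Pearson correlation
#' between samples and average linkage, cut at k = 2. The cluster with the
#' higher mean WNT-LS score is named CL2 (tie: the larger cluster).
#'
#' @param expr An `expr_matrix` (or logcpm matrix).
#' @param samples APCmut- sample ids.
#' @param de_genes Genes to cluster on (typically p_adj < 0.05 from
#'   [moderated_t()]); must have >= 2 members present in `expr`.
#' @param wntls Result of [wnt_ls()] used to orient cluster names.
#' @param method Linkage ("average", "ward.D2", "complete").
#' @param distance "pearson" (1 - correlation) or "euclidean".
#' @return List of class `subtype_labels`: `cluster` (named CL1/CL2
#'   vector), `hclust` (the tree), `newick` (dendrogram as a Newick
#'   string).
#' @export
cluster_apcneg <- function(expr, samples, de_genes, wntls,
                           method = "average", distance = "pearson") {
  mat <- if (inherits(expr, "expr_matrix")) expr$logcpm else expr
  samples <- intersect(samples, colnames(mat))
  if (length(samples) < 2) stop2("need >= 2 APCmut- samples")
  de_genes <- intersect(de_genes, rownames(mat))
  if (length(de_genes) < 2) stop2("need >= 2 DE genes to cluster on")
  sub <- mat[de_genes, samples, drop = FALSE]
  # center each gene so sample-sample correlation reflects relative
  # expression patterns rather than shared gene baselines
  sub <- sub - rowMeans(sub)
  dmat <- if (distance == "pearson") {
    stats::as.dist(1 - stats::cor(sub))
  } else stats::dist(t(sub))
  hc <- stats::hclust(dmat, method = method)
  cut <- stats::cutree(hc, k = 2)
  score <- stats::setNames(wntls$wnt_ls, wntls$sample_id)[samples]
  mean1 <- mean(score[cut == 1], na.rm = TRUE)
  mean2 <- mean(score[cut == 2], na.rm = TRUE)
  cl2 <- if (isTRUE(all.equal(mean1, mean2))) {
    if (sum(cut == 1) >= sum(cut == 2)) 1 else 2
  } else if (mean1 > mean2) 1 else 2
  cluster <- stats::setNames(ifelse(cut == cl2, "CL2", "CL1"), samples)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(cluster = cluster, hclust = hc, newick = newick),
            class = "subtype_labels")
}

#' @export
print.subtype_labels <- function(x, ...) {
  print(table(x$cluster))
  invisible(x)
}

#' Group means of WNT-LS and max WNT ligand expression
#'
#' Summarizes score means over the biologically defined groups: normals,
#' APCmut+, CL1, CL2 without a known driver, and the RNF43-mutant,
#' BRAF-mutant and PTPRK-RSPO3-fusion subgroups of APCmut-. Empty groups
#' are omitted with a warning.
#'
#' @param wntls Result of [wnt_ls()].
#' @param labels Named classification labels.
#' @param subtypes A `subtype_labels` (or named CL1/CL2 vector).
#' @param drivers Named vector over APCmut- samples with values in
#'   fusion / rnf43_mut / braf_mut / none (e.g. derived from the
#'   alteration matrix or the generator truth).
#' @return data.frame (group, n, mean_wnt_ls, mean_max_wnt).
#' @export
wnt_group_summary <- function(wntls, labels, subtypes, drivers) {
  cl <- if (inherits(subtypes, "subtype_labels")) subtypes$cluster else
    subtypes
  groups <- list(
    normal = names(labels)[labels == "normal"],
    APCmut_pos = names(labels)[labels == "APCmut_pos"],
    CL1 = names(cl)[cl == "CL1"],
    CL2_no_driver = intersect(names(cl)[cl == "CL2"],
                              names(drivers)[drivers == "none"]),
    RNF43_mut = names(drivers)[drivers == "rnf43_mut"],
    BRAF_mut = names(drivers)[drivers == "braf_mut"],
    PTPRK_RSPO3_fusion = names(drivers)[drivers == "fusion"])
  score <- stats::setNames(wntls$wnt_ls, wntls$sample_id)
  mw <- stats::setNames(wntls$max_wnt, wntls$sample_id)
  rows <- lapply(names(groups), function(g) {
    ids <- intersect(groups[[g]], wntls$sample_id)
    if (!length(ids)) {
      warning("empty group omitted: ", g, call. = FALSE)
      return(NULL)
    }
    data.frame(group = g, n = length(ids),
               mean_wnt_ls = mean(score[ids]),
               mean_max_wnt = mean(mw[ids]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derive APCmut- driver subgroups from cohort tables
#'
#' Assigns each APCmut- sample to fusion / rnf43_mut / braf_mut / none by
#' the observed alterations (fusion taking precedence, then RNF43
#' mutation, then BRAF V600E).
#'
#' @param cohort A classified `crc_cohort`.
#' @param nonsilent Variant classes counted as mutations.
#' @return Named character vector over APCmut- samples.
#' @export
driver_subgroups <- function(cohort, nonsilent = nonsilent_classes()) {
  stopifnot(!is.null(cohort$labels))
  neg <- names(cohort$labels)[cohort$labels == "APCmut_neg"]
  mut <- cohort$mutations
  mut <- mut[mut$variant_class %in% nonsilent, ]
  fus <- unique(cohort$fusions$sample_id[
    cohort$fusions$gene5 == "PTPRK" & cohort$fusions$gene3 == "RSPO3"])
  rnf <- unique(mut$sample_id[mut$gene == "RNF43"])
  brf <- unique(mut$sample_id[mut$gene == "BRAF" &
                                mut$protein_change == "V600E"])
  drivers <- stats::setNames(rep("none", length(neg)), neg)
  drivers[neg %in% brf] <- "braf_mut"
  drivers[neg %in% rnf] <- "rnf43_mut"
  drivers[neg %in% fus] <- "fusion"
  drivers
}
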