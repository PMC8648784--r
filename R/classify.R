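# Sample classification by APC pathway alteration status. Tumors are
# first filtered for hypermutability (MSI-high or mutation count above a
# threshold), then split on APC/CTNNB1 events: a tumor is APCmut_pos if it
# carries a non-silent APC mutation, an APC deep deletion, or a non-silent
# CTNNB1 mutation, and APCmut_neg if it carries none of these.

#' Classification configuration
#'
#' @param hypermutation_threshold Tumors with more non-silent mutations
#'   than this are excluded (default 700; a cell-line screen would use
#'   800).
#' @param nonsilent Variant classes counted as non-silent.
#' @param apc_gene,ctnnb1_gene Gene symbols defining the APC pathway rule.
#' @param count_all_mutations If TRUE the hypermutation filter counts
#'   silent mutations too.
#' @param strict_msi If TRUE samples with unknown MSI status are excluded
#'   rather than retained with a warning.
#' @return List of class `classify_config`.
#' @export
classify_config <- function(hypermutation_threshold = 700,
                            nonsilent = nonsilent_classes(),
                            apc_gene = "APC", ctnnb1_gene = "CTNNB1",
                            count_all_mutations = FALSE,
                            strict_msi = FALSE) {
  stopifnot(hypermutation_threshold > 0)
  structure(as.list(environment()), class = "classify_config")
}

#' Classify cohort samples by APC status
#'
#' Applies the exclusion filters then the APC/CTNNB1 rule to every tumor;
#' normals are labeled `normal`. The cohort's `labels` slot is filled and
#' an exclusion log is attached.
#'
#' @param cohort A `crc_cohort`.
#' @param config A [classify_config()].
#' @return The cohort with `labels` (named vector: APCmut_neg /
#'   APCmut_pos / excluded / normal) and `exclusions` (data.frame
#'   sample_id, reason).
#' @export
classify_samples <- function(cohort, config = classify_config()) {
  stopifnot(inherits(cohort, "crc_cohort"))
  cl <- cohort$clinical
  ids <- cl$sample_id
  labels <- stats::setNames(rep(NA_character_, length(ids)), ids)
  labels[cl$tissue == "normal"] <- "normal"
  tumors <- ids[cl$tissue == "tumor"]

  mut <- cohort$mutations
  counted <- if (config$count_all_mutations) mut else
    mut[mut$variant_class %in% config$nonsilent, , drop = FALSE]
  mut_counts <- table(factor(counted$sample_id, levels = tumors))

  msi <- stats::setNames(cl$msi_status, ids)[tumors]
  unknown_msi <- is.na(msi) | msi == "unknown"
  if (any(unknown_msi) && !config$strict_msi)
    warning(sprintf("%d tumor(s) with unknown MSI status retained",
                    sum(unknown_msi)), call. = FALSE)

  excl <- character(0); reason <- character(0)
  is_msih <- !unknown_msi & msi == "MSI-H"
  if (config$strict_msi) is_msih <- is_msih | unknown_msi
  is_hyper <- as.integer(mut_counts[tumors]) > config$hypermutation_threshold
  excl <- c(tumors[is_msih], tumors[!is_msih & is_hyper])
  reason <- c(rep("MSI-H", sum(is_msih)),
              rep("hypermutated", sum(!is_msih & is_hyper)))
  labels[excl] <- "excluded"

  keep <- setdiff(tumors, excl)
  ns_mut <- mut[mut$variant_class %in% config$nonsilent, , drop = FALSE]
  apc_mut <- unique(ns_mut$sample_id[ns_mut$gene == config$apc_gene])
  ctnnb1_mut <- unique(ns_mut$sample_id[ns_mut$gene == config$ctnnb1_gene])
  apc_del <- unique(cohort$cna$sample_id[
    cohort$cna$gene == config$apc_gene &
      cohort$cna$call == "deep_deletion"])
  positive <- keep %in% c(apc_mut, ctnnb1_mut, apc_del)
  labels[keep] <- ifelse(positive, "APCmut_pos", "APCmut_neg")

  cohort$labels <- labels
  cohort$exclusions <- data.frame(sample_id = excl, reason = reason,
                                  stringsAsFactors = FALSE)
  cohort
}

#' Group sizes and the APCmut- fraction
#'
#' @param labels Named label vector from [classify_samples()].
#' @return List with n_neg, n_pos, n_excluded, n_normal and fraction_neg
#'   (= n_neg / (n_neg + n_pos); NA with a warning when no tumors pass
#'   the filters).
#' @export
count_groups <- function(labels) {
  n_neg <- sum(labels == "APCmut_neg")
  n_pos <- sum(labels == "APCmut_pos")
  denom <- n_neg + n_pos
  frac <- if (denom == 0) {
    warning("no tumors pass the filters; fraction undefined", call. = FALSE)
    NA_real_
  } else n_neg / denom
  list(n_neg = n_neg, n_pos = n_pos,
       n_excluded = sum(labels == "excluded"),
       n_normal = sum(labels == "normal"), fraction_neg = frac)
}
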