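# End-to-end orchestration: classify -> alterations -> differential
# expression -> WNT-LS + CL1/CL2 -> GSEA -> immune deconvolution -> DMRs
# -> onset scan, with one flat config and optional TSV output.

#' Pipeline configuration
#'
#' One flat, typed key-value set holding every stage threshold, with the
#' study's values as defaults. Serializable to a flat YAML file via
#' [write_config()] / [read_config()].
#'
#' @param hypermutation_threshold Non-silent mutation count above which a
#'   tumor is excluded (700).
#' @param min_altered Minimum altered samples per gene in the enrichment
#'   scan (3).
#' @param de_p_adj DE significance cutoff feeding the clustering (0.05).
#' @param prior_count Prior count for log-CPM (0.5).
#' @param cluster_method,cluster_distance Clustering linkage and distance.
#' @param gsea_n_perm,gsea_min_size,gsea_max_size,gsea_exponent Preranked
#'   GSEA parameters (10000, 15, 500, 1).
#' @param me_n_perm Mutual-exclusivity permutations (10000).
#' @param dmr_p_adj,dmr_max_gap,dmr_min_probes DMR caller parameters
#'   (0.05, 1000 bp, 3 probes).
#' @param onset_max_missing_age Missing-age tolerance in the onset scan.
#' @param seed Seed shared by all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(hypermutation_threshold = 700,
                            min_altered = 3, de_p_adj = 0.05,
                            prior_count = 0.5,
                            cluster_method = "average",
                            cluster_distance = "pearson",
                            gsea_n_perm = 10000, gsea_min_size = 15,
                            gsea_max_size = 500, gsea_exponent = 1,
                            me_n_perm = 10000, dmr_p_adj = 0.05,
                            dmr_max_gap = 1000, dmr_min_probes = 3,
                            onset_max_missing_age = 0.2, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a flat YAML pipeline config
#'
#' Unknown keys raise an error; missing keys keep their defaults.
#'
#' @param path YAML file of scalar key-value pairs.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(vals)] <- vals
  class(defaults) <- "pipeline_config"
  defaults
}

#' Write a pipeline config as flat YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort. Stages whose inputs are absent
#' (methylation without betas, GSEA without gene sets, deconvolution
#' without a signature) are skipped with a message. When `outdir` is
#' given, each stage's tables are written as TSV (DMRs also as BED) along
#' with a run manifest; outputs are deterministic given (cohort, config).
#'
#' @param cohort A `crc_cohort`.
#' @param config A [pipeline_config()].
#' @param gene_sets Optional named list of gene sets for GSEA.
#' @param signature Optional cell-type signature matrix for deconvolution.
#' @param outdir Optional output directory.
#' @return List of class `crc_pipeline_result` with elements labels,
#'   group_counts, exclusions, alterations, enrichment, mutual_exclusivity,
#'   clinical, expr, de, wntls, subtypes, drivers, wnt_summary, gsea,
#'   deconv, immune_groups, immune_correlations, probes, dmrs,
#'   dmr_summary, dmr_correlation, onset, km.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         gene_sets = NULL, signature = NULL,
                         outdir = NULL) {
  stopifnot(inherits(cohort, "crc_cohort"),
            inherits(config, "pipeline_config"))
  res <- list(config = config)
  emit <- function(df, name) {
    if (!is.null(outdir) && !is.null(df))
      write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
  }
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ## classify
  cohort <- classify_samples(
    cohort, classify_config(hypermutation_threshold =
                              config$hypermutation_threshold))
  labels <- cohort$labels
  res$labels <- labels
  res$group_counts <- count_groups(labels)
  res$exclusions <- cohort$exclusions
  emit(data.frame(sample_id = names(labels), label = unname(labels)),
       "labels")
  emit(cohort$exclusions, "exclusions")

  ## alterations
  alt <- build_alteration_matrix(cohort)
  res$alterations <- alt
  res$enrichment <- enrichment_scan(alt, labels,
                                    min_altered = config$min_altered)
  emit(res$enrichment, "enrichment")
  emit(alt$events, "alteration_events")
  if (all(c("PTPRK-RSPO3", "RNF43") %in% rownames(alt$matrix)))
    res$mutual_exclusivity <- mutual_exclusivity(
      alt, c("PTPRK-RSPO3", "RNF43"), n_perm = config$me_n_perm,
      seed = config$seed)
  res$clinical <- clinical_association(cohort$clinical, labels)
  emit(res$clinical, "clinical_association")

  ## expression + DE
  keep_genes <- filter_genes(cohort$counts)
  expr <- normalize_counts(cohort$counts[keep_genes, , drop = FALSE],
                           prior_count = config$prior_count)
  res$expr <- expr
  res$de <- moderated_t(expr, labels)
  emit(res$de, "differential_expression")

  ## WNT-LS + subtype clustering
  scored <- names(labels)[labels %in% c("APCmut_neg", "APCmut_pos",
                                        "normal")]
  res$wntls <- wnt_ls(expr, samples = scored)
  emit(res$wntls, "wnt_ls")
  neg <- names(labels)[labels == "APCmut_neg"]
  de_genes <- res$de$gene[res$de$p_adj < config$de_p_adj]
  if (length(neg) >= 2 && length(de_genes) >= 2) {
    res$subtypes <- cluster_apcneg(expr, neg, de_genes, res$wntls,
                                   method = config$cluster_method,
                                   distance = config$cluster_distance)
    res$drivers <- driver_subgroups(cohort)
    res$wnt_summary <- wnt_group_summary(res$wntls, labels, res$subtypes,
                                         res$drivers)
    emit(res$wnt_summary, "wnt_group_summary")
    emit(data.frame(sample_id = names(res$subtypes$cluster),
                    cluster = unname(res$subtypes$cluster)), "subtypes")
    if (!is.null(outdir))
      writeLines(res$subtypes$newick,
                 file.path(outdir, "dendrogram.newick"))
  } else message("skipping clustering: too few APCmut- samples or DE genes")

  ## GSEA on the CL1-vs-CL2 t ranking
  if (!is.null(gene_sets) && !is.null(res$subtypes)) {
    cl <- res$subtypes$cluster
    if (sum(cl == "CL1") >= 2 && sum(cl == "CL2") >= 2) {
      de_cl <- moderated_t(expr, cl, group1 = "CL1", group2 = "CL2")
      ranking <- stats::setNames(de_cl$t_mod, de_cl$gene)
      res$gsea <- gsea_preranked(ranking, gene_sets,
                                 n_perm = config$gsea_n_perm,
                                 min_size = config$gsea_min_size,
                                 max_size = config$gsea_max_size,
                                 exponent = config$gsea_exponent,
                                 seed = config$seed)
      emit(res$gsea, "gsea")
    }
  } else if (is.null(gene_sets)) message("skipping GSEA: no gene sets")

  ## immune deconvolution
  if (!is.null(signature)) {
    res$deconv <- deconvolve(expr, signature)
    res$immune_groups <- group_absolute_scores(res$deconv, labels,
                                               res$subtypes)
    emit(res$immune_groups$summary, "immune_group_scores")
    tumors <- names(labels)[labels %in% c("APCmut_neg", "APCmut_pos")]
    if ("RSPO3" %in% rownames(expr$logcpm)) {
      rspo3 <- expr$logcpm["RSPO3", intersect(tumors,
                                              colnames(expr$logcpm))]
      res$immune_correlations <- score_correlations(
        res$deconv, list(RSPO3_expression = rspo3))
      emit(res$immune_correlations, "immune_correlations")
    }
  } else message("skipping deconvolution: no signature matrix")

  ## methylation
  if (!is.null(cohort$betas)) {
    res$probes <- probe_tests(cohort$betas, labels)
    res$dmrs <- call_dmrs(res$probes, cohort$probe_anno, cohort$betas,
                          labels, p_adj_cut = config$dmr_p_adj,
                          max_gap = config$dmr_max_gap,
                          min_probes = config$dmr_min_probes)
    res$dmr_summary <- dmr_summary(res$dmrs)
    if (nrow(res$dmrs) && "RNF43" %in% rownames(expr$logcpm))
      res$dmr_correlation <- dmr_expression_correlation(
        res$dmrs, cohort$betas, expr, anchor_gene = "RNF43")
    if (!is.null(outdir))
      write_dmrs(res$dmrs, file.path(outdir, "dmrs.tsv"),
                 file.path(outdir, "dmrs.bed"))
  } else message("skipping methylation: no beta matrix")

  ## onset scan (APCmut- group)
  if (length(neg) >= 4) {
    res$onset <- onset_scan(expr, cohort$clinical, neg,
                            max_missing_age = config$onset_max_missing_age)
    emit(res$onset, "onset_scan")
    top_gene <- res$onset$gene[1]
    sp <- median_split(expr$logcpm[top_gene, neg])
    age <- stats::setNames(cohort$clinical$age_at_diagnosis,
                           cohort$clinical$sample_id)
    res$km <- km_curves(list(high = age[sp$high], low = age[sp$low]))
    emit(res$km$curves, "km_top_onset_gene")
  }

  if (!is.null(outdir)) {
    manifest <- c(sprintf("package: crcwnt %s",
                          as.character(utils::packageVersion("crcwnt"))),
                  sprintf("seed: %d", config$seed),
                  sprintf("config_hash: %s",
                          paste(names(unclass(config)),
                                unlist(config), sep = "=", collapse = ";")))
    writeLines(manifest, file.path(outdir, "manifest.txt"))
  }
  class(res) <- "crc_pipeline_result"
  res
}

#' @export
print.crc_pipeline_result <- function(x, ...) {
  cat("crc_pipeline_result\n")
  gc <- x$group_counts
  cat(sprintf("  APCmut-: %d  APCmut+: %d  excluded: %d  normal: %d\n",
              gc$n_neg, gc$n_pos, gc$n_excluded, gc$n_normal))
  if (!is.null(x$subtypes)) {
    tb <- table(x$subtypes$cluster)
    cat(sprintf("  subtypes: CL1 = %d, CL2 = %d\n", tb["CL1"], tb["CL2"]))
  }
  if (!is.null(x$de))
    cat("  top DE gene:", x$de$gene[1],
        sprintf("(log2FC %.2f, p_adj %.2g)\n", x$de$log2fc[1],
                x$de$p_adj[1]))
  if (!is.null(x$dmrs)) cat("  DMRs called:", nrow(x$dmrs), "\n")
  if (!is.null(x$onset))
    cat("  top onset gene:", x$onset$gene[1],
        sprintf("(p %.2g)\n", x$onset$p[1]))
  invisible(x)
}
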