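# Synthetic cohort generator. Plants the structure every downstream stage
# is designed to recover: an APC-pathway-intact tumor group with a CL1/CL2
# split, RNF43 down / RSPO3 up in CL2, mutually exclusive PTPRK-RSPO3
# fusions and RNF43 truncating mutations, an oxidative-phosphorylation
# module up in CL1, AXIN2 promoter hypermethylation anti-correlated with
# RNF43 expression, immune infiltration coupled to RSPO3, and an
# early-onset subgroup marked by high AP2M1.

IMMUNE_TYPES <- c(
  "B_naive", "B_memory", "Plasma", "T_CD8", "T_CD4_naive",
  "T_CD4_memory_resting", "T_CD4_memory_activated", "T_fh", "Treg",
  "T_gd", "NK_resting", "NK_activated", "Monocytes", "Macrophages_M0",
  "Macrophages_M1", "Macrophages_M2", "DC_resting", "DC_activated",
  "Mast_resting", "Mast_activated", "Eosinophils", "Neutrophils")

WNT_LIGANDS <- c("WNT1", "WNT2", "WNT2B", "WNT3", "WNT3A", "WNT4",
                 "WNT5A", "WNT5B", "WNT6", "WNT7A", "WNT7B", "WNT8A",
                 "WNT8B", "WNT9A", "WNT9B", "WNT10A", "WNT10B", "WNT11",
                 "WNT16")

#' Configuration of the synthetic cohort
#'
#' Defaults reproduce the study conditions the pipeline targets: 63
#' APC-pathway-mutation-negative (APCmut-) tumors vs 362 mutation-positive
#' (APCmut+) tumors plus 12 normals, mean age at diagnosis 61.4 vs 66.4
#' years, a 50/50 CL1/CL2 split of the APCmut- group, and a -0.98 mean
#' log2 fold change of RNF43 in CL2 relative to APCmut+.
#'
#' @param n_apc_neg,n_apc_pos,n_normal Group sizes.
#' @param n_genes,n_probes Expression and methylation feature counts.
#' @param mean_age_neg,mean_age_pos,age_sd Age model (years); ages are
#'   truncated at 25.
#' @param cl2_fraction Fraction of APCmut- tumors in CL2.
#' @param rnf43_log2fc Mean log2 shift of RNF43 in APCmut- vs APCmut+;
#'   allocated as a graded decrease (1.5x in CL2, the remainder in CL1)
#'   so CL2 is the low-RNF43 subcluster.
#' @param rspo3_log2fc,rspo3_log2fc_fusion RSPO3 log2 shift in CL2
#'   (fusion carriers get the larger shift).
#' @param oxphos_log2fc,n_oxphos Oxidative-phosphorylation module planted
#'   in CL1: per-gene log2 shift and module size.
#' @param axin2_delta_beta Maximum beta-value increase of AXIN2 promoter
#'   probes in CL2 (scaled per sample by a latent methylation level).
#' @param rnf43_axin2_coupling Mean-zero per-sample RNF43 log2 term tied
#'   to the AXIN2 methylation latent, producing the anti-correlation.
#' @param m2_rspo3_correlation Target Pearson correlation between the M2
#'   macrophage fraction and realized RSPO3 expression.
#' @param onset_age_shift,onset_log2fc Early-onset subgroup of APCmut-:
#'   age offset (plus/minus half this value, years) and AP2M1 log2 shift.
#' @param fusion_fraction,rnf43_mut_fraction,braf_fraction Driver
#'   fractions of the APCmut- group (assigned within CL2, mutually
#'   exclusively).
#' @param dispersion Negative-binomial dispersion of counts.
#' @param n_msih,n_hypermut Extra tumors planted to be excluded by the
#'   classifier (MSI-high; hypermutated). Default 0.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_apc_neg = 63, n_apc_pos = 362, n_normal = 12,
                          n_genes = 2000, n_probes = 5000,
                          mean_age_neg = 61.4, mean_age_pos = 66.4,
                          age_sd = 10, cl2_fraction = 0.5,
                          rnf43_log2fc = -0.98, rspo3_log2fc = 1.5,
                          rspo3_log2fc_fusion = 3, oxphos_log2fc = 1,
                          n_oxphos = 40, axin2_delta_beta = 0.35,
                          rnf43_axin2_coupling = 1.2,
                          m2_rspo3_correlation = 0.6,
                          onset_age_shift = 12, onset_log2fc = 2,
                          fusion_fraction = 0.12,
                          rnf43_mut_fraction = 0.11, braf_fraction = 0.10,
                          dispersion = 0.1, n_msih = 0, n_hypermut = 0,
                          seed = 1) {
  cfg <- as.list(environment())
  if (any(c(cfg$n_apc_neg, cfg$n_apc_pos, cfg$n_normal) < 0))
    stop2("group sizes must be >= 0")
  if (cfg$cl2_fraction < 0 || cfg$cl2_fraction > 1)
    stop2("cl2_fraction must be in [0, 1]")
  if (cfg$cl2_fraction > 0 && cfg$n_apc_neg == 0)
    stop2("cl2_fraction > 0 requires n_apc_neg > 0")
  if (cfg$dispersion <= 0) stop2("dispersion must be > 0")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a full multi-omic cohort (clinical, mutations, copy number,
#' fusions, RNA counts, methylation betas) under the structure described
#' in [cohort_config()]. Counts are negative binomial around per-gene
#' baselines with log-normal library sizes; betas are beta-distributed
#' around planted probe means.
#'
#' @param config A [cohort_config()].
#' @return List with elements `cohort` (a `crc_cohort`) and `truth`, a
#'   record of every planted assignment (labels, CL1/CL2 clusters,
#'   drivers, latent methylation levels, immune fractions, planted DMRs,
#'   gene modules, the signature matrix) sufficient to score recovery of
#'   the structure without re-inspecting generator internals.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- sample ids and truth labels -------------------------------------
  id <- function(p, n) if (n > 0) sprintf("%s%03d", p, seq_len(n)) else character()
  neg_ids <- id("TNEG", cfg$n_apc_neg)
  pos_ids <- id("TPOS", cfg$n_apc_pos)
  nrm_ids <- id("NORM", cfg$n_normal)
  msih_ids <- id("TMSI", cfg$n_msih)
  hyp_ids <- id("THYP", cfg$n_hypermut)
  tumor_ids <- c(neg_ids, pos_ids, msih_ids, hyp_ids)
  all_ids <- c(tumor_ids, nrm_ids)

  labels <- c(stats::setNames(rep("APCmut_neg", length(neg_ids)), neg_ids),
              stats::setNames(rep("APCmut_pos", length(pos_ids)), pos_ids),
              stats::setNames(rep("excluded", length(c(msih_ids, hyp_ids))),
                              c(msih_ids, hyp_ids)),
              stats::setNames(rep("normal", length(nrm_ids)), nrm_ids))

  ## ---- CL1/CL2, drivers, onset subgroup, methylation latent -----------
  ncl2 <- round(cfg$cl2_fraction * cfg$n_apc_neg)
  cl2_ids <- sort(sample(neg_ids, ncl2))
  cluster <- stats::setNames(
    ifelse(neg_ids %in% cl2_ids, "CL2", "CL1"), neg_ids)

  n_fus <- round(cfg$fusion_fraction * cfg$n_apc_neg)
  n_rnf <- round(cfg$rnf43_mut_fraction * cfg$n_apc_neg)
  n_brf <- round(cfg$braf_fraction * cfg$n_apc_neg)
  if (n_fus + n_rnf + n_brf > ncl2)
    stop2("driver fractions exceed the CL2 cluster size")
  pool <- sample(cl2_ids)          # without replacement: never co-occur
  drivers <- stats::setNames(rep("none", cfg$n_apc_neg), neg_ids)
  drivers[pool[seq_len(n_fus)]] <- "fusion"
  drivers[pool[n_fus + seq_len(n_rnf)]] <- "rnf43_mut"
  drivers[pool[n_fus + n_rnf + seq_len(n_brf)]] <- "braf_mut"

  onset_high <- stats::setNames(rep(FALSE, cfg$n_apc_neg), neg_ids)
  onset_high[sample(neg_ids, floor(cfg$n_apc_neg / 2))] <- TRUE

  u_axin2 <- stats::setNames(stats::runif(ncl2), cl2_ids)

  ## ---- clinical --------------------------------------------------------
  age <- stats::setNames(numeric(length(all_ids)), all_ids)
  age[neg_ids] <- cfg$mean_age_neg +
    ifelse(onset_high[neg_ids], -1, 1) * cfg$onset_age_shift / 2 +
    stats::rnorm(length(neg_ids), 0, cfg$age_sd)
  others <- setdiff(all_ids, neg_ids)
  age[others] <- stats::rnorm(length(others), cfg$mean_age_pos, cfg$age_sd)
  age <- pmax(25, round(age, 1))

  n_all <- length(all_ids)
  clinical <- data.frame(
    sample_id = all_ids,
    age_at_diagnosis = unname(age),
    sex = sample(c("male", "female"), n_all, TRUE),
    race = sample(c("white", "black", "asian", "other"), n_all, TRUE,
                  prob = c(0.82, 0.11, 0.04, 0.03)),
    stage = sample(c("I", "II", "III", "IV"), n_all, TRUE,
                   prob = c(0.16, 0.32, 0.33, 0.19)),
    msi_status = "MSS",
    cimp = sample(c("CIMP-0", "CIMP-low", "CIMP-high"), n_all, TRUE,
                  prob = c(0.68, 0.22, 0.10)),
    tissue = ifelse(all_ids %in% nrm_ids, "normal", "tumor"),
    stringsAsFactors = FALSE)
  clinical$msi_status[clinical$sample_id %in% msih_ids] <- "MSI-H"
  clinical$stage[clinical$tissue == "normal"] <- "unknown"
  clinical$cimp[clinical$tissue == "normal"] <- "unknown"

  ## ---- gene universe ---------------------------------------------------
  special <- c("APC", "CTNNB1", "RNF43", "RSPO3", "ZNRF3", "AXIN2",
               "BRAF", "AP2M1", "PTPRK")
  oxphos_genes <- sprintf("OXP%03d", seq_len(cfg$n_oxphos))
  sig <- generate_signature_matrix(seed = cfg$seed + 1000)
  marker_genes <- rownames(sig)
  n_named <- length(special) + length(WNT_LIGANDS) + length(oxphos_genes) +
    length(marker_genes)
  if (cfg$n_genes < n_named + 50)
    stop2("n_genes too small for the named gene modules")
  filler <- sprintf("G%05d", seq_len(cfg$n_genes - n_named))
  genes <- c(special, WNT_LIGANDS, oxphos_genes, marker_genes, filler)

  base <- stats::setNames(stats::runif(length(genes), 2, 9), genes)
  base[special] <- c(APC = 6, CTNNB1 = 7, RNF43 = 6.5, RSPO3 = 5,
                     ZNRF3 = 6, AXIN2 = 6, BRAF = 6, AP2M1 = 6,
                     PTPRK = 5)[special]
  base[WNT_LIGANDS] <- stats::runif(length(WNT_LIGANDS), 3, 6)
  base[oxphos_genes] <- stats::runif(length(oxphos_genes), 5, 7)
  base[marker_genes] <- 3   # immune contribution added separately

  ## ---- expression deltas (log2 scale) ----------------------------------
  delta <- matrix(0, length(genes), n_all, dimnames = list(genes, all_ids))
  fus_ids <- names(drivers)[drivers == "fusion"]
  cl1_ids <- names(cluster)[cluster == "CL1"]
  # graded RNF43 decrease: CL2 carries 1.5x the group-mean shift, CL1 the
  # remainder, so the APCmut- mean log2FC equals rnf43_log2fc exactly
  f_cl2 <- if (cfg$n_apc_neg > 0) ncl2 / cfg$n_apc_neg else 0
  mult_cl2 <- if (f_cl2 >= 2 / 3) 1 / max(f_cl2, 1e-9) else 1.5
  mult_cl1 <- if (f_cl2 < 1) (1 - f_cl2 * mult_cl2) / (1 - f_cl2) else 0
  u_centered <- u_axin2 - mean(u_axin2)   # mean-zero anti-correlation term
  delta["RNF43", cl2_ids] <- cfg$rnf43_log2fc * mult_cl2 -
    cfg$rnf43_axin2_coupling * u_centered[cl2_ids]
  delta["RNF43", cl1_ids] <- cfg$rnf43_log2fc * mult_cl1
  delta["RSPO3", cl2_ids] <- cfg$rspo3_log2fc
  delta["RSPO3", fus_ids] <- cfg$rspo3_log2fc_fusion
  delta[WNT_LIGANDS, fus_ids] <- -1          # fusions: lowest WNT ligands
  delta["AXIN2", cl2_ids] <- -0.6 * u_axin2[cl2_ids]
  delta[oxphos_genes, cl1_ids] <- cfg$oxphos_log2fc
  delta["AP2M1", names(onset_high)[onset_high]] <- cfg$onset_log2fc

  ## ---- immune fractions ------------------------------------------------
  tau <- stats::setNames(rep(0.35, n_all), all_ids)
  tau[cl1_ids] <- 0.42
  tau[cl2_ids] <- 0.55
  tau[fus_ids] <- 0.42
  tau <- tau * stats::rlnorm(n_all, 0, 0.2)
  dir_raw <- matrix(stats::rgamma(length(IMMUNE_TYPES) * n_all, 1.2),
                    length(IMMUNE_TYPES), n_all,
                    dimnames = list(IMMUNE_TYPES, all_ids))
  fractions <- sweep(dir_raw, 2, colSums(dir_raw), "/")
  fractions <- sweep(fractions, 2, tau, "*")

  ## ---- counts: non-marker genes first ----------------------------------
  libsize <- stats::rlnorm(n_all, log(1.5e6), 0.25)
  denom <- sum(2^base)
  nonmarker <- setdiff(genes, marker_genes)
  r_nm <- 2^(base[nonmarker] + delta[nonmarker, , drop = FALSE])
  mu_nm <- sweep(r_nm, 2, libsize / denom, "*")
  counts_nm <- matrix(
    stats::rnbinom(length(mu_nm), mu = mu_nm, size = 1 / cfg$dispersion),
    nrow(mu_nm), dimnames = dimnames(mu_nm))

  ## ---- couple M2 macrophages to realized RSPO3 -------------------------
  rspo3_log <- log2(counts_nm["RSPO3", ] + 0.5) - log2(libsize) + log2(1e6)
  z <- as.numeric(scale(rspo3_log))
  rho <- cfg$m2_rspo3_correlation
  m2 <- 0.12 + 0.06 * (rho * z + sqrt(max(0, 1 - rho^2)) *
                         stats::rnorm(n_all))
  fractions["Macrophages_M2", ] <- pmax(0.005, m2)

  ## ---- counts: marker genes from signature x fractions ----------------
  r_mk <- 2^base[marker_genes] + 32 * (sig %*% fractions)
  mu_mk <- sweep(r_mk, 2, libsize / denom, "*")
  counts_mk <- matrix(
    stats::rnbinom(length(mu_mk), mu = mu_mk, size = 1 / cfg$dispersion),
    nrow(mu_mk), dimnames = dimnames(mu_mk))
  counts <- rbind(counts_nm, counts_mk)[genes, , drop = FALSE]

  ## ---- mutations / cna / fusions ---------------------------------------
  mut <- list()
  npos <- length(pos_ids)
  apc_driver <- sample(c("apc_mut", "apc_del", "ctnnb1_mut"), npos, TRUE,
                       prob = c(0.85, 0.08, 0.07))
  mut$apc <- data.frame(
    sample_id = pos_ids[apc_driver == "apc_mut"], gene = "APC",
    variant_class = sample(c("nonsense", "frameshift"),
                           sum(apc_driver == "apc_mut"), TRUE),
    protein_change = "T1556fs", stringsAsFactors = FALSE)
  mut$ctnnb1 <- data.frame(
    sample_id = pos_ids[apc_driver == "ctnnb1_mut"], gene = "CTNNB1",
    variant_class = "missense", protein_change = "S45F",
    stringsAsFactors = FALSE)
  rnf_ids <- names(drivers)[drivers == "rnf43_mut"]
  mut$rnf43 <- data.frame(
    sample_id = rnf_ids, gene = "RNF43", variant_class = "nonsense",
    protein_change = "R117*", stringsAsFactors = FALSE)
  brf_ids <- names(drivers)[drivers == "braf_mut"]
  mut$braf <- data.frame(
    sample_id = brf_ids, gene = "BRAF", variant_class = "missense",
    protein_change = "V600E", stringsAsFactors = FALSE)

  bg_pool <- filler
  bg_n <- stats::rpois(length(tumor_ids), 40)
  bg_n[tumor_ids %in% hyp_ids] <- 900   # ~765 non-silent: above threshold
  mut$background <- data.frame(
    sample_id = rep(tumor_ids, bg_n),
    gene = sample(bg_pool, sum(bg_n), TRUE),
    variant_class = sample(c("missense", "nonsense", "silent"),
                           sum(bg_n), TRUE, prob = c(0.72, 0.13, 0.15)),
    protein_change = sprintf("A%d%s", sample(20:900, sum(bg_n), TRUE),
                             sample(LETTERS, sum(bg_n), TRUE)),
    stringsAsFactors = FALSE)
  mutations <- do.call(rbind, mut)
  mutations <- mutations[!duplicated(mutations[c("sample_id", "gene",
                                                 "protein_change")]), ]
  rownames(mutations) <- NULL

  cna <- data.frame(
    sample_id = pos_ids[apc_driver == "apc_del"], gene = "APC",
    call = "deep_deletion", stringsAsFactors = FALSE)
  n_bg_cna <- round(0.1 * length(tumor_ids))
  cna <- rbind(cna, data.frame(
    sample_id = sample(tumor_ids, n_bg_cna, TRUE),
    gene = sample(filler, n_bg_cna, TRUE),
    call = sample(c("amplification", "deep_deletion"), n_bg_cna, TRUE),
    stringsAsFactors = FALSE))
  cna <- cna[!duplicated(cna[c("sample_id", "gene")]), ]
  rownames(cna) <- NULL

  fusions <- data.frame(sample_id = fus_ids, gene5 = "PTPRK",
                        gene3 = "RSPO3", stringsAsFactors = FALSE)

  ## ---- methylation -----------------------------------------------------
  meth <- simulate_methylation(cfg, all_ids, cl2_ids, u_axin2, neg_ids,
                               filler)

  cohort <- new_cohort(clinical, mutations, cna, fusions, counts,
                       meth$betas, meth$anno)

  truth <- list(labels = labels, cluster = cluster, drivers = drivers,
                onset_high = onset_high, onset_gene = "AP2M1",
                u_axin2 = u_axin2, oxphos_genes = oxphos_genes,
                wnt_ligands = WNT_LIGANDS, signature = sig,
                fractions = fractions, tau = tau,
                dmrs = meth$planted, gene_universe = genes,
                config = cfg)
  list(cohort = cohort, truth = truth)
}

# Probe annotation + beta matrix with planted DMRs. Null probes are spaced
# 1500-4000 bp apart (so chance runs of significant probes rarely merge);
# planted regions are runs at 150 bp spacing flanked by normal gaps.
simulate_methylation <- function(cfg, all_ids, cl2_ids, u_axin2, neg_ids,
                                 filler) {
  if (cfg$n_probes < 400) stop2("n_probes too small for planted regions")
  n_chrom <- 20
  per_chrom <- ceiling(cfg$n_probes / n_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = per_chrom))[
    seq_len(cfg$n_probes)]
  gaps <- sample(1500:4000, cfg$n_probes, TRUE)

  # planted regions: index runs, non-overlapping, within one chromosome
  planted <- data.frame(
    gene = c("AXIN2", sprintf("HYPPRO%02d", 1:12), sprintf("HYPBOD%02d", 1:3),
             sprintf("HYPO%02d", 1:4)),
    direction = c(rep("hyper", 16), rep("hypo", 4)),
    region = c(rep("promoter", 13), rep("body", 7)),
    n_probes = c(8, rep(5, 19)),
    stringsAsFactors = FALSE)
  chrom_of <- function(i) chrom[i]
  starts <- integer(0); taken <- integer(0)
  for (k in seq_len(nrow(planted))) {
    repeat {
      s <- sample(cfg$n_probes - 10, 1)
      idx <- s:(s + planted$n_probes[k] - 1)
      if (chrom_of(s) == chrom_of(max(idx)) &&
          !any(c(idx, idx + 1, idx - 1) %in% taken)) break
    }
    starts[k] <- s
    taken <- c(taken, (s - 1):(max(idx) + 1))
  }
  planted$start_idx <- starts
  for (k in seq_len(nrow(planted))) {
    run <- planted$start_idx[k] + seq_len(planted$n_probes[k] - 1)
    gaps[run] <- 150
  }
  pos <- unlist(lapply(split(gaps, chrom)[unique(chrom)], cumsum),
                use.names = FALSE) + 10000L
  probe_id <- sprintf("P%05d", seq_len(cfg$n_probes))

  gene_anno <- sample(c(filler, "."), cfg$n_probes, TRUE)
  region_anno <- sample(c("promoter", "body", "intergenic"),
                        cfg$n_probes, TRUE, prob = c(0.3, 0.45, 0.25))
  region_anno[gene_anno == "."] <- "intergenic"
  base_beta <- stats::runif(cfg$n_probes, 0.15, 0.85)

  probe_sets <- vector("list", nrow(planted))
  for (k in seq_len(nrow(planted))) {
    idx <- planted$start_idx[k] + seq_len(planted$n_probes[k]) - 1
    probe_sets[[k]] <- probe_id[idx]
    gene_anno[idx] <- planted$gene[k]
    region_anno[idx] <- planted$region[k]
    base_beta[idx] <- if (planted$direction[k] == "hyper")
      stats::runif(length(idx), 0.15, 0.3) else
      stats::runif(length(idx), 0.6, 0.8)
  }
  planted$probe_ids <- probe_sets
  planted$chrom <- chrom[planted$start_idx]
  planted$start <- pos[planted$start_idx]
  planted$end <- pos[planted$start_idx + planted$n_probes - 1] + 1

  # per-probe, per-sample mean beta
  m <- matrix(base_beta, cfg$n_probes, length(all_ids),
              dimnames = list(probe_id, all_ids))
  for (k in seq_len(nrow(planted))) {
    idx <- match(planted$probe_ids[[k]], probe_id)
    if (planted$gene[k] == "AXIN2") {
      m[idx, cl2_ids] <- m[idx, cl2_ids] +
        rep(cfg$axin2_delta_beta * u_axin2[cl2_ids], each = length(idx))
    } else {
      hit <- sample(neg_ids, round(0.6 * length(neg_ids)))
      shift <- if (planted$direction[k] == "hyper") 0.1 else -0.1
      m[idx, hit] <- m[idx, hit] + shift
    }
  }
  m <- pmin(pmax(m, 0.02), 0.98)
  phi <- 60
  betas <- matrix(stats::rbeta(length(m), m * phi, (1 - m) * phi),
                  nrow(m), dimnames = dimnames(m))

  anno <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                     gene = gene_anno, region = region_anno,
                     stringsAsFactors = FALSE)
  list(betas = betas, anno = anno,
       planted = planted[c("chrom", "start", "end", "gene", "direction",
                           "region", "probe_ids")])
}

#' Generate a cell-type signature matrix
#'
#' Block-structured non-negative genes x cell-types matrix: each type has
#' `markers_per_type` disjoint marker genes with high expression in its
#' own column and near-zero elsewhere, so the matrix is full column rank.
#'
#' @param n_cell_types Number of cell types (default 22 immune types).
#' @param markers_per_type Marker genes per type.
#' @param seed Integer seed.
#' @return Numeric matrix, (n_cell_types * markers_per_type) x
#'   n_cell_types, with marker gene rownames.
#' @export
generate_signature_matrix <- function(n_cell_types = 22,
                                      markers_per_type = 5, seed = 1) {
  stopifnot(markers_per_type >= 1, n_cell_types >= 1)
  set.seed(seed)
  types <- if (n_cell_types == length(IMMUNE_TYPES)) IMMUNE_TYPES else
    sprintf("celltype%02d", seq_len(n_cell_types))
  genes <- as.vector(vapply(types, function(t)
    sprintf("MRK_%s_%d", t, seq_len(markers_per_type)),
    character(markers_per_type)))
  sig <- matrix(stats::runif(length(genes) * n_cell_types, 0, 2),
                length(genes), n_cell_types,
                dimnames = list(genes, types))
  for (j in seq_len(n_cell_types)) {
    own <- (j - 1) * markers_per_type + seq_len(markers_per_type)
    sig[own, j] <- stats::runif(markers_per_type, 80, 120)
  }
  sig
}

#' Generate gene sets around a planted module
#'
#' Returns the planted oxidative-phosphorylation module as one set plus
#' random decoy sets drawn without replacement from the gene universe.
#'
#' @param truth Truth record from [generate_cohort()].
#' @param n_decoy_sets Number of decoy sets.
#' @param size_range Integer range of decoy set sizes.
#' @param seed Integer seed.
#' @return Named list of gene sets (GMT-compatible, see [write_gmt()]).
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 30,
                               size_range = c(15, 100), seed = 1) {
  set.seed(seed)
  pool <- setdiff(truth$gene_universe, truth$oxphos_genes)
  sizes <- sample(size_range[1]:size_range[2], n_decoy_sets, TRUE)
  decoys <- lapply(sizes, function(s) sample(pool, s))
  names(decoys) <- sprintf("DECOY_%03d", seq_len(n_decoy_sets))
  c(list(OXPHOS_MODULE = truth$oxphos_genes), decoys)
}
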