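# Cohort container: clinical, mutation, copy-number, fusion, counts and
# methylation tables sharing one sample-ID namespace. All genomic
# coordinates are 0-based half-open; missing clinical values use the
# literal token "NA".

CLINICAL_COLS <- c("sample_id", "age_at_diagnosis", "sex", "race", "stage",
                   "msi_status", "cimp", "tissue")
MUTATION_COLS <- c("sample_id", "gene", "variant_class", "protein_change")
CNA_COLS      <- c("sample_id", "gene", "call")
FUSION_COLS   <- c("sample_id", "gene5", "gene3")
PROBE_ANNO_COLS <- c("probe_id", "chrom", "pos", "gene", "region")

CNA_CALLS <- c("deep_deletion", "amplification", "neutral")

#' Variant classes counted as non-silent
#'
#' Default set of somatic variant classes treated as protein-altering when
#' classifying samples and building the alteration matrix.
#'
#' @return Character vector of variant class names.
#' @export
nonsilent_classes <- function() {
  c("missense", "nonsense", "frameshift", "splice",
    "in_frame_indel", "translation_start")
}

#' Assemble and validate a cohort
#'
#' Bundles the component tables into a validated `crc_cohort` object.
#' Rows in the mutation, copy-number, fusion, counts or beta tables that
#' reference sample IDs absent from the clinical table are dropped with a
#' warning reporting the count.
#'
#' @param clinical data.frame with columns sample_id, age_at_diagnosis,
#'   sex, race, stage, msi_status, cimp, tissue.
#' @param mutations data.frame with sample_id, gene, variant_class,
#'   protein_change.
#' @param cna data.frame with sample_id, gene, call (one of
#'   deep_deletion / amplification / neutral).
#' @param fusions data.frame with sample_id, gene5, gene3.
#' @param counts integer matrix, genes x samples, rownames = gene symbols.
#' @param betas optional numeric matrix in \[0,1\], probes x samples.
#' @param probe_anno optional data.frame probe_id, chrom, pos (0-based),
#'   gene, region; required when `betas` is given; sorted by (chrom, pos).
#' @return A `crc_cohort` list with the validated components and an empty
#'   `labels` slot (filled by [classify_samples()]).
#' @export
new_cohort <- function(clinical, mutations, cna, fusions, counts,
                       betas = NULL, probe_anno = NULL) {
  check_columns(clinical, CLINICAL_COLS, "clinical")
  check_columns(mutations, MUTATION_COLS, "mutations")
  check_columns(cna, CNA_COLS, "cna")
  check_columns(fusions, FUSION_COLS, "fusions")
  if (anyDuplicated(clinical$sample_id))
    stop2("clinical: duplicated sample_id")
  ok_age <- is.na(clinical$age_at_diagnosis) | clinical$age_at_diagnosis > 0
  if (!all(ok_age)) stop2("clinical: age_at_diagnosis must be > 0")
  bad_call <- setdiff(unique(cna$call), CNA_CALLS)
  if (length(bad_call))
    stop2("cna: unknown call value(s): ", paste(bad_call, collapse = ", "))
  if (any(fusions$gene5 == fusions$gene3))
    stop2("fusions: gene5 must differ from gene3")
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts)))
    stop2("counts must be a matrix with gene rownames and sample colnames")
  if (any(counts < 0)) stop2("counts: negative entries")
  if (any(colSums(counts) == 0)) stop2("counts: zero library size column")

  ids <- clinical$sample_id
  mutations <- drop_unknown(mutations, ids, "mutations")
  cna <- drop_unknown(cna, ids, "cna")
  fusions <- drop_unknown(fusions, ids, "fusions")
  extra <- setdiff(colnames(counts), ids)
  if (length(extra)) {
    warning(sprintf("counts: dropping %d column(s) with unknown sample_id",
                    length(extra)), call. = FALSE)
    counts <- counts[, setdiff(colnames(counts), extra), drop = FALSE]
  }

  if (!is.null(betas)) {
    if (is.null(probe_anno)) stop2("betas supplied without probe_anno")
    check_columns(probe_anno, PROBE_ANNO_COLS, "probe_anno")
    if (any(betas < 0 | betas > 1))
      stop2("betas: values outside [0, 1]")
    if (!setequal(rownames(betas), probe_anno$probe_id))
      stop2("betas rownames must match probe_anno probe_id")
    ord <- order(probe_anno$chrom, probe_anno$pos)
    probe_anno <- probe_anno[ord, , drop = FALSE]
    rownames(probe_anno) <- NULL
    betas <- betas[probe_anno$probe_id, , drop = FALSE]
    extra_b <- setdiff(colnames(betas), ids)
    if (length(extra_b)) {
      warning(sprintf("betas: dropping %d column(s) with unknown sample_id",
                      length(extra_b)), call. = FALSE)
      betas <- betas[, setdiff(colnames(betas), extra_b), drop = FALSE]
    }
  }

  structure(list(clinical = clinical, mutations = mutations, cna = cna,
                 fusions = fusions, counts = counts, betas = betas,
                 probe_anno = probe_anno, labels = NULL),
            class = "crc_cohort")
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop2(what, ": expected a data.frame")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop2(what, ": missing column(s): ", paste(missing, collapse = ", "))
}

drop_unknown <- function(df, ids, what) {
  bad <- !(df$sample_id %in% ids)
  if (any(bad)) {
    warning(sprintf("%s: dropping %d row(s) with unknown sample_id",
                    what, sum(bad)), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' @export
print.crc_cohort <- function(x, ...) {
  cat("crc_cohort:", nrow(x$clinical), "samples\n")
  cat("  tumors:", sum(x$clinical$tissue == "tumor"),
      " normals:", sum(x$clinical$tissue == "normal"), "\n")
  cat("  mutations:", nrow(x$mutations), "rows;",
      "cna:", nrow(x$cna), "rows;",
      "fusions:", nrow(x$fusions), "rows\n")
  cat("  counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  if (!is.null(x$betas))
    cat("  betas:", nrow(x$betas), "probes x", ncol(x$betas), "samples\n")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Read a cohort from a directory of TSV files
#'
#' Expects the file layout produced by [write_cohort()]: clinical.tsv,
#' mutations.tsv, cna.tsv, fusions.tsv, counts.tsv, and optionally
#' betas.tsv + probe_anno.tsv. Validation is as in [new_cohort()].
#'
#' @param dir Directory containing the cohort TSVs.
#' @return A validated `crc_cohort`.
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  need <- c("clinical.tsv", "mutations.tsv", "cna.tsv", "fusions.tsv",
            "counts.tsv")
  for (f in need) if (!file.exists(path(f))) stop2("missing file: ", path(f))
  clinical <- read_tsv(path("clinical.tsv"))
  clinical$age_at_diagnosis <- as.numeric(clinical$age_at_diagnosis)
  counts <- read_matrix(path("counts.tsv"))
  storage.mode(counts) <- "double"
  betas <- probe_anno <- NULL
  if (file.exists(path("betas.tsv"))) {
    betas <- read_matrix(path("betas.tsv"))
    probe_anno <- read_tsv(path("probe_anno.tsv"))
    probe_anno$pos <- as.integer(probe_anno$pos)
  }
  new_cohort(clinical,
             read_tsv(path("mutations.tsv")),
             read_tsv(path("cna.tsv")),
             read_tsv(path("fusions.tsv")),
             counts, betas, probe_anno)
}

#' Write a cohort to a directory of TSV files
#'
#' @param cohort A `crc_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  write_tsv(cohort$clinical[CLINICAL_COLS], path("clinical.tsv"))
  write_tsv(cohort$mutations[MUTATION_COLS], path("mutations.tsv"))
  write_tsv(cohort$cna[CNA_COLS], path("cna.tsv"))
  write_tsv(cohort$fusions[FUSION_COLS], path("fusions.tsv"))
  write_matrix(cohort$counts, path("counts.tsv"), "gene")
  if (!is.null(cohort$betas)) {
    write_matrix(cohort$betas, path("betas.tsv"), "probe_id")
    write_tsv(cohort$probe_anno[PROBE_ANNO_COLS], path("probe_anno.tsv"))
  }
  if (!is.null(cohort$labels))
    write_tsv(data.frame(sample_id = names(cohort$labels),
                         label = unname(cohort$labels)),
              path("labels.tsv"))
  invisible(dir)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

read_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop2("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write DMRs as TSV and BED
#'
#' The BED file is 0-based half-open with columns
#' (chrom, start, end, name, score); name is the annotated gene, score is
#' `-log10(min_p)` capped at 1000.
#'
#' @param dmrs data.frame as returned by [call_dmrs()].
#' @param path_tsv,path_bed Output paths (either may be NULL to skip).
#' @export
write_dmrs <- function(dmrs, path_tsv = NULL, path_bed = NULL) {
  if (!is.null(path_tsv)) {
    out <- dmrs
    out$probe_ids <- vapply(dmrs$probe_ids, paste, "", collapse = ",")
    write_tsv(out, path_tsv)
  }
  if (!is.null(path_bed)) {
    score <- pmin(1000, round(-log10(pmax(dmrs$min_p, 1e-300)), 2))
    bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                      end = dmrs$end, name = dmrs$gene, score = score)
    utils::write.table(bed, path_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Read DMRs written by [write_dmrs()]
#'
#' @param path_tsv TSV path produced by [write_dmrs()].
#' @return data.frame with the [call_dmrs()] schema (probe_ids as a list
#'   column).
#' @export
read_dmrs <- function(path_tsv) {
  df <- read_tsv(path_tsv)
  df$probe_ids <- strsplit(df$probe_ids, ",", fixed = TRUE)
  df
}
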