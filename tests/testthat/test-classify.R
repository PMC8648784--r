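mini_cohort <- function(mutations, cna = NULL, msi = "MSS", n = NULL) {
  ids <- unique(c(mutations$sample_id, if (!is.null(cna)) cna$sample_id,
                  "S_filler"))
  if (!is.null(n)) ids <- unique(c(ids, sprintf("S%02d", seq_len(n))))
  clinical <- data.frame(
    sample_id = ids, age_at_diagnosis = 60, sex = "female",
    race = "white", stage = "II",
    msi_status = if (length(msi) == 1) msi else msi[match(ids, names(msi))],
    cimp = "CIMP-0", tissue = "tumor", stringsAsFactors = FALSE)
  counts <- matrix(10L, 5, length(ids),
                   dimnames = list(paste0("g", 1:5), ids))
  suppressWarnings(new_cohort(
    clinical, mutations,
    cna %||% data.frame(sample_id = character(), gene = character(),
                        call = character()),
    data.frame(sample_id = character(), gene5 = character(),
               gene3 = character()),
    counts))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("APC/CTNNB1 rule labels samples as intended", {
  mut <- data.frame(
    sample_id = c("S_apc", "S_silent", "S_ctnnb1", "S_neg"),
    gene = c("APC", "APC", "CTNNB1", "TP53"),
    variant_class = c("nonsense", "silent", "missense", "missense"),
    protein_change = c("R213*", "L100L", "S45F", "R175H"),
    stringsAsFactors = FALSE)
  cna <- data.frame(sample_id = "S_del", gene = "APC",
                    call = "deep_deletion", stringsAsFactors = FALSE)
  co <- classify_samples(mini_cohort(mut, cna))
  expect_equal(unname(co$labels["S_apc"]), "APCmut_pos")
  expect_equal(unname(co$labels["S_ctnnb1"]), "APCmut_pos")
  expect_equal(unname(co$labels["S_del"]), "APCmut_pos")
  expect_equal(unname(co$labels["S_silent"]), "APCmut_neg")  # silent only
  expect_equal(unname(co$labels["S_neg"]), "APCmut_neg")
})

test_that("hypermutation and MSI-H filters exclude with logged reasons", {
  hyper <- data.frame(
    sample_id = rep("S_hyper", 701),
    gene = sprintf("g%04d", 1:701), variant_class = "missense",
    protein_change = sprintf("A%dV", 1:701), stringsAsFactors = FALSE)
  ok <- data.frame(sample_id = "S_ok", gene = "TP53",
                   variant_class = "missense", protein_change = "R175H",
                   stringsAsFactors = FALSE)
  co <- classify_samples(mini_cohort(rbind(hyper, ok),
                                     msi = c(S_hyper = "MSS", S_ok = "MSS",
                                             S_filler = "MSI-H")))
  expect_equal(unname(co$labels["S_hyper"]), "excluded")
  expect_equal(unname(co$labels["S_filler"]), "excluded")
  expect_equal(unname(co$labels["S_ok"]), "APCmut_neg")
  expect_setequal(co$exclusions$reason, c("hypermutated", "MSI-H"))
  # 700 exactly is retained (threshold is strict)
  co700 <- classify_samples(mini_cohort(rbind(hyper[1:700, ], ok)))
  expect_equal(unname(co700$labels["S_hyper"]), "APCmut_neg")
})

test_that("unknown MSI status retains with warning, excludes in strict mode", {
  mut <- data.frame(sample_id = "S_unk", gene = "TP53",
                    variant_class = "missense", protein_change = "R175H",
                    stringsAsFactors = FALSE)
  cohort <- mini_cohort(mut, msi = c(S_unk = "unknown", S_filler = "MSS"))
  expect_warning(co <- classify_samples(cohort), "unknown MSI")
  expect_equal(unname(co$labels["S_unk"]), "APCmut_neg")
  strict <- classify_samples(cohort, classify_config(strict_msi = TRUE))
  expect_equal(unname(strict$labels["S_unk"]), "excluded")
})

test_that("classification partitions tumors and is monotone in threshold", {
  sim <- generate_cohort(small_config(seed = 21, n_msih = 3,
                                      n_hypermut = 2))
  co <- classify_samples(sim$cohort)
  tumor_labels <- co$labels[co$clinical$tissue == "tumor"]
  expect_true(all(tumor_labels %in%
                    c("APCmut_neg", "APCmut_pos", "excluded")))
  n_kept <- vapply(c(100, 400, 700, 1000), function(th) {
    l <- classify_samples(sim$cohort,
                          classify_config(hypermutation_threshold = th))$labels
    sum(l %in% c("APCmut_neg", "APCmut_pos"))
  }, numeric(1))
  expect_true(all(diff(n_kept) >= 0))
})

test_that("classifier reproduces generator truth exactly", {
  for (sim in list(small_sim(),
                   generate_cohort(small_config(seed = 4, n_msih = 2,
                                                n_hypermut = 2)))) {
    co <- classify_samples(sim$cohort)
    expect_identical(co$labels[names(sim$truth$labels)], sim$truth$labels)
  }
})

test_that("group counting reproduces the study's fraction arithmetic", {
  labels <- c(rep("APCmut_neg", 63), rep("APCmut_pos", 362),
              rep("normal", 12))
  names(labels) <- sprintf("s%03d", seq_along(labels))
  gc <- count_groups(labels)
  expect_equal(gc$n_neg, 63)
  expect_equal(round(100 * gc$fraction_neg), 15)  # 63 of 425
  empty <- c(a = "excluded", b = "excluded")
  expect_warning(gc2 <- count_groups(empty), "undefined")
  expect_true(is.na(gc2$fraction_neg))
})
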