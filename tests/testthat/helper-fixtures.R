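# Shared fixtures. The small cohort keeps unit tests fast; the default
# cohort (full study-scale conditions) is generated once per run and
# shared by the recovery tests.

small_config <- function(seed = 11, ...) {
  cohort_config(n_apc_neg = 24, n_apc_pos = 60, n_normal = 6,
                n_genes = 400, n_probes = 1200, seed = seed, ...)
}

.fixture_env <- new.env()

small_sim <- function() {
  if (is.null(.fixture_env$small)) .fixture_env$small <-
      generate_cohort(small_config())
  .fixture_env$small
}

default_sim <- function() {
  if (is.null(.fixture_env$default)) .fixture_env$default <-
      generate_cohort(cohort_config())
  .fixture_env$default
}

default_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    sim <- default_sim()
    gs <- generate_gene_sets(sim$truth, n_decoy_sets = 20, seed = 1)
    .fixture_env$pipeline <- run_pipeline(
      sim$cohort,
      pipeline_config(gsea_n_perm = 2000, me_n_perm = 2000, seed = 1),
      gene_sets = gs, signature = sim$truth$signature)
  }
  .fixture_env$pipeline
}
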