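# Shared small simulation, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(...) {
  sim_config(n_chromosome_pairs = 2, n_loci_per_chromosome = 30,
             n_tissues = 3, meth_sites_per_chrom = 1500,
             n_metabolites = 120, n_dam_up = 30, n_dam_down = 20,
             seed = 42L, ...)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- small_config()
    genome <- generate_haplotype_pair(cfg)
    ex <- simulate_expression(cfg, genome)
    .fixture_env$sim <- list(cfg = cfg, genome = genome, expr = ex$expr,
                             truth = ex$truth)
  }
  .fixture_env$sim
}

# dominance calls for the small simulation (TPM -> bias -> aggregate)
small_dominance <- function() {
  if (is.null(.fixture_env$dom)) {
    s <- small_sim()
    tpm <- normalize_expression(s$expr, "TPM")
    calls <- classify_all_tissues(s$truth$allele_map, tpm)
    .fixture_env$dom <- aggregate_asegs(calls)
  }
  .fixture_env$dom
}
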