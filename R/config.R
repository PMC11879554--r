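#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror the
#' reference conditions the pipeline was designed around: allelic CDS identity of
#' 96.35% on average, four allelic-bias categories with most loci unbiased,
#' nine tissues with three replicates, nine histone marks binned at 200 bp,
#' and context-specific methylation levels near 81% (CG), 54% (CHG) and
#' 10% (CHH).
#'
#' @param n_chromosome_pairs number of homologous chromosome pairs
#' @param n_loci_per_chromosome loci simulated per chromosome
#' @param allelic_fraction fraction of loci with a gene on both haplotypes
#' @param target_cds_identity expected pairwise CDS identity of allele pairs
#' @param bias_fractions named proportions over the four planted bias
#'   categories \code{no_bias}, \code{smaller}, \code{larger}, \code{largest};
#'   must sum to 1
#' @param n_tissues,n_replicates expression design dimensions
#' @param base_mean negative-binomial base mean for an expressed allele
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2)
#' @param mark_names histone marks to simulate
#' @param hmm_truth a \code{chromatin_state_model} used as generating chain
#'   for background chromatin; \code{NULL} uses a built-in 4-state model
#' @param bin_width ChIP bin width in bp (fixed at 200 by the downstream
#'   chromatin-state contract)
#' @param lambda_bg background Poisson mean per bin
#' @param mark_enrichment fold elevation of the Poisson mean in mark-positive
#'   bins (and in dominant-allele gene bodies for the active marks)
#' @param methylation_beta_params named list \code{CG}, \code{CHG}, \code{CHH}
#'   of Beta shape pairs \code{c(a, b)} for per-site methylation levels
#' @param meth_sites_per_chrom cytosines simulated per chromosome
#' @param meth_coverage_mu,meth_zero_fraction coverage model: coverage is
#'   1 + NB(mu) for covered sites; a configurable fraction has zero coverage
#' @param n_metabolites,n_dam_up,n_dam_down metabolome design; defaults echo
#'   a 683-compound panel with 423 up and 260 down
#' @param metabolite_effect planted |log2 fold change| for DAMs
#' @param metabolite_noise_sd replicate noise SD on the log2 scale
#' @param exon_lengths,intron_length,utr5_length,utr3_length fixed 3-exon gene
#'   architecture (bp); CDS length must come out a multiple of 3
#' @param intergenic_bp spacing between consecutive genes
#' @param ns_acceptance probability that a proposed nonsynonymous substitution
#'   is retained when diverging allele CDSs (purifying-selection analogue)
#' @param seed master seed; fully determines all outputs
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_chromosome_pairs = 2,
                       n_loci_per_chromosome = 50,
                       allelic_fraction = 0.8,
                       target_cds_identity = 0.9635,
                       bias_fractions = c(no_bias = 0.90, smaller = 0.03,
                                          larger = 0.04, largest = 0.03),
                       n_tissues = 9,
                       n_replicates = 3,
                       base_mean = 200,
                       nb_dispersion = 0.05,
                       mark_names = c("H3K4me2", "H3K4me3", "H3K9me2",
                                      "H3K27me2", "H3K27me3", "H3K36me2",
                                      "H3K36me3", "H3K9ac", "H3K27ac"),
                       hmm_truth = NULL,
                       bin_width = 200,
                       lambda_bg = 1,
                       mark_enrichment = 8,
                       methylation_beta_params = list(
                         CG  = c(1.6214, 0.3786),
                         CHG = c(1.0846, 0.9154),
                         CHH = c(0.2074, 1.7926)),
                       meth_sites_per_chrom = 2000,
                       meth_coverage_mu = 10,
                       meth_zero_fraction = 0.02,
                       n_metabolites = 683,
                       n_dam_up = 423,
                       n_dam_down = 260,
                       metabolite_effect = 3,
                       metabolite_noise_sd = 0.3,
                       exon_lengths = c(400L, 500L, 600L),
                       intron_length = 200L,
                       utr5_length = 100L,
                       utr3_length = 200L,
                       intergenic_bp = 2000L,
                       ns_acceptance = 0.3,
                       seed = 1L) {
  if (n_chromosome_pairs < 1 || n_loci_per_chromosome < 1)
    stop_config("n_chromosome_pairs and n_loci_per_chromosome must be positive")
  if (allelic_fraction < 0 || allelic_fraction > 1)
    stop_config("allelic_fraction must lie in [0,1]")
  if (target_cds_identity < 0 || target_cds_identity > 1)
    stop_config("target_cds_identity must lie in [0,1]")
  need <- c("no_bias", "smaller", "larger", "largest")
  if (!setequal(names(bias_fractions), need))
    stop_config("bias_fractions must be named %s", paste(need, collapse = ", "))
  bias_fractions <- bias_fractions[need]
  if (abs(sum(bias_fractions) - 1) > 1e-9)
    stop_config("bias_fractions must sum to 1 (got %.12f)", sum(bias_fractions))
  if (nb_dispersion <= 0) stop_config("nb_dispersion must be positive")
  if (bin_width != 200) stop_config("bin_width must be 200")
  if (n_replicates < 2) stop_config("need at least 2 replicates")
  if (!setequal(names(methylation_beta_params), c("CG", "CHG", "CHH")))
    stop_config("methylation_beta_params must have contexts CG, CHG, CHH")
  if (metabolite_effect < 0) stop_config("metabolite_effect must be >= 0")
  cds_len <- sum(exon_lengths) - utr5_length - utr3_length
  if (cds_len <= 0 || cds_len %% 3L != 0L)
    stop_config("exon/UTR lengths must give a positive CDS length divisible by 3")
  if (is.null(hmm_truth)) hmm_truth <- default_hmm_truth(mark_names)

  structure(list(
    n_chromosome_pairs = as.integer(n_chromosome_pairs),
    n_loci_per_chromosome = as.integer(n_loci_per_chromosome),
    allelic_fraction = allelic_fraction,
    target_cds_identity = target_cds_identity,
    bias_fractions = bias_fractions,
    n_tissues = as.integer(n_tissues),
    n_replicates = as.integer(n_replicates),
    base_mean = base_mean,
    nb_dispersion = nb_dispersion,
    mark_names = mark_names,
    hmm_truth = hmm_truth,
    bin_width = as.integer(bin_width),
    lambda_bg = lambda_bg,
    mark_enrichment = mark_enrichment,
    methylation_beta_params = methylation_beta_params,
    meth_sites_per_chrom = as.integer(meth_sites_per_chrom),
    meth_coverage_mu = meth_coverage_mu,
    meth_zero_fraction = meth_zero_fraction,
    n_metabolites = as.integer(n_metabolites),
    n_dam_up = as.integer(n_dam_up),
    n_dam_down = as.integer(n_dam_down),
    metabolite_effect = metabolite_effect,
    metabolite_noise_sd = metabolite_noise_sd,
    exon_lengths = as.integer(exon_lengths),
    intron_length = as.integer(intron_length),
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    intergenic_bp = as.integer(intergenic_bp),
    ns_acceptance = ns_acceptance,
    seed = as.integer(seed)), class = "sim_config")
}

#' Built-in 4-state generating chain for background chromatin
#'
#' States loosely emulate: active chromatin (acetylation + H3K4/H3K36
#' methylation), facultative repression (H3K27me2/3), heterochromatin
#' (H3K9me2), and a quiescent state with no marks.
#'
#' @param mark_names marks the emission matrix must cover
#' @return a \code{chromatin_state_model}
#' @export
default_hmm_truth <- function(mark_names) {
  M <- length(mark_names)
  emission <- matrix(0.02, nrow = 4, ncol = M,
                     dimnames = list(NULL, mark_names))
  active <- intersect(c("H3K4me2", "H3K4me3", "H3K36me2", "H3K36me3",
                        "H3K9ac", "H3K27ac"), mark_names)
  polycomb <- intersect(c("H3K27me2", "H3K27me3"), mark_names)
  hetero <- intersect("H3K9me2", mark_names)
  emission[1, active] <- 0.85
  emission[2, polycomb] <- 0.90
  emission[3, hetero] <- 0.95
  transition <- matrix(0.05 / 3, 4, 4)
  diag(transition) <- 0.95
  chromatin_state_model(emission = emission,
                        transition = transition,
                        initial = rep(0.25, 4))
}
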